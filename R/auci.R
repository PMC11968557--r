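#' Signed area under the 95% confidence interval of the difference
#'
#' The per-gene effect size: at each grid time the band contributes its
#' lower bound where the whole interval sits above zero, its upper bound
#' where the whole interval sits below zero, and nothing where the interval
#' contains zero.  Contributions are integrated over the window by the
#' trapezoidal rule on the band's grid (window endpoints entering by linear
#' interpolation of the bounds).  A gene whose difference CI always covers
#' zero therefore scores exactly 0, and the sign encodes the direction of
#' regulation.
#'
#' `mode = "band_gap"` is an alternative reading that integrates the signed
#' gap between the mean-difference band's bounds and zero without the
#' zero-exclusion rule, i.e. the area between the confidence bounds'
#' midline and zero; retained for comparison, not used for DEG calling.
#'
#' @param band a `difference_band`.
#' @param window numeric `c(start, end)` in hours, inside the band's grid
#'   range; default the full grid.
#' @param mode `"ci_excess"` (default, the effect size used throughout) or
#'   `"band_gap"`.
#' @return signed area in log2-expression x hours.
#' @export
signed_auci <- function(band, window = NULL,
                        mode = c("ci_excess", "band_gap")) {
  mode <- match.arg(mode)
  stopifnot(inherits(band, "difference_band"))
  g <- band$grid
  if (is.null(window)) window <- range(g)
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be c(start, end) with start < end", call. = FALSE)
  if (window[1] < min(g) - 1e-9 || window[2] > max(g) + 1e-9)
    stop("window lies outside the band's grid", call. = FALSE)
  inside <- g > window[1] & g < window[2]
  tt <- c(window[1], g[inside], window[2])
  lo <- stats::approx(g, band$lo95, xout = tt)$y
  hi <- stats::approx(g, band$hi95, xout = tt)$y
  contrib <- switch(mode,
    ci_excess = ifelse(lo > 0, lo, ifelse(hi < 0, hi, 0)),
    band_gap = (lo + hi) / 2)
  trapz(tt, contrib)
}

#' Normalize an AUCI by the window duration
#'
#' @param auci95 signed area from [signed_auci()].
#' @param window numeric `c(start, end)` in hours with positive length.
#' @return AUCI per hour of exposure.
#' @export
auci_per_hour <- function(auci95, window) {
  len <- window[2] - window[1]
  if (!is.finite(len) || len <= 0)
    stop("window must have positive length", call. = FALSE)
  auci95 / len
}

#' Score a difference band over a time window
#'
#' Convenience wrapper combining [signed_auci()], [auci_per_hour()] and the
#' DEG call at the active cutoff.
#'
#' @param band a `difference_band`.
#' @param window `c(start, end)` hours; default the band's full grid.
#' @param cutoff |AUCI95%/h| threshold for the DEG call (default 0.046, the
#'   combined calibrated cutoff).
#' @param window_label optional label stored with the score.
#' @param mode passed to [signed_auci()].
#' @return one-row data.frame: `gene_id`, `level`, `window_label`,
#'   `window_start_h`, `window_end_h`, `auci95`, `auci95_per_hour`,
#'   `is_deg`.
#' @export
effect_score <- function(band, window = NULL, cutoff = 0.046,
                         window_label = NA_character_,
                         mode = "ci_excess") {
  if (is.null(window)) window <- range(band$grid)
  a <- signed_auci(band, window, mode = mode)
  aph <- auci_per_hour(a, window)
  data.frame(gene_id = band$gene_id, level = band$level,
             window_label = window_label,
             window_start_h = window[1], window_end_h = window[2],
             auci95 = a, auci95_per_hour = aph,
             is_deg = abs(aph) >= cutoff,
             stringsAsFactors = FALSE)
}

#' Set DEG flags on a score table
#'
#' A gene x level x window entry is a DEG when
#' `|auci95_per_hour| >= cutoff` (boundary inclusive).
#'
#' @param scores data.frame with an `auci95_per_hour` column.
#' @param cutoff positive threshold, default 0.046.
#' @return `scores` with `is_deg` (re)set.
#' @export
call_degs <- function(scores, cutoff = 0.046) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a single positive number", call. = FALSE)
  if (!"auci95_per_hour" %in% names(scores))
    stop("scores must have an 'auci95_per_hour' column", call. = FALSE)
  scores$is_deg <- abs(scores$auci95_per_hour) >= cutoff
  scores
}

#' Calibrate the |AUCI95%/h| cutoff from labelled curves
#'
#' Given curves labelled differentially expressed (`"de"`) or not
#' (`"not_de"`), evaluates the discrete misclassification cost
#' `#{de with |score| < c} + #{not_de with |score| >= c}` over a candidate
#' grid — the midpoints of adjacent sorted distinct absolute scores, the
#' two extreme scores, and one candidate beyond the maximum (so the
#' everything-not-DE rule is reachable) — and returns the exhaustive-grid
#' minimiser.  Ties resolve to the smallest candidate.  Because the cost is
#' piecewise constant with breakpoints only at observed |scores|, this grid
#' search is exact (equivalent to a brute-force scan of the whole axis).
#'
#' @param scores numeric effect scores (sign ignored).
#' @param labels character/factor vector of `"de"` / `"not_de"`, one per
#'   score; both classes must occur.
#' @return object of class `cutoff_calibration`: list with `grid`, `cost`,
#'   `optimum`, `min_cost`, and the labelled absolute scores.
#' @export
calibrate_cutoff <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  labels <- as.character(labels)
  if (!all(labels %in% c("de", "not_de")))
    stop("labels must be 'de' or 'not_de'", call. = FALSE)
  a <- abs(as.numeric(scores))
  if (any(!is.finite(a))) stop("non-finite scores", call. = FALSE)
  de <- a[labels == "de"]; nde <- a[labels == "not_de"]
  if (length(de) == 0L || length(nde) == 0L)
    stop("need >= 1 score in each label class", call. = FALSE)
  s <- sort(unique(a))
  mids <- if (length(s) > 1L) (s[-1] + s[-length(s)]) / 2 else numeric(0)
  beyond <- s[length(s)] + max(diff(range(s)) / 2, s[length(s)] * 0.5, 1e-8)
  grid <- sort(unique(c(s[1], mids, s[length(s)], beyond)))
  cost <- vapply(grid, function(c) sum(de < c) + sum(nde >= c), numeric(1))
  optimum <- grid[which.min(cost)]        # which.min takes the first = smallest
  structure(list(grid = grid, cost = cost, optimum = optimum,
                 min_cost = min(cost),
                 labeled_scores = data.frame(abs_score = a, label = labels)),
            class = "cutoff_calibration")
}

#' @export
print.cutoff_calibration <- function(x, ...) {
  cat(sprintf("<cutoff_calibration> optimum |AUCI95%%/h| cutoff = %.4g (cost %d over %d curves)\n",
              x$optimum, as.integer(x$min_cost), nrow(x$labeled_scores)))
  invisible(x)
}

#' Plot the calibration cost profile
#' @param x a `cutoff_calibration`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cutoff_calibration <- function(x, ...) {
  graphics::plot(x$grid, x$cost, type = "s", xlab = "|AUCI95%/h| cutoff",
                 ylab = "misclassified curves", ...)
  graphics::abline(v = x$optimum, col = "red3", lty = 2)
  invisible(x)
}
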