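#' Define analysis time windows
#'
#' Windows are half-open \[start, end) conceptually, so frames sharing the
#' same span across exposure scenarios (e.g. 24-72 hpf) are "congruent" and
#' adjacent frames are disjoint.  An example configuration mirroring a
#' two-scenario study (frames A-J) ships in
#' `system.file("extdata", "windows_example.yaml", package = "auci")`.
#'
#' @param label window labels.
#' @param start_hpf,end_hpf numeric bounds in hours post fertilization.
#' @param scenario `"early"` or `"late"` exposure start.
#' @param level concentration level the window applies to (optional,
#'   `NA` = all levels).
#' @return data.frame of class `time_windows`.
#' @export
time_windows <- function(label, start_hpf, end_hpf, scenario = "late",
                         level = NA_character_) {
  if (any(start_hpf >= end_hpf))
    stop("window start must precede end", call. = FALSE)
  out <- data.frame(label = as.character(label), start_hpf = start_hpf,
                    end_hpf = end_hpf, scenario = scenario,
                    level = level, stringsAsFactors = FALSE)
  class(out) <- c("time_windows", "data.frame")
  out
}

#' Score difference bands over a set of time windows
#'
#' Evaluates [signed_auci()] and [auci_per_hour()] for every band x window
#' combination and flags DEGs at the active cutoff.
#'
#' @param bands list of `difference_band` objects.
#' @param windows a `time_windows` data.frame (or any data.frame with
#'   `label`, `start_hpf`, `end_hpf`).
#' @param cutoff |AUCI95%/h| DEG threshold, default 0.046.
#' @param mode passed to [signed_auci()].
#' @return score data.frame, one row per band x window.
#' @export
windowed_effects <- function(bands, windows, cutoff = 0.046,
                             mode = "ci_excess") {
  stopifnot(is.list(bands), nrow(windows) >= 1L)
  rows <- lapply(bands, function(b) {
    do.call(rbind, lapply(seq_len(nrow(windows)), function(i) {
      w <- c(windows$start_hpf[i], windows$end_hpf[i])
      if (w[1] < min(b$grid) - 1e-9 || w[2] > max(b$grid) + 1e-9)
        stop(sprintf("window %s [%g, %g] outside modelled range [%g, %g]",
                     windows$label[i], w[1], w[2], min(b$grid), max(b$grid)),
             call. = FALSE)
      effect_score(b, w, cutoff = cutoff, window_label = windows$label[i],
                   mode = mode)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overlap coefficient between two gene sets
#'
#' \eqn{|A \cap B| / \min(|A|, |B|)}: 1 when one set nests in the other,
#' 0 when disjoint.
#'
#' @param a,b non-empty character vectors (treated as sets).
#' @return a number in \[0, 1\].
#' @export
overlap_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("overlap coefficient is undefined for empty sets", call. = FALSE)
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Venn region counts for 2-4 sets
#'
#' @param sets named list of 2-4 character vectors.
#' @return named integer vector; names are `&`-joined set names per
#'   exclusive membership region; counts sum to the union size.
#' @export
venn_counts <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 4L)
    stop("venn_counts supports 2 to 4 sets", call. = FALSE)
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- LETTERS[seq_along(sets)]
  sets <- lapply(sets, unique)
  u <- unique(unlist(sets))
  memb <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 1L) memb <- matrix(memb, nrow = 1L,
                                      dimnames = list(NULL, names(sets)))
  key <- apply(memb, 1L, function(r) paste(names(sets)[r], collapse = "&"))
  tab <- table(key)
  out <- stats::setNames(as.integer(tab), names(tab))
  out
}

#' Global up/down regulation profile across genes
#'
#' Sums, at each grid time, the positive CI-exceedance bound over genes
#' (`up_total`) and the negative one (`down_total`), visualising the bulk
#' of up- vs down-regulation over developmental time.  With
#' `mode = "mean_diff"` the positive/negative parts of the mean difference
#' are summed instead.
#'
#' @param bands list of `difference_band`s sharing one grid.
#' @param mode `"bound"` (default; consistent with the AUCI definition) or
#'   `"mean_diff"`.
#' @return data.frame of class `global_profile` with `time`, `up_total`
#'   (>= 0), `down_total` (<= 0).
#' @export
global_regulation_profile <- function(bands, mode = c("bound", "mean_diff")) {
  mode <- match.arg(mode)
  stopifnot(is.list(bands), length(bands) >= 1L)
  g <- bands[[1L]]$grid
  for (b in bands)
    if (!isTRUE(all.equal(b$grid, g)))
      stop("all bands must share one time grid", call. = FALSE)
  up <- rep(0, length(g)); down <- rep(0, length(g))
  for (b in bands) {
    if (mode == "bound") {
      up <- up + pmax(b$lo95, 0)
      down <- down + pmin(b$hi95, 0)
    } else {
      up <- up + pmax(b$mean_diff, 0)
      down <- down + pmin(b$mean_diff, 0)
    }
  }
  out <- data.frame(time = g, up_total = up, down_total = down)
  class(out) <- c("global_profile", "data.frame")
  out
}

#' Plot a global regulation profile
#' @param x a `global_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.global_profile <- function(x, ...) {
  graphics::plot(NA, xlim = range(x$time),
                 ylim = range(x$up_total, x$down_total),
                 xlab = "time (hpf)", ylab = "summed CI-exceedance", ...)
  graphics::polygon(c(x$time, rev(x$time)), c(x$up_total, rep(0, nrow(x))),
                    col = grDevices::adjustcolor("red3", 0.5), border = NA)
  graphics::polygon(c(x$time, rev(x$time)), c(x$down_total, rep(0, nrow(x))),
                    col = grDevices::adjustcolor("steelblue", 0.5), border = NA)
  graphics::abline(h = 0)
  invisible(x)
}

#' Select top genes by cumulative absolute effect
#'
#' Ranks genes by the sum of `|auci95_per_hour|` over all their windows and
#' levels; ties break deterministically by gene id.
#'
#' @param scores score table from [windowed_effects()].
#' @param n number of genes to return (`n <=` number of distinct genes).
#' @return data.frame `gene_id`, `cumulative_abs_auci_per_hour`, ranked.
#' @export
select_top_genes <- function(scores, n) {
  tot <- tapply(abs(scores$auci95_per_hour), scores$gene_id, sum)
  if (n > length(tot))
    stop(sprintf("n = %d exceeds the %d scored genes", n, length(tot)),
         call. = FALSE)
  ord <- order(-tot, names(tot))
  data.frame(gene_id = names(tot)[ord][seq_len(n)],
             cumulative_abs_auci_per_hour = unname(tot[ord])[seq_len(n)],
             stringsAsFactors = FALSE)
}

#' Build DEG sets per window x level
#'
#' @param scores score table with `is_deg` set.
#' @return named list of gene-id character vectors, one per
#'   `window_label.level` combination present in `scores`.
#' @export
deg_sets <- function(scores) {
  key <- interaction(scores$window_label, scores$level, drop = TRUE)
  lapply(split(scores, key), function(d) unique(d$gene_id[d$is_deg]))
}
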