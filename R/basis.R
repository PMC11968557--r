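#' Cubic regression spline basis over observed times
#'
#' Builds a k-function cubic regression spline basis with knots at the
#' quantiles of the unique observed times, together with the exact
#' roughness penalty \eqn{S_{ij} = \int b_i''(t) b_j''(t)\,dt} (computed
#' analytically for piecewise cubics via [mgcv::smoothCon()]).  In the
#' cardinal parameterisation the coefficient vector holds the function's
#' values at the knots, so the penalty's null space is exactly the straight
#' lines.  The basis dimension k defaults to the number of distinct
#' sampling time points, letting the smooth track the data even where
#' sampling is dense.
#'
#' @param times numeric vector of observed times (hours); >= 3 unique values.
#' @param k basis dimension, `3 <= k <= length(unique(times))`; default is
#'   the number of unique time points.
#' @return object of class `spline_basis`: list with `k`, `degree` (3),
#'   `knots`, `penalty` (k x k), `range`, and the underlying smooth
#'   constructor object.
#' @export
spline_basis <- function(times, k = NULL) {
  if (any(!is.finite(times))) stop("non-finite times", call. = FALSE)
  ut <- sort(unique(times))
  if (length(ut) < 3L) stop("need >= 3 unique time points", call. = FALSE)
  if (is.null(k)) k <- length(ut)
  if (k > length(ut))
    stop(sprintf("basis dimension k = %d exceeds the %d unique time points",
                 k, length(ut)), call. = FALSE)
  if (k < 3L) stop("k must be >= 3", call. = FALSE)
  sm <- mgcv::smoothCon(mgcv::s(time, bs = "cr", k = k),
                        data = data.frame(time = ut),
                        absorb.cons = FALSE, scale.penalty = FALSE)[[1L]]
  structure(list(k = k, degree = 3L, knots = sm$xp,
                 penalty = sm$S[[1L]], range = range(ut), sm = sm),
            class = "spline_basis")
}

#' Evaluate the basis functions at given times
#'
#' @param basis a `spline_basis`.
#' @param times numeric vector within the basis range (no extrapolation).
#' @return numeric matrix, `length(times)` x `k`.
#' @export
eval_basis <- function(basis, times) {
  stopifnot(inherits(basis, "spline_basis"))
  if (any(!is.finite(times))) stop("non-finite times", call. = FALSE)
  if (any(times < basis$range[1] - 1e-9) || any(times > basis$range[2] + 1e-9))
    stop(sprintf("times outside the modelled range [%g, %g]: no extrapolation",
                 basis$range[1], basis$range[2]), call. = FALSE)
  mgcv::PredictMat(basis$sm, data.frame(time = times))
}

#' @export
print.spline_basis <- function(x, ...) {
  cat(sprintf("<spline_basis> cubic regression spline, k = %d, range [%g, %g]\n",
              x$k, x$range[1], x$range[2]))
  invisible(x)
}

#' Model design for per-gene time-course fits
#'
#' Lays out the columns of the model
#' `expression ~ concentration_level + s(time)` with one independent smooth
#' per concentration level: an intercept, L-1 level-offset indicators, and
#' L blocks of smooth coefficients.  Each smooth is centred (sum-to-zero
#' over the level's unique observed times) by absorbing the constraint into
#' a k-1 column reparameterisation, which keeps the level offsets
#' identifiable.  The control curve depends only on the intercept and the
#' control block, so treatment coefficients never leak into it.
#'
#' @param metadata validated metadata data.frame (see [validate_metadata()])
#'   for the samples being modelled; must contain the control and >= 1
#'   treatment level.
#' @param basis a `spline_basis` covering the metadata's time range; default
#'   builds one with k = number of unique time points.
#' @return object of class `model_design`: list with the design matrix `X`
#'   (one row per metadata row), per-smooth penalty matrices embedded in
#'   full column dimension, column index bookkeeping, levels, and cached
#'   cross-products.
#' @export
model_design <- function(metadata, basis = NULL) {
  md <- validate_metadata(metadata)
  levs <- levels(md$concentration_level)
  if (length(levs) < 2L)
    stop("design needs the control plus >= 1 treatment level", call. = FALSE)
  if (levs[1] != "control") stop("first level must be control", call. = FALSE)
  if (is.null(basis)) basis <- spline_basis(md$time_hpf)
  k <- basis$k

  # Sum-to-zero constraint over each level's unique observed times,
  # absorbed by the QR-complement reparameterisation: B -> B Z, S -> Z'SZ.
  Zs <- lapply(levs, function(l) {
    ut <- sort(unique(md$time_hpf[md$concentration_level == l]))
    if (length(ut) < 2L)
      stop("level ", l, " observed at < 2 time points", call. = FALSE)
    cvec <- colSums(eval_basis(basis, ut))
    qr.Q(qr(matrix(cvec, ncol = 1)), complete = TRUE)[, -1L, drop = FALSE]
  })
  names(Zs) <- levs

  L <- length(levs)
  p_par <- L                      # intercept + (L-1) offsets
  p_sm <- k - 1L                  # per constrained smooth block
  p <- p_par + L * p_sm
  col_names <- c("(Intercept)",
                 if (L > 1) paste0("offset_", levs[-1L]),
                 unlist(lapply(levs, function(l) paste0("s(", l, ").", seq_len(p_sm)))))
  block_idx <- lapply(seq_len(L), function(j) p_par + (j - 1L) * p_sm + seq_len(p_sm))
  names(block_idx) <- levs

  row_builder <- function(level, times) {
    level <- as.character(level)
    if (!level %in% levs)
      stop("level '", level, "' was not present in the fitted design",
           call. = FALSE)
    B <- eval_basis(basis, times) %*% Zs[[level]]
    X <- matrix(0, nrow = length(times), ncol = p,
                dimnames = list(NULL, col_names))
    X[, 1L] <- 1
    if (level != levs[1L]) X[, paste0("offset_", level)] <- 1
    X[, block_idx[[level]]] <- B
    X
  }

  X <- do.call(rbind, lapply(seq_len(nrow(md)), function(i)
    row_builder(md$concentration_level[i], md$time_hpf[i])))
  rownames(X) <- md$sample_id

  qrX <- qr(X)
  if (qrX$rank < p)
    stop(sprintf("design is rank deficient (rank %d < %d columns)",
                 qrX$rank, p), call. = FALSE)

  S_full <- lapply(seq_len(L), function(j) {
    S <- matrix(0, p, p)
    S[block_idx[[j]], block_idx[[j]]] <- crossprod(Zs[[j]], basis$penalty %*% Zs[[j]])
    S
  })
  names(S_full) <- levs

  # penalty ranks and total null-space dimension, needed by REML scoring
  pen_rank <- vapply(seq_len(L), function(j) {
    ev <- eigen(S_full[[j]][block_idx[[j]], block_idx[[j]]],
                symmetric = TRUE, only.values = TRUE)$values
    sum(ev > 1e-10 * max(ev))
  }, numeric(1))
  Mp <- p - sum(pen_rank)

  structure(list(X = X, basis = basis, levels = levs,
                 block_idx = block_idx, n_par = p_par, p = p,
                 S = S_full, Zs = Zs, row_builder = row_builder,
                 metadata = md, pen_rank = pen_rank, Mp = Mp,
                 XtX = crossprod(X)),
            class = "model_design")
}

#' @export
print.model_design <- function(x, ...) {
  cat(sprintf(paste0("<model_design> %d samples, levels: %s; k = %d ",
                     "(%d columns after constraints)\n"),
              nrow(x$X), paste(x$levels, collapse = ", "),
              x$basis$k, x$p))
  invisible(x)
}

# Internal: design rows for the treatment-minus-control difference curve.
difference_rows <- function(design, level, times) {
  if (identical(as.character(level), design$levels[1L]))
    stop("difference curves are defined against the control; pick a treatment level",
         call. = FALSE)
  design$row_builder(level, times) - design$row_builder(design$levels[1L], times)
}
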