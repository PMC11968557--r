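#' Fit a per-gene penalized-spline time-course model
#'
#' Fits `E ~ concentration_level + s(time)` for one gene by penalized least
#' squares: \eqn{\hat\beta = \arg\min \|y - X\beta\|^2 + \sum_j \lambda_j
#' \beta^T S_j \beta}, with one roughness penalty (and one smoothing
#' parameter) per concentration-level smooth.  In `lambda = "auto"` mode
#' each \eqn{\lambda_j} is selected on a 41-point log10 grid spanning
#' \[1e-6, 1e6\] by coordinate descent (3 sweeps), minimising either the
#' restricted marginal likelihood (`select = "REML"`, the default: better
#' calibrated confidence bands) or the GCV score \eqn{n\,RSS/(n - edf)^2}
#' (`select = "GCV"`).  The search is deterministic and dependency-free;
#' ties on a flat score profile resolve to the largest candidate (the
#' smoothest fit).
#'
#' The conditional posterior covariance is \eqn{V_\beta = \hat\sigma^2
#' (X^TX + \sum_j \lambda_j S_j)^{-1}}.  For REML fits a first-order
#' correction for smoothing-parameter uncertainty is added
#' (\eqn{V_c = V_\beta + J V_\rho J^T} with \eqn{J = d\hat\beta/d\rho},
#' \eqn{\rho = \log\lambda}, and \eqn{V_\rho} the inverse curvature of the
#' restricted likelihood): without it, pointwise bands built from a single
#' selected \eqn{\lambda} undercover.  [simulate.tcgam()] draws from the
#' corrected covariance by default.
#'
#' @param y numeric response vector (log2 expression), one value per design
#'   row.
#' @param design a `model_design` from [model_design()]; alternatively pass
#'   `metadata` to build one.
#' @param metadata sample metadata, used only when `design` is missing.
#' @param lambda `"auto"` for data-driven selection, or a fixed
#'   non-negative vector (length 1, recycled, or one value per smooth;
#'   `Inf` restricts a smooth to its penalty null space exactly).
#' @param select score driving auto selection: `"REML"` (default) or
#'   `"GCV"`.
#' @param gene_id identifier stored in the fit.
#' @param grid log10 smoothing-parameter grid for auto mode.
#' @param sweeps coordinate-descent sweeps for auto mode.
#' @return object of class `tcgam`: list with `beta`, `Vb` (conditional
#'   covariance), `Vc` (uncertainty-corrected covariance; equals `Vb`
#'   where no correction applies), `lambda`, `sigma2`, `edf`, `score`,
#'   `design`, `y`, `fitted.values`, `gene_id`.
#' @examples
#' md <- data.frame(
#'   sample_id = paste0("s", 1:12),
#'   time_hpf = rep(c(24, 48, 72, 96), each = 3),
#'   concentration_level = rep(c("control", "control", "C_high"), 4),
#'   exposure_start = "late", replicate = rep(c(1, 2, 1), 4))
#' des <- model_design(md, spline_basis(md$time_hpf, k = 4))
#' fit <- tcgam(rnorm(12, mean = 8), des, gene_id = "toy")
#' coef(fit)
#' @export
tcgam <- function(y, design = NULL, metadata = NULL, lambda = "auto",
                  select = c("REML", "GCV"), gene_id = "gene",
                  grid = seq(-6, 6, length.out = 41), sweeps = 3L) {
  select <- match.arg(select)
  if (is.null(design)) {
    if (is.null(metadata)) stop("supply 'design' or 'metadata'", call. = FALSE)
    design <- model_design(metadata)
  }
  stopifnot(inherits(design, "model_design"))
  X <- design$X
  n <- nrow(X); p <- design$p
  if (length(y) != n)
    stop(sprintf("length(y) = %d but design has %d rows", length(y), n),
         call. = FALSE)
  if (any(!is.finite(y))) stop("non-finite response values", call. = FALSE)

  Ss <- design$S
  J <- length(Ss)

  # lambda = Inf for a smooth restricts it to its penalty null space
  # (straight lines after centring): exact, no large-lambda roundoff.
  Tmat <- diag(p)
  lam_report <- NULL
  if (!identical(lambda, "auto")) {
    lam_in <- rep_len(as.numeric(lambda), J)
    if (any(is.infinite(lam_in))) {
      lam_report <- lam_in
      blocks <- vector("list", J + 1L)
      blocks[[1L]] <- diag(design$n_par)
      for (j in seq_len(J)) {
        idx <- design$block_idx[[j]]
        if (is.infinite(lam_in[j])) {
          Sb <- Ss[[j]][idx, idx]
          ei <- eigen(Sb, symmetric = TRUE)
          keep <- ei$values <= 1e-10 * max(ei$values)
          blocks[[j + 1L]] <- ei$vectors[, keep, drop = FALSE]
        } else blocks[[j + 1L]] <- diag(length(idx))
      }
      Tmat <- matrix(0, p, sum(vapply(blocks, ncol, integer(1))))
      at <- 0L
      all_idx <- c(list(seq_len(design$n_par)), design$block_idx)
      for (b in seq_along(blocks)) {
        nb <- ncol(blocks[[b]])
        Tmat[all_idx[[b]], at + seq_len(nb)] <- blocks[[b]]
        at <- at + nb
      }
      X <- X %*% Tmat
      Ss <- lapply(Ss, function(S) crossprod(Tmat, S %*% Tmat))
      lambda <- ifelse(is.infinite(lam_in), 0, lam_in)
    }
  }
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  yty <- sum(y * y)

  Mp <- design$Mp
  pen_rank <- design$pen_rank

  eval_lambda <- function(lam) {
    A <- XtX
    for (j in seq_len(J)) if (lam[j] > 0) A <- A + lam[j] * Ss[[j]]
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Ainv <- chol2inv(R)
    beta <- drop(Ainv %*% Xty)
    edf <- sum(Ainv * XtX)
    rss <- max(yty - 2 * sum(beta * Xty) + sum(beta * drop(XtX %*% beta)), 0)
    denom <- n - edf
    gcv <- if (denom <= 0) Inf else n * rss / denom^2
    # restricted marginal likelihood (-2 log, profiled scale, constants
    # dropped): valid only when every lambda is positive
    reml <- if (all(lam > 0) && n > Mp) {
      rss_pen <- max(yty - sum(beta * Xty), 0)
      (n - Mp) * log(max(rss_pen, 1e-300)) + 2 * sum(log(diag(R))) -
        sum(pen_rank * log(lam))
    } else Inf
    list(beta = beta, Ainv = Ainv, edf = edf, rss = rss, gcv = gcv,
         reml = reml, lambda = lam)
  }
  score_of <- function(f) if (select == "REML") f$reml else f$gcv

  if (identical(lambda, "auto")) {
    cand <- 10^grid
    lam <- rep(1, J)
    best <- eval_lambda(lam)
    if (is.null(best)) stop("singular penalized system at lambda = 1", call. = FALSE)
    for (sw in seq_len(sweeps)) {
      for (j in seq_len(J)) {
        scores <- rep(Inf, length(cand))
        fits <- vector("list", length(cand))
        for (ci in seq_along(cand)) {
          lam_try <- lam; lam_try[j] <- cand[ci]
          f <- eval_lambda(lam_try)
          if (!is.null(f)) { scores[ci] <- score_of(f); fits[[ci]] <- f }
        }
        smin <- min(scores)
        if (!is.finite(smin)) next
        # ties (flat score) resolve to the largest lambda -> smoothest fit
        tol <- abs(smin) * 1e-10 + 1e-300
        ok <- which(scores <= smin + tol)
        pick <- max(ok)
        lam[j] <- cand[pick]
        best <- fits[[pick]]
      }
    }
    fit <- best
  } else {
    lam <- rep_len(as.numeric(lambda), J)
    if (any(lam < 0) || any(!is.finite(lam)))
      stop("fixed lambda must be finite and >= 0", call. = FALSE)
    if (all(lam == 0) && n <= ncol(X) && ncol(X) == p)
      stop(sprintf("unidentifiable: n = %d <= %d columns with lambda = 0",
                   n, p), call. = FALSE)
    fit <- eval_lambda(lam)
    if (is.null(fit))
      stop("singular penalized system at the supplied lambda", call. = FALSE)
  }

  auto <- identical(lambda, "auto")
  # recompute the residual sum of squares directly: the cross-product form
  # used during selection loses precision for near-interpolating fits
  fitted_vals <- drop(X %*% fit$beta)
  fit$rss <- sum((y - fitted_vals)^2)
  pen_at_fit <- sum(vapply(seq_len(J), function(j)
    fit$lambda[j] * drop(crossprod(fit$beta, Ss[[j]] %*% fit$beta)),
    numeric(1)))
  sigma2 <- if (auto && select == "REML" && n > Mp) {
    (fit$rss + pen_at_fit) / (n - Mp)
  } else if (n - fit$edf > 0) fit$rss / (n - fit$edf) else 0
  Vb <- sigma2 * fit$Ainv

  # first-order smoothing-parameter-uncertainty correction (REML fits):
  # Vc = Vb + J V_rho J', J = d beta / d log(lambda), V_rho from the
  # regularized inverse curvature of the restricted likelihood
  Vc <- Vb
  if (auto && select == "REML" && sigma2 > 0) {
    lam <- fit$lambda
    Jm <- vapply(seq_len(J), function(j)
      drop(-lam[j] * fit$Ainv %*% (Ss[[j]] %*% fit$beta)),
      numeric(length(fit$beta)))
    Jm <- matrix(Jm, ncol = J)
    h <- 0.5
    f0 <- fit$reml
    score_at <- function(rho) {
      f <- eval_lambda(exp(rho))
      if (is.null(f)) Inf else f$reml
    }
    rho0 <- log(lam)
    H <- matrix(0, J, J)
    for (j in seq_len(J)) {
      ej <- rho0; ej[j] <- ej[j] + h
      mj <- rho0; mj[j] <- mj[j] - h
      H[j, j] <- (score_at(ej) - 2 * f0 + score_at(mj)) / h^2
      if (j > 1) for (k in seq_len(j - 1L)) {
        pp <- rho0; pp[c(j, k)] <- pp[c(j, k)] + h
        pm <- rho0; pm[j] <- pm[j] + h; pm[k] <- pm[k] - h
        mp <- rho0; mp[j] <- mp[j] - h; mp[k] <- mp[k] + h
        mm <- rho0; mm[c(j, k)] <- mm[c(j, k)] - h
        H[j, k] <- H[k, j] <-
          (score_at(pp) - score_at(pm) - score_at(mp) + score_at(mm)) / (4 * h^2)
      }
    }
    if (all(is.finite(H))) {
      ei <- eigen(H / 2, symmetric = TRUE)   # curvature of -log REML lik
      # floor the curvature so flat/boundary directions cannot explode
      Vrho <- ei$vectors %*% (1 / pmax(ei$values, 0.1) * t(ei$vectors))
      Vc <- Vb + Jm %*% Vrho %*% t(Jm)
    }
  }

  beta_full <- drop(Tmat %*% fit$beta)
  Vb <- Tmat %*% Vb %*% t(Tmat); Vb <- (Vb + t(Vb)) / 2
  Vc <- Tmat %*% Vc %*% t(Tmat); Vc <- (Vc + t(Vc)) / 2
  beta <- stats::setNames(beta_full, colnames(design$X))
  structure(list(beta = beta, Vb = Vb, Vc = Vc,
                 lambda = stats::setNames(lam_report %||% fit$lambda,
                                          names(Ss)),
                 sigma2 = sigma2, edf = fit$edf, rss = fit$rss,
                 score = score_of(fit), gcv = fit$gcv, select = select,
                 design = design, y = y,
                 fitted.values = fitted_vals,
                 df.residual = n - fit$edf, gene_id = gene_id),
            class = "tcgam")
}

#' @export
print.tcgam <- function(x, ...) {
  cat(sprintf("<tcgam> gene %s: %d obs, levels %s\n", x$gene_id,
              length(x$y), paste(x$design$levels, collapse = "/")))
  cat(sprintf("  edf = %.2f, sigma^2 = %.4g, lambda = [%s]\n",
              x$edf, x$sigma2,
              paste(signif(x$lambda, 3), collapse = ", ")))
  invisible(x)
}

#' @export
coef.tcgam <- function(object, ...) object$beta

#' @export
fitted.tcgam <- function(object, ...) object$fitted.values

#' @export
residuals.tcgam <- function(object, ...) object$y - object$fitted.values

#' @export
summary.tcgam <- function(object, ...) {
  out <- list(gene_id = object$gene_id, n = length(object$y),
              levels = object$design$levels, edf = object$edf,
              sigma2 = object$sigma2, lambda = object$lambda,
              select = object$select, score = object$score,
              r.squared = 1 - object$rss / sum((object$y - mean(object$y))^2))
  class(out) <- "summary.tcgam"
  out
}

#' @export
print.summary.tcgam <- function(x, ...) {
  cat(sprintf("Time-course penalized-spline fit for gene %s\n", x$gene_id))
  cat(sprintf("  n = %d, levels: %s\n", x$n, paste(x$levels, collapse = ", ")))
  cat(sprintf("  edf = %.2f, residual sigma^2 = %.4g, %s score = %.4g, R^2 = %.3f\n",
              x$edf, x$sigma2, x$select, x$score, x$r.squared))
  cat("  lambda:", paste(sprintf("%s = %.3g", names(x$lambda), x$lambda),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Predict a concentration level's expression curve
#'
#' Evaluates the fitted curve (intercept + level offset + level smooth) and
#' its pointwise standard error \eqn{\sqrt{diag(X_g V_\beta X_g^T)}} on a
#' time grid.  Extrapolation beyond the observed time range is refused.
#'
#' @param object a `tcgam` fit.
#' @param level concentration level present at fit time.
#' @param times numeric grid within the modelled time range; default 101
#'   equally spaced points.
#' @param covariance `"corrected"` (default; includes smoothing-parameter
#'   uncertainty) or `"conditional"` for the pointwise standard errors.
#' @param ... unused.
#' @return data.frame with `time`, `fit`, `se`.
#' @export
predict.tcgam <- function(object, level = "control", times = NULL,
                          covariance = c("corrected", "conditional"), ...) {
  covariance <- match.arg(covariance)
  rng <- object$design$basis$range
  if (is.null(times)) times <- seq(rng[1], rng[2], length.out = 101)
  Xg <- object$design$row_builder(level, times)
  V <- if (covariance == "corrected") object$Vc else object$Vb
  se <- sqrt(pmax(rowSums((Xg %*% V) * Xg), 0))
  data.frame(time = times, fit = drop(Xg %*% object$beta), se = se)
}

#' Draw coefficient vectors from the fit's posterior
#'
#' Samples `nsim` coefficient vectors from \eqn{MVN(\hat\beta, V_\beta)}
#' via the Cholesky factor of \eqn{V_\beta} (falling back to an eigen
#' square root when \eqn{V_\beta} is only positive semi-definite, e.g. a
#' noise-free fit).  These posterior draws are the raw material for the
#' treatment-minus-control difference bands.
#'
#' @param object a `tcgam` fit.
#' @param nsim number of draws (the reference workflow uses 10000).
#' @param seed integer seed; if `NULL` the current RNG state is used.
#' @param covariance `"corrected"` (default) or `"conditional"`, see
#'   [tcgam()].
#' @param ... unused.
#' @return numeric matrix, `nsim` x `length(coef(object))`.
#' @export
simulate.tcgam <- function(object, nsim = 10000, seed = NULL,
                           covariance = c("corrected", "conditional"), ...) {
  covariance <- match.arg(covariance)
  if (nsim < 2) stop("nsim must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  V <- if (covariance == "corrected") object$Vc else object$Vb
  p <- ncol(V)
  nrmV <- max(abs(V))
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    ei <- eigen(V, symmetric = TRUE)
    if (any(ei$values < -1e-8 * max(nrmV, 1)))
      stop("posterior covariance has a materially negative eigenvalue",
           call. = FALSE)
    R <- t(ei$vectors %*% (sqrt(pmax(ei$values, 0)) * t(ei$vectors)))
  }
  Z <- matrix(stats::rnorm(nsim * p), nrow = nsim, ncol = p)
  sweep(Z %*% R, 2L, object$beta, "+")
}

#' Plot fitted curves per concentration level
#'
#' @param x a `tcgam` fit.
#' @param times grid for the curves (default 101 points over the range).
#' @param ci half-width multiplier for the shaded pointwise band
#'   (default 1.96, i.e. 95%).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.tcgam <- function(x, times = NULL, ci = 1.96, ...) {
  rng <- x$design$basis$range
  if (is.null(times)) times <- seq(rng[1], rng[2], length.out = 101)
  preds <- lapply(x$design$levels, function(l) predict(x, l, times))
  fits <- sapply(preds, `[[`, "fit")
  ses <- sapply(preds, `[[`, "se")
  cols <- grDevices::hcl.colors(length(preds), "Dark 3")
  ylim <- range(fits - ci * ses, fits + ci * ses, x$y)
  graphics::matplot(times, fits, type = "l", lty = 1, col = cols,
                    xlab = "time (hpf)", ylab = "log2 expression",
                    ylim = ylim, main = x$gene_id, ...)
  for (j in seq_along(preds)) {
    graphics::polygon(c(times, rev(times)),
                      c(fits[, j] - ci * ses[, j], rev(fits[, j] + ci * ses[, j])),
                      col = grDevices::adjustcolor(cols[j], 0.15), border = NA)
  }
  md <- x$design$metadata
  graphics::points(md$time_hpf, x$y,
                   col = cols[match(md$concentration_level, x$design$levels)],
                   pch = 16)
  graphics::legend("topleft", legend = x$design$levels, col = cols, lty = 1,
                   bty = "n")
  invisible(x)
}

#' Fit time-course models for every gene of an expression matrix
#'
#' Builds one shared design from the metadata and fits [tcgam()] per gene.
#' Gene-level fit failures are caught, logged and skipped (count reported).
#'
#' @param x an `expr_matrix` on the log2 scale.
#' @param metadata metadata covering `colnames(x)`.
#' @param k basis dimension; default = number of unique time points.
#' @param lambda,select see [tcgam()].
#' @param threads number of worker processes; results are independent of
#'   this value (per-gene work is deterministic given the fit inputs).
#' @return object of class `tcgam_set`: list of `tcgam` fits keyed by
#'   gene id, plus the shared design.
#' @export
fit_timecourse <- function(x, metadata, k = NULL, lambda = "auto",
                           select = "REML", threads = 1L) {
  stopifnot(inherits(x, "expr_matrix"))
  if (scale_tag(x) != "log2")
    stop("fit_timecourse expects log2-scale expression", call. = FALSE)
  md <- validate_metadata(metadata)
  md <- md[match(colnames(x), md$sample_id), , drop = FALSE]
  if (any(is.na(md$sample_id)))
    stop_listing("samples missing from metadata",
                 setdiff(colnames(x), metadata$sample_id))
  if (is.null(k)) {
    # the basis dimension cannot exceed what the sparsest level supports
    # (relevant when QC removed samples from an otherwise balanced design)
    k <- min(tapply(md$time_hpf, md$concentration_level,
                    function(t) length(unique(t))))
  }
  basis <- spline_basis(md$time_hpf, k = k)
  design <- model_design(md, basis)
  genes <- rownames(x)
  fit_one <- function(g) {
    tryCatch(tcgam(unclass(x)[g, ], design, lambda = lambda,
                   select = select, gene_id = g),
             error = function(e) e)
  }
  fits <- if (threads > 1L) {
    parallel::mclapply(genes, fit_one, mc.cores = threads)
  } else lapply(genes, fit_one)
  names(fits) <- genes
  failed <- vapply(fits, inherits, logical(1), what = "error")
  if (any(failed))
    message(sum(failed), " gene fit(s) failed and were skipped")
  structure(list(fits = fits[!failed], design = design,
                 n_failed = sum(failed)),
            class = "tcgam_set")
}

#' @export
print.tcgam_set <- function(x, ...) {
  cat(sprintf("<tcgam_set> %d gene fits (%d failed), levels %s\n",
              length(x$fits), x$n_failed,
              paste(x$design$levels, collapse = "/")))
  invisible(x)
}

#' @export
`[[.tcgam_set` <- function(x, i) .subset2(x, "fits")[[i]]

#' @export
length.tcgam_set <- function(x) length(.subset2(x, "fits"))

#' Serialize a set of fits to a JSON container
#'
#' Stores per gene the coefficient vector, posterior covariance, smoothing
#' parameters and residual variance, keyed by gene id, so downstream
#' scoring can run without refitting.
#'
#' @param fits a `tcgam_set`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_fits_json <- function(fits, path) {
  stopifnot(inherits(fits, "tcgam_set"))
  payload <- lapply(fits$fits, function(f)
    list(beta = unname(f$beta), Vb = f$Vb, lambda = unname(f$lambda),
         sigma2 = f$sigma2, edf = f$edf))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
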