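test_that("spline basis dimension, knots and penalty null space", {
  tp <- c(0, 12, 24, 36, 48, 72)
  b <- spline_basis(tp)                       # k defaults to #time points
  expect_equal(b$k, 6L)
  expect_equal(dim(b$penalty), c(6L, 6L))
  expect_equal(b$penalty, t(b$penalty), tolerance = 1e-12)
  expect_true(all(eigen(b$penalty, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-8))

  # cardinal parameterisation: a straight line's coefficients are its
  # values at the knots, and a line has zero roughness
  co <- 2 + 0.5 * b$knots
  expect_lt(abs(drop(t(co) %*% b$penalty %*% co)), 1e-10)

  expect_error(spline_basis(tp, k = 7), "exceeds")
  expect_error(spline_basis(c(1, 2, NA)), "non-finite")
  expect_error(eval_basis(b, 100), "extrapolation")
})

test_that("penalty quadratic form equals the integral of squared curvature", {
  tp <- c(24, 30, 42, 60, 84, 96)
  b <- spline_basis(tp)
  set.seed(3)
  for (r in 1:3) {
    co <- rnorm(b$k)
    qf <- drop(t(co) %*% b$penalty %*% co)
    # numerical quadrature oracle: the spline is piecewise cubic, so a
    # central second difference is exact away from knots and f''^2 is
    # piecewise quadratic -> fine trapezoid converges fast
    h <- 1e-3
    tt <- seq(min(tp) + h, max(tp) - h, by = h)
    f <- function(t) drop(eval_basis(b, t) %*% co)
    d2 <- (f(tt + h) - 2 * f(tt) + f(tt - h)) / h^2
    num <- sum((d2[-1]^2 + d2[-length(d2)]^2) / 2) * h
    expect_equal(qf, num, tolerance = 1e-5)
  }
})

test_that("design layout, rank and determinism", {
  md <- make_md(times = c(24, 48, 72), levels = "C_high", n_ctrl = 1L)
  des <- model_design(md, spline_basis(md$time_hpf, k = 3))
  # 1 intercept + 1 offset + 2 blocks of (k-1) = 6 columns, full rank
  expect_equal(ncol(des$X), 6L)
  expect_equal(qr(des$X)$rank, 6L)
  expect_equal(nrow(des$X), 6L)

  r1 <- des$row_builder("C_high", c(30, 60))
  r2 <- des$row_builder("C_high", c(30, 60))
  expect_identical(r1, r2)
  expect_error(des$row_builder("C_low", 30), "C_low")

  ctrl_only <- md[md$concentration_level == "control", ]
  expect_error(model_design(ctrl_only), "control plus")
})

test_that("constant response reproduces the constant at every level", {
  md <- make_md(times = c(24, 36, 48, 60, 72, 84, 96))
  des <- model_design(md)
  fit <- tcgam(rep(5, nrow(md)), des)
  expect_equal(unname(fitted(fit)), rep(5, nrow(md)), tolerance = 1e-8)
  for (lev in des$levels)
    expect_equal(predict(fit, lev, c(30, 55, 80))$fit, rep(5, 3),
                 tolerance = 1e-6)
  expect_lte(fit$edf, des$Mp + 0.05)   # smoothest fit on a flat profile
})

test_that("lambda limits: interpolation at 0, the OLS line at infinity", {
  md <- make_md()
  des <- model_design(md)
  f <- function(t) sin(t / 15) + 0.01 * t
  y <- f(md$time_hpf) +
    ifelse(md$concentration_level == "C_medium", 0.8, 0)
  fit0 <- tcgam(y, des, lambda = 1e-10)
  expect_lt(max(abs(residuals(fit0))), 1e-8)
  expect_equal(predict(fit0, "control", sort(unique(md$time_hpf)))$fit,
               f(sort(unique(md$time_hpf))), tolerance = 1e-6)

  yl <- 1 + 0.1 * md$time_hpf
  fitI <- tcgam(yl, des, lambda = Inf)
  ols <- stats::lm(yl ~ md$time_hpf)
  expect_lt(max(abs(fitted(fitI) - fitted(ols))), 1e-6)

  expect_error(tcgam(rep(NA_real_, nrow(md)), des), "non-finite")
  small <- make_md(times = c(24, 48, 72), levels = "C_high", n_ctrl = 1L)
  des_s <- model_design(small)
  expect_error(tcgam(rnorm(6), des_s, lambda = 0), "unidentifiable")
})

test_that("GCV-selected smoothing beats every grid candidate", {
  md <- make_md()
  des <- model_design(md)
  set.seed(21)
  y <- sin(md$time_hpf / 20) + rnorm(nrow(md), 0, 0.3)
  fit <- tcgam(y, des, select = "GCV")
  for (lam_try in 10^seq(-6, 6, length.out = 13)) {
    for (j in 1:2) {
      lam <- fit$lambda
      lam[j] <- lam_try
      alt <- tcgam(y, des, lambda = lam)
      expect_lte(fit$gcv, alt$gcv + 1e-8)
    }
  }
})

test_that("fits are invariant to sample-row permutation and Vb is PSD", {
  md <- make_md(times = c(24, 36, 48, 60, 72, 96))
  set.seed(5)
  y <- rnorm(nrow(md), 8, 0.5)
  f1 <- tcgam(y, metadata = md)
  perm <- sample(nrow(md))
  f2 <- tcgam(y[perm], metadata = md[perm, ])
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  expect_equal(f1$lambda, f2$lambda)
  # PSD check by Cholesky of Vb + tiny jitter-free tolerance via eigen
  expect_true(min(eigen(f1$Vb, symmetric = TRUE,
                        only.values = TRUE)$values) > -1e-10)
  expect_true(min(eigen(f1$Vc, symmetric = TRUE,
                        only.values = TRUE)$values) > -1e-10)
})

test_that("predictions carry positive uncertainty and block separation", {
  md <- make_md()
  set.seed(6)
  y <- rnorm(nrow(md), 8, 0.4)
  fit <- tcgam(y, metadata = md)
  pr <- predict(fit, "C_medium", c(30, 50, 90))
  expect_true(all(pr$se > 0))
  expect_error(predict(fit, "C_medium", 120), "extrapolation")

  # control prediction never touches the treatment smooth block
  fit2 <- fit
  idx <- fit$design$block_idx[["C_medium"]]
  fit2$beta[idx] <- fit2$beta[idx] + 3
  expect_equal(predict(fit2, "control", c(30, 60))$fit,
               predict(fit, "control", c(30, 60))$fit)
})

test_that("per-gene fitting over a matrix skips failures and keeps names", {
  md <- make_md(times = c(24, 40, 56, 72, 88, 96))
  set.seed(8)
  vals <- matrix(rnorm(5 * nrow(md), 8, 0.4), nrow = 5,
                 dimnames = list(paste0("g", 1:5), md$sample_id))
  x <- expression_matrix(vals, "log2")
  fits <- fit_timecourse(x, md)
  expect_s3_class(fits, "tcgam_set")
  expect_length(fits, 5L)
  expect_named(fits$fits, paste0("g", 1:5))
  expect_identical(fits[["g3"]]$gene_id, "g3")

  path <- tempfile(fileext = ".json")
  write_fits_json(fits, path)
  back <- jsonlite::read_json(path)
  expect_named(back, paste0("g", 1:5))
  expect_equal(unlist(back$g1$beta), unname(fits[["g1"]]$beta),
               tolerance = 1e-6)
})
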