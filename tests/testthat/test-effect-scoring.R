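test_that("posterior draws respect degenerate and regular covariances", {
  md <- make_md(times = c(24, 40, 56, 72, 88, 96))
  f <- function(t) 7 + 0.02 * t
  y <- f(md$time_hpf)
  fit <- tcgam(y, metadata = md, lambda = 1)   # noise-free: sigma2 ~ 0
  expect_lt(fit$sigma2, 1e-12)
  dr <- simulate(fit, nsim = 10, seed = 1)
  expect_equal(dr, matrix(rep(unname(fit$beta), each = 10), nrow = 10),
               tolerance = 1e-8, ignore_attr = TRUE)

  set.seed(30)
  yn <- y + rnorm(length(y), 0, 0.3)
  fitn <- tcgam(yn, metadata = md)
  dr2 <- simulate(fitn, nsim = 1e5, seed = 2)
  se <- sqrt(diag(fitn$Vc) / 1e5)
  expect_true(all(abs(colMeans(dr2) - fitn$beta) < 4 * se + 1e-12))
  # reproducible given the seed
  expect_identical(simulate(fitn, nsim = 50, seed = 7),
                   simulate(fitn, nsim = 50, seed = 7))
})

test_that("difference bands collapse correctly in degenerate cases", {
  md <- make_md(times = c(24, 40, 56, 72, 88, 96))
  # no treatment effect, noise-free: curves coincide, band pins to 0
  y <- 6 + sin(md$time_hpf / 25)
  fit <- tcgam(y, metadata = md, lambda = 1e-8)
  b <- difference_band(fit, "C_medium", n_sim = 500, seed = 3)
  expect_lt(max(abs(b$mean_diff)), 1e-6)
  expect_true(all(b$lo95 <= 1e-6 & b$hi95 >= -1e-6))

  # known offset delta with Vb = 0 degenerates to the offset everywhere
  delta <- 1.25
  y2 <- 6 + ifelse(md$concentration_level == "C_medium", delta, 0)
  fit2 <- tcgam(y2, metadata = md, lambda = 1)
  b2 <- difference_band(fit2, "C_medium", n_sim = 100, seed = 4)
  expect_equal(b2$mean_diff, rep(delta, length(b2$grid)), tolerance = 1e-6)
  expect_equal(b2$lo95, b2$hi95, tolerance = 1e-8)

  expect_error(difference_band(fit, "control"), "control")
})

test_that("empirical band quantiles match the Gaussian closed form", {
  md <- make_md(times = c(24, 40, 56, 72, 88, 96))
  set.seed(31)
  fit <- tcgam(rnorm(nrow(md), 8, 0.3), metadata = md)
  # prescribe an exactly known posterior
  p <- length(fit$beta)
  fit$beta[] <- seq(-0.5, 0.5, length.out = p)
  fit$Vb <- fit$Vc <- diag(0.04, p)
  grid <- seq(30, 90, length.out = 11)
  Xd <- auci:::difference_rows(fit$design, "C_medium", grid)
  mu <- drop(Xd %*% fit$beta)
  sd_t <- sqrt(rowSums((Xd %*% fit$Vc) * Xd))
  b <- difference_band(fit, "C_medium", grid = grid, n_sim = 1e5, seed = 5)
  expect_equal(b$lo95, qnorm(0.025, mu, sd_t), tolerance = 0.01)
  expect_equal(b$hi95, qnorm(0.975, mu, sd_t), tolerance = 0.01)
  expect_equal(b$mean_diff, mu, tolerance = 0.01)
})

test_that("signed AUCI integrates CI-exceedance bounds over windows", {
  g <- seq(0, 10, length.out = 101)
  expect_equal(signed_auci(const_band(g, 1, 2)), 10)
  expect_equal(signed_auci(const_band(g, -1, 2)), 0)
  g2 <- seq(0, 20, length.out = 201)
  expect_equal(signed_auci(const_band(g2, -2, -0.5)), -10)

  # window endpoints by interpolation
  expect_equal(signed_auci(const_band(g, 1, 2), c(2.5, 7.25)), 4.75)
  expect_equal(auci_per_hour(signed_auci(const_band(g, 1, 2), c(2, 7)),
                             c(2, 7)), 1)
  expect_error(signed_auci(const_band(g, 1, 2), c(9, 12)), "outside")
  expect_error(auci_per_hour(5, c(3, 3)), "positive length")

  # doubling the window doubles the area, not the rate
  a1 <- signed_auci(const_band(g2, 0.5, 1), c(0, 10))
  a2 <- signed_auci(const_band(g2, 0.5, 1), c(0, 20))
  expect_equal(a2, 2 * a1)
  expect_equal(auci_per_hour(a1, c(0, 10)), auci_per_hour(a2, c(0, 20)))
})

test_that("signed AUCI is antisymmetric and converges under grid halving", {
  g <- seq(0, 24, length.out = 51)
  lo <- 0.3 * sin(g / 4) - 0.1
  hi <- lo + 0.4
  band <- auci:::make_band(g, lo, hi)
  nband <- auci:::make_band(g, -hi, -lo)
  expect_equal(signed_auci(nband), -signed_auci(band))

  gf <- seq(0, 24, length.out = 101)   # halved spacing
  bandf <- auci:::make_band(gf, 0.3 * sin(gf / 4) - 0.1,
                            0.3 * sin(gf / 4) + 0.3)
  a_coarse <- signed_auci(band)
  a_fine <- signed_auci(bandf)
  expect_lt(abs(a_fine - a_coarse) / abs(a_fine), 0.01)
})

test_that("the band_gap reading integrates the interval midline", {
  g <- seq(0, 10, length.out = 101)
  expect_equal(signed_auci(const_band(g, 1, 2), mode = "band_gap"), 15)
  expect_equal(signed_auci(const_band(g, -1, 1), mode = "band_gap"), 0)
})

test_that("DEG calls use an inclusive absolute cutoff", {
  sc <- data.frame(gene_id = c("a", "b", "c"),
                   auci95_per_hour = c(0.046, 0, -0.1))
  out <- call_degs(sc)
  expect_identical(out$is_deg, c(TRUE, FALSE, TRUE))
  expect_error(call_degs(sc, cutoff = 0), "positive")
})

test_that("cutoff calibration minimizes the discrete cost exactly", {
  cal <- calibrate_cutoff(c(0.1, 0.2, 0.01, 0.02),
                          c("de", "de", "not_de", "not_de"))
  expect_equal(cal$optimum, 0.06)     # midpoint of the zero-cost region
  expect_equal(cal$min_cost, 0)

  # inseparable single-pair case: both extremes cost 1; smallest wins
  cal2 <- calibrate_cutoff(c(0.01, 0.5), c("de", "not_de"))
  expect_equal(cal2$min_cost, 1)
  expect_equal(cal2$optimum, 0.01)

  expect_error(calibrate_cutoff(c(1, 2), c("de", "de")), "each label")
})

test_that("calibration equals an exhaustive uniform scan on random cases", {
  brute_cost <- function(c, de, nde) sum(de < c) + sum(nde >= c)
  set.seed(77)
  for (r in 1:25) {
    n <- sample(4:40, 1)
    sc <- abs(rnorm(n, 0, 0.2))
    lab <- sample(c("de", "not_de"), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- c("de", "not_de")
    de <- sc[lab == "de"]; nde <- sc[lab == "not_de"]
    cal <- calibrate_cutoff(sc, lab)
    scan <- seq(0, max(sc) * 1.1 + 1e-6, length.out = 1e4)
    scan_cost <- vapply(scan, brute_cost, numeric(1), de = de, nde = nde)
    expect_equal(cal$min_cost, min(scan_cost))
    expect_equal(brute_cost(cal$optimum, de, nde), cal$min_cost)
  }
})
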