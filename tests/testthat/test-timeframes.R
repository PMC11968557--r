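test_that("windowed effects split a band into time frames", {
  g <- seq(24, 96, length.out = 145)
  w <- time_windows(c("B", "C"), c(24, 72), c(72, 96))
  b <- const_band(g, 1, 1.5)
  sc <- windowed_effects(list(b), w)
  expect_equal(sc$auci95_per_hour, c(1, 1))
  expect_true(all(sc$is_deg))

  # positive only inside 24-72: later frame scores zero
  lo <- ifelse(g < 72, 0.5, -0.5)
  hi <- lo + 1
  b2 <- auci:::make_band(g, lo, hi)
  sc2 <- windowed_effects(list(b2), w)
  expect_gt(sc2$auci95[sc2$window_label == "B"], 0)
  expect_equal(sc2$auci95[sc2$window_label == "C"], 0)

  wbad <- time_windows("X", 10, 50)
  expect_error(windowed_effects(list(b), wbad), "outside")
  expect_error(time_windows("A", 24, 24), "precede")
})

test_that("an early impulse loads the early frame, not the later one", {
  md <- make_md(times = c(2, 12, 24, 48, 72, 96), levels = "C_medium",
                scenario = "early")
  # centred inside frame A and decayed by its 24 hpf edge
  imp <- function(t) 2 * exp(-(t - 14)^2 / (2 * 4^2))
  set.seed(55)
  y <- 8 + 0.01 * md$time_hpf +
    ifelse(md$concentration_level == "C_medium", imp(md$time_hpf), 0) +
    rnorm(nrow(md), 0, 0.05)
  fit <- tcgam(y, metadata = md)
  b <- difference_band(fit, "C_medium", n_sim = 2000, seed = 56)
  w <- time_windows(c("A", "B"), c(2, 24), c(24, 72))
  sc <- windowed_effects(list(b), w)
  sA <- abs(sc$auci95_per_hour[sc$window_label == "A"])
  sB <- abs(sc$auci95_per_hour[sc$window_label == "B"])
  expect_gt(sA, 5 * max(sB, 1e-9))
})

test_that("overlap coefficient and Venn regions behave as set algebra", {
  expect_equal(overlap_coefficient(c("a", "b", "c"), c("b", "c", "d")), 2 / 3)
  expect_equal(overlap_coefficient(c("a", "b"), c("a", "b", "c")), 1)
  expect_equal(overlap_coefficient("x", "y"), 0)
  expect_error(overlap_coefficient(character(0), "a"), "empty")

  v <- venn_counts(list(A = c("1", "2"), B = c("2", "3")))
  expect_equal(v[["A"]], 1L)
  expect_equal(v[["B"]], 1L)
  expect_equal(v[["A&B"]], 1L)

  same <- venn_counts(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(same, c(`A&B` = 2L))
  expect_error(venn_counts(rep(list(c("a")), 5)), "2 to 4")
})

test_that("Venn counts equal brute-force membership enumeration", {
  set.seed(60)
  for (r in 1:10) {
    ns <- sample(2:4, 1)
    sets <- lapply(seq_len(ns), function(i)
      sample(sprintf("g%02d", 1:30), sample(5:20, 1)))
    names(sets) <- LETTERS[seq_len(ns)]
    v <- venn_counts(sets)
    u <- unique(unlist(sets))
    expect_equal(sum(v), length(u))
    brute <- table(vapply(u, function(g)
      paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
            collapse = "&"), character(1)))
    expect_equal(v[sort(names(v))],
                 stats::setNames(as.integer(brute), names(brute))[sort(names(brute))])
  }
})

test_that("global regulation profiles sum bound exceedances additively", {
  g <- seq(0, 10, length.out = 21)
  null_b <- const_band(g, -0.5, 0.5)
  expect_equal(global_regulation_profile(list(null_b, null_b))$up_total,
               rep(0, 21))

  up <- const_band(g, 1, 2, gene_id = "up")
  down <- const_band(g, -2, -1, gene_id = "down")
  prof <- global_regulation_profile(list(up, down))
  expect_equal(prof$up_total, rep(1, 21))
  expect_equal(prof$down_total, rep(-1, 21))

  # additive over disjoint gene groups
  p1 <- global_regulation_profile(list(up))
  p2 <- global_regulation_profile(list(down))
  expect_equal(prof$up_total, p1$up_total + p2$up_total)
  expect_equal(prof$down_total, p1$down_total + p2$down_total)

  other <- const_band(seq(0, 10, length.out = 11), 1, 2)
  expect_error(global_regulation_profile(list(up, other)), "share")
})

test_that("balanced synthetic directions yield a near-balanced profile", {
  set.seed(61)
  g <- seq(0, 10, length.out = 21)
  bands <- lapply(1:100, function(i) {
    amp <- runif(1, 0.5, 1.5) * sample(c(-1, 1), 1)
    const_band(g, amp - 0.2, amp + 0.2, gene_id = paste0("g", i))
  })
  prof <- global_regulation_profile(bands)
  expect_lt(max(abs(prof$up_total + prof$down_total)),
            0.25 * max(prof$up_total))
})

test_that("top genes rank by cumulative absolute per-hour effect", {
  sc <- data.frame(
    gene_id = rep(c("g1", "g2", "g3", "g4", "g5"), each = 2),
    window_label = rep(c("B", "C"), 5),
    auci95_per_hour = c(2, 0,    0.6, 0.7,   -1.4, -1.2,   0.1, 0.1,
                        1.3, -0.4))
  top <- select_top_genes(sc, 3)
  # enumeration oracle: cumulative sums are 2.0, 1.3, 2.6, 0.2, 1.7
  expect_equal(top$gene_id, c("g3", "g1", "g5"))
  expect_equal(top$cumulative_abs_auci_per_hour, c(2.6, 2.0, 1.7))

  all5 <- select_top_genes(sc, 5)
  expect_equal(nrow(all5), 5L)
  expect_equal(all5$gene_id[4:5], c("g2", "g4"))

  # deterministic tie-break by gene id
  tie <- data.frame(gene_id = c("gB", "gA"), window_label = "B",
                    auci95_per_hour = c(1, 1))
  expect_equal(select_top_genes(tie, 2)$gene_id, c("gA", "gB"))
  expect_error(select_top_genes(sc, 9), "exceeds")
})

test_that("pattern clustering recovers planted groups and tree properties", {
  set.seed(62)
  g <- seq(0, 20, length.out = 30)
  up_imp <- exp(-(g - 8)^2 / 8)
  down_sus <- -1 / (1 + exp(-(g - 10) / 2))
  m <- rbind(
    t(replicate(10, up_imp + rnorm(30, 0, 0.1))),
    t(replicate(10, down_sus + rnorm(30, 0, 0.1))))
  rownames(m) <- paste0("g", 1:20)
  cl <- cluster_patterns(m, n_clusters = 2)
  expect_equal(cl$n_clusters, 2L)
  expect_length(unique(cl$assignment[1:10]), 1L)
  expect_length(unique(cl$assignment[11:20]), 1L)
  expect_false(cl$assignment[1] == cl$assignment[11])

  # duplicate rows co-cluster; merge heights never decrease
  m2 <- rbind(m, g1_copy = m[1, ])
  cl2 <- cluster_patterns(m2, n_clusters = 4)
  expect_equal(unname(cl2$assignment["g1_copy"]),
               unname(cl2$assignment["g1"]))
  expect_true(all(diff(cl2$tree$height) >= -1e-12))

  # permutation invariance up to relabelling
  perm <- sample(20)
  cl3 <- cluster_patterns(m[perm, ], n_clusters = 2)
  expect_equal(unname(cl3$assignment[rownames(m)[1:10]] ==
                        cl3$assignment[rownames(m)[1]]), rep(TRUE, 10))

  flat <- matrix(1, 4, 5, dimnames = list(paste0("g", 1:4), NULL))
  expect_error(cluster_patterns(flat, 2), "single cluster")
})

test_that("the pattern matrix concatenates exceedance curves per condition", {
  g <- seq(0, 10, length.out = 5)
  b1 <- const_band(g, 1, 2, gene_id = "g1")
  b2 <- const_band(g, -1, 1, gene_id = "g2")
  c1 <- list(b1, b2)
  c2 <- list(const_band(g, -2, -1, gene_id = "g1"),
             const_band(g, 0.5, 1, gene_id = "g2"))
  m <- effect_pattern_matrix(list(lev1 = c1, lev2 = c2))
  expect_equal(dim(m), c(2L, 10L))
  expect_equal(unname(m["g1", ]), c(rep(1, 5), rep(-1, 5)))
  expect_equal(unname(m["g2", ]), c(rep(0, 5), rep(0.5, 5)))
})
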