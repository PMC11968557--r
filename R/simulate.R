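#' Configuration for the synthetic time-course generator
#'
#' Encodes the study design being emulated: per sampling time point two
#' control replicates and one replicate per treatment concentration level;
#' six sampling time points for the early exposure scenario (from 2 hpf)
#' and ten for the late one (from 24 hpf); gene responses drawn from three
#' archetypes — null (no treatment effect), impulse (transient Gaussian
#' bump that returns to baseline) and sustained (logistic step that
#' persists) — superimposed on a shared smooth developmental baseline.
#' Treatment effects scale with concentration rank so higher levels respond
#' at least as strongly.
#'
#' @param n_genes number of simulated genes.
#' @param scenario `"early"` or `"late"`; sets the default time grid.
#' @param time_points sampling times (hpf); defaults: early
#'   `c(2, 12, 24, 48, 72, 96)`, late `c(24, 30, 36, 42, 48, 54, 60, 72,
#'   84, 96)`.
#' @param treatment_levels treatment concentration levels; defaults: early
#'   `c("C_low", "C_medium")`, late `c("C_medium", "C_high")`.
#' @param n_control_reps control replicates per time point (default 2).
#' @param pattern_mix named fractions for `null`, `impulse`, `sustained`
#'   (must sum to 1).
#' @param magnitude effect magnitude in log2 units at the highest level
#'   (a single value or sampler range `c(min, max)`).
#' @param noise_sd residual noise SD on the log2 scale (default 0.3).
#' @param baseline_sd amplitude of the shared developmental baseline trend.
#' @param count_mode `"gaussian_log2"` (default) or `"negative_binomial"`.
#' @param dispersion NB dispersion (counts mode).
#' @param library_size_range per-sample library-size range (counts mode).
#' @param seed integer seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 100L,
                       scenario = c("late", "early"),
                       time_points = NULL,
                       treatment_levels = NULL,
                       n_control_reps = 2L,
                       pattern_mix = c(null = 0.6, impulse = 0.2,
                                       sustained = 0.2),
                       magnitude = 1,
                       noise_sd = 0.3,
                       baseline_sd = 1,
                       count_mode = c("gaussian_log2", "negative_binomial"),
                       dispersion = 0.05,
                       library_size_range = c(1e6, 2e6),
                       seed = 1L) {
  scenario <- match.arg(scenario)
  count_mode <- match.arg(count_mode)
  if (is.null(time_points))
    time_points <- if (scenario == "early") c(2, 12, 24, 48, 72, 96)
                   else c(24, 30, 36, 42, 48, 54, 60, 72, 84, 96)
  if (is.unsorted(time_points, strictly = TRUE))
    stop("time points must be strictly increasing", call. = FALSE)
  if (is.null(treatment_levels))
    treatment_levels <- if (scenario == "early") c("C_low", "C_medium")
                        else c("C_medium", "C_high")
  if (!all(treatment_levels %in% c("C_low", "C_medium", "C_high")))
    stop("treatment levels must be C_low/C_medium/C_high", call. = FALSE)
  if (!setequal(names(pattern_mix), c("null", "impulse", "sustained")) ||
      abs(sum(pattern_mix) - 1) > 1e-8 || any(pattern_mix < 0))
    stop("pattern_mix must be non-negative fractions over null/impulse/sustained summing to 1",
         call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (count_mode == "negative_binomial" && dispersion <= 0)
    stop("dispersion must be > 0", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes), scenario = scenario,
                 time_points = time_points,
                 treatment_levels = treatment_levels,
                 n_control_reps = as.integer(n_control_reps),
                 pattern_mix = pattern_mix[c("null", "impulse", "sustained")],
                 magnitude = magnitude, noise_sd = noise_sd,
                 baseline_sd = baseline_sd, count_mode = count_mode,
                 dispersion = dispersion,
                 library_size_range = library_size_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Internal: sample layout + truth, shared by both simulators.
sim_truth_and_layout <- function(cfg) {
  tp <- cfg$time_points
  levs <- c("control", cfg$treatment_levels)
  reps <- c(cfg$n_control_reps, rep(1L, length(cfg$treatment_levels)))
  md <- do.call(rbind, lapply(tp, function(t)
    do.call(rbind, lapply(seq_along(levs), function(j)
      data.frame(time_hpf = t, concentration_level = levs[j],
                 replicate = seq_len(reps[j]), stringsAsFactors = FALSE)))))
  md$exposure_start <- cfg$scenario
  md$sample_id <- sprintf("s%03d_%s_t%02d_r%d", seq_len(nrow(md)),
                          md$concentration_level, round(md$time_hpf),
                          md$replicate)
  md <- md[, c("sample_id", "time_hpf", "concentration_level",
               "exposure_start", "replicate")]

  n <- cfg$n_genes
  pat <- sample(names(cfg$pattern_mix), n, replace = TRUE,
                prob = cfg$pattern_mix)
  rng <- range(tp); span <- diff(rng)
  mag <- if (length(cfg$magnitude) == 2L)
    stats::runif(n, cfg$magnitude[1], cfg$magnitude[2])
  else rep(cfg$magnitude, n)
  truth <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n)),
    pattern = pat,
    direction = sample(c("up", "down"), n, replace = TRUE),
    magnitude = ifelse(pat == "null", 0, mag),
    onset_hpf = stats::runif(n, rng[1], rng[1] + 0.6 * span),
    width_h = stats::runif(n, 0.08 * span, 0.2 * span),
    rise_h = stats::runif(n, 0.03 * span, 0.1 * span),
    stringsAsFactors = FALSE)
  list(md = md, truth = truth)
}

# Internal: noise-free log2 signal matrix (genes x samples) for a layout.
sim_signal <- function(cfg, md, truth) {
  tp <- cfg$time_points
  rng <- range(tp)
  n <- nrow(truth)
  # shared developmental baseline per gene: smooth random cubic spline
  bk <- seq(rng[1], rng[2], length.out = 5)
  base_level <- stats::runif(n, 4, 12)
  base_coefs <- matrix(stats::rnorm(n * length(bk), 0, cfg$baseline_sd),
                       nrow = n)
  lev_rank <- stats::setNames(seq_along(cfg$treatment_levels),
                              cfg$treatment_levels)
  scale_of <- function(level) {
    if (level == "control") 0 else lev_rank[[level]] / max(lev_rank)
  }
  effect_at <- function(i, t) {
    tr <- truth[i, ]
    if (tr$pattern == "null") return(rep(0, length(t)))
    sgn <- if (tr$direction == "up") 1 else -1
    core <- switch(tr$pattern,
      impulse = exp(-(t - tr$onset_hpf)^2 / (2 * tr$width_h^2)),
      sustained = 1 / (1 + exp(-(t - tr$onset_hpf) / tr$rise_h)))
    sgn * tr$magnitude * core
  }
  sig <- matrix(0, nrow = n, ncol = nrow(md),
                dimnames = list(truth$gene_id, md$sample_id))
  scales <- vapply(as.character(md$concentration_level), scale_of, numeric(1))
  for (i in seq_len(n)) {
    bfun <- stats::splinefun(bk, base_coefs[i, ], method = "natural")
    sig[i, ] <- base_level[i] + bfun(md$time_hpf) +
      scales * effect_at(i, md$time_hpf)
  }
  sig
}

#' Simulate a log2-scale expression time course
#'
#' Generates the full study layout (see [sim_config()]): per gene a smooth
#' developmental baseline shared across levels, plus a treatment effect —
#' impulse `g * exp(-(t - onset)^2 / 2w^2)` or sustained
#' `g / (1 + exp(-(t - onset)/r))` — scaled in proportion to concentration
#' rank, plus i.i.d. Gaussian noise on the log2 scale.
#'
#' @param cfg a `sim_config` (with `count_mode = "gaussian_log2"`).
#' @return list with `expression` (`expr_matrix`, log2 scale), `metadata`
#'   (data.frame), `truth` (per-gene truth table) and `signal` (the
#'   noise-free log2 matrix).
#' @export
simulate_timecourse <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  lay <- sim_truth_and_layout(cfg)
  sig <- sim_signal(cfg, lay$md, lay$truth)
  vals <- sig + matrix(stats::rnorm(length(sig), 0, cfg$noise_sd),
                       nrow = nrow(sig))
  dimnames(vals) <- dimnames(sig)
  list(expression = expression_matrix(vals, "log2"),
       metadata = lay$md, truth = lay$truth, signal = sig)
}

#' Simulate a negative-binomial count time course
#'
#' Uses the same signal model as [simulate_timecourse()] but emits counts:
#' per sample the noise-free log2 signal is converted to proportions and
#' scaled to a random library size, then counts are drawn from
#' `NB(mean = libsize * 2^signal / sum(2^signal), size = 1/dispersion)`.
#' [log_cpm_transform()] recovers the log2 signal up to sampling noise.
#'
#' @param cfg a `sim_config` with `count_mode = "negative_binomial"`.
#' @return list with `expression` (`expr_matrix`, counts scale),
#'   `metadata`, `truth`, `signal` and `library_sizes`.
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$count_mode != "negative_binomial")
    stop("simulate_counts requires count_mode = 'negative_binomial'",
         call. = FALSE)
  set.seed(cfg$seed)
  lay <- sim_truth_and_layout(cfg)
  sig <- sim_signal(cfg, lay$md, lay$truth)
  lib <- round(stats::runif(ncol(sig), cfg$library_size_range[1],
                            cfg$library_size_range[2]))
  props <- sweep(2^sig, 2L, colSums(2^sig), "/")
  mu <- sweep(props, 2L, lib, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / cfg$dispersion),
                   nrow = nrow(mu), dimnames = dimnames(sig))
  list(expression = expression_matrix(counts, "counts"),
       metadata = lay$md, truth = lay$truth, signal = sig,
       library_sizes = stats::setNames(lib, colnames(sig)))
}

#' Simulate labelled effect scores for cutoff calibration
#'
#' Runs the full fit -> difference band -> AUCI pipeline on simulated
#' matrices for both exposure scenarios and attaches the simulation truth
#' as the label (`pattern != "null"` is `"de"`), emulating a visually
#' labelled calibration curve set: by default 300 curves, 150 per exposure
#' start.
#'
#' @param n_per_scenario genes per exposure scenario (default 150).
#' @param magnitude,noise_sd,pattern_mix passed to [sim_config()].
#' @param n_sim posterior draws per gene.
#' @param seed root seed.
#' @return data.frame with `gene_id`, `scenario`, `score`
#'   (`auci95_per_hour` over the full modelled range) and `label`.
#' @export
simulate_labeled_scores <- function(n_per_scenario = 150L,
                                    magnitude = 1, noise_sd = 0.3,
                                    pattern_mix = c(null = 0.5,
                                                    impulse = 0.25,
                                                    sustained = 0.25),
                                    n_sim = 1000L, seed = 1L) {
  one <- function(scn) {
    scn_seed <- derive_seed(seed, scn)
    cfg <- sim_config(n_genes = n_per_scenario, scenario = scn,
                      pattern_mix = pattern_mix, magnitude = magnitude,
                      noise_sd = noise_sd, seed = scn_seed)
    sim <- simulate_timecourse(cfg)
    fits <- fit_timecourse(sim$expression, sim$metadata)
    lev <- utils::tail(fits$design$levels, 1L)
    rows <- lapply(names(fits$fits), function(g) {
      b <- difference_band(fits$fits[[g]], lev, n_sim = n_sim,
                           seed = derive_seed(scn_seed, g))
      effect_score(b)
    })
    sc <- do.call(rbind, rows)
    pat <- sim$truth$pattern[match(sc$gene_id, sim$truth$gene_id)]
    data.frame(gene_id = sc$gene_id, scenario = scn,
               score = sc$auci95_per_hour,
               label = ifelse(pat == "null", "not_de", "de"),
               stringsAsFactors = FALSE)
  }
  rbind(one("early"), one("late"))
}
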