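#' Default run configuration
#'
#' Materialises every pipeline option with its default so a template can be
#' written, edited and passed to [run_stage()].  The configuration is a
#' plain named list and serialises to YAML.
#'
#' @param output_dir directory for stage artifacts.
#' @return named list of class `run_config`.
#' @export
default_run_config <- function(output_dir = "auci_run") {
  structure(list(
    schema_version = 1L,
    paths = list(expression = NULL, metadata = NULL, gmt = NULL,
                 ortholog_map = NULL, output_dir = output_dir),
    qc = list(enabled = TRUE),
    model = list(k = NULL, lambda_mode = "auto", grid_size = 101L),
    scoring = list(n_sim = 10000L, seed = 1L, cutoff = 0.046,
                   auci_mode = "ci_excess"),
    windows = list(label = "full", start_hpf = NULL, end_hpf = NULL),
    clustering = list(n_clusters = 4L, linkage = "complete"),
    ora = list(min_K = 5L, max_K = 2000L, min_coverage = 0.5,
               alpha = 0.05),
    simulate = list(n_genes = 100L, scenario = "late", noise_sd = 0.3,
                    magnitude = 1,
                    pattern_mix = list(null = 0.6, impulse = 0.2,
                                       sustained = 0.2))
  ), class = "run_config")
}

#' Read a YAML run configuration
#'
#' Missing options fall back to [default_run_config()]; unknown top-level
#' sections are a schema error reported before any computation.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  base <- default_run_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0L)
    stop_listing("unknown config section(s)", unknown)
  for (sec in names(user)) {
    if (is.list(base[[sec]]) && is.list(user[[sec]])) {
      bad <- setdiff(names(user[[sec]]), names(base[[sec]]))
      if (length(bad) > 0L)
        stop_listing(paste0("unknown option(s) in '", sec, "'"), bad)
      base[[sec]][names(user[[sec]])] <- user[[sec]]
    } else base[[sec]] <- user[[sec]]
  }
  validate_run_config(base)
}

# Internal: structural checks that must fail before any computation.
validate_run_config <- function(cfg) {
  if (cfg$scoring$cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  if (cfg$scoring$n_sim < 2) stop("n_sim must be >= 2", call. = FALSE)
  for (p in c("expression", "metadata", "gmt", "ortholog_map")) {
    pth <- cfg$paths[[p]]
    if (!is.null(pth) && !file.exists(pth))
      stop("configured ", p, " path does not exist: ", pth, call. = FALSE)
  }
  cfg
}

#' Write the YAML template of the default configuration
#'
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config_template <- function(path = "auci_config.yaml") {
  yaml::write_yaml(unclass(default_run_config()), path)
  invisible(path)
}

# Internal: write the machine-readable run manifest.
write_manifest <- function(cfg, stage, out_dir, seed) {
  manifest <- list(stage = stage,
                   config_hash = config_hash(unclass(cfg)),
                   seed = seed,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("auci")))
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
}

# Internal: require an upstream artifact, naming the producing stage.
require_artifact <- function(path, producer) {
  if (!file.exists(path))
    stop("missing artifact '", basename(path),
         "': run the '", producer, "' stage first", call. = FALSE)
  path
}

#' Run one pipeline stage (or the whole chain)
#'
#' Stages: `simulate` (write a synthetic study), `qc` (four-metric outlier
#' screen), `fit` (per-gene models), `score` (difference bands + AUCI + DEG
#' calls), `calibrate` (cutoff from labelled synthetic curves), `windows`
#' (per-window scores and DEG sets), `cluster` (pattern clustering), `ora`
#' (overrepresentation), `all` (chains every stage in order).  Each stage
#' writes its artifacts plus a JSON manifest (config hash, seed, versions)
#' under the configured output directory; downstream stages read the
#' upstream artifacts and fail with an actionable message when one is
#' missing.
#'
#' @param cfg a `run_config`.
#' @param stage stage name.
#' @param seed overrides `cfg$scoring$seed` when non-NULL.
#' @param threads worker processes for the fit stage; results are
#'   independent of this value.
#' @return the output directory, invisibly.
#' @export
run_stage <- function(cfg, stage = c("all", "simulate", "qc", "fit", "score",
                                     "calibrate", "windows", "cluster", "ora"),
                      seed = NULL, threads = 1L) {
  stage <- match.arg(stage)
  cfg <- validate_run_config(cfg)
  if (!is.null(seed)) cfg$scoring$seed <- as.integer(seed)
  out <- cfg$paths$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  if (stage == "all") {
    for (s in c("simulate", "qc", "fit", "score", "calibrate", "windows",
                "cluster", "ora"))
      run_stage(cfg, s, threads = threads)
    return(invisible(out))
  }
  root_seed <- cfg$scoring$seed

  if (stage == "simulate") {
    scfg <- sim_config(n_genes = cfg$simulate$n_genes,
                       scenario = cfg$simulate$scenario,
                       noise_sd = cfg$simulate$noise_sd,
                       magnitude = cfg$simulate$magnitude,
                       pattern_mix = unlist(cfg$simulate$pattern_mix),
                       seed = root_seed)
    sim <- simulate_timecourse(scfg)
    write_expression_table(sim$expression, file.path(out, "expression.tsv"))
    utils::write.table(sim$metadata, file.path(out, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$truth, file.path(out, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  expr_path <- cfg$paths$expression %||% file.path(out, "expression.tsv")
  md_path <- cfg$paths$metadata %||% file.path(out, "metadata.tsv")

  if (stage == "qc") {
    x <- read_expression_table(require_artifact(expr_path, "simulate"))
    rep_qc <- qc_flag_outliers(x)
    write_qc_report(rep_qc, out)
    write_expression_table(apply_qc(x, rep_qc),
                           file.path(out, "expression_qc.tsv"))
  }

  if (stage == "fit") {
    qc_path <- file.path(out, "expression_qc.tsv")
    src <- if (cfg$qc$enabled) require_artifact(qc_path, "qc") else
      require_artifact(expr_path, "simulate")
    x <- read_expression_table(src)
    md <- read_sample_metadata(require_artifact(md_path, "simulate"))
    md <- md[md$sample_id %in% colnames(x), , drop = FALSE]
    fits <- fit_timecourse(x, md, k = cfg$model$k,
                           lambda = if (identical(cfg$model$lambda_mode, "auto"))
                             "auto" else cfg$model$lambda_mode,
                           threads = threads)
    saveRDS(fits, file.path(out, "fits.rds"))
    write_fits_json(fits, file.path(out, "fits.json"))
  }

  if (stage %in% c("score", "windows", "cluster")) {
    fits <- readRDS(require_artifact(file.path(out, "fits.rds"), "fit"))
    rngT <- fits$design$basis$range
    grid <- seq(rngT[1], rngT[2], length.out = cfg$model$grid_size)
    trt <- setdiff(fits$design$levels, "control")
    bands <- list()
    for (lev in trt) {
      bands[[lev]] <- lapply(names(fits$fits), function(g)
        difference_band(fits$fits[[g]], lev, grid = grid,
                        n_sim = cfg$scoring$n_sim,
                        seed = derive_seed(root_seed, paste0(g, ":", lev))))
    }
  }

  if (stage == "score") {
    rows <- lapply(unlist(bands, recursive = FALSE), function(b)
      effect_score(b, cutoff = cfg$scoring$cutoff,
                   window_label = "full", mode = cfg$scoring$auci_mode))
    scores <- do.call(rbind, rows)
    utils::write.table(scores, file.path(out, "scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    prof <- global_regulation_profile(bands[[length(bands)]])
    utils::write.table(prof, file.path(out, "global_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (stage == "calibrate") {
    lab <- simulate_labeled_scores(n_per_scenario = 25L,
                                   n_sim = min(cfg$scoring$n_sim, 1000L),
                                   seed = root_seed)
    cal <- calibrate_cutoff(lab$score, lab$label)
    jsonlite::write_json(list(grid = cal$grid, cost = cal$cost,
                              optimum = cal$optimum,
                              min_cost = cal$min_cost),
                         file.path(out, "calibration.json"), digits = NA)
  }

  if (stage == "windows") {
    w <- if (is.null(cfg$windows$start_hpf)) {
      rngT <- fits$design$basis$range
      time_windows("full", rngT[1], rngT[2])
    } else time_windows(cfg$windows$label, cfg$windows$start_hpf,
                        cfg$windows$end_hpf)
    ws <- do.call(rbind, lapply(unlist(bands, recursive = FALSE),
                                function(b) windowed_effects(list(b), w,
                                  cutoff = cfg$scoring$cutoff,
                                  mode = cfg$scoring$auci_mode)))
    utils::write.table(ws, file.path(out, "window_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sets <- deg_sets(ws)
    maxlen <- max(lengths(sets), 1L)
    tab <- as.data.frame(lapply(sets, function(s)
      c(s, rep("", maxlen - length(s)))), check.names = FALSE)
    utils::write.table(tab, file.path(out, "deg_sets.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  if (stage == "cluster") {
    m <- effect_pattern_matrix(bands)
    keep <- rowSums(abs(m)) > 0
    if (sum(keep) >= 2L) {
      cl <- cluster_patterns(m[keep, , drop = FALSE],
                             n_clusters = min(cfg$clustering$n_clusters,
                                              sum(keep)),
                             linkage = cfg$clustering$linkage)
      utils::write.table(data.frame(gene_id = names(cl$assignment),
                                    cluster = cl$assignment),
                         file.path(out, "clusters.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    } else message("cluster stage skipped: fewer than 2 responsive genes")
  }

  if (stage == "ora") {
    sc_path <- require_artifact(file.path(out, "scores.tsv"), "score")
    scores <- utils::read.table(sc_path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    universe <- unique(scores$gene_id)
    query <- unique(scores$gene_id[scores$is_deg])
    if (is.null(cfg$paths$gmt)) {
      message("ora stage skipped: no GMT collection configured")
    } else if (length(query) == 0L) {
      message("ora stage skipped: no DEGs at the active cutoff")
    } else {
      coll <- read_gmt(cfg$paths$gmt)
      if (!is.null(cfg$paths$ortholog_map)) {
        map <- utils::read.table(cfg$paths$ortholog_map, header = TRUE,
                                 sep = "\t", stringsAsFactors = FALSE)
        coll <- map_orthologs(coll, map,
                              min_coverage = cfg$ora$min_coverage)
      }
      res <- run_ora(query, universe, coll, min_K = cfg$ora$min_K,
                     max_K = cfg$ora$max_K, scores = scores,
                     alpha = cfg$ora$alpha)
      utils::write.table(res, file.path(out, "ora.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }

  write_manifest(cfg, stage, out, cfg$scoring$seed)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
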