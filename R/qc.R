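#' Flag outlier samples by four distributional metrics
#'
#' Computes, per sample: (a) the two-sample Kolmogorov-Smirnov statistic of
#' its value distribution against the pooled values of all other samples,
#' (b) the sum of its expression values, (c) the interquartile range of its
#' values, and (d) its mean Euclidean distance to all other samples.  For
#' each metric the acceptance interval is
#' \eqn{[Q_{25} - m \cdot IQR_m,\; Q_{75} + m \cdot IQR_m]} over the
#' per-sample metric values, with multiplier m = 3 for (a)-(c) and m = 1
#' for the Euclidean distance.  A sample outside any interval is flagged;
#' flagged samples populate `removed`.
#'
#' Quantiles use R's default linear-interpolation convention (type 7), so
#' the bounds are bit-reproducible.
#'
#' @param x an `expr_matrix` on the log2 scale with >= 4 samples.
#' @return an object of class `qc_report`: list with `metrics` (per-sample
#'   data.frame), `bounds` (per-metric lower/upper), `flags`
#'   (sample_id/metric pairs) and `removed` (character vector).
#' @export
qc_flag_outliers <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (scale_tag(x) != "log2")
    stop("QC expects log2-scale values", call. = FALSE)
  v <- unclass(x)
  n <- ncol(v)
  if (n < 4L) stop("QC needs >= 4 samples (quantile bounds degenerate)",
                   call. = FALSE)
  ks <- vapply(seq_len(n), function(j) {
    unname(suppressWarnings(
      stats::ks.test(v[, j], as.vector(v[, -j, drop = FALSE]))$statistic))
  }, numeric(1))
  sums <- colSums(v)
  iqrs <- apply(v, 2L, stats::IQR)
  d <- as.matrix(stats::dist(t(v)))
  mean_dist <- rowSums(d) / (n - 1L)

  metrics <- data.frame(
    sample_id = colnames(v),
    ks_statistic = ks,
    expression_sum = sums,
    iqr = iqrs,
    mean_euclidean_distance = mean_dist,
    row.names = NULL
  )
  mult <- c(ks_statistic = 3, expression_sum = 3, iqr = 3,
            mean_euclidean_distance = 1)
  bounds <- do.call(rbind, lapply(names(mult), function(m) {
    q <- stats::quantile(metrics[[m]], c(0.25, 0.75), names = FALSE, type = 7)
    iqr_m <- q[2] - q[1]
    data.frame(metric = m, lower = q[1] - mult[[m]] * iqr_m,
               upper = q[2] + mult[[m]] * iqr_m)
  }))
  flags <- do.call(rbind, lapply(names(mult), function(m) {
    out <- metrics[[m]] < bounds$lower[bounds$metric == m] |
           metrics[[m]] > bounds$upper[bounds$metric == m]
    if (!any(out)) return(NULL)
    data.frame(sample_id = metrics$sample_id[out], metric = m)
  }))
  if (is.null(flags))
    flags <- data.frame(sample_id = character(0), metric = character(0))
  structure(list(metrics = metrics, bounds = bounds, flags = flags,
                 removed = unique(flags$sample_id)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d samples, %d flagged\n",
              nrow(x$metrics), length(x$removed)))
  if (length(x$removed) > 0) {
    cat("removed:", paste(x$removed, collapse = ", "), "\n")
    print(x$flags)
  }
  invisible(x)
}

#' Write a QC report as TSV tables and JSON
#'
#' @param report a `qc_report`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix, default `"qc"`.
#' @return paths of the written files, invisibly.
#' @export
write_qc_report <- function(report, dir, prefix = "qc") {
  stopifnot(inherits(report, "qc_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, paste0(prefix, "_metrics.tsv"))
  utils::write.table(report$metrics, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  js <- file.path(dir, paste0(prefix, "_report.json"))
  jsonlite::write_json(
    list(bounds = report$bounds, flags = report$flags,
         removed = report$removed),
    js, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}

#' Drop flagged samples from an expression matrix
#'
#' @param x an `expr_matrix`.
#' @param report the `qc_report` for `x`.
#' @return `x` without the samples listed in `report$removed`.
#' @export
apply_qc <- function(x, report) {
  stopifnot(inherits(x, "expr_matrix"), inherits(report, "qc_report"))
  keep <- setdiff(colnames(x), report$removed)
  expression_matrix(unclass(x)[, keep, drop = FALSE], scale_tag(x))
}
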