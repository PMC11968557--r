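#' Construct an expression matrix with a declared measurement scale
#'
#' The modelling substrate is a genes-by-samples numeric matrix carrying a
#' scale tag: `"log2"` for log-scale intensities (microarray, or RNA-seq
#' after [log_cpm_transform()]) or `"counts"` for raw RNA-seq counts.
#'
#' @param values numeric matrix, genes in rows, samples in columns; must
#'   have unique, non-empty row and column names.
#' @param scale_tag `"log2"` or `"counts"`. Log-scale values must be finite;
#'   counts must be non-negative integers.
#' @return the matrix with class `expr_matrix` and attribute `scale_tag`.
#' @export
expression_matrix <- function(values, scale_tag = c("log2", "counts")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  gn <- rownames(values); sn <- colnames(values)
  if (is.null(gn) || is.null(sn))
    stop("expression matrix needs gene row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(gn))
    stop_listing("duplicate gene ids", unique(gn[duplicated(gn)]))
  if (anyDuplicated(sn))
    stop_listing("duplicate sample ids", unique(sn[duplicated(sn)]))
  if (scale_tag == "log2") {
    if (!all(is.finite(values)))
      stop("log2-scale expression values must all be finite", call. = FALSE)
  } else {
    if (any(!is.finite(values)) || any(values < 0) ||
        any(abs(values - round(values)) > 1e-8))
      stop("counts must be finite non-negative integers", call. = FALSE)
  }
  structure(values, class = c("expr_matrix", "matrix", "array"),
            scale_tag = scale_tag)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x), ncol(x), attr(x, "scale_tag")))
  invisible(x)
}

#' Scale tag of an expression matrix
#' @param x an `expr_matrix`.
#' @return `"log2"` or `"counts"`.
#' @export
scale_tag <- function(x) attr(x, "scale_tag")

#' Read a delimited gene-by-sample expression table
#'
#' Expects a header row of sample ids and gene ids in the first column.
#' The delimiter is taken from the file extension (`.csv` is comma,
#' anything else tab) unless given explicitly. Parsing uses the decimal
#' point regardless of locale.
#'
#' @param path path to the table.
#' @param scale_tag declared scale of the stored values, see
#'   [expression_matrix()].
#' @param sep field separator; default guesses from the extension.
#' @return an `expr_matrix`.
#' @export
read_expression_table <- function(path, scale_tag = c("log2", "counts"),
                                  sep = NULL) {
  scale_tag <- match.arg(scale_tag)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "")
  if (ncol(raw) < 2L)
    stop("expression table needs a gene-id column plus >= 1 sample column",
         call. = FALSE)
  gene_ids <- raw[[1L]]
  if (anyDuplicated(gene_ids))
    stop_listing("duplicate gene ids in expression table",
                 unique(gene_ids[duplicated(gene_ids)]))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                 vals[bad[1, 1], bad[1, 2]], gene_ids[bad[1, 1]],
                 colnames(vals)[bad[1, 2]]), call. = FALSE)
  dimnames(num) <- list(gene_ids, colnames(vals))
  expression_matrix(num, scale_tag)
}

#' Read a sample metadata table
#'
#' Required columns: `sample_id`, `time_hpf`, `concentration_level`,
#' `exposure_start`, `replicate`. Concentration levels are ordered
#' control < C_low < C_medium < C_high.
#'
#' @param path path to a TSV/CSV metadata table.
#' @param sep field separator; default guesses from the extension.
#' @return a data.frame with validated, typed columns.
#' @export
read_sample_metadata <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  md <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_metadata(md)
}

#' Validate a sample metadata data.frame
#'
#' @param md data.frame with the columns listed in [read_sample_metadata()].
#' @return the validated data.frame with `concentration_level` as an ordered
#'   set of levels (control first).
#' @export
validate_metadata <- function(md) {
  req <- c("sample_id", "time_hpf", "concentration_level",
           "exposure_start", "replicate")
  missing_cols <- setdiff(req, names(md))
  if (length(missing_cols) > 0L)
    stop_listing("metadata is missing required columns", missing_cols)
  if (anyDuplicated(md$sample_id))
    stop_listing("duplicate sample ids in metadata",
                 unique(md$sample_id[duplicated(md$sample_id)]))
  md$time_hpf <- as.numeric(md$time_hpf)
  if (any(!is.finite(md$time_hpf)) || any(md$time_hpf < 0))
    stop("time_hpf must be finite and non-negative", call. = FALSE)
  known <- c("control", "C_low", "C_medium", "C_high")
  bad_lvl <- setdiff(unique(as.character(md$concentration_level)), known)
  if (length(bad_lvl) > 0L)
    stop_listing("unknown concentration levels", bad_lvl)
  md$concentration_level <- factor(as.character(md$concentration_level),
                                   levels = known)
  md$concentration_level <- droplevels(md$concentration_level)
  bad_sc <- setdiff(unique(as.character(md$exposure_start)), c("early", "late"))
  if (length(bad_sc) > 0L)
    stop_listing("exposure_start must be 'early' or 'late'; found", bad_sc)
  md$replicate <- as.integer(md$replicate)
  if (any(is.na(md$replicate)) || any(md$replicate < 1L))
    stop("replicate must be an integer >= 1", call. = FALSE)
  if (!"control" %in% levels(md$concentration_level))
    stop("metadata must contain control samples", call. = FALSE)
  # control must be present at every modelled time point
  tt <- sort(unique(md$time_hpf))
  ctrl_t <- unique(md$time_hpf[md$concentration_level == "control"])
  miss_t <- setdiff(tt, ctrl_t)
  if (length(miss_t) > 0L)
    stop_listing("control samples missing at time points", miss_t)
  md
}

#' Collapse replicate probes to one row per gene
#'
#' Microarray platforms carry several probes per gene; the per-sample
#' median over a gene's probes becomes the gene's value. Probes absent
#' from the map are dropped (count reported via `message()`).
#'
#' @param x an `expr_matrix` whose rows are probe ids.
#' @param probe_to_gene named character vector or two-column data.frame
#'   (`probe_id`, `gene_id`); each probe maps to at most one gene.
#' @return an `expr_matrix` with one row per gene.
#' @export
collapse_replicate_probes <- function(x, probe_to_gene) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.data.frame(probe_to_gene)) {
    map <- stats::setNames(as.character(probe_to_gene[[2L]]),
                           as.character(probe_to_gene[[1L]]))
  } else map <- probe_to_gene
  if (length(map) == 0L) stop("empty probe-to-gene mapping", call. = FALSE)
  if (anyDuplicated(names(map)))
    stop_listing("probes mapping to more than one gene",
                 unique(names(map)[duplicated(names(map))]))
  genes <- map[rownames(x)]
  dropped <- sum(is.na(genes))
  if (dropped > 0L)
    message(dropped, " unmapped probe(s) dropped")
  keep <- !is.na(genes)
  if (!any(keep)) stop("no probes could be mapped to genes", call. = FALSE)
  xm <- unclass(x)[keep, , drop = FALSE]
  by_gene <- split(seq_len(nrow(xm)), genes[keep])
  out <- matrix(NA_real_, nrow = length(by_gene), ncol = ncol(xm),
                dimnames = list(names(by_gene), colnames(xm)))
  for (i in seq_along(by_gene)) {
    idx <- by_gene[[i]]
    out[i, ] <- if (length(idx) == 1L) xm[idx, ] else
      apply(xm[idx, , drop = FALSE], 2L, stats::median)
  }
  expression_matrix(out, scale_tag(x))
}

#' Transform counts to log2 counts per million
#'
#' `log2((count + prior) / (library_size + 2 * prior) * 1e6)` with
#' `library_size` the per-sample column sum. The prior keeps zero counts
#' finite. Precision weights are not computed: downstream time-course
#' models treat transformed counts and array intensities identically.
#'
#' @param x an `expr_matrix` with scale tag `"counts"`.
#' @param prior_count positive offset added to each count (default 0.5).
#' @return an `expr_matrix` with scale tag `"log2"`.
#' @export
log_cpm_transform <- function(x, prior_count = 0.5) {
  stopifnot(inherits(x, "expr_matrix"))
  if (scale_tag(x) != "counts")
    stop("log_cpm_transform expects a counts-scale matrix", call. = FALSE)
  if (!is.numeric(prior_count) || prior_count <= 0)
    stop("prior_count must be > 0", call. = FALSE)
  lib <- colSums(unclass(x))
  zero <- which(lib == 0)
  if (length(zero) > 0L)
    stop_listing("zero library size for sample(s)", colnames(x)[zero])
  out <- log2(sweep(unclass(x) + prior_count, 2L, lib + 2 * prior_count, "/") * 1e6)
  expression_matrix(out, "log2")
}

#' Cyclic loess normalization between samples
#'
#' For each pair of samples a loess trend of M (difference) on A (average)
#' is fitted and half the trend subtracted from each member; all pairs are
#' visited `iterations` times. Delegates to
#' [limma::normalizeCyclicLoess()] with `method = "pairs"`.
#'
#' @param x an `expr_matrix` on the log2 scale with >= 2 samples.
#' @param span loess span in (0, 1], default 0.7.
#' @param iterations number of passes over all sample pairs, default 3.
#' @return the normalized `expr_matrix`.
#' @export
cyclic_loess_normalize <- function(x, span = 0.7, iterations = 3L) {
  stopifnot(inherits(x, "expr_matrix"))
  if (scale_tag(x) != "log2")
    stop("cyclic loess normalization expects log2-scale values", call. = FALSE)
  if (ncol(x) < 2L) stop("need >= 2 samples to normalize", call. = FALSE)
  if (!is.numeric(span) || span <= 0 || span > 1)
    stop("span must be in (0, 1]", call. = FALSE)
  out <- limma::normalizeCyclicLoess(unclass(x), span = span,
                                     iterations = iterations,
                                     method = "pairs")
  dimnames(out) <- dimnames(x)
  expression_matrix(out, "log2")
}

#' Write an expression matrix as a TSV table
#'
#' @param x an `expr_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
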