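#' Read a GMT gene-set collection
#'
#' Standard GMT: one term per line, tab-separated `term_id`, description,
#' then member gene ids.  Duplicate members within a term are deduplicated;
#' duplicate term ids or lines with fewer than three fields are errors.
#'
#' @param path path to a `.gmt` file.
#' @param source_db optional database tag stored with every term.
#' @return object of class `gene_set_collection`: list with `members`
#'   (named list of character vectors), `info` (data.frame `term_id`,
#'   `name`, `source_db`).
#' @export
read_gmt <- function(path, source_db = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("malformed GMT line ", which(nf < 3L)[1L],
         ": fewer than 3 tab-separated fields", call. = FALSE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop_listing("duplicate term ids in GMT", unique(ids[duplicated(ids)]))
  members <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(members) <- ids
  gene_set_collection(members,
                      name = vapply(parts, `[[`, character(1), 2L),
                      source_db = source_db)
}

#' Construct a gene-set collection
#'
#' @param members named list of non-empty character vectors of gene ids.
#' @param name optional term descriptions (default term ids).
#' @param source_db optional database tag(s).
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(members, name = names(members),
                                source_db = NA_character_) {
  if (!is.list(members) || is.null(names(members)) ||
      anyDuplicated(names(members)))
    stop("members must be a uniquely named list", call. = FALSE)
  if (any(lengths(members) == 0L))
    stop_listing("terms with no members",
                 names(members)[lengths(members) == 0L])
  info <- data.frame(term_id = names(members),
                     name = rep_len(name, length(members)),
                     source_db = rep_len(source_db, length(members)),
                     stringsAsFactors = FALSE)
  structure(list(members = members, info = info),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d terms, %d distinct genes\n",
              length(x$members), length(unique(unlist(x$members)))))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(.subset2(x, "members"))

#' Map a gene-set collection through an ortholog table
#'
#' Each term's members are translated through a many-to-many ortholog map
#' (union of targets).  A term's coverage is the fraction of its source
#' members with at least one target; terms with coverage strictly below
#' `min_coverage` are dropped (exactly 50% coverage is retained under the
#' default) and the dropped count is reported.
#'
#' @param collection a `gene_set_collection` (e.g. human gene sets).
#' @param map two-column data.frame `source_gene`, `target_gene` (or a
#'   named character vector source -> target).
#' @param min_coverage minimum retained coverage in (0, 1], default 0.5.
#' @return the mapped `gene_set_collection`.
#' @export
map_orthologs <- function(collection, map, min_coverage = 0.5) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (min_coverage <= 0 || min_coverage > 1)
    stop("min_coverage must be in (0, 1]", call. = FALSE)
  if (is.data.frame(map)) {
    src <- as.character(map[[1L]]); tgt <- as.character(map[[2L]])
  } else {
    src <- names(map); tgt <- as.character(map)
  }
  if (length(src) == 0L) stop("empty ortholog map", call. = FALSE)
  pairs <- unique(data.frame(src = src, tgt = tgt, stringsAsFactors = FALSE))
  by_src <- split(pairs$tgt, pairs$src)
  mapped <- lapply(collection$members, function(m) {
    hits <- m %in% names(by_src)
    list(coverage = mean(hits),
         members = unique(unlist(by_src[m[hits]], use.names = FALSE)))
  })
  cov <- vapply(mapped, `[[`, numeric(1), "coverage")
  keep <- cov >= min_coverage
  if (any(!keep))
    message(sum(!keep), " term(s) dropped: ortholog coverage below ",
            min_coverage)
  if (!any(keep)) stop("no terms survive the coverage filter", call. = FALSE)
  gene_set_collection(lapply(mapped[keep], `[[`, "members"),
                      name = collection$info$name[keep],
                      source_db = collection$info$source_db[keep])
}

#' Benjamini-Hochberg adjustment
#'
#' Thin validated wrapper around [stats::p.adjust()] with `method = "BH"`:
#' \eqn{padj_{(i)} = \min_{j \ge i} \min(1, m\,p_{(j)}/j)}, order restored.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric overrepresentation analysis
#'
#' For each term, with universe size N, effective term size
#' K = |members ∩ universe|, query size n and overlap k, the upper-tail
#' probability \eqn{p = \sum_{i=k}^{\min(K,n)} \binom{K}{i}
#' \binom{N-K}{n-i} / \binom{N}{n}} asks how likely at least k of the
#' term's genes land in the query by chance.  P-values are BH-adjusted over
#' the tested terms; `significant` means `padj < 0.05`.  Terms whose
#' effective size falls outside `[min_K, max_K]` are skipped.
#'
#' When a score table is supplied, each term's `direction` is the median
#' `auci95_per_hour` over its overlapping query genes (`NA`, not 0, when no
#' overlapping gene carries a score); the median of an even-sized set is
#' the mean of the two central values.
#'
#' @param query character vector of DEG ids; must be a subset of `universe`.
#' @param universe character vector of all scored genes.
#' @param collection a `gene_set_collection`.
#' @param min_K,max_K effective term-size bounds (defaults 5 and 2000).
#' @param scores optional score table with `gene_id` and
#'   `auci95_per_hour` columns for the direction summary.
#' @param alpha significance level on the adjusted p-value, default 0.05.
#' @return data.frame of class `ora_result`: `term_id`, `name`,
#'   `source_db`, `k`, `K`, `n`, `N`, `p`, `padj`, `direction`,
#'   `significant`, ordered by `p`.
#' @export
run_ora <- function(query, universe, collection, min_K = 5L, max_K = 2000L,
                    scores = NULL, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(query); universe <- unique(universe)
  extra <- setdiff(query, universe)
  if (length(extra) > 0L)
    stop_listing("query genes missing from the universe", extra)
  if (min_K < 1L) stop("min_K must be >= 1", call. = FALSE)
  N <- length(universe); n <- length(query)
  rows <- lapply(seq_along(collection$members), function(i) {
    mem <- intersect(collection$members[[i]], universe)
    K <- length(mem)
    if (K < min_K || K > max_K) return(NULL)
    ov <- intersect(mem, query)
    k <- length(ov)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    dir <- NA_real_
    if (!is.null(scores)) {
      sc <- scores$auci95_per_hour[scores$gene_id %in% ov]
      if (length(sc) > 0L) dir <- stats::median(sc)
    }
    data.frame(term_id = collection$info$term_id[i],
               name = collection$info$name[i],
               source_db = collection$info$source_db[i],
               k = k, K = K, n = n, N = N, p = p, direction = dir,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    stop("no terms within the [min_K, max_K] size bounds", call. = FALSE)
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  out$significant <- out$padj < alpha
  out <- out[order(out$p, out$term_id), ]
  rownames(out) <- NULL
  class(out) <- c("ora_result", "data.frame")
  out
}

#' Median effect direction of a term's scored genes
#'
#' @param term_genes member gene ids of the term.
#' @param scores score table with `gene_id` and `auci95_per_hour`.
#' @return median `auci95_per_hour` over the overlap, or `NA` if no member
#'   is scored.
#' @export
term_direction <- function(term_genes, scores) {
  sc <- scores$auci95_per_hour[scores$gene_id %in% term_genes]
  if (length(sc) == 0L) return(NA_real_)
  stats::median(sc)
}
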