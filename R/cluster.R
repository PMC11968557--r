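#' Concatenated effect-pattern matrix for clustering
#'
#' Builds, per gene, the concatenation of its AUCI-contribution curves
#' (the CI-exceedance bound: `lo95` where positive, `hi95` where negative,
#' else 0) across all supplied conditions — the substrate of the modelled
#' differential-expression heatmap.
#'
#' @param band_groups named list of conditions; each element a list of
#'   `difference_band`s covering the same genes on one grid.
#' @return numeric matrix, genes x (grid points x conditions).
#' @export
effect_pattern_matrix <- function(band_groups) {
  stopifnot(is.list(band_groups), length(band_groups) >= 1L)
  if (!is.list(band_groups[[1L]]) || inherits(band_groups[[1L]], "difference_band"))
    band_groups <- list(condition = band_groups)
  genes <- vapply(band_groups[[1L]], `[[`, character(1), "gene_id")
  blocks <- lapply(band_groups, function(bands) {
    g2 <- vapply(bands, `[[`, character(1), "gene_id")
    if (!setequal(g2, genes))
      stop("all conditions must cover the same genes", call. = FALSE)
    bands <- bands[match(genes, g2)]
    t(vapply(bands, function(b)
      ifelse(b$lo95 > 0, b$lo95, ifelse(b$hi95 < 0, b$hi95, 0)),
      numeric(length(bands[[1L]]$grid))))
  })
  m <- do.call(cbind, blocks)
  rownames(m) <- genes
  m
}

#' Hierarchical clustering of expression-response patterns
#'
#' Agglomerative clustering of a genes-by-features pattern matrix using
#' Euclidean distance (via [stats::dist()] and [stats::hclust()]); the tree
#' is cut either into `n_clusters` groups or at height `h`.
#'
#' @param m numeric matrix, genes in rows; no missing values.
#' @param n_clusters number of clusters (>= 2); ignored when `h` is given.
#' @param h optional dendrogram cut height.
#' @param linkage agglomeration method, default `"complete"`.
#' @return object of class `pattern_clusters`: list with `assignment`
#'   (named integer vector), `tree` (the `hclust` object), `n_clusters`,
#'   `metric`, `linkage`, `cut_height`.
#' @export
cluster_patterns <- function(m, n_clusters = NULL, h = NULL,
                             linkage = "complete") {
  if (any(!is.finite(m))) stop("pattern matrix has missing values", call. = FALSE)
  if (nrow(m) < 2L) stop("need >= 2 genes to cluster", call. = FALSE)
  d <- stats::dist(m, method = "euclidean")
  if (all(d == 0))
    stop("all pairwise distances are zero: only a single cluster exists",
         call. = FALSE)
  tree <- stats::hclust(d, method = linkage)
  if (is.null(h)) {
    if (is.null(n_clusters) || n_clusters < 2L)
      stop("give n_clusters >= 2 or a cut height h", call. = FALSE)
    assignment <- stats::cutree(tree, k = n_clusters)
    # height at which cutting reproduces this k-cluster assignment
    hts <- sort(tree$height, decreasing = TRUE)
    cut_height <- if (n_clusters <= length(hts))
      mean(c(hts[n_clusters - 1L],
             if (n_clusters > 1L) hts[n_clusters - 1L] else 0)) else 0
    cut_height <- if (n_clusters - 1L <= length(hts))
      hts[n_clusters - 1L] * (1 - 1e-9) else 0
  } else {
    assignment <- stats::cutree(tree, h = h)
    cut_height <- h
  }
  structure(list(assignment = assignment, tree = tree,
                 n_clusters = length(unique(assignment)),
                 metric = "euclidean", linkage = linkage,
                 cut_height = cut_height),
            class = "pattern_clusters")
}

#' @export
print.pattern_clusters <- function(x, ...) {
  cat(sprintf("<pattern_clusters> %d genes in %d clusters (%s linkage, %s distance)\n",
              length(x$assignment), x$n_clusters, x$linkage, x$metric))
  print(table(cluster = x$assignment))
  invisible(x)
}

#' Plot the clustering dendrogram
#' @param x a `pattern_clusters`.
#' @param ... passed to [plot()] for `hclust`.
#' @export
plot.pattern_clusters <- function(x, ...) {
  graphics::plot(x$tree, labels = FALSE, main = "response-pattern clustering",
                 xlab = "", sub = "", ...)
  if (is.finite(x$cut_height) && x$cut_height > 0)
    graphics::abline(h = x$cut_height, col = "red3", lty = 2)
  invisible(x)
}
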