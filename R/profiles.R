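#' Z-score stage profiles
#'
#' Standardizes each gene's stage means to mean 0, sd 1 across stages,
#' using the population standard deviation (n denominator — with only
#' three stages the sample sd would discard a third of the information;
#' either convention is defensible and this one is fixed here). Genes with
#' zero variance across stages carry no profile shape and are excluded.
#'
#' @param stage_means Gene x stage numeric matrix (e.g. mean
#'   log2-normalized expression per stage).
#' @return List with `z` (the standardized matrix, zero-variance genes
#'   dropped) and `excluded` (their gene ids).
#' @export
zscore_stage_profile <- function(stage_means) {
  stage_means <- as.matrix(stage_means)
  if (ncol(stage_means) < 2) abort("need at least two stages.")
  m <- rowMeans(stage_means)
  s <- sqrt(rowMeans((stage_means - m)^2))
  keep <- s > 0
  z <- (stage_means[keep, , drop = FALSE] - m[keep]) / s[keep]
  list(z = z, excluded = rownames(stage_means)[!keep] %||% which(!keep))
}

#' K-means clustering of expression profiles
#'
#' Partitions Z-scored stage profiles into `k` clusters (default 12, the
#' number of spermatogenic expression profiles established for these
#' transcriptomes) by best-of-restarts k-means. A seed is required; given
#' (seed, n_restarts) the result is reproducible.
#'
#' @param z Gene x stage matrix of Z-scored profiles (see
#'   [zscore_stage_profile()]).
#' @param k Number of clusters (default 12).
#' @param seed Integer seed (mandatory).
#' @param n_restarts Random restarts; the solution with the lowest
#'   within-cluster sum of squares wins (default 50).
#' @return An object of class `msci_clusters` with `labels` (tibble
#'   `gene_id`, `cluster`), `centroids` (k x stage matrix), `proportions`,
#'   `wcss`, `k`, `seed`. [generics::tidy()] returns the label table,
#'   [generics::glance()] a one-row fit summary.
#' @export
kmeans_profiles <- function(z, k = 12, seed, n_restarts = 50) {
  if (missing(seed)) abort("`seed` is mandatory for kmeans_profiles().")
  z <- as.matrix(z)
  if (k < 2) abort("`k` must be >= 2.")
  if (nrow(z) < k) abort("fewer profiles than clusters.")
  fit <- withr::with_seed(as.integer(seed),
                          kmeans(z, centers = k, nstart = n_restarts,
                                 iter.max = 100))
  structure(
    list(
      labels = tibble(gene_id = rownames(z) %||% as.character(seq_len(nrow(z))),
                      cluster = unname(fit$cluster)),
      centroids = fit$centers,
      proportions = as.numeric(table(factor(fit$cluster, levels = seq_len(k)))) / nrow(z),
      wcss = fit$tot.withinss,
      k = k, seed = as.integer(seed)
    ),
    class = "msci_clusters"
  )
}

#' @export
print.msci_clusters <- function(x, ...) {
  cat("<msci_clusters> k = ", x$k, ", ", nrow(x$labels),
      " profiles, total WCSS = ", signif(x$wcss, 6), "\n", sep = "")
  invisible(x)
}

#' @rdname kmeans_profiles
#' @param x An `msci_clusters` object.
#' @param ... Unused.
#' @method tidy msci_clusters
#' @export
tidy.msci_clusters <- function(x, ...) x$labels

#' @rdname kmeans_profiles
#' @method glance msci_clusters
#' @export
glance.msci_clusters <- function(x, ...) {
  tibble(k = x$k, n_profiles = nrow(x$labels), wcss = x$wcss, seed = x$seed)
}

#' Pearson correlation of two samples on the log2 scale
#'
#' @param x,y Equal-length non-negative expression vectors (>= 3 genes).
#' @param pseudocount Added before log2 (default 1).
#' @return Pearson r, or NA (with a warning) if either log-vector has zero
#'   variance.
#' @export
pearson_log2 <- function(x, y, pseudocount = 1) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("need equal-length vectors with at least 3 genes.")
  }
  lx <- log2(x + pseudocount)
  ly <- log2(y + pseudocount)
  if (sd(lx) == 0 || sd(ly) == 0) {
    warn("zero variance on the log2 scale; correlation undefined.")
    return(NA_real_)
  }
  cor(lx, ly)
}

#' All pairwise log2 Pearson correlations between samples
#'
#' @param dataset An `expression_dataset`.
#' @param unit `"counts"` or `"tpm"`.
#' @param pseudocount Added before log2.
#' @return Tidy tibble: `sample_a`, `sample_b`, `r`.
#' @export
sample_correlations <- function(dataset, unit = c("counts", "tpm"),
                                pseudocount = 1) {
  unit <- match.arg(unit)
  mat <- if (unit == "tpm") dataset$tpm else dataset$counts
  ids <- colnames(mat)
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    tibble(sample_a = pr[1], sample_b = pr[2],
           r = pearson_log2(mat[, pr[1]], mat[, pr[2]], pseudocount))
  })
}

#' Sample-level PCA of log2 expression
#'
#' Principal component analysis of samples over shared genes on
#' log2(value + pseudocount), centered per gene. Used as a QC view: with
#' stage effects dominating, samples separate by spermatogenesis stage
#' along the leading component.
#'
#' @param dataset An `expression_dataset` (or a gene x sample matrix).
#' @param unit `"counts"` or `"tpm"` when a dataset is given.
#' @param pseudocount Added before log2.
#' @param scale. Scale genes to unit variance (default FALSE).
#' @return List with `coordinates` (tibble: `sample_id`, sample metadata if
#'   available, `PC1`, `PC2`, ...) and `variance_explained` (non-increasing
#'   fractions summing to <= 1).
#' @export
pca_samples <- function(dataset, unit = c("counts", "tpm"), pseudocount = 1,
                        scale. = FALSE) {
  unit <- match.arg(unit)
  mat <- if (inherits(dataset, "expression_dataset")) {
    if (unit == "tpm") dataset$tpm else dataset$counts
  } else {
    as.matrix(dataset)
  }
  if (ncol(mat) < 3) abort("need at least 3 samples.")
  lm2 <- t(log2(mat + pseudocount))
  keep <- apply(lm2, 2, sd) > 0
  if (!any(keep)) abort("constant expression matrix; PCA undefined.")
  fit <- prcomp(lm2[, keep, drop = FALSE], center = TRUE, scale. = scale.)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  coords <- as_tibble(fit$x, rownames = "sample_id")
  if (inherits(dataset, "expression_dataset")) {
    coords <- left_join(coords, dataset$samples, by = "sample_id") %>%
      select("sample_id", "species", "stage", "replicate", dplyr::everything())
  }
  list(coordinates = coords, variance_explained = ve)
}
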