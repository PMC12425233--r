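row_vars <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1)
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes of
#' the ratio of that sample's count to the gene's geometric mean across
#' samples. Genes with a zero count in any sample are excluded from the
#' median (their geometric mean reference is degenerate).
#'
#' @param counts Gene x sample count matrix.
#' @param pseudo_reference If no gene is nonzero in every sample, setting
#'   this to `TRUE` computes each gene's geometric mean over its positive
#'   counts only (a pseudo-reference), using genes expressed in at least
#'   half the samples.
#' @return Named numeric vector of positive per-sample factors.
#' @export
#' @examples
#' compute_size_factors(cbind(s1 = c(4, 1), s2 = c(16, 4)))
compute_size_factors <- function(counts, pseudo_reference = FALSE) {
  counts <- as.matrix(counts)
  usable <- rowSums(counts == 0) == 0
  if (!any(usable)) {
    if (!pseudo_reference) {
      abort(paste0("no gene has nonzero counts in every sample; rerun with ",
                   "pseudo_reference = TRUE to use a positive-count pseudo-reference."))
    }
    usable <- rowSums(counts > 0) >= ncol(counts) / 2
    if (!any(usable)) abort("no gene expressed in at least half the samples.")
    geo <- apply(counts[usable, , drop = FALSE], 1,
                 function(r) exp(mean(log(r[r > 0]))))
  } else {
    geo <- exp(rowMeans(log(counts[usable, , drop = FALSE])))
  }
  ratios <- counts[usable, , drop = FALSE] / geo
  sf <- apply(ratios, 2, function(r) median(r[r > 0]))
  if (any(!is.finite(sf)) || any(sf <= 0)) abort("degenerate size factors.")
  sf
}

#' Transcripts per million from counts and gene lengths
#'
#' `tpm[g, j] = (c[g, j] / L[g]) / sum_h (c[h, j] / L[h]) * 1e6`; every
#' column sums to one million.
#'
#' @param counts Gene x sample count matrix.
#' @param lengths Positive gene lengths in bp, named by gene or in row
#'   order.
#' @return TPM matrix with the dimensions and dimnames of `counts`.
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    lengths <- lengths[rownames(counts)]
  }
  if (any(is.na(lengths)) || any(lengths <= 0)) abort("gene lengths must be > 0.")
  rate <- counts / lengths
  denom <- colSums(rate)
  if (any(denom == 0)) abort("all-zero sample column; TPM undefined.")
  sweep(rate, 2, denom, "/") * 1e6
}

#' Method-of-moments NB dispersion per gene
#'
#' On size-factor-normalized counts, within each replicate group with at
#' least two samples, `alpha = (s^2 - m) / m^2` (the NB relation
#' Var = mu + alpha mu^2 solved for alpha), floored at `alpha_floor`;
#' per-group estimates are combined by a degrees-of-freedom-weighted mean.
#' Genes with zero mean in every group get `NA` (untested downstream).
#'
#' @param counts Gene x sample count matrix.
#' @param size_factors Per-sample factors, as from [compute_size_factors()].
#' @param groups Character/factor of length `ncol(counts)` giving replicate
#'   groups (e.g. stages).
#' @param alpha_floor Lower bound for the dispersion (default 1e-8).
#' @return Named numeric vector of per-gene dispersions (NA where
#'   undefined).
#' @export
estimate_dispersions <- function(counts, size_factors, groups, alpha_floor = 1e-8) {
  counts <- as.matrix(counts)
  norm <- sweep(counts, 2, size_factors, "/")
  groups <- as.character(groups)
  num <- rep(0, nrow(counts))
  den <- rep(0, nrow(counts))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    sub <- norm[, idx, drop = FALSE]
    m <- rowMeans(sub)
    s2 <- row_vars(sub)
    a <- ifelse(m > 0, pmax(alpha_floor, (s2 - m) / m^2), NA_real_)
    df <- length(idx) - 1
    ok <- !is.na(a)
    num[ok] <- num[ok] + df * a[ok]
    den[ok] <- den[ok] + df
  }
  if (all(den == 0)) abort("need >= 2 replicates in at least one group.")
  out <- ifelse(den > 0, num / den, NA_real_)
  names(out) <- rownames(counts)
  out
}

#' Two-group negative binomial Wald test
#'
#' Fits, per gene, the NB GLM `log mu = log(size_factor) + b0 + b1 *
#' I(sample in group B)` at fixed dispersion by iteratively reweighted
#' least squares (Fisher scoring), and tests `b1 = 0` with a Wald statistic
#' whose standard error comes from the observed information at the MLE.
#' Group B is the contrast numerator, so `log2fc > 0` means higher in B.
#' Genes whose mean normalized count across the contrast's samples falls
#' below `min_mean` are reported `tested = FALSE` with missing statistics
#' (the independent expression filter), as are all-zero genes.
#'
#' @param counts Gene x sample count matrix.
#' @param size_factors Per-sample positive factors.
#' @param dispersions Per-gene NB dispersion alpha (NA genes are skipped).
#' @param group_a,group_b Column names (or indices) of the denominator and
#'   numerator samples.
#' @param min_mean Independent filter threshold on the mean normalized
#'   count (default 1).
#' @param tol,max_iter IRLS convergence tolerance on coefficients and
#'   iteration cap.
#' @return Tibble: `gene_id`, `base_mean`, `log2fc`, `se`, `stat`,
#'   `wald_p`, `tested`, `converged`.
#' @export
wald_stage_contrast <- function(counts, size_factors, dispersions,
                                group_a, group_b,
                                min_mean = 1, tol = 1e-8, max_iter = 100) {
  counts <- as.matrix(counts)
  if (length(group_a) == 0 || length(group_b) == 0) abort("both groups must be non-empty.")
  cols <- c(group_a, group_b)
  y <- counts[, cols, drop = FALSE]
  sf <- size_factors[cols]
  is_b <- c(rep(FALSE, length(group_a)), rep(TRUE, length(group_b)))
  off <- matrix(log(sf), nrow(y), ncol(y), byrow = TRUE)
  alpha <- pmax(dispersions, 0)

  norm <- sweep(y, 2, sf, "/")
  base_mean <- rowMeans(norm)
  tested <- base_mean >= min_mean & rowSums(y) > 0 & !is.na(alpha)

  g <- which(tested)
  res <- tibble(
    gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    base_mean = base_mean,
    log2fc = NA_real_, se = NA_real_, stat = NA_real_, wald_p = NA_real_,
    tested = tested, converged = NA
  )
  if (length(g) == 0) return(res)

  ys <- y[g, , drop = FALSE]
  offs <- off[g, , drop = FALSE]
  a <- alpha[g]
  mu_a <- rowMeans(norm[g, !is_b, drop = FALSE])
  mu_b <- rowMeans(norm[g, is_b, drop = FALSE])
  b0 <- log(mu_a + 0.1)
  b1 <- log(mu_b + 0.1) - log(mu_a + 0.1)
  xb <- matrix(as.numeric(is_b), length(g), ncol(y), byrow = TRUE)

  converged <- rep(FALSE, length(g))
  for (it in seq_len(max_iter)) {
    eta <- b0 + b1 * xb + offs
    mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
    w <- mu / (1 + a * mu)
    z <- (eta - offs) + (ys - mu) / mu
    sw <- rowSums(w)
    swb <- rowSums(w * xb)
    swz <- rowSums(w * z)
    swbz <- rowSums(w * xb * z)
    det <- sw * swb - swb^2          # design is 0/1 so Swxx = Swx
    det[det < 1e-300] <- 1e-300
    b1_new <- (sw * swbz - swb * swz) / det
    b0_new <- (swz - swb * b1_new) / sw
    b1_new <- pmin(pmax(b1_new, -50), 50)
    b0_new <- pmin(pmax(b0_new, -50), 50)
    delta <- pmax(abs(b1_new - b1), abs(b0_new - b0))
    b0 <- b0_new
    b1 <- b1_new
    converged <- converged | delta < tol
    if (all(delta < tol)) break
  }

  # observed information at the MLE
  eta <- b0 + b1 * xb + offs
  mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
  wobs <- mu * (1 + a * ys) / (1 + a * mu)^2
  i11 <- rowSums(wobs)
  i12 <- rowSums(wobs * xb)
  i22 <- i12                         # x in {0,1}
  detI <- pmax(i11 * i22 - i12^2, 1e-300)
  var_b1 <- i11 / detI
  se <- sqrt(var_b1)
  stat <- b1 / se
  p <- 2 * pnorm(-abs(stat))
  p[!converged] <- NA_real_

  res$log2fc[g] <- b1 / log(2)
  res$se[g] <- se / log(2)
  res$stat[g] <- stat
  res$wald_p[g] <- p
  res$converged[g] <- converged
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts p-values for false discovery rate control. Missing p-values
#' (untested genes) are passed through and do not count toward the number
#' of tests.
#'
#' @param p Numeric p-values in \[0, 1\], NA allowed.
#' @return Adjusted q-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1].")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Classify genes as down, up, unchanged or untested
#'
#' Down means significantly lower in the contrast's numerator stage
#' (`q < q_threshold` and `log2fc < 0`); up the opposite; genes excluded by
#' the expression filter stay untested.
#'
#' @param results Tibble with `log2fc`, `q`, `tested` columns (as produced
#'   within [de_contrast()]).
#' @param q_threshold FDR threshold (default 0.05).
#' @return The tibble with a `class` column.
#' @export
classify_genes <- function(results, q_threshold = 0.05) {
  results %>% mutate(class = dplyr::case_when(
    !.data$tested | is.na(.data$q) ~ "untested",
    .data$q < q_threshold & .data$log2fc < 0 ~ "down",
    .data$q < q_threshold & .data$log2fc > 0 ~ "up",
    TRUE ~ "unchanged"
  ))
}

#' Differential expression between two spermatogenesis stages
#'
#' End-to-end stage contrast on an [expression_dataset()]: median-of-ratios
#' normalization over all samples, per-gene moment dispersions pooled
#' across stages, the NB Wald test for numerator vs denominator, BH
#' adjustment, and down/up/unchanged classification.
#'
#' @param dataset An `expression_dataset`.
#' @param numerator,denominator Stage names; `log2fc > 0` means higher in
#'   the numerator (default meiosis vs mitosis, the MSCI contrast).
#' @param q_threshold FDR threshold for the classes (default 0.05).
#' @param min_mean Independent expression filter (mean normalized count).
#' @param alpha_floor Dispersion floor.
#' @return An object of class `msci_de`; use [generics::tidy()] for the
#'   per-gene table and [generics::glance()] for a one-row summary.
#' @export
#' @examples
#' sim <- simulate_experiment(simulation_config(
#'   seed = 7, n_genes = c(X = 60, Autosome = 240)))
#' fit <- de_contrast(sim$dataset)
#' glance(fit)
de_contrast <- function(dataset, numerator = "meiosis", denominator = "mitosis",
                        q_threshold = 0.05, min_mean = 1, alpha_floor = 1e-8) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!all(c(numerator, denominator) %in% dataset$samples$stage)) {
    abort("both contrast stages must be present in the sample sheet.")
  }
  sf <- compute_size_factors(dataset$counts)
  disp <- estimate_dispersions(dataset$counts, sf, dataset$samples$stage,
                               alpha_floor = alpha_floor)
  cols_a <- dataset$samples$sample_id[dataset$samples$stage == denominator]
  cols_b <- dataset$samples$sample_id[dataset$samples$stage == numerator]
  res <- wald_stage_contrast(dataset$counts, sf, disp, cols_a, cols_b,
                             min_mean = min_mean)
  res$q <- bh_adjust(res$wald_p)
  res <- classify_genes(res, q_threshold)
  res$contrast <- paste0(numerator, ":", denominator)
  structure(
    list(results = res %>%
           select("gene_id", "contrast", "base_mean", "log2fc", "se", "stat",
                  "wald_p", "q", "class", "tested", "converged"),
         numerator = numerator, denominator = denominator,
         q_threshold = q_threshold, size_factors = sf, dispersions = disp),
    class = "msci_de"
  )
}

#' @export
print.msci_de <- function(x, ...) {
  cat("<msci_de> ", x$numerator, " vs ", x$denominator, ": ",
      sum(x$results$class == "down"), " down, ",
      sum(x$results$class == "up"), " up of ",
      sum(x$results$tested), " tested (q < ", x$q_threshold, ")\n", sep = "")
  invisible(x)
}

#' @rdname de_contrast
#' @param x An `msci_de` object.
#' @param ... Unused.
#' @method tidy msci_de
#' @export
tidy.msci_de <- function(x, ...) x$results

#' @rdname de_contrast
#' @method glance msci_de
#' @export
glance.msci_de <- function(x, ...) {
  tibble(
    contrast = paste0(x$numerator, ":", x$denominator),
    n_genes = nrow(x$results),
    n_tested = sum(x$results$tested),
    n_down = sum(x$results$class == "down"),
    n_up = sum(x$results$class == "up"),
    q_threshold = x$q_threshold
  )
}
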