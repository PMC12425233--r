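#' Fraction of genes strictly above an expression threshold
#'
#' @param expr Non-negative per-gene expression values (TPM).
#' @param t Threshold; the comparison is strict (`> t`), matching the
#'   threshold set 0, 2, 10 used throughout.
#' @return Fraction in \[0, 1\].
#' @export
fraction_above <- function(expr, t) {
  if (length(expr) == 0) abort("empty expression vector.")
  mean(expr > t)
}

#' Select the top-expressed fraction of a gene set
#'
#' Picks the `k = floor(f * n + 1e-9)` (at least 1) highest-expressed
#' genes. Ties at the selection boundary are broken by the stable input
#' order, so results are deterministic for id-sorted input; the small
#' epsilon makes `f` values that are exact multiples of `1/n` recover
#' exactly `f * n` genes despite floating-point representation.
#'
#' @param expr Expression values.
#' @param f Fraction in (0, 1].
#' @return The selected values (in decreasing order of expression).
#' @export
select_top_fraction <- function(expr, f) {
  if (f <= 0 || f > 1) abort("`f` must lie in (0, 1].")
  n <- length(expr)
  if (n == 0) abort("empty expression vector.")
  k <- max(1L, as.integer(floor(f * n + 1e-9)))
  ord <- order(-expr, seq_len(n))   # stable: earlier genes win ties
  expr[ord[seq_len(k)]]
}

.xaa_one <- function(num_expr, a_expr, t, f, num_class, method) {
  if (method == "by_fraction") {
    top_num <- select_top_fraction(num_expr, f)
    top_den <- select_top_fraction(a_expr, f)
  } else {
    top_num <- num_expr[num_expr > t]
    top_den <- a_expr[a_expr > t]
  }
  tibble(
    method = method, threshold = t, numerator_class = num_class,
    f_used = if (method == "by_fraction") f else NA_real_,
    n_top_num = length(top_num), n_top_den = length(top_den),
    ratio = median(top_num) / median(top_den)
  )
}

#' Matched-fraction (filter-by-fraction) X:AA expression ratio
#'
#' Computes the fraction of X-linked and autosomal genes strictly above the
#' TPM threshold, takes the smaller fraction, extracts that top-expressed
#' fraction from both classes, and divides the median of the top X genes by
#' the median of the top autosomal genes. Comparing equally sized
#' top-expressed fractions avoids the inflation of X:AA estimates that
#' plain median ratios suffer when the X has fewer lowly expressed genes.
#' With a neo-X vector supplied, the common fraction is the smallest among
#' X, neo-X and autosomes, and both X:AA and NeoX:AA are returned.
#'
#' @param x_expr,a_expr TPM values for X-linked and autosomal genes.
#' @param t TPM threshold (strict).
#' @param neox_expr Optional TPM values for neo-X genes.
#' @return Tibble with one row per numerator class: `method`, `threshold`,
#'   `numerator_class`, `f_used`, `n_top_num`, `n_top_den`, `ratio`
#'   (NA with zero rows marked undefined when a class has nothing above
#'   `t`).
#' @export
#' @examples
#' xaa_filter_by_fraction(c(1, 2, 3, 4, 10), 1:10, t = 2)
xaa_filter_by_fraction <- function(x_expr, a_expr, t, neox_expr = NULL) {
  fracs <- c(X = fraction_above(x_expr, t), Autosome = fraction_above(a_expr, t))
  if (!is.null(neox_expr)) fracs <- c(fracs, NeoX = fraction_above(neox_expr, t))
  f <- min(fracs)
  num <- list(X = x_expr)
  if (!is.null(neox_expr)) num$NeoX <- neox_expr
  purrr::imap_dfr(num, function(expr, cls) {
    if (f == 0) {
      return(tibble(method = "by_fraction", threshold = t, numerator_class = cls,
                    f_used = NA_real_, n_top_num = 0L, n_top_den = 0L,
                    ratio = NA_real_))
    }
    .xaa_one(expr, a_expr, t, f, cls, "by_fraction")
  })
}

#' Simple-threshold X:AA expression ratio
#'
#' The ratio of the median of X-linked values strictly above `t` to the
#' median of autosomal values strictly above `t`, with no fraction
#' matching. At `t = 0` this reduces to the ratio of medians over expressed
#' genes.
#'
#' @inheritParams xaa_filter_by_fraction
#' @return Tibble in the same shape as [xaa_filter_by_fraction()] with
#'   `method = "by_expression"`.
#' @export
xaa_by_expression <- function(x_expr, a_expr, t, neox_expr = NULL) {
  num <- list(X = x_expr)
  if (!is.null(neox_expr)) num$NeoX <- neox_expr
  purrr::imap_dfr(num, function(expr, cls) {
    if (!any(expr > t) || !any(a_expr > t)) {
      return(tibble(method = "by_expression", threshold = t, numerator_class = cls,
                    f_used = NA_real_, n_top_num = 0L, n_top_den = 0L,
                    ratio = NA_real_))
    }
    .xaa_one(expr, a_expr, t, NA_real_, cls, "by_expression")
  })
}

#' X:AA ratios across stages, thresholds, methods and replicates
#'
#' Evaluates both estimators at every stage and TPM threshold, per
#' replicate (the sample's TPM column) and pooled (mean TPM across a
#' stage's replicates). Genes enter by chromosome class from the
#' annotation; the neo-X three-way extension is used automatically when
#' the annotation contains NeoX genes.
#'
#' @param dataset An `expression_dataset`.
#' @param annotation Annotation tibble with `gene_id`, `chromosome_class`,
#'   `biotype`.
#' @param thresholds TPM thresholds (default `c(0, 2, 10)`).
#' @param methods Estimators to run (default both).
#' @param biotype Gene universe (default `"coding"`).
#' @return Tidy tibble with columns `stage`, `replicate` (`"pooled"` for
#'   stage means), `method`, `threshold`, `numerator_class`, `f_used`,
#'   `n_top_num`, `n_top_den`, `ratio`.
#' @export
xaa_stage_table <- function(dataset, annotation,
                            thresholds = c(0, 2, 10),
                            methods = c("by_fraction", "by_expression"),
                            biotype = "coding") {
  stopifnot(inherits(dataset, "expression_dataset"))
  ann <- annotation %>% filter(.data$biotype == !!biotype) %>%
    arrange(.data$gene_id)
  ids <- list(
    X = ann$gene_id[ann$chromosome_class == "X"],
    Autosome = ann$gene_id[ann$chromosome_class == "Autosome"],
    NeoX = ann$gene_id[ann$chromosome_class == "NeoX"]
  )
  if (length(ids$X) == 0 || length(ids$Autosome) == 0) {
    abort("need annotated X and Autosome genes for X:AA ratios.")
  }
  has_neox <- length(ids$NeoX) > 0

  expr_sets <- list()
  for (st in unique(dataset$samples$stage)) {
    reps <- dataset$samples[dataset$samples$stage == st, ]
    for (i in seq_len(nrow(reps))) {
      expr_sets[[paste0(st, "::", reps$replicate[i])]] <-
        list(stage = st, replicate = as.character(reps$replicate[i]),
             tpm = dataset$tpm[, reps$sample_id[i]])
    }
    expr_sets[[paste0(st, "::pooled")]] <-
      list(stage = st, replicate = "pooled",
           tpm = rowMeans(dataset$tpm[, reps$sample_id, drop = FALSE]))
  }

  purrr::map_dfr(expr_sets, function(es) {
    x <- es$tpm[ids$X]
    a <- es$tpm[ids$Autosome]
    nx <- if (has_neox) es$tpm[ids$NeoX] else NULL
    purrr::map_dfr(thresholds, function(t) {
      bind_rows(
        if ("by_fraction" %in% methods) xaa_filter_by_fraction(x, a, t, nx),
        if ("by_expression" %in% methods) xaa_by_expression(x, a, t, nx)
      )
    }) %>%
      mutate(stage = es$stage, replicate = es$replicate, .before = 1)
  })
}

#' Compare per-replicate X:AA ratios between stages
#'
#' For every (method, threshold, numerator class), runs pairwise two-sided
#' Wilcoxon rank-sum tests on the per-replicate ratios of each stage pair
#' (exact for small samples without ties, normal approximation otherwise)
#' and annotates significance stars.
#'
#' @param xaa_table Output of [xaa_stage_table()].
#' @return Tibble: `method`, `threshold`, `numerator_class`, `stage_a`,
#'   `stage_b`, `n_a`, `n_b`, `p`, `stars`.
#' @export
stage_ratio_comparison <- function(xaa_table) {
  reps <- xaa_table %>% filter(.data$replicate != "pooled", !is.na(.data$ratio))
  combos <- reps %>% distinct(.data$method, .data$threshold, .data$numerator_class)
  stages <- intersect(STAGES, unique(reps$stage))
  purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    cmb <- combos[i, ]
    sub <- reps %>%
      filter(.data$method == cmb$method, .data$threshold == cmb$threshold,
             .data$numerator_class == cmb$numerator_class)
    pairs <- utils::combn(stages, 2, simplify = FALSE)
    purrr::map_dfr(pairs, function(pr) {
      a <- sub$ratio[sub$stage == pr[1]]
      b <- sub$ratio[sub$stage == pr[2]]
      if (length(a) < 2 || length(b) < 2) return(tibble())
      p <- wilcoxon_rank_sum(a, b)
      tibble(method = cmb$method, threshold = cmb$threshold,
             numerator_class = cmb$numerator_class,
             stage_a = pr[1], stage_b = pr[2],
             n_a = length(a), n_b = length(b),
             p = p, stars = stars_for_p(p))
    })
  })
}
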