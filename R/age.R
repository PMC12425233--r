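#' Per-gene stage expression values
#'
#' Computes, per gene and stage, the mean across replicates of
#' `log2(normalized expression + pseudocount)`. Normalization defaults to
#' size-factor-scaled counts (TPM is available as an alternative unit).
#'
#' @param dataset An `expression_dataset`.
#' @param pseudocount Positive pseudocount added before log2 (default 1;
#'   required because zeros are common at stage boundaries).
#' @param unit `"normalized_counts"` (median-of-ratios scaled) or `"tpm"`.
#' @return Tibble: `gene_id`, `stage`, `value`.
#' @export
gene_stage_values <- function(dataset, pseudocount = 1,
                              unit = c("normalized_counts", "tpm")) {
  stopifnot(inherits(dataset, "expression_dataset"))
  unit <- match.arg(unit)
  if (pseudocount <= 0) abort("`pseudocount` must be > 0.")
  mat <- if (unit == "tpm") {
    dataset$tpm
  } else {
    sweep(dataset$counts, 2, compute_size_factors(dataset$counts), "/")
  }
  logmat <- log2(mat + pseudocount)
  purrr::map_dfr(unique(dataset$samples$stage), function(st) {
    cols <- dataset$samples$sample_id[dataset$samples$stage == st]
    tibble(gene_id = rownames(mat), stage = st,
           value = rowMeans(logmat[, cols, drop = FALSE]))
  })
}

#' Mean stage trajectories by gene age group and chromosome class
#'
#' Summarizes per-gene stage values (see [gene_stage_values()]) into cell
#' means and standard errors over genes per (age group, chromosome class,
#' stage): the stage trajectory of new versus old genes on each chromosome
#' class. Genes with unknown age are excluded; empty cells are absent from
#' the output (e.g. chromosomes carrying no new genes).
#'
#' @inheritParams gene_stage_values
#' @param annotation Annotation tibble with `gene_id`, `chromosome_class`,
#'   `age_branch`.
#' @return Tibble: `age_group`, `chromosome_class`, `stage`, `mean`, `sem`,
#'   `n`.
#' @export
stage_trajectories <- function(dataset, annotation, pseudocount = 1,
                               unit = c("normalized_counts", "tpm")) {
  values <- gene_stage_values(dataset, pseudocount, unit)
  ann <- annotation %>%
    mutate(age_group = assign_age_group(.data$age_branch)) %>%
    filter(.data$age_group != "unknown") %>%
    select("gene_id", "age_group", "chromosome_class")
  values %>%
    dplyr::inner_join(ann, by = "gene_id") %>%
    group_by(.data$age_group, .data$chromosome_class, .data$stage) %>%
    summarise(mean = mean(.data$value),
              sem = sd(.data$value) / sqrt(dplyr::n()),
              n = dplyr::n(), .groups = "drop") %>%
    mutate(sem = if_else(is.na(.data$sem), 0, .data$sem),
           stage = factor(.data$stage, levels = STAGES)) %>%
    arrange(.data$age_group, .data$chromosome_class, .data$stage)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact when the smaller group has at most 10 observations and the pooled
#' values have no ties; otherwise the normal approximation with continuity
#' and tie correction. Completely tied data give p = 1.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return Two-sided p-value.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty.")
  pooled <- c(a, b)
  if (all(pooled == pooled[1])) return(1)
  has_ties <- anyDuplicated(pooled) > 0
  exact <- min(length(a), length(b)) <= 10 && !has_ties
  suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE, alternative = "two.sided")$p.value
  )
}

#' Age-by-location expression contrasts
#'
#' Runs the rank-sum contrasts that probe age-dependent expression
#' dynamics, with genes as the sampling unit (per-gene stage values average
#' replicates first): new-X vs old-X at every stage, new-X vs new-autosome
#' at every stage (post-meiotic convergence shows up as a non-significant
#' post-meiosis contrast), and old-X mitosis vs meiosis (the MSCI-driven
#' drop in old X-linked expression). Contrast groups with fewer than two
#' genes are skipped with a warning.
#'
#' @inheritParams stage_trajectories
#' @return Tibble: `contrast`, `stage`, `n_a`, `n_b`, `median_a`,
#'   `median_b`, `direction`, `p`, `stars`.
#' @export
compare_age_location_groups <- function(dataset, annotation, pseudocount = 1,
                                        unit = c("normalized_counts", "tpm")) {
  values <- gene_stage_values(dataset, pseudocount, unit)
  ann <- annotation %>%
    mutate(age_group = assign_age_group(.data$age_branch)) %>%
    select("gene_id", "age_group", "chromosome_class")
  dat <- values %>% dplyr::inner_join(ann, by = "gene_id")

  pick <- function(age, cls, st) {
    dat$value[dat$age_group == age & dat$chromosome_class == cls & dat$stage == st]
  }
  one <- function(label, st, a, b) {
    if (length(a) < 2 || length(b) < 2) {
      warn(paste0("contrast ", label, " (", st, ") has < 2 genes in a group; skipped."))
      return(tibble())
    }
    p <- wilcoxon_rank_sum(a, b)
    tibble(contrast = label, stage = st, n_a = length(a), n_b = length(b),
           median_a = median(a), median_b = median(b),
           direction = dplyr::case_when(median(a) > median(b) ~ "a_higher",
                                        median(a) < median(b) ~ "b_higher",
                                        TRUE ~ "equal"),
           p = p, stars = stars_for_p(p))
  }

  bind_rows(
    purrr::map_dfr(STAGES, function(st) {
      one("new_X_vs_old_X", st, pick("new", "X", st), pick("old", "X", st))
    }),
    purrr::map_dfr(STAGES, function(st) {
      one("new_X_vs_new_autosome", st, pick("new", "X", st),
          pick("new", "Autosome", st))
    }),
    one("old_X_mitosis_vs_meiosis", "mitosis_vs_meiosis",
        pick("old", "X", "mitosis"), pick("old", "X", "meiosis"))
  )
}
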