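#' Tabulate down/up gene counts per chromosome class
#'
#' Counts down- and up-regulated genes per chromosome class against the
#' total number of annotated genes of the chosen biotype in that class —
#' the denominator is all annotated genes, not only tested ones, so the
#' proportions are comparable across classes regardless of detection.
#'
#' @param de Either an `msci_de` object or a tibble with `gene_id` and
#'   `class` columns.
#' @param annotation Annotation tibble with `gene_id`, `chromosome_class`,
#'   `biotype`.
#' @param biotype Biotype universe (default `"coding"`).
#' @return A `ProportionTable` tibble: `chromosome_class`, `n_down`,
#'   `n_up`, `n_total`, `prop_down`, `prop_up`, plus `biotype` and
#'   `contrast` attributes carried as columns.
#' @export
tabulate_class_counts <- function(de, annotation, biotype = "coding") {
  classes <- if (inherits(de, "msci_de")) de$results else as_tibble(de)
  contrast <- if ("contrast" %in% names(classes)) classes$contrast[1] else NA_character_
  ann <- annotation %>% filter(.data$biotype == !!biotype)
  joined <- ann %>%
    left_join(classes %>% select("gene_id", de_class = "class"), by = "gene_id") %>%
    mutate(de_class = tidyr::replace_na(.data$de_class, "untested"))
  if (any(is.na(joined$chromosome_class))) abort("gene with missing chromosome class.")
  joined %>%
    group_by(.data$chromosome_class) %>%
    summarise(n_down = sum(.data$de_class == "down"),
              n_up = sum(.data$de_class == "up"),
              n_total = dplyr::n(), .groups = "drop") %>%
    mutate(prop_down = .data$n_down / .data$n_total,
           prop_up = .data$n_up / .data$n_total,
           biotype = !!biotype, contrast = contrast)
}

#' Yates-corrected chi-square test on a 2x2 table
#'
#' `chi2 = sum((|O - E| - 0.5)^2 / E)` with the continuity excess clipped
#' at zero (|O - E| smaller than 0.5 contributes nothing), referred to a
#' chi-square distribution with one degree of freedom.
#'
#' @param table 2x2 matrix of non-negative counts; both margins must be
#'   positive.
#' @return List with `chi2` and `p`.
#' @export
#' @examples
#' chisq_yates(matrix(c(30, 10, 70, 90), 2))
chisq_yates <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0)) {
    abort("need a 2x2 table of non-negative counts.")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("zero margin: the test is undefined.")
  }
  e <- outer(rowSums(table), colSums(table)) / sum(table)
  excess <- pmax(abs(table - e) - 0.5, 0)
  chi2 <- sum(excess^2 / e)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Chromosomal enrichment of regulated genes versus autosomes
#'
#' For each non-autosomal chromosome class and each direction (down, up),
#' tests the 2x2 table (class regulated / not vs autosomal regulated / not)
#' with the Yates-corrected chi-square, records whether the class deviates
#' above or below the autosomal proportion, and annotates significance
#' stars at p <= 0.05 (*), 0.01 (**), 0.001 (***). Unplaced and Y classes
#' are excluded from testing; classes with fewer than `low_power_n`
#' annotated genes are flagged low-power (the dot chromosome has roughly an
#' order of magnitude fewer genes than the other classes).
#'
#' @param proportion_table Output of [tabulate_class_counts()].
#' @param low_power_n Flag threshold on `n_total` (default 100).
#' @return Tibble: `chromosome_class`, `direction`, `n_regulated`,
#'   `n_total`, `proportion`, `autosome_regulated`, `autosome_total`,
#'   `chi2`, `p`, `stars`, `deviation`, `low_power`.
#' @export
run_enrichment <- function(proportion_table, low_power_n = 100) {
  aut <- proportion_table %>% filter(.data$chromosome_class == "Autosome")
  if (nrow(aut) != 1) abort("proportion table must contain exactly one Autosome row.")
  others <- proportion_table %>%
    filter(!.data$chromosome_class %in% c("Autosome", "Unplaced", "Y"))
  purrr::map_dfr(c("down", "up"), function(dir) {
    n_aut <- if (dir == "down") aut$n_down else aut$n_up
    purrr::map_dfr(seq_len(nrow(others)), function(i) {
      row <- others[i, ]
      n_reg <- if (dir == "down") row$n_down else row$n_up
      if (row$n_total == 0) {
        warn(paste0("class ", row$chromosome_class, " has no annotated genes; skipped."))
        return(tibble())
      }
      tab <- matrix(c(n_reg, row$n_total - n_reg,
                      n_aut, aut$n_total - n_aut), 2, 2, byrow = TRUE)
      # a zero column margin (e.g. no regulated gene anywhere) carries no
      # evidence of enrichment; report a null result rather than erroring
      test <- if (any(colSums(tab) == 0)) {
        list(chi2 = 0, p = 1)
      } else {
        chisq_yates(tab)
      }
      prop <- n_reg / row$n_total
      prop_aut <- n_aut / aut$n_total
      tibble(
        chromosome_class = row$chromosome_class,
        direction = dir,
        n_regulated = n_reg, n_total = row$n_total,
        proportion = prop,
        autosome_regulated = n_aut, autosome_total = aut$n_total,
        chi2 = test$chi2, p = test$p,
        stars = stars_for_p(test$p),
        deviation = dplyr::case_when(
          test$p > 0.05 ~ "none", prop > prop_aut ~ "over", prop < prop_aut ~ "under",
          TRUE ~ "none"),
        low_power = row$n_total < low_power_n
      )
    })
  })
}

#' Positional distribution of a gene set along a chromosome
#'
#' Bins gene midpoints along the chromosome and reports a one-sample
#' Kolmogorov-Smirnov statistic of the midpoints against the uniform
#' distribution — a descriptive operationalization of "uniformly
#' distributed along the chromosome" (the choice of test is this
#' package's, not a published one).
#'
#' @param gene_ids Genes of interest (e.g. meiotically downregulated
#'   lncRNAs).
#' @param annotation Annotation tibble with coordinates.
#' @param chromosome Chromosome/scaffold name to profile.
#' @param n_bins Number of equal-width bins (default 20).
#' @param chrom_length Chromosome length; defaults to the maximum annotated
#'   end position.
#' @return List with `profile` (tibble `bin_start`, `bin_end`, `count`) and
#'   `uniformity` (tibble `n`, `ks_d`, `p`; NA when no genes).
#' @export
positional_profile <- function(gene_ids, annotation, chromosome, n_bins = 20,
                               chrom_length = NULL) {
  on_chrom <- annotation %>%
    filter(.data$gene_id %in% gene_ids,
           .data$chromosome_or_scaffold == chromosome)
  chrom_length <- chrom_length %||%
    max(annotation$end[annotation$chromosome_or_scaffold == chromosome], 1)
  breaks <- seq(0, chrom_length, length.out = n_bins + 1)
  mid <- (on_chrom$start + on_chrom$end) / 2
  profile <- tibble(
    bin_start = breaks[-length(breaks)] + 1,
    bin_end = breaks[-1],
    count = as.integer(table(cut(mid, breaks, include.lowest = TRUE)))
  )
  uniformity <- if (length(mid) == 0) {
    tibble(n = 0L, ks_d = NA_real_, p = NA_real_)
  } else {
    ks <- suppressWarnings(ks.test(mid / chrom_length, "punif"))
    tibble(n = length(mid), ks_d = unname(ks$statistic), p = ks$p.value)
  }
  list(profile = profile, uniformity = uniformity)
}
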