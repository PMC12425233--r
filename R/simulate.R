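#' Configure a synthetic stage-enriched spermatogenesis experiment
#'
#' Builds a validated configuration for [simulate_experiment()]. The generator
#' emulates the structure of stage-enriched testis RNA-seq: three ordered
#' stages (mitosis, meiosis, post-meiosis) with replicated libraries, genes
#' distributed over chromosome classes in roughly Drosophila proportions,
#' negative binomial counts, an MSCI effect (a fraction of X/neo-X genes
#' fold-reduced during meiosis), gene-age-dependent stage offsets, and
#' imperfect stage enrichment modelled as a mixture of stage expectations.
#'
#' @param n_genes Named integer vector of genes per chromosome class. Names
#'   must be a subset of `c("X", "NeoX", "Autosome", "Dot", "Y")`.
#' @param n_replicates Replicates per stage (>= 1).
#' @param baseline_log2_mean Length-2 numeric `c(mean, sd)` of the per-gene
#'   log2 baseline expected normalized count.
#' @param dispersion Either a single NB dispersion alpha >= 0 (Var = mu +
#'   alpha mu^2; 0 degenerates to Poisson), or `c(meanlog, sdlog)` for
#'   per-gene log-normal dispersions.
#' @param msci_fraction Fraction of X/neo-X genes silenced in meiosis, in
#'   \[0, 1\].
#' @param msci_log2fc Log2 fold-change applied to affected genes in meiosis
#'   (<= 0 for silencing).
#' @param stage_effects Tibble with columns `chromosome_class`, `age_group`,
#'   `stage`, `log2_offset`, or `NULL` for no class/age-specific offsets.
#'   See [default_stage_effects()].
#' @param age_new_fraction Fraction of genes labelled new (age branches 1-6).
#' @param library_size Length-2 numeric `c(meanlog, sdlog)` of log-normal
#'   per-sample size factors.
#' @param purity Stage-by-stage mixture matrix: row s gives the composition
#'   of a nominally stage-s sample over true stages (rows sum to 1). The
#'   identity matrix means perfectly pure stage enrichment.
#' @param gene_length Length-2 numeric `c(meanlog, sdlog)` of log-normal
#'   gene lengths in bp (used only for TPM).
#' @param seed Integer seed; mandatory, there is no implicit seeding.
#'
#' @return A `simulation_config` object (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(seed = 1, n_genes = c(X = 50, Autosome = 200))
#' sim <- simulate_experiment(cfg)
#' dim(sim$dataset$counts)
simulation_config <- function(n_genes = c(X = 750, Autosome = 4100, Dot = 30, Y = 20),
                              n_replicates = 3,
                              baseline_log2_mean = c(mean = 5, sd = 2),
                              dispersion = 0.1,
                              msci_fraction = 0.5,
                              msci_log2fc = -1,
                              stage_effects = default_stage_effects(),
                              age_new_fraction = 0.1,
                              library_size = c(meanlog = 0, sdlog = 0.2),
                              purity = default_purity(),
                              gene_length = c(meanlog = log(2000), sdlog = 0.5),
                              seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` is mandatory and must be a single integer.")
  }
  classes <- c("X", "NeoX", "Autosome", "Dot", "Y")
  if (is.null(names(n_genes)) || !all(names(n_genes) %in% classes)) {
    abort("`n_genes` must be named with chromosome classes X, NeoX, Autosome, Dot, Y.")
  }
  if (any(n_genes < 0)) abort("gene counts per class must be >= 0.")
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  if (!length(dispersion) %in% c(1, 2) || any(is.na(dispersion))) {
    abort("`dispersion` must be a scalar alpha or c(meanlog, sdlog).")
  }
  if (length(dispersion) == 1 && dispersion < 0) abort("dispersion alpha must be >= 0.")
  if (msci_fraction < 0 || msci_fraction > 1) abort("`msci_fraction` must lie in [0, 1].")
  if (age_new_fraction < 0 || age_new_fraction > 1) abort("`age_new_fraction` must lie in [0, 1].")
  purity <- as.matrix(purity)
  if (!all(dim(purity) == c(3, 3)) || any(purity < 0) ||
      any(abs(rowSums(purity) - 1) > 1e-12)) {
    abort("`purity` must be a 3x3 non-negative matrix with rows summing to 1 (+/- 1e-12).")
  }
  dimnames(purity) <- list(STAGES, STAGES)
  if (!is.null(stage_effects)) {
    stage_effects <- as_tibble(stage_effects)
    needed <- c("chromosome_class", "age_group", "stage", "log2_offset")
    if (!all(needed %in% names(stage_effects))) {
      abort("`stage_effects` needs columns chromosome_class, age_group, stage, log2_offset.")
    }
  }
  structure(
    list(
      n_genes = n_genes[n_genes > 0],
      n_replicates = as.integer(n_replicates),
      stages = STAGES,
      baseline_log2_mean = unname(baseline_log2_mean),
      dispersion = unname(dispersion),
      msci_fraction = msci_fraction,
      msci_log2fc = msci_log2fc,
      stage_effects = stage_effects,
      age_new_fraction = age_new_fraction,
      library_size = unname(library_size),
      purity = purity,
      gene_length = unname(gene_length),
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Default gene-age stage offsets
#'
#' New X (and neo-X) genes are elevated by +1 log2 across all stages, so they
#' stand above old X genes in mitosis and meiosis; new autosomal genes rise
#' toward post-meiosis (0, +0.5, +1) and so converge with new X genes
#' post-meiotically. Old genes carry no offset.
#'
#' @return A tibble with columns `chromosome_class`, `age_group`, `stage`,
#'   `log2_offset`.
#' @export
default_stage_effects <- function() {
  bind_rows(
    tidyr::expand_grid(chromosome_class = c("X", "NeoX"), age_group = "new",
                       stage = STAGES) %>%
      mutate(log2_offset = 1),
    tibble(chromosome_class = "Autosome", age_group = "new",
           stage = STAGES, log2_offset = c(0, 0.5, 1))
  )
}

#' Default stage-purity mixture (70% target stage, 15% each other stage)
#' @return A 3x3 row-stochastic matrix.
#' @export
default_purity <- function() {
  p <- matrix(0.15, 3, 3, dimnames = list(STAGES, STAGES))
  diag(p) <- 0.7
  p
}

#' Global-null simulation configuration
#'
#' Convenience constructor for calibration runs: no MSCI effect and no
#' class- or age-specific stage offsets, so no gene class behaves differently
#' across stages (the global null of the enrichment analysis). Stage impurity
#' and library-size variation are retained; they do not break the null.
#'
#' @param seed Integer seed.
#' @param ... Passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
null_simulation_config <- function(seed, ...) {
  simulation_config(seed = seed, msci_fraction = 0, msci_log2fc = 0,
                    stage_effects = NULL, ...)
}

# chromosome scaffolding used for simulated annotations: Muller element,
# chromosome name, and a plausible length for coordinate placement
SIM_CHROMS <- data.frame(
  chromosome_class = c("X", "NeoX", "Autosome", "Autosome", "Autosome", "Dot", "Y"),
  muller_element = c("A", "D", "B", "C", "E", "F", "unknown"),
  chromosome = c("chrX", "chrNeoX", "chr2L", "chr2R", "chr3R", "chr4", "chrY"),
  chrom_length = c(23.5e6, 24.5e6, 23e6, 25e6, 28e6, 1.35e6, 3.5e6)
)

# per-gene by-stage log2 offsets implied by the config (pre-mixture), as a
# genes x stages matrix; includes age offsets and the meiotic MSCI effect
.stage_offset_matrix <- function(genes, config) {
  off <- matrix(0, nrow(genes), 3, dimnames = list(genes$gene_id, STAGES))
  if (!is.null(config$stage_effects)) {
    se <- config$stage_effects
    for (i in seq_len(nrow(se))) {
      hit <- genes$chromosome_class == se$chromosome_class[i] &
        genes$age_group == se$age_group[i]
      off[hit, se$stage[i]] <- off[hit, se$stage[i]] + se$log2_offset[i]
    }
  }
  off[genes$msci_affected, "meiosis"] <-
    off[genes$msci_affected, "meiosis"] + config$msci_log2fc
  off
}

#' Simulate a stage-enriched spermatogenesis experiment
#'
#' Draws a gene annotation, per-gene negative binomial counts over
#' stages x replicates, and a TPM matrix, together with the ground truth
#' needed for parameter-recovery and calibration tests. Counts for a sample
#' nominally of stage s are NB with mean
#' `size_factor * sum_s' purity[s, s'] * mu[g, s']`, where `mu[g, s']` is the
#' pre-mixture stage expectation. Identical configs (including seed) give
#' bit-identical output.
#'
#' @param config A [simulation_config()].
#' @return A list with components `dataset` (an `expression_dataset`:
#'   `counts`, `tpm`, `samples`), `annotation` (a tibble, one row per gene),
#'   and `truth` (a `synthetic_truth` list: `genes`, `size_factors`, `xaa`).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, .simulate_experiment_impl(config))
}

.simulate_experiment_impl <- function(config) {
  n_total <- sum(config$n_genes)
  if (n_total < 1) abort("configuration yields zero genes.")

  genes <- purrr::imap(config$n_genes, function(n, cls) {
    rows <- SIM_CHROMS[SIM_CHROMS$chromosome_class == cls, ]
    idx <- rep(seq_len(nrow(rows)), length.out = n)
    tibble(chromosome_class = cls,
           muller_element = rows$muller_element[idx],
           chromosome = rows$chromosome[idx],
           chrom_length = rows$chrom_length[idx])
  }) %>%
    bind_rows() %>%
    mutate(gene_id = sprintf("g%05d", dplyr::row_number()))

  # ages, lengths, coordinates
  is_new <- runif(n_total) < config$age_new_fraction
  genes$age_branch <- ifelse(is_new, sample(1:6, n_total, replace = TRUE), 0L)
  genes$age_group <- assign_age_group(genes$age_branch)
  genes$length <- pmax(200L, as.integer(round(
    rlnorm(n_total, config$gene_length[1], config$gene_length[2]))))
  genes$start <- as.integer(floor(runif(n_total, 1, genes$chrom_length - genes$length)))
  genes$end <- genes$start + genes$length - 1L
  genes$strand <- sample(c("+", "-"), n_total, replace = TRUE)
  genes$biotype <- "coding"
  genes$n_transcripts <- 1L

  # MSCI membership: a fraction of X/neo-X genes silenced in meiosis
  on_x <- genes$chromosome_class %in% c("X", "NeoX")
  genes$msci_affected <- on_x & (runif(n_total) < config$msci_fraction)

  # per-gene baseline and dispersion
  b <- rnorm(n_total, config$baseline_log2_mean[1], config$baseline_log2_mean[2])
  mu0 <- 2^b
  alpha <- if (length(config$dispersion) == 1) {
    rep(config$dispersion, n_total)
  } else {
    rlnorm(n_total, config$dispersion[1], config$dispersion[2])
  }

  off <- .stage_offset_matrix(genes, config)
  mu_pre <- mu0 * 2^off                       # genes x stages, pre-mixture
  lambda <- mu_pre %*% t(config$purity)       # genes x stages, post-mixture
  colnames(lambda) <- STAGES

  samples <- tidyr::expand_grid(stage = STAGES,
                                replicate = seq_len(config$n_replicates)) %>%
    mutate(sample_id = paste0(.data$stage, "_", .data$replicate),
           species = "synthetic") %>%
    select("sample_id", "species", "stage", "replicate")
  sf <- rlnorm(nrow(samples), config$library_size[1], config$library_size[2])

  counts <- matrix(0L, n_total, nrow(samples),
                   dimnames = list(genes$gene_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    mu_j <- sf[j] * lambda[, samples$stage[j]]
    counts[, j] <- if (all(alpha == 0)) {
      rpois(n_total, mu_j)
    } else {
      pois <- alpha == 0
      out <- integer(n_total)
      if (any(pois)) out[pois] <- rpois(sum(pois), mu_j[pois])
      if (any(!pois)) out[!pois] <- rnbinom(sum(!pois), mu = mu_j[!pois],
                                            size = 1 / alpha[!pois])
      out
    }
  }

  tpm <- compute_tpm(counts, setNames(genes$length, genes$gene_id))

  annotation <- genes %>%
    select("gene_id", chromosome_or_scaffold = "chromosome", "start", "end",
           "strand", "muller_element", "chromosome_class", "biotype",
           "length", "age_branch", "n_transcripts")

  exp_tab <- analytic_expectations(config)
  truth_genes <- genes %>%
    select("gene_id", "chromosome_class", "age_group", "msci_affected") %>%
    mutate(true_log2fc = log2(lambda[, "meiosis"] / lambda[, "mitosis"]),
           mean_mitosis = lambda[, "mitosis"],
           mean_meiosis = lambda[, "meiosis"],
           mean_post_meiosis = lambda[, "post_meiosis"])

  dataset <- expression_dataset(counts, tpm, samples)
  truth <- structure(
    list(genes = truth_genes,
         size_factors = tibble(sample_id = samples$sample_id, size_factor = sf),
         xaa = exp_tab$xaa,
         config = config),
    class = "synthetic_truth"
  )
  list(dataset = dataset, annotation = annotation, truth = truth)
}

#' Closed-form expectations implied by a simulation configuration
#'
#' Returns, per (chromosome class, age group, MSCI status) stratum and stage,
#' the expected normalized count before and after stage mixing, plus the
#' population X:AA (and NeoX:AA) ratio of class medians per stage at
#' threshold 0. Strata weights use the configured fractions, not realized
#' draws, so these are targets that empirical summaries converge to.
#'
#' @param config A [simulation_config()].
#' @return A list with tibbles `strata` (columns `chromosome_class`,
#'   `age_group`, `msci_affected`, `stage`, `weight`, `expected_mean_premix`,
#'   `expected_mean`) and `xaa` (`stage`, `numerator_class`,
#'   `expected_ratio`).
#' @export
analytic_expectations <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  m <- config$baseline_log2_mean[1]
  s <- config$baseline_log2_mean[2]
  e_mu0 <- exp(m * log(2) + (s * log(2))^2 / 2)   # E[2^N(m, s)]

  classes <- names(config$n_genes)
  strata <- tidyr::expand_grid(
    chromosome_class = classes,
    age_group = c("old", "new"),
    msci_affected = c(FALSE, TRUE)
  ) %>%
    filter(.data$msci_affected == FALSE |
             .data$chromosome_class %in% c("X", "NeoX")) %>%
    mutate(weight = if_else(.data$age_group == "new",
                            config$age_new_fraction, 1 - config$age_new_fraction) *
             dplyr::case_when(
               !.data$chromosome_class %in% c("X", "NeoX") ~ 1,
               .data$msci_affected ~ config$msci_fraction,
               TRUE ~ 1 - config$msci_fraction
             ))

  # pre-mixture per-stratum multiplier per stage
  pre <- purrr::pmap(strata, function(chromosome_class, age_group, msci_affected, weight) {
    cls <- chromosome_class; ag <- age_group
    off <- setNames(numeric(3), STAGES)
    if (!is.null(config$stage_effects)) {
      se <- config$stage_effects[config$stage_effects$chromosome_class == cls &
                                   config$stage_effects$age_group == ag, ]
      for (i in seq_len(nrow(se))) off[se$stage[i]] <- off[se$stage[i]] + se$log2_offset[i]
    }
    if (msci_affected) off["meiosis"] <- off["meiosis"] + config$msci_log2fc
    2^off
  })
  mult_pre <- do.call(rbind, pre)                 # strata x stages
  mult_post <- mult_pre %*% t(config$purity)
  colnames(mult_post) <- STAGES

  strata_long <- strata %>%
    tidyr::expand_grid(stage = STAGES) %>%
    mutate(expected_mean_premix = e_mu0 * mult_pre[cbind(
             rep(seq_len(nrow(strata)), each = 3), match(.data$stage, STAGES))],
           expected_mean = e_mu0 * mult_post[cbind(
             rep(seq_len(nrow(strata)), each = 3), match(.data$stage, STAGES))])

  # population median of a class at a stage: the per-gene mean is
  # 2^N(m, s) * c_k with stratum multipliers c_k; solve F(x) = 1/2
  class_median <- function(cls, stage) {
    rows <- which(strata$chromosome_class == cls)
    w <- strata$weight[rows]
    ck <- mult_post[rows, stage]
    if (s == 0) {
      vals <- sort(2^m * ck)
      cw <- cumsum(w[order(2^m * ck)])
      return(vals[which(cw >= 0.5)[1]])
    }
    f <- function(x) sum(w * pnorm((log2(x) - log2(ck) - m) / s)) - 0.5
    lo <- 2^(m - 10 * s) * min(ck)
    hi <- 2^(m + 10 * s) * max(ck)
    uniroot(f, c(lo, hi), tol = 1e-12)$root
  }

  num_classes <- intersect(c("X", "NeoX"), classes)
  xaa <- tidyr::expand_grid(stage = STAGES, numerator_class = num_classes) %>%
    mutate(expected_ratio = purrr::map2_dbl(
      .data$numerator_class, .data$stage,
      ~ class_median(.x, .y) / class_median("Autosome", .y)))

  list(strata = strata_long, xaa = xaa)
}

#' Bundle count, TPM and sample tables into an expression dataset
#'
#' @param counts Gene x sample matrix of non-negative integers.
#' @param tpm Gene x sample matrix of TPM values (columns sum to 1e6).
#' @param samples Tibble with columns `sample_id`, `species`, `stage`,
#'   `replicate`; `stage` must be one of mitosis, meiosis, post_meiosis.
#' @return An `expression_dataset` list.
#' @export
expression_dataset <- function(counts, tpm, samples) {
  counts <- as.matrix(counts)
  tpm <- as.matrix(tpm)
  samples <- as_tibble(samples)
  if (any(counts < 0) || any(tpm < 0)) abort("negative expression values.")
  if (!identical(dim(counts), dim(tpm))) abort("counts and tpm dimensions differ.")
  if (!identical(colnames(counts), samples$sample_id)) {
    abort("count columns must match samples$sample_id in order.")
  }
  if (!all(samples$stage %in% STAGES)) {
    abort("sample stages must be mitosis, meiosis or post_meiosis.")
  }
  cs <- colSums(tpm)
  if (any(abs(cs - 1e6) > 1e-6 * 1e6)) abort("TPM columns must sum to 1e6.")
  structure(list(counts = counts, tpm = tpm, samples = samples),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples (", paste(unique(x$samples$stage), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config> ", sum(x$n_genes), " genes (",
      paste(names(x$n_genes), x$n_genes, sep = "=", collapse = ", "),
      "), ", x$n_replicates, " reps/stage, msci_fraction=", x$msci_fraction,
      ", msci_log2fc=", x$msci_log2fc, ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}
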