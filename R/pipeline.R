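matrix_to_tsv <- function(mat, path) {
  readr::write_tsv(as_tibble(mat, rownames = "gene_id"), path)
}

tsv_to_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  mat <- as.matrix(df[, -1])
  rownames(mat) <- df[[1]]
  mat
}

#' Write a simulated experiment to TSV files
#'
#' @param sim Output of [simulate_experiment()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    tpm = file.path(dir, "tpm.tsv"),
    samples = file.path(dir, "samples.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_size_factors = file.path(dir, "truth_size_factors.tsv"),
    truth_xaa = file.path(dir, "truth_xaa.tsv")
  )
  matrix_to_tsv(sim$dataset$counts, paths["counts"])
  matrix_to_tsv(sim$dataset$tpm, paths["tpm"])
  readr::write_tsv(sim$dataset$samples, paths["samples"])
  readr::write_tsv(sim$annotation, paths["annotation"])
  readr::write_tsv(sim$truth$genes, paths["truth_genes"])
  readr::write_tsv(sim$truth$size_factors, paths["truth_size_factors"])
  readr::write_tsv(sim$truth$xaa, paths["truth_xaa"])
  invisible(paths)
}

#' Read an expression dataset from TSV files
#'
#' @param counts_path,tpm_path Gene x sample TSVs with a leading `gene_id`
#'   column.
#' @param samples_path Sample sheet TSV (`sample_id`, `species`, `stage`,
#'   `replicate`).
#' @return An `expression_dataset`.
#' @export
read_expression_dataset <- function(counts_path, tpm_path, samples_path) {
  expression_dataset(tsv_to_matrix(counts_path), tsv_to_matrix(tpm_path),
                     readr::read_tsv(samples_path, show_col_types = FALSE))
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [simulation_config()]; `purity` is given as
#' a list of rows and `stage_effects` as a list of records.
#'
#' @param path YAML file path.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$n_genes)) raw$n_genes <- unlist(raw$n_genes)
  if (!is.null(raw$purity)) raw$purity <- do.call(rbind, raw$purity)
  if (!is.null(raw$stage_effects)) {
    raw$stage_effects <- purrr::map_dfr(raw$stage_effects, as_tibble)
  }
  for (nm in c("baseline_log2_mean", "dispersion", "library_size", "gene_length")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(simulation_config, raw)
}

#' Run the full MSCI analysis pipeline on a simulated experiment
#'
#' Orchestrates simulate -> differential expression (meiosis:mitosis and
#' post_meiosis:meiosis) -> chromosomal enrichment -> X:AA ratios with
#' stage comparisons -> age trajectories and contrasts -> profile
#' clustering, writing every stage output as TSV plus a JSON report and a
#' manifest with a checksum for every file. Reruns with the same
#' configuration produce byte-identical outputs.
#'
#' @param sim_config A [simulation_config()] (its seed drives every
#'   stochastic step).
#' @param output_dir Directory for outputs.
#' @param q_threshold FDR threshold for DE classes.
#' @param tpm_thresholds TPM thresholds for the X:AA estimators.
#' @param k Number of profile clusters.
#' @param pseudocount Pseudocount for log2 summaries.
#' @return Invisibly, a list with all in-memory results (`sim`, `de`,
#'   `proportions`, `enrichment`, `xaa`, `xaa_comparison`, `trajectories`,
#'   `age_contrasts`, `clusters`, `report`, `manifest`).
#' @export
run_full_pipeline <- function(sim_config, output_dir,
                              q_threshold = 0.05, tpm_thresholds = c(0, 2, 10),
                              k = 12, pseudocount = 1) {
  stopifnot(inherits(sim_config, "simulation_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  message("[simulate] seed ", sim_config$seed)
  sim <- simulate_experiment(sim_config)
  write_dataset(sim, file.path(output_dir, "dataset"))

  message("[de] meiosis:mitosis and post_meiosis:meiosis")
  de_mei <- de_contrast(sim$dataset, "meiosis", "mitosis", q_threshold)
  de_pm <- de_contrast(sim$dataset, "post_meiosis", "meiosis", q_threshold)
  readr::write_tsv(tidy(de_mei), file.path(output_dir, "de_meiosis_vs_mitosis.tsv"))
  readr::write_tsv(tidy(de_pm), file.path(output_dir, "de_postmeiosis_vs_meiosis.tsv"))

  message("[enrich] chromosomal proportions, Yates chi-square vs autosomes")
  props <- tabulate_class_counts(de_mei, sim$annotation)
  enrich <- run_enrichment(props)
  readr::write_tsv(props, file.path(output_dir, "class_proportions.tsv"))
  readr::write_tsv(enrich, file.path(output_dir, "enrichment.tsv"))

  message("[xaa] matched-fraction and threshold ratios")
  xaa <- xaa_stage_table(sim$dataset, sim$annotation, tpm_thresholds)
  xaa_cmp <- stage_ratio_comparison(xaa)
  readr::write_tsv(xaa, file.path(output_dir, "xaa_ratios.tsv"))
  readr::write_tsv(xaa_cmp, file.path(output_dir, "xaa_stage_comparison.tsv"))

  message("[age] trajectories and rank-sum contrasts")
  traj <- stage_trajectories(sim$dataset, sim$annotation, pseudocount)
  contrasts <- compare_age_location_groups(sim$dataset, sim$annotation, pseudocount)
  readr::write_tsv(traj, file.path(output_dir, "age_trajectories.tsv"))
  readr::write_tsv(contrasts, file.path(output_dir, "age_contrasts.tsv"))

  message("[cluster] k-means on Z-scored stage profiles, k = ", k)
  stage_means <- gene_stage_values(sim$dataset, pseudocount) %>%
    tidyr::pivot_wider(names_from = "stage", values_from = "value")
  sm <- as.matrix(stage_means[, -1])
  rownames(sm) <- stage_means$gene_id
  zs <- zscore_stage_profile(sm)
  clusters <- kmeans_profiles(zs$z, k = min(k, nrow(zs$z)),
                              seed = sim_config$seed)
  readr::write_tsv(tidy(clusters), file.path(output_dir, "clusters.tsv"))
  readr::write_tsv(as_tibble(clusters$centroids) %>%
                     mutate(cluster = dplyr::row_number(), .before = 1),
                   file.path(output_dir, "cluster_centroids.tsv"))

  report <- list(
    seed = sim_config$seed,
    n_genes = as.list(sim_config$n_genes),
    de = list(meiosis_vs_mitosis = as.list(glance(de_mei)),
              post_meiosis_vs_meiosis = as.list(glance(de_pm))),
    enrichment = enrich %>% select("chromosome_class", "direction",
                                   "proportion", "chi2", "p", "stars"),
    xaa_pooled = xaa %>% filter(.data$replicate == "pooled") %>%
      select("stage", "method", "threshold", "numerator_class", "ratio"),
    cluster_proportions = clusters$proportions,
    msci_flagged = any(enrich$chromosome_class %in% c("X", "NeoX") &
                         enrich$direction == "down" &
                         enrich$deviation == "over" & enrich$p <= 0.05)
  )
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- sort(setdiff(list.files(output_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(output_dir, files))),
    bytes = file.size(file.path(output_dir, files))
  )
  jsonlite::write_json(list(seed = sim_config$seed, files = manifest),
                       file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(sim = sim, de = list(meiosis_vs_mitosis = de_mei,
                                      post_meiosis_vs_meiosis = de_pm),
                 proportions = props, enrichment = enrich,
                 xaa = xaa, xaa_comparison = xaa_cmp,
                 trajectories = traj, age_contrasts = contrasts,
                 clusters = clusters, report = report, manifest = manifest))
}
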