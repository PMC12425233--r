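test_that("size factors follow the median-of-ratios definition", {
  counts <- cbind(s1 = c(4, 1), s2 = c(16, 4))
  expect_equal(unname(compute_size_factors(counts)), c(0.5, 2.0))
  same <- cbind(a = c(5, 9, 2), b = c(5, 9, 2), c = c(5, 9, 2))
  expect_equal(unname(compute_size_factors(same)), c(1, 1, 1))
})

test_that("size factors are scale-equivariant relative to the other samples", {
  # tripling one column triples its factor relative to every other sample;
  # the absolute factors all shift by 3^(1/n) because the geometric-mean
  # reference includes the scaled sample
  sim <- tiny_sim(seed = 12)
  counts <- sim$dataset$counts
  sf <- compute_size_factors(counts)
  scaled <- counts
  scaled[, 2] <- scaled[, 2] * 3L
  sf2 <- compute_size_factors(scaled)
  expect_equal(sf2[2] / sf2[-2], 3 * sf[2] / sf[-2], tolerance = 1e-12)
  n <- ncol(counts)
  shift <- rep(3^(-1 / n), n)
  shift[2] <- 3^((n - 1) / n)
  expect_equal(unname(sf2 / sf), shift, tolerance = 1e-12)
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  counts <- tiny_sim(seed = 77)$dataset$counts
  ours <- compute_size_factors(counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  # DESeq2 takes the median on the log scale; with an even reference-gene
  # count the midpoint convention differs at the 1e-5 level
  expect_equal(unname(ours), unname(ref), tolerance = 1e-3)
})

test_that("TPM follows its closed form and normalizes columns", {
  counts <- cbind(s1 = c(10, 10), s2 = c(7, 7))
  tpm <- compute_tpm(counts, c(1000, 2000))
  expect_equal(tpm[, 1], c(2e6 / 3, 1e6 / 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(colSums(tpm), c(s1 = 1e6, s2 = 1e6))
  equal <- compute_tpm(cbind(c(3, 3), c(8, 8)), c(500, 500))
  expect_true(all(equal == 5e5))
  expect_error(compute_tpm(counts, c(1000, -1)), "> 0")
  expect_error(compute_tpm(cbind(c(0, 0)), c(1, 1)), "all-zero")
})

test_that("moment dispersion matches its defining formula", {
  counts <- matrix(c(10, 20, 30), 1)
  a <- estimate_dispersions(counts, rep(1, 3), rep("g", 3))
  expect_equal(unname(a), 0.2)
})

test_that("dispersion estimates recover the simulating alpha", {
  cfg <- null_simulation_config(
    seed = 6, n_genes = c(Autosome = 5000), n_replicates = 2,
    dispersion = 0.2, baseline_log2_mean = c(7, 1), purity = diag(3))
  sim <- simulate_experiment(cfg)
  sf <- compute_size_factors(sim$dataset$counts)
  a <- estimate_dispersions(sim$dataset$counts, sf,
                            rep("all", ncol(sim$dataset$counts)))
  expect_lt(abs(median(a, na.rm = TRUE) - 0.2) / 0.2, 0.2)
})

test_that("Poisson data give near-floor dispersions", {
  cfg <- null_simulation_config(
    seed = 6, n_genes = c(Autosome = 2000), n_replicates = 3,
    dispersion = 0, baseline_log2_mean = c(7, 1), purity = diag(3))
  sim <- simulate_experiment(cfg)
  sf <- compute_size_factors(sim$dataset$counts)
  a <- estimate_dispersions(sim$dataset$counts, sf, sim$dataset$samples$stage)
  expect_lt(median(a, na.rm = TRUE), 0.01)
})

test_that("an exact 4x count ratio yields log2fc = 2", {
  counts <- rbind(g1 = c(10, 12, 11, 40, 48, 44),
                  g2 = c(100, 100, 100, 100, 100, 100))
  colnames(counts) <- paste0("s", 1:6)
  res <- wald_stage_contrast(counts, setNames(rep(1, 6), colnames(counts)),
                             c(g1 = 0.05, g2 = 0.05),
                             paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(res$log2fc[1], 2, tolerance = 1e-6)
  expect_equal(res$log2fc[2], 0, tolerance = 1e-9)
  expect_equal(res$wald_p[2], 1, tolerance = 1e-9)
})

test_that("the Wald fit matches a direct likelihood-optimization oracle", {
  ya <- c(5, 7, 6); yb <- c(14, 13, 15)
  counts <- rbind(g1 = c(ya, yb))
  colnames(counts) <- paste0("s", 1:6)
  res <- wald_stage_contrast(counts, setNames(rep(1, 6), colnames(counts)),
                             c(g1 = 0.05), paste0("s", 1:3), paste0("s", 4:6))
  oracle <- oracle_nb_fit(ya, yb, alpha = 0.05)
  expect_equal(res$log2fc[1], oracle$log2fc, tolerance = 1e-3)
  expect_equal(res$se[1], oracle$se, tolerance = 1e-3)
  expect_equal(res$wald_p[1], oracle$p, tolerance = 1e-3)
})

test_that("the Wald fit agrees with a fixed-theta NB GLM", {
  skip_if_not_installed("MASS")
  sim <- tiny_sim(seed = 33)
  counts <- sim$dataset$counts
  sf <- compute_size_factors(counts)
  disp <- estimate_dispersions(counts, sf, sim$dataset$samples$stage)
  cols_a <- paste0("mitosis_", 1:3); cols_b <- paste0("meiosis_", 1:3)
  res <- wald_stage_contrast(counts, sf, disp, cols_a, cols_b)
  idx <- head(which(res$tested & res$base_mean > 20 & res$converged), 25)
  x <- c(0, 0, 0, 1, 1, 1)
  off <- log(sf[c(cols_a, cols_b)])
  for (i in idx) {
    y <- counts[i, c(cols_a, cols_b)]
    fit <- suppressWarnings(glm(
      y ~ x + offset(off),
      family = MASS::negative.binomial(theta = 1 / max(disp[i], 1e-8))))
    expect_equal(res$log2fc[i], unname(coef(fit)[2]) / log(2), tolerance = 1e-4)
  }
})

test_that("swapping groups negates log2fc and keeps the p-value", {
  sim <- tiny_sim(seed = 14)
  counts <- sim$dataset$counts
  sf <- compute_size_factors(counts)
  disp <- estimate_dispersions(counts, sf, sim$dataset$samples$stage)
  a <- paste0("mitosis_", 1:3); b <- paste0("meiosis_", 1:3)
  fwd <- wald_stage_contrast(counts, sf, disp, a, b)
  rev <- wald_stage_contrast(counts, sf, disp, b, a)
  ok <- fwd$tested & fwd$converged & rev$converged
  expect_equal(fwd$log2fc[ok], -rev$log2fc[ok], tolerance = 1e-5)
  expect_equal(fwd$wald_p[ok], rev$wald_p[ok], tolerance = 1e-5)
})

test_that("jointly rescaling counts and size factors leaves Poisson estimates unchanged", {
  counts <- rbind(g1 = c(12, 9, 30, 25), g2 = c(40, 44, 41, 39))
  colnames(counts) <- paste0("s", 1:4)
  sf <- setNames(rep(1, 4), colnames(counts))
  disp <- c(g1 = 0, g2 = 0)
  base <- wald_stage_contrast(counts, sf, disp, c("s1", "s2"), c("s3", "s4"))
  res <- wald_stage_contrast(counts * 3L, sf * 3, disp,
                             c("s1", "s2"), c("s3", "s4"))
  expect_equal(res$log2fc, base$log2fc, tolerance = 1e-8)
  # rescaling a single sample jointly with its factor is invariant only up
  # to the count weighting of the likelihood: the estimate moves a little
  scaled <- counts; scaled[, 3] <- scaled[, 3] * 2L
  sf2 <- sf; sf2[3] <- 2
  res1 <- wald_stage_contrast(scaled, sf2, disp, c("s1", "s2"), c("s3", "s4"))
  expect_equal(res1$log2fc, base$log2fc, tolerance = 0.1)
})

test_that("BH adjustment matches the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # NA passthrough without inflating the test count
  expect_equal(bh_adjust(c(0.01, NA, 0.02)),
               c(p.adjust(c(0.01, 0.02), "BH")[1], NA,
                 p.adjust(c(0.01, 0.02), "BH")[2]))
  set.seed(1)
  p <- runif(200)^2
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))   # monotone in p
  expect_true(all(q >= 0 & q <= 1))
})

test_that("gene classes follow the q-and-sign definition", {
  res <- tibble::tibble(
    log2fc = c(-1, -3, 2, 0.5, NA),
    q = c(0.01, 0.20, 0.001, 0.5, NA),
    tested = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  out <- classify_genes(res, 0.05)
  expect_equal(out$class, c("down", "unchanged", "up", "unchanged", "untested"))
})

test_that("most strongly silenced well-expressed genes are recovered", {
  # 30% of X genes silenced four-fold, pure stages: the analytic normal
  # approximation of the Wald power (integrated over the baseline
  # distribution) is the oracle the empirical rate must match
  cfg <- simulation_config(seed = 5, msci_fraction = 0.3, msci_log2fc = -2,
                           dispersion = 0.05, purity = diag(3),
                           stage_effects = NULL)
  sim <- simulate_experiment(cfg)
  fit <- de_contrast(sim$dataset)
  tr <- dplyr::left_join(tidy(fit), sim$truth$genes, by = "gene_id")
  aff <- tr[tr$msci_affected, ]
  power_all <- mean(aff$class == "down")
  # oracle: per-gene two-group Wald power at the BH-realized threshold
  z_cut <- qnorm(1 - max(aff$wald_p[aff$class == "down"], na.rm = TRUE) / 2)
  mu_a <- 2^rnorm(20000, 5, 2)
  se_b1 <- sqrt((1 / mu_a + 0.05 + 1 / (mu_a / 4) + 0.05) / 3)
  predicted <- mean(pnorm(-z_cut + log(4) / se_b1))
  expect_equal(power_all, predicted, tolerance = 0.08)
  # well-expressed silenced genes are detected nearly always
  strong <- aff[aff$base_mean >= 30, ]
  expect_gt(mean(strong$class == "down"), 0.9)
})

test_that("de_contrast output is internally consistent and tidy", {
  sim <- tiny_sim(seed = 3)
  fit <- de_contrast(sim$dataset)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$gene_id, rownames(sim$dataset$counts))
  expect_true(all(td$class %in% c("down", "up", "unchanged", "untested")))
  expect_true(all(is.na(td$wald_p) | (td$wald_p >= 0 & td$wald_p <= 1)))
  g <- glance(fit)
  expect_equal(g$n_down, sum(td$class == "down"))
  expect_equal(g$n_tested, sum(td$tested))
})
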