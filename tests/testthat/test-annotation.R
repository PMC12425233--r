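make_ann <- function(...) {
  tibble::tibble(...)
}

test_that("Muller elements map to chromosome classes per species", {
  ann <- make_ann(
    gene_id = paste0("g", 1:4),
    chromosome_or_scaffold = c("chrX", "chr3L", "chr4", "chr2L"),
    start = c(100L, 100L, 100L, 100L),
    muller_element = c("A", "D", "F", "B")
  )
  mel <- classify_chromosome(ann, species_scheme("melanogaster"))
  expect_equal(mel$chromosome_class, c("X", "Autosome", "Dot", "Autosome"))
  wil <- classify_chromosome(ann, species_scheme("willistoni"))
  expect_equal(wil$chromosome_class[2], "NeoX")   # Muller D is neo-X there
})

test_that("the willistoni E-F fusion rule overrides the element map", {
  junction <- 2014728
  ann <- make_ann(
    gene_id = c("dotward", "eward"),
    chromosome_or_scaffold = rep("scf2_1100000004943", 2),
    start = c(junction - 1e5, junction + 1e5),
    muller_element = c("E", "E")
  )
  cls <- classify_chromosome(ann, species_scheme("willistoni"))
  expect_equal(cls$chromosome_class, c("Dot", "Autosome"))
  # the dot side is configurable because the published mapping leaves it open
  flipped <- species_scheme("willistoni",
                            fusion = list(scaffold = "scf2_1100000004943",
                                          junction = junction,
                                          dot_side = "above"))
  expect_equal(classify_chromosome(ann, flipped)$chromosome_class,
               c("Autosome", "Dot"))
})

test_that("classification is pure: idempotent and order-independent", {
  sim <- tiny_sim(seed = 21)
  ann <- sim$annotation
  scheme <- species_scheme("generic")
  once <- classify_chromosome(ann, scheme)
  twice <- classify_chromosome(once, scheme)
  expect_identical(once$chromosome_class, twice$chromosome_class)
  perm <- sample(nrow(ann))
  shuffled <- classify_chromosome(ann[perm, ], scheme)
  expect_identical(shuffled$chromosome_class, once$chromosome_class[perm])
  # the simulated annotation's own classes round-trip
  expect_identical(once$chromosome_class, ann$chromosome_class)
})

test_that("unknown elements become Unplaced with a warning, never a guess", {
  ann <- make_ann(gene_id = "g1", chromosome_or_scaffold = "scf_unknown",
                  start = 1L, muller_element = "Z")
  expect_warning(out <- classify_chromosome(ann, species_scheme("melanogaster")),
                 "Unplaced")
  expect_equal(out$chromosome_class, "Unplaced")
})

test_that("age branches split into old (0), new (1-6), unknown (missing)", {
  expect_equal(assign_age_group(c(0, 1, 6, NA)),
               c("old", "new", "new", "unknown"))
  expect_error(assign_age_group(7), "\\[0, 6\\]")
  expect_error(assign_age_group(-1), "\\[0, 6\\]")
})

test_that("ortholog filtering applies the three criteria in printed order", {
  anns <- list(
    mel = make_ann(gene_id = c("m1", "m2", "m3", "m4"),
                   muller_element = c("B", "B", "D", "A"),
                   chromosome_class = c("Autosome", "Autosome", "Autosome", "X"),
                   n_transcripts = c(1L, 2L, 1L, 1L)),
    wil = make_ann(gene_id = c("w1", "w2", "w3", "w4"),
                   muller_element = c("B", "B", "D", "B"),
                   chromosome_class = c("Autosome", "Autosome", "NeoX", "Autosome"),
                   n_transcripts = c(1L, 1L, 1L, 1L))
  )
  tab <- tibble::tibble(
    ortholog_id = rep(c("o1", "o2", "o3", "o4"), each = 2),
    species = rep(c("mel", "wil"), 4),
    gene_id = c("m1", "w1", "m2", "w2", "m3", "w3", "m4", "w4")
  )
  out <- filter_orthologs(tab, anns)
  expect_equal(unique(out$retained$ortholog_id), "o1")
  expect_equal(out$rejected$criterion[out$rejected$ortholog_id == "o2"], 1L)
  expect_equal(out$rejected$criterion[out$rejected$ortholog_id == "o3"], 3L)
  expect_equal(out$rejected$criterion[out$rejected$ortholog_id == "o4"], 2L)
  # partition property: retained + rejected = input, disjoint
  expect_equal(sort(c(unique(out$retained$ortholog_id), out$rejected$ortholog_id)),
               sort(unique(tab$ortholog_id)))
})

test_that("ortholog filtering matches an exhaustive rule-by-rule oracle", {
  set.seed(2024)
  species <- c("a", "b", "c")
  anns <- lapply(setNames(species, species), function(sp) {
    tibble::tibble(
      gene_id = paste0(sp, 1:30),
      muller_element = sample(c(LETTERS[1:6]), 30, replace = TRUE),
      n_transcripts = sample(1:3, 30, replace = TRUE, prob = c(0.7, 0.2, 0.1))
    ) |>
      dplyr::mutate(chromosome_class = dplyr::case_when(
        muller_element == "A" ~ "X", muller_element == "F" ~ "Dot",
        gene_id %in% paste0(sp, 29:30) ~ "Y", TRUE ~ "Autosome"))
  })
  member_ids <- as.vector(vapply(1:10, function(i) {
    paste0(species, sample(1:30, 3))
  }, character(3)))
  tab <- tibble::tibble(
    ortholog_id = rep(paste0("o", 1:10), each = 3),
    species = rep(species, 10),
    gene_id = member_ids
  )
  out <- filter_orthologs(tab, anns)
  oracle <- oracle_filter_orthologs(tab, anns)
  expect_setequal(unique(out$retained$ortholog_id), oracle$retained)
  got <- setNames(out$rejected$criterion, out$rejected$ortholog_id)
  expect_identical(got[names(oracle$criterion)], oracle$criterion)
})

test_that("unresolvable ortholog members raise a validation error", {
  anns <- list(a = make_ann(gene_id = "a1", muller_element = "B",
                            chromosome_class = "Autosome", n_transcripts = 1L))
  tab <- tibble::tibble(ortholog_id = "o1", species = "a", gene_id = "missing")
  expect_error(filter_orthologs(tab, anns), "unresolvable")
})
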