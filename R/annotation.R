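#' Species schemes mapping Muller elements to chromosome classes
#'
#' Drosophila chromosome arms correspond to conserved Muller elements A-F:
#' A is the X and F the dot in *D. melanogaster*. Built-in schemes cover the
#' four study species. In *D. willistoni*, Muller D is fused to the X and
#' classified as neo-X, so autosomes are elements B, C and E only; the
#' ancestral dot (element F) is fused into the Muller E scaffold
#' `scf2_1100000004943`, and genes are split at the E-F junction
#' (coordinate 2,014,728, between CG34036-PA on the F side and CG17119-PA on
#' the E side).
#'
#' @param species One of `"melanogaster"`, `"simulans"`, `"mojavensis"`,
#'   `"willistoni"`, or `"generic"` (A = X, B/C/D/E = autosome, F = dot,
#'   used for synthetic data where the neo-X carries its own element D
#'   mapping, see Details).
#' @param element_map Optional named character vector overriding the
#'   element-to-class map.
#' @param fusion Optional list `list(scaffold =, junction =, dot_side =)`
#'   overriding the dot-fusion rule; `dot_side` is `"below"` (positions
#'   before the junction are dot) or `"above"`. The published mapping does
#'   not fully determine the side, so it is configurable; default `"below"`.
#'
#' @return A `species_scheme` list.
#' @details The `"generic"` scheme, used for simulated annotations, maps
#'   D to NeoX so that a simulated neo-X class round-trips; real
#'   melanogaster-group species map D to Autosome.
#' @export
species_scheme <- function(species = c("melanogaster", "simulans", "mojavensis",
                                       "willistoni", "generic"),
                           element_map = NULL, fusion = NULL) {
  species <- match.arg(species)
  base_map <- switch(species,
    melanogaster = ,
    simulans = ,
    mojavensis = c(A = "X", B = "Autosome", C = "Autosome", D = "Autosome",
                   E = "Autosome", F = "Dot"),
    willistoni = c(A = "X", B = "Autosome", C = "Autosome", D = "NeoX",
                   E = "Autosome", F = "Dot"),
    generic = c(A = "X", B = "Autosome", C = "Autosome", D = "NeoX",
                E = "Autosome", F = "Dot")
  )
  if (!is.null(element_map)) base_map[names(element_map)] <- element_map
  if (!all(LETTERS[1:6] %in% names(base_map))) {
    abort("element map must cover Muller elements A-F.")
  }
  if (is.null(fusion) && species == "willistoni") {
    fusion <- list(scaffold = "scf2_1100000004943", junction = 2014728,
                   dot_side = "below")
  }
  if (!is.null(fusion)) {
    stopifnot(all(c("scaffold", "junction") %in% names(fusion)))
    fusion$dot_side <- fusion$dot_side %||% "below"
    if (!fusion$dot_side %in% c("below", "above")) {
      abort('`dot_side` must be "below" or "above".')
    }
  }
  structure(list(species = species, element_map = base_map, fusion = fusion),
            class = "species_scheme")
}

#' Classify genes into chromosome classes
#'
#' Assigns each gene a class in X, NeoX, Autosome, Dot, Y, Unplaced from its
#' Muller element under a species scheme. A dot-fusion rule (willistoni E-F
#' junction) takes precedence over the element map: genes on the fusion
#' scaffold whose start lies on the dot side of the junction are classified
#' Dot. Genes on a Y scaffold (chromosome name containing "Y") are Y-linked.
#' Unknown elements map to Unplaced with a warning, never to a silent guess.
#' The classification is a pure function of (annotation, scheme): it is
#' idempotent and independent of row order.
#'
#' @param annotation Tibble with at least `gene_id`,
#'   `chromosome_or_scaffold`, `start`, `muller_element`.
#' @param scheme A [species_scheme()].
#' @return The annotation tibble with a `chromosome_class` column
#'   (re)computed.
#' @export
classify_chromosome <- function(annotation, scheme) {
  stopifnot(inherits(scheme, "species_scheme"))
  annotation <- as_tibble(annotation)
  elem <- as.character(annotation$muller_element)
  cls <- unname(scheme$element_map[elem])
  is_y <- grepl("Y", annotation$chromosome_or_scaffold, ignore.case = FALSE)
  cls[is_y] <- "Y"
  unknown <- is.na(cls) & !is_y
  if (any(unknown)) {
    warn(paste0(sum(unknown), " gene(s) with unmapped Muller element set to Unplaced."))
    cls[unknown] <- "Unplaced"
  }
  if (!is.null(scheme$fusion)) {
    f <- scheme$fusion
    on_scaffold <- annotation$chromosome_or_scaffold == f$scaffold
    dot_side <- if (f$dot_side == "below") {
      annotation$start < f$junction
    } else {
      annotation$start > f$junction
    }
    cls[on_scaffold & dot_side] <- "Dot"
    cls[on_scaffold & !dot_side & !is_y] <- "Autosome"
  }
  annotation$chromosome_class <- cls
  annotation
}

#' Assign gene age groups from phylogenetic branch labels
#'
#' Branch 0 genes predate the Sophophora/Drosophila subgenus split and form
#' the old-gene group; branches 1-6 (less than ~62 My old, branch 6 being
#' melanogaster-specific) are new genes. Missing branches give `"unknown"`
#' and are excluded from age analyses.
#'
#' @param age_branch Integer vector of branch labels in 0..6, NA allowed.
#' @return Character vector in `c("old", "new", "unknown")`.
#' @export
#' @examples
#' assign_age_group(c(0, 3, 6, NA))
assign_age_group <- function(age_branch) {
  ok <- is.na(age_branch) | (age_branch >= 0 & age_branch <= 6)
  if (!all(ok)) {
    abort(paste0("age branches outside [0, 6]: ",
                 paste(unique(age_branch[!ok]), collapse = ", ")))
  }
  dplyr::case_when(
    is.na(age_branch) ~ "unknown",
    age_branch == 0 ~ "old",
    TRUE ~ "new"
  )
}

#' Filter an ortholog table by the cross-species comparability criteria
#'
#' Retains ortholog tuples where (1) every member has exactly one annotated
#' transcript (enabling 1:1 comparisons), (2) all members lie on the same
#' Muller element, and (3) no member is Y-linked or on Muller element D
#' (neo-X in willistoni, autosomal elsewhere, so D would bias
#' chromosome-level comparisons; dropping the tuple removes the D members'
#' partners in every species). A tuple failing several criteria is counted
#' once, under the first failed criterion in the order (1), (2), (3).
#'
#' @param ortholog_table Long tibble with columns `ortholog_id`, `species`,
#'   `gene_id`: one row per member gene.
#' @param annotations Named list of per-species annotation tibbles (names =
#'   species) with `gene_id`, `muller_element`, `chromosome_class`,
#'   `n_transcripts`.
#' @return A list with `retained` (the surviving subset of
#'   `ortholog_table`), `rejected` (tuple ids with `criterion` 1, 2 or 3),
#'   and `summary` (a tibble of per-criterion rejection counts).
#' @export
filter_orthologs <- function(ortholog_table, annotations) {
  ortholog_table <- as_tibble(ortholog_table)
  stopifnot(all(c("ortholog_id", "species", "gene_id") %in% names(ortholog_table)))

  ann <- purrr::imap_dfr(annotations, function(a, sp) {
    tibble(species = sp, gene_id = a$gene_id,
           muller_element = as.character(a$muller_element),
           chromosome_class = a$chromosome_class,
           n_transcripts = a$n_transcripts)
  })
  joined <- dplyr::left_join(ortholog_table, ann, by = c("species", "gene_id"))
  if (anyNA(joined$n_transcripts)) {
    bad <- joined %>% filter(is.na(.data$n_transcripts)) %>%
      mutate(key = paste0(.data$species, ":", .data$gene_id))
    abort(paste0("unresolvable ortholog members: ",
                 paste(head(bad$key, 5), collapse = ", "),
                 if (nrow(bad) > 5) " ..." else ""))
  }

  verdict <- joined %>%
    group_by(.data$ortholog_id) %>%
    summarise(
      fail1 = any(.data$n_transcripts != 1),
      fail2 = dplyr::n_distinct(.data$muller_element) > 1,
      fail3 = any(.data$chromosome_class == "Y" | .data$muller_element == "D"),
      .groups = "drop"
    ) %>%
    mutate(criterion = dplyr::case_when(
      .data$fail1 ~ 1L, .data$fail2 ~ 2L, .data$fail3 ~ 3L,
      TRUE ~ NA_integer_))

  rejected <- verdict %>% filter(!is.na(.data$criterion)) %>%
    select("ortholog_id", "criterion")
  retained <- ortholog_table %>%
    filter(!.data$ortholog_id %in% rejected$ortholog_id)
  summary <- tibble(criterion = 1:3) %>%
    left_join(count(rejected, .data$criterion, name = "n_rejected"),
              by = "criterion") %>%
    mutate(n_rejected = tidyr::replace_na(.data$n_rejected, 0L))
  list(retained = retained, rejected = rejected, summary = summary)
}
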