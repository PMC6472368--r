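#' Annotation rulesets
#'
#' A ruleset bundles (i) per-database hit-retention cutoffs, (ii)
#' per-pathway minimum distinct-gene counts, and (iii) the pathway
#' membership map assigning gene families to pathways.
#'
#' `default_ruleset()` carries the cutoffs used for seep-sediment MAG
#' annotation — dbCAN carbohydrate-active enzymes (e-value <= 1e-18,
#' coverage fraction >= 0.40), MEROPS peptidases and the custom
#' hydrocarbon-degradation database (e-value <= 1e-20, identity >= 30%),
#' read-level marker searches (e-value <= 1e-10, identity >= 70%), and
#' GhostKOALA KO assignments (no additional thresholds) — together with the
#' multi-gene pathway rules: at least 5 distinct Embden-Meyerhof-Parnas
#' genes, 3 beta-oxidation genes, 4 Wood-Ljungdahl genes and 6 TCA-cycle
#' genes; any pathway without an explicit rule (single-marker functions
#' such as lactate/ethanol dehydrogenases, dsrAB, rdhA, mcrA, hydrogenase
#' subgroups) requires >= 1 retained hit. All threshold comparisons are
#' inclusive. The default family->pathway map follows standard KEGG module
#' definitions and ships as an editable TSV
#' (`seep_example("pathway_families.tsv")`).
#'
#' @param cutoffs Tibble `database_tag`, `max_evalue`, `min_identity_pct`,
#'   `min_coverage_frac` (`NA` = field not tested).
#' @param pathway_rules Tibble `pathway`, `min_genes`.
#' @param families Tibble `family_id`, `pathway` (membership map).
#' @return A list of class `seep_ruleset`.
#' @examples
#' default_ruleset()
#' @export
ruleset <- function(cutoffs, pathway_rules, families) {
  stopifnot(all(c("database_tag", "max_evalue", "min_identity_pct",
                  "min_coverage_frac") %in% names(cutoffs)),
            all(c("pathway", "min_genes") %in% names(pathway_rules)),
            all(c("family_id", "pathway") %in% names(families)))
  if (any(pathway_rules$min_genes < 1)) {
    abort("pathway rules must require at least one gene")
  }
  with_vals <- c(cutoffs$max_evalue, cutoffs$min_identity_pct,
                 cutoffs$min_coverage_frac)
  if (any(with_vals <= 0, na.rm = TRUE)) {
    abort("cutoff thresholds must be positive")
  }
  structure(list(cutoffs = as_tibble(cutoffs),
                 pathway_rules = as_tibble(pathway_rules),
                 families = as_tibble(families)),
            class = "seep_ruleset")
}

#' @rdname ruleset
#' @export
default_ruleset <- function() {
  cutoffs <- tibble(
    database_tag      = c("dbcan", "merops", "custom", "reads", "ghostkoala"),
    max_evalue        = c(1e-18, 1e-20, 1e-20, 1e-10, NA),
    min_identity_pct  = c(NA, 30, 30, 70, NA),
    min_coverage_frac = c(0.40, NA, NA, NA, NA))
  pathway_rules <- tibble(
    pathway   = c("emp", "beta_oxidation", "wood_ljungdahl", "tca"),
    min_genes = c(5L, 3L, 4L, 6L))
  families <- readr::read_tsv(seep_example("pathway_families.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  ruleset(cutoffs, pathway_rules, families)
}

#' @export
print.seep_ruleset <- function(x, ...) {
  cat("<seep_ruleset>\n  database cutoffs:\n")
  print(x$cutoffs)
  cat("  multi-gene pathway rules (others default to >= 1):\n")
  print(x$pathway_rules)
  cat(sprintf("  family map: %d families across %d pathways\n",
              nrow(x$families), dplyr::n_distinct(x$families$pathway)))
  invisible(x)
}

#' Read an annotation hit table
#'
#' Reads a TSV of per-gene annotation hits with columns `genome_id`,
#' `gene_id`, `family_id`, `evalue`, and optionally `pathway_label`,
#' `identity_pct`, `coverage_frac`, `bitscore`, `database_tag`. Missing
#' optional columns are filled with `NA` so downstream rules simply skip
#' the fields they cannot test.
#'
#' @param path TSV path.
#' @return A hit tibble.
#' @export
read_hits <- function(path) {
  hits <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("genome_id", "gene_id", "family_id", "evalue")
  missing <- setdiff(needed, names(hits))
  if (length(missing) > 0) {
    abort(paste0("hit table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  for (col in c("identity_pct", "coverage_frac", "bitscore")) {
    if (!col %in% names(hits)) hits[[col]] <- NA_real_
  }
  if (!"pathway_label" %in% names(hits)) hits$pathway_label <- NA_character_
  if (!"database_tag" %in% names(hits)) hits$database_tag <- NA_character_
  validate_hits(hits)
}

validate_hits <- function(hits) {
  hits <- as_tibble(hits)
  if (any(hits$evalue < 0, na.rm = TRUE)) abort("e-values must be >= 0")
  if (any(hits$identity_pct < 0 | hits$identity_pct > 100, na.rm = TRUE)) {
    abort("identity_pct must lie in [0, 100]")
  }
  if (any(hits$coverage_frac < 0 | hits$coverage_frac > 1, na.rm = TRUE)) {
    abort("coverage_frac must lie in [0, 1]")
  }
  hits
}

#' Filter annotation hits by database cutoffs
#'
#' Retains a hit iff every threshold its database rule defines passes, with
#' inclusive comparisons: `evalue <= max_evalue`, `identity_pct >=
#' min_identity_pct`, `coverage_frac >= min_coverage_frac`. Thresholds a
#' rule leaves `NA` are not tested. Row order is preserved and no field is
#' mutated, so the operation is idempotent.
#'
#' @param hits A hit tibble ([read_hits()]); if it has a `database_tag`
#'   column each row is judged under its own tag, otherwise `database_tag`
#'   must be supplied.
#' @param rules A `seep_ruleset` (default [default_ruleset()]).
#' @param database_tag Tag applied to all rows lacking one.
#' @return The retained subset, same columns, original order.
#' @examples
#' hits <- tibble::tibble(
#'   genome_id = "g1", gene_id = paste0("p", 1:4), family_id = "K00001",
#'   evalue = c(1e-21, 1e-19, 1e-21, 1e-20),
#'   identity_pct = c(35, 35, 25, 30), coverage_frac = NA_real_)
#' filter_hits(hits, database_tag = "merops")  # rows 1 and 4 survive
#' @export
filter_hits <- function(hits, rules = default_ruleset(), database_tag = NULL) {
  stopifnot(inherits(rules, "seep_ruleset"))
  hits <- validate_hits(hits)
  if (nrow(hits) == 0) return(hits)
  tags <- if ("database_tag" %in% names(hits) && !all(is.na(hits$database_tag))) {
    if (anyNA(hits$database_tag) && is.null(database_tag)) {
      abort("some hits lack database_tag and no default was supplied")
    }
    dplyr::coalesce(hits$database_tag, database_tag %||% NA_character_)
  } else {
    if (is.null(database_tag)) {
      abort("hits carry no database_tag column; supply database_tag =")
    }
    rep(database_tag, nrow(hits))
  }
  unknown <- setdiff(unique(tags), rules$cutoffs$database_tag)
  if (length(unknown) > 0) {
    abort(sprintf("unknown database tag(s) %s; known tags: %s",
                  paste(unknown, collapse = ", "),
                  paste(rules$cutoffs$database_tag, collapse = ", ")))
  }
  rule <- rules$cutoffs[match(tags, rules$cutoffs$database_tag), ]
  keep <- (is.na(rule$max_evalue) | hits$evalue <= rule$max_evalue) &
    (is.na(rule$min_identity_pct) |
       (!is.na(hits$identity_pct) & hits$identity_pct >= rule$min_identity_pct)) &
    (is.na(rule$min_coverage_frac) |
       (!is.na(hits$coverage_frac) & hits$coverage_frac >= rule$min_coverage_frac))
  hits[keep, , drop = FALSE]
}

#' Genome function profiles: distinct gene families per pathway
#'
#' Collapses retained hits to the count of *distinct* gene families per
#' genome and pathway (duplicate hits to one enzyme never satisfy a
#' multi-gene rule). Families are assigned to pathways via the ruleset's
#' membership map; hits to unmapped families are dropped with a message.
#'
#' @inheritParams filter_hits
#' @return A tibble `genome_id`, `pathway`, `n_families`.
#' @export
profile_genomes <- function(hits, rules = default_ruleset()) {
  stopifnot(inherits(rules, "seep_ruleset"))
  hits <- validate_hits(hits)
  mapped <- inner_join(hits, select(rules$families, "family_id", "pathway"),
                       by = "family_id")
  n_unmapped <- nrow(hits) - nrow(mapped)
  if (n_unmapped > 0) {
    inform(sprintf("%d hit(s) to families outside the pathway map were dropped",
                   n_unmapped))
  }
  mapped %>%
    distinct(.data$genome_id, .data$pathway, .data$family_id) %>%
    count(.data$genome_id, .data$pathway, name = "n_families")
}

#' Rule-based pathway presence calling
#'
#' Applies the per-pathway minimum distinct-gene rules to a genome function
#' profile: a pathway is present in a genome iff its distinct-family count
#' meets its threshold (inclusive). Pathways without an explicit rule get
#' the single-marker default (>= 1) with a warning and are flagged in
#' `rule_defaulted`. Genomes listed in `genomes` but absent from the
#' profile yield all-absent rows.
#'
#' @param profile A tibble from [profile_genomes()] (columns `genome_id`,
#'   `pathway`, `n_families`).
#' @param rules A `seep_ruleset`.
#' @param genomes Optional character vector forcing the full genome set
#'   (so hit-less genomes appear as all-absent rows).
#' @return A presence tibble: `genome_id`, `pathway`, `n_families`,
#'   `min_genes`, `present`, `rule_defaulted`, covering every
#'   genome x known-pathway combination.
#' @examples
#' prof <- tibble::tibble(genome_id = "g1",
#'                        pathway = c("emp", "tca"), n_families = c(5L, 5L))
#' call_pathways(prof)  # emp present (5 >= 5), tca absent (5 < 6)
#' @export
call_pathways <- function(profile, rules = default_ruleset(), genomes = NULL) {
  stopifnot(inherits(rules, "seep_ruleset"),
            all(c("genome_id", "pathway", "n_families") %in% names(profile)))
  known <- unique(c(rules$pathway_rules$pathway, rules$families$pathway))
  extra <- setdiff(unique(profile$pathway), known)
  if (length(extra) > 0) {
    warn(sprintf("pathway(s) absent from ruleset, defaulting to >= 1: %s",
                 paste(extra, collapse = ", ")))
  }
  all_pathways <- union(known, extra)
  all_genomes <- union(genomes %||% character(), unique(profile$genome_id))
  grid <- tidyr::expand_grid(genome_id = all_genomes, pathway = all_pathways)
  grid %>%
    left_join(profile, by = c("genome_id", "pathway")) %>%
    mutate(n_families = dplyr::coalesce(.data$n_families, 0L)) %>%
    left_join(rules$pathway_rules, by = "pathway") %>%
    mutate(rule_defaulted = is.na(.data$min_genes),
           min_genes = dplyr::coalesce(.data$min_genes, 1L),
           present = .data$n_families >= .data$min_genes) %>%
    arrange(.data$genome_id, .data$pathway)
}

#' @rdname call_pathways
#' @param presence A presence tibble from `call_pathways()`.
#' @return `presence_wide()`: a genome x pathway 0/1 tibble.
#' @export
presence_wide <- function(presence) {
  presence %>%
    mutate(value = as.integer(.data$present)) %>%
    select("genome_id", "pathway", "value") %>%
    tidyr::pivot_wider(names_from = "pathway", values_from = "value",
                       values_fill = 0L)
}

#' Marker-gene census as relative frequencies
#'
#' Maps each retained hit to a single category (hydrogenase subtype, mcrA
#' clade, taxon, ...) and reports per-category counts and fractions of all
#' categorized hits (fractions sum to 1). Hits whose family has no category
#' are counted under `"unassigned"`. With `total_reads` given, a
#' hits-per-million-reads column is added.
#'
#' @inheritParams filter_hits
#' @param category_map Tibble `family_id`, `category`.
#' @param total_reads Optional library size for per-million normalization.
#' @return A tibble `category`, `n_hits`, `fraction` (and `per_million`).
#' @examples
#' hits <- tibble::tibble(genome_id = "s1", gene_id = as.character(1:10),
#'                        family_id = rep(c("1a", "3b", "3c"), c(2, 5, 3)),
#'                        evalue = 1e-30)
#' marker_census(hits, tibble::tibble(family_id = c("1a", "3b", "3c"),
#'                                    category = c("1a", "3b", "3c")))
#' @export
marker_census <- function(hits, category_map, total_reads = NULL) {
  stopifnot(all(c("family_id", "category") %in% names(category_map)))
  hits <- validate_hits(hits)
  if (nrow(hits) == 0) abort("no categorized hits: census fractions undefined")
  out <- hits %>%
    left_join(select(category_map, "family_id", "category"), by = "family_id") %>%
    mutate(category = dplyr::coalesce(.data$category, "unassigned")) %>%
    count(.data$category, name = "n_hits") %>%
    mutate(fraction = .data$n_hits / sum(.data$n_hits))
  if (!is.null(total_reads)) {
    out$per_million <- out$n_hits * 1e6 / total_reads
  }
  out
}

#' Chao1 richness estimator
#'
#' Nonparametric richness estimate from singleton and doubleton counts.
#' Classic form: `S_obs + F1^2 / (2 F2)` (requires `F2 > 0` unless
#' `F1 == 0`); bias-corrected form: `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`,
#' defined for every input. The estimate never falls below the observed
#' richness and equals it exactly when there are no singletons.
#'
#' @param counts Non-negative integer abundance vector (zeros allowed and
#'   ignored), or a data frame with a `count` column.
#' @param bias_corrected Use the bias-corrected form (default `FALSE`).
#' @return A one-row tibble: `s_obs`, `f1`, `f2`, `estimator`, `chao1`.
#' @examples
#' chao1(c(rep(1, 4), rep(2, 2), 5, 9, 10, 11))  # S=10, F1=4, F2=2 -> 14
#' @export
chao1 <- function(counts, bias_corrected = FALSE) {
  if (is.data.frame(counts)) {
    if (!"count" %in% names(counts)) abort("data-frame input needs a 'count' column")
    counts <- counts$count
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("counts must be non-negative integers")
  }
  counts <- counts[counts > 0]
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  est <- if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    if (f2 == 0 && f1 > 0) {
      abort("F2 = 0: classic Chao1 undefined; use bias_corrected = TRUE")
    }
    s_obs + if (f1 == 0) 0 else f1^2 / (2 * f2)
  }
  tibble(s_obs = s_obs, f1 = f1, f2 = f2,
         estimator = if (bias_corrected) "bias_corrected" else "classic",
         chao1 = est)
}
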