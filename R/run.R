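# Pipeline stage runners: thin orchestration over the analysis functions.
# Each stage writes its outputs atomically (temp file + rename within the
# output directory) together with a JSON run manifest recording inputs
# (with md5 checksums), parameters, seed and package version, so any run is
# reproducible from its manifest alone. Manifests carry no timestamps:
# rerunning a stage with identical config yields byte-identical outputs.

write_atomic <- function(data, path, writer = readr::write_tsv) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile("stage_", tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(data, tmp)
  file.rename(tmp, path)
  invisible(path)
}

write_manifest <- function(out_dir, stage, inputs = character(),
                           params = list(), seed = NULL) {
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    stage = stage,
    package = "seepcat",
    version = as.character(utils::packageVersion("seepcat")),
    inputs = if (length(inputs)) {
      lapply(stats::setNames(as.list(inputs), basename(inputs)),
             function(p) list(path = p, md5 = unname(tools::md5sum(p))))
    } else list(),
    params = params,
    seed = seed)
  path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile("manifest_", tmpdir = out_dir)
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the reaction-energetics stage
#'
#' Reads a reaction file and a species constants file, computes standard
#' and in-situ energies under the given conditions, and writes a
#' deterministic report (`thermo_report.tsv`, ordered by `reaction_id`)
#' with columns `reaction_id`, `label`, `class`, `dG0_kJ`, `dH0_kJ`,
#' `dG_T_kJ`, `rtlnQ_kJ`, `dG_insitu_kJ`, `balanced`, `warnings`.
#'
#' @param reactions_file,species_file TSV paths (defaults: the bundled
#'   deep-sea reaction set and constants).
#' @param cond A [conditions()] object.
#' @param out_dir Output directory; `NULL` returns the report without
#'   writing.
#' @param energies Optional tabulated standard energies (see
#'   [insitu_energy()]).
#' @return The report tibble, invisibly when written.
#' @export
run_thermo <- function(reactions_file = seep_example("catabolic_reactions.tsv"),
                       species_file = seep_example("species_constants.tsv"),
                       cond = deep_sea_conditions(), out_dir = NULL,
                       energies = NULL) {
  reactions <- read_reactions(reactions_file)
  db <- read_species(species_file)
  if (nrow(reactions) == 0) {
    report <- tibble(reaction_id = character(), label = character(),
                     class = character(), dG0_kJ = numeric(),
                     dH0_kJ = numeric(), dG_T_kJ = numeric(),
                     rtlnQ_kJ = numeric(), dG_insitu_kJ = numeric(),
                     balanced = logical(), warnings = character())
  } else {
    bal <- check_balance(reactions, db)
    rec <- insitu_energy(reactions, db, cond, energies = energies, quiet = TRUE)
    meta <- distinct(reactions, .data$reaction_id, .data$label, .data$class)
    report <- rec %>%
      left_join(meta, by = "reaction_id") %>%
      left_join(select(bal, "reaction_id", "balanced"), by = "reaction_id") %>%
      mutate(warnings = if_else(.data$balanced, "",
                                "element/charge balance residuals nonzero")) %>%
      select("reaction_id", "label", "class", "dG0_kJ", "dH0_kJ",
             "dG_T_kJ", "rtlnQ_kJ", "dG_insitu_kJ", "balanced",
             "warnings") %>%
      arrange(.data$reaction_id)
  }
  if (!is.null(out_dir)) {
    write_atomic(report, file.path(out_dir, "thermo_report.tsv"))
    write_manifest(out_dir, "thermo",
                   inputs = c(reactions_file, species_file),
                   params = list(temperature_K = cond$temperature_K,
                                 pressure_atm = cond$pressure_atm,
                                 pH = cond$pH,
                                 concentrations = as.list(cond$concentrations)))
    return(invisible(report))
  }
  report
}

#' Run the pathway-calling stage
#'
#' Filters a hit table under the ruleset cutoffs, profiles distinct gene
#' families per genome and pathway, calls presence, and writes
#' `presence.tsv` (wide genome x pathway 0/1), `presence_counts.tsv`
#' (long, with counts and thresholds) and a manifest.
#'
#' @param hits_file Hit-table TSV ([read_hits()]).
#' @param rules A `seep_ruleset`.
#' @param out_dir Output directory; `NULL` returns without writing.
#' @return The long presence tibble, invisibly when written.
#' @export
run_call <- function(hits_file, rules = default_ruleset(), out_dir = NULL) {
  hits <- read_hits(hits_file)
  kept <- filter_hits(hits, rules)
  presence <- call_pathways(profile_genomes(kept, rules), rules,
                            genomes = unique(hits$genome_id))
  if (!is.null(out_dir)) {
    write_atomic(presence_wide(presence), file.path(out_dir, "presence.tsv"))
    write_atomic(presence, file.path(out_dir, "presence_counts.tsv"))
    write_manifest(out_dir, "call", inputs = hits_file,
                   params = list(n_hits = nrow(hits), n_retained = nrow(kept)))
    return(invisible(presence))
  }
  presence
}

#' Run the gas-geochemistry stage
#'
#' For each site: approximate methane from total alkane gas minus C2+
#' alkanes, carry the measured Bernard ratio (never recomputed from bulk
#' columns), and classify gas origin. Writes `geochem_report.tsv` and a
#' manifest.
#'
#' @param gas_file Site gas table TSV with columns `site_id`,
#'   `total_alkane_gas_ppm`, `c2plus_ppm`, `c1_c2c3_ratio`,
#'   `d13C_CH4_permil` (defaults to the bundled site table).
#' @param out_dir Output directory; `NULL` returns without writing.
#' @return The per-site report tibble, invisibly when written.
#' @export
run_geochem <- function(gas_file = seep_example("site_geochemistry.tsv"),
                        out_dir = NULL) {
  gas <- readr::read_tsv(gas_file, show_col_types = FALSE, progress = FALSE)
  needed <- c("site_id", "total_alkane_gas_ppm", "c2plus_ppm",
              "c1_c2c3_ratio", "d13C_CH4_permil")
  missing <- setdiff(needed, names(gas))
  if (length(missing) > 0) {
    abort(paste0("gas table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  calls <- classify_gas_origin(gas$c1_c2c3_ratio, gas$d13C_CH4_permil)
  report <- gas %>%
    mutate(methane_ppm = approximate_methane(.data$total_alkane_gas_ppm,
                                             .data$c2plus_ppm),
           origin = calls$label, evidence = calls$evidence) %>%
    arrange(.data$site_id)
  if (!is.null(out_dir)) {
    write_atomic(report, file.path(out_dir, "geochem_report.tsv"))
    write_manifest(out_dir, "geochem", inputs = gas_file)
    return(invisible(report))
  }
  report
}

#' Run the metabolomics-normalization stage
#'
#' Constant-sum normalizes an intensity matrix, computes log fractions and
#' the per-site replicate summary, and writes the heatmap-ready long table
#' (`metabolites_long.csv`: pathway, compound, site, replicate, fraction,
#' log_fraction) plus `replicate_summary.csv` and a manifest.
#'
#' @param intensity_file CSV, rows = compounds (column `compound`),
#'   remaining columns = samples.
#' @param sample_file CSV mapping `sample` to `site` (and `replicate`).
#' @param pathway_file Optional CSV `compound`, `pathway`,
#'   `dual_pathway_flag`.
#' @param floor Log-display floor (see [log_fractional()]).
#' @param out_dir Output directory; `NULL` returns without writing.
#' @return A list of `long` and `summary` tibbles, invisibly when written.
#' @export
run_metab <- function(intensity_file, sample_file, pathway_file = NULL,
                      floor = 1e-6, out_dir = NULL) {
  raw <- readr::read_csv(intensity_file, show_col_types = FALSE, progress = FALSE)
  sample_map <- readr::read_csv(sample_file, show_col_types = FALSE, progress = FALSE)
  pathway_map <- if (!is.null(pathway_file)) {
    readr::read_csv(pathway_file, show_col_types = FALSE, progress = FALSE)
  }
  frac <- constant_sum_normalize(raw)
  logf <- log_fractional(frac, floor = floor)
  long <- pathway_ordered_matrix(frac, pathway_map) %>%
    rename(fraction = "value") %>%
    left_join(pathway_ordered_matrix(logf, pathway_map) %>%
                rename(log_fraction = "value") %>%
                select("compound", "sample", "log_fraction"),
              by = c("compound", "sample")) %>%
    left_join(sample_map, by = "sample")
  summary <- replicate_summary(frac, sample_map)
  if (!is.null(out_dir)) {
    write_atomic(long, file.path(out_dir, "metabolites_long.csv"),
                 writer = readr::write_csv)
    write_atomic(summary, file.path(out_dir, "replicate_summary.csv"),
                 writer = readr::write_csv)
    write_manifest(out_dir, "metab",
                   inputs = c(intensity_file, sample_file,
                              pathway_file %||% character()),
                   params = list(floor = floor))
    return(invisible(list(long = long, summary = summary)))
  }
  list(long = long, summary = summary)
}

#' Run the synthetic-study stage
#'
#' Writes a complete synthetic fixture directory ([synthetic_study()])
#' plus a manifest.
#'
#' @inheritParams synthetic_study
#' @param ... Passed to [synthetic_study()].
#' @return The generated object list, invisibly.
#' @export
run_simulate <- function(out_dir, seed = 1, ...) {
  out <- synthetic_study(out_dir = out_dir, seed = seed, ...)
  write_manifest(out_dir, "simulate", params = list(...), seed = seed)
  invisible(out)
}
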