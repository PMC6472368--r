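#' Constant-sum normalization of metabolite intensities
#'
#' Divides each sample column by its own total so every column becomes a
#' vector of fractional abundances summing to 1 — the standard control for
#' varying total organic content across sediment extracts. The operation is
#' scale-invariant per sample and idempotent.
#'
#' @param table Data frame with a `compound` character column and one
#'   numeric column per sample (non-negative intensities).
#' @return Tibble of the same shape with columns normalized.
#' @examples
#' constant_sum_normalize(
#'   tibble::tibble(compound = c("a", "b", "c"), s1 = c(2, 2, 4)))
#' @export
constant_sum_normalize <- function(table) {
  table <- as_tibble(table)
  samples <- sample_columns(table)
  for (s in samples) {
    if (any(table[[s]] < 0, na.rm = TRUE)) {
      abort(sprintf("negative intensities in sample '%s'", s))
    }
    total <- sum(table[[s]], na.rm = TRUE)
    if (total <= 0) {
      abort(sprintf("sample '%s' has zero total intensity; cannot normalize", s))
    }
    table[[s]] <- dplyr::coalesce(table[[s]], 0) / total
  }
  table
}

sample_columns <- function(table) {
  if (!"compound" %in% names(table)) {
    abort("metabolite table needs a 'compound' column")
  }
  samples <- names(table)[vapply(table, is.numeric, logical(1))]
  if (length(samples) == 0) abort("no numeric sample columns found")
  samples
}

#' Log10 fractional abundance
#'
#' Maps constant-sum normalized fractions to `log10(max(fraction, floor))`.
#' The floor keeps zero fractions displayable on a log scale; it is recorded
#' in the output's `"floor"` attribute. Monotone: a larger fraction never
#' maps to a smaller log value.
#'
#' @param table A constant-sum normalized table ([constant_sum_normalize()]).
#' @param floor Positive lower bound applied before taking log10
#'   (default `1e-6`).
#' @return Tibble of log10 fractions, attribute `"floor"` set.
#' @export
log_fractional <- function(table, floor = 1e-6) {
  if (!is.numeric(floor) || length(floor) != 1 || floor <= 0) {
    abort("floor must be a single positive number")
  }
  table <- as_tibble(table)
  samples <- sample_columns(table)
  for (s in samples) table[[s]] <- log10(pmax(table[[s]], floor))
  attr(table, "floor") <- floor
  table
}

#' Per-site replicate summary of fractional abundances
#'
#' Summarizes technical replicates per site: the mean fractional abundance
#' of each compound and its coefficient of variation (sample standard
#' deviation with the n-1 denominator, divided by the mean). Sites with a
#' single replicate get a mean and `NA` CV, flagged in `cv_defined`.
#'
#' @param table A constant-sum normalized table.
#' @param sample_map Tibble `sample`, `site` (and optionally `replicate`)
#'   mapping each sample column to its site.
#' @return A tibble `site`, `compound`, `n_replicates`, `mean_fraction`,
#'   `cv`, `cv_defined`.
#' @examples
#' tbl <- tibble::tibble(compound = "x", r1 = 0.1, r2 = 0.3)
#' replicate_summary(tbl, tibble::tibble(sample = c("r1", "r2"), site = "A"))
#' @export
replicate_summary <- function(table, sample_map) {
  stopifnot(all(c("sample", "site") %in% names(sample_map)))
  table <- as_tibble(table)
  samples <- sample_columns(table)
  unmapped <- setdiff(samples, sample_map$sample)
  if (length(unmapped) > 0) {
    abort(sprintf("sample(s) missing from sample_map: %s",
                  paste(unmapped, collapse = ", ")))
  }
  long <- table %>%
    tidyr::pivot_longer(all_of(samples), names_to = "sample",
                        values_to = "fraction") %>%
    mutate(fraction = dplyr::coalesce(.data$fraction, 0)) %>%
    left_join(select(sample_map, "sample", "site"), by = "sample")
  long %>%
    group_by(.data$site, .data$compound) %>%
    summarise(n_replicates = dplyr::n(),
              mean_fraction = mean(.data$fraction),
              cv = if (dplyr::n() >= 2 && mean(.data$fraction) > 0) {
                stats::sd(.data$fraction) / mean(.data$fraction)
              } else NA_real_,
              .groups = "drop") %>%
    mutate(cv_defined = !is.na(.data$cv))
}

#' Pathway-grouped long table for heatmap rendering
#'
#' Pivots a (log-)fraction table to long format and orders rows by pathway
#' then compound name — the layout of pathway-annotated metabolite
#' heatmaps. Compounds without a pathway label fall under `"unassigned"`;
#' compounds flagged as intermediates of more than one pathway carry
#' `dual_pathway = TRUE`. The grouping is a pure permutation: the row
#' multiset is unchanged.
#'
#' @param table A metabolite table (fractions or log fractions).
#' @param pathway_map Tibble `compound`, `pathway` and optional
#'   `dual_pathway_flag`.
#' @return A long tibble `pathway`, `compound`, `dual_pathway`, `sample`,
#'   `value`, ordered by (pathway, compound, sample).
#' @export
pathway_ordered_matrix <- function(table, pathway_map = NULL) {
  table <- as_tibble(table)
  samples <- sample_columns(table)
  if (is.null(pathway_map) || nrow(pathway_map) == 0) {
    pathway_map <- tibble(compound = character(), pathway = character())
  }
  stopifnot(all(c("compound", "pathway") %in% names(pathway_map)))
  if (!"dual_pathway_flag" %in% names(pathway_map)) {
    pathway_map$dual_pathway_flag <- FALSE
  }
  table %>%
    tidyr::pivot_longer(all_of(samples), names_to = "sample",
                        values_to = "value") %>%
    left_join(select(pathway_map, "compound", "pathway", "dual_pathway_flag"),
              by = "compound") %>%
    mutate(pathway = dplyr::coalesce(.data$pathway, "unassigned"),
           dual_pathway = dplyr::coalesce(.data$dual_pathway_flag, FALSE)) %>%
    select("pathway", "compound", "dual_pathway", "sample", "value") %>%
    arrange(.data$pathway, .data$compound, .data$sample)
}
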