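#' Approximate methane from bulk alkane-gas measurements
#'
#' Where methane was not itemized, its concentration is approximated by
#' subtracting the summed C2+ alkanes from the total alkane gas. A negative
#' difference (C2+ exceeding the total, a measurement inconsistency) is
#' floored at zero with a warning.
#'
#' @param total_alkane_gas_ppm,c2plus_ppm Total alkane gas and summed C2+
#'   alkanes, ppm by volume. Vectorized.
#' @return Approximate methane, ppm.
#' @examples
#' approximate_methane(936012, 17.5)  # 935994.5
#' @export
approximate_methane <- function(total_alkane_gas_ppm, c2plus_ppm) {
  if (anyNA(total_alkane_gas_ppm) || anyNA(c2plus_ppm)) {
    abort("total_alkane_gas_ppm and c2plus_ppm must both be present")
  }
  if (any(total_alkane_gas_ppm < 0) || any(c2plus_ppm < 0)) {
    abort("gas concentrations must be >= 0")
  }
  out <- total_alkane_gas_ppm - c2plus_ppm
  if (any(out < 0)) {
    warn("C2+ exceeds total alkane gas for some site(s); methane floored at 0")
    out <- pmax(out, 0)
  }
  out
}

#' Bernard ratio C1/(C2+C3)
#'
#' The molar ratio of methane to the sum of ethane and propane, the
#' gas-wetness axis of the Bernard diagram. Undefined when `c2 + c3` is
#' zero (reported as NA in field tables); this raises an error rather than
#' returning infinity.
#'
#' @param c1,c2,c3 Methane, ethane, propane concentrations (same units;
#'   the ratio is scale-invariant). Vectorized.
#' @return Dimensionless ratio.
#' @examples
#' bernard_ratio(994000, 200, 50)  # 3976
#' @export
bernard_ratio <- function(c1, c2, c3) {
  if (any(c(c1, c2, c3) < 0, na.rm = TRUE)) {
    abort("gas concentrations must be >= 0")
  }
  denom <- c2 + c3
  if (any(denom == 0, na.rm = TRUE)) {
    abort("C2 + C3 is zero: Bernard ratio undefined (field tables print NA)")
  }
  c1 / denom
}

#' Classify hydrocarbon gas origin
#'
#' Joint Bernard-ratio / methane-carbon-isotope classification. Biogenic
#' gas: ratio > 1000 *and* delta13C more negative than -60 permil.
#' Thermogenic gas (conventional Bernard-diagram bands, configurable):
#' ratio < 100 *and* delta13C above -50 permil. Sites where the two lines
#' of evidence fire in opposite directions are `mixed`; a single line of
#' evidence, or values between the bands, give `indeterminate`. Every call
#' carries machine-readable evidence strings recording which rules fired.
#'
#' @param ratio Bernard ratio C1/(C2+C3); `NA` if unavailable.
#' @param delta13C Methane delta13C, permil vs PDB; `NA` if unavailable.
#' @param thresholds Named list overriding the classification bands
#'   (`biogenic_ratio`, `biogenic_d13C`, `thermogenic_ratio`,
#'   `thermogenic_d13C`).
#' @return A tibble with one row per input: `bernard_ratio`, `delta13C`,
#'   `label` (`biogenic`/`thermogenic`/`mixed`/`indeterminate`),
#'   `evidence` (semicolon-joined rule strings).
#' @examples
#' classify_gas_origin(3974.2, -85.1)  # biogenic
#' classify_gas_origin(50, -40)        # thermogenic
#' classify_gas_origin(2000, NA)       # indeterminate (isotope missing)
#' @export
classify_gas_origin <- function(ratio, delta13C,
                                thresholds = list()) {
  th <- modifyList(list(biogenic_ratio = 1000, biogenic_d13C = -60,
                        thermogenic_ratio = 100, thermogenic_d13C = -50),
                   thresholds)
  n <- max(length(ratio), length(delta13C))
  ratio <- rep_len(ratio, n)
  delta13C <- rep_len(delta13C, n)
  one <- function(r, d) {
    ev <- character()
    bio_r <- !is.na(r) && r > th$biogenic_ratio
    bio_d <- !is.na(d) && d < th$biogenic_d13C
    thermo_r <- !is.na(r) && r < th$thermogenic_ratio
    thermo_d <- !is.na(d) && d > th$thermogenic_d13C
    if (bio_r)    ev <- c(ev, sprintf("ratio %.4g > %g (biogenic band)", r, th$biogenic_ratio))
    if (bio_d)    ev <- c(ev, sprintf("d13C %.4g < %g (biogenic band)", d, th$biogenic_d13C))
    if (thermo_r) ev <- c(ev, sprintf("ratio %.4g < %g (thermogenic band)", r, th$thermogenic_ratio))
    if (thermo_d) ev <- c(ev, sprintf("d13C %.4g > %g (thermogenic band)", d, th$thermogenic_d13C))
    if (is.na(r)) ev <- c(ev, "no Bernard ratio")
    if (is.na(d)) ev <- c(ev, "no methane d13C")
    label <- if (bio_r && bio_d) "biogenic"
      else if (thermo_r && thermo_d) "thermogenic"
      else if ((bio_r || bio_d) && (thermo_r || thermo_d)) "mixed"
      else "indeterminate"
    tibble(bernard_ratio = r, delta13C = d, label = label,
           evidence = paste(ev, collapse = "; "))
  }
  purrr::map2_dfr(ratio, delta13C, one)
}

#' Liquid n-alkane summary
#'
#' Sums per-carbon-number n-alkane concentrations over the C15-C34 window
#' (the petroleum-relevant range reported in sediment surveys) and flags
#' the presence of an unresolved complex mixture (UCM), the chromatographic
#' hump of degraded petroleum.
#'
#' @param alkanes Data frame with `carbon_number` (integer) and
#'   `conc_ng_g` columns; rows with `NA` carbon numbers are an error.
#' @param ucm_ug_g UCM concentration, ug/g (default 0 = none detected).
#' @param range Inclusive carbon-number window (default `c(15, 34)`).
#' @return A one-row tibble: `sum_n_alkanes_ng_g`, `ucm_flag`.
#' @examples
#' alkane_summary(tibble::tibble(carbon_number = c(14, 15, 34, 35),
#'                               conc_ng_g = c(100, 200, 300, 50)))
#' @export
alkane_summary <- function(alkanes, ucm_ug_g = 0, range = c(15, 34)) {
  if (nrow(alkanes) == 0) {
    return(tibble(sum_n_alkanes_ng_g = 0, ucm_flag = ucm_ug_g > 0))
  }
  stopifnot(all(c("carbon_number", "conc_ng_g") %in% names(alkanes)))
  if (anyNA(alkanes$carbon_number)) {
    abort("alkane rows without a carbon-number label")
  }
  in_range <- alkanes$carbon_number >= range[1] & alkanes$carbon_number <= range[2]
  tibble(sum_n_alkanes_ng_g = sum(alkanes$conc_ng_g[in_range]),
         ucm_flag = ucm_ug_g > 0)
}

#' Bundled site geochemistry table
#'
#' The three-site deep-sea seep geochemistry table shipped with the
#' package (water depth, fluorescence, UCM, n-alkane sums, alkane gas,
#' Bernard ratio and methane delta13C). Measured ratios are inputs, never
#' recomputed from the other columns.
#'
#' @return A tibble, one row per site.
#' @export
seep_sites <- function() {
  readr::read_tsv(seep_example("site_geochemistry.tsv"),
                  show_col_types = FALSE, progress = FALSE)
}
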