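#' Gibbs-Helmholtz temperature correction
#'
#' Adjusts a standard Gibbs energy from the 298.15 K reference to
#' temperature `T` assuming the reaction enthalpy is constant over the
#' interval: `dG(T) = dG0 * (T/T0) + dH0 * (1 - T/T0)` with `T0 = 298.15 K`.
#' At the reference temperature this is the identity; when `dG0 == dH0`
#' (zero reaction entropy) the energy is temperature-independent.
#'
#' @param dG0_kJ,dH0_kJ Standard Gibbs energy and enthalpy at 298.15 K, kJ.
#' @param temperature_K Absolute temperature, K (> 0). Vectorized over all
#'   three arguments.
#' @return Temperature-corrected standard Gibbs energy, kJ.
#' @examples
#' temperature_correct(-846.3, -1091.3, 277.15)
#' @export
temperature_correct <- function(dG0_kJ, dH0_kJ, temperature_K) {
  if (any(!is.finite(temperature_K) | temperature_K <= 0)) {
    abort("temperature must be positive (kelvin)")
  }
  ratio <- temperature_K / .T_REF
  dG0_kJ * ratio + dH0_kJ * (1 - ratio)
}

#' Reaction-quotient (activity) correction term
#'
#' The concentration correction `RT ln Q = R * T * sum(nu_i * ln a_i)` in kJ,
#' with activities resolved from the conditions: listed concentrations in
#' mol/L, `10^-pH` for the proton, 1 for water/pure liquids and for any
#' species left at standard state. At all-unity activities the term is zero;
#' reversing a reaction flips its sign.
#'
#' @inheritParams check_balance
#' @param cond A [conditions()] object.
#' @return A tibble with `reaction_id` and `rtlnQ_kJ`.
#' @examples
#' reaction_quotient_term(seep_reactions(), seep_species(), deep_sea_conditions())
#' @export
reaction_quotient_term <- function(reactions, db, cond) {
  db <- validate_species(db)
  stopifnot(inherits(cond, "seep_conditions"))
  RT <- .R_GAS * cond$temperature_K / 1000  # kJ/mol
  if (nrow(reactions) == 0) {
    return(tibble(reaction_id = character(), rtlnQ_kJ = numeric()))
  }
  reactions %>%
    group_by(.data$reaction_id) %>%
    dplyr::group_modify(function(rx, key) {
      sp <- species_rows(rx$species, db,
                        context = sprintf("reaction '%s'", key$reaction_id))
      a <- species_activity(sp, cond)
      tibble(rtlnQ_kJ = RT * sum(rx$nu * log(a)))
    }) %>%
    ungroup()
}

#' In-situ reaction Gibbs energy
#'
#' Corrects standard reaction energies to in-situ conditions as the sum of a
#' Gibbs-Helmholtz temperature correction and a reaction-quotient activity
#' correction: `dG_insitu = dG_T + RT ln Q`. The returned energy record
#' keeps every intermediate term.
#'
#' Standard energies are taken from the `energies` table when supplied
#' (e.g. [seep_reference_energies()], to correct tabulated values as
#' printed) and are otherwise computed from formation energies via
#' [standard_reaction_energy()].
#'
#' Pressure policy: the recorded `pressure_atm` does not enter the
#' correction by default — for the bundled reaction set the temperature and
#' activity terms alone reproduce the tabulated in-situ energies. Setting
#' `pressure_term = TRUE` adds a gas-compression term
#' `RT * nu_gas * ln(P/1 atm)` over gas-phase participants for users who
#' want an explicit (ideal-gas) pressure correction.
#'
#' @inheritParams reaction_quotient_term
#' @param energies Optional tibble `reaction_id`, `dG0_kJ`, `dH0_kJ`
#'   overriding computation from formation values.
#' @param pressure_term Add the optional ideal-gas compression term
#'   (default `FALSE`).
#' @return An energy-record tibble: `reaction_id`, `dG0_kJ`, `dH0_kJ`,
#'   `dG_T_kJ`, `rtlnQ_kJ`, `dG_insitu_kJ`, plus the conditions as an
#'   attribute `"conditions"`.
#' @examples
#' insitu_energy(seep_reactions(), seep_species(), deep_sea_conditions(),
#'               energies = seep_reference_energies())
#' @export
insitu_energy <- function(reactions, db, cond = deep_sea_conditions(),
                          energies = NULL, pressure_term = FALSE,
                          quiet = FALSE) {
  db <- validate_species(db)
  if (is.null(energies)) {
    energies <- standard_reaction_energy(reactions, db, quiet = quiet)
  } else {
    missing <- setdiff(unique(reactions$reaction_id), energies$reaction_id)
    if (length(missing) > 0) {
      abort(sprintf("no standard energies supplied for reaction(s): %s",
                    paste(missing, collapse = ", ")))
    }
  }
  q <- reaction_quotient_term(reactions, db, cond)
  out <- energies %>%
    select("reaction_id", "dG0_kJ", "dH0_kJ") %>%
    inner_join(q, by = "reaction_id") %>%
    mutate(dG_T_kJ = temperature_correct(.data$dG0_kJ, .data$dH0_kJ,
                                         cond$temperature_K),
           .before = "rtlnQ_kJ")
  if (pressure_term) {
    RT <- .R_GAS * cond$temperature_K / 1000
    gas_nu <- reactions %>%
      left_join(select(db, "name", "phase"),
                by = c(species = "name")) %>%
      group_by(.data$reaction_id) %>%
      summarise(nu_gas = sum(.data$nu[.data$phase == "gas"]), .groups = "drop")
    out <- out %>%
      left_join(gas_nu, by = "reaction_id") %>%
      mutate(rtlnQ_kJ = .data$rtlnQ_kJ +
               RT * dplyr::coalesce(.data$nu_gas, 0) * log(cond$pressure_atm)) %>%
      select(-"nu_gas")
  }
  out <- out %>%
    mutate(dG_insitu_kJ = .data$dG_T_kJ + .data$rtlnQ_kJ) %>%
    arrange(.data$reaction_id)
  attr(out, "conditions") <- cond
  out
}

#' Thermodynamic feasibility window over a concentration grid
#'
#' Evaluates the in-situ Gibbs energy of one reaction over the Cartesian
#' product of two log-spaced concentration grids (typically acetate and
#' hydrogen, the syntrophic intermediates), holding all other conditions
#' fixed. The zero contour — the feasibility boundary dG = 0 — is located
#' along each x-grid column by sign change, with linear interpolation in
#' log10 concentration of the y species.
#'
#' @inheritParams insitu_energy
#' @param var_x,var_y Named lists `list(species =, grid =)`; `grid` is a
#'   positive, strictly increasing concentration vector (mol/L). Both
#'   species must participate in the reaction.
#' @return A `seep_feasibility` tibble in long format: `x_species`,
#'   `x_conc`, `y_species`, `y_conc`, `dG_kJ`; the interpolated zero
#'   contour is attached as attribute `"contour"` (tibble `x_conc`,
#'   `y_conc_zero`) and retrievable with [zero_contour()].
#' @examples
#' rx <- dplyr::filter(seep_reactions(), reaction_id == "R2")
#' fw <- feasibility_window(
#'   rx, seep_species(), deep_sea_conditions(),
#'   var_x = list(species = "acetate", grid = 10^seq(-9, 0, length.out = 25)),
#'   var_y = list(species = "HCO3-", grid = 10^seq(-4, -1, length.out = 25)),
#'   energies = seep_reference_energies())
#' zero_contour(fw)
#' @export
feasibility_window <- function(reactions, db, cond = deep_sea_conditions(),
                               var_x, var_y, energies = NULL,
                               pressure_term = FALSE) {
  id <- unique(reactions$reaction_id)
  if (length(id) != 1) abort("feasibility_window() expects a single reaction")
  for (v in list(var_x, var_y)) {
    if (!all(c("species", "grid") %in% names(v))) {
      abort("var_x/var_y must be lists with elements 'species' and 'grid'")
    }
    if (!v$species %in% reactions$species) {
      abort(sprintf("varied species '%s' does not participate in reaction '%s'",
                    v$species, id))
    }
    if (any(v$grid <= 0) || is.unsorted(v$grid, strictly = TRUE)) {
      abort("grids must be positive and strictly increasing")
    }
  }
  grid <- tidyr::expand_grid(x_conc = var_x$grid, y_conc = var_y$grid)
  dG <- purrr::map2_dbl(grid$x_conc, grid$y_conc, function(cx, cy) {
    conc <- cond$concentrations
    conc[var_x$species] <- cx
    conc[var_y$species] <- cy
    cnd <- conditions(temperature_C = cond$temperature_K - 273.15,
                      pressure_atm = cond$pressure_atm, pH = cond$pH,
                      concentrations = conc)
    rec <- insitu_energy(reactions, db, cnd, energies = energies,
                         pressure_term = pressure_term, quiet = TRUE)
    rec$dG_insitu_kJ
  })
  out <- tibble(reaction_id = id,
                x_species = var_x$species, x_conc = grid$x_conc,
                y_species = var_y$species, y_conc = grid$y_conc,
                dG_kJ = dG)
  contour <- out %>%
    group_by(.data$x_conc) %>%
    dplyr::group_modify(function(col, key) {
      tibble(y_conc_zero = interp_zero_log(col$y_conc, col$dG_kJ))
    }) %>%
    ungroup() %>%
    filter(!is.na(.data$y_conc_zero))
  structure(out, contour = contour,
            class = c("seep_feasibility", class(out)))
}

#' @rdname feasibility_window
#' @param x A `seep_feasibility` grid.
#' @export
zero_contour <- function(x) {
  stopifnot(inherits(x, "seep_feasibility"))
  attr(x, "contour")
}

# First sign change along (conc, dG), interpolated linearly in log10(conc).
interp_zero_log <- function(conc, dG) {
  s <- sign(dG)
  if (any(dG == 0)) return(conc[which(dG == 0)[1]])
  flip <- which(s[-1] != s[-length(s)])
  if (length(flip) == 0) return(NA_real_)
  i <- flip[1]
  lx <- log10(conc)
  f <- dG[i] / (dG[i] - dG[i + 1])
  10^(lx[i] + f * (lx[i + 1] - lx[i]))
}
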