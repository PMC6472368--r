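#' Standard reaction energies from formation energies
#'
#' Computes the standard Gibbs energy and enthalpy of each reaction at
#' 298.15 K as the stoichiometry-weighted sum of species formation values,
#' `dG0 = sum(nu_i * dGf0_i)` (and likewise for `dH0`). Energies are in kJ
#' per mole of reaction as written.
#'
#' A species lacking the needed formation value raises an error naming the
#' species and the missing constant — values are never silently defaulted to
#' zero (the proton carries an explicit 0 by convention in the species
#' table). Element- or charge-unbalanced reactions are computed as given,
#' with a warning: tabulated reaction sets sometimes print stoichiometries
#' whose energies match the printed coefficients even where an element
#' balance fails, and reproducing the table takes precedence over repairing
#' it.
#'
#' @inheritParams check_balance
#' @param quiet Suppress the unbalanced-reaction warning.
#' @return A tibble with one row per reaction: `reaction_id`, `dG0_kJ`,
#'   `dH0_kJ`, `balanced`.
#' @examples
#' standard_reaction_energy(seep_reactions(), seep_species())
#' @export
standard_reaction_energy <- function(reactions, db, quiet = FALSE) {
  db <- validate_species(db)
  if (nrow(reactions) == 0) {
    return(tibble(reaction_id = character(), dG0_kJ = numeric(),
                  dH0_kJ = numeric(), balanced = logical()))
  }
  bal <- check_balance(reactions, db)
  if (!quiet && any(!bal$balanced)) {
    warn(sprintf("computing energies for element/charge-unbalanced reaction(s): %s",
                 paste(bal$reaction_id[!bal$balanced], collapse = ", ")))
  }
  out <- reactions %>%
    group_by(.data$reaction_id) %>%
    dplyr::group_modify(function(rx, key) {
      sp <- species_rows(rx$species, db,
                        context = sprintf("reaction '%s'", key$reaction_id))
      tibble(dG0_kJ = weighted_formation_sum(rx, sp, "dGf0_kJ_mol", key$reaction_id),
             dH0_kJ = weighted_formation_sum(rx, sp, "dHf0_kJ_mol", key$reaction_id))
    }) %>%
    ungroup() %>%
    left_join(select(bal, "reaction_id", "balanced"), by = "reaction_id")
  out[order(out$reaction_id), ]
}

weighted_formation_sum <- function(rx, sp, column, id, allow_na = FALSE) {
  vals <- sp[[column]]
  if (anyNA(vals)) {
    if (allow_na) return(NA_real_)
    abort(sprintf("species %s lack(s) %s needed for reaction '%s'",
                  paste(sp$name[is.na(vals)], collapse = ", "),
                  sub("_kJ_mol$", "", column), id))
  }
  sum(rx$nu * vals)
}

#' Back-derive a missing formation energy from a tabulated reaction energy
#'
#' Given a reaction whose tabulated standard energy is known but in which
#' exactly one participating species lacks the relevant formation value,
#' solves `tabulated = sum(nu_i * f_i)` for the missing `f`:
#' `f_unknown = (tabulated - sum_known(nu_i * f_i)) / nu_unknown`. Storing
#' the returned value in the species table makes
#' [standard_reaction_energy()] reproduce the tabulated energy exactly.
#' This is how the bundled constants for hexadecane(aq) (Gibbs) and
#' benzoate(aq) (enthalpy) were obtained.
#'
#' @inheritParams check_balance
#' @param tabulated_kJ The known standard reaction energy, kJ.
#' @param unknown Name of the species whose formation value is to be solved
#'   for; it must be the only participating species lacking it.
#' @param which `"dGf0"` or `"dHf0"`.
#' @return The derived formation value, kJ/mol.
#' @examples
#' db <- seep_species()
#' db$dGf0_kJ_mol[db$name == "hexadecane"] <- NA
#' rx <- dplyr::filter(seep_reactions(), reaction_id == "R2")
#' derive_formation_energy(rx, 176.3, db, "hexadecane")
#' @export
derive_formation_energy <- function(reactions, tabulated_kJ, db, unknown,
                                    which = c("dGf0", "dHf0")) {
  which <- match.arg(which)
  column <- paste0(which, "_kJ_mol")
  db <- validate_species(db)
  ids <- unique(reactions$reaction_id)
  if (length(ids) != 1) {
    abort("derive_formation_energy() expects a single reaction")
  }
  sp <- species_rows(reactions$species, db,
                     context = sprintf("reaction '%s'", ids))
  missing <- sp$name[is.na(sp[[column]])]
  if (!identical(sort(missing), sort(unknown)) || length(missing) != 1) {
    abort(sprintf(
      "exactly one species (%s) must lack %s; found missing: %s",
      unknown, which,
      if (length(missing)) paste(missing, collapse = ", ") else "none"))
  }
  i <- match(unknown, sp$name)
  known <- sum(reactions$nu[-i] * sp[[column]][-i])
  (tabulated_kJ - known) / reactions$nu[i]
}
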