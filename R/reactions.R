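#' Catabolic reaction sets
#'
#' A reaction set is a long-format tibble with one row per (reaction,
#' species) pair: columns `reaction_id`, `label`, `class` (one of
#' `"hydrogenogenic_oxidation"`, `"acetogenic_oxidation"`,
#' `"complete_oxidation"`, `"other"`), `species`, `nu` (signed stoichiometric
#' coefficient, negative for reactants) and exact-rational bookkeeping
#' columns `nu_num`/`nu_den`. Coefficients are short decimals carried as
#' exact rationals so balance checks distinguish true zero from rounding.
#'
#' `reaction()` builds a one-reaction set from a named coefficient vector;
#' `read_reactions()` reads a TSV whose `equation` column holds
#' semicolon-separated `species:coefficient` pairs; `seep_reactions()`
#' returns the bundled six-reaction deep-sea set (hydrogenogenic, acetogenic
#' and sulfate-coupled complete oxidation of hexadecane and benzoate).
#'
#' @param id,label,class Reaction identifier, human-readable label and
#'   reaction class.
#' @param coefficients Named numeric (or character-decimal) vector of signed
#'   stoichiometric coefficients, names are species; at least one negative
#'   and one positive entry, no duplicated species.
#' @param path TSV with columns `reaction_id`, `label`, `class`, `equation`.
#' @return A reaction tibble (long format, one row per species).
#' @examples
#' reaction("toy", "A to B", "other", c(A = -1, B = 1))
#' seep_reactions()
#' @export
reaction <- function(id, coefficients, label = id, class = "other") {
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))) {
    abort("coefficients must be a named vector (names are species)")
  }
  if (anyDuplicated(names(coefficients))) {
    abort(sprintf("duplicated species in reaction '%s': %s", id,
                  paste(unique(names(coefficients)[duplicated(names(coefficients))]),
                        collapse = ", ")))
  }
  rat <- as_rational(unname(coefficients))
  nu <- rat$num / rat$den
  if (any(nu == 0)) {
    abort(sprintf("zero coefficient in reaction '%s'", id))
  }
  if (!any(nu < 0) || !any(nu > 0)) {
    abort(sprintf("reaction '%s' needs at least one reactant and one product", id))
  }
  valid_class <- c("hydrogenogenic_oxidation", "acetogenic_oxidation",
                   "complete_oxidation", "other")
  if (!class %in% valid_class) {
    abort(sprintf("unknown reaction class '%s'", class))
  }
  tibble(reaction_id = id, label = label, class = class,
         species = names(coefficients), nu = nu,
         nu_num = rat$num, nu_den = rat$den)
}

#' @rdname reaction
#' @export
read_reactions <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("reaction_id", "label", "class", "equation")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    abort(paste0("reaction table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    return(reaction("x", c(A = -1, B = 1))[0, ])
  }
  purrr::pmap_dfr(raw, function(reaction_id, label, class, equation, ...) {
    pairs <- strsplit(equation, ";", fixed = TRUE)[[1]]
    parts <- strsplit(pairs, ":", fixed = TRUE)
    bad <- vapply(parts, length, integer(1)) != 2L
    if (any(bad)) {
      abort(sprintf("reaction '%s': malformed species:coefficient pair(s) %s",
                    reaction_id, paste(pairs[bad], collapse = ", ")))
    }
    coefs <- vapply(parts, `[[`, character(1), 2)
    names(coefs) <- trimws(vapply(parts, `[[`, character(1), 1))
    reaction(reaction_id, coefs, label = label, class = class)
  })
}

#' @rdname reaction
#' @export
seep_reactions <- function() {
  read_reactions(seep_example("catabolic_reactions.tsv"))
}

#' Reference standard reaction energies for the bundled reaction set
#'
#' Standard Gibbs energies and enthalpies (kJ per mole of reaction as
#' written, 298.15 K) tabulated for the six bundled deep-sea catabolic
#' reactions, used as inputs when correcting tabulated energies to in-situ
#' conditions rather than recomputing them from formation values.
#'
#' @return A tibble with columns `reaction_id`, `dG0_kJ`, `dH0_kJ`.
#' @export
seep_reference_energies <- function() {
  readr::read_tsv(seep_example("reference_reaction_energies.tsv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Element and charge balance of reactions
#'
#' For each reaction, the residual of element `e` is the exact rational sum
#' of `nu * count(e)` over participating species (products positive), and
#' the charge residual is the same sum over species charges. A reaction is
#' balanced iff every residual is exactly zero — the arithmetic is done on
#' exact rationals, so no tolerance is involved.
#'
#' @param reactions A reaction tibble (see [reaction()]).
#' @param db A species table (see [read_species()]); every species named in
#'   `reactions` must be present.
#' @return A tibble with one row per reaction: `reaction_id`, `balanced`,
#'   `charge_residual`, and `element_residuals` (a list column of named
#'   numeric vectors, only nonzero residuals retained).
#' @examples
#' db <- seep_species()
#' check_balance(seep_reactions(), db)
#' @export
check_balance <- function(reactions, db) {
  db <- validate_species(db)
  if (nrow(reactions) == 0) {
    return(tibble(reaction_id = character(), balanced = logical(),
                  charge_residual = numeric(), element_residuals = list()))
  }
  reactions %>%
    group_by(.data$reaction_id) %>%
    dplyr::group_modify(function(rx, key) {
      sp <- species_rows(rx$species, db,
                        context = sprintf("reaction '%s'", key$reaction_id))
      counts <- lapply(sp$formula, parse_formula)
      elements <- unique(unlist(lapply(counts, names)))
      res <- vapply(elements, function(e) {
        w <- vapply(counts, function(ct) if (e %in% names(ct)) ct[[e]] else 0,
                    numeric(1))
        r <- rational_weighted_sum(rx$nu_num, rx$nu_den, w)
        r[["num"]] / r[["den"]]
      }, numeric(1))
      qr <- rational_weighted_sum(rx$nu_num, rx$nu_den, sp$charge)
      charge <- qr[["num"]] / qr[["den"]]
      tibble(balanced = all(res == 0) && charge == 0,
             charge_residual = charge,
             element_residuals = list(res[res != 0]))
    }) %>%
    ungroup()
}
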