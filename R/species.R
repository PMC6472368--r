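#' Species formation-energy tables
#'
#' A species table is a tibble with one row per chemical species and columns
#' `name`, `formula` (Hill-style element counts, e.g. `"C2H3O2"`), `charge`
#' (signed elementary charges), `phase` (`"aqueous"`, `"liquid"` or `"gas"`),
#' `dGf0_kJ_mol` and `dHf0_kJ_mol` (standard Gibbs energy and enthalpy of
#' formation at 298.15 K, `NA` when unknown), and free-text `provenance`.
#'
#' `read_species()` reads such a table from TSV and validates it;
#' `seep_species()` returns the bundled constants table used for the deep-sea
#' catabolic reaction set. The proton (`H+`) carries `dGf0 = dHf0 = 0` by the
#' 1 M standard-state convention; molecular hydrogen is present both as the
#' gas reference state `H2(g)` (formation energies zero) and as dissolved
#' `H2(aq)` (+17.6 / -4.2 kJ/mol), selectable per reaction.
#'
#' @param path Path to a TSV file with the columns above.
#' @return A validated species tibble.
#' @examples
#' seep_species()
#' @export
read_species <- function(path) {
  sp <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_species(sp)
}

#' @rdname read_species
#' @export
seep_species <- function() {
  read_species(seep_example("species_constants.tsv"))
}

validate_species <- function(sp) {
  sp <- as_tibble(sp)
  needed <- c("name", "formula", "charge", "phase")
  missing <- setdiff(needed, names(sp))
  if (length(missing) > 0) {
    abort(paste0("species table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"dGf0_kJ_mol" %in% names(sp)) sp$dGf0_kJ_mol <- NA_real_
  if (!"dHf0_kJ_mol" %in% names(sp)) sp$dHf0_kJ_mol <- NA_real_
  if (anyDuplicated(sp$name)) {
    abort(sprintf("duplicated species name(s): %s",
                  paste(unique(sp$name[duplicated(sp$name)]), collapse = ", ")))
  }
  bad_phase <- setdiff(unique(sp$phase), c("aqueous", "liquid", "gas"))
  if (length(bad_phase) > 0) {
    abort(sprintf("unknown phase(s): %s", paste(bad_phase, collapse = ", ")))
  }
  counts <- lapply(sp$formula, parse_formula)
  empty <- vapply(counts, function(x) length(x) == 0 || all(x == 0), logical(1))
  if (any(empty)) {
    abort(sprintf("species with empty formula: %s",
                  paste(sp$name[empty], collapse = ", ")))
  }
  sp
}

# "C2H3O2" -> c(C = 2, H = 3, O = 2); a bare symbol means count 1.
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(numeric(0))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    abort(sprintf("cannot parse formula '%s'", formula))
  }
  el <- sub("[0-9]*$", "", tokens)
  n <- sub("^[A-Z][a-z]?", "", tokens)
  n <- ifelse(nzchar(n), as.numeric(n), 1)
  if (any(n < 0) || any(n != floor(n))) {
    abort(sprintf("formula '%s' has non-integer element counts", formula))
  }
  tapply(n, el, sum)[unique(el)]
}

# Look up species rows by name with a helpful error.
species_rows <- function(names, db, context = "reaction") {
  idx <- match(names, db$name)
  if (anyNA(idx)) {
    abort(sprintf("unknown species in %s: %s", context,
                  paste(unique(names[is.na(idx)]), collapse = ", ")))
  }
  db[idx, , drop = FALSE]
}
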