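# Shared fixtures, built in code.

# Minimal species table for toy reactions: six aqueous species with small
# integer formation energies, two of them isomers (same formula), plus
# water and a proton.
toy_species <- function() {
  tibble::tibble(
    name = c("A", "B", "C", "D", "E", "F", "H2O", "H+"),
    formula = c("C2H4O2", "C2H4O2", "C1H4", "C3H6O1", "C1O2", "H2", "H2O1", "H1"),
    charge = c(0, 0, 0, 0, 0, 0, 0, 1),
    phase = c(rep("aqueous", 6), "liquid", "aqueous"),
    dGf0_kJ_mol = c(-100, -80, -50.5, -120, -394, 17.6, -237.18, 0),
    dHf0_kJ_mol = c(-150, -130, -74, -180, -413, -4.2, -285.83, 0),
    provenance = "toy")
}

# Random small reaction over the toy species (guaranteed valid), with
# dyadic coefficients so stoichiometry is exact.
random_toy_reaction <- function(id) {
  nms <- sample(c("A", "B", "C", "D", "E", "F"), sample(2:4, 1))
  coef <- sample(c(-8:-1, 1:8), length(nms), replace = TRUE) / 4
  coef[1] <- -abs(coef[1])
  coef[length(coef)] <- abs(coef[length(coef)])
  reaction(id, stats::setNames(coef, nms))
}

# Independent brute-force standard-energy oracle: explicit loop over
# (species, coefficient) pairs against the species table.
oracle_energy <- function(rx, db, column = "dGf0_kJ_mol") {
  total <- 0
  for (i in seq_len(nrow(rx))) {
    row <- db[db$name == rx$species[i], ]
    total <- total + rx$nu[i] * row[[column]]
  }
  total
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")
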