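# Temperature correction, reaction-quotient term, in-situ energies and
# feasibility windows.

RT_at <- function(T_K) 8.314 * T_K / 1000

test_that("Gibbs-Helmholtz correction matches hand evaluation and identities", {
  expect_equal(temperature_correct(-846.3, -1091.3, 277.15), -863.556,
               tolerance = 1e-5)
  # reference temperature is the identity regardless of enthalpy
  expect_equal(temperature_correct(12.3, -999, 298.15), 12.3)
  # zero-entropy case: dG == dH is temperature-independent
  for (T_K in c(250, 277.15, 350)) {
    expect_equal(temperature_correct(-55, -55, T_K), -55)
  }
  expect_error(temperature_correct(1, 1, -3), "positive")
})

test_that("quotient term is zero at standard state and antisymmetric", {
  db <- seep_species()
  rx <- seep_reactions()
  std <- conditions(temperature_C = 25, pH = 0, concentrations = c())
  q <- reaction_quotient_term(rx, db, std)
  expect_true(all(abs(q$rtlnQ_kJ) < 1e-12))
  # benzoate acetogenic oxidation under deep-sea conditions
  r5 <- dplyr::filter(rx, reaction_id == "R5")
  q5 <- reaction_quotient_term(r5, db, deep_sea_conditions())$rtlnQ_kJ
  expect_equal(q5, -88.3, tolerance = 0.001)
  # reversal flips the sign exactly
  rev5 <- reaction("R5r", stats::setNames(-r5$nu, r5$species))
  q5r <- reaction_quotient_term(rev5, db, deep_sea_conditions())$rtlnQ_kJ
  expect_equal(q5 + q5r, 0)
})

test_that("water activity is fixed at 1 and the proton follows pH", {
  db <- seep_species()
  # hydrogenogenic hexadecane oxidation consumes 16 waters and releases
  # 8 protons: at pH 8 with everything else standard the whole quotient is
  # the proton term
  r1 <- dplyr::filter(seep_reactions(), reaction_id == "R1")
  cond <- conditions(temperature_C = 4, pH = 8, concentrations = c())
  q <- reaction_quotient_term(r1, db, cond)$rtlnQ_kJ
  expect_equal(q, RT_at(277.15) * 8 * log(1e-8), tolerance = 1e-9)
  expect_error(conditions(concentrations = c("H+" = 1e-8)), "pH")
  expect_error(conditions(concentrations = c(acetate = 0)), "positive")
})

test_that("in-situ energies reproduce the tabulated deep-sea corrections", {
  db <- seep_species()
  rx <- seep_reactions()
  rec <- insitu_energy(rx, db, deep_sea_conditions(),
                       energies = seep_reference_energies())
  got <- function(id) rec$dG_insitu_kJ[rec$reaction_id == id]
  expect_equal(got("R5"), -950.3, tolerance = 3 / 950.3)
  expect_equal(got("R2"), 133.9, tolerance = 3 / 133.9)
  expect_equal(got("R1"), 753.3, tolerance = 6 / 753.3)
  # record invariant: total = temperature term + activity term
  expect_true(all(abs(rec$dG_insitu_kJ - (rec$dG_T_kJ + rec$rtlnQ_kJ)) < 1e-9))
})

test_that("at 298.15 K and unit activities the in-situ energy is the standard one", {
  db <- seep_species()
  rx <- seep_reactions()
  std <- conditions(temperature_C = 25, pH = 0, concentrations = c())
  rec <- insitu_energy(rx, db, std, energies = seep_reference_energies())
  expect_equal(rec$dG_insitu_kJ, rec$dG0_kJ, tolerance = 1e-12)
})

test_that("in-situ energy is additive over summed reactions", {
  db <- toy_species()
  cond <- conditions(temperature_C = 4, pH = 7,
                     concentrations = c(A = 1e-4, B = 0.3, C = 2e-5, D = 0.01))
  r1 <- reaction("u", c(A = -2, B = 1, C = 1))
  r2 <- reaction("v", c(C = -1, D = 2))
  rsum <- reaction("w", c(A = -2, B = 1, D = 2))
  e <- function(r) insitu_energy(r, db, cond, quiet = TRUE)$dG_insitu_kJ
  expect_equal(e(rsum), e(r1) + e(r2), tolerance = 1e-12)
})

test_that("in-situ energy is monotone in concentrations with slope nu*RT", {
  db <- toy_species()
  r <- reaction("m", c(A = -1, D = 2))
  base <- c(A = 1e-3, D = 1e-3)
  RT <- RT_at(277.15)
  for (sp in c("A", "D")) {
    for (fac in c(3, 10)) {
      c1 <- base; c2 <- base; c2[sp] <- c2[sp] * fac
      g1 <- insitu_energy(r, db, conditions(concentrations = c1),
                          quiet = TRUE)$dG_insitu_kJ
      g2 <- insitu_energy(r, db, conditions(concentrations = c2),
                          quiet = TRUE)$dG_insitu_kJ
      nu <- r$nu[r$species == sp]
      expect_equal(g2 - g1, nu * RT * log(fac), tolerance = 1e-9)
      if (nu > 0) expect_gt(g2, g1) else expect_lt(g2, g1)
    }
  }
})

test_that("syntrophic window: low hydrogen and acetate make all three
          endergonic oxidations exergonic", {
  db <- seep_species()
  rx <- dplyr::filter(seep_reactions(), reaction_id %in% c("R1", "R2", "R4"))
  cond <- conditions(temperature_C = 4, pressure_atm = 300, pH = 8,
                     concentrations = c("HCO3-" = 0.002,
                                        "acetate" = 2.5e-6,
                                        "H2(aq)" = 1e-6))
  rec <- insitu_energy(rx, db, cond, energies = seep_reference_energies())
  expect_equal(nrow(rec), 3)
  expect_true(all(rec$dG_insitu_kJ < 0))
})

test_that("feasibility grid matches the closed-form zero contour for A -> B", {
  db <- toy_species()
  # isomers, so dG_T = dGf(B) - dGf(A) at the reference temperature
  r <- reaction("iso", c(A = -1, B = 1))
  cond <- conditions(temperature_C = 25, pH = 7, concentrations = c())
  dG_T <- temperature_correct(20, 20, 298.15)  # forced via energies below
  en <- tibble::tibble(reaction_id = "iso", dG0_kJ = 20, dH0_kJ = 20)
  fw <- feasibility_window(
    r, db, cond,
    var_x = list(species = "A", grid = 10^seq(-6, -1, length.out = 21)),
    var_y = list(species = "B", grid = 10^seq(-9, -2, length.out = 31)),
    energies = en)
  contour <- zero_contour(fw)
  expect_gt(nrow(contour), 0)
  RT <- RT_at(298.15)
  expected <- contour$x_conc * exp(-20 / RT)
  expect_equal(contour$y_conc_zero, expected, tolerance = 1e-6)
  # monotone in the product concentration along every column
  by_x <- split(fw$dG_kJ, fw$x_conc)
  expect_true(all(vapply(by_x, function(col) all(diff(col) > 0), logical(1))))
})

test_that("varied species must participate and grids must be sorted", {
  db <- seep_species()
  r2 <- dplyr::filter(seep_reactions(), reaction_id == "R2")
  en <- seep_reference_energies()
  expect_error(feasibility_window(
    r2, db, deep_sea_conditions(),
    var_x = list(species = "HS-", grid = c(1e-6, 1e-5)),
    var_y = list(species = "acetate", grid = c(1e-6, 1e-5)),
    energies = en), "does not participate")
  expect_error(feasibility_window(
    r2, db, deep_sea_conditions(),
    var_x = list(species = "acetate", grid = c(1e-5, 1e-6)),
    var_y = list(species = "HCO3-", grid = c(1e-6, 1e-5)),
    energies = en), "increasing")
  # both axes pinned at 1 M: constant matrix equal to the pH/bicarbonate-
  # corrected energy
  fw <- feasibility_window(
    r2, db, deep_sea_conditions(),
    var_x = list(species = "acetate", grid = 1),
    var_y = list(species = "H2O", grid = 1),
    energies = en)
  rec <- insitu_energy(r2, db, deep_sea_conditions(), energies = en)
  expect_equal(unique(fw$dG_kJ), rec$dG_insitu_kJ, tolerance = 1e-12)
})

test_that("feasibility summaries and plot scaffolding work", {
  db <- seep_species()
  r2 <- dplyr::filter(seep_reactions(), reaction_id == "R2")
  fw <- feasibility_window(
    r2, db, deep_sea_conditions(),
    var_x = list(species = "acetate", grid = 10^seq(-9, 0, length.out = 8)),
    var_y = list(species = "HCO3-", grid = 10^seq(-4, -1, length.out = 8)),
    energies = seep_reference_energies())
  g <- glance(fw)
  expect_equal(g$n_grid, 64)
  expect_true(g$frac_exergonic > 0 && g$frac_exergonic < 1)
  expect_s3_class(autoplot(fw), "ggplot")
  expect_false(inherits(tidy(fw), "seep_feasibility"))
})
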