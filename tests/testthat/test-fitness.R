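test_that("four-point reorganisation energy is exact and gauge invariant", {
  # independent arithmetic: [E-(R0) - E0(R0)] + [E0(R-) - E-(R-)]
  e_an_r0 <- -100.00; e_n_r0 <- -100.10; e_n_rm <- -100.05; e_an_rm <- -100.02
  expected <- (e_an_r0 - e_n_r0) + (e_n_rm - e_an_rm)
  expect_equal(reorganisation_energy(e_an_r0, e_n_r0, e_n_rm, e_an_rm), expected)
  expect_equal(expected, 0.07)
  # identical surfaces: zero
  expect_equal(reorganisation_energy(-5, -5, -7, -7), 0)
  # adding a constant to all four energies changes nothing
  expect_equal(
    reorganisation_energy(e_an_r0 + 13, e_n_r0 + 13, e_n_rm + 13, e_an_rm + 13),
    expected
  )
  expect_warning(reorganisation_energy(-1, 0, 0, 0), "negative")
})

test_that("solid-state EA calibration is linear, monotone and invertible", {
  cal <- ea_calibration(slope = 1, intercept = 0)
  expect_equal(solid_state_ea(2.5, cal), 2.5)
  cal2 <- ea_calibration(slope = 1.2, intercept = 0.9)
  ea <- c(1, 2, 3)
  s <- solid_state_ea(ea, cal2)
  expect_true(all(diff(s) > 0))
  expect_equal((s - 0.9) / 1.2, ea, tolerance = 1e-12)
  expect_error(ea_calibration(slope = -1))
})

test_that("F_A and F_B implement the Schottky-penalised scalarisation", {
  cal <- ea_calibration(slope = 1, intercept = 0)  # A_s = ea_gas directly
  fa <- fitness_spec("F_A", calibration = cal)
  fb <- fitness_spec("F_B", work_function = 4.1, calibration = cal)
  props <- function(lam, ea) data.frame(lambda_minus_eV = lam, ea_gas_eV = ea)

  # above the work function the penalty vanishes
  expect_equal(fitness_value(props(0.15, 4.3), fb), 0.15)
  # below: lambda + (W - A_s)
  expect_equal(fitness_value(props(0.20, 3.1), fb), 0.20 + (4.1 - 3.1))
  # F_A ignores the electron affinity entirely
  expect_equal(fitness_value(props(0.2, 1), fa), fitness_value(props(0.2, 9), fa))
  # F_B >= F_A, equality iff A_s >= W; continuous at A_s = W
  for (ea in c(2, 4.0999, 4.1, 4.2)) {
    expect_gte(fitness_value(props(0.2, ea), fb), fitness_value(props(0.2, ea), fa))
  }
  eps <- 1e-9
  expect_equal(fitness_value(props(0.2, 4.1 - eps), fb),
               fitness_value(props(0.2, 4.1 + eps), fb), tolerance = 1e-6)
  # lambda assembled from the four energies when not given directly
  p4 <- data.frame(e_anion_r0_eV = -2, e_neutral_r0_eV = -2.1,
                   e_neutral_rm_eV = -2.05, e_anion_rm_eV = -2.12)
  expect_equal(fitness_value(p4, fa), (-2 - -2.1) + (-2.05 - -2.12))
  expect_error(fitness_value(data.frame(lambda_minus_eV = 0.2), fb), "ea_gas")
})

test_that("the surrogate oracle has the documented structure", {
  ora <- surrogate_oracle()
  p_pent <- ora(mol$pentacene)
  p_phen5 <- ora(parse_molecule("c1ccc2ccc3cc4cc5ccccc5cc4cc3c2c1"))
  # nonlinearity raises lambda
  expect_lt(p_pent$lambda_minus_eV, p_phen5$lambda_minus_eV)
  # properties depend only on the canonical key
  expect_identical(ora(parse_molecule(canonical_key(mol$pentacene))), p_pent)
  # one CH -> N substitution strictly raises the surrogate electron
  # affinity on any fixed skeleton
  set.seed(2)
  sp <- space_definition()
  for (i in 1:20) {
    m <- random_molecule(sp)
    up <- mol_mutation(m, c("[cH]", "n"))
    while (n_nitrogens(up) != n_nitrogens(m) + 1L) {
      up <- mol_mutation(m, c("[cH]", "n"))
    }
    expect_gt(ora(up)$ea_gas_eV, ora(m)$ea_gas_eV)
  }
  # the four-point energies are consistent with the direct lambda
  lam4 <- reorganisation_energy(p_pent$e_anion_r0_eV, p_pent$e_neutral_r0_eV,
                                p_pent$e_neutral_rm_eV, p_pent$e_anion_rm_eV)
  expect_equal(lam4, p_pent$lambda_minus_eV, tolerance = 1e-12)
})

test_that("the surrogate lambda minimum over the whole space is pentacene", {
  sp <- space_definition()
  tab <- make_surrogate_table(sp, complement_paired = FALSE)
  i <- which.min(tab$lambda_minus_eV)
  expect_identical(tab$canonical_key[i], pentacene_key)
  expect_true(all(tab$lambda_minus_eV[-i] > tab$lambda_minus_eV[i]))
  # Pareto front: minimal lambda over molecules above a rising EA
  # threshold is non-decreasing
  thr <- seq(min(tab$ea_gas_eV), max(tab$ea_gas_eV), length.out = 20L)
  front <- vapply(thr, function(t0) {
    min(tab$lambda_minus_eV[tab$ea_gas_eV >= t0])
  }, numeric(1))
  expect_true(all(diff(front) >= 0))
})

test_that("the table oracle looks up by canonical key and fails cleanly", {
  tab <- tibble::tibble(
    canonical_key = c(pentacene_key, "c1ccccc1"),
    lambda_minus_eV = c(0.1346, 0.3),
    ea_gas_eV = c(2.64, 1.1)
  )
  ora <- table_oracle(tab)
  expect_equal(fitness_value(ora(mol$pentacene), fitness_spec("F_A")), 0.1346)
  expect_null(ora(mol$naphthalene))
  # empty table: every lookup fails
  ora0 <- table_oracle(tab[0, ])
  expect_null(ora0(mol$pentacene))
  # duplicate keys with conflicting values refuse to load
  bad <- dplyr::bind_rows(tab, dplyr::mutate(tab[1, ], lambda_minus_eV = 0.2))
  expect_error(table_oracle(bad), "conflicting")
  # exact duplicates are tolerated
  expect_silent(table_oracle(dplyr::bind_rows(tab, tab[1, ])))
  # CSV round trip
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE)
  ora2 <- table_oracle(f)
  expect_equal(ora2(mol$pentacene)$lambda_minus_eV, 0.1346)
})
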