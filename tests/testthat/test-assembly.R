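test_that("the ground-state combination collapses correctly for small chains", {
  eng <- mock_engine(preset_pairwise(1))

  ## N = 3: single capped term, no concap, no pairs -> whole-chain energy
  toy3 <- toy_chain_only(3)
  g3 <- ee_gmfcc_ground(toy3$system, toy3$model, eng, lambda = Inf)
  expect_equal(length(g3$capped), 1)
  expect_equal(length(g3$concaps), 0)
  expect_equal(nrow(g3$pairs), 0)
  full3 <- full_system_reference(toy3$system, toy3$model, eng, "ground_energy")
  expect_equal(g3$energy, full3$E_ground, tolerance = 1e-10)

  ## zero pair list isolates the cap/concap terms
  toy6 <- toy_chain_only(6)
  g0 <- ee_gmfcc_ground(toy6$system, toy6$model, eng, lambda = 0)
  caps <- sum(vapply(g0$capped, function(r) r$E_ground, numeric(1)))
  cons <- sum(vapply(g0$concaps, function(r) r$E_ground, numeric(1)))
  expect_equal(g0$energy, caps - cons, tolerance = 1e-12)

  expect_error(ground_state_energy(list()), "completeness error")
})

test_that("nonbonded excitation assembly follows the one-body plus corrections form", {
  ## no neighbors: omega stays at the one-body value
  empty <- excitation_energy_nonbonded(3.1)
  expect_equal(empty$omega, 3.1)
  expect_equal(empty$report$omega_assembled,
               empty$report$omega_1b + sum(empty$report$pair_corrections))

  ## single-pair collapse: fluorophore 3.309 eV with one G contact at 3.499
  single <- excitation_energy_nonbonded(3.309, c(G13 = 3.499))
  expect_equal(single$omega, 3.499, tolerance = 1e-12)

  ## order invariance and telescoping
  set.seed(47)
  omegas <- runif(6, 2.8, 3.6)
  names(omegas) <- as.character(1:6)
  a <- excitation_energy_nonbonded(3.2, omegas)$omega
  b <- excitation_energy_nonbonded(3.2, sample(omegas))$omega
  expect_equal(a, b, tolerance = 1e-12)
  c <- excitation_energy_nonbonded(3.2, c(omegas, extra = 3.2))$omega
  expect_equal(c, a, tolerance = 1e-12)
})

test_that("bonded excitation assembly telescopes when the excitation is localized", {
  ## identical capped omegas and matching concaps cancel to the central value
  expect_equal(excitation_energy_bonded(c(3.3, 3.3, 3.3), c(3.3, 3.3),
                                        numeric(0), 3.3), 3.3)
  ## empty far-pair list isolates the local three-term combination
  expect_equal(excitation_energy_bonded(c(3.31, 3.35, 3.30), c(3.32, 3.33),
                                        numeric(0), 3.3),
               3.31 + 3.35 + 3.30 - 3.32 - 3.33)
  expect_error(excitation_energy_bonded(c(3.3, 3.3), c(3.3, 3.3), omega_m = 3.3),
               "completeness error")
})

test_that("TEDM assembly and zero-correction telescoping behave componentwise", {
  mu_m <- c(3.2193, 1.0487, 0.7567)
  expect_equal(assemble_tedm(mu_m), mu_m)
  expect_equal(assemble_tedm(mu_m, list(mu_m, mu_m)), mu_m)
  got <- assemble_tedm(c(1, 0, 0), list(c(1.5, 0.2, 0), c(0.8, 0, -0.1)))
  expect_equal(got, c(1 + 0.5 - 0.2, 0.2, -0.1))
  expect_error(assemble_tedm(mu_m, list(c(1, 2))), "alignment error")
})

test_that("oscillator strength converts eV to hartree and reproduces printed rows", {
  expect_equal(oscillator_strength(3.0019, c(2.7694, 0.9656, 0.6412)),
               0.6629, tolerance = 0.001)
  expect_equal(oscillator_strength(2.9954, c(2.9222, 1.0278, 0.6810)),
               0.7382, tolerance = 0.001)
  expect_equal(oscillator_strength(1, c(0, 0, 0)), 0)
  expect_error(oscillator_strength(-1, c(1, 0, 0)), "domain error")
  set.seed(53)
  for (k in 1:10) {
    expect_gte(oscillator_strength(runif(1, 0.1, 5), rnorm(3)), 0)
  }
})

test_that("force assembly applies the correction pattern per atom and component", {
  F_m <- matrix(rnorm(12), 4, 3, dimnames = list(1:4, c("x", "y", "z")))
  expect_equal(assemble_forces(F_m), F_m)
  expect_equal(assemble_forces(F_m, list(F_m)), F_m)
  Fj <- F_m + 0.1
  expect_equal(assemble_forces(F_m, list(Fj)), Fj)
  expect_error(assemble_forces(F_m, list(F_m[1:3, ])), "alignment error")
})

test_that("per-residue decomposition reproduces printed shifts and guards provenance", {
  bench <- decomposition_benchmark()
  hf <- bench[bench$level == "TD-HF/6-31G*", ]
  omega_m <- hf$omega_eV[hf$name == "EKJ37"]
  pair <- setNames(hf$omega_eV[hf$name != "EKJ37"], hf$name[hf$name != "EKJ37"])
  tab <- decompose_per_residue(omega_m, pair)

  expect_equal(tab$dEx_meV[tab$residue == "A12"], -48, tolerance = 1e-9)
  expect_equal(tab$dEx_meV[tab$residue == "G13"], 190, tolerance = 1e-9)
  expect_equal(tab$dEx_meV[tab$residue == "A17"], 90, tolerance = 1e-9)
  expect_equal(tab$shift[tab$residue == "A12"], "red")
  expect_equal(tab$shift[tab$residue == "G13"], "blue")
  ## wavelength shifts match the printed column to its rounding
  expect_equal(tab$dWL_nm[tab$residue == "A12"], 5.4, tolerance = 0.2)
  expect_equal(tab$dWL_nm[tab$residue == "G13"], -20.4, tolerance = 0.2)

  ident <- decompose_per_residue(3.309, c(X = 3.309))
  expect_equal(ident$dEx_meV, 0)
  expect_equal(ident$dWL_nm, 0)
  expect_equal(ident$shift, "none")

  expect_error(decompose_per_residue(omega_m, pair, embedded = TRUE),
               "provenance error")
})

test_that("snapshot averaging treats absent residues as absent, not zero", {
  t1 <- decompose_per_residue(3.3, c(A1 = 3.31, G2 = 3.29))
  t2 <- decompose_per_residue(3.3, c(A1 = 3.32))
  avg <- snapshot_average(list(t1, t2))
  expect_equal(avg$dEx_meV[avg$residue == "A1"], mean(c(10, 20)),
               tolerance = 1e-9)
  expect_equal(avg$n_snapshots[avg$residue == "A1"], 2)
  expect_equal(avg$dEx_meV[avg$residue == "G2"], -10, tolerance = 1e-9)
  expect_equal(avg$n_snapshots[avg$residue == "G2"], 1)

  expect_equal(snapshot_average(list(t1))$dEx_meV, t1$dEx_meV)
  expect_error(snapshot_average(list()), "argument error")

  ## random tables equal an independent recomputation by summation
  set.seed(59)
  tabs <- lapply(1:4, function(s) {
    decompose_per_residue(3.3, setNames(runif(3, 3.0, 3.6), c("A1", "G2", "C3")))
  })
  avg <- snapshot_average(tabs)
  for (r in c("A1", "G2", "C3")) {
    vals <- vapply(tabs, function(t) t$dEx_meV[t$residue == r], numeric(1))
    expect_equal(avg$dEx_meV[avg$residue == r], sum(vals) / 4, tolerance = 1e-12)
  }
})

test_that("the GMFCC decomposition pipeline runs unembedded end to end", {
  toy <- toy_std()
  eng <- mock_engine(preset_pairwise(1))
  tab <- gmfcc_decomposition(toy$system, toy$model, eng, lambda_2b = 5)
  expect_setequal(tab$residue, c("G2", "C3", "A5"))
  expect_true(all(is.finite(tab$dEx_meV)))
  ## consistency: meV and nm columns derive from the same omegas
  om <- attr(tab, "omega_m")
  expect_equal(tab$dEx_meV, (tab$omega_mj_eV - om) * 1000, tolerance = 1e-9)
})

test_that("assembly reports serialize to JSON", {
  toy <- toy_std()
  rep <- ee_gmfcc_excited(toy$system, toy$model,
                          mock_engine(preset_pairwise(1)), lambda_2b = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_assembly_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$omega_assembled, rep$omega_assembled, tolerance = 1e-12)
  expect_equal(unlist(back$pair_corrections),
               rep$pair_corrections, tolerance = 1e-12)
})
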