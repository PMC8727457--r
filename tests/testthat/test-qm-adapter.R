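test_that("mock excitation reduces to its closed form on minimal systems", {
  params <- mock_engine_params(omega0 = 3.25, alpha = 0.07, beta = 0.04,
                               mu0 = c(2.5, 1.0, 0.5), tau = 0)
  eng <- mock_engine(params)
  toy <- make_toy_complex(1, seed = 5)
  sys <- toy$system
  m <- chromophore_index(sys)
  frag <- sever_and_cap(sys, m)

  ## vacuum, chromophore only: baseline values
  vac <- run_qm(build_qm_task(sys, frag, toy$model, embedded = FALSE), eng)
  expect_equal(vac$omega, params$omega0)
  expect_equal(vac$tedm, params$mu0)

  ## embedded: omega0 + beta * sum q/d over the background charges
  emb_task <- build_qm_task(sys, frag, toy$model, embedded = TRUE)
  emb <- run_qm(emb_task, eng)
  qall <- atom_charges(sys, toy$model)
  catoms <- residue_atoms(sys, m)
  rc <- colMeans(catoms[, c("x", "y", "z")])
  bg_idx <- match(emb_task$background$charges$serial, sys$atoms$serial)
  d <- sqrt((sys$atoms$x[bg_idx] - rc[1])^2 + (sys$atoms$y[bg_idx] - rc[2])^2 +
              (sys$atoms$z[bg_idx] - rc[3])^2)
  expect_equal(emb$omega, params$omega0 + params$beta * sum(qall[bg_idx] / d),
               tolerance = 1e-12)

  ## determinism: identical tasks give bit-identical results
  again <- run_qm(emb_task, eng)
  expect_identical(emb$omega, again$omega)
  expect_identical(emb$tedm, again$tedm)
})

test_that("with equal couplings, moving a residue between QM region and background is neutral", {
  toy <- toy_std()
  sys <- toy$system
  m <- chromophore_index(sys)
  eng <- mock_engine(mock_engine_params(alpha = 0.06, beta = 0.06, tau = 0))
  o1 <- run_qm(build_qm_task(sys, sever_and_cap(sys, m), toy$model), eng)$omega
  o2 <- run_qm(build_qm_task(sys, build_two_body(sys, m, 3), toy$model), eng)$omega
  expect_equal(o2, o1, tolerance = 1e-12)
})

test_that("mock results satisfy the omega/energy consistency invariant", {
  toy <- toy_std()
  sys <- toy$system
  m <- chromophore_index(sys)
  eng <- mock_engine(preset_pairwise(1))
  res <- run_qm(build_qm_task(sys, build_two_body(sys, m, 2), toy$model,
                              wants = c("ground_energy", "excitation")), eng)
  expect_equal(res$omega, (res$E_excited - res$E_ground) * 27.211386245988,
               tolerance = 1e-9)
})

test_that("task validation rejects unknown properties and missing chromophores", {
  toy <- toy_std()
  sys <- toy$system
  expect_error(build_qm_task(sys, sever_and_cap(sys, 2), toy$model,
                             wants = "hessian"), "capability error")
  task <- build_qm_task(sys, sever_and_cap(sys, 2), toy$model,
                        wants = "excitation")
  expect_error(run_qm(task, mock_engine(preset_pairwise(1))), "role error")
  expect_error(run_qm(task, structure(list(), class = "no_such_engine")),
               "engine failure")
})

test_that("task serialize/parse round-trips geometry, charges and results", {
  toy <- toy_std()
  sys <- toy$system
  m <- chromophore_index(sys)
  eng <- mock_engine(preset_pairwise(1))
  task <- build_qm_task(sys, build_two_body(sys, m, 3), toy$model,
                        wants = c("ground_energy", "excitation", "tedm"),
                        method_tag = "TD-HF/6-31G*", state_index = 2L)
  dir <- withr::local_tempdir()
  serialize_task(task, dir)
  back <- parse_task(dir)

  expect_equal(back$method_tag, "TD-HF/6-31G*")
  expect_equal(back$state_index, 2L)
  expect_setequal(back$fragment$source_residues, task$fragment$source_residues)
  expect_equal(as.matrix(back$fragment$qm_atoms[, c("x", "y", "z")]),
               as.matrix(task$fragment$qm_atoms[, c("x", "y", "z")]),
               tolerance = 1e-6, ignore_attr = TRUE)

  r1 <- run_qm(task, eng); r2 <- run_qm(back, eng)
  expect_equal(r2$omega, r1$omega, tolerance = 1e-9)
  expect_equal(r2$tedm, r1$tedm, tolerance = 1e-9)
  expect_equal(r2$E_ground, r1$E_ground, tolerance = 1e-9)

  ## empty background still serializes to a valid (zero-line) charges file
  vac <- build_qm_task(sys, sever_and_cap(sys, m), toy$model, embedded = FALSE)
  dir2 <- withr::local_tempdir()
  serialize_task(vac, dir2)
  expect_equal(nrow(parse_task(dir2)$background$charges), 0)
})

test_that("result files are validated on parse", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(E_ground = -1.0, E_excited = -0.9), path,
                       auto_unbox = TRUE)
  res <- parse_result(path)
  expect_equal(res$omega, 2.7211386245988, tolerance = 1e-9)

  jsonlite::write_json(list(E_ground = -1.0, E_excited = -0.9, omega = 5.0),
                       path, auto_unbox = TRUE)
  expect_error(parse_result(path), "validation error")

  jsonlite::write_json(list(tedm = c(1, 2, 3)), path, auto_unbox = TRUE)
  expect_equal(parse_result(path)$tedm, c(1, 2, 3))
  expect_null(parse_result(path)$omega)

  jsonlite::write_json(list(comment = "nothing"), path, auto_unbox = TRUE)
  expect_error(parse_result(path), "schema error")

  ## write_result/parse_result round trip
  toy <- toy_std()
  full <- full_system_reference(toy$system, toy$model,
                                mock_engine(preset_pairwise(1)))
  write_result(full, path)
  back <- parse_result(path)
  expect_equal(back$omega, full$omega, tolerance = 1e-12)
  expect_equal(max(abs(back$forces - full$forces)), 0, tolerance = 1e-12)
})

test_that("mock forces agree with central-difference gradients of the excited energy", {
  toy <- toy_std()
  sys <- toy$system
  m <- chromophore_index(sys)
  eng <- mock_engine(preset_pairwise(1))
  for (frag in list(sever_and_cap(sys, m), build_two_body(sys, m, 2))) {
    task <- build_qm_task(sys, frag, toy$model,
                          wants = c("ground_energy", "excitation", "forces"))
    res <- run_qm(task, eng)
    num <- numerical_forces(task, eng)
    expect_lt(max(abs(num - res$forces)), 1e-6)
  }
})
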