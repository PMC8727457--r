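## Shared fixtures: the standard toy complex is an 8-residue pseudo-RNA with
## the chromophore in contact with residues 2, 3, 5 and 7 at staggered
## distances, so every threshold between 2 and 6 A changes the neighbor set.

.toy_cache <- new.env(parent = emptyenv())

toy_std <- function() {
  if (is.null(.toy_cache$std)) {
    .toy_cache$std <- make_toy_complex(
      n_residues = 8,
      contact_distances = c("2" = 2.5, "3" = 3.4, "5" = 4.5, "7" = 5.5),
      seed = 1
    )
  }
  .toy_cache$std
}

toy_chain_only <- function(n = 6, seed = 1) {
  ## a pure pseudo-RNA chain (no chromophore) for ground-state tests
  toy <- make_toy_complex(n, seed = seed)
  atoms <- toy$system$atoms
  atoms <- atoms[atoms$resname != "EKJ", , drop = FALSE]
  list(system = molecular_system(atoms), model = toy$model)
}

## two single-atom residues in different chains carrying +1/-1 e, one bohr
## apart: the textbook Coulomb configuration
two_point_system <- function(separation_bohr = 1) {
  d_ang <- separation_bohr / 1.8897259886
  atoms <- data.frame(
    serial = 1:2, name = c("X1", "X2"), elem = c("Na", "Cl"),
    x = c(0, d_ang), y = 0, z = 0,
    chain = c("A", "B"), resno = 1L, resname = c("PLS", "MNS"),
    res_index = 1:2, role = "other", stringsAsFactors = FALSE
  )
  model <- charge_model(data.frame(
    resname = c("PLS", "MNS"), name = c("X1", "X2"), q = c(1, -1)
  ), "template")
  list(system = molecular_system(atoms), model = model)
}

## central-difference gradient of the mock excited-state energy with
## respect to the chromophore atoms of a task (hartree/bohr)
numerical_forces <- function(task, engine, h_bohr = 1e-3) {
  h_ang <- h_bohr / 1.8897259886
  rows <- which(task$fragment$qm_atoms$role == "chromophore" &
                  !task$fragment$qm_atoms$is_link)
  out <- matrix(0, length(rows), 3)
  for (ki in seq_along(rows)) {
    for (c in 1:3) {
      col <- c("x", "y", "z")[c]
      tp <- task; tm <- task
      tp$fragment$qm_atoms[rows[ki], col] <-
        tp$fragment$qm_atoms[rows[ki], col] + h_ang
      tm$fragment$qm_atoms[rows[ki], col] <-
        tm$fragment$qm_atoms[rows[ki], col] - h_ang
      ep <- run_qm(tp, engine)$E_excited
      em <- run_qm(tm, engine)$E_excited
      out[ki, c] <- -(ep - em) / (2 * h_bohr)
    }
  }
  out
}
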