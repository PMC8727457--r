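test_that("link hydrogens are placed on the severed-bond axis at the rule length", {
  expect_equal(place_link_hydrogen(c(0, 0, 0), c(0, 0, 1.6), 1.09),
               c(0, 0, 1.09))
  expect_equal(place_link_hydrogen(c(1, 1, 1), c(1, 1, 2.6), 0.96),
               c(1, 1, 1.96))
  expect_error(place_link_hydrogen(c(1, 1, 1), c(1, 1, 1), 1.0),
               "geometry error")
  expect_error(place_link_hydrogen(c(0, 0, 0), c(1, 0, 0), -1),
               "argument error")

  set.seed(7)
  for (k in 1:25) {
    a <- rnorm(3); r <- a + rnorm(3)
    len <- runif(1, 0.5, 1.5)
    h <- place_link_hydrogen(a, r, len)
    expect_equal(sqrt(sum((h - a)^2)), len, tolerance = 1e-12)
    ## collinearity: cross product of (h-a) and (r-a) vanishes
    u <- h - a; v <- r - a
    expect_equal(sqrt(sum((c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1]))^2)), 0,
                 tolerance = 1e-12)
  }
})

test_that("sever_and_cap caps exactly the boundary-crossing backbone bonds", {
  toy <- make_toy_complex(5, seed = 1)
  sys <- toy$system
  m <- chromophore_index(sys)

  interior <- sever_and_cap(sys, 3)
  expect_equal(nrow(interior$link_atoms), 2)
  expect_equal(nrow(interior$qm_atoms),
               sys$residues$n_atoms[3] + 2)

  whole <- sever_and_cap(sys, sys$residues$res_index)
  expect_equal(nrow(whole$link_atoms), 0)

  chrom <- sever_and_cap(sys, m)
  expect_equal(nrow(chrom$link_atoms), 0)
  expect_setequal(chrom$qm_atoms$serial, residue_atoms(sys, m)$serial)

  expect_error(sever_and_cap(sys, 99), "lookup error")
  expect_error(sever_and_cap(sys, integer(0)), "argument error")

  ## conservation audit over random subsets
  set.seed(11)
  for (k in 1:10) {
    subset <- sort(sample(sys$residues$res_index, sample(1:4, 1)))
    fr <- sever_and_cap(sys, subset)
    n_src <- sum(sys$residues$n_atoms[subset])
    expect_equal(nrow(fr$qm_atoms), n_src + nrow(fr$link_atoms))
    expect_true(all(fr$qm_atoms$serial[!fr$qm_atoms$is_link] %in%
                      sys$atoms$serial))
    expect_false(any(duplicated(fr$qm_atoms$serial)))
  }
})

test_that("capped residues span i-1..i+1 with terminal caps omitted", {
  toy <- make_toy_complex(5, seed = 1)
  sys <- toy$system

  f3 <- build_capped_residue(sys, 3)
  expect_setequal(f3$source_residues, 2:4)
  expect_equal(nrow(f3$link_atoms), 2)

  f2 <- build_capped_residue(sys, 2)
  expect_setequal(f2$source_residues, 1:3)
  expect_equal(nrow(f2$link_atoms), 1)   # 5'-terminal side has no bond

  expect_error(build_capped_residue(sys, 1), "range error")
  expect_error(build_capped_residue(sys, 5), "range error")
})

test_that("concaps fuse neighbor pairs over the ground-state index range", {
  toy <- make_toy_complex(5, seed = 1)
  sys <- toy$system

  c2 <- build_concap(sys, 2)
  expect_setequal(c2$source_residues, 2:3)
  expect_equal(nrow(c2$link_atoms), 2)

  expect_error(build_concap(sys, 1), "range error")
  expect_error(build_concap(sys, 4), "range error")

  ## a 4-residue chain admits exactly one concap, pairing residues 2 and 3
  toy4 <- toy_chain_only(4)
  ok <- vapply(1:4, function(i) {
    !inherits(try(build_concap(toy4$system, i), silent = TRUE), "try-error")
  }, logical(1))
  expect_identical(which(ok), 2L)

  ## bookkeeping audit: concap pairs are exactly the interior neighbor pairs
  toy6 <- toy_chain_only(6)
  pairs <- lapply(2:4, function(i) build_concap(toy6$system, i)$source_residues)
  expect_identical(pairs, list(c(2L, 3L), c(3L, 4L), c(4L, 5L)))
})

test_that("two-body fragments join the chromophore with one H-capped residue", {
  toy <- toy_std()
  sys <- toy$system
  m <- chromophore_index(sys)

  fr <- build_two_body(sys, m, 3)
  expect_equal(nrow(fr$link_atoms), 2)
  one_body <- sever_and_cap(sys, m)
  capped_j <- sever_and_cap(sys, 3)
  expect_setequal(fr$qm_atoms$serial[!fr$qm_atoms$is_link],
                  c(one_body$qm_atoms$serial, capped_j$qm_atoms$serial[
                    !capped_j$qm_atoms$is_link]))

  terminal <- build_two_body(sys, m, 1)
  expect_equal(nrow(terminal$link_atoms), 1)

  expect_error(build_two_body(sys, 3, 2), "role error")
  expect_error(build_two_body(sys, m, m), "argument error")
})

test_that("ground-pair enumeration applies the j >= i+3 rule and the threshold", {
  toy6 <- toy_chain_only(6)

  all_pairs <- enumerate_ground_pairs(toy6$system, Inf)
  expect_equal(nrow(all_pairs), 6)
  expect_identical(paste(all_pairs$i, all_pairs$j),
                   c("1 4", "1 5", "1 6", "2 5", "2 6", "3 6"))

  none <- enumerate_ground_pairs(toy6$system, 2)
  expect_equal(nrow(none), 0)

  ## hairpin contact: side atom of residue 1 moved next to residue 5
  sys <- toy6$system
  at <- sys$atoms
  p5 <- unlist(at[at$res_index == 5 & at$name == "P", c("x", "y", "z")])
  c2 <- which(at$res_index == 1 & at$name == "C2")
  at$x[c2] <- p5[1]; at$y[c2] <- p5[2] + 3.5; at$z[c2] <- p5[3]
  hairpin <- molecular_system(at)
  got <- enumerate_ground_pairs(hairpin, 4)
  expect_identical(paste(got$i, got$j), "1 5")

  ## brute-force audit against min_distance on the standard toy
  toy <- toy_std()
  lam <- 5
  got <- enumerate_ground_pairs(toy$system, lam)
  res <- toy$system$residues
  for (i in seq_len(toy$system$n_res - 1)) for (j in seq(i + 1, toy$system$n_res)) {
    eligible <- res$chain[i] != res$chain[j] || j >= i + 3
    within <- min_distance(residue_atoms(toy$system, i),
                           residue_atoms(toy$system, j)) <= lam
    expect_equal(any(got$i == i & got$j == j), eligible && within)
  }
})

test_that("excited-pair enumeration honours the threshold and bonded window", {
  toy <- make_toy_complex(5, contact_distances = c("2" = 3.5, "4" = 6.0),
                          seed = 1)
  m <- chromophore_index(toy$system)
  expect_identical(enumerate_excited_pairs(toy$system, m, 4)$j, 2L)
  expect_true(all(enumerate_excited_pairs(toy$system, m, 4)$j %in%
                    enumerate_excited_pairs(toy$system, m, 5)$j))
  expect_error(enumerate_excited_pairs(toy$system, 2, 4), "role error")

  ## bonded mode: all contacts inside [m-2, m+2] leave an empty list
  toyB <- make_toy_complex(5, seed = 2, bonded_chromophore = TRUE)
  mB <- chromophore_index(toyB$system)
  near <- enumerate_excited_pairs(toyB$system, mB, 8, bonded = TRUE)
  expect_true(all(near$j < mB - 2 | near$j > mB + 2))
  local_only <- enumerate_excited_pairs(toyB$system, mB, 5, bonded = TRUE)
  expect_equal(nrow(local_only), 0)
})

test_that("truncated full-system regions grow monotonically with lambda_FS", {
  toy <- toy_std()
  sys <- toy$system
  m <- chromophore_index(sys)

  only_m <- build_truncated_full(sys, m, 0)
  expect_identical(only_m$source_residues, m)

  r4 <- build_truncated_full(sys, m, 4)
  expect_setequal(r4$source_residues, c(2L, 3L, m))

  r7 <- build_truncated_full(sys, m, 7)
  expect_true(all(r4$source_residues %in% r7$source_residues))
})

test_that("every link hydrogen sits at its exact rule length on random fragments", {
  toy <- toy_std()
  sys <- toy$system
  rules <- link_atom_rules()
  set.seed(19)
  n_checked <- 0
  for (k in 1:100) {
    subset <- sort(sample(1:8, sample(1:3, 1)))
    fr <- sever_and_cap(sys, subset)
    if (nrow(fr$link_atoms) == 0) next
    for (li in seq_len(nrow(fr$link_atoms))) {
      link <- fr$link_atoms[li, ]
      anchor <- sys$atoms[match(link$anchor_serial, sys$atoms$serial), ]
      kept_name <- anchor$name_canon
      rule_len <- rules$h_bond_length[rules$kept == kept_name]
      d <- sqrt((link$hx - anchor$x)^2 + (link$hy - anchor$y)^2 +
                  (link$hz - anchor$z)^2)
      expect_equal(d, rule_len, tolerance = 1e-9)
      expect_equal(link$bond_length, rule_len)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 50)
})

test_that("fragment XYZ serialization writes geometry plus provenance manifest", {
  toy <- toy_std()
  fr <- build_two_body(toy$system, chromophore_index(toy$system), 3)
  stem <- withr::local_tempfile()
  write_fragment_xyz(fr, stem)
  xyz <- readLines(paste0(stem, ".xyz"))
  expect_equal(as.integer(xyz[1]), nrow(fr$qm_atoms))
  man <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  expect_setequal(man$source_residues, fr$source_residues)
  expect_equal(NROW(man$link_atoms), nrow(fr$link_atoms))
})
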