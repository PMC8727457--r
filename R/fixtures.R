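## Toy fluorophore / pseudo-RNA generator.
##
## The residues are chemically nonsensical minimal templates: geometric and
## bookkeeping fidelity (named cut-site atoms, consistent backbone bond
## lengths, controllable chromophore contact distances) is the goal, not
## realism -- only the closed-form mock engine ever interprets them.

TOY_SPACING <- 4.53      # residue-to-residue offset along x, angstrom
TOY_NUC_TEMPLATE <- data.frame(
  name = c("O3'", "P", "C3'", "N1", "C2"),
  elem = c("O", "P", "C", "N", "C"),
  lx = c(0, 1.55, 3.10, 1.55, 1.55),
  ly = c(0, 0, 0, 1.40, 2.70),
  lz = c(0, 0, 0, 0, 0),
  stringsAsFactors = FALSE
)
## per-type side-group charges; every template sums to zero
TOY_NUC_CHARGES <- list(
  A = c("O3'" = -0.50, P = 1.20, "C3'" = 0.10, N1 = -0.60, C2 = -0.20),
  G = c("O3'" = -0.50, P = 1.20, "C3'" = 0.10, N1 = -0.70, C2 = -0.10),
  C = c("O3'" = -0.50, P = 1.20, "C3'" = 0.10, N1 = -0.55, C2 = -0.25),
  U = c("O3'" = -0.50, P = 1.20, "C3'" = 0.10, N1 = -0.65, C2 = -0.15)
)
## rigid 7-atom toy chromophore (ring + exocyclic sulfur); net charge +1
TOY_CHROM_TEMPLATE <- data.frame(
  name = c("CA1", "CA2", "NA3", "CA4", "CA5", "SA6", "SX"),
  elem = c("C", "C", "N", "C", "C", "S", "S"),
  q = c(0.25, 0.05, -0.35, 0.25, 0.05, -0.35, 1.10),
  stringsAsFactors = FALSE
)

toy_charge_table <- function(bonded_chromophore = FALSE) {
  nuc <- do.call(rbind, lapply(names(TOY_NUC_CHARGES), function(rn) {
    q <- TOY_NUC_CHARGES[[rn]]
    data.frame(resname = rn, name = names(q), q = as.numeric(q),
               stringsAsFactors = FALSE)
  }))
  ekj <- data.frame(resname = "EKJ", name = TOY_CHROM_TEMPLATE$name,
                    q = TOY_CHROM_TEMPLATE$q, stringsAsFactors = FALSE)
  if (bonded_chromophore) {
    ## chain-bonded variant carries backbone atoms too; ring sum rescaled so
    ## the residue total stays +1
    backbone <- data.frame(resname = "EKJ",
                           name = c("O3'", "P", "C3'"),
                           q = c(-0.50, 1.20, 0.10), stringsAsFactors = FALSE)
    ekj$q <- TOY_CHROM_TEMPLATE$q - (sum(TOY_CHROM_TEMPLATE$q) +
                                       sum(backbone$q) - 1) / nrow(ekj)
    ekj <- rbind(backbone, ekj)
  }
  rbind(nuc, ekj)
}

#' Generate a deterministic toy fluorophore--pseudo-RNA complex
#'
#' Builds a short pseudo-RNA chain (five atoms per residue including the
#' C3'/O3' cut-site atoms and the phosphate; consecutive residues joined by
#' a 1.43 A C3'-O3' bond) plus a rigid seven-atom toy chromophore
#' (residue code EKJ). By default the chromophore sits in its own chain,
#' well below the backbone (closest approach ~12 A); residues listed in
#' \code{contact_distances} have one side-group atom repositioned so their
#' closest-contact distance to the chromophore equals the requested value
#' (verified to 0.05 A; a construction error is raised if the geometry
#' cannot be realised). With \code{bonded_chromophore = TRUE} the
#' chromophore is instead a mid-chain residue carrying backbone atoms, for
#' exercising the bonded excitation combination.
#'
#' @param n_residues Chain length (>= 1).
#' @param contact_distances Named numeric vector: residue index ->
#'   intended closest-contact distance from the chromophore, angstrom
#'   (>= 1.5).
#' @param seed Integer seed for the small deterministic side-group jitter.
#' @param bonded_chromophore Build the chromophore into the chain.
#' @return List with \code{system} (a \code{molecular_system} with the
#'   chromophore flagged) and \code{model} (a \code{charge_model}).
#' @export
make_toy_complex <- function(n_residues = 5, contact_distances = NULL,
                             seed = 1, bonded_chromophore = FALSE) {
  if (n_residues < 1) stop("argument error: n_residues must be >= 1", call. = FALSE)
  if (!is.null(contact_distances)) {
    ks <- as.integer(names(contact_distances))
    if (any(is.na(ks)) || any(ks < 1) || any(ks > n_residues)) {
      stop("construction error: contact residue indices out of range",
           call. = FALSE)
    }
    if (any(contact_distances < 1.5)) {
      stop("construction error: contact distances must be >= 1.5 A",
           call. = FALSE)
    }
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  codes <- rep(c("A", "G", "C", "U"), length.out = n_residues)
  chrom_pos <- if (bonded_chromophore) max(1L, (n_residues + 1L) %/% 2L) else NA

  rows <- list()
  serial <- 0L
  add_atom <- function(name, elem, x, y, z, chain, resno, resname, idx, role) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = name, elem = elem, x = x, y = y, z = z,
      chain = chain, resno = resno, resname = resname, res_index = idx,
      role = role, stringsAsFactors = FALSE)
  }

  for (i in seq_len(n_residues)) {
    off <- (i - 1) * TOY_SPACING
    if (bonded_chromophore && i == chrom_pos) {
      ## backbone atoms keep the chain intact; ring hangs below
      bt <- TOY_NUC_TEMPLATE[TOY_NUC_TEMPLATE$name %in% c("O3'", "P", "C3'"), ]
      for (r in seq_len(nrow(bt))) {
        add_atom(bt$name[r], bt$elem[r], off + bt$lx[r], bt$ly[r], bt$lz[r],
                 "A", i, "EKJ", i, "other")
      }
      ring <- chrom_ring_coords(centre = c(off + 1.55, -4.0, 0))
      for (r in seq_len(nrow(ring))) {
        add_atom(TOY_CHROM_TEMPLATE$name[r], TOY_CHROM_TEMPLATE$elem[r],
                 ring$x[r], ring$y[r], ring$z[r], "A", i, "EKJ", i, "other")
      }
    } else {
      jit <- stats::runif(2, -0.03, 0.03)
      for (r in seq_len(nrow(TOY_NUC_TEMPLATE))) {
        dy <- if (TOY_NUC_TEMPLATE$name[r] == "N1") jit[1] else
          if (TOY_NUC_TEMPLATE$name[r] == "C2") jit[2] else 0
        add_atom(TOY_NUC_TEMPLATE$name[r], TOY_NUC_TEMPLATE$elem[r],
                 off + TOY_NUC_TEMPLATE$lx[r], TOY_NUC_TEMPLATE$ly[r] + dy,
                 TOY_NUC_TEMPLATE$lz[r], "A", i, codes[i], i, "nucleotide")
      }
    }
  }

  if (!bonded_chromophore) {
    x_mid <- (n_residues - 1) * TOY_SPACING / 2 + 1.55
    ring <- chrom_ring_coords(centre = c(x_mid, -12, 0))
    idx <- n_residues + 1L
    for (r in seq_len(nrow(ring))) {
      add_atom(TOY_CHROM_TEMPLATE$name[r], TOY_CHROM_TEMPLATE$elem[r],
               ring$x[r], ring$y[r], ring$z[r], "B", 1L, "EKJ", idx, "other")
    }
  }

  atoms <- do.call(rbind, rows)

  ## realise requested contact distances by repositioning the side C2 atom
  if (!is.null(contact_distances)) {
    chrom_rows <- atoms$resname == "EKJ" &
      atoms$name %in% TOY_CHROM_TEMPLATE$name
    cx <- atoms[chrom_rows, c("x", "y", "z")]
    for (k in as.integer(names(contact_distances))) {
      if (bonded_chromophore && k == chrom_pos) {
        stop("construction error: contact distance requested for the ",
             "chromophore residue itself", call. = FALSE)
      }
      d_k <- contact_distances[[as.character(k)]]
      p_row <- which(atoms$res_index == k & atoms$name == "P")
      p <- unlist(atoms[p_row, c("x", "y", "z")])
      dists <- sqrt((cx$x - p[1])^2 + (cx$y - p[2])^2 + (cx$z - p[3])^2)
      astar <- unlist(cx[which.min(dists), ])
      u <- (p - astar) / sqrt(sum((p - astar)^2))
      c2 <- astar + d_k * u
      c2_row <- which(atoms$res_index == k & atoms$name == "C2")
      atoms$x[c2_row] <- c2[1]; atoms$y[c2_row] <- c2[2]; atoms$z[c2_row] <- c2[3]
    }
  }

  system <- molecular_system(atoms)
  system <- select_chromophore(system, "EKJ")
  model <- charge_model(toy_charge_table(bonded_chromophore), "template")

  ## verify the realised geometry
  if (!is.null(contact_distances)) {
    m <- chromophore_index(system)
    for (k in as.integer(names(contact_distances))) {
      got <- min_distance(residue_atoms(system, k), residue_atoms(system, m))
      if (abs(got - contact_distances[[as.character(k)]]) > 0.05) {
        stop("construction error: residue ", k, " realised at ",
             round(got, 3), " A, requested ",
             contact_distances[[as.character(k)]], " A", call. = FALSE)
      }
    }
  }
  list(system = system, model = model)
}

chrom_ring_coords <- function(centre) {
  th <- seq(0, by = pi / 3, length.out = 6)
  data.frame(
    x = c(centre[1] + 1.4 * cos(th), centre[1]),
    y = c(rep(centre[2], 6), centre[2] - 1.3),
    z = c(centre[3] + 1.4 * sin(th), centre[3])
  )
}

#' Mock-engine preset: strictly pairwise regime
#'
#' Parameters with no collective term (tau = 0) and distinct QM/background
#' couplings, so two-body corrections are non-trivial yet the two-body
#' assembly reproduces the whole-system mock values exactly once the
#' threshold covers every residue.
#'
#' @param seed Integer; small deterministic perturbation of the baseline
#'   parameters so different seeds give different (still pairwise) engines.
#' @return A \code{mock_engine_params}.
#' @export
preset_pairwise <- function(seed = 1) {
  s <- as.integer(seed) %% 97L
  mock_engine_params(
    omega0 = 3.1 + 0.001 * s,
    alpha = 0.08 + 0.0005 * (s %% 5),
    beta = 0.05 - 0.0005 * (s %% 3),
    gamma = 0.3 + 0.001 * (s %% 7),
    alpha_g = 0.8,
    tau = 0
  )
}

#' Mock-engine preset: controlled non-additive regime
#'
#' Equal QM/background couplings plus a positive collective (three-body)
#' term, so the two-body-truncated assembly has a non-zero error that
#' shrinks monotonically as the two-body threshold grows.
#'
#' @param seed Integer; deterministic perturbation as in
#'   \code{\link{preset_pairwise}}.
#' @return A \code{mock_engine_params}.
#' @export
preset_nonadditive <- function(seed = 1) {
  s <- as.integer(seed) %% 97L
  mock_engine_params(
    omega0 = 3.1 + 0.001 * s,
    alpha = 0.06, beta = 0.06,
    gamma = 0.3,
    alpha_g = 0.8,
    tau = 0.02 + 0.0002 * (s %% 5)
  )
}
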