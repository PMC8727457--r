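#' Full EE-GMFCC excited-state calculation
#'
#' Orchestrates the whole fragment pipeline for one structure: builds the
#' one-body chromophore fragment, enumerates the two-body partners within
#' \code{lambda_2b}, runs every fragment on the engine (embedded in the
#' point-charge field of the remainder of the system unless
#' \code{embedded = FALSE}), and assembles excitation energy, transition
#' dipole, oscillator strength and chromophore forces. If the chromophore is
#' covalently part of a chain (it participates in backbone bonds), the
#' bonded combination is used for the excitation energy: the three local
#' capped fragments minus the two local concaps plus far-pair corrections.
#'
#' @param system A \code{molecular_system} with a flagged chromophore.
#' @param model A \code{charge_model}.
#' @param engine An engine for \code{\link{run_qm}}.
#' @param lambda_2b Two-body distance threshold, angstrom.
#' @param embedded Electrostatic embedding flag (EE-GMFCC vs GMFCC).
#' @param properties Properties to compute, subset of
#'   \code{c("excitation", "tedm", "forces")}.
#' @param method_tag,state_index Passed to \code{\link{build_qm_task}}.
#' @return An \code{assembly_report}; the raw per-fragment results are
#'   attached as attribute \code{"results"}.
#' @export
ee_gmfcc_excited <- function(system, model, engine, lambda_2b = 4,
                             embedded = TRUE,
                             properties = c("excitation", "tedm", "forces"),
                             method_tag = "mock", state_index = 1L) {
  m <- chromophore_index(system)
  bonds <- backbone_bonds(system)
  bonded <- m %in% c(bonds$res_i, bonds$res_j)
  wants <- intersect(c("excitation", "tedm", "forces"), properties)
  if (length(wants) == 0) stop("argument error: nothing to compute", call. = FALSE)
  if ("forces" %in% wants) wants <- union(wants, "ground_energy")

  run_frag <- function(frag) {
    task <- build_qm_task(system, frag, model, wants = wants,
                          embedded = embedded, method_tag = method_tag,
                          state_index = state_index)
    run_qm(task, engine)
  }

  res_1b <- run_frag(sever_and_cap(system, m, label = sprintf("ONE_BODY(%d)", m)))
  pairs <- enumerate_excited_pairs(system, m, lambda_2b, bonded = bonded)
  res_2b <- lapply(pairs$j, function(j) run_frag(build_two_body(system, m, j)))
  names(res_2b) <- as.character(pairs$j)

  omega_m <- res_1b$omega
  pair_omegas <- vapply(res_2b, function(r) r$omega, numeric(1))

  if (!bonded) {
    asm <- excitation_energy_nonbonded(omega_m, pair_omegas,
                                       lambda_2b = lambda_2b,
                                       embedded = embedded)
    omega <- asm$omega
    corrections <- asm$report$pair_corrections
  } else {
    span <- chain_span(system, m)
    pos <- match(m, span)
    if (pos < 3 || pos > length(span) - 2) {
      stop("range error: a chain-bonded chromophore needs two residues on ",
           "each side for the local capped fragments", call. = FALSE)
    }
    capped <- vapply((m - 1):(m + 1), function(i) {
      run_frag(build_capped_residue(system, i))$omega
    }, numeric(1))
    concaps <- vapply((m - 1):m, function(i) {
      run_frag(build_concap(system, i))$omega
    }, numeric(1))
    omega <- excitation_energy_bonded(capped, concaps, pair_omegas, omega_m)
    corrections <- if (length(pair_omegas) > 0) pair_omegas - omega_m else numeric(0)
  }

  tedm <- NULL; f <- NULL
  if ("tedm" %in% wants) {
    tedm <- assemble_tedm(res_1b$tedm, lapply(res_2b, function(r) r$tedm))
    if (omega > 0) f <- oscillator_strength(omega, tedm)
  }
  forces <- NULL
  if ("forces" %in% wants) {
    forces <- assemble_forces(res_1b$forces, lapply(res_2b, function(r) r$forces))
  }
  report <- new_assembly_report(omega, omega_m, corrections, tedm = tedm,
                                oscillator = f, forces = forces,
                                lambda_2b = lambda_2b, embedded = embedded)
  attr(report, "results") <- c(list(one_body = res_1b), res_2b)
  report
}

#' Full EE-GMFCC ground-state energy calculation
#'
#' Builds and runs every species of the ground-state combination for each
#' chain: embedded capped-residue fragments (i = 2..N-1), embedded concaps
#' (i = 2..N-2; chains of one or two residues contribute a single embedded
#' whole-chain fragment instead), the vacuum two-body triples for
#' non-neighboring pairs within \code{lambda}, and the charge-charge
#' double-counting correction over the same pair list.
#'
#' @param system A \code{molecular_system}.
#' @param model A \code{charge_model}.
#' @param engine An engine for \code{\link{run_qm}}.
#' @param lambda Ground-state two-body threshold, angstrom (\code{Inf} for
#'   all non-neighboring pairs).
#' @param method_tag Engine/method label.
#' @return List with \code{energy} (hartree), \code{e_dc}, \code{pairs} and
#'   the per-species result lists.
#' @export
ee_gmfcc_ground <- function(system, model, engine, lambda = Inf,
                            method_tag = "mock") {
  stopifnot(inherits(system, "molecular_system"))
  run_frag <- function(frag, embedded = TRUE) {
    task <- build_qm_task(system, frag, model, wants = "ground_energy",
                          embedded = embedded, method_tag = method_tag)
    run_qm(task, engine)
  }
  capped <- list(); concaps <- list()
  for (ch in unique(system$residues$chain)) {
    span <- system$residues$res_index[system$residues$chain == ch]
    L <- length(span)
    if (L <= 2) {
      capped[[length(capped) + 1]] <-
        run_frag(sever_and_cap(system, span,
                               label = sprintf("CHAIN(%s)", ch)))
      next
    }
    for (pos in 2:(L - 1)) {
      capped[[length(capped) + 1]] <-
        run_frag(build_capped_residue(system, span[pos]))
    }
    if (L >= 4) {
      for (pos in 2:(L - 2)) {
        concaps[[length(concaps) + 1]] <-
          run_frag(build_concap(system, span[pos]))
      }
    }
  }
  pairs <- enumerate_ground_pairs(system, lambda)
  pair_results <- lapply(seq_len(nrow(pairs)), function(k) {
    frags <- build_pair_ground(system, pairs$i[k], pairs$j[k])
    lapply(frags, run_frag, embedded = FALSE)
  })
  e_dc <- double_counting_correction(system, pairs, model)
  energy <- ground_state_energy(capped, concaps, pair_results, e_dc)
  list(energy = energy, e_dc = e_dc, pairs = pairs, capped = capped,
       concaps = concaps, pair_results = pair_results)
}

#' Brute-force whole-system reference calculation
#'
#' Runs the engine once on the entire system as a single fragment with no
#' background charges. For the mock engine this is the exact value every
#' fragment assembly is compared against.
#'
#' @param system A \code{molecular_system}.
#' @param model A \code{charge_model}.
#' @param engine An engine for \code{\link{run_qm}}.
#' @param properties Requested properties.
#' @return A \code{qm_result}.
#' @export
full_system_reference <- function(system, model, engine,
                                  properties = c("ground_energy", "excitation",
                                                 "tedm", "forces")) {
  frag <- sever_and_cap(system, system$residues$res_index,
                        label = "FULL_SYSTEM")
  task <- build_qm_task(system, frag, model, wants = properties,
                        embedded = FALSE)
  run_qm(task, engine)
}

#' Truncated full-system QM/MM reference
#'
#' The conventional reference: the chromophore plus all residues within
#' \code{lambda_fs} as one QM region, embedded in the point charges of the
#' remaining system.
#'
#' @param system A \code{molecular_system} with a flagged chromophore.
#' @param model A \code{charge_model}.
#' @param engine An engine for \code{\link{run_qm}}.
#' @param lambda_fs QM-region distance threshold, angstrom.
#' @param properties Requested properties.
#' @return A \code{qm_result}.
#' @export
truncated_full_reference <- function(system, model, engine, lambda_fs = 4,
                                     properties = c("excitation", "tedm")) {
  m <- chromophore_index(system)
  frag <- build_truncated_full(system, m, lambda_fs)
  task <- build_qm_task(system, frag, model, wants = properties,
                        embedded = TRUE)
  run_qm(task, engine)
}

#' Per-ribonucleotide spectral-shift decomposition (GMFCC)
#'
#' Runs the chromophore one-body fragment and every two-body fragment
#' within \code{lambda_2b} WITHOUT embedding charges and tabulates each
#' residue's excitation-energy and wavelength shift contribution.
#'
#' @param system A \code{molecular_system} with a flagged chromophore.
#' @param model A \code{charge_model} (the mock engine still draws its
#'   internal charges from it).
#' @param engine An engine for \code{\link{run_qm}}.
#' @param lambda_2b Two-body distance threshold, angstrom.
#' @return A decomposition table (see \code{\link{decompose_per_residue}});
#'   the chromophore-only excitation is attached as attribute
#'   \code{"omega_m"}.
#' @export
gmfcc_decomposition <- function(system, model, engine, lambda_2b = 4) {
  m <- chromophore_index(system)
  run_frag <- function(frag) {
    task <- build_qm_task(system, frag, model, wants = "excitation",
                          embedded = FALSE)
    run_qm(task, engine)
  }
  res_1b <- run_frag(sever_and_cap(system, m, label = sprintf("ONE_BODY(%d)", m)))
  pairs <- enumerate_excited_pairs(system, m, lambda_2b, bonded = FALSE)
  pair_omegas <- vapply(pairs$j, function(j) {
    run_frag(build_two_body(system, m, j))$omega
  }, numeric(1))
  res <- system$residues
  names(pair_omegas) <- paste0(res$resname[match(pairs$j, res$res_index)],
                               pairs$j)
  tab <- decompose_per_residue(res_1b$omega, pair_omegas, embedded = FALSE)
  attr(tab, "omega_m") <- res_1b$omega
  tab
}
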