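result_field <- function(results, field, what) {
  vals <- lapply(results, function(r) r[[field]])
  missing <- vapply(vals, is.null, logical(1))
  if (any(missing)) {
    labs <- vapply(results[missing], function(r) r$label, character(1))
    stop("completeness error: missing ", what, " for fragment(s): ",
         paste(labs, collapse = ", "), call. = FALSE)
  }
  vals
}

#' Assemble the ground-state energy from fragment results
#'
#' The generalized molecular fractionation combination: the sum of embedded
#' capped-residue energies, minus the conjugate-cap energies deducting the
#' overlap double counting, plus the two-body corrections
#' (E_ij - E_i - E_j) for non-neighboring residue pairs in close contact,
#' minus the charge-charge double-counting correction.
#'
#' @param capped List of \code{qm_result}s for the capped-residue fragments
#'   (chains shorter than three residues contribute their whole-chain
#'   fragment here).
#' @param concaps List of \code{qm_result}s for the concap fragments (may be
#'   empty).
#' @param pair_results List of lists with elements \code{pair},
#'   \code{mono_i}, \code{mono_j} (\code{qm_result}s for each enumerated
#'   ground pair).
#' @param e_dc Double-counting correction energy, hartree
#'   (\code{\link{double_counting_correction}}).
#' @return Total ground-state energy in hartree.
#' @export
ground_state_energy <- function(capped, concaps = list(),
                                pair_results = list(), e_dc = 0) {
  if (length(capped) == 0) {
    stop("completeness error: no capped-residue results", call. = FALSE)
  }
  e <- sum(unlist(result_field(capped, "E_ground", "ground energy"))) -
    (if (length(concaps) > 0) {
      sum(unlist(result_field(concaps, "E_ground", "ground energy")))
    } else 0)
  for (pr in pair_results) {
    trip <- result_field(pr[c("pair", "mono_i", "mono_j")],
                         "E_ground", "ground energy")
    e <- e + trip[[1]] - trip[[2]] - trip[[3]]
  }
  e - e_dc
}

new_assembly_report <- function(omega_assembled, omega_1b, pair_corrections,
                                tedm = NULL, oscillator = NULL, forces = NULL,
                                lambda_2b = NA_real_, embedded = TRUE) {
  structure(
    list(omega_assembled = omega_assembled, omega_1b = omega_1b,
         pair_corrections = pair_corrections, tedm_assembled = tedm,
         oscillator_strength = oscillator, forces_assembled = forces,
         lambda_2b = lambda_2b, embedded = embedded),
    class = "assembly_report"
  )
}

#' @export
print.assembly_report <- function(x, ...) {
  cat(sprintf("<assembly_report> %s, lambda_2B = %s A\n",
              if (x$embedded) "EE-GMFCC" else "GMFCC",
              format(x$lambda_2b)))
  cat(sprintf("  omega: 1B = %.6f eV, assembled = %.6f eV (%d pair corrections)\n",
              x$omega_1b, x$omega_assembled, length(x$pair_corrections)))
  if (!is.null(x$tedm_assembled)) {
    cat(sprintf("  tedm = (%.4f, %.4f, %.4f) a.u.",
                x$tedm_assembled[1], x$tedm_assembled[2], x$tedm_assembled[3]))
    if (!is.null(x$oscillator_strength)) {
      cat(sprintf("  f = %.4f", x$oscillator_strength))
    }
    cat("\n")
  }
  invisible(x)
}

#' Assemble the excitation energy of a non-covalently bound chromophore
#'
#' omega = omega_m + sum_j (omega_mj - omega_m): the one-body chromophore
#' excitation corrected by the two-body change from including each nearby
#' residue in the QM region.
#'
#' @param omega_m One-body chromophore excitation energy, eV.
#' @param pair_omegas Named numeric vector of two-body excitation energies
#'   (names = residue indices j).
#' @param lambda_2b Threshold used to enumerate the pairs (for the report).
#' @param embedded Whether the fragments were electrostatically embedded.
#' @return List with \code{omega} (eV) and \code{report}
#'   (\code{assembly_report}).
#' @export
excitation_energy_nonbonded <- function(omega_m, pair_omegas = numeric(0),
                                        lambda_2b = NA_real_,
                                        embedded = TRUE) {
  stopifnot(is.numeric(omega_m), length(omega_m) == 1)
  pair_omegas <- unlist(pair_omegas)
  corrections <- if (length(pair_omegas) > 0) pair_omegas - omega_m else numeric(0)
  omega <- omega_m + sum(corrections)
  report <- new_assembly_report(omega, omega_m, corrections,
                                lambda_2b = lambda_2b, embedded = embedded)
  list(omega = omega, report = report)
}

#' Assemble the excitation energy of a chain-bonded chromophore
#'
#' For a chromophore covalently embedded as residue m of the chain:
#' the sum of the three local capped-fragment excitations (i = m-1..m+1)
#' minus the two local concap excitations (i = m-1, m), plus two-body
#' corrections from residues outside the local window [m-2, m+2].
#'
#' @param capped_omegas Numeric length-3: excitation energies of the capped
#'   fragments centred at m-1, m, m+1, eV.
#' @param concap_omegas Numeric length-2: excitation energies of the concaps
#'   at m-1 and m, eV.
#' @param pair_omegas Named numeric vector of two-body excitations for far
#'   residues (j outside [m-2, m+2]).
#' @param omega_m One-body chromophore excitation used in the two-body
#'   differences, eV.
#' @return Assembled excitation energy, eV.
#' @export
excitation_energy_bonded <- function(capped_omegas, concap_omegas,
                                     pair_omegas = numeric(0), omega_m) {
  if (length(capped_omegas) != 3 || any(!is.finite(capped_omegas))) {
    stop("completeness error: need the three local capped-fragment omegas",
         call. = FALSE)
  }
  if (length(concap_omegas) != 2 || any(!is.finite(concap_omegas))) {
    stop("completeness error: need the two local concap omegas", call. = FALSE)
  }
  pair_omegas <- unlist(pair_omegas)
  sum(capped_omegas) - sum(concap_omegas) +
    (if (length(pair_omegas) > 0) sum(pair_omegas - omega_m) else 0)
}

#' Assemble the transition electric dipole moment
#'
#' Componentwise mu = mu_m + sum_j (mu_mj - mu_m).
#'
#' @param mu_m One-body TEDM, length-3 numeric, a.u.
#' @param pair_mus List of length-3 numerics (two-body TEDMs).
#' @return Assembled TEDM, length-3 numeric, a.u.
#' @export
assemble_tedm <- function(mu_m, pair_mus = list()) {
  mu_m <- as.numeric(mu_m)
  stopifnot(length(mu_m) == 3)
  mu <- mu_m
  for (mj in pair_mus) {
    mj <- as.numeric(mj)
    if (length(mj) != 3) {
      stop("alignment error: two-body TEDM must have 3 components", call. = FALSE)
    }
    mu <- mu + (mj - mu_m)
  }
  mu
}

#' Oscillator strength from excitation energy and transition dipole
#'
#' f = (2/3) * omega * |mu|^2 in atomic units; omega is converted from eV
#' to hartree before use.
#'
#' @param omega Excitation energy in eV, > 0.
#' @param mu Transition dipole, length-3 numeric, a.u.
#' @return Dimensionless oscillator strength (>= 0).
#' @examples
#' oscillator_strength(3.0019, c(2.7694, 0.9656, 0.6412))  # ~0.6629
#' @export
oscillator_strength <- function(omega, mu) {
  if (!is.numeric(omega) || length(omega) != 1 || !is.finite(omega) ||
      omega <= 0) {
    stop("domain error: omega must be a positive excitation energy in eV",
         call. = FALSE)
  }
  mu <- as.numeric(mu)
  stopifnot(length(mu) == 3, all(is.finite(mu)))
  (2 / 3) * (omega / HARTREE_EV) * sum(mu^2)
}

#' Assemble excited-state atomic forces on the chromophore
#'
#' Per-atom, per-component application of the two-body correction pattern:
#' F_k = F_k^m + sum_j (F_k^mj - F_k^m). All force matrices must be indexed
#' by the same chromophore-atom ordering.
#'
#' @param F_m One-body force matrix (n_atoms x 3), hartree/bohr.
#' @param pair_Fs List of two-body force matrices over the same atoms.
#' @return Assembled force matrix (n_atoms x 3), hartree/bohr.
#' @export
assemble_forces <- function(F_m, pair_Fs = list()) {
  F_m <- as.matrix(F_m)
  out <- F_m
  for (Fj in pair_Fs) {
    Fj <- as.matrix(Fj)
    if (!all(dim(Fj) == dim(F_m))) {
      stop("alignment error: force matrices differ in shape (",
           paste(dim(Fj), collapse = "x"), " vs ",
           paste(dim(F_m), collapse = "x"), ")", call. = FALSE)
    }
    if (!is.null(rownames(F_m)) && !is.null(rownames(Fj)) &&
        !identical(rownames(F_m), rownames(Fj))) {
      stop("alignment error: force matrices ordered by different atoms",
           call. = FALSE)
    }
    out <- out + (Fj - F_m)
  }
  out
}

#' Per-residue decomposition of the excitation-energy shift
#'
#' The spectral-shift contribution of each nearby ribonucleotide: the
#' two-body excitation change dEx_j = omega_mj - omega_m (meV) and the
#' corresponding wavelength change dWL_j = hc/omega_mj - hc/omega_m (nm).
#' Positive dEx is a blue shift, negative a red shift. The inputs must come
#' from unembedded (plain GMFCC) calculations -- an embedding field folds
#' many-body electrostatics into every term and obscures the individual
#' contributions -- so embedded inputs are refused.
#'
#' @param omega_m Chromophore-only excitation energy, eV (vacuum).
#' @param pair_omegas Named numeric vector of two-body excitation energies
#'   (names = residue labels or indices), eV (vacuum).
#' @param embedded Logical scalar or vector: provenance of the inputs;
#'   any TRUE triggers a provenance error.
#' @return data.frame with columns \code{residue}, \code{omega_mj_eV},
#'   \code{dEx_meV}, \code{dWL_nm}, \code{shift}.
#' @export
decompose_per_residue <- function(omega_m, pair_omegas, embedded = FALSE) {
  if (any(embedded)) {
    stop("provenance error: per-residue decomposition requires unembedded ",
         "(GMFCC) excitation energies; got electrostatically embedded inputs",
         call. = FALSE)
  }
  pair_omegas <- unlist(pair_omegas)
  if (is.null(names(pair_omegas))) {
    names(pair_omegas) <- as.character(seq_along(pair_omegas))
  }
  dEx <- (pair_omegas - omega_m) * 1000
  dWL <- HC_EV_NM / pair_omegas - HC_EV_NM / omega_m
  data.frame(
    residue = names(pair_omegas),
    omega_mj_eV = as.numeric(pair_omegas),
    dEx_meV = as.numeric(dEx),
    dWL_nm = as.numeric(dWL),
    shift = ifelse(dEx > 0, "blue", ifelse(dEx < 0, "red", "none")),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Average per-residue decompositions over snapshots
#'
#' Arithmetic mean of dEx and dWL per residue across configuration
#' snapshots. Residues absent from a snapshot are treated as absent (not
#' zero) and averaged over the snapshots where they appear; the per-residue
#' snapshot count is reported.
#'
#' @param tables List of decomposition tables
#'   (\code{\link{decompose_per_residue}} output).
#' @return data.frame with columns \code{residue}, \code{dEx_meV},
#'   \code{dWL_nm}, \code{n_snapshots}.
#' @export
snapshot_average <- function(tables) {
  if (!is.list(tables) || length(tables) == 0 ||
      !all(vapply(tables, is.data.frame, logical(1)))) {
    stop("argument error: need a non-empty list of decomposition tables",
         call. = FALSE)
  }
  all_res <- unique(unlist(lapply(tables, function(t) t$residue)))
  rows <- lapply(all_res, function(r) {
    dex <- unlist(lapply(tables, function(t) t$dEx_meV[t$residue == r]))
    dwl <- unlist(lapply(tables, function(t) t$dWL_nm[t$residue == r]))
    data.frame(residue = r, dEx_meV = mean(dex), dWL_nm = mean(dwl),
               n_snapshots = length(dex), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write an assembly report to JSON
#'
#' @param report An \code{assembly_report}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_assembly_report <- function(report, path) {
  stopifnot(inherits(report, "assembly_report"))
  out <- unclass(report)
  if (!is.null(out$forces_assembled)) {
    out$forces_assembled <- unclass(as.matrix(out$forces_assembled))
  }
  out$pair_corrections <- as.list(out$pair_corrections)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
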