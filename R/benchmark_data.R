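#' Published TD-HF/6-31G* benchmark tables for fluorescent RNA aptamers
#'
#' Reference values from the published fragment-QM benchmark study of the
#' Mango-II aptamer bound to its thiazole-orange fluorophore (ligand code
#' EKJ, crystal structure 6C63) and of seven further fluorescent
#' RNA-aptamer complexes. They are shipped so the package's assembly and
#' statistics operations can be exercised against printed reference
#' numbers without any electronic-structure software.
#'
#' @name benchmark_tables
NULL

#' Mango-II TEDM / oscillator-strength benchmark (TD-HF/6-31G*)
#'
#' Transition electric dipole moments (a.u.), excitation energies (eV) and
#' oscillator strengths for the one-body region, the two-body assemblies,
#' and the truncated full-system references at QM-region thresholds
#' lambda_FS = 4..7 A (two-body threshold lambda_2B set equal to
#' lambda_FS).
#'
#' @return data.frame with columns \code{system}, \code{lambda_fs},
#'   \code{mu_x}, \code{mu_y}, \code{mu_z}, \code{omega_eV}, \code{f}.
#' @export
tedm_benchmark <- function() {
  data.frame(
    system = c("1B", "2B", "fullsys", "2B", "fullsys", "2B", "fullsys",
               "2B", "fullsys"),
    lambda_fs = c(NA, 4, 4, 5, 5, 6, 6, 7, 7),
    mu_x = c(3.2193, 2.9735, 2.9222, 2.9887, 2.9392, 2.8269, 2.8015,
             2.7828, 2.7694),
    mu_y = c(1.0487, 1.0657, 1.0278, 1.0059, 0.9858, 1.0060, 0.9762,
             1.0056, 0.9656),
    mu_z = c(0.7567, 0.6880, 0.6810, 0.6550, 0.6411, 0.6267, 0.6288,
             0.6438, 0.6412),
    omega_eV = c(3.0896, 2.9938, 2.9954, 2.9917, 2.9966, 2.9954, 3.0018,
                 2.9943, 3.0019),
    f = c(0.9111, 0.7666, 0.7382, 0.7603, 0.7358, 0.6896, 0.6764,
          0.6727, 0.6629),
    stringsAsFactors = FALSE
  )
}

#' Mango-II snapshot excitation-energy benchmark (TD-HF/6-31G*)
#'
#' Excitation energies of ten MD-simulation configurations of the Mango-II
#' complex: one-body and two-body assemblies (lambda_2B = 4 A) against the
#' truncated full-system reference (lambda_FS = 4 A).
#'
#' @return data.frame with columns \code{snapshot}, \code{e_1b},
#'   \code{e_2b}, \code{e_ref} (eV).
#' @export
snapshot_benchmark <- function() {
  data.frame(
    snapshot = 1:10,
    e_1b = c(3.334, 3.256, 3.397, 3.349, 3.070, 3.307, 3.404, 3.329,
             3.218, 3.174),
    e_2b = c(3.162, 3.110, 3.295, 3.251, 3.005, 3.204, 3.256, 3.266,
             3.195, 3.115),
    e_ref = c(3.215, 3.151, 3.300, 3.261, 2.972, 3.238, 3.302, 3.266,
              3.204, 3.123)
  )
}

#' Per-ribonucleotide decomposition benchmark (GMFCC)
#'
#' Ensemble-averaged (ten MD snapshots) excitation energies of the bare
#' fluorophore (EKJ37) and of the two-body species with each close-contact
#' ribonucleotide, without embedding charges, at two levels of theory.
#' The printed shift columns are recomputed by
#' \code{\link{decompose_per_residue}} from the excitation energies.
#'
#' @return data.frame with columns \code{level}, \code{name},
#'   \code{omega_eV}.
#' @export
decomposition_benchmark <- function() {
  data.frame(
    level = rep(c("TD-HF/6-31G*", "TD-wB97X/6-31G*"), each = 9),
    name = rep(c("EKJ37", "A12", "G13", "A17", "G18", "A22", "A23", "G24",
                 "G29"), 2),
    omega_eV = c(3.309, 3.261, 3.499, 3.399, 3.319, 3.328, 3.281, 3.252,
                 3.141,
                 2.821, 2.771, 3.005, 2.910, 2.823, 2.841, 2.803, 2.781,
                 2.677),
    stringsAsFactors = FALSE
  )
}

#' Multi-aptamer excitation-energy benchmark (TD-HF/6-31G*)
#'
#' One-body, two-body (lambda_2B = 4 A) and truncated full-system
#' (lambda_FS = 4 A) excitation energies for eight fluorescent RNA-aptamer
#' systems.
#'
#' @return data.frame with columns \code{system}, \code{e_1b}, \code{e_2b},
#'   \code{e_ref} (eV).
#' @export
aptamer_benchmark <- function() {
  data.frame(
    system = c("6UP0 chain-C", "6UP0 chain-D", "6E84", "6E82", "6C64",
               "5BJO", "6E8S", "6V9D chain-E"),
    e_1b = c(3.557, 3.610, 3.809, 3.684, 4.249, 3.381, 3.759, 3.489),
    e_2b = c(3.280, 3.327, 3.872, 3.571, 4.146, 3.254, 3.522, 3.345),
    e_ref = c(3.329, 3.365, 3.877, 3.617, 4.149, 3.266, 3.541, 3.367),
    stringsAsFactors = FALSE
  )
}
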