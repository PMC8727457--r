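#' Build a per-fragment QM task
#'
#' Bundles everything an engine needs for one fragment calculation: the
#' fragment geometry (link hydrogens included), the background charge field
#' (empty for unembedded GMFCC runs), the model charges of the QM atoms
#' (link hydrogens carry zero charge; the charges of the atoms they replace
#' are kept in the link provenance), and the requested properties.
#'
#' @param system A \code{molecular_system}.
#' @param fragment A \code{fragment_spec}.
#' @param model A \code{charge_model}.
#' @param wants Character subset of
#'   \code{c("ground_energy", "excitation", "tedm", "forces")}.
#' @param embedded Logical; embed the fragment in the background charges of
#'   the remainder of the system (EE-GMFCC) or run in vacuum (GMFCC).
#' @param method_tag Free-form engine/method label.
#' @param state_index Excited-state ordinal, >= 1 (lowest excited state).
#' @return A \code{qm_task}.
#' @export
build_qm_task <- function(system, fragment, model,
                          wants = c("ground_energy", "excitation", "tedm"),
                          embedded = TRUE,
                          method_tag = "mock", state_index = 1L) {
  stopifnot(inherits(system, "molecular_system"),
            inherits(fragment, "fragment_spec"),
            inherits(model, "charge_model"))
  known <- c("ground_energy", "excitation", "tedm", "forces")
  bad <- setdiff(wants, known)
  if (length(bad) > 0) {
    stop("capability error: unknown requested properties: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (state_index < 1) stop("argument error: state_index must be >= 1", call. = FALSE)
  allq <- atom_charges(system, model)
  qm <- fragment$qm_atoms
  qm_q <- ifelse(qm$is_link, 0,
                 allq[match(qm$serial, system$atoms$serial)])
  link_q <- allq[match(fragment$link_atoms$removed_serial, system$atoms$serial)]
  background <- if (embedded) {
    background_charges(system, fragment, model)
  } else {
    empty_charge_set()
  }
  structure(
    list(fragment = fragment, background = background,
         qm_charges = as.numeric(qm_q),
         link_charges = as.numeric(link_q),
         method_tag = method_tag, state_index = as.integer(state_index),
         wants = wants, embedded = embedded),
    class = "qm_task"
  )
}

#' Parameters of the deterministic mock engine
#'
#' A closed-form stand-in for a TD-HF/TD-DFT engine, built so that every
#' assembly formula can be checked against a brute-force whole-system
#' evaluation. \code{alpha} and \code{beta} weight the excitation response
#' to atoms treated inside the QM region and to background charges
#' respectively (setting them unequal models the QM-vs-MM treatment
#' difference; the assembled two-body corrections are then non-trivial).
#' \code{alpha_g} scales the internal residue-pair Coulomb term of the
#' ground-state energy. \code{tau} adds a collective quadratic term on the
#' QM environment, a controlled many-body contribution making the
#' two-body-truncated assembly inexact (zero for the strictly pairwise
#' regime).
#'
#' @param omega0 Baseline chromophore excitation, eV.
#' @param epsilon Named per-element ground self-energies, hartree; elements
#'   missing from the vector fall back to \code{epsilon_default}.
#' @param epsilon_default Fallback per-atom self-energy, hartree.
#' @param alpha QM-environment excitation coupling, eV * angstrom / e.
#' @param beta Background-charge excitation coupling, eV * angstrom / e.
#' @param mu0 Baseline transition dipole, length-3, atomic units.
#' @param gamma Transition-dipole perturbation coefficient.
#' @param alpha_g Internal residue-pair Coulomb coupling of the ground state.
#' @param tau Collective (non-pairwise) excitation coefficient.
#' @return A \code{mock_engine_params} list.
#' @export
mock_engine_params <- function(omega0 = 3.1,
                               epsilon = c(H = -0.5, C = -37.8, N = -54.4,
                                           O = -74.9, P = -340.7, S = -397.5),
                               epsilon_default = -1.0,
                               alpha = 0.08, beta = 0.05,
                               mu0 = c(3.2, 1.0, 0.75), gamma = 0.3,
                               alpha_g = 0.8, tau = 0) {
  stopifnot(length(mu0) == 3, is.finite(omega0), all(is.finite(epsilon)),
            is.finite(alpha), is.finite(beta), is.finite(gamma),
            is.finite(alpha_g), is.finite(tau))
  structure(
    list(omega0 = omega0, epsilon = epsilon,
         epsilon_default = epsilon_default, alpha = alpha, beta = beta,
         mu0 = as.numeric(mu0), gamma = gamma, alpha_g = alpha_g, tau = tau),
    class = "mock_engine_params"
  )
}

#' The deterministic mock QM engine
#'
#' Returns an engine honouring the \code{\link{run_qm}} contract with exact
#' closed-form results. Ground state: per-element self-energies, an internal
#' residue-pair Coulomb term (coupling \code{alpha_g}), and half of the
#' fragment-background Coulomb interaction (the symmetric partition: summing
#' embedded fragments then counts each interaction once). Excitation: the
#' baseline \code{omega0} perturbed by \code{alpha * q/d} for environment
#' atoms inside the QM region and \code{beta * q/d} for background charges
#' (d = distance to the chromophore centroid), plus the \code{tau}
#' collective term. Link hydrogens are zero-charge QM atoms; for embedded
#' tasks the engine restores each replaced atom's point charge to the
#' background at its original position, so a fragment's electrostatic
#' footprint is exactly its source residues. Transition dipole:
#' \code{mu0 + gamma * sum q (r - r_c) / d^2} over QM environment atoms.
#' Forces: the analytic gradient of the excited-state energy with respect
#' to the chromophore atom positions.
#'
#' @param params A \code{mock_engine_params}.
#' @return An engine object for \code{\link{run_qm}}.
#' @export
mock_engine <- function(params = mock_engine_params()) {
  stopifnot(inherits(params, "mock_engine_params"))
  structure(list(params = params), class = c("mock_engine", "qm_engine"))
}

#' Run a QM task on an engine
#'
#' Deterministic for a fixed task; the returned \code{qm_result} satisfies
#' omega = (E_excited - E_ground) * 27.211386245988 whenever both energies
#' are present.
#'
#' @param task A \code{qm_task}.
#' @param engine An engine object (e.g. \code{\link{mock_engine}}).
#' @return A \code{qm_result}.
#' @export
run_qm <- function(task, engine) {
  stopifnot(inherits(task, "qm_task"))
  UseMethod("run_qm", engine)
}

#' @export
run_qm.default <- function(task, engine) {
  stop("engine failure [", task$fragment$label, "]: no run_qm() method for ",
       "class ", paste(class(engine), collapse = "/"), call. = FALSE)
}

mock_eps <- function(params, elem) {
  e <- params$epsilon[elem]
  ifelse(is.na(e), params$epsilon_default, e)
}

## effective MM field seen by the mock: the task background plus, for
## embedded tasks, the charges of the atoms replaced by link hydrogens,
## restored at their original positions
mock_background <- function(task) {
  bg <- task$background$charges[, c("x", "y", "z", "q"), drop = FALSE]
  links <- task$fragment$link_atoms
  if (task$embedded && nrow(links) > 0) {
    bg <- rbind(bg, data.frame(x = links$removed_x, y = links$removed_y,
                               z = links$removed_z, q = task$link_charges))
  }
  bg
}

#' @export
run_qm.mock_engine <- function(task, engine) {
  p <- engine$params
  qm <- task$fragment$qm_atoms
  qq <- task$qm_charges
  bg <- mock_background(task)
  wants <- task$wants

  chrom <- which(qm$role == "chromophore" & !qm$is_link)
  env <- which(!qm$is_link & qm$role != "chromophore")
  needs_chrom <- any(c("excitation", "tedm", "forces") %in% wants)
  if (needs_chrom && length(chrom) == 0) {
    stop("role error [", task$fragment$label,
         "]: excited-state properties requested for a fragment without ",
         "chromophore atoms", call. = FALSE)
  }

  E_ground <- NULL
  if ("ground_energy" %in% wants || "forces" %in% wants) {
    E_ground <- sum(mock_eps(p, qm$elem))
    ## internal residue-pair Coulomb (real atoms, model charges)
    real <- which(!qm$is_link)
    groups <- split(real, qm$res_index[real])
    if (length(groups) > 1) {
      gi <- names(groups)
      for (a in seq_len(length(groups) - 1)) for (b in seq(a + 1, length(groups))) {
        fa <- data.frame(x = qm$x[groups[[a]]], y = qm$y[groups[[a]]],
                         z = qm$z[groups[[a]]], q = qq[groups[[a]]])
        fb <- data.frame(x = qm$x[groups[[b]]], y = qm$y[groups[[b]]],
                         z = qm$z[groups[[b]]], q = qq[groups[[b]]])
        E_ground <- E_ground + p$alpha_g * coulomb_xyzq(fa, fb)
      }
    }
    if (nrow(bg) > 0) {
      fr <- data.frame(x = qm$x[real], y = qm$y[real], z = qm$z[real],
                       q = qq[real])
      E_ground <- E_ground + 0.5 * coulomb_xyzq(fr, bg)
    }
  }

  omega <- NULL; tedm <- NULL; forces <- NULL
  if (needs_chrom) {
    rc <- c(mean(qm$x[chrom]), mean(qm$y[chrom]), mean(qm$z[chrom]))
    env_d <- if (length(env) > 0) {
      sqrt((qm$x[env] - rc[1])^2 + (qm$y[env] - rc[2])^2 +
             (qm$z[env] - rc[3])^2)
    } else numeric(0)
    bg_d <- if (nrow(bg) > 0) {
      sqrt((bg$x - rc[1])^2 + (bg$y - rc[2])^2 + (bg$z - rc[3])^2)
    } else numeric(0)
    if (any(env_d < 1e-9) || any(bg_d < 1e-9)) {
      stop("geometry error [", task$fragment$label,
           "]: charge coincides with the chromophore centroid", call. = FALSE)
    }
    S_env <- sum(abs(qq[env]) / env_d)
    omega <- p$omega0 +
      p$alpha * sum(qq[env] / env_d) +
      (if (nrow(bg) > 0) p$beta * sum(bg$q / bg_d) else 0) +
      p$tau * S_env^2

    if ("tedm" %in% wants) {
      tedm <- p$mu0
      if (length(env) > 0) {
        rel <- cbind(qm$x[env] - rc[1], qm$y[env] - rc[2], qm$z[env] - rc[3])
        tedm <- tedm + p$gamma * colSums(rel * (qq[env] / env_d^2))
      }
    }

    if ("forces" %in% wants) {
      n_m <- length(chrom)
      ## d(omega)/d(r_k), identical for every chromophore atom (centroid only)
      cgrad <- c(0, 0, 0)
      if (length(env) > 0) {
        rel <- cbind(qm$x[env] - rc[1], qm$y[env] - rc[2], qm$z[env] - rc[3])
        cgrad <- cgrad + colSums(rel * (p$alpha * qq[env] / env_d^3)) / n_m
        cgrad <- cgrad +
          2 * p$tau * S_env * colSums(rel * (abs(qq[env]) / env_d^3)) / n_m
      }
      if (nrow(bg) > 0) {
        relb <- cbind(bg$x - rc[1], bg$y - rc[2], bg$z - rc[3])
        cgrad <- cgrad + colSums(relb * (p$beta * bg$q / bg_d^3)) / n_m
      }
      grad_omega <- cgrad / (HARTREE_EV * BOHR_PER_ANG)  # eV/A -> hartree/bohr

      forces <- matrix(0, nrow = n_m, ncol = 3,
                       dimnames = list(qm$serial[chrom], c("x", "y", "z")))
      others <- rbind(
        if (length(env) > 0) {
          data.frame(x = qm$x[env], y = qm$y[env], z = qm$z[env],
                     q = qq[env], w = p$alpha_g)
        },
        if (nrow(bg) > 0) cbind(bg, w = 0.5)
      )
      for (ki in seq_along(chrom)) {
        k <- chrom[ki]
        g <- grad_omega
        if (!is.null(others) && nrow(others) > 0) {
          dx <- (qm$x[k] - others$x) * BOHR_PER_ANG
          dy <- (qm$y[k] - others$y) * BOHR_PER_ANG
          dz <- (qm$z[k] - others$z) * BOHR_PER_ANG
          r3 <- (dx^2 + dy^2 + dz^2)^1.5
          cf <- -others$w * qq[k] * others$q / r3
          g <- g + c(sum(cf * dx), sum(cf * dy), sum(cf * dz))
        }
        forces[ki, ] <- -g
      }
    }
  }

  E_excited <- if (!is.null(E_ground) && !is.null(omega)) {
    E_ground + omega / HARTREE_EV
  } else NULL

  qm_result(E_ground = E_ground, E_excited = E_excited, omega = omega,
            tedm = tedm, forces = forces, label = task$fragment$label,
            embedded = task$embedded)
}

#' Construct and validate a per-fragment QM result
#'
#' @param E_ground Ground-state energy (self + background interaction),
#'   hartree, or NULL.
#' @param E_excited Excited-state total energy, hartree, or NULL.
#' @param omega Excitation energy, eV, or NULL (derived from the energies
#'   when both are present).
#' @param tedm Transition dipole, length-3 numeric, a.u., or NULL.
#' @param forces Per-chromophore-atom force matrix (n x 3, hartree/bohr),
#'   or NULL.
#' @param label Fragment label.
#' @param embedded Whether the calculation was electrostatically embedded.
#' @return A \code{qm_result}.
#' @export
qm_result <- function(E_ground = NULL, E_excited = NULL, omega = NULL,
                      tedm = NULL, forces = NULL, label = "",
                      embedded = TRUE) {
  if (!is.null(E_ground) && !is.null(E_excited)) {
    derived <- (E_excited - E_ground) * HARTREE_EV
    if (is.null(omega)) {
      omega <- derived
    } else if (abs(omega - derived) > 1e-6) {
      stop("validation error [", label, "]: omega (", omega,
           " eV) inconsistent with E_excited - E_ground (", derived, " eV)",
           call. = FALSE)
    }
  }
  if (!is.null(tedm) && (length(tedm) != 3 || any(!is.finite(tedm)))) {
    stop("validation error [", label, "]: tedm must be a finite 3-vector",
         call. = FALSE)
  }
  if (!is.null(forces) && any(!is.finite(forces))) {
    stop("validation error [", label, "]: non-finite forces", call. = FALSE)
  }
  structure(
    list(E_ground = E_ground, E_excited = E_excited, omega = omega,
         tedm = tedm, forces = forces, label = label, embedded = embedded),
    class = "qm_result"
  )
}

#' @export
print.qm_result <- function(x, ...) {
  cat(sprintf("<qm_result> %s%s\n", x$label,
              if (x$embedded) " (embedded)" else " (vacuum)"))
  if (!is.null(x$omega)) cat(sprintf("  omega  = %.6f eV\n", x$omega))
  if (!is.null(x$E_ground)) cat(sprintf("  E      = %.8f hartree\n", x$E_ground))
  if (!is.null(x$tedm)) cat(sprintf("  tedm   = (%.4f, %.4f, %.4f) a.u.\n",
                                    x$tedm[1], x$tedm[2], x$tedm[3]))
  invisible(x)
}

#' Serialize a QM task for an external engine
#'
#' Writes \code{geometry.xyz} (element x y z, angstrom, link hydrogens
#' included), \code{charges.txt} ("x y z q" lines; zero data lines for an
#' empty background) and \code{task.json} (all remaining metadata) into a
#' directory. Round-trips through \code{\link{parse_task}}.
#'
#' @param task A \code{qm_task}.
#' @param directory Writable directory (created if absent).
#' @return Path to the manifest, invisibly.
#' @export
serialize_task <- function(task, directory) {
  stopifnot(inherits(task, "qm_task"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  qm <- task$fragment$qm_atoms
  writeLines(
    c(nrow(qm), task$fragment$label,
      sprintf("%-2s %16.10f %16.10f %16.10f", qm$elem, qm$x, qm$y, qm$z)),
    file.path(directory, "geometry.xyz"))
  write_background_charges(task$background, file.path(directory, "charges.txt"))
  manifest <- list(
    schema = "eegmfcc-task-v1",
    label = task$fragment$label,
    source_residues = task$fragment$source_residues,
    method_tag = task$method_tag,
    state_index = task$state_index,
    wants = as.list(task$wants),
    embedded = task$embedded,
    atoms = task$fragment$qm_atoms[, c("serial", "name", "elem", "res_index",
                                       "resname", "chain", "resno", "role",
                                       "is_link")],
    qm_charges = task$qm_charges,
    link_atoms = task$fragment$link_atoms,
    link_charges = task$link_charges,
    background_serials = task$background$charges$serial,
    excluded_atoms = task$background$excluded_atoms
  )
  path <- file.path(directory, "task.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Parse a serialized QM task
#'
#' @param directory Directory written by \code{\link{serialize_task}}.
#' @return A \code{qm_task}.
#' @export
parse_task <- function(directory) {
  manifest_path <- file.path(directory, "task.json")
  if (!file.exists(manifest_path)) {
    stop("I/O error: no task.json in ", directory, call. = FALSE)
  }
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  xyz <- readLines(file.path(directory, "geometry.xyz"))
  n <- as.integer(xyz[1])
  geo <- utils::read.table(text = xyz[3:(2 + n)], col.names = c("elem", "x", "y", "z"),
                    stringsAsFactors = FALSE)
  atoms <- as.data.frame(man$atoms)
  atoms$x <- geo$x; atoms$y <- geo$y; atoms$z <- geo$z
  atoms$name_canon <- normalize_atom_name(atoms$name)
  ch_path <- file.path(directory, "charges.txt")
  ch_lines <- readLines(ch_path)
  charges <- if (length(ch_lines) > 0 && any(nzchar(ch_lines))) {
    cf <- utils::read.table(text = ch_lines, col.names = c("x", "y", "z", "q"))
    cf$serial <- as.integer(man$background_serials)
    cf[, c("serial", "x", "y", "z", "q")]
  } else {
    empty_charge_set()$charges
  }
  links <- if (length(man$link_atoms) > 0 && NROW(man$link_atoms) > 0) {
    as.data.frame(man$link_atoms)
  } else empty_link_table()
  frag <- new_fragment_spec(man$label, atoms, links,
                            as.integer(man$source_residues))
  excluded <- if (length(man$excluded_atoms) > 0 && NROW(man$excluded_atoms) > 0) {
    as.data.frame(man$excluded_atoms)
  } else empty_charge_set()$excluded_atoms
  structure(
    list(fragment = frag,
         background = new_charge_set(charges, excluded),
         qm_charges = as.numeric(man$qm_charges),
         link_charges = as.numeric(man$link_charges %||% numeric(0)),
         method_tag = man$method_tag, state_index = as.integer(man$state_index),
         wants = unlist(man$wants), embedded = isTRUE(man$embedded)),
    class = "qm_task"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a QM result to JSON
#'
#' @param result A \code{qm_result}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "qm_result"))
  out <- result[!vapply(result, is.null, logical(1))]
  if (!is.null(result$forces)) out$forces <- unclass(result$forces)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Parse and validate an engine result file
#'
#' Reads a JSON result and enforces the omega / energy consistency contract
#' (1e-6 eV). Partial results (e.g. transition dipole only) are accepted.
#'
#' @param path Path to a result JSON.
#' @return A validated \code{qm_result}.
#' @export
parse_result <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(raw) == 0 ||
      !any(c("E_ground", "E_excited", "omega", "tedm", "forces") %in% names(raw))) {
    stop("schema error: result file carries none of the known fields",
         call. = FALSE)
  }
  forces <- raw$forces
  if (!is.null(forces)) forces <- as.matrix(forces)
  qm_result(E_ground = raw$E_ground, E_excited = raw$E_excited,
            omega = raw$omega, tedm = raw$tedm, forces = forces,
            label = raw$label %||% basename(path),
            embedded = isTRUE(raw$embedded %||% TRUE))
}
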