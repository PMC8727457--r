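#' Link-atom capping rules
#'
#' The backbone is severed at the C3'-O3' ester bond. The dangling valence on
#' each side is saturated with a hydrogen placed along the severed bond
#' direction: 1.09 A from a kept C3' (C-H) and 0.96 A from a kept O3' (O-H).
#'
#' @return A data.frame with one rule per kept atom.
#' @export
link_atom_rules <- function() {
  data.frame(
    kept = c("C3'", "O3'"),
    removed = c("O3'", "C3'"),
    h_bond_length = c(1.09, 0.96),
    stringsAsFactors = FALSE
  )
}

#' Place a link hydrogen along a severed bond
#'
#' Returns a hydrogen at \code{anchor + bond_length * unit(removed - anchor)}:
#' on the original bond axis, at the rule distance from the kept (anchor)
#' atom.
#'
#' @param anchor Numeric xyz of the kept atom (angstrom).
#' @param removed Numeric xyz of the excised bond partner.
#' @param bond_length Target H-anchor distance in angstrom, > 0.
#' @return Numeric xyz of the hydrogen.
#' @export
place_link_hydrogen <- function(anchor, removed, bond_length) {
  anchor <- as.numeric(anchor); removed <- as.numeric(removed)
  stopifnot(length(anchor) == 3, length(removed) == 3)
  if (!is.numeric(bond_length) || bond_length <= 0) {
    stop("argument error: bond_length must be positive", call. = FALSE)
  }
  v <- removed - anchor
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) {
    stop("geometry error: anchor and removed atoms coincide", call. = FALSE)
  }
  anchor + bond_length * v / nv
}

#' Backbone bonds of a system
#'
#' Detects, for every pair of consecutive residues within a chain, the
#' covalent C3'-O3' linkage crossing the residue boundary (either
#' orientation, cross-pair distance <= 1.8 A). Consecutive residues with no
#' such pair (chain breaks, non-covalent ligands) simply contribute no bond.
#'
#' @param system A \code{molecular_system}.
#' @return data.frame with columns \code{res_i}, \code{res_j} (j = i + 1),
#'   \code{serial_i}, \code{serial_j}, \code{name_i}, \code{name_j}.
#' @export
backbone_bonds <- function(system) {
  stopifnot(inherits(system, "molecular_system"))
  res <- system$residues
  out <- list()
  for (i in seq_len(system$n_res - 1)) {
    if (res$chain[i] != res$chain[i + 1]) next
    a <- residue_atoms(system, i)
    b <- residue_atoms(system, i + 1)
    a <- a[a$name_canon %in% c("C3'", "O3'"), , drop = FALSE]
    b <- b[b$name_canon %in% c("C3'", "O3'"), , drop = FALSE]
    if (nrow(a) == 0 || nrow(b) == 0) next
    best <- NULL
    for (p in seq_len(nrow(a))) for (q in seq_len(nrow(b))) {
      if (a$name_canon[p] == b$name_canon[q]) next
      d <- sqrt(sum((unlist(a[p, c("x", "y", "z")]) -
                       unlist(b[q, c("x", "y", "z")]))^2))
      if (d <= 1.8 && (is.null(best) || d < best$d)) {
        best <- list(p = p, q = q, d = d)
      }
    }
    if (!is.null(best)) {
      out[[length(out) + 1]] <- data.frame(
        res_i = i, res_j = i + 1L,
        serial_i = a$serial[best$p], serial_j = b$serial[best$q],
        name_i = a$name_canon[best$p], name_j = b$name_canon[best$q],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(res_i = integer(), res_j = integer(),
                      serial_i = integer(), serial_j = integer(),
                      name_i = character(), name_j = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

new_fragment_spec <- function(label, qm_atoms, link_atoms, source_residues) {
  structure(
    list(label = label, qm_atoms = qm_atoms, link_atoms = link_atoms,
         source_residues = sort(source_residues)),
    class = "fragment_spec"
  )
}

#' @export
print.fragment_spec <- function(x, ...) {
  cat(sprintf("<fragment_spec> %s: %d QM atoms (%d link H), residues {%s}\n",
              x$label, nrow(x$qm_atoms), nrow(x$link_atoms),
              paste(x$source_residues, collapse = ",")))
  invisible(x)
}

empty_link_table <- function() {
  data.frame(
    h_serial = integer(), anchor_serial = integer(), removed_serial = integer(),
    hx = numeric(), hy = numeric(), hz = numeric(),
    removed_x = numeric(), removed_y = numeric(), removed_z = numeric(),
    bond_length = numeric(), stringsAsFactors = FALSE
  )
}

#' Sever backbone bonds around a residue subset and cap with hydrogens
#'
#' The QM region consists of all atoms of the subset residues; every backbone
#' C3'-O3' bond with exactly one end inside the subset is severed and the
#' dangling valence capped with a link hydrogen per
#' \code{\link{link_atom_rules}} (kept C3' gets H at 1.09 A, kept O3' at
#' 0.96 A). Link provenance (placed H, kept anchor, removed partner and its
#' coordinates) is recorded so embedding and engines can account for the
#' replaced atoms.
#'
#' @param system A \code{molecular_system}.
#' @param residue_subset Non-empty set of residue indices.
#' @param label Fragment label string.
#' @return A \code{fragment_spec}. Link hydrogens appear as extra rows of
#'   \code{qm_atoms} with \code{is_link = TRUE} and negative serials.
#' @export
sever_and_cap <- function(system, residue_subset, label = NULL) {
  stopifnot(inherits(system, "molecular_system"))
  residue_subset <- sort(unique(as.integer(residue_subset)))
  if (length(residue_subset) == 0) {
    stop("argument error: empty residue subset", call. = FALSE)
  }
  unknown <- setdiff(residue_subset, system$residues$res_index)
  if (length(unknown) > 0) {
    stop("lookup error: unknown residue indices ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(label)) {
    label <- paste0("SUBSET(", paste(residue_subset, collapse = ","), ")")
  }
  qm <- system$atoms[system$atoms$res_index %in% residue_subset, , drop = FALSE]
  qm$is_link <- FALSE
  bonds <- backbone_bonds(system)
  rules <- link_atom_rules()
  links <- empty_link_table()
  if (nrow(bonds) > 0) {
    in_i <- bonds$res_i %in% residue_subset
    in_j <- bonds$res_j %in% residue_subset
    cut <- which(xor(in_i, in_j))
    for (k in cut) {
      if (in_i[k]) {
        kept_serial <- bonds$serial_i[k]; removed_serial <- bonds$serial_j[k]
        kept_name <- bonds$name_i[k]
      } else {
        kept_serial <- bonds$serial_j[k]; removed_serial <- bonds$serial_i[k]
        kept_name <- bonds$name_j[k]
      }
      rule <- rules[rules$kept == kept_name, ]
      if (nrow(rule) != 1) {
        stop("structure error: no capping rule for kept atom ",
             sQuote(kept_name), call. = FALSE)
      }
      anchor <- system$atoms[match(kept_serial, system$atoms$serial), ]
      removed <- system$atoms[match(removed_serial, system$atoms$serial), ]
      h <- place_link_hydrogen(unlist(anchor[c("x", "y", "z")]),
                               unlist(removed[c("x", "y", "z")]),
                               rule$h_bond_length)
      h_serial <- -(nrow(links) + 1L)
      hrow <- anchor
      hrow$serial <- h_serial
      hrow$name <- "HL"; hrow$name_canon <- "HL"; hrow$elem <- "H"
      hrow$x <- h[1]; hrow$y <- h[2]; hrow$z <- h[3]
      hrow$is_link <- TRUE
      qm <- rbind(qm, hrow)
      links <- rbind(links, data.frame(
        h_serial = h_serial, anchor_serial = kept_serial,
        removed_serial = removed_serial,
        hx = h[1], hy = h[2], hz = h[3],
        removed_x = removed$x, removed_y = removed$y, removed_z = removed$z,
        bond_length = rule$h_bond_length, stringsAsFactors = FALSE
      ))
    }
  }
  rownames(qm) <- NULL
  new_fragment_spec(label, qm, links, residue_subset)
}

chain_span <- function(system, i) {
  ## residue indices of the chain containing residue i, in order
  ch <- system$residues$chain[system$residues$res_index == i]
  system$residues$res_index[system$residues$chain == ch]
}

#' Build the capped-residue fragment of residue i
#'
#' Residue i together with its left and right neighbor caps: the subset
#' \{i-1, i, i+1\} severed and hydrogen-capped at its outer boundaries. These
#' are the one-body species of the ground-state assembly, which sums them for
#' i = 2..N-1 within a chain.
#'
#' @param system A \code{molecular_system}.
#' @param i Residue index with both neighbors in the same chain
#'   (2 <= position <= chain length - 1).
#' @return A \code{fragment_spec} labelled \code{CAPPED_RESIDUE(i)}.
#' @export
build_capped_residue <- function(system, i) {
  span <- chain_span(system, i)
  pos <- match(i, span)
  if (is.na(pos) || pos < 2 || pos > length(span) - 1) {
    stop("range error: capped residue needs 2 <= i <= N-1 within its chain",
         call. = FALSE)
  }
  sever_and_cap(system, span[(pos - 1):(pos + 1)],
                label = sprintf("CAPPED_RESIDUE(%d)", i))
}

#' Build the conjugate-cap (concap) fragment at position i
#'
#' The fused species of the two neighboring residues i and i+1, whose energy
#' is deducted to cancel the double counting of cap regions; the ground-state
#' assembly subtracts them for i = 2..N-2 within a chain.
#'
#' @param system A \code{molecular_system}.
#' @param i Left residue index (2 <= position <= chain length - 2).
#' @return A \code{fragment_spec} labelled \code{CONCAP(i)}.
#' @export
build_concap <- function(system, i) {
  span <- chain_span(system, i)
  pos <- match(i, span)
  if (is.na(pos) || pos < 2 || pos > length(span) - 2) {
    stop("range error: concap needs 2 <= i <= N-2 within its chain",
         call. = FALSE)
  }
  sever_and_cap(system, span[pos:(pos + 1)], label = sprintf("CONCAP(%d)", i))
}

#' Build a chromophore + capped-residue two-body fragment
#'
#' QM region of the two-body excited-state correction: all chromophore atoms
#' plus residue j severed from the chain and hydrogen-capped.
#'
#' @param system A \code{molecular_system}.
#' @param m Chromophore residue index.
#' @param j Partner residue index, j != m.
#' @return A \code{fragment_spec} labelled \code{TWO_BODY(m,j)}.
#' @export
build_two_body <- function(system, m, j) {
  stopifnot(inherits(system, "molecular_system"))
  if (system$residues$role[system$residues$res_index == m] != "chromophore") {
    stop("role error: residue ", m, " is not flagged as the chromophore",
         call. = FALSE)
  }
  if (j == m) stop("argument error: j must differ from m", call. = FALSE)
  sever_and_cap(system, c(m, j), label = sprintf("TWO_BODY(%d,%d)", m, j))
}

#' Build the fused and monomer species of a ground-state pair
#'
#' The two-body ground-state term needs three fragments per pair: the fused
#' species \{i, j\} and the two identically H-capped monomers, so that
#' E_ij - E_i - E_j is size-consistent (caps cancel exactly).
#'
#' @param system A \code{molecular_system}.
#' @param i,j Residue indices of a non-neighboring pair.
#' @return List with elements \code{pair}, \code{mono_i}, \code{mono_j}
#'   (\code{fragment_spec}s).
#' @export
build_pair_ground <- function(system, i, j) {
  if (i == j) stop("argument error: i and j must differ", call. = FALSE)
  list(
    pair = sever_and_cap(system, c(i, j),
                         label = sprintf("PAIR_GROUND(%d,%d)", i, j)),
    mono_i = sever_and_cap(system, i, label = sprintf("MONO(%d)", i)),
    mono_j = sever_and_cap(system, j, label = sprintf("MONO(%d)", j))
  )
}

#' Enumerate ground-state two-body pairs
#'
#' All residue pairs treated at the QM level in the ground-state assembly:
#' same-chain pairs with sequence separation j >= i+3 (nearer pairs are
#' already covered by the capped-residue/concap sums), and any cross-chain
#' pair (non-neighboring at every index separation), subject to the
#' closest-contact threshold \code{lambda} (closed: distances equal to
#' lambda are included).
#'
#' @param system A \code{molecular_system}.
#' @param lambda Distance threshold in angstrom (use \code{Inf} for all).
#' @return A \code{pair_list}: data.frame of (i, j) with attribute
#'   \code{lambda}.
#' @export
enumerate_ground_pairs <- function(system, lambda) {
  stopifnot(inherits(system, "molecular_system"))
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0) {
    stop("argument error: lambda must be a single non-negative length",
         call. = FALSE)
  }
  n <- system$n_res
  res <- system$residues
  out <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      same_chain <- res$chain[i] == res$chain[j]
      if (same_chain && j < i + 3) next
      if (is.finite(lambda)) {
        d <- min_distance(residue_atoms(system, i), residue_atoms(system, j))
        if (d > lambda) next
      }
      out[[length(out) + 1]] <- c(i, j)
    }
  }
  pairs <- if (length(out) > 0) {
    as.data.frame(do.call(rbind, out)) |> setNames(c("i", "j"))
  } else {
    data.frame(i = integer(), j = integer())
  }
  structure(pairs, lambda = lambda, class = c("pair_list", "data.frame"))
}

#' Enumerate excited-state two-body partners of the chromophore
#'
#' Nonbonded mode (chromophore attached non-covalently): all residues within
#' \code{lambda_2b} of the chromophore. Bonded mode (chromophore covalently
#' part of the chain): the same set minus indices in [m-2, m+2], which are
#' already treated by the local capped-fragment terms.
#'
#' @param system A \code{molecular_system}.
#' @param m Chromophore residue index.
#' @param lambda_2b Distance threshold in angstrom, >= 0.
#' @param bonded Logical; apply the [m-2, m+2] exclusion window.
#' @return A \code{pair_list} of (m, j) pairs.
#' @export
enumerate_excited_pairs <- function(system, m, lambda_2b, bonded = FALSE) {
  stopifnot(inherits(system, "molecular_system"))
  if (!bonded &&
      system$residues$role[system$residues$res_index == m] != "chromophore") {
    stop("role error: residue ", m, " is not flagged as the chromophore",
         call. = FALSE)
  }
  js <- neighbors_within(system, m, lambda_2b)
  if (bonded) js <- js[js < m - 2 | js > m + 2]
  pairs <- data.frame(i = rep(m, length(js)), j = js)
  structure(pairs, lambda = lambda_2b, class = c("pair_list", "data.frame"))
}

#' Build the truncated full-system QM region
#'
#' The conventional QM/MM reference region: the chromophore plus every
#' residue within \code{lambda_fs}, severed from the remaining chain and
#' hydrogen-capped. With \code{lambda_fs = 0} (and no interpenetrating
#' atoms) this is the chromophore-only one-body region.
#'
#' @param system A \code{molecular_system}.
#' @param m Chromophore residue index.
#' @param lambda_fs Distance threshold in angstrom, >= 0.
#' @return A \code{fragment_spec} labelled \code{TRUNCATED_FULL(lambda)}.
#' @export
build_truncated_full <- function(system, m, lambda_fs) {
  subset <- c(m, neighbors_within(system, m, lambda_fs))
  sever_and_cap(system, subset,
                label = sprintf("TRUNCATED_FULL(%g)", lambda_fs))
}

#' Serialize a fragment to XYZ plus a JSON manifest
#'
#' Writes \code{<stem>.xyz} (element x y z, angstrom, link hydrogens
#' included) and \code{<stem>.json} carrying the label, source residues and
#' link-atom provenance.
#'
#' @param fragment A \code{fragment_spec}.
#' @param stem Output path stem (no extension).
#' @return The manifest path, invisibly.
#' @export
write_fragment_xyz <- function(fragment, stem) {
  stopifnot(inherits(fragment, "fragment_spec"))
  qm <- fragment$qm_atoms
  xyz <- c(nrow(qm), fragment$label,
           sprintf("%-2s %14.8f %14.8f %14.8f", qm$elem, qm$x, qm$y, qm$z))
  writeLines(xyz, paste0(stem, ".xyz"))
  manifest <- list(
    label = fragment$label,
    source_residues = fragment$source_residues,
    link_atoms = fragment$link_atoms
  )
  jsonlite::write_json(manifest, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paste0(stem, ".json"))
}
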