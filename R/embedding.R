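#' Construct a charge model
#'
#' Maps every atom of a system to a point charge for electrostatic
#' embedding. Two modes mirror the two charge schemes practitioners use:
#' a force-field-style template keyed by (residue name, atom name), and a
#' per-structure explicit table keyed by atom serial (ESP-style).
#'
#' @param table data.frame; template mode needs columns \code{resname},
#'   \code{name}, \code{q}; per-atom mode needs \code{serial}, \code{q}.
#' @param mode \code{"template"} or \code{"per_atom"}.
#' @return A \code{charge_model}.
#' @export
charge_model <- function(table, mode = c("template", "per_atom")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(table))
  if (mode == "template") {
    need <- c("resname", "name", "q")
  } else {
    need <- c("serial", "q")
  }
  miss <- setdiff(need, names(table))
  if (length(miss) > 0) {
    stop("charge-model error: table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(table$q))) {
    stop("charge-model error: non-finite charges", call. = FALSE)
  }
  if (mode == "template") {
    table$name <- normalize_atom_name(table$name)
    key <- paste(table$resname, table$name, sep = "|")
    if (anyDuplicated(key)) {
      stop("charge-model error: duplicate (resname, atom name) entries: ",
           key[duplicated(key)][1], call. = FALSE)
    }
    ## residue templates must carry integral total charge
    tot <- tapply(table$q, table$resname, sum)
    bad <- names(tot)[abs(tot - round(tot)) > 1e-6]
    if (length(bad) > 0) {
      stop("charge-model error: residue template(s) with non-integral total ",
           "charge: ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(table = table, mode = mode), class = "charge_model")
}

#' Read a charge table from a text file
#'
#' Whitespace-separated columns; template mode:
#' \code{residue_name atom_name charge}, per-atom mode:
#' \code{serial charge}. Lines starting with \code{#} are comments.
#'
#' @param path File path.
#' @param mode \code{"template"} or \code{"per_atom"}.
#' @return A \code{charge_model}.
#' @export
read_charge_table <- function(path, mode = c("template", "per_atom")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (mode == "template") {
    if (ncol(raw) < 3) stop("charge-model error: template table needs 3 columns",
                            call. = FALSE)
    tab <- data.frame(resname = as.character(raw[[1]]),
                      name = as.character(raw[[2]]),
                      q = as.numeric(raw[[3]]), stringsAsFactors = FALSE)
  } else {
    if (ncol(raw) < 2) stop("charge-model error: per-atom table needs 2 columns",
                            call. = FALSE)
    tab <- data.frame(serial = as.integer(raw[[1]]),
                      q = as.numeric(raw[[2]]), stringsAsFactors = FALSE)
  }
  charge_model(tab, mode)
}

#' Write a charge model to a text file
#'
#' Inverse of \code{\link{read_charge_table}}; charges are written to six
#' decimals.
#'
#' @param model A \code{charge_model}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_charge_table <- function(model, path) {
  stopifnot(inherits(model, "charge_model"))
  tab <- model$table
  lines <- if (model$mode == "template") {
    sprintf("%-6s %-6s %12.6f", tab$resname, tab$name, tab$q)
  } else {
    sprintf("%8d %12.6f", tab$serial, tab$q)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Per-atom charges of a system under a charge model
#'
#' @param system A \code{molecular_system}.
#' @param model A \code{charge_model} resolving every atom.
#' @return Numeric vector of charges aligned with \code{system$atoms}.
#' @export
atom_charges <- function(system, model) {
  stopifnot(inherits(system, "molecular_system"), inherits(model, "charge_model"))
  at <- system$atoms
  if (model$mode == "template") {
    key <- paste(at$resname, at$name_canon, sep = "|")
    tkey <- paste(model$table$resname, model$table$name, sep = "|")
    idx <- match(key, tkey)
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[1]
      stop("charge-model error: no charge for atom ", sQuote(at$name[bad]),
           " of residue ", sQuote(at$resname[bad]),
           " (index ", at$res_index[bad], ")", call. = FALSE)
    }
    model$table$q[idx]
  } else {
    idx <- match(at$serial, model$table$serial)
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[1]
      stop("charge-model error: no charge for atom serial ", at$serial[bad],
           " (residue ", sQuote(at$resname[bad]), ")", call. = FALSE)
    }
    model$table$q[idx]
  }
}

new_charge_set <- function(charges, excluded) {
  structure(list(charges = charges, excluded_atoms = excluded),
            class = "charge_set")
}

#' An empty background charge set
#'
#' Used for unembedded (vacuum / plain GMFCC) fragment calculations.
#' @return A \code{charge_set} with zero charges.
#' @export
empty_charge_set <- function() {
  new_charge_set(
    data.frame(serial = integer(), x = numeric(), y = numeric(),
               z = numeric(), q = numeric(), stringsAsFactors = FALSE),
    data.frame(serial = integer(), reason = character(),
               stringsAsFactors = FALSE)
  )
}

#' Background point charges for an embedded fragment calculation
#'
#' One point charge per system atom outside the fragment's QM region. Atoms
#' replaced by link hydrogens (the removed bond partners) are excluded, not
#' redistributed, and listed in \code{excluded_atoms} with the reason.
#'
#' @param system A \code{molecular_system}.
#' @param fragment A \code{fragment_spec}.
#' @param model A \code{charge_model} resolving all system atoms.
#' @return A \code{charge_set} with elements \code{charges}
#'   (serial, x, y, z, q) and \code{excluded_atoms}.
#' @export
background_charges <- function(system, fragment, model) {
  stopifnot(inherits(system, "molecular_system"),
            inherits(fragment, "fragment_spec"))
  q <- atom_charges(system, model)
  qm_serials <- fragment$qm_atoms$serial[!fragment$qm_atoms$is_link]
  removed <- fragment$link_atoms$removed_serial
  keep <- !(system$atoms$serial %in% c(qm_serials, removed))
  ex_idx <- match(removed, system$atoms$serial)
  excluded <- data.frame(
    serial = removed,
    reason = rep("replaced by link hydrogen", length(removed)),
    q = q[ex_idx],
    x = system$atoms$x[ex_idx], y = system$atoms$y[ex_idx],
    z = system$atoms$z[ex_idx],
    stringsAsFactors = FALSE
  )
  charges <- data.frame(
    serial = system$atoms$serial[keep],
    x = system$atoms$x[keep], y = system$atoms$y[keep],
    z = system$atoms$z[keep], q = q[keep],
    stringsAsFactors = FALSE
  )
  new_charge_set(charges, excluded)
}

coulomb_xyzq <- function(a, b) {
  ## a, b: data.frames with x, y, z (angstrom) and q (e); energy in hartree
  pa <- as.matrix(a[, c("x", "y", "z")]) * BOHR_PER_ANG
  pb <- as.matrix(b[, c("x", "y", "z")]) * BOHR_PER_ANG
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
  d2[d2 < 0] <- 0
  r <- sqrt(d2)
  if (any(r < 1e-12)) {
    stop("singularity error: coincident charges in Coulomb sum", call. = FALSE)
  }
  sum(outer(a$q, b$q) / r)
}

#' Pairwise Coulomb energy between two charge sets
#'
#' Sum over all cross pairs of q_a q_b / r_ab with r in bohr; result in
#' hartree. Symmetric in its arguments and exactly 1/r under uniform
#' dilation.
#'
#' @param setA,setB \code{charge_set}s (or data.frames with x, y, z, q).
#' @return Energy in hartree.
#' @export
coulomb_energy <- function(setA, setB) {
  a <- if (inherits(setA, "charge_set")) setA$charges else setA
  b <- if (inherits(setB, "charge_set")) setB$charges else setB
  if (NROW(a) == 0 || NROW(b) == 0) return(0)
  coulomb_xyzq(a, b)
}

residue_charge_frame <- function(system, model, i) {
  at <- residue_atoms(system, i)
  q <- atom_charges(system, model)
  data.frame(x = at$x, y = at$y, z = at$z,
             q = q[match(at$serial, system$atoms$serial)])
}

#' Double-counting correction of the ground-state assembly
#'
#' The MM-level pairwise charge-charge interaction summed over the
#' QM-treated ground-state pairs. Each such pair's mutual interaction is
#' counted both by its explicit two-body QM term and once at the MM level
#' through the embedding fields of the one-body sums, so one MM copy is
#' subtracted.
#'
#' @param system A \code{molecular_system}.
#' @param ground_pairs A \code{pair_list} from
#'   \code{\link{enumerate_ground_pairs}}.
#' @param model A \code{charge_model}.
#' @return Energy in hartree.
#' @export
double_counting_correction <- function(system, ground_pairs, model) {
  stopifnot(inherits(system, "molecular_system"))
  if (nrow(ground_pairs) == 0) return(0)
  total <- 0
  for (k in seq_len(nrow(ground_pairs))) {
    a <- residue_charge_frame(system, model, ground_pairs$i[k])
    b <- residue_charge_frame(system, model, ground_pairs$j[k])
    total <- total + coulomb_xyzq(a, b)
  }
  total
}

#' Serialize background charges as "x y z q" lines
#'
#' @param set A \code{charge_set}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_background_charges <- function(set, path) {
  stopifnot(inherits(set, "charge_set"))
  ch <- set$charges
  lines <- sprintf("%14.8f %14.8f %14.8f %12.6f", ch$x, ch$y, ch$z, ch$q)
  writeLines(lines, path)
  invisible(path)
}
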