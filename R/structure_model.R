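#' @importFrom stats setNames
NULL

STANDARD_NUCLEOTIDES <- c(
  "A", "G", "C", "U", "I", "T",
  "RA", "RG", "RC", "RU",
  "DA", "DG", "DC", "DT"
)

#' Normalize a PDB atom name
#'
#' PDB dialects write the sugar carbon / ester oxygen of the nucleic-acid
#' backbone as \code{C3'}, \code{C3*} or plain \code{C3} (and likewise for
#' \code{O3'}). All cut-site logic works on the canonical primed names, so the
#' reader and the fragmenter normalize through this table. Names without a
#' dialect variant are returned trimmed but otherwise untouched.
#'
#' @param name Character vector of atom names as read from a file.
#' @return Canonical atom names (e.g. \code{"C3'"}, \code{"O3'"}).
#' @export
normalize_atom_name <- function(name) {
  nm <- trimws(name)
  tab <- c(
    "C3"  = "C3'", "C3*" = "C3'", "C3'" = "C3'",
    "O3"  = "O3'", "O3*" = "O3'", "O3'" = "O3'",
    "C5"  = "C5'", "C5*" = "C5'", "C5'" = "C5'",
    "O5"  = "O5'", "O5*" = "O5'", "O5'" = "O5'"
  )
  hit <- unname(tab[nm])
  ifelse(is.na(hit), nm, hit)
}

new_atom_table <- function(serial, name, elem, x, y, z,
                           chain, resno, resname, res_index, role) {
  data.frame(
    serial = as.integer(serial),
    name = as.character(name),
    name_canon = normalize_atom_name(name),
    elem = as.character(elem),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    chain = as.character(chain),
    resno = as.integer(resno),
    resname = as.character(resname),
    res_index = as.integer(res_index),
    role = as.character(role),
    stringsAsFactors = FALSE
  )
}

#' Construct a molecular system from an atom table
#'
#' The central container of the structure layer: an ordered atom table plus a
#' per-residue summary. Residues are indexed 1..N in file order within chains,
#' chains concatenated; this global index is the residue index \code{i} used
#' by every fragmentation sum.
#'
#' @param atoms A data.frame with columns \code{serial}, \code{name},
#'   \code{elem}, \code{x}, \code{y}, \code{z}, \code{chain}, \code{resno},
#'   \code{resname}, \code{res_index}, \code{role}. \code{role} is one of
#'   \code{"nucleotide"}, \code{"chromophore"}, \code{"other"}.
#' @return An object of class \code{molecular_system} with elements
#'   \code{atoms}, \code{residues} (one row per residue) and \code{n_res}.
#' @export
molecular_system <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "name", "elem", "x", "y", "z",
            "chain", "resno", "resname", "res_index", "role")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    stop("atom table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(atoms) == 0) stop("a molecular system needs at least one atom", call. = FALSE)
  if (!"name_canon" %in% names(atoms)) {
    atoms$name_canon <- normalize_atom_name(atoms$name)
  }
  if (anyDuplicated(atoms$serial)) {
    stop("structure error: duplicated atom serial numbers", call. = FALSE)
  }
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("structure error: non-finite coordinates", call. = FALSE)
  }
  if (any(!nzchar(atoms$elem))) {
    stop("structure error: empty element symbols", call. = FALSE)
  }
  atoms$res_index <- as.integer(atoms$res_index)
  atoms$serial <- as.integer(atoms$serial)
  idx <- sort(unique(atoms$res_index))
  if (!identical(idx, seq_along(idx))) {
    stop("structure error: residue indices must be contiguous 1..N", call. = FALSE)
  }
  first <- match(idx, atoms$res_index)
  residues <- data.frame(
    res_index = idx,
    resname = atoms$resname[first],
    chain = atoms$chain[first],
    role = atoms$role[first],
    n_atoms = as.integer(table(factor(atoms$res_index, levels = idx))),
    stringsAsFactors = FALSE
  )
  structure(
    list(atoms = atoms, residues = residues, n_res = length(idx)),
    class = "molecular_system"
  )
}

#' @export
print.molecular_system <- function(x, ...) {
  cat(sprintf("<molecular_system> %d residues, %d atoms, %d chain(s)\n",
              x$n_res, nrow(x$atoms), length(unique(x$residues$chain))))
  roles <- table(x$residues$role)
  cat("  roles:", paste(sprintf("%s=%d", names(roles), roles), collapse = ", "), "\n")
  invisible(x)
}

#' Atoms belonging to one residue
#'
#' @param system A \code{molecular_system}.
#' @param i Residue index (1-based global order).
#' @return The atom-table rows of residue \code{i}.
#' @export
residue_atoms <- function(system, i) {
  stopifnot(inherits(system, "molecular_system"))
  if (length(i) != 1 || !(i %in% system$residues$res_index)) {
    stop("lookup error: unknown residue index ", i, call. = FALSE)
  }
  system$atoms[system$atoms$res_index == i, , drop = FALSE]
}

## Reassign the ester O3' of standard-convention PDB nucleotides to the
## residue whose phosphate it bonds, so that the C3'-O3' cut bond always
## crosses a fragment boundary. Grouping only; author numbering is kept.
regroup_ester_oxygens <- function(atoms) {
  idx <- sort(unique(atoms$res_index))
  for (i in idx[-length(idx)]) {
    a <- which(atoms$res_index == i & atoms$name_canon == "O3'")
    p <- which(atoms$res_index == i + 1 & atoms$name_canon == "P")
    if (length(a) == 1 && length(p) == 1 &&
        atoms$chain[a] == atoms$chain[p]) {
      d <- sqrt(sum((unlist(atoms[a, c("x", "y", "z")]) -
                       unlist(atoms[p, c("x", "y", "z")]))^2))
      if (d <= 1.8) atoms$res_index[a] <- i + 1L
    }
  }
  atoms
}

#' Read a PDB file into a molecular system
#'
#' Parsing is delegated to \code{bio3d::read.pdb}; on top of it the reader
#' resolves alternate locations to the first conformer, orders residues by
#' file order within chains (chains concatenated, insertion-coded residues
#' kept as distinct residues), assigns roles from residue codes, and checks
#' the atom-table invariants. HETATM ligand residues are retained. For
#' standard-convention nucleotides (ester O3' stored with the upstream
#' residue, bonded to the next residue's P) the O3' atom is regrouped onto
#' the downstream residue for fragmentation purposes.
#'
#' @param path Path to a PDB file with at least one ATOM/HETATM record.
#' @param regroup_ester Move each nucleotide's O3' to the residue whose
#'   phosphate it bonds (default \code{TRUE}).
#' @return A \code{molecular_system}.
#' @export
read_pdb <- function(path, regroup_ester = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) {
    first <- if (length(lines) > 0) lines[1] else ""
    stop("format error: no ATOM/HETATM records; first line was: ",
         sQuote(substr(first, 1, 60)), call. = FALSE)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE,
                                     verbose = FALSE)),
    error = function(e) {
      stop("format error: unparseable PDB (", conditionMessage(e),
           "); first atom line: ",
           sQuote(substr(lines[which(is_atom)[1]], 1, 60)), call. = FALSE)
    }
  )
  at <- pdb$atom
  key <- paste(at$chain, at$resno, at$insert, trimws(at$elety), sep = "|")
  if (anyDuplicated(key)) {
    stop("structure error: duplicate atom ",
         sQuote(key[duplicated(key)][1]), " (chain|resno|insert|name)",
         call. = FALSE)
  }
  elem <- trimws(ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                        substr(trimws(at$elety), 1, 1), at$elesy))
  chain <- ifelse(is.na(at$chain) | !nzchar(at$chain), " ", at$chain)
  insert <- ifelse(is.na(at$insert), "", at$insert)
  ## residues in file order within chain; chains in order of first appearance
  rkey <- paste(chain, at$resno, insert, sep = "|")
  chain_order <- unique(chain)
  ord <- order(match(chain, chain_order), seq_len(nrow(at)))
  rkey_ordered <- unique(rkey[ord])
  res_index <- match(rkey, rkey_ordered)
  resname <- trimws(at$resid)
  role <- ifelse(resname %in% STANDARD_NUCLEOTIDES, "nucleotide", "other")
  atoms <- new_atom_table(
    serial = at$eleno, name = trimws(at$elety), elem = elem,
    x = at$x, y = at$y, z = at$z,
    chain = chain, resno = at$resno, resname = resname,
    res_index = res_index, role = role
  )
  atoms <- atoms[order(atoms$res_index, match(atoms$serial, atoms$serial)), ]
  rownames(atoms) <- NULL
  if (regroup_ester) atoms <- regroup_ester_oxygens(atoms)
  molecular_system(atoms)
}

#' Write a molecular system to a PDB file
#'
#' Fixed-width ATOM/HETATM records (coordinates to 3 decimals, element in
#' columns 77-78). Nucleotide residues are written as ATOM records, all other
#' roles as HETATM. Round-trips through \code{\link{read_pdb}} preserving
#' names, ordering and coordinates to 3 decimals.
#'
#' @param system A \code{molecular_system} with at least one atom.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_pdb <- function(system, path) {
  stopifnot(inherits(system, "molecular_system"))
  at <- system$atoms
  if (nrow(at) == 0) stop("format error: refusing to write an empty system", call. = FALSE)
  rec <- ifelse(at$role == "nucleotide", "ATOM  ", "HETATM")
  ## names shorter than 4 characters start in column 14
  nm <- ifelse(nchar(at$name) < 4, paste0(" ", at$name), at$name)
  lines <- sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, at$serial, nm, "", substr(at$resname, 1, 3), at$chain,
                   at$resno, "", at$x, at$y, at$z, 1, 0, at$elem)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Flag the chromophore residue of a system
#'
#' Marks the residue matching \code{resname} as the chromophore and every
#' standard nucleotide code as \code{"nucleotide"}. If several residues share
#' the code (e.g. one ligand copy per chain), a chain qualifier must pick one.
#'
#' @param system A \code{molecular_system}.
#' @param resname Residue code of the fluorophore (e.g. \code{"EKJ"}).
#' @param chain Optional chain identifier disambiguating multiple matches.
#' @return The system with roles updated.
#' @export
select_chromophore <- function(system, resname, chain = NULL) {
  stopifnot(inherits(system, "molecular_system"))
  hits <- which(system$residues$resname == resname)
  if (!is.null(chain)) hits <- hits[system$residues$chain[hits] == chain]
  if (length(hits) == 0) {
    stop("lookup error: no residue named ", sQuote(resname),
         if (!is.null(chain)) paste0(" in chain ", sQuote(chain)) else "",
         call. = FALSE)
  }
  if (length(hits) > 1) {
    stop("ambiguity error: ", length(hits), " residues named ",
         sQuote(resname), " (chains ",
         paste(system$residues$chain[hits], collapse = ", "),
         "); pass a chain qualifier", call. = FALSE)
  }
  target <- system$residues$res_index[hits]
  role <- ifelse(system$atoms$resname %in% STANDARD_NUCLEOTIDES,
                 "nucleotide", "other")
  role[system$atoms$res_index == target] <- "chromophore"
  atoms <- system$atoms
  atoms$role <- role
  molecular_system(atoms)
}

#' Index of the chromophore residue
#'
#' @param system A \code{molecular_system}.
#' @return The residue index flagged as chromophore.
#' @export
chromophore_index <- function(system) {
  stopifnot(inherits(system, "molecular_system"))
  m <- system$residues$res_index[system$residues$role == "chromophore"]
  if (length(m) != 1) {
    stop("role error: expected exactly one chromophore residue, found ",
         length(m), "; call select_chromophore() first", call. = FALSE)
  }
  m
}

#' Minimum inter-group atomic distance
#'
#' The closest-contact distance R_ij between two atom groups: the minimum
#' over all cross pairs of Euclidean distances, in angstrom. This is the
#' distance entering every neighbor-selection threshold.
#'
#' @param groupA,groupB Atom tables (rows of a system's \code{atoms}).
#' @return Minimum cross-pair distance in angstrom.
#' @export
min_distance <- function(groupA, groupB) {
  if (NROW(groupA) == 0 || NROW(groupB) == 0) {
    stop("argument error: min_distance() needs two non-empty atom groups",
         call. = FALSE)
  }
  a <- as.matrix(groupA[, c("x", "y", "z")])
  b <- as.matrix(groupB[, c("x", "y", "z")])
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Residues within a distance threshold of a residue
#'
#' All residues j != m whose closest-contact distance to residue \code{m} is
#' at or below \code{lambda} (closed threshold), ascending by index. Monotone
#' in \code{lambda} by construction.
#'
#' @param system A \code{molecular_system}.
#' @param m Reference residue index.
#' @param lambda Distance threshold in angstrom, >= 0.
#' @return Integer vector of residue indices.
#' @export
neighbors_within <- function(system, m, lambda) {
  stopifnot(inherits(system, "molecular_system"))
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0) {
    stop("argument error: lambda must be a single non-negative length",
         call. = FALSE)
  }
  ref <- residue_atoms(system, m)   # errors on unknown m
  others <- setdiff(system$residues$res_index, m)
  hit <- vapply(others, function(j) {
    min_distance(residue_atoms(system, j), ref) <= lambda
  }, logical(1))
  sort(others[hit])
}
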