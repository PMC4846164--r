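#' Atom topology for ensemble analysis
#'
#' A \code{Topology} records, for each atom, its identifier, mass (amu) and
#' 1-based residue index, plus optionally the atom name and element.  Residue
#' indices must be contiguous per residue (all atoms of residue r appear as one
#' block of the atom order) and every atom belongs to exactly one residue.
#'
#' @param mass numeric vector of atomic masses in amu, strictly positive.
#' @param resid integer vector of 1-based residue indices, one per atom;
#'   contiguous blocks, starting at 1, no gaps.
#' @param atom_id optional integer atom identifiers (default \code{seq_along(mass)}).
#' @param name optional character atom names (e.g. \code{"CA"}).
#' @param element optional character element symbols.
#' @return An object of class \code{"Topology"}: a list with fields
#'   \code{atom_id}, \code{mass}, \code{resid}, \code{name}, \code{element},
#'   \code{n_atoms}, \code{residue_count}.
#' @examples
#' top <- topology(mass = rep(12.011, 6), resid = rep(1:2, each = 3))
#' top$residue_count
#' @export
topology <- function(mass, resid, atom_id = seq_along(mass),
                     name = NULL, element = NULL) {
  mass <- as.numeric(mass)
  resid <- as.integer(resid)
  n <- length(mass)
  if (n < 1L) stop("topology needs at least one atom")
  if (length(resid) != n) stop("'mass' and 'resid' lengths differ")
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("atomic masses must be finite and strictly positive")
  if (any(is.na(resid)) || any(resid < 1L))
    stop("residue indices must be positive integers")
  # contiguity: each residue occupies one consecutive block, numbered 1..R
  runs <- rle(resid)$values
  if (anyDuplicated(runs))
    stop("residue blocks must be contiguous in the atom order")
  if (!identical(sort(unique(resid)), seq_len(max(resid))))
    stop("residue indices must cover 1..R without gaps")
  if (length(atom_id) != n) stop("'atom_id' length must match atom count")
  if (!is.null(name) && length(name) != n) stop("'name' length must match atom count")
  if (!is.null(element) && length(element) != n) stop("'element' length must match atom count")
  structure(list(atom_id = as.integer(atom_id), mass = mass, resid = resid,
                 name = name, element = element,
                 n_atoms = n, residue_count = max(resid)),
            class = "Topology")
}

#' @export
print.Topology <- function(x, ...) {
  cat("Topology:", x$n_atoms, "atoms in", x$residue_count, "residues; total mass",
      format(sum(x$mass), digits = 6), "amu\n")
  invisible(x)
}

#' Atom indices of one residue
#'
#' @param topology a \code{Topology}.
#' @param resid residue index (1-based).
#' @return Integer vector of atom positions belonging to the residue.
#' @export
residue_atoms <- function(topology, resid) {
  stopifnot(inherits(topology, "Topology"))
  resid <- as.integer(resid)
  if (length(resid) != 1L || is.na(resid) || resid < 1L || resid > topology$residue_count)
    stop("unknown residue index: ", resid)
  which(topology$resid == resid)
}

# 3N coordinate indices (x,y,z per atom) for a set of atom positions
coord_indices <- function(atoms) {
  as.vector(rbind(3L * atoms - 2L, 3L * atoms - 1L, 3L * atoms))
}

#' Read a topology from a PDB file
#'
#' Uses the ATOM/HETATM records of a PDB file; masses are looked up from the
#' element via \code{bio3d::atom2mass}.  Residue indices are renumbered to a
#' contiguous 1..R in order of first appearance.
#'
#' @param file path to a PDB file.
#' @return A \code{Topology}.
#' @export
read_topology_pdb <- function(file) {
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  # element symbols -> masses via bio3d's periodic table
  env <- new.env()
  utils::data("elements", package = "bio3d", envir = env)
  sym <- at$elesy
  sym[is.na(sym) | sym == ""] <- substr(trimws(at$elety[is.na(sym) | sym == ""]), 1L, 1L)
  sym <- paste0(toupper(substr(sym, 1L, 1L)), tolower(substring(sym, 2L)))
  mass <- env$elements$mass[match(sym, env$elements$symb)]
  if (anyNA(mass))
    stop("unknown element symbol(s): ", paste(unique(sym[is.na(mass)]), collapse = ", "))
  key <- paste(at$chain, at$resno, at$insert)
  resid <- match(key, unique(key))
  topology(mass = mass, resid = resid, atom_id = at$eleno,
           name = at$elety, element = sym)
}

#' Read a topology from a plain-text atom table
#'
#' Expects a whitespace- or comma-separated table with columns \code{id},
#' \code{element}, \code{mass}, \code{resid} (header required).
#'
#' @param file path to the table.
#' @return A \code{Topology}.
#' @export
read_topology_table <- function(file) {
  first <- readLines(file, n = 1L)
  tab <- if (grepl(",", first)) utils::read.csv(file) else
    utils::read.table(file, header = TRUE)
  need <- c("id", "element", "mass", "resid")
  if (!all(need %in% names(tab)))
    stop("atom table must have columns: ", paste(need, collapse = ", "))
  topology(mass = tab$mass, resid = tab$resid, atom_id = tab$id,
           element = as.character(tab$element))
}
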