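#' Build a topology object
#'
#' A topology is the static part of a molecular system: an atom table and a
#' residue table. It underpins all per-frame analyses (distance series,
#' occupancy maps, RMSD/RMSF) and carries the heavy-atom flags used for
#' ion-protein contact criteria.
#'
#' @param atoms data.frame with columns `atom_id` (integer, unique,
#'   contiguous in file order), `name` (short atom name), `element` (element
#'   symbol), `is_heavy` (logical; must equal `element != "H"`) and
#'   `residue_index` (integer key into `residues`).
#' @param residues data.frame with columns `residue_index` (integer, unique),
#'   `residue_name` (3-letter code), `chain` (string) and optionally `resid`
#'   (author numbering, e.g. PDB resSeq).
#' @return An object of class `"topology"`.
#' @export
topology <- function(atoms, residues) {
  req_a <- c("atom_id", "name", "element", "is_heavy", "residue_index")
  req_r <- c("residue_index", "residue_name", "chain")
  if (!all(req_a %in% names(atoms)))
    stop_ib("atoms must have columns: ", paste(req_a, collapse = ", "))
  if (!all(req_r %in% names(residues)))
    stop_ib("residues must have columns: ", paste(req_r, collapse = ", "))
  atoms$atom_id <- as.integer(atoms$atom_id)
  atoms$residue_index <- as.integer(atoms$residue_index)
  residues$residue_index <- as.integer(residues$residue_index)
  if (anyDuplicated(atoms$atom_id))
    stop_ib("atom_id values must be unique")
  if (!identical(atoms$atom_id, seq_len(nrow(atoms))))
    stop_ib("atom_id values must be contiguous 1..n in file order")
  if (anyDuplicated(residues$residue_index))
    stop_ib("residue_index values must be unique")
  dangling <- setdiff(atoms$residue_index, residues$residue_index)
  if (length(dangling))
    stop_ib("atoms reference missing residue_index: ",
            paste(utils::head(dangling, 5L), collapse = ", "))
  if (any(atoms$is_heavy != (toupper(atoms$element) != "H")))
    stop_ib("is_heavy flags inconsistent with element symbols")
  if (is.null(residues$resid)) residues$resid <- residues$residue_index
  structure(list(atoms = atoms, residues = residues), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("<topology> ", nrow(x$atoms), " atoms (",
      sum(x$atoms$is_heavy), " heavy), ",
      nrow(x$residues), " residues\n", sep = "")
  invisible(x)
}

#' Number of atoms in a topology or trajectory
#' @param x topology or trajectory object.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "trajectory")) x <- x$topology
  nrow(x$atoms)
}

# Infer an element symbol from a PDB atom name (fallback when the element
# column is absent). Leading digits are stripped (e.g. "1HB" -> H); two-letter
# elements common in biomolecules are recognised by prefix.
infer_element <- function(name) {
  nm <- toupper(gsub("^[0-9' ]+", "", trimws(name)))
  two <- substr(nm, 1L, 2L)
  vapply(seq_along(nm), function(i) {
    if (two[i] %in% c("CL", "NA", "MG", "ZN", "FE", "BR", "MN", "CA ")) {
      # bare ion names; CA inside a residue is an alpha-carbon, handled below
      return(substr(two[i], 1L, 2L))
    }
    substr(nm[i], 1L, 1L)
  }, character(1L))
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records into a [topology()] plus single-frame
#' coordinates. Records are pre-validated so that malformed lines are
#' reported with their line number; the actual field parsing is done by
#' \pkg{bio3d}. Elements come from the PDB element column when present,
#' otherwise from a leading-letter heuristic on the atom name; hydrogens set
#' `is_heavy = FALSE`.
#'
#' @param path path to a PDB file.
#' @return list with components `topology` and `coords` (n x 3 matrix, Angstrom).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop_ib("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  if (!any(rec)) stop_ib("no ATOM/HETATM records found in ", path)
  bad <- which(rec & nchar(lines) < 54L)
  if (length(bad))
    stop_ib("malformed ATOM/HETATM record at line ", bad[1L],
            " of ", path, " (truncated before coordinate fields)")
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  element <- toupper(trimws(at$elesy))
  missing_el <- is.na(element) | element == ""
  if (any(missing_el)) element[missing_el] <- infer_element(at$elety[missing_el])
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  res_key <- paste(chain, at$resno, at$resid, sep = "|")
  residue_index <- match(res_key, unique(res_key))
  first <- !duplicated(res_key)
  residues <- data.frame(
    residue_index = residue_index[first],
    residue_name = at$resid[first],
    chain = chain[first],
    resid = at$resno[first],
    stringsAsFactors = FALSE
  )
  atoms <- data.frame(
    atom_id = seq_len(nrow(at)),
    name = trimws(at$elety),
    element = element,
    is_heavy = element != "H",
    residue_index = residue_index,
    stringsAsFactors = FALSE
  )
  coords <- cbind(at$x, at$y, at$z)
  colnames(coords) <- c("x", "y", "z")
  list(topology = topology(atoms, residues), coords = coords)
}

#' Define an ion selection
#'
#' Selects the one or two atoms that make up a monatomic (e.g. chloride) or
#' diatomic (e.g. superoxide) ion within a topology.
#'
#' @param label ion label, e.g. `"superoxide"` or `"chloride"`.
#' @param atom_ids integer vector of length 1 or 2.
#' @param charge signed charge (units of e).
#' @param topology optional [topology()]; if given, atom ids are validated
#'   against it.
#' @return An object of class `"ion_selection"`.
#' @export
ion_selection <- function(label, atom_ids, charge = -1, topology = NULL) {
  atom_ids <- as.integer(atom_ids)
  if (!length(atom_ids) %in% 1:2)
    stop_ib("an ion has 1 or 2 atoms, got ", length(atom_ids))
  lab <- tolower(label)
  if (grepl("superoxide", lab) && length(atom_ids) != 2L)
    stop_ib("superoxide must have exactly 2 atoms")
  if (grepl("chloride", lab) && length(atom_ids) != 1L)
    stop_ib("chloride must have exactly 1 atom")
  if (!is.null(topology)) {
    missing <- setdiff(atom_ids, topology$atoms$atom_id)
    if (length(missing))
      stop_ib("ion atom ids not in topology: ", paste(missing, collapse = ", "))
  }
  structure(list(label = label, atom_ids = atom_ids, charge = charge),
            class = "ion_selection")
}

#' Define a binding site
#'
#' A binding site is a named set of residues; an ion is considered
#' site-bound when it comes within `bound_cutoff` of any heavy atom of those
#' residues (default 3 Angstrom).
#'
#' @param name site name.
#' @param residues integer vector of residue indices defining the site.
#' @param bound_cutoff bound-state distance criterion in Angstrom.
#' @param topology optional [topology()] for validation.
#' @return An object of class `"site_definition"`.
#' @export
site_definition <- function(name, residues, bound_cutoff = 3.0,
                            topology = NULL) {
  residues <- as.integer(residues)
  if (!length(residues)) stop_ib("site '", name, "' has no residues")
  check_number(bound_cutoff, "bound_cutoff", lower = 0, strict = TRUE)
  if (!is.null(topology)) {
    missing <- setdiff(residues, topology$residues$residue_index)
    if (length(missing))
      stop_ib("site '", name, "' references missing residues: ",
              paste(missing, collapse = ", "))
  }
  structure(list(name = name, residues = residues,
                 bound_cutoff = bound_cutoff),
            class = "site_definition")
}

# Heavy-atom ids belonging to a residue set.
site_heavy_atoms <- function(topology, residues) {
  a <- topology$atoms
  a$atom_id[a$is_heavy & a$residue_index %in% residues]
}
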