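#' Molecular data model for a two-protomer receptor complex
#'
#' A `dimer_complex` is a flat atom table plus light annotation, in the spirit
#' of the `bio3d` atom data frame. Each row is one atom with Cartesian
#' coordinates (Angstrom), a partial charge `q` (e) and 12-6 Lennard-Jones
#' self coefficients `lj_A` (kcal A^12/mol) and `lj_C` (kcal A^6/mol).
#' Residues are identified by `(chain, resno)`; Ballesteros-Weinstein (BW)
#' positions, where supplied, are stored per residue in the `bw` column.
#' Lipid ligands (cholesterol, palmitoyl) are flagged with `is_ligand` and a
#' `ligand_tag` such as `"CHOL_A"`, meaning the cholesterol associated with
#' protomer A.
#'
#' @param atoms data frame with at least columns `type` ("ATOM"/"HETATM"),
#'   `eleno`, `elety` (atom name), `resid` (residue name), `chain`, `resno`,
#'   `x`, `y`, `z`. Optional: `q`, `lj_A`, `lj_C`, `bw`, `is_ligand`,
#'   `ligand_tag`, `elesy` (element symbol).
#' @param chains character vector of the protomer chain identifiers, in
#'   (A, B) order. Defaults to the unique chains of the non-ligand atoms.
#' @param helix_segments optional named list, `TMH number -> c(first, last)`
#'   residue numbers (shared by both protomers).
#' @return an object of class `dimer_complex`.
#' @export
dimer_complex <- function(atoms, chains = NULL, helix_segments = NULL) {
  needed <- c("type", "eleno", "elety", "resid", "chain", "resno", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols))
    stop("atom table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!nrow(atoms)) stop("empty complex: the atom table has no rows")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in atom table")
  for (col in c("q", "lj_A", "lj_C")) if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  if (is.null(atoms$bw)) atoms$bw <- NA_character_
  if (is.null(atoms$is_ligand)) atoms$is_ligand <- FALSE
  if (is.null(atoms$ligand_tag)) atoms$ligand_tag <- NA_character_
  if (is.null(atoms$elesy)) atoms$elesy <- substr(trimws(atoms$elety), 1L, 1L)
  if (any(atoms$lj_A < 0, na.rm = TRUE) || any(atoms$lj_C < 0, na.rm = TRUE))
    stop("Lennard-Jones coefficients must be non-negative")
  if (is.null(chains)) {
    chains <- unique(atoms$chain[!atoms$is_ligand])
  }
  # BW positions must be a bijection within each protomer where defined
  for (ch in chains) {
    sub <- unique(atoms[!atoms$is_ligand & atoms$chain == ch & !is.na(atoms$bw),
                        c("resno", "bw")])
    if (anyDuplicated(sub$bw))
      stop("duplicate BW position within chain ", ch, ": ",
           paste(sub$bw[duplicated(sub$bw)], collapse = ", "))
    bad <- !grepl("^[0-9]+\\.[0-9]+$", sub$bw)
    if (any(bad))
      stop("malformed BW position(s): ", paste(sub$bw[bad], collapse = ", "))
  }
  n_chol <- length(unique(atoms$ligand_tag[grepl("^CHOL", atoms$ligand_tag)]))
  if (n_chol > 2L)
    stop("at most two cholesterol ligands are supported, found ", n_chol)
  if (!is.null(helix_segments)) {
    seg <- do.call(rbind, helix_segments)
    if (any(seg[, 1L] > seg[, 2L])) stop("helix segment bounds reversed")
    o <- order(seg[, 1L])
    if (nrow(seg) > 1L && any(seg[o, 1L][-1L] <= seg[o, 2L][-nrow(seg)]))
      stop("helix segments overlap")
  }
  structure(list(atoms = atoms, chains = chains,
                 helix_segments = helix_segments),
            class = "dimer_complex")
}

#' @export
print.dimer_complex <- function(x, ...) {
  a <- x$atoms
  cat("dimer_complex:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resno))), "residues, chains",
      paste(x$chains, collapse = "/"), "\n")
  lig <- unique(a$ligand_tag[a$is_ligand])
  if (length(lig)) cat("  ligands:", paste(lig, collapse = ", "), "\n")
  if (any(!is.na(a$q))) cat("  nonbonded parameters attached\n")
  invisible(x)
}

# Validate the fixed-width coordinate fields of ATOM/HETATM records before
# handing the file to bio3d, so a truncated or corrupt line is reported with
# its line number.
validate_pdb_lines <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54L)
      stop("PDB parse error at line ", i, ": record truncated (", nchar(ln),
           " characters, need at least 54)")
    xyz <- c(substr(ln, 31L, 38L), substr(ln, 39L, 46L), substr(ln, 47L, 54L))
    num <- suppressWarnings(as.numeric(xyz))
    if (any(is.na(num)))
      stop("PDB parse error at line ", i, ": non-numeric coordinate field")
  }
  invisible(TRUE)
}

#' Read a dimer complex from a PDB file
#'
#' Parses ATOM/HETATM records (through \pkg{bio3d}), splits chains into
#' protomers, flags ligand residues by residue name, and attaches
#' Ballesteros-Weinstein positions from a user-supplied map. No BW inference
#' is attempted: positions come only from `bw_map`.
#'
#' @param path path to a PDB file.
#' @param bw_map optional named character vector mapping residue sequence
#'   numbers (names) to BW positions (values), e.g. `c("170" = "3.55")`.
#'   Applied identically to every protomer chain.
#' @param ligand_tags named character vector mapping PDB residue names to
#'   ligand base tags; the owning chain is appended, so a `CLR` residue on
#'   chain A becomes `"CHOL_A"`. Default `c(CLR = "CHOL", PLM = "PALM")`.
#' @param helix_segments optional named list `TMH -> c(first, last)`.
#' @param palmitoyl_atoms optional data frame (`chain`, `resno`, `elety`)
#'   naming atoms that belong to a palmitoyl chain represented as extra atoms
#'   on a cysteine rather than as a separate residue; those atoms are tagged
#'   `"PALM_<chain>"` while remaining part of their residue.
#' @return a [dimer_complex].
#' @export
read_pdb <- function(path, bw_map = NULL,
                     ligand_tags = c(CLR = "CHOL", PLM = "PALM"),
                     helix_segments = NULL, palmitoyl_atoms = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  validate_pdb_lines(readLines(path, warn = FALSE))
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(type = a$type, eleno = a$eleno, elety = a$elety,
                      resid = a$resid, chain = a$chain, resno = a$resno,
                      x = a$x, y = a$y, z = a$z,
                      elesy = ifelse(is.na(a$elesy) | a$elesy == "",
                                     substr(trimws(a$elety), 1L, 1L), a$elesy),
                      stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- "A"
  atoms$is_ligand <- atoms$resid %in% names(ligand_tags)
  atoms$ligand_tag <- NA_character_
  il <- atoms$is_ligand
  atoms$ligand_tag[il] <- paste(ligand_tags[atoms$resid[il]], atoms$chain[il],
                                sep = "_")
  atoms$bw <- NA_character_
  if (!is.null(bw_map)) {
    hit <- match(as.character(atoms$resno), names(bw_map))
    atoms$bw <- ifelse(atoms$is_ligand, NA_character_,
                       unname(bw_map[hit]))
  }
  if (!is.null(palmitoyl_atoms)) {
    key <- paste(atoms$chain, atoms$resno, atoms$elety)
    pk <- paste(palmitoyl_atoms$chain, palmitoyl_atoms$resno,
                palmitoyl_atoms$elety)
    miss <- setdiff(pk, key)
    if (length(miss)) stop("palmitoyl_atoms not found in structure: ",
                           paste(miss, collapse = "; "))
    sel <- key %in% pk
    atoms$ligand_tag[sel] <- paste("PALM", atoms$chain[sel], sep = "_")
  }
  dimer_complex(atoms, helix_segments = helix_segments)
}

#' Attach nonbonded parameters to every atom of a complex
#'
#' @param complex a [dimer_complex].
#' @param params data frame with columns `residue_name`, `atom_name`,
#'   `charge_e`, `lj_A`, `lj_C`, keyed by (residue name, atom name).
#' @param default optional list with elements `charge_e`, `lj_A`, `lj_C`
#'   applied to atoms absent from `params`; without it any unmatched atom is
#'   an error listing the offending (residue, atom) pairs.
#' @return the complex with `q`, `lj_A`, `lj_C` populated.
#' @export
attach_parameters <- function(complex, params, default = NULL) {
  stopifnot(inherits(complex, "dimer_complex"))
  needed <- c("residue_name", "atom_name", "charge_e", "lj_A", "lj_C")
  if (!all(needed %in% names(params)))
    stop("parameter table needs columns: ", paste(needed, collapse = ", "))
  atoms <- complex$atoms
  key <- paste(atoms$resid, atoms$elety)
  pk <- paste(params$residue_name, params$atom_name)
  if (anyDuplicated(pk)) stop("duplicate (residue, atom) keys in parameter table")
  idx <- match(key, pk)
  unmatched <- is.na(idx)
  if (any(unmatched) && is.null(default)) {
    bad <- unique(key[unmatched])
    stop("missing nonbonded parameters (no default declared) for: ",
         paste(bad, collapse = "; "))
  }
  atoms$q <- ifelse(unmatched, default$charge_e, params$charge_e[idx])
  atoms$lj_A <- ifelse(unmatched, default$lj_A, params$lj_A[idx])
  atoms$lj_C <- ifelse(unmatched, default$lj_C, params$lj_C[idx])
  if (any(atoms$lj_A < 0) || any(atoms$lj_C < 0))
    stop("Lennard-Jones coefficients must be non-negative")
  complex$atoms <- atoms
  complex
}

#' Write a dimer complex to a PDB file
#'
#' Ligand residues are emitted as HETATM records. Coordinates are written at
#' PDB precision (3 decimals), so a read/write round trip reproduces them to
#' 3 decimals.
#'
#' @param complex a [dimer_complex].
#' @param path output file path.
#' @export
write_pdb <- function(complex, path) {
  stopifnot(inherits(complex, "dimer_complex"))
  a <- complex$atoms
  if (!nrow(a)) stop("refusing to write an empty complex")
  type <- ifelse(a$is_ligand, "HETATM", a$type)
  ok <- tryCatch({
    bio3d::write.pdb(pdb = NULL,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     type = type, eleno = a$eleno, elety = a$elety,
                     resid = a$resid, chain = a$chain, resno = a$resno,
                     elesy = a$elesy, file = path)
    TRUE
  }, error = function(e) stop("could not write PDB to ", path, ": ",
                              conditionMessage(e)))
  invisible(ok)
}

#' Atoms of one protomer
#'
#' Returns the atom rows belonging to a protomer chain, excluding ligand
#' residues and (by default) palmitoyl-tagged atoms, which the energy
#' decomposition treats separately from the protomer proper.
#'
#' @param complex a [dimer_complex].
#' @param chain chain identifier, e.g. `"A"`.
#' @param include_palmitoyl keep atoms tagged `PALM_*`? Default `FALSE`.
#' @return data frame of atom rows.
#' @export
protomer_atoms <- function(complex, chain, include_palmitoyl = FALSE) {
  a <- complex$atoms
  if (!chain %in% a$chain) stop("unknown chain: ", chain)
  sel <- a$chain == chain & !a$is_ligand
  if (!include_palmitoyl)
    sel <- sel & !(!is.na(a$ligand_tag) & grepl("^PALM", a$ligand_tag))
  a[sel, , drop = FALSE]
}

#' Atoms of a tagged ligand
#'
#' @param complex a [dimer_complex].
#' @param tag full ligand tag, e.g. `"CHOL_A"`.
#' @return data frame of atom rows (possibly empty).
#' @export
ligand_atoms <- function(complex, tag) {
  a <- complex$atoms
  a[!is.na(a$ligand_tag) & a$ligand_tag == tag, , drop = FALSE]
}

# Residue key helper: unique id per (chain, resno).
residue_key <- function(atoms) paste(atoms$chain, atoms$resno, sep = ":")

# Atoms of the residue carrying a given BW position on a chain.
residue_by_bw <- function(complex, chain, bw) {
  a <- complex$atoms
  sel <- a$chain == chain & !a$is_ligand & !is.na(a$bw) & a$bw == bw
  a[sel, , drop = FALSE]
}
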