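#' Options for the nonbonded interface-energy decomposition
#'
#' The pairwise energy between atoms i and j is
#' \deqn{E_{ij} = k q_i q_j / (\epsilon(r) r_{ij}) + A_{ij}/r_{ij}^{12} -
#'   C_{ij}/r_{ij}^6}
#' with geometric-mean combining rules \eqn{A_{ij} = \sqrt{A_{ii} A_{jj}}},
#' \eqn{C_{ij} = \sqrt{C_{ii} C_{jj}}} (the OPLS convention). In
#' distance-dependent mode the dielectric is \eqn{\epsilon(r) = r_{ij}}, the
#' same screening used by the force-field minimisations this decomposition
#' follows; a constant dielectric is switchable.
#'
#' @param residue_radius residue-selection cutoff in Angstrom: a residue of
#'   the opposite group enters the sum when its minimum any-atom distance to
#'   the anchor residue is at most this value (boundary inclusive).
#'   Default 7.0.
#' @param dielectric_mode `"distance_dependent"` (default) or `"constant"`.
#' @param dielectric_constant unitless epsilon for constant mode. Default 1.
#' @param coulomb_constant electrostatic conversion constant,
#'   kcal A / (mol e^2). Default 332.0636.
#' @return list of class `energy_options`.
#' @export
energy_options <- function(residue_radius = 7.0,
                           dielectric_mode = c("distance_dependent", "constant"),
                           dielectric_constant = 1.0,
                           coulomb_constant = 332.0636) {
  dielectric_mode <- match.arg(dielectric_mode)
  if (residue_radius <= 0) stop("residue_radius must be positive")
  structure(list(residue_radius = residue_radius,
                 dielectric_mode = dielectric_mode,
                 dielectric_constant = dielectric_constant,
                 coulomb_constant = coulomb_constant),
            class = "energy_options")
}

#' An energy term split into Coulombic and van der Waals parts
#'
#' For terms computed by this package the total is exactly
#' `coulombic + vdw`. Terms ingested from a printed table may carry a printed
#' total differing from that sum in the last rounded digit (each column is
#' rounded independently from full precision); the printed total is then
#' authoritative and propagates through sums.
#'
#' @param coulombic,vdw energies in kcal/mol.
#' @param total total energy; defaults to `coulombic + vdw`.
#' @return named numeric vector of class `energy_term` with components
#'   `coulombic`, `vdw`, `total`.
#' @export
energy_term <- function(coulombic = 0, vdw = 0, total = coulombic + vdw) {
  structure(c(coulombic = as.numeric(coulombic), vdw = as.numeric(vdw),
              total = as.numeric(total)),
            class = "energy_term")
}

#' Total of an energy term (Coulombic + VDW)
#' @param x an `energy_term`.
#' @return numeric total in kcal/mol.
#' @export
term_total <- function(x) unname(x[["total"]])

add_terms <- function(a, b) energy_term(a[["coulombic"]] + b[["coulombic"]],
                                        a[["vdw"]] + b[["vdw"]],
                                        a[["total"]] + b[["total"]])

#' Nonbonded energy of one atom pair
#'
#' @param atom_i,atom_j single atom rows (lists or one-row data frames) with
#'   `x`, `y`, `z`, `q`, `lj_A`, `lj_C`.
#' @param opts an [energy_options] object.
#' @return an [energy_term] (kcal/mol).
#' @export
pair_energy <- function(atom_i, atom_j, opts = energy_options()) {
  r <- sqrt((atom_i$x - atom_j$x)^2 + (atom_i$y - atom_j$y)^2 +
            (atom_i$z - atom_j$z)^2)
  if (r == 0) stop("coincident atoms: r_ij = 0 is a singularity")
  eps <- if (opts$dielectric_mode == "distance_dependent") r else
    opts$dielectric_constant
  coul <- opts$coulomb_constant * (atom_i$q * atom_j$q) / (eps * r)
  aij <- sqrt(atom_i$lj_A * atom_j$lj_A)
  cij <- sqrt(atom_i$lj_C * atom_j$lj_C)
  vdw <- aij / r^12 - cij / r^6
  energy_term(coul, vdw)
}

# Vectorised sum of pair energies between two atom tables. Any coincident
# atom pair is an error, matching pair_energy.
group_energy <- function(atoms_a, atoms_b, opts) {
  if (!nrow(atoms_a) || !nrow(atoms_b)) return(energy_term(0, 0))
  if (any(is.na(atoms_a$q)) || any(is.na(atoms_b$q)))
    stop("unparameterized atoms: run attach_parameters() first")
  r <- cross_dist(as.matrix(atoms_a[, c("x", "y", "z")]),
                  as.matrix(atoms_b[, c("x", "y", "z")]))
  if (any(r == 0)) stop("coincident atoms: r_ij = 0 is a singularity")
  eps <- if (opts$dielectric_mode == "distance_dependent") r else
    opts$dielectric_constant
  coul <- sum(opts$coulomb_constant * outer(atoms_a$q, atoms_b$q) / (eps * r))
  aij <- sqrt(outer(atoms_a$lj_A, atoms_b$lj_A))
  cij <- sqrt(outer(atoms_a$lj_C, atoms_b$lj_C))
  vdw <- sum(aij / r^12 - cij / r^6)
  energy_term(coul, vdw)
}

#' Residues within a cutoff radius of an anchor residue
#'
#' A pool residue is selected when its minimum any-atom-to-any-atom distance
#' to the anchor is less than or equal to `radius` (boundary inclusive).
#'
#' @param anchor atom rows of the anchor residue.
#' @param pool atom table holding candidate residues (any number).
#' @param radius cutoff in Angstrom, positive.
#' @return the rows of `pool` belonging to selected residues.
#' @export
residues_within_radius <- function(anchor, pool, radius) {
  if (radius <= 0) stop("radius must be positive")
  if (!nrow(pool)) return(pool)
  d <- cross_dist(as.matrix(anchor[, c("x", "y", "z")]),
                  as.matrix(pool[, c("x", "y", "z")]))
  dmin <- apply(d, 2L, min)
  keys <- residue_key(pool)
  keep_keys <- unique(keys[dmin <= radius])
  # whole residues enter or leave together
  res_min <- tapply(dmin, keys, min)
  keep_keys <- names(res_min)[res_min <= radius]
  pool[keys %in% keep_keys, , drop = FALSE]
}

#' Interaction energy of one residue with a protomer
#'
#' Sums [pair_energy] over all atom pairs between the residue and every
#' residue of the opposite group lying within `opts$residue_radius` of it.
#'
#' @param res atom rows of the anchor residue (parameterized).
#' @param other atom table of the opposite protomer (or any residue pool).
#' @param opts an [energy_options] object.
#' @return an [energy_term].
#' @export
residue_vs_protomer_energy <- function(res, other, opts = energy_options()) {
  sel <- residues_within_radius(res, other, opts$residue_radius)
  group_energy(res, sel, opts)
}

new_energy_decomposition <- function(rows, chol_a_vs_b, chol_b_vs_a,
                                     palm_a_vs_b = NULL, palm_b_vs_a = NULL,
                                     ingested_subtotal = NULL) {
  structure(list(rows = rows,
                 chol_a_vs_b = chol_a_vs_b,
                 chol_b_vs_a = chol_b_vs_a,
                 palm_a_vs_b = palm_a_vs_b,
                 palm_b_vs_a = palm_b_vs_a,
                 ingested_subtotal = ingested_subtotal,
                 protomer_subtotal = NULL, chol_subtotal = NULL,
                 grand_total = NULL, chol_fraction_percent = NULL),
            class = "energy_decomposition")
}

#' Residue-level decomposition of the homodimer interface energy
#'
#' Computes one row per listed interface position: the residue of protomer A
#' at that Ballesteros-Weinstein position against all residues of protomer B
#' within the cutoff radius. Rows are one-directional (A vs B); by dimer
#' symmetry this sums to the protomer-protomer interface energy, and adding
#' B-vs-A rows would double count. The cholesterol associated with each
#' protomer is evaluated against the *opposite* protomer only:
#' cholesterol-cholesterol and palmitoyl-palmitoyl pairs are never summed
#' (sterically blocked at this interface), and palmitoyl cross terms, where
#' palmitoyls are present, are computed but reported separately from -- and
#' never added to -- the grand total.
#'
#' @param complex a parameterized [dimer_complex] with two protomer chains.
#' @param interface_positions character vector of BW positions on protomer A
#'   defining the rows, e.g. `c("4.41", "4.44")`. Labels are rendered as
#'   `<aa><bw>` (e.g. `"I4.44"`).
#' @param opts an [energy_options] object.
#' @return an `energy_decomposition` with per-residue rows and cholesterol
#'   (and any palmitoyl) cross terms; run [summarize_table] to fill
#'   subtotals, the grand total and the cholesterol contribution percentage.
#' @export
decompose_interface <- function(complex, interface_positions,
                                opts = energy_options()) {
  stopifnot(inherits(complex, "dimer_complex"))
  if (length(complex$chains) < 2L)
    stop("decompose_interface needs two protomer chains")
  ch_a <- complex$chains[1L]; ch_b <- complex$chains[2L]
  prot_a <- protomer_atoms(complex, ch_a)
  prot_b <- protomer_atoms(complex, ch_b)
  rows <- data.frame(residue_label = character(0), coulombic = numeric(0),
                     vdw = numeric(0), total = numeric(0))
  for (bw in interface_positions) {
    res <- residue_by_bw(complex, ch_a, bw)
    # palmitoyl atoms grafted onto a residue stay out of the protomer rows
    res <- res[is.na(res$ligand_tag) | !grepl("^PALM", res$ligand_tag), ,
               drop = FALSE]
    if (!nrow(res))
      stop("interface position ", bw, " is missing on protomer ", ch_a)
    aa <- aa_one_letter(res$resid[1L])
    term <- residue_vs_protomer_energy(res, prot_b, opts)
    rows <- rbind(rows, data.frame(residue_label = paste0(aa, bw),
                                   coulombic = term[["coulombic"]],
                                   vdw = term[["vdw"]],
                                   total = term_total(term)))
  }
  chol_term <- function(tag, other) {
    ca <- ligand_atoms(complex, tag)
    if (!nrow(ca)) return(energy_term(0, 0))
    residue_vs_protomer_energy(ca, other, opts)
  }
  palm_term <- function(chain, other) {
    pa <- complex$atoms[!is.na(complex$atoms$ligand_tag) &
                          complex$atoms$ligand_tag == paste0("PALM_", chain), ,
                        drop = FALSE]
    if (!nrow(pa)) return(NULL)
    residue_vs_protomer_energy(pa, other, opts)
  }
  new_energy_decomposition(
    rows = rows,
    chol_a_vs_b = chol_term(paste0("CHOL_", ch_a), prot_b),
    chol_b_vs_a = chol_term(paste0("CHOL_", ch_b), prot_a),
    palm_a_vs_b = palm_term(ch_a, prot_b),
    palm_b_vs_a = palm_term(ch_b, prot_a))
}

#' Fill subtotals, grand total and cholesterol contribution of a decomposition
#'
#' Subtotals are computed in full precision from the per-residue rows, never
#' by summing rounded display values. For an ingested (printed) table the
#' transcribed subtotal is authoritative: the sum of its rounded rows may
#' legitimately differ from it by up to 0.02 kcal/mol, and when it does the
#' discrepancy is recorded in the `rounding_note` field.
#'
#' @param decomp an `energy_decomposition` with rows populated (computed or
#'   ingested).
#' @return the decomposition with `protomer_subtotal`, `chol_subtotal`,
#'   `grand_total` and `chol_fraction_percent` filled.
#' @export
summarize_table <- function(decomp) {
  stopifnot(inherits(decomp, "energy_decomposition"))
  if (!nrow(decomp$rows)) stop("no per-residue rows to summarize")
  out <- unclass(decomp)   # drop any read-only marker on ingested fixtures
  row_sum <- energy_term(sum(decomp$rows$coulombic), sum(decomp$rows$vdw))
  if (!is.null(decomp$ingested_subtotal)) {
    out$protomer_subtotal <- decomp$ingested_subtotal
    dc <- abs(row_sum[["coulombic"]] - decomp$ingested_subtotal[["coulombic"]])
    dv <- abs(row_sum[["vdw"]] - decomp$ingested_subtotal[["vdw"]])
    if (dc > 1e-9 || dv > 1e-9) {
      out$rounding_note <- sprintf(
        paste("sum of rounded rows (%.2f, %.2f) differs from the printed",
              "subtotal (%.2f, %.2f) by rounding of the display columns"),
        row_sum[["coulombic"]], row_sum[["vdw"]],
        decomp$ingested_subtotal[["coulombic"]],
        decomp$ingested_subtotal[["vdw"]])
    }
  } else {
    out$protomer_subtotal <- row_sum
  }
  out$chol_subtotal <- add_terms(decomp$chol_a_vs_b, decomp$chol_b_vs_a)
  out$grand_total <- add_terms(out$protomer_subtotal, out$chol_subtotal)
  gt <- term_total(out$grand_total)
  if (gt == 0) {
    warning("grand total is exactly zero; cholesterol fraction is undefined")
    out$chol_fraction_percent <- NaN
  } else {
    out$chol_fraction_percent <- 100 * term_total(out$chol_subtotal) / gt
  }
  structure(out, class = "energy_decomposition")
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat("Interface energy decomposition (kcal/mol)\n")
  r <- x$rows
  if (nrow(r)) {
    cat(sprintf("  %-8s %9s %9s %9s\n", "residue", "Coulombic", "VDW", "Total"))
    for (i in seq_len(nrow(r)))
      cat(sprintf("  %-8s %9.2f %9.2f %9.2f\n", r$residue_label[i],
                  r$coulombic[i], r$vdw[i], r$total[i]))
  }
  fmt_term <- function(lbl, t) cat(sprintf("  %-8s %9.2f %9.2f %9.2f\n", lbl,
                                           t[["coulombic"]], t[["vdw"]],
                                           term_total(t)))
  if (!is.null(x$protomer_subtotal)) fmt_term("Subtotal", x$protomer_subtotal)
  fmt_term("CholA~B", x$chol_a_vs_b)
  fmt_term("CholB~A", x$chol_b_vs_a)
  if (!is.null(x$chol_subtotal)) fmt_term("Subtotal", x$chol_subtotal)
  if (!is.null(x$grand_total)) fmt_term("Total", x$grand_total)
  if (!is.null(x$chol_fraction_percent))
    cat(sprintf("  cholesterol contribution: %.1f%%\n",
                x$chol_fraction_percent))
  if (!is.null(x$rounding_note)) cat("  note:", x$rounding_note, "\n")
  invisible(x)
}

# three-letter -> one-letter amino-acid codes (plus pass-through for codes
# already one letter)
aa_one_letter <- function(code) {
  tbl <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V")
  code <- toupper(code)
  out <- ifelse(nchar(code) == 1L, code, unname(tbl[code]))
  out[is.na(out)] <- "X"
  out
}
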