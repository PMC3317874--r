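#' An alpha-helical backbone defined by internal coordinates
#'
#' A `helix_conformation` stores the per-residue backbone dihedrals phi, psi
#' and omega, the N-CA-C bond angles, and Cartesian backbone coordinates
#' (N, CA, C per residue) regenerated deterministically from the internal
#' coordinates with standard bond lengths. Transmembrane helices are built by
#' default at phi = -63, psi = -41.6 degrees, the standard values for
#' membrane-embedded alpha helices.
#'
#' Bond lengths are fixed (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom), as
#' are the CA-C-N (116.2) and C-N-CA (121.7) bond angles; only the declared
#' variables (phi, psi, N-CA-C) ever move during sampling, and omega stays at
#' 180 degrees.
#'
#' @param sequence amino-acid sequence, a single string of one-letter codes
#'   (or a character vector of them). Length >= 5.
#' @param phi,psi backbone dihedrals in degrees, recycled per residue.
#' @param omega peptide-bond dihedral in degrees, default 180.
#' @param bond_angle N-CA-C bond angle in degrees, default 111.0.
#' @return object of class `helix_conformation` with elements `sequence`
#'   (character vector), `phi`, `psi`, `omega`, `bond_angles`, `coords`
#'   (3N x 3 matrix), `atom_names`, `atom_resno`.
#' @export
build_helix <- function(sequence, phi = -63, psi = -41.6, omega = 180,
                        bond_angle = 111.0) {
  seq_vec <- if (length(sequence) == 1L && nchar(sequence) > 1L)
    strsplit(sequence, "")[[1L]] else as.character(sequence)
  seq_vec <- toupper(seq_vec)
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  bad <- setdiff(unique(seq_vec), valid)
  if (length(bad)) stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  n <- length(seq_vec)
  if (n < 5L) stop("sequence must have at least 5 residues")
  h <- structure(list(sequence = seq_vec,
                      phi = wrap_angle(rep_len(phi, n)),
                      psi = wrap_angle(rep_len(psi, n)),
                      omega = wrap_angle(rep_len(omega, n)),
                      bond_angles = rep_len(bond_angle, n)),
                 class = "helix_conformation")
  rebuild_coords(h)
}

# Standard backbone geometry (Angstrom / degrees).
.bb <- list(len_n_ca = 1.458, len_ca_c = 1.525, len_c_n = 1.329,
            ang_ca_c_n = 116.2, ang_c_n_ca = 121.7)

# NeRF placement: position atom D given A-B-C, bond length |C-D|, bond angle
# B-C-D and dihedral A-B-C-D (degrees). Hot path of the sampler, so the
# vector algebra is inlined.
place_atom <- function(a, b, c, length, angle, dihedral) {
  bc <- c - b
  bc <- bc / sqrt(sum(bc * bc))
  ab <- b - a
  nv <- c(ab[2L] * bc[3L] - ab[3L] * bc[2L],
          ab[3L] * bc[1L] - ab[1L] * bc[3L],
          ab[1L] * bc[2L] - ab[2L] * bc[1L])
  nv <- nv / sqrt(sum(nv * nv))
  m <- c(nv[2L] * bc[3L] - nv[3L] * bc[2L],
         nv[3L] * bc[1L] - nv[1L] * bc[3L],
         nv[1L] * bc[2L] - nv[2L] * bc[1L])
  th <- angle * (pi / 180); ph <- dihedral * (pi / 180)
  st <- length * sin(th)
  c + (-length * cos(th)) * bc + (st * cos(ph)) * m + (st * sin(ph)) * nv
}

#' Regenerate Cartesian backbone coordinates from internal coordinates
#'
#' @param helix a `helix_conformation`.
#' @return the helix with `coords`, `atom_names`, `atom_resno` refreshed.
#' @export
rebuild_coords <- function(helix) {
  n <- length(helix$sequence)
  coords <- matrix(NA_real_, nrow = 3L * n, ncol = 3L,
                   dimnames = list(NULL, c("x", "y", "z")))
  tau1 <- deg2rad(helix$bond_angles[1L])
  # first residue in a canonical frame: CA at origin, C along +x
  coords[1L, ] <- c(.bb$len_n_ca * cos(tau1), .bb$len_n_ca * sin(tau1), 0)  # N1
  coords[2L, ] <- c(0, 0, 0)                                               # CA1
  coords[3L, ] <- c(.bb$len_ca_c, 0, 0)                                    # C1
  for (i in seq_len(n - 1L)) {
    iN <- 3L * i + 1L; iCA <- iN + 1L; iC <- iN + 2L
    pN0 <- coords[3L * i - 2L, ]; pCA0 <- coords[3L * i - 1L, ]
    pC0 <- coords[3L * i, ]
    # N_{i+1}: dihedral psi_i about N_i-CA_i-C_i
    coords[iN, ] <- place_atom(pN0, pCA0, pC0, .bb$len_c_n, .bb$ang_ca_c_n,
                               helix$psi[i])
    # CA_{i+1}: dihedral omega_i about CA_i-C_i-N_{i+1}
    coords[iCA, ] <- place_atom(pCA0, pC0, coords[iN, ], .bb$len_n_ca,
                                .bb$ang_c_n_ca, helix$omega[i])
    # C_{i+1}: dihedral phi_{i+1} about C_i-N_{i+1}-CA_{i+1}, bond angle is
    # the residue's own N-CA-C
    coords[iC, ] <- place_atom(pC0, coords[iN, ], coords[iCA, ], .bb$len_ca_c,
                               helix$bond_angles[i + 1L], helix$phi[i + 1L])
  }
  helix$coords <- coords
  helix$atom_names <- rep(c("N", "CA", "C"), n)
  helix$atom_resno <- rep(seq_len(n), each = 3L)
  helix
}

#' C-alpha coordinates of a helix
#' @param helix a `helix_conformation`, or an n x 3 matrix of C-alpha
#'   coordinates (returned unchanged).
#' @return n x 3 matrix of C-alpha positions.
#' @export
helix_ca <- function(helix) {
  if (is.matrix(helix)) return(helix)
  stopifnot(inherits(helix, "helix_conformation"))
  helix$coords[helix$atom_names == "CA", , drop = FALSE]
}

#' @export
print.helix_conformation <- function(x, ...) {
  cat("helix_conformation:", length(x$sequence), "residues (",
      paste(x$sequence[seq_len(min(8L, length(x$sequence)))], collapse = ""),
      if (length(x$sequence) > 8L) "..." else "", ")\n", sep = "")
  cat("  phi/psi (res 2):", round(x$phi[2L], 1L), "/",
      round(x$psi[2L], 1L), "deg\n")
  invisible(x)
}

#' Write helix conformations as a multi-model PDB file
#'
#' @param conformers a single `helix_conformation` or a list of them.
#' @param path output file path.
#' @export
write_conformers_pdb <- function(conformers, path) {
  if (inherits(conformers, "helix_conformation")) conformers <- list(conformers)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(conformers)) {
    h <- conformers[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    for (k in seq_len(nrow(h$coords))) {
      writeLines(sprintf(
        "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        k, paste0(" ", h$atom_names[k]), "ALA", h$atom_resno[k],
        h$coords[k, 1L], h$coords[k, 2L], h$coords[k, 3L],
        substr(h$atom_names[k], 1L, 1L)), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
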