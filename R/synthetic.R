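# Synthetic-data generators. Every generator is a pure function of its
# parameters and seed, and records its ground-truth construction parameters
# as attributes so that recovery tests can compare against them.

#' Construct an ideal helix with a rigid-body kink of known geometry
#'
#' Builds a straight transmembrane helix, then rotates the post-flex segment
#' rigidly by `bend_deg` about an in-plane axis whose azimuth is set by
#' `wobble_deg` (so that [kink_geometry] recovers the pair), optionally
#' followed by a twist of the post segment about its own axis
#' (`face_twist_deg`), which appears as face shift. Construction parameters
#' are stored in the `"ground_truth"` attribute.
#'
#' @param sequence amino-acid sequence (string or character vector).
#' @param flex_residue hinge residue number; must leave at least 5 residues
#'   before and after.
#' @param bend_deg bend angle in [0, 90] degrees.
#' @param wobble_deg wobble azimuth in (-180, 180] degrees.
#' @param seed accepted for interface uniformity; the construction is
#'   deterministic and ignores it.
#' @param face_twist_deg extra twist of the post segment about its own axis,
#'   degrees. Default 0.
#' @return a `helix_conformation` with kinked Cartesian coordinates.
#' @export
make_kinked_helix <- function(sequence, flex_residue, bend_deg, wobble_deg,
                              seed = NULL, face_twist_deg = 0) {
  if (bend_deg < 0 || bend_deg > 90) stop("bend_deg must lie in [0, 90]")
  h <- build_helix(sequence)
  n <- length(h$sequence)
  if (flex_residue < 5L || n - flex_residue < 5L)
    stop("flex residue too close to the termini (need >= 5 residues either side)")
  if (bend_deg == 0 && face_twist_deg == 0) {
    attr(h, "ground_truth") <- list(bend_deg = 0, wobble_deg = wobble_deg,
                                    face_twist_deg = 0,
                                    flex_residue = flex_residue)
    return(h)
  }
  ca <- helix_ca(h)
  fit_pre <- fit_axis(ca[1:(flex_residue - 1L), , drop = FALSE])
  a1 <- fit_pre$axis
  pivot <- ca[flex_residue, ]
  u <- vunit(axis_offset(pivot, fit_pre))
  v <- vcross(a1, u)
  # rotation axis at azimuth (wobble + 90) puts the post axis at azimuth
  # `wobble` about the pre axis
  w <- cos(deg2rad(wobble_deg + 90)) * u + sin(deg2rad(wobble_deg + 90)) * v
  R <- rotation_matrix(w, bend_deg)
  post <- h$atom_resno > flex_residue
  moved <- sweep(h$coords[post, , drop = FALSE], 2L, pivot)
  h$coords[post, ] <- sweep(moved %*% t(R), 2L, pivot, "+")
  if (face_twist_deg != 0) {
    a2 <- as.numeric(R %*% a1)
    Rt <- rotation_matrix(a2, face_twist_deg)
    moved <- sweep(h$coords[post, , drop = FALSE], 2L, pivot)
    h$coords[post, ] <- sweep(moved %*% t(Rt), 2L, pivot, "+")
  }
  attr(h, "ground_truth") <- list(bend_deg = bend_deg, wobble_deg = wobble_deg,
                                  face_twist_deg = face_twist_deg,
                                  flex_residue = flex_residue)
  h
}

#' Build a parameterized toy dimer complex
#'
#' Two parallel single-atom-per-residue protomers at a given separation,
#' optionally with a cholesterol proxy per protomer placed between them. The
#' cholesterol proxy is a small rigid group of three uncharged Lennard-Jones
#' sites, not a sterol topology: the fixture exercises the summation and
#' exclusion logic of the decomposition, not chemistry. Residues carry BW
#' positions `"1.<i>"` so they can be addressed by [decompose_interface].
#'
#' @param n_residues_per_protomer residues per protomer.
#' @param separation inter-protomer distance along x, Angstrom (> 0).
#' @param charge_scheme `"zero"`, `"alternating"` (+/- `charge`), or
#'   `"random"` (uniform in +/- `charge`, from `seed`).
#' @param charge magnitude used by the charge scheme, e. Default 0.2.
#' @param lj_scheme `"zero"` or `"uniform"`.
#' @param lj_A,lj_C uniform Lennard-Jones self coefficients for the uniform
#'   scheme.
#' @param n_cholesterol 0, 1 or 2 cholesterol proxies; with 2, exactly one is
#'   tagged per protomer.
#' @param spacing residue spacing along z, Angstrom. Default 3.8.
#' @param seed RNG seed for the random charge scheme.
#' @return a parameterized [dimer_complex]; the generator settings are kept
#'   in the `"spec"` attribute.
#' @export
make_dimer_fixture <- function(n_residues_per_protomer = 10,
                               separation = 6,
                               charge_scheme = c("zero", "alternating", "random"),
                               charge = 0.2,
                               lj_scheme = c("uniform", "zero"),
                               lj_A = 1e5, lj_C = 500,
                               n_cholesterol = 0, spacing = 3.8, seed = 1L) {
  charge_scheme <- match.arg(charge_scheme)
  lj_scheme <- match.arg(lj_scheme)
  if (separation <= 0) stop("separation must be positive")
  if (!n_cholesterol %in% 0:2) stop("n_cholesterol must be 0, 1 or 2")
  n <- n_residues_per_protomer
  set.seed(seed)
  charges_for <- function(n) switch(charge_scheme,
    zero = rep(0, n),
    alternating = charge * (-1)^(seq_len(n) - 1L),
    random = stats::runif(n, -charge, charge))
  ljA <- if (lj_scheme == "zero") 0 else lj_A
  ljC <- if (lj_scheme == "zero") 0 else lj_C
  protomer <- function(chain, x0) {
    data.frame(type = "ATOM", eleno = NA_integer_, elety = "CA",
               resid = "GLY", chain = chain, resno = seq_len(n),
               x = x0, y = 0, z = spacing * (seq_len(n) - 1L),
               q = charges_for(n), lj_A = ljA, lj_C = ljC,
               bw = paste0("1.", seq_len(n)), is_ligand = FALSE,
               ligand_tag = NA_character_)
  }
  atoms <- rbind(protomer("A", 0), protomer("B", separation))
  chol <- function(chain, xfrac, z0) {
    data.frame(type = "HETATM", eleno = NA_integer_,
               elety = c("C1", "C2", "C3"), resid = "CLR", chain = chain,
               resno = 900L, x = separation * xfrac,
               y = 2.5, z = z0 + c(-1.2, 0, 1.2),
               q = 0, lj_A = ljA, lj_C = ljC, bw = NA_character_,
               is_ligand = TRUE, ligand_tag = paste0("CHOL_", chain))
  }
  zmid <- spacing * (n - 1L) / 2
  if (n_cholesterol >= 1L) atoms <- rbind(atoms, chol("A", 0.4, zmid - 2))
  if (n_cholesterol == 2L) atoms <- rbind(atoms, chol("B", 0.6, zmid + 2))
  atoms$eleno <- seq_len(nrow(atoms))
  cx <- dimer_complex(atoms, chains = c("A", "B"))
  attr(cx, "spec") <- list(n_residues_per_protomer = n, separation = separation,
                           charge_scheme = charge_scheme, charge = charge,
                           lj_scheme = lj_scheme, lj_A = ljA, lj_C = ljC,
                           n_cholesterol = n_cholesterol, spacing = spacing,
                           seed = seed)
  cx
}

#' Generate synthetic three-channel FRET ROI tables
#'
#' Donor and acceptor intensities are drawn lognormally around
#' `intensity_scale` (strictly positive, realistic coefficient of variation);
#' the FRET-channel intensity is composed as
#' `co_a * i_cfp + co_b * i_yfp + true_nfret * sqrt(i_cfp * i_yfp)` and then
#' perturbed by mean-one multiplicative lognormal noise with coefficient of
#' variation `noise_cv`. Donor-only and acceptor-only control tables are
#' generated with the same bleed-through so the full pipeline (coefficient
#' estimation, normalization, aggregation) can run end to end. Defaults
#' emulate the wild-type receptor homodimer condition: NFRET 0.49 over 12
#' cells x 20 membrane ROIs.
#'
#' @param true_nfret ground-truth normalized net FRET. Default 0.49.
#' @param co_a,co_b true bleed-through coefficients. Defaults 0.30, 0.15.
#' @param intensity_scale median channel intensity, a.u. Default 1000.
#' @param noise_cv coefficient of variation of the multiplicative FRET-channel
#'   noise. Default 0.05.
#' @param n_cells,n_rois_per_cell experimental sampling. Defaults 12 and 20.
#' @param n_control_rois ROIs in each single-fluorophore control. Default 60.
#' @param intensity_sdlog log-sd of the channel intensities. Default 0.3.
#' @param seed integer RNG seed.
#' @return list with elements `experimental`, `donor_only`, `acceptor_only`
#'   (ROI data frames with `cell_id`, `roi_id`, `i_fret`, `i_cfp`, `i_yfp`);
#'   ground truth in the `"ground_truth"` attribute.
#' @export
make_fret_rois <- function(true_nfret = 0.49, co_a = 0.30, co_b = 0.15,
                           intensity_scale = 1000, noise_cv = 0.05,
                           n_cells = 12L, n_rois_per_cell = 20L,
                           n_control_rois = 60L, intensity_sdlog = 0.3,
                           seed = 1L) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  set.seed(seed)
  mlog <- log(intensity_scale)
  noise <- function(n) {
    if (noise_cv == 0) return(rep(1, n))
    sd2 <- log(1 + noise_cv^2)
    stats::rlnorm(n, meanlog = -sd2 / 2, sdlog = sqrt(sd2))
  }
  n_exp <- n_cells * n_rois_per_cell
  i_cfp <- stats::rlnorm(n_exp, mlog, intensity_sdlog)
  i_yfp <- stats::rlnorm(n_exp, mlog, intensity_sdlog)
  i_fret <- (co_a * i_cfp + co_b * i_yfp +
               true_nfret * sqrt(i_cfp * i_yfp)) * noise(n_exp)
  experimental <- data.frame(
    cell_id = rep(sprintf("cell%02d", seq_len(n_cells)),
                  each = n_rois_per_cell),
    roi_id = sprintf("roi%03d", seq_len(n_exp)),
    i_fret = i_fret, i_cfp = i_cfp, i_yfp = i_yfp)
  d_cfp <- stats::rlnorm(n_control_rois, mlog, intensity_sdlog)
  donor_only <- data.frame(
    cell_id = rep("donor", n_control_rois),
    roi_id = sprintf("droi%03d", seq_len(n_control_rois)),
    i_fret = co_a * d_cfp * noise(n_control_rois), i_cfp = d_cfp, i_yfp = 0)
  a_yfp <- stats::rlnorm(n_control_rois, mlog, intensity_sdlog)
  acceptor_only <- data.frame(
    cell_id = rep("acceptor", n_control_rois),
    roi_id = sprintf("aroi%03d", seq_len(n_control_rois)),
    i_fret = co_b * a_yfp * noise(n_control_rois), i_cfp = 0, i_yfp = a_yfp)
  out <- list(experimental = experimental, donor_only = donor_only,
              acceptor_only = acceptor_only)
  attr(out, "ground_truth") <- list(true_nfret = true_nfret, co_a = co_a,
                                    co_b = co_b, noise_cv = noise_cv,
                                    intensity_scale = intensity_scale,
                                    n_cells = n_cells,
                                    n_rois_per_cell = n_rois_per_cell,
                                    seed = seed)
  out
}

#' Load the packaged published interface-energy table
#'
#' Returns the transcribed per-residue interface table for the
#' cholesterol-bound receptor homodimer: 16 per-residue rows (T4.38 ... P4.59)
#' of Coulombic/VDW energies for protomer A against protomer B, plus the two
#' cholesterol cross terms (cholesterol A vs protomer B and cholesterol B vs
#' protomer A). Subtotals are not filled; [summarize_table] computes them.
#' The printed protomer subtotal travels with the object because the printed
#' per-residue rows are rounded to 2 decimals and their sum differs from the
#' full-precision subtotal by up to 0.02 kcal/mol.
#'
#' The returned object is read-only: assignments to its fields are rejected.
#'
#' @return a read-only `energy_decomposition` (rows and ligand terms
#'   populated, subtotals empty).
#' @export
load_table3_fixture <- function() {
  path <- system.file("extdata", "table3_interface_energies.tsv",
                      package = "gpcrdimer", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  prot <- tab[tab$section == "protomer", ]
  rows <- data.frame(residue_label = prot$label, coulombic = prot$coulombic,
                     vdw = prot$vdw, total = prot$total)
  term_of <- function(label) {
    r <- tab[tab$label == label, ]
    energy_term(r$coulombic, r$vdw, r$total)
  }
  d <- new_energy_decomposition(
    rows = rows,
    chol_a_vs_b = term_of("CHOL_A_vs_B"),
    chol_b_vs_a = term_of("CHOL_B_vs_A"),
    ingested_subtotal = term_of("protomer_subtotal"))
  class(d) <- c("frozen_decomposition", class(d))
  d
}

#' @export
`$<-.frozen_decomposition` <- function(x, name, value) {
  stop("this decomposition is read-only; summarize_table() returns a ",
       "modifiable copy")
}

#' @export
`[[<-.frozen_decomposition` <- function(x, i, value) {
  stop("this decomposition is read-only; summarize_table() returns a ",
       "modifiable copy")
}
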