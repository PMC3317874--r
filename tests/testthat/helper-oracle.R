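# Independent brute-force reference implementations used as oracles. These
# deliberately use plain double loops and the literal pair formula, sharing
# no code with the package's vectorised path.

COULOMB_K <- 332.0636

naive_pair_terms <- function(a1, a2, dielectric = "distance") {
  r <- sqrt((a1$x - a2$x)^2 + (a1$y - a2$y)^2 + (a1$z - a2$z)^2)
  eps <- if (dielectric == "distance") r else 1
  coul <- COULOMB_K * a1$q * a2$q / (eps * r)
  vdw <- sqrt(a1$lj_A * a2$lj_A) / r^12 - sqrt(a1$lj_C * a2$lj_C) / r^6
  c(coul, vdw)
}

naive_min_dist <- function(atoms1, atoms2) {
  best <- Inf
  for (i in seq_len(nrow(atoms1))) for (j in seq_len(nrow(atoms2))) {
    d <- sqrt((atoms1$x[i] - atoms2$x[j])^2 + (atoms1$y[i] - atoms2$y[j])^2 +
              (atoms1$z[i] - atoms2$z[j])^2)
    if (d < best) best <- d
  }
  best
}

# anchor (atom rows) vs a pool of residues with the radius rule, all pairs
naive_group_energy <- function(anchor, pool, radius = 7.0) {
  coul <- 0; vdw <- 0
  for (key in unique(paste(pool$chain, pool$resno))) {
    res <- pool[paste(pool$chain, pool$resno) == key, , drop = FALSE]
    if (naive_min_dist(anchor, res) > radius) next
    for (i in seq_len(nrow(anchor))) for (j in seq_len(nrow(res))) {
      t <- naive_pair_terms(anchor[i, ], res[j, ])
      coul <- coul + t[1L]; vdw <- vdw + t[2L]
    }
  }
  c(coulombic = coul, vdw = vdw)
}

# full interface decomposition of a toy dimer complex, the slow way
naive_decompose <- function(cx, positions, radius = 7.0) {
  a <- cx$atoms
  prot <- function(ch) a[a$chain == ch & !a$is_ligand, , drop = FALSE]
  pa <- prot("A"); pb <- prot("B")
  rows <- t(vapply(positions, function(bw) {
    anchor <- pa[!is.na(pa$bw) & pa$bw == bw, , drop = FALSE]
    naive_group_energy(anchor, pb, radius)
  }, numeric(2L)))
  lig <- function(tag) a[!is.na(a$ligand_tag) & a$ligand_tag == tag, ,
                         drop = FALSE]
  chol_ab <- if (nrow(lig("CHOL_A"))) naive_group_energy(lig("CHOL_A"), pb, radius)
             else c(coulombic = 0, vdw = 0)
  chol_ba <- if (nrow(lig("CHOL_B"))) naive_group_energy(lig("CHOL_B"), pa, radius)
             else c(coulombic = 0, vdw = 0)
  list(rows = rows, chol_a_vs_b = chol_ab, chol_b_vs_a = chol_ba,
       grand_total = sum(rows) + sum(chol_ab) + sum(chol_ba))
}

# quick single-atom helper for pair_energy tests
atom1 <- function(x = 0, y = 0, z = 0, q = 0, A = 0, C = 0) {
  list(x = x, y = y, z = z, q = q, lj_A = A, lj_C = C)
}

# small ROI table builder
roi_table <- function(i_fret, i_cfp, i_yfp, cell_id = "c1") {
  data.frame(cell_id = cell_id, i_fret = i_fret, i_cfp = i_cfp, i_yfp = i_yfp)
}
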