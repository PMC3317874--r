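test_that("pair_energy matches closed forms and is exactly symmetric", {
  opts <- energy_options()
  # null parameters -> exactly zero
  z <- pair_energy(atom1(), atom1(x = 3), opts)
  expect_identical(unname(z[c("coulombic", "vdw")]), c(0, 0))
  # LJ minimum: at r = (2A/C)^(1/6) the well depth is -C^2/(4A)
  A <- 1.0e6; C <- 1.0e3
  r_star <- (2 * A / C)^(1 / 6)
  e <- pair_energy(atom1(A = A, C = C), atom1(x = r_star, A = A, C = C), opts)
  expect_equal(e[["vdw"]], -C^2 / (4 * A), tolerance = 1e-9)
  expect_equal(e[["coulombic"]], 0)
  # Coulomb hand arithmetic: unit charges, constant eps = 1, r = k/100
  co <- energy_options(dielectric_mode = "constant")
  e2 <- pair_energy(atom1(q = 1), atom1(x = 3.320636, q = 1), co)
  expect_equal(e2[["coulombic"]], 100.0, tolerance = 1e-9)
  # distance-dependent dielectric divides by r twice
  e3 <- pair_energy(atom1(q = 1), atom1(x = 2, q = 1), opts)
  expect_equal(e3[["coulombic"]], 332.0636 / 4, tolerance = 1e-12)
  # symmetry is exact
  set.seed(11)
  for (k in 1:5) {
    ai <- atom1(runif(1), runif(1), runif(1), q = runif(1, -1, 1),
                A = runif(1, 0, 1e6), C = runif(1, 0, 1e3))
    aj <- atom1(2 + runif(1), runif(1), runif(1), q = runif(1, -1, 1),
                A = runif(1, 0, 1e6), C = runif(1, 0, 1e3))
    expect_identical(pair_energy(ai, aj, opts), pair_energy(aj, ai, opts))
  }
  expect_error(pair_energy(atom1(), atom1(), opts), "singular")
})

test_that("the LJ curve is minimised at (2A/C)^(1/6) and vanishes at range", {
  A <- 1.0e6; C <- 1.0e3
  r_star <- (2 * A / C)^(1 / 6)
  vdw_at <- function(r) pair_energy(atom1(A = A, C = C),
                                    atom1(x = r, A = A, C = C))[["vdw"]]
  rs <- seq(2.5, 12, by = 0.01)
  vals <- vapply(rs, vdw_at, numeric(1))
  expect_equal(rs[which.min(vals)], r_star, tolerance = 1e-2)
  expect_true(all(diff(vals[rs > r_star + 0.01]) > 0))  # monotone rise past r*
  expect_lt(abs(vdw_at(100)), 1e-9)
})

test_that("residue selection radius is inclusive at the boundary", {
  res_at <- function(x, resno) data.frame(type = "ATOM", eleno = 1, elety = "CA",
                                          resid = "GLY", chain = "B",
                                          resno = resno, x = x, y = 0, z = 0,
                                          q = 0, lj_A = 0, lj_C = 0)
  anchor <- res_at(0, 1)
  expect_equal(nrow(residues_within_radius(anchor, res_at(7.0, 2), 7.0)), 1L)
  expect_equal(nrow(residues_within_radius(anchor, res_at(7.01, 2), 7.0)), 0L)
  expect_equal(nrow(residues_within_radius(anchor, res_at(7, 2)[0, ], 7.0)), 0L)
  expect_error(residues_within_radius(anchor, res_at(1, 2), 0))
})

test_that("radius selection agrees with a brute-force double loop", {
  set.seed(42)
  pool <- do.call(rbind, lapply(1:50, function(i) {
    n_at <- sample(1:3, 1)
    data.frame(type = "ATOM", eleno = i, elety = paste0("C", seq_len(n_at)),
               resid = "GLY", chain = "B", resno = i,
               x = runif(n_at, -20, 20), y = runif(n_at, -20, 20),
               z = runif(n_at, -20, 20), q = 0, lj_A = 0, lj_C = 0)
  }))
  anchor <- data.frame(type = "ATOM", eleno = 0, elety = "CA", resid = "GLY",
                       chain = "A", resno = 0, x = 0, y = 0, z = 0,
                       q = 0, lj_A = 0, lj_C = 0)
  got <- residues_within_radius(anchor, pool, 7.0)
  want <- vapply(split(pool, pool$resno),
                 function(res) naive_min_dist(anchor, res) <= 7.0, logical(1))
  expect_setequal(unique(got$resno), as.integer(names(want))[want])
})

test_that("one-atom residue against a one-atom protomer reduces to pair_energy", {
  a <- data.frame(type = "ATOM", eleno = 1, elety = "CA", resid = "GLY",
                  chain = "A", resno = 1, x = 0, y = 0, z = 0,
                  q = 0.5, lj_A = 1e5, lj_C = 500)
  b <- a; b$chain <- "B"; b$x <- 4; b$q <- -0.5
  opts <- energy_options()
  expect_equal(residue_vs_protomer_energy(a, b, opts),
               pair_energy(as.list(a), as.list(b), opts))
})

test_that("decompose_interface matches the naive all-pairs oracle on toy dimers", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(5:12, 1)
    cx <- make_dimer_fixture(n_residues_per_protomer = n,
                             separation = runif(1, 4.5, 8),
                             charge_scheme = "random",
                             n_cholesterol = sample(0:2, 1), seed = seed)
    pos <- paste0("1.", seq_len(n))
    got <- suppressWarnings(summarize_table(decompose_interface(cx, pos)))
    want <- naive_decompose(cx, pos)
    expect_equal(got$rows$coulombic, unname(want$rows[, "coulombic"]),
                 tolerance = 1e-9)
    expect_equal(got$rows$vdw, unname(want$rows[, "vdw"]), tolerance = 1e-9)
    expect_equal(got$chol_a_vs_b[["coulombic"]],
                 unname(want$chol_a_vs_b["coulombic"]), tolerance = 1e-9)
    expect_equal(got$chol_b_vs_a[["vdw"]], unname(want$chol_b_vs_a["vdw"]),
                 tolerance = 1e-9)
    expect_equal(term_total(got$grand_total), want$grand_total,
                 tolerance = 1e-9)
  }
})

test_that("summation invariants hold in full precision on computed tables", {
  cx <- make_dimer_fixture(n_residues_per_protomer = 8, separation = 5.5,
                           charge_scheme = "alternating", n_cholesterol = 2,
                           seed = 3)
  d <- summarize_table(decompose_interface(cx, paste0("1.", 1:8)))
  expect_equal(d$protomer_subtotal[["coulombic"]], sum(d$rows$coulombic))
  expect_equal(d$protomer_subtotal[["vdw"]], sum(d$rows$vdw))
  expect_equal(unname(d$chol_subtotal),
               unname(d$chol_a_vs_b + d$chol_b_vs_a))
  expect_equal(term_total(d$grand_total),
               term_total(d$protomer_subtotal) + term_total(d$chol_subtotal))
  expect_equal(d$chol_fraction_percent,
               100 * term_total(d$chol_subtotal) / term_total(d$grand_total))
  # with zero charges the Coulombic column is identically zero
  cz <- make_dimer_fixture(n_residues_per_protomer = 8, separation = 5.5,
                           charge_scheme = "zero", n_cholesterol = 2, seed = 3)
  dz <- summarize_table(decompose_interface(cz, paste0("1.", 1:8)))
  expect_true(all(dz$rows$coulombic == 0))
  expect_equal(dz$grand_total[["coulombic"]], 0)
})

test_that("degenerate summaries: all-zero table and single-row table", {
  cx <- make_dimer_fixture(n_residues_per_protomer = 4, lj_scheme = "zero",
                           charge_scheme = "zero", n_cholesterol = 1)
  d <- decompose_interface(cx, paste0("1.", 1:4))
  expect_warning(s <- summarize_table(d), "undefined")
  expect_true(is.nan(s$chol_fraction_percent))
  expect_true(all(s$rows$total == 0))
  # single row (1,1), zero ligand terms
  one <- gpcrdimer:::new_energy_decomposition(
    rows = data.frame(residue_label = "G1.1", coulombic = 1, vdw = 1,
                      total = 2),
    chol_a_vs_b = energy_term(0, 0), chol_b_vs_a = energy_term(0, 0))
  s1 <- summarize_table(one)
  expect_equal(unname(s1$protomer_subtotal), c(1, 1, 2))
  expect_equal(term_total(s1$grand_total), 2)
  expect_equal(s1$chol_fraction_percent, 0)
})

test_that("a listed interface position missing on protomer A is a named error", {
  cx <- make_dimer_fixture(n_residues_per_protomer = 3)
  expect_error(decompose_interface(cx, c("1.1", "4.44")), "4\\.44")
})

test_that("unparameterized atoms are refused", {
  cx <- make_dimer_fixture(n_residues_per_protomer = 3)
  cx$atoms$q <- NA_real_
  expect_error(decompose_interface(cx, "1.1"), "unparameterized|attach_parameters")
})
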