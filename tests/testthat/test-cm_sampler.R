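# Helpers: compact schedules and single-variable toys so the Monte-Carlo
# properties can be checked at desk scale.

one_var_set <- function(helix, kind = "psi", resno = 5L, center = 0,
                        halfwidth = 50) {
  structure(data.frame(var_id = paste(kind, resno, sep = "_"), resno = resno,
                       kind = kind, center = center, halfwidth = halfwidth),
            class = c("variable_set", "data.frame"))
}

flat_model <- energy_model("custom", fn = function(h) 0)

test_that("build_helix produces a canonical transmembrane helix, deterministically", {
  h <- build_helix(strrep("A", 20))
  ca <- helix_ca(h)
  fit <- fit_axis(ca)
  rise <- mean(diff(ca %*% fit$axis))
  expect_equal(rise, 1.5, tolerance = 0.1 / 1.5)
  expect_identical(h$coords, build_helix(strrep("A", 20))$coords)
  expect_error(build_helix("AX"), "X")
  expect_error(build_helix("AAAA"), "at least 5")
})

test_that("Metropolis criterion matches its closed forms", {
  expect_true(metropolis_accept(-5, 310))
  expect_true(metropolis_accept(0, 310))
  expect_error(metropolis_accept(NaN, 310), "non-finite")
  expect_error(metropolis_accept(1, 0), "positive")
  # at dE = kB T ln 2 the acceptance probability is exactly 1/2
  set.seed(99)
  de <- kB * 310 * log(2)
  acc <- mean(vapply(1:1e5, function(i) metropolis_accept(de, 310), logical(1)))
  expect_equal(acc, 0.5, tolerance = 0.01 / 0.5)
  # dE = 100 kcal/mol at 310 K: acceptance ~ e^-162, never accepted
  rej <- vapply(1:1e5, function(i) metropolis_accept(100, 310), logical(1))
  expect_false(any(rej))
  # effectively infinite temperature accepts any bounded uphill move
  hot <- vapply(1:1e3, function(i) metropolis_accept(100, 1e9), logical(1))
  expect_true(all(hot))
})

test_that("seeded exploratory runs are bit-reproducible and seeds matter", {
  h <- build_helix(strrep("A", 8))
  vars <- variable_set(h)
  sched <- cm_schedule(steps_per_variable = 60)
  m1 <- exploratory_phase(h, vars, sched, flat_model, seed = 5)
  m2 <- exploratory_phase(h, vars, sched, flat_model, seed = 5)
  expect_identical(m1$counts, m2$counts)
  expect_identical(m1$populated_310K, m2$populated_310K)
  m3 <- exploratory_phase(h, vars, sched, flat_model, seed = 6)
  expect_false(identical(m1$counts, m3$counts))
})

test_that("flat-energy sampling covers the window and is uniform over bins", {
  h <- build_helix(strrep("A", 8))
  vars <- one_var_set(h)                       # one psi, +/- 50 degrees
  sched <- cm_schedule(steps_per_variable = 3e4)  # 1e4 composite steps/stage
  mem <- exploratory_phase(h, vars, sched, flat_model, seed = 12)
  nb <- mem$bins[[1]]$nbins
  occupied <- mem$populated_310K[[1]]
  expect_gte(length(occupied) / nb, 0.95)
  # on a flat surface every proposal is accepted: uniform over the window
  counts <- mem$counts[[1]][length(mem$temps), ]
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("a harmonic well concentrates the 310 K memory around its minimum", {
  h <- build_helix(strrep("A", 8))
  vars <- one_var_set(h)
  well <- energy_model("custom", fn = function(hh) 0.02 * (hh$psi[5] - 20)^2)
  sched <- cm_schedule(steps_per_variable = 3e4)
  mem <- exploratory_phase(h, vars, sched, well, seed = 21)
  b <- mem$bins[[1]]
  counts <- mem$counts[[1]][length(mem$temps), ]
  mids <- b$lo + (seq_len(b$nbins) - 0.5) * b$width
  mean_accepted <- sum(mids * counts) / sum(counts)
  expect_lt(abs(mean_accepted - 20), 5)
})

test_that("acceptance ratio does not rise as the ladder cools a rugged surface", {
  h <- build_helix(strrep("A", 8))
  vars <- one_var_set(h)
  rugged <- energy_model("custom",
                         fn = function(hh) 2.5 * sin(hh$psi[5] / 3)^2 +
                           1.5 * cos(hh$psi[5] / 1.1))
  sched <- cm_schedule(steps_per_variable = 1500)
  hot_minus_cold <- vapply(1:10, function(s) {
    mem <- exploratory_phase(h, vars, sched, rugged, seed = s)
    mem$accept_ratio[1] - mem$accept_ratio[length(mem$accept_ratio)]
  }, numeric(1))
  expect_gt(mean(hot_minus_cold), 0)
  expect_gte(sum(hot_minus_cold >= 0), 8)
})

test_that("biased annealing stays inside populated space and emits n_output structures", {
  h <- build_helix(strrep("A", 8))
  vars <- variable_set(h)
  sched <- cm_schedule(steps_per_variable = 45)
  mem <- exploratory_phase(h, vars, sched, flat_model, seed = 31)
  ens <- biased_annealing(h, mem, sched, flat_model, seed = 32)
  expect_length(ens$conformers, 105L)        # the published output count
  expect_gt(ens$proposals_total, 0L)
  expect_identical(ens$proposals_outside, 0L)
})

test_that("degenerate memory (one bin per variable) pins every output", {
  h <- build_helix(strrep("A", 8))
  vars <- variable_set(h)
  sched <- cm_schedule(steps_per_variable = 45, n_output = 20)
  mem <- exploratory_phase(h, vars, sched, flat_model, seed = 41)
  for (v in seq_along(mem$populated_310K))
    mem$populated_310K[[v]] <- mem$populated_310K[[v]][1]
  ens <- biased_annealing(h, mem, sched, flat_model, seed = 42)
  for (kind in c("phi", "psi")) {
    vals <- sapply(ens$conformers, function(cf) cf[[kind]][4])
    expect_lte(diff(range(vals)), 5)  # torsion bin width
  }
  bvals <- sapply(ens$conformers, function(cf) cf$bond_angles[4])
  expect_lte(diff(range(bvals)), 2)   # bond-angle bin width
})

test_that("a variable with no populated space is a named error in the biased phase", {
  h <- build_helix(strrep("A", 8))
  vars <- variable_set(h)
  sched <- cm_schedule(steps_per_variable = 45)
  mem <- exploratory_phase(h, vars, sched, flat_model, seed = 51)
  mem$populated_310K[[which(mem$vars$var_id == "psi_3")]] <- integer(0)
  expect_error(biased_annealing(h, mem, sched, flat_model, seed = 52), "psi_3")
})

test_that("the default schedule carries the published constants", {
  sched <- cm_schedule()
  expect_equal(sched$t_initial, 3000)
  expect_equal(sched$steps_per_variable, 50000)
  expect_equal(sched$cooling_steps_exploratory, 18)
  expect_equal(sched$t_final, 310)
  expect_equal(sched$t_biased_start, 749.4)
  expect_equal(sched$cooling_steps_biased, 7)
  expect_equal(sched$n_output, 105)
  expect_error(cm_schedule(t_final = 4000))
})

test_that("variable windows follow the sampling protocol defaults", {
  h <- build_helix(strrep("A", 12))
  vars <- variable_set(h, flexible_region = 5:9)
  expect_equal(unique(vars$halfwidth[vars$kind == "bond"]), 8)
  tor <- vars[vars$kind != "bond", ]
  expect_equal(unique(tor$halfwidth[tor$resno %in% 5:9]), 50)
  expect_equal(unique(tor$halfwidth[!tor$resno %in% 5:9]), 10)
})

test_that("select_fitting_conformer returns the first non-clashing candidate", {
  h <- build_helix(strrep("A", 10))
  far <- h; far$coords <- h$coords + 100     # planted fit, far from the bundle
  bundle <- h$coords                          # a bundle right on top of h
  # empty bundle: first candidate wins trivially
  sel0 <- select_fitting_conformer(list(h, far), NULL)
  expect_true(sel0$found); expect_equal(sel0$index, 1L)
  # candidates 1 clashes, candidate 2 fits
  sel <- select_fitting_conformer(list(h, far), bundle, clash_cutoff = 2.5)
  expect_true(sel$found); expect_equal(sel$index, 2L)
  # a huge cutoff rejects everything: reported, not an error
  selN <- select_fitting_conformer(list(h, far), bundle, clash_cutoff = 1e4)
  expect_false(selN$found)
  expect_true(is.na(selN$index))
  expect_error(select_fitting_conformer(list(), bundle), "no candidate")
})
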