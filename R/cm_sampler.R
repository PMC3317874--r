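# Two-phase Conformational Memories (CM) Monte-Carlo/simulated-annealing
# sampler for single transmembrane helices. The exploratory phase maps the
# accepted ("populated") torsion/bond-angle space as a function of
# temperature; the biased annealing phase re-anneals with proposals
# restricted to the space populated at physiological temperature.

#' Boltzmann constant in kcal/(mol K)
#' @export
kB <- 0.0019872

#' Variable set for CM sampling
#'
#' Declares which internal coordinates of a helix may move and by how much.
#' Every phi (residues 2..n) and psi (residues 1..n-1) torsion varies within
#' +/- 10 degrees of its start value by default, widened to +/- 50 degrees
#' inside a declared flexible region (the neighbourhood of helix-bending
#' residues such as prolines, glycines, serines and threonines); every
#' N-CA-C bond angle varies within +/- 8 degrees.
#'
#' @param helix a `helix_conformation`.
#' @param flexible_region optional integer vector of residue numbers whose
#'   torsions get the wide window.
#' @param torsion_halfwidth half-width for torsions, degrees. Default 10.
#' @param flex_halfwidth half-width inside the flexible region. Default 50.
#' @param bond_halfwidth half-width for bond angles. Default 8.
#' @return data frame of class `variable_set` with columns `var_id`, `resno`,
#'   `kind` ("phi"/"psi"/"bond"), `center`, `halfwidth`.
#' @export
variable_set <- function(helix, flexible_region = NULL,
                         torsion_halfwidth = 10, flex_halfwidth = 50,
                         bond_halfwidth = 8) {
  stopifnot(inherits(helix, "helix_conformation"))
  n <- length(helix$sequence)
  vars <- rbind(
    data.frame(resno = 2:n, kind = "phi", center = helix$phi[2:n],
               halfwidth = torsion_halfwidth),
    data.frame(resno = 1:(n - 1L), kind = "psi", center = helix$psi[1:(n - 1L)],
               halfwidth = torsion_halfwidth),
    data.frame(resno = 1:n, kind = "bond", center = helix$bond_angles,
               halfwidth = bond_halfwidth))
  if (!is.null(flexible_region)) {
    wide <- vars$kind %in% c("phi", "psi") & vars$resno %in% flexible_region
    vars$halfwidth[wide] <- flex_halfwidth
  }
  vars$var_id <- paste(vars$kind, vars$resno, sep = "_")
  rownames(vars) <- NULL
  structure(vars[, c("var_id", "resno", "kind", "center", "halfwidth")],
            class = c("variable_set", "data.frame"))
}

#' CM temperature schedule
#'
#' Geometric cooling ladders, endpoints inclusive: the exploratory phase
#' cools `t_initial` to `t_final` in `cooling_steps_exploratory` stages; the
#' biased phase cools `t_biased_start` to `t_final` in `cooling_steps_biased`
#' stages and emits `n_output` structures at the final temperature.
#'
#' @param t_initial exploratory start temperature, K. Default 3000.
#' @param steps_per_variable Monte-Carlo trial moves applied to each variable
#'   at each temperature. Default 50000. Each composite step varies two
#'   dihedrals and one bond angle, so a stage runs
#'   `steps_per_variable * n_vars / 3` composite steps (times the
#'   desk-scale multiplier of the sampling functions).
#' @param cooling_steps_exploratory number of exploratory stages. Default 18.
#' @param t_final final temperature, K. Default 310.
#' @param t_biased_start biased-phase start temperature, K. Default 749.4.
#' @param cooling_steps_biased number of biased stages. Default 7.
#' @param n_output structures emitted at the final temperature. Default 105.
#' @param cooling_law only `"geometric"` is provided.
#' @return list of class `cm_schedule`.
#' @export
cm_schedule <- function(t_initial = 3000, steps_per_variable = 50000,
                        cooling_steps_exploratory = 18, t_final = 310,
                        t_biased_start = 749.4, cooling_steps_biased = 7,
                        n_output = 105, cooling_law = "geometric") {
  if (!(t_initial > t_biased_start && t_biased_start > t_final && t_final > 0))
    stop("need t_initial > t_biased_start > t_final > 0")
  cooling_law <- match.arg(cooling_law, "geometric")
  structure(list(t_initial = t_initial, steps_per_variable = steps_per_variable,
                 cooling_steps_exploratory = cooling_steps_exploratory,
                 t_final = t_final, t_biased_start = t_biased_start,
                 cooling_steps_biased = cooling_steps_biased,
                 n_output = n_output, cooling_law = cooling_law),
            class = "cm_schedule")
}

# Geometric ladder hitting both endpoints exactly.
cooling_ladder <- function(t_hi, t_lo, k) {
  if (k == 1L) return(t_lo)
  t_hi * (t_lo / t_hi)^((seq_len(k) - 1) / (k - 1))
}

#' Energy model for CM sampling
#'
#' The default objective is the helix's own intra-molecular nonbonded energy:
#' the same 12-6 Lennard-Jones (plus optional Coulomb) pair function used by
#' the interface decomposition, evaluated over backbone atoms with 1-2 and
#' 1-3 pairs excluded and 1-4 pairs scaled by 0.5. Any custom objective can
#' be plugged in as a function of the helix conformation.
#'
#' @param mode `"intra_nonbonded"` (default) or `"custom"`.
#' @param fn for custom mode, `function(helix) -> energy (kcal/mol)`. Custom
#'   objectives that do not use Cartesian coordinates should leave
#'   `needs_coords = FALSE` so the sampler can skip coordinate rebuilds.
#' @param scale_14 scaling of 1-4 nonbonded pairs. Default 0.5.
#' @param lj_A,lj_C uniform per-atom Lennard-Jones self coefficients for the
#'   backbone sites (kcal A^12/mol, kcal A^6/mol).
#' @param needs_coords does the objective read `helix$coords`?
#' @return list of class `cm_energy_model` with elements `fn`, `needs_coords`.
#' @export
energy_model <- function(mode = c("intra_nonbonded", "custom"), fn = NULL,
                         scale_14 = 0.5, lj_A = 2.75e5, lj_C = 425,
                         needs_coords = NULL) {
  mode <- match.arg(mode)
  if (mode == "custom") {
    if (!is.function(fn)) stop("custom mode needs fn(helix) -> energy")
    return(structure(list(fn = fn,
                          needs_coords = isTRUE(needs_coords)),
                     class = "cm_energy_model"))
  }
  cache <- new.env(parent = emptyenv())
  nb_fn <- function(helix) {
    xyz <- helix$coords
    n <- nrow(xyz)
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      sep <- abs(outer(seq_len(n), seq_len(n), "-"))
      w <- matrix(1, n, n)
      w[sep <= 2L] <- 0          # self, 1-2, 1-3 excluded
      w[sep == 3L] <- scale_14   # 1-4 scaled
      w[lower.tri(w, diag = TRUE)] <- 0
      cache[[key]] <- w
    }
    w <- cache[[key]]
    r <- cross_dist(xyz, xyz)
    r[r == 0] <- Inf
    sum(w * (lj_A / r^12 - lj_C / r^6))
  }
  structure(list(fn = nb_fn, needs_coords = TRUE), class = "cm_energy_model")
}

#' Metropolis acceptance decision
#'
#' Accepts with probability `min(1, exp(-delta_e / (kB * temperature)))`.
#' Uses the session RNG stream, so seeded runs are reproducible.
#'
#' @param delta_e energy change of the trial move, kcal/mol.
#' @param temperature temperature in kelvin, positive.
#' @return logical: accept the move?
#' @export
metropolis_accept <- function(delta_e, temperature) {
  if (!is.finite(delta_e)) stop("non-finite energy change")
  if (temperature <= 0) stop("temperature must be positive")
  if (delta_e <= 0) return(TRUE)
  stats::runif(1L) < exp(-delta_e / (kB * temperature))
}

# write a variable-state vector back into a helix
apply_variables <- function(helix, vars, values) {
  for (kind in c("phi", "psi")) {
    k <- vars$kind == kind
    if (any(k)) helix[[kind]][vars$resno[k]] <- wrap_angle(values[k])
  }
  k <- vars$kind == "bond"
  if (any(k)) helix$bond_angles[vars$resno[k]] <- values[k]
  helix
}

memory_bins <- function(vars, bin_width_torsion, bin_width_bond) {
  lapply(seq_len(nrow(vars)), function(i) {
    w <- if (vars$kind[i] == "bond") bin_width_bond else bin_width_torsion
    lo <- vars$center[i] - vars$halfwidth[i]
    hi <- vars$center[i] + vars$halfwidth[i]
    nb <- as.integer(max(1, ceiling((hi - lo) / w - 1e-9)))
    list(lo = lo, hi = hi, width = (hi - lo) / nb, nbins = nb)
  })
}

bin_index <- function(value, binspec) {
  b <- floor((value - binspec$lo) / binspec$width) + 1L
  min(max(b, 1L), binspec$nbins)
}

# pick indices of the variables moved in one composite step: two dihedrals
# and one bond angle chosen at random from the variable set (fewer when a
# kind has fewer members).
pick_move_set <- function(torsion_idx, bond_idx) {
  moved <- integer(0)
  if (length(torsion_idx))
    moved <- torsion_idx[sample.int(length(torsion_idx),
                                    min(2L, length(torsion_idx)))]
  if (length(bond_idx))
    moved <- c(moved, bond_idx[sample.int(length(bond_idx), 1L)])
  moved
}

#' Exploratory phase of a CM run
#'
#' Cools from `sched$t_initial` to `sched$t_final` over
#' `sched$cooling_steps_exploratory` geometric stages. At every stage each
#' composite step varies two dihedral angles and one bond angle chosen at
#' random, proposes fresh values uniformly within each variable's window, and
#' accepts or rejects by the Metropolis criterion. Accepted values are binned
#' into per-variable, per-temperature memories; the occupied bins at the
#' final (310 K) stage become the populated space consumed by
#' [biased_annealing].
#'
#' @param helix starting `helix_conformation`.
#' @param vars a [variable_set] (one row per variable; at least one row).
#' @param sched a [cm_schedule].
#' @param model a [energy_model].
#' @param seed integer RNG seed.
#' @param scale desk-scale multiplier on `steps_per_variable` (1 runs the
#'   full published schedule).
#' @param bin_width_torsion,bin_width_bond memory bin widths in degrees.
#'   Defaults 5 and 2.
#' @return object of class `angle_memory`: the variable table, the
#'   temperature ladder, per-variable bin specs and stage-by-bin counts, the
#'   `populated_310K` occupied-bin list (variables whose 310 K memory is
#'   empty fall back to the full window and are listed in `fallback_vars`),
#'   and per-stage acceptance ratios.
#' @export
exploratory_phase <- function(helix, vars, sched, model, seed, scale = 1,
                              bin_width_torsion = 5, bin_width_bond = 2) {
  stopifnot(inherits(sched, "cm_schedule"), inherits(model, "cm_energy_model"))
  if (!nrow(vars)) stop("variable set is empty")
  set.seed(seed)
  temps <- cooling_ladder(sched$t_initial, sched$t_final,
                          sched$cooling_steps_exploratory)
  bins <- memory_bins(vars, bin_width_torsion, bin_width_bond)
  counts <- lapply(bins, function(b) matrix(0L, length(temps), b$nbins))
  torsion_idx <- which(vars$kind %in% c("phi", "psi"))
  bond_idx <- which(vars$kind == "bond")
  state <- vars$center
  cur <- apply_variables(helix, vars, state)
  if (model$needs_coords) cur <- rebuild_coords(cur)
  e_cur <- model$fn(cur)
  n_steps <- max(1L, ceiling(scale * sched$steps_per_variable * nrow(vars) / 3))
  accept_ratio <- numeric(length(temps))
  for (s in seq_along(temps)) {
    acc <- 0L
    for (step in seq_len(n_steps)) {
      moved <- pick_move_set(torsion_idx, bond_idx)
      cand <- state
      cand[moved] <- stats::runif(length(moved),
                                  vars$center[moved] - vars$halfwidth[moved],
                                  vars$center[moved] + vars$halfwidth[moved])
      trial <- apply_variables(cur, vars[moved, , drop = FALSE], cand[moved])
      if (model$needs_coords) trial <- rebuild_coords(trial)
      e_new <- model$fn(trial)
      if (metropolis_accept(e_new - e_cur, temps[s])) {
        state <- cand; cur <- trial; e_cur <- e_new; acc <- acc + 1L
        for (v in moved) {
          b <- bin_index(state[v], bins[[v]])
          counts[[v]][s, b] <- counts[[v]][s, b] + 1L
        }
      }
    }
    accept_ratio[s] <- acc / n_steps
  }
  last <- length(temps)
  populated <- lapply(seq_len(nrow(vars)),
                      function(v) which(counts[[v]][last, ] > 0L))
  fallback <- vars$var_id[vapply(populated, length, 1L) == 0L]
  if (length(fallback)) {
    warning("empty 310 K memory for ", paste(fallback, collapse = ", "),
            "; falling back to the full window for these variables")
    for (v in which(vars$var_id %in% fallback))
      populated[[v]] <- seq_len(bins[[v]]$nbins)
  }
  structure(list(vars = vars, temps = temps, bins = bins, counts = counts,
                 populated_310K = populated, fallback_vars = fallback,
                 accept_ratio = accept_ratio),
            class = "angle_memory")
}

#' @export
print.angle_memory <- function(x, ...) {
  cat("angle_memory:", nrow(x$vars), "variables,", length(x$temps),
      "temperatures (", round(max(x$temps)), "->", round(min(x$temps)), "K )\n")
  occ <- vapply(x$populated_310K, length, 1L)
  nb <- vapply(x$bins, function(b) b$nbins, 1L)
  cat("  populated 310 K bins:", sum(occ), "of", sum(nb), "\n")
  if (length(x$fallback_vars))
    cat("  full-window fallback:", paste(x$fallback_vars, collapse = ", "), "\n")
  invisible(x)
}

#' Biased annealing phase of a CM run
#'
#' Re-anneals from `sched$t_biased_start` to `sched$t_final` in
#' `sched$cooling_steps_biased` geometric stages. Every proposed value is
#' drawn from the populated 310 K space recorded in `memory` (an occupied bin
#' chosen uniformly, then a uniform draw within that bin), so by construction
#' no proposal leaves the populated space; the returned object carries an
#' audit count. After cooling, `sched$n_output` structures are sampled at the
#' final temperature, one every `thin` composite steps.
#'
#' @param helix starting `helix_conformation`.
#' @param memory an `angle_memory` from [exploratory_phase].
#' @param sched a [cm_schedule].
#' @param model a [energy_model].
#' @param seed integer RNG seed.
#' @param scale desk-scale multiplier on `steps_per_variable`.
#' @param thin composite steps between emitted structures. Default 5.
#' @return object of class `cm_ensemble`: `conformers` (list of
#'   `helix_conformation`, length `sched$n_output`), `proposals_total`,
#'   `proposals_outside` (always 0 by construction, audited), and per-stage
#'   acceptance ratios.
#' @export
biased_annealing <- function(helix, memory, sched, model, seed, scale = 1,
                             thin = 5L) {
  stopifnot(inherits(memory, "angle_memory"), inherits(sched, "cm_schedule"))
  vars <- memory$vars
  empty <- vars$var_id[vapply(memory$populated_310K, length, 1L) == 0L]
  if (length(empty))
    stop("no populated 310 K space for variable(s): ",
         paste(empty, collapse = ", "))
  set.seed(seed)
  temps <- cooling_ladder(sched$t_biased_start, sched$t_final,
                          sched$cooling_steps_biased)
  torsion_idx <- which(vars$kind %in% c("phi", "psi"))
  bond_idx <- which(vars$kind == "bond")
  state <- vars$center
  cur <- apply_variables(helix, vars, state)
  if (model$needs_coords) cur <- rebuild_coords(cur)
  e_cur <- model$fn(cur)
  n_steps <- max(1L, ceiling(scale * sched$steps_per_variable * nrow(vars) / 3))
  proposals_total <- 0L; proposals_outside <- 0L
  draw_from_memory <- function(v) {
    b <- memory$bins[[v]]
    occ <- memory$populated_310K[[v]]
    pick <- occ[sample.int(length(occ), 1L)]
    val <- stats::runif(1L, b$lo + (pick - 1L) * b$width, b$lo + pick * b$width)
    # audit: the drawn value must map back into a populated bin
    proposals_total <<- proposals_total + 1L
    if (!(bin_index(val, b) %in% occ))
      proposals_outside <<- proposals_outside + 1L
    val
  }
  run_steps <- function(n, temperature) {
    acc <- 0L
    for (step in seq_len(n)) {
      moved <- pick_move_set(torsion_idx, bond_idx)
      cand <- state
      for (v in moved) cand[v] <- draw_from_memory(v)
      trial <- apply_variables(cur, vars[moved, , drop = FALSE], cand[moved])
      if (model$needs_coords) trial <- rebuild_coords(trial)
      e_new <- model$fn(trial)
      if (metropolis_accept(e_new - e_cur, temperature)) {
        state <<- cand; cur <<- trial; e_cur <<- e_new; acc <- acc + 1L
      }
    }
    acc
  }
  accept_ratio <- numeric(length(temps))
  for (s in seq_along(temps))
    accept_ratio[s] <- run_steps(n_steps, temps[s]) / n_steps
  conformers <- vector("list", sched$n_output)
  for (k in seq_len(sched$n_output)) {
    run_steps(thin, sched$t_final)
    out <- cur
    if (!model$needs_coords) out <- rebuild_coords(out)
    conformers[[k]] <- out
  }
  structure(list(conformers = conformers,
                 proposals_total = proposals_total,
                 proposals_outside = proposals_outside,
                 accept_ratio = accept_ratio,
                 final_temperature = sched$t_final),
            class = "cm_ensemble")
}

#' @export
print.cm_ensemble <- function(x, ...) {
  cat("cm_ensemble:", length(x$conformers), "structures at",
      x$final_temperature, "K\n")
  cat("  proposal audit:", x$proposals_outside, "of", x$proposals_total,
      "outside populated space\n")
  invisible(x)
}

#' Select the first sampled conformer that fits a helix bundle without clashes
#'
#' Candidates are taken in input order; each is (optionally) superposed onto
#' a template C-alpha trace by least-squares (Kabsch) fitting and then
#' screened against the bundle atoms. The first candidate whose minimum
#' interatomic distance to the bundle is at least `clash_cutoff` is returned;
#' if none fits, the absence is a reported outcome, not an error.
#'
#' @param candidates non-empty list of `helix_conformation` objects.
#' @param bundle a [dimer_complex], an atom data frame, an n x 3 coordinate
#'   matrix, or `NULL`/empty (in which case the first candidate trivially
#'   fits).
#' @param clash_cutoff minimum tolerated interatomic distance, Angstrom.
#' @param template_ca optional n x 3 C-alpha matrix defining the target helix
#'   position; candidates are Kabsch-superposed onto it before screening.
#' @return list of class `conformer_selection`: `found`, `index`, `conformer`
#'   (NULL when nothing fits).
#' @export
select_fitting_conformer <- function(candidates, bundle, clash_cutoff = 2.5,
                                     template_ca = NULL) {
  if (!length(candidates)) stop("no candidate conformers supplied")
  bundle_xyz <- NULL
  if (!is.null(bundle)) {
    bundle_xyz <- if (inherits(bundle, "dimer_complex"))
      as.matrix(bundle$atoms[, c("x", "y", "z")])
    else if (is.data.frame(bundle)) as.matrix(bundle[, c("x", "y", "z")])
    else if (is.matrix(bundle)) bundle
    else stop("unsupported bundle type")
  }
  if (is.null(bundle_xyz) || !nrow(bundle_xyz))
    return(structure(list(found = TRUE, index = 1L,
                          conformer = candidates[[1L]]),
                     class = "conformer_selection"))
  for (i in seq_along(candidates)) {
    h <- candidates[[i]]
    xyz <- h$coords
    if (!is.null(template_ca)) {
      fit <- kabsch(helix_ca(h), template_ca)
      xyz <- apply_kabsch(xyz, fit)
    }
    if (min(cross_dist(xyz, bundle_xyz)) >= clash_cutoff)
      return(structure(list(found = TRUE, index = i, conformer = candidates[[i]]),
                       class = "conformer_selection"))
  }
  structure(list(found = FALSE, index = NA_integer_, conformer = NULL),
            class = "conformer_selection")
}
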