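#!/usr/bin/env Rscript
# Residue-level decomposition on synthetic toy dimers with known nonbonded
# parameters: how the cholesterol-proxy contribution to the interface energy
# varies with protomer separation.
#
# What this shows: the decomposition is a pure function of coordinates and
# parameters; as the protomers separate, per-residue terms fade to zero once
# the 7 A residue-selection radius excludes them, while the mid-placed
# cholesterol proxies keep contributing longer -- their share of the total
# rises before everything vanishes.

library(gpcrdimer)

dir.create("results", showWarnings = FALSE)

seps <- c(4.5, 5.0, 5.5, 6.0, 7.0, 8.0)
rows <- lapply(seps, function(s) {
  cx <- make_dimer_fixture(n_residues_per_protomer = 10, separation = s,
                           charge_scheme = "alternating", n_cholesterol = 2,
                           seed = 1)
  d <- suppressWarnings(
    summarize_table(decompose_interface(cx, paste0("1.", 1:10))))
  data.frame(separation = s,
             protomer_total = term_total(d$protomer_subtotal),
             chol_total = term_total(d$chol_subtotal),
             grand_total = term_total(d$grand_total),
             chol_percent = d$chol_fraction_percent)
})
tab <- do.call(rbind, rows)
utils::write.table(format(tab, digits = 4), "results/toy_dimer_scan.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(tab, digits = 3)

# one fully rendered table at a glance, contact distance
cx <- make_dimer_fixture(n_residues_per_protomer = 10, separation = 5,
                         charge_scheme = "alternating", n_cholesterol = 2,
                         seed = 1)
d <- summarize_table(decompose_interface(cx, paste0("1.", 1:10)))
render_energy_table(d, "results/toy_dimer_interface.tsv")
write_manifest(run_manifest(config = attr(cx, "spec"), seeds = c(fixture = 1)),
               "results/toy_dimer_interface.manifest.json")
cat("wrote results/toy_dimer_scan.tsv and results/toy_dimer_interface.tsv\n")
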