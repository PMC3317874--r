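#!/usr/bin/env Rscript
# Kinked-helix geometry: bend / wobble / face-shift descriptors.
#
# What this shows: on helices constructed with known kink parameters the
# descriptors recover the ground truth to within ~2 degrees (bend) and ~5
# degrees (wobble, face shift); the descriptors of the CM-sampled ensemble
# from analysis/03 quantify how much hinge flexibility the sampler explored.
# The published descriptor values for the receptor's own helices are not
# recomputable (their model coordinates were never deposited); the recovery
# table is the verifiable surface.

library(gpcrdimer)

dir.create("results", showWarnings = FALSE)

# 1. construction-recovery sweep
grid <- expand.grid(bend = c(10, 15, 20, 25, 30, 35, 40),
                    wobble = c(-150, -105, -60, 0, 60, 120))
rec <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
  h <- make_kinked_helix(strrep("A", 26), 13, grid$bend[i], grid$wobble[i])
  g <- kink_geometry(h, 13)
  data.frame(bend_set = grid$bend[i], wobble_set = grid$wobble[i],
             bend_got = g$bend_deg, wobble_got = g$wobble_deg,
             face_shift_got = g$face_shift_deg)
}))
utils::write.table(format(rec, digits = 4), "results/kink_recovery.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("recovery over %d constructions: max |bend error| %.2f deg, max |wobble error| %.2f deg\n",
            nrow(rec), max(abs(rec$bend_got - rec$bend_set)),
            max(abs(wrap_angle(rec$wobble_got - rec$wobble_set)))))

# 2. descriptors of the CM ensemble, if analysis/03 has been run
if (file.exists("results/cm_conformers.pdb")) {
  lines <- readLines("results/cm_conformers.pdb")
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  cas <- lapply(seq_along(starts), function(m) {
    block <- lines[starts[m]:ends[m]]
    at <- block[grepl("^ATOM", block) & substr(block, 13, 16) == " CA "]
    matrix(as.numeric(c(substr(at, 31, 38), substr(at, 39, 46),
                        substr(at, 47, 54))), ncol = 3)
  })
  # 20-residue helices: 5-residue segment fits on either side of the hinge
  geo <- kink_geometry_table(cas, flex_residues = 14, window = 5)
  utils::write.table(format(geo, digits = 4), "results/cm_ensemble_kinks.tsv",
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("CM ensemble (n = %d): bend %.1f +/- %.1f deg\n", nrow(geo),
              mean(geo$bend_deg), stats::sd(geo$bend_deg)))
}
cat("wrote results/kink_recovery.tsv\n")
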