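#!/usr/bin/env Rscript
# Sensitized-emission FRET pipeline on synthetic three-channel data for the
# four receptor-pair conditions, plus the colocalization index.
#
# What this shows: bleed-through coefficients estimated from singly
# transfected controls, normalized net FRET per ROI, and per-condition
# summaries (12 cells x 20 membrane ROIs each, as in the study design) that
# recover the generator's ground truth: wild-type homodimer 0.49 down to the
# palmitoylation-deficient pair 0.07.

library(gpcrdimer)

dir.create("results", showWarnings = FALSE)

conditions <- data.frame(
  condition = c("CFPwt/YFPwt", "CFPwt/YFPmut", "CFPmut/YFPwt", "CFPmut/YFPmut"),
  true_nfret = c(0.49, 0.30, 0.27, 0.07))

seed0 <- 7L
summaries <- lapply(seq_len(nrow(conditions)), function(i) {
  g <- make_fret_rois(true_nfret = conditions$true_nfret[i], seed = seed0 + i)
  co <- estimate_bleedthrough(g$donor_only, g$acceptor_only)
  summarize_fret(g$experimental, co, condition = conditions$condition[i])
})
for (s in summaries) print(s)

render_fret_summary(summaries, "results/fret_summaries.tsv")

# colocalization worked examples: full overlap, none, partial
coloc <- data.frame(
  case = c("full_overlap", "no_overlap", "partial"),
  n_red = c(100, 10, 150), n_green = c(100, 90, 50), n_yellow = c(100, 0, 40))
coloc$index <- mapply(colocalization_index, coloc$n_red, coloc$n_green,
                      coloc$n_yellow)
utils::write.table(coloc, "results/colocalization_examples.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(coloc)

write_manifest(run_manifest(config = list(conditions = conditions),
                            seeds = c(base = seed0)),
               "results/fret_summaries.manifest.json")
cat("wrote results/fret_summaries.tsv and results/colocalization_examples.tsv\n")
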