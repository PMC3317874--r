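# Table renderers and the run manifest. Display rounding follows the
# conventions of published interaction-energy tables: energies at 2 decimals,
# percentages at 1 decimal, subtotals computed in full precision and then
# rounded (never summed from rounded rows), with an explicit note whenever
# the rounded rows do not add up to the rounded subtotal.

#' Render an interface-energy decomposition as a TSV table
#'
#' Writes per-residue rows at 2 decimals, the protomer and cholesterol
#' subtotal rows, the grand total, and a trailing cholesterol-percentage line
#' at 1 decimal. A full-precision companion file (`*_full.tsv`) carries the
#' unrounded values. When the sum of the rounded rows differs from the
#' rounded subtotal a rounding note is appended as a `#` comment line.
#'
#' @param decomp a summarized `energy_decomposition` (see [summarize_table]).
#' @param path output TSV path.
#' @return invisibly, the main output path.
#' @export
render_energy_table <- function(decomp, path) {
  stopifnot(inherits(decomp, "energy_decomposition"))
  if (is.null(decomp$grand_total))
    stop("decomposition is not summarized; run summarize_table() first")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con), add = TRUE)
  f2 <- function(x) sprintf("%.2f", x)
  line <- function(...) writeLines(paste(..., sep = "\t"), con)
  term_line <- function(label, section, t)
    line(label, section, f2(t[["coulombic"]]), f2(t[["vdw"]]),
         f2(term_total(t)))
  line("label", "section", "coulombic", "vdw", "total")
  r <- decomp$rows
  for (i in seq_len(nrow(r)))
    line(r$residue_label[i], "protomer", f2(r$coulombic[i]), f2(r$vdw[i]),
         f2(r$coulombic[i] + r$vdw[i]))
  term_line("protomer_subtotal", "subtotal", decomp$protomer_subtotal)
  term_line("CHOL_A_vs_B", "cholesterol", decomp$chol_a_vs_b)
  term_line("CHOL_B_vs_A", "cholesterol", decomp$chol_b_vs_a)
  term_line("chol_subtotal", "subtotal", decomp$chol_subtotal)
  if (!is.null(decomp$palm_a_vs_b))
    term_line("PALM_A_vs_B", "palmitoyl_not_in_total", decomp$palm_a_vs_b)
  if (!is.null(decomp$palm_b_vs_a))
    term_line("PALM_B_vs_A", "palmitoyl_not_in_total", decomp$palm_b_vs_a)
  term_line("grand_total", "total", decomp$grand_total)
  pct <- decomp$chol_fraction_percent
  line("cholesterol_percent", "percent",
       if (is.nan(pct)) "n/a" else sprintf("%.1f", pct), "", "")
  # rounded rows vs rounded subtotal
  row_sum_c <- sum(round(r$coulombic, 2L)); row_sum_v <- sum(round(r$vdw, 2L))
  sub_c <- round(decomp$protomer_subtotal[["coulombic"]], 2L)
  sub_v <- round(decomp$protomer_subtotal[["vdw"]], 2L)
  if (abs(row_sum_c - sub_c) > 1e-9 || abs(row_sum_v - sub_v) > 1e-9)
    writeLines(sprintf(
      paste0("# note: rounded rows sum to (%.2f, %.2f) vs subtotal ",
             "(%.2f, %.2f); subtotals are rounded from full precision, ",
             "not summed from rounded rows"),
      row_sum_c, row_sum_v, sub_c, sub_v), con)
  if (!is.null(decomp$rounding_note))
    writeLines(paste("# note:", decomp$rounding_note), con)
  # full-precision companion
  full_path <- sub("(\\.[^.]+)?$", "_full.tsv", path)
  full <- rbind(
    data.frame(label = r$residue_label, section = "protomer",
               coulombic = r$coulombic, vdw = r$vdw, total = r$total),
    data.frame(label = c("protomer_subtotal", "CHOL_A_vs_B", "CHOL_B_vs_A",
                         "chol_subtotal", "grand_total"),
               section = c("subtotal", "cholesterol", "cholesterol",
                           "subtotal", "total"),
               coulombic = c(decomp$protomer_subtotal[["coulombic"]],
                             decomp$chol_a_vs_b[["coulombic"]],
                             decomp$chol_b_vs_a[["coulombic"]],
                             decomp$chol_subtotal[["coulombic"]],
                             decomp$grand_total[["coulombic"]]),
               vdw = c(decomp$protomer_subtotal[["vdw"]],
                       decomp$chol_a_vs_b[["vdw"]],
                       decomp$chol_b_vs_a[["vdw"]],
                       decomp$chol_subtotal[["vdw"]],
                       decomp$grand_total[["vdw"]]),
               total = c(term_total(decomp$protomer_subtotal),
                         term_total(decomp$chol_a_vs_b),
                         term_total(decomp$chol_b_vs_a),
                         term_total(decomp$chol_subtotal),
                         term_total(decomp$grand_total))))
  utils::write.table(full, full_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Parse a rendered interface-energy TSV back into a data frame
#'
#' @param path path written by [render_energy_table].
#' @return data frame with the rendered (rounded) values.
#' @export
read_energy_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}

#' Render FRET summaries for several conditions as a TSV table
#'
#' @param summaries list of `fret_summary` objects (see [summarize_fret]),
#'   rendered in input order.
#' @param path output TSV path.
#' @return invisibly, the output path.
#' @export
render_fret_summary <- function(summaries, path) {
  if (inherits(summaries, "fret_summary")) summaries <- list(summaries)
  if (!length(summaries)) stop("no summaries to render")
  tab <- do.call(rbind, lapply(summaries, function(s) {
    stopifnot(inherits(s, "fret_summary"))
    data.frame(condition = s$condition, mean_nfret = s$mean_nfret, sd = s$sd,
               n_cells = s$n_cells, n_rois_per_cell = s$n_rois_per_cell,
               validity = if (s$valid) "ok" else "warn")
  }))
  tryCatch(utils::write.table(tab, path, sep = "\t", quote = FALSE,
                              row.names = FALSE),
           error = function(e) stop("cannot write to ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Build a reproducibility manifest for a pipeline run
#'
#' @param config named list: the configuration snapshot for the run.
#' @param seeds named or unnamed vector of the seeds used.
#' @param inputs character vector of input file paths; their MD5 checksums
#'   are recorded.
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(config = list(), seeds = integer(), inputs = character()) {
  checksums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  structure(list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 tool = "gpcrdimer",
                 version = as.character(utils::packageVersion("gpcrdimer")),
                 config = config, seeds = as.list(seeds),
                 input_checksums = checksums),
            class = "run_manifest")
}

#' Write a run manifest as JSON
#'
#' @param manifest a [run_manifest].
#' @param path output path.
#' @return invisibly, the output path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
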