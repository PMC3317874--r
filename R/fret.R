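# Sensitized-emission FRET normalization and pixel colocalization.
#
# Three filter cubes are measured per region of interest (ROI): the FRET
# channel (donor excitation / acceptor emission, `i_fret`), the donor channel
# (`i_cfp`) and the acceptor channel (`i_yfp`). Bleed-through of donor and
# acceptor fluorescence into the FRET channel is removed with coefficients
# CoA and CoB estimated from singly-transfected cells, and the net signal is
# scaled by sqrt(I_CFP * I_YFP), which removes the dependence on the
# expression levels of the two fluorophores.

#' Bleed-through coefficients for three-cube FRET
#'
#' @param co_a donor (CFP) bleed-through into the FRET channel, unitless.
#' @param co_b acceptor (YFP) bleed-through into the FRET channel, unitless.
#' @param n_a,n_b number of ROIs behind each estimate (optional).
#' @param sd_a,sd_b standard deviations of the per-ROI ratios (optional).
#' @return list of class `bleedthrough_coefficients`.
#' @export
bleedthrough_coefficients <- function(co_a, co_b, n_a = NA_integer_,
                                      n_b = NA_integer_, sd_a = NA_real_,
                                      sd_b = NA_real_) {
  if (co_a < 0 || co_b < 0) stop("bleed-through coefficients must be >= 0")
  if (co_a >= 1 || co_b >= 1)
    warning("bleed-through coefficient >= 1 is unusual; check the inputs")
  structure(list(co_a = co_a, co_b = co_b, n_a = n_a, n_b = n_b,
                 sd_a = sd_a, sd_b = sd_b),
            class = "bleedthrough_coefficients")
}

#' @export
print.bleedthrough_coefficients <- function(x, ...) {
  cat(sprintf("bleed-through: CoA = %.4f (n = %s), CoB = %.4f (n = %s)\n",
              x$co_a, x$n_a, x$co_b, x$n_b))
  invisible(x)
}

check_roi_table <- function(rois) {
  needed <- c("i_fret", "i_cfp", "i_yfp")
  if (!all(needed %in% names(rois)))
    stop("ROI table needs columns: ", paste(needed, collapse = ", "))
  if (any(rois$i_fret < 0 | rois$i_cfp < 0 | rois$i_yfp < 0))
    stop("intensities must be non-negative")
  invisible(rois)
}

#' Estimate bleed-through coefficients from singly-transfected controls
#'
#' CoA is the mean of `i_fret / i_cfp` over donor-only ROIs (cells expressing
#' only the CFP construct); CoB is the mean of `i_fret / i_yfp` over
#' acceptor-only ROIs. ROIs with a zero denominator are rejected with a
#' warning; if all ROIs of a set are rejected it is an error.
#'
#' @param donor_only,acceptor_only ROI tables with columns `i_fret`,
#'   `i_cfp`, `i_yfp`.
#' @return a [bleedthrough_coefficients] object.
#' @export
estimate_bleedthrough <- function(donor_only, acceptor_only) {
  check_roi_table(donor_only); check_roi_table(acceptor_only)
  if (!nrow(donor_only) || !nrow(acceptor_only))
    stop("both control collections must be non-empty")
  ratio_of <- function(tab, denom_col, label) {
    ok <- tab[[denom_col]] > 0
    if (any(!ok))
      warning(sum(!ok), " ", label, " ROI(s) with zero ", denom_col,
              " excluded")
    if (!any(ok)) stop("all ", label, " ROIs rejected (zero ", denom_col, ")")
    tab$i_fret[ok] / tab[[denom_col]][ok]
  }
  ra <- ratio_of(donor_only, "i_cfp", "donor-only")
  rb <- ratio_of(acceptor_only, "i_yfp", "acceptor-only")
  bleedthrough_coefficients(mean(ra), mean(rb), n_a = length(ra),
                            n_b = length(rb),
                            sd_a = stats::sd(ra), sd_b = stats::sd(rb))
}

#' Normalized net FRET of one or more ROIs
#'
#' The default (`variant = "standard"`) is the three-cube normalized net
#' FRET,
#' \deqn{NFRET = (I_{FRET} - CoA \cdot I_{CFP} - CoB \cdot I_{YFP}) /
#'   \sqrt{I_{CFP} I_{YFP}}}
#' i.e. the FRET-channel intensity stripped of donor and acceptor
#' bleed-through, scaled by the geometric mean of the donor and acceptor
#' intensities so that it is invariant under uniform rescaling of all three
#' channels. `variant = "printed"` evaluates the literal variant
#' \eqn{(CoA \cdot I_{CFP} - CoB \cdot I_{YFP}) / \sqrt{I_{CFP} I_{YFP}}}
#' for audit purposes only: that expression omits the measured FRET-channel
#' term and is not a transfer statistic (see the methods vignette).
#'
#' @param roi ROI table (one or more rows) with `i_fret`, `i_cfp`, `i_yfp`.
#' @param co a [bleedthrough_coefficients] object.
#' @param variant `"standard"` (default) or `"printed"`.
#' @return numeric vector of NFRET values, one per ROI.
#' @export
normalized_net_fret <- function(roi, co, variant = c("standard", "printed")) {
  variant <- match.arg(variant)
  check_roi_table(roi)
  denom2 <- roi$i_cfp * roi$i_yfp
  if (any(denom2 <= 0))
    stop("i_cfp * i_yfp must be positive for normalization")
  num <- if (variant == "standard")
    roi$i_fret - co$co_a * roi$i_cfp - co$co_b * roi$i_yfp
  else
    co$co_a * roi$i_cfp - co$co_b * roi$i_yfp
  num / sqrt(denom2)
}

#' Summarize normalized net FRET over cells and ROIs
#'
#' Computes per-ROI NFRET, then the mean and standard deviation across all
#' ROIs (SD, not SEM, is reported). A summary is flagged when it is based on
#' fewer than 20 ROIs per cell or fewer than 12 cells, the minimum sampling
#' used for a valid membrane FRET estimate.
#'
#' When the bleed-through coefficients carry their own sampling uncertainty
#' (`sd_a`/`n_a`, `sd_b`/`n_b`, as produced by [estimate_bleedthrough]), the
#' reported standard error of the mean NFRET propagates it: the mean NFRET
#' depends linearly on CoA and CoB with sensitivities
#' `mean(sqrt(I_CFP/I_YFP))` and `mean(sqrt(I_YFP/I_CFP))`, so
#' \deqn{SE^2 = sd^2/n + (sd_A^2/n_A)\,\overline{\sqrt{C/Y}}^2 +
#'   (sd_B^2/n_B)\,\overline{\sqrt{Y/C}}^2.}
#'
#' @param rois ROI table with `cell_id`, `i_fret`, `i_cfp`, `i_yfp`.
#' @param co a [bleedthrough_coefficients] object.
#' @param condition optional condition label carried into the summary.
#' @return list of class `fret_summary`: `condition`, `mean_nfret`, `sd`,
#'   `se_nfret` (standard error of the mean including bleed-through
#'   uncertainty where available), `n_cells`, `n_rois_per_cell` (minimum per
#'   cell), `n_rois_total`, `valid`.
#' @export
summarize_fret <- function(rois, co, condition = NA_character_) {
  check_roi_table(rois)
  if (!nrow(rois)) stop("no ROIs to summarize")
  if (is.null(rois$cell_id)) stop("ROI table needs a cell_id column")
  nf <- normalized_net_fret(rois, co)
  per_cell <- table(rois$cell_id)
  n_cells <- length(per_cell)
  n_min <- min(per_cell)
  valid <- n_cells >= 12L && n_min >= 20L
  if (!valid)
    warning("summary below sampling thresholds (", n_cells, " cells, >= ",
            n_min, " ROIs/cell; need >= 12 cells and >= 20 ROIs/cell)")
  se2 <- stats::var(nf) / length(nf)
  if (is.finite(co$sd_a) && is.finite(co$n_a) && co$n_a > 0)
    se2 <- se2 + (co$sd_a^2 / co$n_a) * mean(sqrt(rois$i_cfp / rois$i_yfp))^2
  if (is.finite(co$sd_b) && is.finite(co$n_b) && co$n_b > 0)
    se2 <- se2 + (co$sd_b^2 / co$n_b) * mean(sqrt(rois$i_yfp / rois$i_cfp))^2
  structure(list(condition = condition, mean_nfret = mean(nf),
                 sd = stats::sd(nf), se_nfret = sqrt(se2), n_cells = n_cells,
                 n_rois_per_cell = as.integer(n_min),
                 n_rois_total = length(nf), valid = valid),
            class = "fret_summary")
}

#' @export
print.fret_summary <- function(x, ...) {
  cat(sprintf("NFRET %s: %.3f +/- %.3f (SD), %d cells x >=%d ROIs%s\n",
              if (is.na(x$condition)) "" else x$condition,
              x$mean_nfret, x$sd, x$n_cells, x$n_rois_per_cell,
              if (x$valid) "" else " [below sampling thresholds]"))
  invisible(x)
}

#' Pixel colocalization index
#'
#' `2 * n_yellow / (n_red + n_green)`, where the counts are numbers of pixels
#' above a pre-defined per-channel intensity threshold and yellow pixels are
#' those above threshold in both channels. Lies in [0, 1] because
#' `n_yellow <= min(n_red, n_green)`.
#'
#' @param n_red,n_green,n_yellow pixel counts (non-negative).
#' @return unitless index in [0, 1].
#' @export
colocalization_index <- function(n_red, n_green, n_yellow) {
  if (any(c(n_red, n_green, n_yellow) < 0)) stop("pixel counts must be >= 0")
  if (n_red + n_green == 0) stop("n_red + n_green is zero")
  if (n_yellow > min(n_red, n_green))
    stop("n_yellow exceeds min(n_red, n_green): counts are inconsistent")
  2 * n_yellow / (n_red + n_green)
}
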