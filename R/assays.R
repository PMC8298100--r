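# Small assay quantifications: 3D invasion depth fraction, liposome-binding
# densitometry correction, and the amplification co-occurrence statistic.

#' Invasion fraction of a depth profile
#'
#' Fraction of total fluorescence found at depths at or beyond the invasion
#' threshold (inclusive: "45 um or more"). Confocal slices are typically
#' spaced 15 um apart.
#'
#' @param depths Slice depths in um, strictly increasing, >= 0.
#' @param intensities Total fluorescence per slice (a.u., >= 0).
#' @param threshold_depth Invasion threshold in um (default 45, inclusive).
#' @return Fraction in `[0, 1]`.
#' @examples
#' invasion_fraction(seq(0, 90, 15), rep(1, 7))  # 4/7
#' @export
invasion_fraction <- function(depths, intensities, threshold_depth = 45) {
  if (length(depths) != length(intensities)) {
    stop("depths and intensities lengths differ", call. = FALSE)
  }
  if (any(depths < 0) || any(diff(depths) <= 0)) {
    stop("depths must be non-negative and strictly increasing", call. = FALSE)
  }
  if (any(intensities < 0)) stop("intensities must be >= 0", call. = FALSE)
  total <- sum(intensities)
  if (total <= 0) stop("total intensity is zero; fraction undefined", call. = FALSE)
  sum(intensities[depths >= threshold_depth]) / total
}

#' Normalize invasion fractions to the control condition
#'
#' Divides each well's invasion fraction by the mean fraction of the control
#' condition, so the control averages exactly 1.
#'
#' @param data Data frame with columns `condition` and `fraction`.
#' @param control Control condition label.
#' @return `data` with an added `relative` column.
#' @export
normalize_invasion <- function(data, control) {
  if (!all(c("condition", "fraction") %in% names(data))) {
    stop("`data` needs columns condition and fraction", call. = FALSE)
  }
  if (!control %in% data$condition) {
    stop(sprintf("control condition '%s' not present", control), call. = FALSE)
  }
  ctrl_mean <- mean(data$fraction[data$condition == control])
  if (ctrl_mean <= 0) stop("control mean is zero; cannot normalize", call. = FALSE)
  data$relative <- data$fraction / ctrl_mean
  data
}

#' Corrected, normalized liposome binding from gel densitometry
#'
#' Per lane: subtract the lane background, subtract the protein's
#' no-liposome (precipitation) control band, divide by the pelleting
#' efficiency of that liposome diameter (measured relative to 100-nm
#' liposomes), and normalize to the same corrected quantity for the
#' reference condition (wild-type protein on 100-nm liposomes). Negative
#' corrected densities are clipped to 0 and flagged.
#'
#' @param quants Data frame with columns `protein`, `diameter` (nm; `NA` for
#'   the no-liposome control lane), `band_density`, `lane_background`.
#' @param pelleting_efficiency Named numeric vector mapping diameter (as
#'   character, e.g. `"100"`) to pelleting efficiency relative to 100 nm
#'   (all > 0).
#' @param reference_protein,reference_diameter The normalization reference
#'   (default wild type, `"WT"`, at 100 nm).
#' @return `quants` (liposome lanes only) with added columns `corrected`,
#'   `normalized`, `clipped`.
#' @export
liposome_binding <- function(quants, pelleting_efficiency,
                             reference_protein = "WT", reference_diameter = 100) {
  req <- c("protein", "diameter", "band_density", "lane_background")
  if (!all(req %in% names(quants))) {
    stop("`quants` needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(pelleting_efficiency <= 0)) {
    stop("pelleting efficiencies must be > 0", call. = FALSE)
  }
  ctrl <- quants[is.na(quants$diameter), , drop = FALSE]
  samp <- quants[!is.na(quants$diameter), , drop = FALSE]
  if (!nrow(samp)) stop("no liposome lanes present", call. = FALSE)
  ctrl_of <- setNames(ctrl$band_density - ctrl$lane_background, ctrl$protein)
  missing_ctrl <- setdiff(unique(samp$protein), names(ctrl_of))
  if (length(missing_ctrl)) {
    stop("no no-liposome control lane for: ", paste(missing_ctrl, collapse = ", "),
         call. = FALSE)
  }
  eff <- pelleting_efficiency[as.character(samp$diameter)]
  if (anyNA(eff)) {
    stop("no pelleting efficiency for diameter(s): ",
         paste(unique(samp$diameter[is.na(eff)]), collapse = ", "), call. = FALSE)
  }
  corrected <- (samp$band_density - samp$lane_background -
                  ctrl_of[samp$protein]) / eff
  samp$clipped <- corrected < 0
  samp$corrected <- pmax(corrected, 0)
  ref_row <- samp$protein == reference_protein & samp$diameter == reference_diameter
  if (!any(ref_row)) {
    stop(sprintf("reference condition %s @ %g nm not present",
                 reference_protein, reference_diameter), call. = FALSE)
  }
  ref_val <- mean(samp$corrected[ref_row])
  if (ref_val <= 0) stop("reference corrected density is zero", call. = FALSE)
  samp$normalized <- samp$corrected / ref_val
  rownames(samp) <- NULL
  samp
}

#' Amplification co-occurrence statistics from a 2x2 table
#'
#' From the marginal counts of patients with amplification of gene A, gene B
#' and both, builds the 2x2 contingency table (both; A only; B only;
#' neither), and returns the odds ratio
#' `(both * neither) / (A_only * B_only)`, its log2, the two-sided Fisher
#' exact p-value, and the marginal percentages. A zero cell triggers the
#' Haldane correction (0.5 added to every cell of the odds ratio, flagged).
#'
#' @param n_total Total patients.
#' @param n_a,n_b Patients with amplification of A, of B.
#' @param n_ab Patients with both.
#' @param alternative Passed to [stats::fisher.test()] (default two-sided).
#' @return A list with `table` (2x2 matrix), `odds_ratio`,
#'   `log2_odds_ratio`, `fisher_p`, `pct_a`, `pct_b`, `pct_ab`,
#'   `haldane_corrected`.
#' @examples
#' cooccurrence_stats(398, 29, 20, 7)$log2_odds_ratio  # about 3.12
#' @export
cooccurrence_stats <- function(n_total, n_a, n_b, n_ab,
                               alternative = "two.sided") {
  for (v in c(n_total, n_a, n_b, n_ab)) check_number(v, "count", 0, integer = TRUE)
  if (n_ab > min(n_a, n_b)) stop("n_ab exceeds a margin", call. = FALSE)
  if (n_a + n_b - n_ab > n_total) stop("margins exceed n_total", call. = FALSE)
  both <- n_ab
  a_only <- n_a - n_ab
  b_only <- n_b - n_ab
  neither <- n_total - n_a - n_b + n_ab
  tab <- matrix(c(both, a_only, b_only, neither), 2L, 2L,
                dimnames = list(A = c("A+", "A-"), B = c("B+", "B-")))
  haldane <- any(tab == 0)
  ct <- if (haldane) tab + 0.5 else tab
  or <- (ct[1L, 1L] * ct[2L, 2L]) / (ct[1L, 2L] * ct[2L, 1L])
  list(table = tab, odds_ratio = or, log2_odds_ratio = log2(or),
       fisher_p = fisher.test(tab, alternative = alternative)$p.value,
       pct_a = 100 * n_a / n_total, pct_b = 100 * n_b / n_total,
       pct_ab = 100 * n_ab / n_total, haldane_corrected = haldane)
}
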