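#' Phosphatase assay scoring
#'
#' Converts raw colorimetric phosphatase assay readouts into rates and
#' verdicts: malachite-green style endpoint assays are calibrated against
#' phosphate standards and read out as mol product/min; pNPP-style
#' time courses are scored by their initial linear slope; activity that
#' disappears under a sub-stoichiometric dose of a specific inhibitor
#' (okadaic acid for PP2A-family enzymes) is attributed to a contaminating
#' phosphatase rather than the purified target; and MMTS:IAA differential
#' cysteine alkylation ratios are turned into buried/exposed accessibility
#' calls.
#'
#' @name biochem_scores
NULL

#' Fit a phosphate calibration curve
#'
#' Ordinary least squares of absorbance on phosphate amount. Refuses to
#' return a poorly linear standard curve (r-squared < `min_r2`) unless
#' `force = TRUE`, since downstream rates divide by the fitted slope.
#'
#' @param standards Data frame with columns `amount` (mol phosphate) and
#'   `absorbance`.
#' @param min_r2 Linearity threshold (default 0.98).
#' @param force Accept a sub-threshold fit.
#' @return List: `slope` (absorbance per mol), `intercept`, `r_squared`, `n`.
#' @export
fit_calibration <- function(standards, min_r2 = 0.98, force = FALSE) {
  stopifnot(all(c("amount", "absorbance") %in% names(standards)))
  if (nrow(standards) < 2L) stop_invalid("need at least 2 standards")
  if (length(unique(standards$amount)) < 2L) {
    stop_invalid("standards need at least 2 distinct phosphate amounts")
  }
  fit <- stats::lm(absorbance ~ amount, data = standards)
  r2 <- if (stats::var(standards$absorbance) == 0) 1 else
    suppressWarnings(summary(fit)$r.squared)
  if (nrow(standards) == 2L) r2 <- 1  # exact interpolating line
  if (r2 < min_r2 && !force) {
    stop_invalid("calibration r-squared %.4f below %.2f; pass force = TRUE to accept",
                 r2, min_r2)
  }
  list(slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, n = nrow(standards))
}

#' Endpoint absorbance to reaction rate
#'
#' Converts a blank-corrected endpoint absorbance to mol product/min through
#' the calibration line, and flags detectability by the standard
#' limit-of-detection rule: the signal must exceed the blank mean by three
#' blank standard deviations.
#'
#' @param absorbance Endpoint absorbance of the reaction.
#' @param blanks Numeric vector of blank-replicate absorbances.
#' @param calibration A [fit_calibration()] result.
#' @param incubation_time Incubation time in minutes (> 0).
#' @return List: `rate` (mol product/min, floored at 0) and `detectable`.
#' @export
endpoint_rate <- function(absorbance, blanks, calibration, incubation_time) {
  if (incubation_time <= 0) stop_invalid("incubation time must be positive")
  if (calibration$slope <= 0) stop_invalid("calibration slope must be positive")
  blank_mean <- mean(blanks)
  blank_sd <- if (length(blanks) > 1L) stats::sd(blanks) else 0
  rate <- max(0, (absorbance - blank_mean - calibration$intercept) / calibration$slope) /
    incubation_time
  list(rate = rate, detectable = absorbance > blank_mean + 3 * blank_sd)
}

#' Initial-rate slope of an assay time course
#'
#' Fits the longest initial window (prefix of the time course, at least 5
#' points) whose linear fit achieves r-squared >= `min_r2`, and scales the
#' slope (absorbance per minute) by `conversion_factor` to obtain mol
#' product/min. A perfectly flat course is treated as perfectly linear
#' (rate 0). If no 5-point prefix qualifies, the full course is fit and the
#' result flagged as low linearity.
#'
#' @param times Seconds, strictly increasing, length >= 5.
#' @param absorbance Same length as `times`.
#' @param conversion_factor Mol product per absorbance unit.
#' @param min_r2 Window linearity bound (default 0.99).
#' @return List: `rate` (mol/min), `slope` (absorbance/min), `window_points`,
#'   `r_squared`, `low_linearity` flag.
#' @export
timecourse_rate <- function(times, absorbance, conversion_factor, min_r2 = 0.99) {
  if (length(times) < 5L) stop_invalid("time course needs at least 5 points")
  if (length(times) != length(absorbance)) stop_invalid("times/absorbance length mismatch")
  if (any(diff(times) <= 0)) stop_invalid("times must be strictly increasing")
  mins <- times / 60
  fit_window <- function(k) {
    x <- mins[1:k]; y <- absorbance[1:k]
    if (stats::var(y) < .Machine$double.eps) return(list(slope = 0, r2 = 1))
    f <- stats::lm(y ~ x)
    list(slope = unname(stats::coef(f)[2]),
         r2 = suppressWarnings(summary(f)$r.squared))
  }
  best <- NULL
  for (k in seq(length(times), 5L)) {
    w <- fit_window(k)
    if (w$r2 >= min_r2) { best <- c(w, window_points = k); break }
  }
  low <- is.null(best)
  if (low) best <- c(fit_window(length(times)), window_points = length(times))
  list(rate = best$slope * conversion_factor, slope = best$slope,
       window_points = best$window_points, r_squared = best$r2,
       low_linearity = low)
}

#' Attribute inhibitor-sensitive activity to a contaminant or the target
#'
#' Operationalizes the okadaic-acid control: if essentially all measured
#' activity (`f >= f_threshold` of it) disappears under an inhibitor dose
#' that the purified enzyme exceeds in molar terms, the activity cannot come
#' from the enzyme itself and is attributed to a co-purifying contaminant
#' phosphatase. If the activity is essentially untouched
#' (`f < 1 - f_threshold`), it is attributed to the target. Anything in
#' between is indeterminate.
#'
#' @param rate_untreated,rate_treated Rates (mol/min) without/with inhibitor.
#' @param enzyme_conc,inhibitor_conc Molar concentrations.
#' @param f_threshold Inhibited-fraction threshold for "entirely lost"
#'   (default 0.9).
#' @param untreated_detectable Was the untreated rate above the detection
#'   limit? If `FALSE`, `f` is 0 by convention.
#' @return List: `verdict` in `{contaminant_attributed, target_attributed,
#'   indeterminate}` and `inhibited_fraction`.
#' @export
oa_attribution <- function(rate_untreated, rate_treated, enzyme_conc,
                           inhibitor_conc, f_threshold = 0.9,
                           untreated_detectable = TRUE) {
  stopifnot(rate_untreated >= 0, rate_treated >= 0)
  f <- if (!untreated_detectable || rate_untreated == 0) 0 else
    min(1, max(0, 1 - rate_treated / rate_untreated))
  verdict <- if (f >= f_threshold && enzyme_conc > inhibitor_conc) {
    "contaminant_attributed"
  } else if (f < 1 - f_threshold) {
    "target_attributed"
  } else {
    "indeterminate"
  }
  list(verdict = verdict, inhibited_fraction = f)
}

#' Cysteine accessibility from differential alkylation ratios
#'
#' Scores each cysteine by `log2((I_MMTS + pseudocount) / (I_IAA +
#' pseudocount))`: residues labeled mostly by MMTS (applied under denaturing
#' conditions, after native IAA labeling) were protected in the folded
#' protein and are called buried; IAA-dominant residues were solvent
#' accessible and are called exposed. Ratios between the thresholds are
#' intermediate. Within-row ratios cancel peptide-specific ionization
#' efficiency.
#'
#' @param table Data frame with columns `residue`, `intensity_IAA`,
#'   `intensity_MMTS` (optionally `peptide`).
#' @param pseudocount Positive count guarding zero intensities (default 1).
#' @param t_buried log2-ratio at or above which a residue is buried
#'   (default 2).
#' @param t_exposed log2-ratio at or below which a residue is exposed
#'   (default -1).
#' @return Data frame: `residue`, `log2_ratio`, `call`.
#' @export
alkylation_accessibility <- function(table, pseudocount = 1, t_buried = 2.0,
                                     t_exposed = -1.0) {
  stopifnot(all(c("residue", "intensity_IAA", "intensity_MMTS") %in% names(table)))
  if (pseudocount <= 0) stop_invalid("pseudocount must be positive")
  if (any(table$intensity_IAA < 0 | table$intensity_MMTS < 0)) {
    stop_invalid("intensities must be nonnegative")
  }
  if (anyDuplicated(table$residue)) stop_invalid("residue ids must be unique")
  lr <- log2((table$intensity_MMTS + pseudocount) / (table$intensity_IAA + pseudocount))
  call <- ifelse(lr >= t_buried, "buried",
                 ifelse(lr <= t_exposed, "exposed", "intermediate"))
  data.frame(residue = table$residue, log2_ratio = lr, call = call,
             stringsAsFactors = FALSE)
}
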