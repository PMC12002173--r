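#' Simulate a two-label cysteine alkylation intensity table
#'
#' Emulates differential MMTS/IAA alkylation read out by mass spectrometry:
#' buried cysteines escape native IAA labeling and end up MMTS-dominant,
#' exposed ones IAA-dominant. Each residue's log2(MMTS/IAA) ratio is drawn
#' normally around its class center (log-normal intensities), the two class
#' centers sitting `separation` log2 units apart, symmetric about the
#' midpoint of the default classification thresholds.
#'
#' @param n_buried,n_exposed Number of residues per class.
#' @param separation Gap between expected class log2 ratios (> 0; default 6).
#' @param seed Integer seed.
#' @param noise_sd Standard deviation of the log2 ratio (default 0.25).
#' @param base_intensity Median total intensity per residue (default 1e6).
#' @return List: `table` (residue, peptide, intensity_IAA, intensity_MMTS)
#'   and `truth` (`cysteine_classes`: residue -> buried/exposed).
#' @export
sim_alkylation_table <- function(n_buried, n_exposed, separation = 6, seed = 1L,
                                 noise_sd = 0.25, base_intensity = 1e6) {
  if (separation <= 0) stop_invalid("separation must be positive")
  n <- n_buried + n_exposed
  if (n == 0L) stop_invalid("need at least one residue")
  center <- 0.5  # midpoint of default thresholds t_buried = 2, t_exposed = -1
  with_seed(seed, {
    residues <- sort(sample.int(1500L, n))
    classes <- c(rep("buried", n_buried), rep("exposed", n_exposed))
    mu <- ifelse(classes == "buried", center + separation / 2,
                 center - separation / 2)
    lr <- stats::rnorm(n, mu, noise_sd)
    total <- stats::rlnorm(n, log(base_intensity), 0.5)
    i_mmts <- total * 2^lr / (1 + 2^lr)
    i_iaa <- total / (1 + 2^lr)
    list(
      table = data.frame(
        residue = residues,
        peptide = sprintf("pep%03d", seq_len(n)),
        intensity_IAA = i_iaa,
        intensity_MMTS = i_mmts,
        stringsAsFactors = FALSE
      ),
      truth = list(cysteine_classes = stats::setNames(classes, residues))
    )
  })
}

#' Simulate calibration standards, endpoints and time courses for a
#' phosphatase assay
#'
#' Emulates a malachite-green/pNPP style experiment with a known calibration
#' line, known true enzyme rates, and an okadaic-acid-sensitive contaminant
#' fraction. Standards are `(amount, absorbance)` pairs on
#' `A = slope * amount + intercept` plus noise. Each true rate gets an
#' endpoint absorbance pair (untreated / +inhibitor) and a time-course pair;
#' the untreated signal encodes `true_rate + contaminant_rate`, and the
#' inhibitor removes the contaminant contribution iff
#' `oa_inhibits_contaminant`.
#'
#' @param true_rates Numeric vector of target-enzyme rates (mol product/min).
#' @param calib_slope Absorbance per mol phosphate (default 3e8).
#' @param calib_intercept Calibration intercept (default 0: the
#'   zero-phosphate response is carried by `blank_mean`, so complete
#'   zero-enzyme blanks and zero-rate reactions read the same level).
#' @param contaminant_rate Contaminating-phosphatase rate (mol/min).
#' @param oa_inhibits_contaminant Does the inhibitor abolish the contaminant?
#' @param noise_sd Absorbance noise SD (>= 0).
#' @param seed Integer seed.
#' @param incubation_time Endpoint incubation, minutes (default 60).
#' @param blank_mean Blank absorbance level (default 0.05); 16 blank
#'   replicates are generated (a full plate column), enough for the
#'   three-sigma detection rule to hold its nominal error rate.
#' @param enzyme_conc,inhibitor_conc Molar concentrations recorded for
#'   attribution (defaults 100e-9 and 12.5e-9: enzyme in molar excess over
#'   inhibitor).
#' @param times Time-course sampling times in seconds (default every 30 s
#'   for 90 min).
#' @return List: `standards`, `blanks`, `endpoints` (rate_id, treatment,
#'   absorbance), `timecourses` (rate_id, treatment, time_s, absorbance),
#'   `incubation_time`, `enzyme_conc`, `inhibitor_conc`, and `truth`
#'   (calibration slope/intercept, true rates, contaminant rate, flag).
#' @export
sim_assay <- function(true_rates, calib_slope = 3e8, calib_intercept = 0,
                      contaminant_rate = 0, oa_inhibits_contaminant = TRUE,
                      noise_sd = 0, seed = 1L, incubation_time = 60,
                      blank_mean = 0.05, enzyme_conc = 100e-9,
                      inhibitor_conc = 12.5e-9,
                      times = seq(0, 5400, by = 30)) {
  if (!is.finite(calib_slope) || !is.finite(calib_intercept)) {
    stop_invalid("calibration parameters must be finite")
  }
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (any(true_rates < 0) || contaminant_rate < 0) stop_invalid("rates must be >= 0")
  amounts <- c(0, 0.5, 1, 2, 3, 4) * 1e-9
  with_seed(seed, {
    noise <- function(n) if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else rep(0, n)
    standards <- data.frame(
      amount = amounts,
      absorbance = calib_slope * amounts + calib_intercept + noise(length(amounts))
    )
    blanks <- blank_mean + noise(16L)
    rate_ids <- sprintf("r%02d", seq_along(true_rates))
    eps <- lapply(seq_along(true_rates), function(i) {
      untreated <- true_rates[i] + contaminant_rate
      treated <- true_rates[i] + if (oa_inhibits_contaminant) 0 else contaminant_rate
      data.frame(
        rate_id = rate_ids[i],
        treatment = c("untreated", "inhibitor"),
        absorbance = blank_mean + calib_intercept +
          calib_slope * c(untreated, treated) * incubation_time + noise(2L),
        stringsAsFactors = FALSE
      )
    })
    tc_rows <- list()
    for (i in seq_along(true_rates)) {
      untreated <- true_rates[i] + contaminant_rate
      treated <- true_rates[i] + if (oa_inhibits_contaminant) 0 else contaminant_rate
      for (tr in c("untreated", "inhibitor")) {
        r <- if (tr == "untreated") untreated else treated
        tc_rows[[length(tc_rows) + 1L]] <- data.frame(
          rate_id = rate_ids[i], treatment = tr, time_s = times,
          absorbance = blank_mean + calib_slope * r * (times / 60) +
            noise(length(times)),
          stringsAsFactors = FALSE
        )
      }
    }
    list(
      standards = standards,
      blanks = blanks,
      endpoints = do.call(rbind, eps),
      timecourses = do.call(rbind, tc_rows),
      incubation_time = incubation_time,
      enzyme_conc = enzyme_conc,
      inhibitor_conc = inhibitor_conc,
      truth = list(
        calib_slope = calib_slope, calib_intercept = calib_intercept,
        true_rates = stats::setNames(true_rates, rate_ids),
        contaminant_rate = contaminant_rate,
        oa_inhibits_contaminant = oa_inhibits_contaminant
      )
    )
  })
}
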