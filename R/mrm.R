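#' Integrate a chromatographic peak
#'
#' Baseline-subtracted trapezoidal area over a retention-time window.
#' Negative areas (over-subtracted baseline) are clipped to zero.
#'
#' @param time,intensity Trace vectors (min, counts), or pass a data
#'   frame with `time`/`intensity` columns as `time`.
#' @param window Length-2 numeric, integration window (min); must lie
#'   within the trace span and contain at least two points.
#' @param baseline Constant baseline level subtracted before
#'   integration.
#' @return Area in intensity.min.
#' @export
integrate_peak <- function(time, intensity = NULL, window = range(time),
                           baseline = 0) {
  if (is.data.frame(time)) {
    intensity <- time$intensity
    time <- time$time
  }
  stopifnot(length(time) == length(intensity), length(window) == 2L)
  if (window[1] >= window[2]) stop("empty integration window")
  if (window[1] < min(time) || window[2] > max(time)) {
    stop("integration window outside trace span")
  }
  keep <- time >= window[1] & time <= window[2]
  if (sum(keep) < 2L) stop("integration window contains < 2 points")
  area <- pracma::trapz(time[keep], intensity[keep] - baseline)
  max(area, 0)
}

# integrate every (fragment, label) channel of a chromatogram_set
integrate_channels <- function(chrom, window = NULL, baseline = 0) {
  stopifnot(is.data.frame(chrom))
  out <- list()
  for (key in unique(paste(chrom$fragment, chrom$label))) {
    parts <- strsplit(key, " ")[[1]]
    tr <- chrom[chrom$fragment == parts[1] & chrom$label == parts[2], ]
    w <- if (is.null(window)) range(tr$time) else window
    out[[length(out) + 1L]] <- data.frame(
      fragment = parts[1], label = parts[2],
      area = integrate_peak(tr$time, tr$intensity, w, baseline),
      apex_rt = tr$time[which.max(tr$intensity)])
  }
  do.call(rbind, out)
}

#' Light:heavy peak-area ratio
#'
#' Ratio of summed light to summed heavy areas over the selected
#' fragments — the quantity calibrated against the stable
#' isotope-labelled internal standard.
#'
#' @param light,heavy Named numeric vectors of per-fragment areas.
#' @param fragments Fragment names to sum (default: all shared names).
#' @return The dimensionless ratio.
#' @export
light_heavy_ratio <- function(light, heavy,
                              fragments = intersect(names(light), names(heavy))) {
  if (!length(fragments)) stop("no shared fragments selected")
  if (!all(fragments %in% names(light)) || !all(fragments %in% names(heavy))) {
    stop("selected fragments missing from a channel")
  }
  hs <- sum(heavy[fragments])
  if (hs <= 0) {
    stop("no internal standard signal: heavy area sum is zero, ",
         "quantitation impossible")
  }
  sum(light[fragments]) / hs
}

#' Relative dot-product spectral identity score
#'
#' Normalised dot product between the observed (endogenous) and
#' reference (heavy standard) transition-intensity vectors:
#' `sum(x*y) / sqrt(sum(x^2) * sum(y^2))`, in [0, 1] for non-negative
#' intensities. Identity verdicts follow the assay rule: "identified"
#' at rdotp >= 0.9, "tentative" at >= 0.8 near the detection limit,
#' otherwise "not identified".
#'
#' @param observed,reference Intensity vectors of equal length >= 2.
#' @return The score.
#' @export
rdotp <- function(observed, reference) {
  stopifnot(length(observed) == length(reference))
  if (length(observed) < 2L) stop("need at least two transitions")
  so <- sum(observed^2)
  sr <- sum(reference^2)
  if (so == 0 || sr == 0) {
    stop("rdotp undefined: an all-zero intensity vector was supplied")
  }
  sum(observed * reference) / sqrt(so * sr)
}

#' @rdname rdotp
#' @param score An rdotp value.
#' @param near_lod Is the measurement near the limit of detection
#'   (concentration at or below twice the LOD)?
#' @param identify_cut,tentative_cut Verdict thresholds.
#' @export
rdotp_verdict <- function(score, near_lod = FALSE,
                          identify_cut = 0.9, tentative_cut = 0.8) {
  if (score >= identify_cut) "identified"
  else if (near_lod && score >= tentative_cut) "tentative"
  else "not identified"
}

#' Fit a ratio-to-heavy calibration curve
#'
#' Weighted least-squares line `ratio = slope * concentration +
#' intercept`. Default weighting is 1/x (x = nominal concentration),
#' appropriate for ladders spanning several orders of magnitude.
#'
#' @param nominal Nominal concentrations (fmol/uL), >= 2 distinct
#'   non-zero levels.
#' @param ratio Observed light:heavy ratios, parallel to `nominal`.
#' @param weighting `"1/x"` or `"none"`.
#' @param analysis Identifier stored with the curve.
#' @return An object of class `"calibration_curve"` with the fit,
#'   per-replicate back-calculated concentrations, and per-level
#'   summary statistics (mean, %CV, %RE).
#' @export
fit_calibration <- function(nominal, ratio, weighting = c("1/x", "none"),
                            analysis = 1L) {
  weighting <- match.arg(weighting)
  stopifnot(length(nominal) == length(ratio), all(nominal > 0))
  if (length(unique(nominal)) < 2L) {
    stop("calibration requires >= 2 distinct non-zero levels")
  }
  w <- if (weighting == "1/x") 1 / nominal else rep(1, length(nominal))
  fit <- stats::lm(ratio ~ nominal, weights = w)
  curve <- structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         weighting = weighting, analysis = analysis,
         data = data.frame(nominal = nominal, ratio = ratio)),
    class = "calibration_curve")
  back <- back_calculate(curve, ratio)
  curve$data$back_calculated <- back
  curve$levels <- do.call(rbind, lapply(split(back, nominal), function(b) {
    data.frame(mean = mean(b),
               cv = if (length(b) > 1) stats::sd(b) / mean(b) * 100 else NA_real_,
               n = length(b))
  }))
  curve$levels$nominal <- as.numeric(rownames(curve$levels))
  curve$levels$re <- (curve$levels$mean - curve$levels$nominal) /
    curve$levels$nominal * 100
  rownames(curve$levels) <- NULL
  curve
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> analysis %s: ratio = %.5g x conc %+.4g (%s weights), %d levels\n",
    x$analysis, x$slope, x$intercept, x$weighting,
    length(unique(x$data$nominal))))
  invisible(x)
}

#' Back-calculate concentration from a ratio
#'
#' Inverts the calibration line: `(ratio - intercept) / slope`.
#' Negative results are reported as 0 and flagged below range.
#'
#' @param curve A [fit_calibration()] object.
#' @param ratio Light:heavy ratio(s).
#' @return Concentration(s) in fmol/uL; attribute `"below_range"` marks
#'   clipped values.
#' @export
back_calculate <- function(curve, ratio) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("calibration slope is zero; cannot invert")
  conc <- (ratio - curve$intercept) / curve$slope
  below <- conc < 0
  conc[below] <- 0
  attr(conc, "below_range") <- below
  conc
}

#' Validate calibration curves against precision/accuracy criteria
#'
#' Pools back-calculated replicate concentrations across analyses and
#' reports, per nominal level, the precision (%CV = sd/mean x 100) and
#' accuracy (%RE = percent deviation of the mean from nominal). A level
#' passes when %CV <= `cv_limit` and |%RE| <= `re_limit` (defaults
#' 15/15). The limit of detection is operationalised as the lowest
#' passing level. Levels with a single replicate have undefined %CV and
#' are flagged unevaluable.
#'
#' @param curves A `calibration_curve` or list of them.
#' @param cv_limit,re_limit Acceptance limits in percent.
#' @return List with `levels` (per-level report) and `lod`.
#' @export
validate_curve <- function(curves, cv_limit = 15, re_limit = 15) {
  if (inherits(curves, "calibration_curve")) curves <- list(curves)
  stopifnot(length(curves) >= 1)
  pooled <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(nominal = cv$data$nominal,
               back_calculated = cv$data$back_calculated)
  }))
  report <- do.call(rbind, lapply(
    split(pooled, pooled$nominal), function(d) {
      b <- d$back_calculated
      nom <- d$nominal[1]
      cv <- if (length(b) > 1) stats::sd(b) / mean(b) * 100 else NA_real_
      re <- (mean(b) - nom) / nom * 100
      data.frame(nominal = nom, n = length(b),
                 mean_back = mean(b), cv = cv, re = re,
                 evaluable = length(b) > 1,
                 pass = length(b) > 1 && cv <= cv_limit && abs(re) <= re_limit)
    }))
  report <- report[order(report$nominal), ]
  rownames(report) <- NULL
  passing <- report$nominal[report$pass]
  list(levels = report,
       lod = if (length(passing)) min(passing) else NA_real_,
       cv_limit = cv_limit, re_limit = re_limit)
}

#' Convert concentration to amount per protein mass
#'
#' fmol/uL times the reconstitution volume (uL per 100 ug of digested
#' protein) gives fmol per 100 ug total protein. The default 30 uL is
#' the assay's reconstitution volume.
#'
#' @param concentration fmol/uL.
#' @param reconstitution_volume uL per 100 ug digest; must be positive.
#' @return fmol/100 ug total protein.
#' @examples
#' convert_to_per_protein(7.6)   # 228
#' convert_to_per_protein(13.5)  # 405
#' @export
convert_to_per_protein <- function(concentration, reconstitution_volume = 30) {
  if (reconstitution_volume <= 0) {
    stop("reconstitution volume must be positive")
  }
  concentration * reconstitution_volume
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact two-sided p by enumeration when the combined sample size is at
#' most 12 and there are no ties; normal approximation with tie
#' correction (and continuity correction) otherwise.
#'
#' @param group_a,group_b Numeric vectors, each with >= 2 observations.
#' @return List with `statistic` (W) and `p.value`.
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least two observations")
  }
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- (length(group_a) + length(group_b)) <= 12 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}

#' Quantify a sample from its chromatograms
#'
#' End-to-end ratio-to-heavy quantitation: integrate light and heavy
#' transition peaks, form the light:heavy ratio over the selected
#' fragments, score spectral identity (rdotp of light vs heavy
#' per-fragment areas), back-calculate concentration from the
#' calibration curve, and convert to fmol/100 ug. The verdict is
#' "not detected" when no light signal is present or the back-calculated
#' concentration falls below the LOD; the rdotp gate downgrades
#' identity per [rdotp_verdict()].
#'
#' @param chromatograms A `chromatogram_set` containing light and heavy
#'   channels.
#' @param curve A [fit_calibration()] curve.
#' @param fragments Fragment names used for the ratio (default: all
#'   present in both channels).
#' @param lod Limit of detection (fmol/uL) from [validate_curve()];
#'   `NA` disables the LOD gate.
#' @param reconstitution_volume uL per 100 ug digest.
#' @param window Optional integration window.
#' @param coelution_tol Maximum allowed light/heavy apex separation
#'   (min) before a co-elution warning.
#' @return List of class `"quant_result"`: `ratio`, `rdotp`,
#'   `concentration` (fmol/uL), `amount_per_100ug`, `verdict`.
#' @export
quantify_sample <- function(chromatograms, curve, fragments = NULL,
                            lod = NA_real_, reconstitution_volume = 30,
                            window = NULL, coelution_tol = 0.05) {
  areas <- integrate_channels(chromatograms, window = window)
  light <- areas[areas$label == "light", ]
  heavy <- areas[areas$label == "heavy", ]
  if (!nrow(heavy) || sum(heavy$area) <= 0) {
    stop("no internal standard signal: heavy channels missing or empty")
  }
  la <- stats::setNames(light$area, light$fragment)
  ha <- stats::setNames(heavy$area, heavy$fragment)
  if (is.null(fragments)) fragments <- intersect(names(la), names(ha))
  if (sum(la[fragments]) <= 0) {
    return(structure(list(ratio = 0, rdotp = NA_real_,
                          concentration = 0, amount_per_100ug = 0,
                          verdict = "not detected"),
                     class = "quant_result"))
  }
  rt_sep <- max(abs(light$apex_rt[match(fragments, light$fragment)] -
                    heavy$apex_rt[match(fragments, heavy$fragment)]))
  if (is.finite(rt_sep) && rt_sep > coelution_tol) {
    warning(sprintf("light/heavy apex separation %.3f min exceeds %.2f min",
                    rt_sep, coelution_tol))
  }
  ratio <- light_heavy_ratio(la, ha, fragments)
  score <- rdotp(unname(la[fragments]), unname(ha[fragments]))
  conc <- as.numeric(back_calculate(curve, ratio))
  near_lod <- !is.na(lod) && conc <= 2 * lod
  verdict <- rdotp_verdict(score, near_lod = near_lod)
  if (!is.na(lod) && conc < lod) verdict <- "not detected"
  if (verdict == "not identified") verdict <- "not detected"
  structure(list(ratio = ratio, rdotp = score, concentration = conc,
                 amount_per_100ug = convert_to_per_protein(
                   conc, reconstitution_volume),
                 verdict = verdict),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf(
    "<quant_result> ratio %.4g, rdotp %.3f, %.3g fmol/uL (%.3g fmol/100ug) [%s]\n",
    x$ratio, x$rdotp, x$concentration, x$amount_per_100ug, x$verdict))
  invisible(x)
}

#' Process a simulated calibration series into validated curves
#'
#' Integrates every injection of a [simulate_calibration_series()]
#' output, forms light:heavy ratios, fits one weighted curve per
#' analysis, and validates pooled levels.
#'
#' @param series Output of [simulate_calibration_series()].
#' @param weighting Passed to [fit_calibration()].
#' @param cv_limit,re_limit Passed to [validate_curve()].
#' @return List with `curves`, `validation`, and the per-injection
#'   `ratios` table.
#' @export
process_calibration <- function(series, weighting = "1/x",
                                cv_limit = 15, re_limit = 15) {
  cal <- series[series$level == "cal", ]
  ratios <- do.call(rbind, lapply(seq_len(nrow(cal)), function(i) {
    areas <- integrate_channels(cal$chromatogram[[i]])
    la <- stats::setNames(areas$area[areas$label == "light"],
                          areas$fragment[areas$label == "light"])
    ha <- stats::setNames(areas$area[areas$label == "heavy"],
                          areas$fragment[areas$label == "heavy"])
    data.frame(analysis = cal$analysis[i], nominal = cal$nominal[i],
               replicate = cal$replicate[i],
               ratio = light_heavy_ratio(la, ha))
  }))
  curves <- lapply(split(ratios, ratios$analysis), function(d) {
    fit_calibration(d$nominal, d$ratio, weighting = weighting,
                    analysis = d$analysis[1])
  })
  list(curves = curves,
       validation = validate_curve(curves, cv_limit, re_limit),
       ratios = ratios)
}
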