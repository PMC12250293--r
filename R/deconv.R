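# Paralog deconvolution: estimate the proportion of paralog A in the PCR
# product pool from marker positions, correct paralog-specific CpG
# methylation by that proportion, substitute readings beyond the limits of
# quantification, and tier the result's reliability.

#' Analysis parameters
#'
#' Reporting and reliability parameters for pyrosequencing analysis. Readings
#' at or below `lloq` (default 5.00%) are substituted with `lloq_default`
#' (2.50%); readings at or above `uloq` (95.00%) with `uloq_default` (97.50%).
#' Reliability tiers cut at a paralog proportion of 80% and 90%; the
#' boundaries 80 and 90 belong to the moderate band.
#'
#' @param lloq,uloq Lower/upper limits of quantification (percent).
#' @param lloq_default,uloq_default Substitution values (percent).
#' @param reliability_low,reliability_high Tier cutpoints (percent).
#' @param loq_on_markers Apply the LOQ substitution to the marker nucleotide
#'   fractions when *reporting* the paralog proportion (default TRUE). The
#'   correction of CpG levels always uses the raw proportion.
#' @param quality_thresholds Named vector passed to [assess_quality()].
#' @return Object of class `analysis_params`.
#' @export
analysis_params <- function(lloq = 5.00, uloq = 95.00,
                            lloq_default = 2.50, uloq_default = 97.50,
                            reliability_low = 80, reliability_high = 90,
                            loq_on_markers = TRUE,
                            quality_thresholds = c(failed = 0.1, check = 0.3)) {
  stopifnot(lloq < uloq, lloq_default < lloq, uloq_default > uloq,
            reliability_low < reliability_high)
  structure(list(lloq = lloq, uloq = uloq,
                 lloq_default = lloq_default, uloq_default = uloq_default,
                 reliability_low = reliability_low,
                 reliability_high = reliability_high,
                 loq_on_markers = isTRUE(loq_on_markers),
                 quality_thresholds = quality_thresholds),
            class = "analysis_params")
}

#' Limit-of-quantification substitution
#'
#' Values at or below the LLOQ are replaced by the lower default, values at
#' or above the ULOQ by the upper default; everything else is unchanged.
#' Idempotent; `NA` values pass through.
#'
#' @param value Numeric vector of percentages in \[0, 100\].
#' @param params An [analysis_params()] object.
#' @return Substituted values.
#' @export
#' @examples
#' apply_loq(c(4, 50, 96))  # 2.5 50 97.5
apply_loq <- function(value, params = analysis_params()) {
  ok <- is.na(value) | (value >= 0 & value <= 100)
  if (!all(ok))
    stop("values outside [0, 100] cannot be LOQ-substituted", call. = FALSE)
  out <- value
  out[!is.na(value) & value <= params$lloq] <- params$lloq_default
  out[!is.na(value) & value >= params$uloq] <- params$uloq_default
  out
}

#' Estimate the paralog-A proportion from marker positions
#'
#' The fraction of the A-specific base at each A marker estimates the
#' proportion of paralog A directly; the fraction of the B-specific base at
#' each B marker estimates it as its complement. The default combination is
#' the unweighted mean of the two (symmetric and unbiased under equal marker
#' noise); single-marker estimates are available via `method`.
#'
#' @param pyrogram A pyrogram.
#' @param positions Variable-position map from [map_dispensation_positions()].
#' @param method `"mean"` (default), `"marker_a"` or `"marker_b"`.
#' @return Object of class `paralog_proportion`: list with `p_a` (percent,
#'   raw, no LOQ substitution), `f_marker_a`, `f_marker_b`, `method`.
#' @export
estimate_paralog_proportion <- function(pyrogram, positions,
                                        method = c("mean", "marker_a", "marker_b")) {
  method <- match.arg(method)
  stopifnot(inherits(positions, "variable_positions"))
  mk <- positions[positions$kind == "paralog_marker" & positions$usable, ,
                  drop = FALSE]
  if (nrow(mk) == 0L)
    stop("deconvolution impossible: no usable paralog marker positions",
         call. = FALSE)
  frac <- function(side) {
    sub <- mk[mk$marker_for == side, , drop = FALSE]
    if (nrow(sub) == 0L) return(NA_real_)
    mean(vapply(seq_len(nrow(sub)), function(i)
      peak_fraction(pyrogram, sub$variant_slots[[i]], sub$reference_slots[[i]]),
      numeric(1)))
  }
  f_a <- frac("A")
  f_b <- frac("B")
  p_a <- switch(method,
    mean = {
      comp <- c(f_a, 100 - f_b)
      mean(comp[!is.na(comp)])
    },
    marker_a = {
      if (is.na(f_a)) stop("no usable A marker position", call. = FALSE)
      f_a
    },
    marker_b = {
      if (is.na(f_b)) stop("no usable B marker position", call. = FALSE)
      100 - f_b
    })
  structure(list(p_a = p_a, f_marker_a = f_a, f_marker_b = f_b,
                 method = method),
            class = "paralog_proportion")
}

#' @export
print.paralog_proportion <- function(x, ...) {
  cat(sprintf("paralog A proportion: %.2f%% (marker A: %.2f%%, marker B: %.2f%%, method: %s)\n",
              x$p_a, x$f_marker_a, x$f_marker_b, x$method))
  invisible(x)
}

#' Correct a paralog-specific CpG level by the paralog proportion
#'
#' A CpG private to one paralog is read against the total product pool, so
#' its raw level is diluted by the other paralog. The specific level is
#' `raw * 100 / proportion`, clipped to 100 (values above 100, possible under
#' noise, are clipped and flagged via the `"clipped"` attribute).
#'
#' @param raw_percent Raw methylation percent(s).
#' @param proportion_percent Proportion (percent, > 0) of the paralog the
#'   CpG belongs to.
#' @return Corrected percent(s), with attribute `clipped` (logical vector).
#' @export
#' @examples
#' correct_specific_cpg(45, 90)  # 50
correct_specific_cpg <- function(raw_percent, proportion_percent) {
  if (length(proportion_percent) != 1L || is.na(proportion_percent) ||
      proportion_percent <= 0)
    stop("correction undefined: paralog proportion must be > 0", call. = FALSE)
  val <- raw_percent * 100 / proportion_percent
  clipped <- !is.na(val) & val > 100
  val[clipped] <- 100
  structure(val, clipped = clipped)
}

#' Reliability tier of a deconvolution
#'
#' Below a paralog-A proportion of 80% only paralog-specific CpGs are
#' reliable (`"specific_only"`); between 80% and 90% (inclusive) the result
#' is `"moderate"`; above 90% shared CpGs may be attributed to paralog A
#' (`"full"`).
#'
#' @param proportion A [estimate_paralog_proportion()] result or a numeric
#'   percent.
#' @param params An [analysis_params()] object.
#' @return `"specific_only"`, `"moderate"` or `"full"`.
#' @export
#' @examples
#' classify_reliability(51.2)  # "specific_only"
classify_reliability <- function(proportion, params = analysis_params()) {
  p <- if (inherits(proportion, "paralog_proportion")) proportion$p_a
       else as.numeric(proportion)
  if (p < params$reliability_low) "specific_only"
  else if (p <= params$reliability_high) "moderate"
  else "full"
}

#' Full paralog-aware methylation profile from a pyrogram
#'
#' Pipeline: raw per-CpG quantification, paralog proportion estimate,
#' correction of paralog-specific CpGs (A-specific by `p_a`, B-specific by
#' `100 - p_a`), reliability masking of shared CpGs (reported uncorrected only
#' at the `"full"` tier, otherwise not analyzable because both paralogs are
#' measured simultaneously), and LOQ substitution as the final reporting
#' step. Deterministic.
#'
#' @param pyrogram A pyrogram (or, for assays with several sequencing
#'   primers, a list of pyrograms indexed like the position map's
#'   `seq_primer`).
#' @param positions Variable-position map from [map_dispensation_positions()].
#' @param params An [analysis_params()] object.
#' @return Object of class `methylation_profile`: list with `cpgs` (one row
#'   per CpG position: `specificity`, `cpg_number_a/b`, `raw`, `corrected`
#'   (pre-LOQ; `NA` for masked shared CpGs), `reported` (post-LOQ),
#'   `analyzable`, `quality`), `proportion` (with `p_a_reported` after the
#'   marker LOQ rule and the `tier`), and `params`.
#' @export
build_profile <- function(pyrogram, positions, params = analysis_params()) {
  stopifnot(inherits(positions, "variable_positions"))
  pyr_for <- function(i) {
    if (inherits(pyrogram, "pyrogram")) pyrogram else pyrogram[[i]]
  }
  prop <- NULL
  primers <- sort(unique(positions$seq_primer))
  # markers may sit under any sequencing primer; estimate per primer and pool
  fa <- fb <- numeric(0)
  for (i in primers) {
    sub <- positions[positions$seq_primer == i, , drop = FALSE]
    class(sub) <- class(positions)
    est <- tryCatch(estimate_paralog_proportion(pyr_for(i), sub),
                    error = function(e) NULL)
    if (!is.null(est)) {
      if (!is.na(est$f_marker_a)) fa <- c(fa, est$f_marker_a)
      if (!is.na(est$f_marker_b)) fb <- c(fb, est$f_marker_b)
    }
  }
  if (length(fa) == 0L && length(fb) == 0L)
    stop("deconvolution impossible: no usable paralog marker positions",
         call. = FALSE)
  f_a <- if (length(fa)) mean(fa) else NA_real_
  f_b <- if (length(fb)) mean(fb) else NA_real_
  comp <- c(f_a, 100 - f_b)
  p_a <- mean(comp[!is.na(comp)])
  prop <- structure(list(p_a = p_a, f_marker_a = f_a, f_marker_b = f_b,
                         method = "mean"), class = "paralog_proportion")
  tier <- classify_reliability(prop, params)
  comp_rep <- if (params$loq_on_markers) {
    c(apply_loq(f_a, params), 100 - apply_loq(f_b, params))
  } else comp
  prop$p_a_reported <- mean(comp_rep[!is.na(comp_rep)])
  prop$tier <- tier

  cp_list <- lapply(primers, function(i) {
    sub <- positions[positions$seq_primer == i, , drop = FALSE]
    class(sub) <- class(positions)
    cp <- methylation_from_pyrogram(pyr_for(i), sub)
    cp$quality <- vapply(seq_len(nrow(cp)), function(k)
      assess_quality(pyr_for(i), cp[k, , drop = FALSE],
                     params$quality_thresholds)$level, "")
    cp
  })
  cp <- do.call(rbind, cp_list)

  n <- nrow(cp)
  corrected <- rep(NA_real_, n)
  clipped <- rep(FALSE, n)
  analyzable <- rep(TRUE, n)
  for (k in seq_len(n)) {
    sp <- cp$specificity[k]
    if (sp == "a_specific") {
      v <- correct_specific_cpg(cp$raw[k], p_a)
      corrected[k] <- v
      clipped[k] <- attr(v, "clipped")
    } else if (sp == "b_specific") {
      if (100 - p_a <= 0) {
        analyzable[k] <- FALSE
      } else {
        v <- correct_specific_cpg(cp$raw[k], 100 - p_a)
        corrected[k] <- v
        clipped[k] <- attr(v, "clipped")
      }
    } else {  # shared (or single-region)
      if (sp == "shared" && tier != "full") {
        analyzable[k] <- FALSE  # simultaneous measurement of both paralogs
      } else {
        corrected[k] <- cp$raw[k]
      }
    }
  }
  out <- data.frame(seq_primer = cp$seq_primer,
                    pyrogram_index = cp$pyrogram_index,
                    specificity = cp$specificity,
                    cpg_number_a = cp$cpg_number_a,
                    cpg_number_b = cp$cpg_number_b,
                    raw = cp$raw,
                    corrected = corrected,
                    reported = apply_loq(corrected, params),
                    analyzable = analyzable,
                    clipped = clipped,
                    quality = cp$quality,
                    stringsAsFactors = FALSE)
  structure(list(cpgs = out, proportion = prop, params = params),
            class = "methylation_profile")
}

#' @export
print.methylation_profile <- function(x, ...) {
  cat(sprintf("methylation profile: %d CpG positions, paralog A = %.2f%% (%s tier)\n",
              nrow(x$cpgs), x$proportion$p_a, x$proportion$tier))
  print(x$cpgs[, c("pyrogram_index", "specificity", "cpg_number_a",
                   "cpg_number_b", "raw", "reported", "analyzable")],
        digits = 4)
  invisible(x)
}
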