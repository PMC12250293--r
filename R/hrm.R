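# High-resolution melting (HRM) quantification: curve normalization,
# negative-derivative curves via Savitzky-Golay filtering, per-temperature
# cubic calibration against methylation standards, sample quantification,
# melt-curve simulation and GC-based melt-species attribution.

#' Melt curve container
#'
#' @param temperature Strictly increasing temperature grid (deg C), at least
#'   20 points.
#' @param fluorescence Fluorescence readings, same length.
#' @param sample_id Optional sample label.
#' @return Object of class `melt_curve`.
#' @export
melt_curve <- function(temperature, fluorescence, sample_id = NA_character_) {
  if (length(temperature) < 20L)
    stop("a melt curve needs at least 20 points", call. = FALSE)
  if (length(fluorescence) != length(temperature))
    stop("temperature and fluorescence lengths differ", call. = FALSE)
  if (any(diff(temperature) <= 0))
    stop("temperature grid must be strictly increasing", call. = FALSE)
  structure(list(temperature = as.numeric(temperature),
                 fluorescence = as.numeric(fluorescence),
                 sample_id = sample_id),
            class = "melt_curve")
}

#' HRM analysis parameters
#'
#' @param pre_melt_window,post_melt_window Temperature intervals
#'   `c(lo, hi)` used to fit the upper/lower linear baselines; `NULL`
#'   (default) auto-places 1.0 deg C windows at the curve ends.
#' @param sg_degree Savitzky-Golay polynomial degree (default 3).
#' @param sg_window Savitzky-Golay window length in points (odd, default 11
#'   at 0.1 deg C spacing).
#' @param calibration_window Temperature interval of the per-temperature
#'   calibration, default `c(79.6, 81.6)` deg C.
#' @param calibration_levels Standard methylation levels used for
#'   calibration, default `c(0, 25, 50, 75)` percent (four points determine
#'   the cubic exactly).
#' @param aggregate `"median"` (default, robust to non-invertible
#'   temperatures) or `"mean"` across window temperatures.
#' @return Object of class `hrm_params`.
#' @export
hrm_params <- function(pre_melt_window = NULL, post_melt_window = NULL,
                       sg_degree = 3L, sg_window = 11L,
                       calibration_window = c(79.6, 81.6),
                       calibration_levels = c(0, 25, 50, 75),
                       aggregate = c("median", "mean")) {
  if (sg_window %% 2L != 1L || sg_window <= sg_degree)
    stop("sg_window must be odd and greater than sg_degree", call. = FALSE)
  structure(list(pre_melt_window = pre_melt_window,
                 post_melt_window = post_melt_window,
                 sg_degree = as.integer(sg_degree),
                 sg_window = as.integer(sg_window),
                 calibration_window = calibration_window,
                 calibration_levels = sort(calibration_levels),
                 aggregate = match.arg(aggregate)),
            class = "hrm_params")
}

baseline_windows <- function(curve, params) {
  tr <- range(curve$temperature)
  pre <- params$pre_melt_window %||% c(tr[1], tr[1] + 1.0)
  post <- params$post_melt_window %||% c(tr[2] - 1.0, tr[2])
  list(pre = pre, post = post)
}

fit_line <- function(x, y) {
  if (length(x) < 2L)
    stop("baseline window contains fewer than 2 points", call. = FALSE)
  cf <- coef(lm(y ~ x))
  c(intercept = unname(cf[1]), slope = unname(cf[2]))
}

#' Normalize a melt curve to [0, 1]
#'
#' Fits linear baselines in the pre-melt (fully double-stranded, upper) and
#' post-melt (fully dissociated, lower) windows and rescales
#' `(F - lower(T)) / (upper(T) - lower(T))`, clipped to \[0, 1\]. Invariant
#' under affine transforms of the raw fluorescence.
#'
#' @param raw A [melt_curve()].
#' @param params An [hrm_params()] object.
#' @return Normalized [melt_curve()].
#' @export
normalize_curve <- function(raw, params = hrm_params()) {
  stopifnot(inherits(raw, "melt_curve"))
  w <- baseline_windows(raw, params)
  tt <- raw$temperature
  ff <- raw$fluorescence
  pre_idx <- which(tt >= w$pre[1] & tt <= w$pre[2])
  post_idx <- which(tt >= w$post[1] & tt <= w$post[2])
  up <- fit_line(tt[pre_idx], ff[pre_idx])
  lo <- fit_line(tt[post_idx], ff[post_idx])
  upper <- up["intercept"] + up["slope"] * tt
  lower <- lo["intercept"] + lo["slope"] * tt
  denom <- upper - lower
  if (any(denom <= .Machine$double.eps * 100))
    stop("degenerate melt curve: upper and lower baselines coincide",
         call. = FALSE)
  norm <- pmin(1, pmax(0, (ff - lower) / denom))
  melt_curve(tt, norm, raw$sample_id)
}

#' Negative derivative melt curve (-dF/dT)
#'
#' Savitzky-Golay smoothed first derivative (degree `sg_degree`, window
#' `sg_window`), negated so that melting transitions appear as peaks. Length
#' matches the input; edges are handled by the filter's least-squares end
#' rules.
#'
#' @param curve A [melt_curve()].
#' @param params An [hrm_params()] object.
#' @return A [melt_curve()] whose `fluorescence` holds `-dF/dT`.
#' @export
neg_derivative <- function(curve, params = hrm_params()) {
  stopifnot(inherits(curve, "melt_curve"))
  n <- length(curve$temperature)
  if (params$sg_window > n)
    stop("sg_window larger than the curve", call. = FALSE)
  dt <- mean(diff(curve$temperature))
  d <- signal::sgolayfilt(curve$fluorescence, p = params$sg_degree,
                          n = params$sg_window, m = 1L, ts = dt)
  melt_curve(curve$temperature, -d, curve$sample_id)
}

#' Local maxima of a derivative melt curve
#'
#' Simple peak finder: points higher than both neighbours and above
#' `min_height` times the global maximum.
#'
#' @param curve A derivative [melt_curve()].
#' @param min_height Relative height threshold (default 0.2).
#' @return data.frame with `temperature` and `height`, sorted by height.
#' @export
find_melt_peaks <- function(curve, min_height = 0.2) {
  y <- curve$fluorescence
  n <- length(y)
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  idx <- idx[y[idx] >= min_height * max(y)]
  out <- data.frame(temperature = curve$temperature[idx], height = y[idx])
  out[order(-out$height), , drop = FALSE]
}

#' Fit a per-temperature cubic calibration from methylation standards
#'
#' For every temperature on the grid inside the calibration window, fits the
#' unique cubic through the four (normalized fluorescence, methylation level)
#' points of the standards. Temperatures where two standards have practically
#' identical fluorescence (non-invertible) are excluded; if all temperatures
#' are excluded, an error is raised.
#'
#' @param standards Named list of [melt_curve()]s; names are the standard
#'   levels in percent and must match `params$calibration_levels`
#'   (default 0, 25, 50, 75). Curves must share one temperature grid.
#' @param params An [hrm_params()] object.
#' @return Object of class `calibration_model`: list with `temperature`,
#'   `coefficients` (4 x n matrix of cubic coefficients, constant first),
#'   `levels`, `excluded`.
#' @export
fit_calibration <- function(standards, params = hrm_params()) {
  levels <- params$calibration_levels
  nm <- suppressWarnings(as.numeric(names(standards)))
  if (length(standards) != length(levels) || anyNA(nm) ||
      !isTRUE(all.equal(sort(nm), levels)))
    stop("standards must be named by level and match calibration_levels (",
         paste(levels, collapse = "/"), ")", call. = FALSE)
  standards <- standards[order(nm)]
  grids <- lapply(standards, function(s) s$temperature)
  if (!all(vapply(grids[-1], function(g)
    isTRUE(all.equal(g, grids[[1]])), logical(1))))
    stop("standards must share one temperature grid", call. = FALSE)
  norm <- lapply(standards, normalize_curve, params = params)
  tt <- grids[[1]]
  keep <- which(tt >= params$calibration_window[1] &
                tt <= params$calibration_window[2])
  if (length(keep) == 0L)
    stop("calibration window contains no grid temperatures", call. = FALSE)
  fmat <- vapply(norm, function(cv) cv$fluorescence[keep],
                 numeric(length(keep)))  # temps x levels
  coefs <- matrix(NA_real_, 4L, length(keep))
  excl <- logical(length(keep))
  for (k in seq_along(keep)) {
    x <- fmat[k, ]
    if (min(dist(x)) < 1e-9) {
      excl[k] <- TRUE
      next
    }
    v <- outer(x, 0:3, `^`)
    coefs[, k] <- solve(v, levels)
  }
  if (all(excl))
    stop("calibration impossible: all window temperatures non-invertible",
         call. = FALSE)
  structure(list(temperature = tt[keep][!excl],
                 coefficients = coefs[, !excl, drop = FALSE],
                 levels = levels,
                 excluded = tt[keep][excl],
                 params = params),
            class = "calibration_model")
}

#' Quantify a sample against an HRM calibration
#'
#' Normalizes the sample curve, evaluates each per-temperature cubic at the
#' sample's normalized fluorescence and aggregates across the calibration
#' window (median by default). Estimates are clipped to \[0, 100\].
#'
#' @param curve Sample [melt_curve()]; must cover the calibration window.
#' @param model A [fit_calibration()] result.
#' @param params An [hrm_params()] object (normalization settings must match
#'   those used for the standards).
#' @return List with `estimate` (percent) and `per_temperature`
#'   (data.frame `temperature`, `estimate`).
#' @export
quantify_sample <- function(curve, model, params = hrm_params()) {
  stopifnot(inherits(model, "calibration_model"))
  norm <- normalize_curve(curve, params)
  if (min(curve$temperature) > min(model$temperature) ||
      max(curve$temperature) < max(model$temperature))
    stop("sample curve does not cover the calibration window", call. = FALSE)
  x <- approx(norm$temperature, norm$fluorescence,
              xout = model$temperature)$y
  est <- vapply(seq_along(x), function(k)
    sum(model$coefficients[, k] * x[k]^(0:3)), numeric(1))
  est <- pmin(100, pmax(0, est))
  agg <- switch(params$aggregate, median = median(est), mean = mean(est))
  list(estimate = agg,
       per_temperature = data.frame(temperature = model$temperature,
                                    estimate = est))
}

#' Simulate a melt curve from a mixture of melt species
#'
#' Two-state melting per species: the double-stranded fraction at temperature
#' T is `logistic((tm - T) / width)`; the curve is the weighted sum over
#' species, mapped between linear lower and upper baselines, plus seeded
#' Gaussian noise.
#'
#' @param species data.frame with columns `label`, `tm` (deg C), `gc_percent`
#'   (optional) and `weight` (fractions summing to 1).
#' @param baselines List with `upper` and `lower`, each `c(intercept, slope)`
#'   in fluorescence units; defaults to flat 1 and 0.
#' @param noise_sd Gaussian noise SD (default 0).
#' @param seed Optional integer seed.
#' @param grid Temperature grid (default 65-95 deg C in 0.1 steps).
#' @param width Transition width in deg C (default 0.35).
#' @param sample_id Sample label.
#' @return A [melt_curve()].
#' @export
simulate_melt <- function(species, baselines = list(upper = c(1, 0),
                                                    lower = c(0, 0)),
                          noise_sd = 0, seed = NULL,
                          grid = seq(65, 95, by = 0.1), width = 0.35,
                          sample_id = NA_character_) {
  if (abs(sum(species$weight) - 1) > 1e-9)
    stop("species weights must sum to 1", call. = FALSE)
  frac <- rep(0, length(grid))
  for (s in seq_len(nrow(species))) {
    frac <- frac + species$weight[s] * plogis((species$tm[s] - grid) / width)
  }
  upper <- baselines$upper[1] + baselines$upper[2] * grid
  lower <- baselines$lower[1] + baselines$lower[2] * grid
  f <- lower + (upper - lower) * frac
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    f <- f + rnorm(length(grid), 0, noise_sd)
  }
  melt_curve(grid, f, sample_id)
}

#' Attribute observed melting peaks to candidate species
#'
#' Assigns each observed melting temperature to the nearest candidate, after
#' removing candidates excluded by other evidence (e.g. transcripts whose
#' expected products were absent). Equidistant candidates leave the peak
#' unresolved rather than guessed. When candidate GC contents are given, the
#' assignment is checked for consistency with the expectation that higher GC
#' melts higher; a discordant candidate table triggers a warning and sets the
#' `gc_consistent` attribute to `FALSE`.
#'
#' @param observed_tms Numeric vector of observed peak temperatures (deg C).
#' @param candidates data.frame with `label`, `tm` and optionally
#'   `gc_percent`.
#' @param exclude Labels to remove before assignment.
#' @param tie_tol Distance difference below which two candidates count as
#'   equidistant (default 1e-6 deg C).
#' @return data.frame with `observed_tm`, `label` (`NA` when unresolved),
#'   `candidate_tm`, `distance`, `resolved`; attribute `gc_consistent`.
#' @export
attribute_species <- function(observed_tms, candidates, exclude = character(0),
                              tie_tol = 1e-6) {
  cand <- candidates[!(candidates$label %in% exclude), , drop = FALSE]
  if (nrow(cand) < 1L) stop("no candidates left after exclusion", call. = FALSE)
  if (anyDuplicated(cand$tm) && is.null(cand$gc_percent))
    stop("candidates must have distinct tm or gc", call. = FALSE)
  gc_consistent <- TRUE
  if (!is.null(cand$gc_percent) && nrow(cand) > 1L) {
    if (any(order(cand$tm) != order(cand$gc_percent))) {
      gc_consistent <- FALSE
      warning("candidate GC order is discordant with melting-temperature order",
              call. = FALSE)
    }
  }
  rows <- lapply(observed_tms, function(tm) {
    d <- abs(cand$tm - tm)
    o <- order(d)
    tie <- nrow(cand) > 1L && abs(d[o[1]] - d[o[2]]) < tie_tol
    if (tie) {
      data.frame(observed_tm = tm, label = NA_character_,
                 candidate_tm = NA_real_, distance = d[o[1]],
                 resolved = FALSE, stringsAsFactors = FALSE)
    } else {
      data.frame(observed_tm = tm, label = cand$label[o[1]],
                 candidate_tm = cand$tm[o[1]], distance = d[o[1]],
                 resolved = TRUE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "gc_consistent") <- gc_consistent
  out
}
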