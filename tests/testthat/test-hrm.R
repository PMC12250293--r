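# HRM: normalization, Savitzky-Golay derivative, per-temperature cubic
# calibration, quantification, melt simulation and species attribution.

test_that("melt_curve validates its grid", {
  expect_error(melt_curve(1:10, 1:10), "20 points")
  expect_error(melt_curve(c(1:19, 19), rep(1, 20)), "strictly increasing")
  expect_error(melt_curve(1:20, 1:19), "lengths differ")
})

test_that("normalization leaves an already-normalized sigmoid unchanged", {
  cv <- level_curve(100)
  norm <- normalize_curve(cv)
  # deviations come only from the logistic tails' residual slope entering
  # the baseline fits
  expect_lt(max(abs(norm$fluorescence - cv$fluorescence)), 1e-5)
})

test_that("normalization is invariant under affine transforms", {
  cv <- level_curve(50)
  aff <- melt_curve(cv$temperature, 3.7 * cv$fluorescence + 11.2, "aff")
  expect_equal(normalize_curve(aff)$fluorescence,
               normalize_curve(cv)$fluorescence, tolerance = 1e-9)
})

test_that("sloped baselines are removed and the melt region is monotone", {
  sp <- data.frame(label = "x", tm = 81, gc_percent = NA, weight = 1)
  raw <- simulate_melt(sp, baselines = list(upper = c(30, -0.15),
                                            lower = c(8, -0.05)),
                       grid = seq(74, 88, by = 0.1))
  norm <- normalize_curve(raw)
  expect_true(all(norm$fluorescence >= 0 & norm$fluorescence <= 1))
  mid <- norm$temperature > 79 & norm$temperature < 83
  expect_true(all(diff(norm$fluorescence[mid]) <= 1e-9))
  # degenerate curve: baselines coincide
  flat <- melt_curve(seq(74, 88, by = 0.1),
                     rep(1, length(seq(74, 88, by = 0.1))))
  expect_error(normalize_curve(flat), "degenerate")
})

test_that("the negative derivative peaks at the melting temperature", {
  sp <- data.frame(label = "x", tm = 81.4, gc_percent = NA, weight = 1)
  cv <- simulate_melt(sp, grid = seq(74, 88, by = 0.1))
  d <- neg_derivative(normalize_curve(cv))
  peak <- find_melt_peaks(d)$temperature[1]
  expect_lte(abs(peak - 81.4), 0.1)
  # a linear curve has a constant derivative
  tt <- seq(70, 90, by = 0.1)
  lin <- melt_curve(tt, 5 - 0.2 * tt)
  dl <- neg_derivative(lin)
  expect_equal(dl$fluorescence, rep(0.2, length(tt)), tolerance = 1e-9)
  # two species five degrees apart give two local maxima
  sp2 <- data.frame(label = c("u", "m"), tm = c(78, 83), gc_percent = NA,
                    weight = c(0.5, 0.5))
  cv2 <- simulate_melt(sp2, grid = seq(71, 90, by = 0.1))
  pk <- find_melt_peaks(neg_derivative(normalize_curve(cv2)))
  expect_gte(nrow(pk), 2L)
  expect_lte(abs(sort(pk$temperature[1:2])[1] - 78), 0.2)
  expect_lte(abs(sort(pk$temperature[1:2])[2] - 83), 0.2)
  expect_error(neg_derivative(lin, hrm_params(sg_window = 2001)), "larger")
})

test_that("calibration reproduces its standard nodes exactly", {
  std <- level_standards()
  model <- fit_calibration(std)
  expect_gt(length(model$temperature), 0)
  for (lev in c(0, 25, 50, 75)) {
    q <- quantify_sample(std[[as.character(lev)]], model)
    expect_equal(q$estimate, lev, tolerance = 1e-6)
    expect_equal(q$per_temperature$estimate,
                 rep(lev, nrow(q$per_temperature)), tolerance = 1e-6)
  }
  expect_error(fit_calibration(std[1:3]), "match calibration_levels")
})

test_that("standards affine in methylation give essentially affine interpolants", {
  model <- fit_calibration(level_standards())
  scale <- max(abs(model$coefficients[1:2, ]))
  expect_lt(max(abs(model$coefficients[3:4, ])) / scale, 1e-3)
})

test_that("held-out levels are recovered from synthetic standards", {
  model <- fit_calibration(level_standards())
  for (lev in seq(10, 90, by = 10)) {
    expect_lt(abs(quantify_sample(level_curve(lev), model)$estimate - lev), 2)
  }
  # a smoothly nonlinear fluorescence-vs-methylation map: within the node
  # span the cubic recovers held-out levels; beyond 75 the call is an
  # extrapolation and only a looser band holds
  modeln <- fit_calibration(level_standards(power = 1.25))
  for (lev in seq(10, 70, by = 10)) {
    expect_lt(abs(quantify_sample(level_curve(lev, power = 1.25),
                                  modeln)$estimate - lev), 2)
  }
  for (lev in c(80, 90)) {
    expect_lt(abs(quantify_sample(level_curve(lev, power = 1.25),
                                  modeln)$estimate - lev), 5)
  }
})

test_that("a noisy low-methylation sample is recovered on average", {
  model <- fit_calibration(level_standards())
  ests <- vapply(1:100, function(s)
    quantify_sample(level_curve(10, noise_sd = 0.01, seed = s),
                    model)$estimate, numeric(1))
  expect_lt(abs(mean(ests) - 10), 5)
})

test_that("melt simulation obeys its two-state model", {
  sp <- data.frame(label = "x", tm = 80, gc_percent = NA, weight = 1)
  cv <- simulate_melt(sp, grid = seq(72, 88, by = 0.1))
  expect_equal(cv$fluorescence[cv$temperature == 80], 0.5, tolerance = 1e-9)
  # a zero-weight species contributes nothing
  sp2 <- data.frame(label = c("x", "y"), tm = c(80, 85), gc_percent = NA,
                    weight = c(1, 0))
  cv2 <- simulate_melt(sp2[sp2$weight > 0, ], grid = seq(72, 88, by = 0.1))
  expect_equal(cv2$fluorescence, cv$fluorescence, tolerance = 1e-12)
  # linearity: an equal mixture is the average of the pure curves
  mix <- simulate_melt(data.frame(label = c("x", "y"), tm = c(78, 84),
                                  gc_percent = NA, weight = c(0.5, 0.5)),
                       grid = seq(72, 88, by = 0.1))
  p1 <- simulate_melt(data.frame(label = "x", tm = 78, gc_percent = NA,
                                 weight = 1), grid = seq(72, 88, by = 0.1))
  p2 <- simulate_melt(data.frame(label = "y", tm = 84, gc_percent = NA,
                                 weight = 1), grid = seq(72, 88, by = 0.1))
  expect_equal(mix$fluorescence, (p1$fluorescence + p2$fluorescence) / 2,
               tolerance = 1e-12)
})

test_that("melt species attribution picks the nearest candidate or abstains", {
  cand <- data.frame(label = c("p15", "p16"), tm = c(88.8, 90.2),
                     gc_percent = c(70.3, 71.6))
  hit <- attribute_species(88.9, cand)
  expect_identical(hit$label, "p15")
  expect_true(hit$resolved)
  expect_true(attr(hit, "gc_consistent"))
  # exclusion removes candidates before assignment
  only <- attribute_species(88.9, cand, exclude = "p15")
  expect_identical(only$label, "p16")
  # equidistant observation stays unresolved
  tie <- attribute_species(89.5, cand)
  expect_false(tie$resolved)
  expect_true(is.na(tie$label))
  # discordant GC ordering is flagged
  bad <- data.frame(label = c("a", "b"), tm = c(88.8, 90.2),
                    gc_percent = c(75, 70))
  expect_warning(res <- attribute_species(89.0, bad), "discordant")
  expect_false(attr(res, "gc_consistent"))
})
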