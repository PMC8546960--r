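test_that("QC rules flag peaks on S/N, ppm and spike-ratio criteria", {
  peaks <- data.frame(metabolite = letters[1:6],
                      h12 = c(100, 100, 600, 100, 15, 100),
                      h13 = c(100, 100, 100, 100, 100, 0),
                      sn = c(2.9, 12, 12, 3, 12, 12),
                      ppm = c(1, 1, 1, 1, 6, 1))
  out <- qc_filter(peaks)
  expect_true(out$sn_fail[1])                 # S/N 2.9 is not > 3
  expect_true(out$sn_fail[4])                 # boundary: exactly 3 fails
  expect_true(out$spike_ratio_fail[3])        # ratio 6 exceeds 5-fold
  expect_true(out$ppm_fail[5])
  expect_true(out$spike_ratio_fail[6])        # zero internal standard
  expect_true(is.na(out$ratio[6]))
  expect_true(out$quantifiable[2])
  expect_error(qc_filter(peaks[, 1:3]), "columns")
})

test_that("relaxing a QC threshold never flags a previously passing peak", {
  set.seed(31)
  peaks <- data.frame(metabolite = sprintf("m%02d", 1:50),
                      h12 = rlnorm(50, log(100), 1),
                      h13 = rlnorm(50, log(100), 1),
                      sn = runif(50, 0, 20), ppm = runif(50, 0, 10))
  strict <- qc_filter(peaks, sn_min = 5, ppm_max = 3, spike_fold = 3)
  lax <- qc_filter(peaks, sn_min = 3, ppm_max = 5, spike_fold = 5)
  expect_true(all(lax$quantifiable[strict$quantifiable]))
})

test_that("calibration curves invert exactly in the noise-free limit", {
  conc <- 50 / 2^(0:6)
  curve <- fit_calibration(conc, 0.1 * conc)
  expect_equal(curve$slope, 0.1)
  expect_equal(curve$intercept, 0)
  inv <- invert_calibration(curve, 2.0)
  expect_equal(inv$conc_uM, 20)
  expect_false(inv$out_of_range)

  # round trip on every standard
  inv_all <- invert_calibration(curve, 0.1 * conc)
  expect_equal(inv_all$conc_uM, conc)

  # ratios mapping above the top standard are flagged, checked against LOQ
  hi <- invert_calibration(curve, 6.0, sn = 12)
  expect_true(hi$out_of_range)
  expect_false(hi$below_loq)
  lo <- invert_calibration(curve, 0.05, sn = 4)
  expect_true(lo$out_of_range)
  expect_true(lo$below_loq)

  expect_error(fit_calibration(rep(1, 5), 1:5), "degenerate|distinct")
})

test_that("noisy calibration recovers the slope within its standard error", {
  set.seed(41)
  conc <- rep(50 / 2^(0:6), 2)
  for (i in 1:10) {
    ratio <- 0.2 * conc + rnorm(14, 0, 0.05)
    curve <- fit_calibration(conc, ratio)
    expect_lt(abs(curve$slope - 0.2), 3 * curve$slope_se)
    # oracle: plain least squares on the same points
    expect_equal(curve$slope, unname(coef(lm(ratio ~ conc))[2]))
  }
})

test_that("biomass normalization reduces to umol/gDCW", {
  # 10 uM in 1 mL extract from 0.01 gDCW: 10 * 0.001 / 0.01 = 1
  expect_equal(normalize_to_biomass(10, 0.001, 0.01), 1.0)
  expect_equal(normalize_to_biomass(0, 0.001, 0.01), 0)
  expect_equal(normalize_to_biomass(10, 0.001, 0.02), 0.5)
  expect_error(normalize_to_biomass(10, 0.001, 0), "> 0")
})

test_that("glog approaches log2 for small offsets and damps near zero", {
  expect_equal(glog(8, a = 1e-12), 3)
  expect_equal(glog(c(2, 4, 8), a = 1e-10), c(1, 2, 3))
  # finite at zero, unlike log2
  expect_true(is.finite(glog(0, a = 0.5)))
})

test_that("SVD imputation reconstructs low-rank structure", {
  set.seed(51)
  u <- rnorm(20); v <- rnorm(8)
  x <- outer(u, v)                      # exactly rank 1
  miss <- matrix(runif(160) < 0.1, 20, 8)
  x_na <- x; x_na[miss] <- NA
  filled <- svd_impute(x_na, rank = 1)
  expect_equal(filled[miss], x[miss], tolerance = 0.05)
  expect_equal(filled[!miss], x[!miss])  # observed entries untouched
  expect_error(svd_impute(rbind(c(NA, NA), c(1, 2))), "entirely missing")
})

test_that("metabolite significance testing flags planted accumulations", {
  set.seed(61)
  mets <- sprintf("m%02d", 1:20)
  truth <- rlnorm(20, log(1), 0.5)
  wt <- matrix(truth, 20, 6) * rlnorm(120, 0, 0.1)
  mult <- rep(1, 20); mult[1:5] <- 3    # five planted 3-fold accumulations
  mut <- matrix(truth * mult, 20, 6) * rlnorm(120, 0, 0.1)
  rownames(wt) <- rownames(mut) <- mets
  res <- test_metabolite_changes(wt, mut)
  expect_true(all(res$significant[1:5]))
  expect_true(all(res$direction[1:5] == 1))
  expect_true(mean(res$significant[6:20]) <= 0.2)   # FDR control, roughly

  # identical groups are never significant
  same <- test_metabolite_changes(wt, wt)
  expect_false(any(same$significant))

  # all-missing metabolites are dropped with a warning
  wt2 <- wt; wt2[1, ] <- NA
  expect_warning(res2 <- test_metabolite_changes(wt2, mut), "all-missing")
  expect_false("m01" %in% res2$metabolite)
})

test_that("full quantification recovers planted concentrations on the noise-free bundle", {
  b <- noise_free_bundle()
  cfg <- b$truth$config
  quant <- quantify_metabolites(b$peaks, b$calibration,
                                cfg$extract_volume, cfg$biomass_gdcw)
  truth <- b$truth$metabolite_conc
  for (s in colnames(truth)) {
    got <- quant[quant$strain == s & quant$bio_rep == 1 &
                   quant$tech_rep == 1, ]
    expect_equal(got$conc_gdcw[match(rownames(truth), got$metabolite)],
                 unname(truth[, s]), tolerance = 1e-9)
  }
})
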