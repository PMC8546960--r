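# Absolute metabolite quantification by 13C isotope dilution.
#
# Samples are spiked with a uniformly 13C-labeled internal standard; the
# 12C/13C peak-height ratio is calibrated against serially diluted 12C
# chemical standards (0.781-50 uM) carrying the same spike, then converted
# to biomass-specific concentrations (umol/gDCW).

#' Quality-control filter for peak measurements
#'
#' A peak is quantifiable iff signal/noise > 3, mass error < 5 ppm and the
#' 12C/13C height ratio lies strictly within (1/5, 5) (sample and internal
#' standard heights differ < 5-fold). A zero internal-standard height is a
#' spike failure. Values outside the calibration range are flagged and, per
#' protocol, individually checked against the limit of quantification
#' (S/N = 10) downstream.
#'
#' @param peaks `data.frame` with columns `metabolite`, `h12`, `h13`, `sn`,
#'   `ppm` (and any replicate bookkeeping columns, carried through).
#' @param sn_min S/N threshold, exclusive (default 3).
#' @param ppm_max ppm-error threshold, exclusive (default 5).
#' @param spike_fold Maximum fold difference of H12 vs H13 (default 5).
#' @return The input with logical columns `sn_fail`, `ppm_fail`,
#'   `spike_ratio_fail`, `quantifiable`, and `ratio` (= h12/h13, NA on
#'   spike failure).
#' @export
qc_filter <- function(peaks, sn_min = 3, ppm_max = 5, spike_fold = 5) {
  need <- c("metabolite", "h12", "h13", "sn", "ppm")
  stop_if(!all(need %in% names(peaks)),
          "peaks needs columns: %s", paste(need, collapse = ", "))
  stop_if(any(peaks$h12 < 0 | peaks$h13 < 0), "peak heights must be >= 0")
  peaks$sn_fail <- !(peaks$sn > sn_min)
  peaks$ppm_fail <- !(peaks$ppm < ppm_max)
  ratio <- ifelse(peaks$h13 > 0, peaks$h12 / peaks$h13, NA_real_)
  peaks$spike_ratio_fail <- is.na(ratio) |
    !(ratio > 1 / spike_fold & ratio < spike_fold)
  peaks$ratio <- ratio
  peaks$quantifiable <- !(peaks$sn_fail | peaks$ppm_fail |
                            peaks$spike_ratio_fail)
  peaks
}

#' Fit a calibration curve for one metabolite
#'
#' Least-squares line of 12C/13C height ratio versus standard concentration
#' (uM). The declared range (default 0.781-50 uM) bounds where inversion is
#' interpolation; outside it results are flagged.
#'
#' @param conc Standard concentrations (uM), >= 3 distinct values.
#' @param ratio Observed height ratios at those standards.
#' @param range Calibration range `c(lo, hi)` in uM (default
#'   `c(0.781, 50)`).
#' @return Object of class `calibration_curve`: `slope`, `intercept`,
#'   `r_squared`, `slope_se`, `range`, `n`.
#' @export
fit_calibration <- function(conc, ratio, range = c(0.781, 50)) {
  stop_if(length(conc) != length(ratio), "conc and ratio lengths differ")
  stop_if(length(unique(conc)) < 3L, "need >= 3 distinct standards")
  stop_if(stats::var(conc) == 0, "degenerate standards (zero variance)")
  fit <- stats::lm(ratio ~ conc)
  sm <- suppressWarnings(summary(fit))  # silence exact-fit notes
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 slope_se = sm$coefficients[2, 2],
                 range = range, n = length(conc)),
            class = "calibration_curve")
}

#' Invert a calibration curve
#'
#' Maps sample height ratios to concentrations (uM):
#' `(ratio - intercept) / slope`. Ratios mapping outside the calibration
#' range are flagged `out_of_range` (extrapolation); per protocol these are
#' then individually checked against the LOQ (S/N = 10).
#'
#' @param curve A [fit_calibration()] object.
#' @param ratio Sample height ratios.
#' @param sn Optional S/N values for the LOQ check of out-of-range peaks.
#' @param loq_sn LOQ signal-to-noise (default 10).
#' @return `data.frame`: `conc_uM`, `out_of_range`, `below_loq` (NA when
#'   in range or `sn` missing).
#' @export
invert_calibration <- function(curve, ratio, sn = NULL, loq_sn = 10) {
  stop_if(curve$slope == 0, "flat calibration curve cannot be inverted")
  conc <- (ratio - curve$intercept) / curve$slope
  oor <- conc < curve$range[1] | conc > curve$range[2]
  below <- rep(NA, length(conc))
  if (!is.null(sn)) below[oor] <- sn[oor] < loq_sn
  data.frame(conc_uM = conc, out_of_range = oor, below_loq = below)
}

#' Biomass normalization of extract concentrations
#'
#' `umol/gDCW = conc (uM = umol/L) * extract volume (L) / biomass (gDCW)`.
#'
#' @param conc_uM Extract concentration, uM.
#' @param extract_volume Extraction volume in liters, > 0.
#' @param biomass_gdcw Harvested biomass, g dry cell weight, > 0.
#' @return Concentration in umol/gDCW.
#' @export
normalize_to_biomass <- function(conc_uM, extract_volume, biomass_gdcw) {
  assert_number(extract_volume, "extract_volume", lower = 0,
                strict_lower = TRUE)
  assert_number(biomass_gdcw, "biomass_gdcw", lower = 0, strict_lower = TRUE)
  conc_uM * extract_volume / biomass_gdcw
}

#' Generalized log transform
#'
#' `glog(x) = log2((x + sqrt(x^2 + a^2)) / 2)`; as `a -> 0` this approaches
#' `log2(x)`, while damping the variance of near-zero values.
#'
#' @param x Numeric vector/matrix.
#' @param a Offset; by default the minimum positive finite value of `x`.
#' @return Transformed values.
#' @export
glog <- function(x, a = NULL) {
  if (is.null(a)) {
    pos <- x[is.finite(x) & x > 0]
    a <- if (length(pos)) min(pos) else 1
  }
  log2((x + sqrt(x^2 + a^2)) / 2)
}

#' Impute missing values by iterative truncated SVD
#'
#' Missing entries are initialized at row means and refined by repeatedly
#' reconstructing the matrix from its leading `rank` singular components
#' until the imputed entries change by less than `tol` (relative Frobenius
#' norm).
#'
#' @param x Numeric matrix (features x observations) with `NA` gaps.
#' @param rank Reconstruction rank (default 2).
#' @param tol Convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 200).
#' @return The completed matrix.
#' @export
svd_impute <- function(x, rank = 2L, tol = 1e-6, max_iter = 200L) {
  x <- as.matrix(x)
  miss <- is.na(x)
  if (!any(miss)) return(x)
  stop_if(any(rowSums(!miss) == 0L), "a row is entirely missing")
  rank <- min(rank, dim(x) - 1L)
  rank <- max(rank, 1L)
  filled <- x
  rm_ <- rowMeans(x, na.rm = TRUE)
  filled[miss] <- rm_[row(x)[miss]]
  for (i in seq_len(max_iter)) {
    s <- svd(filled, nu = rank, nv = rank)
    recon <- s$u %*% (s$d[seq_len(rank)] * t(s$v))
    new <- filled
    new[miss] <- recon[miss]
    delta <- sqrt(sum((new[miss] - filled[miss])^2)) /
      max(sqrt(sum(filled[miss]^2)), .Machine$double.eps)
    filled <- new
    if (delta < tol) break
  }
  filled
}

#' Significance testing of metabolite changes
#'
#' Biomass-normalized concentrations are g-log transformed, missing values
#' imputed by [svd_impute()], then each metabolite is tested mutant vs wild
#' type with a two-sided unpaired t-test; Benjamini-Hochberg FDR across
#' metabolites; significant at FDR < `alpha`. Replicate columns (3
#' biological x 2 technical, n = 6) all enter the test.
#'
#' @param wt,mutant Numeric matrices metabolite x replicate (same rownames)
#'   of concentrations in umol/gDCW; `NA` allowed.
#' @param alpha FDR threshold (default 0.05).
#' @param impute_rank Rank for [svd_impute()] (default 2).
#' @return `data.frame` per metabolite: `metabolite`, `mean_wt`,
#'   `mean_mutant`, `log2_change` (of means on the raw scale), `t`, `p`,
#'   `fdr`, `significant`, `direction` (+1/-1).
#' @export
test_metabolite_changes <- function(wt, mutant, alpha = 0.05,
                                    impute_rank = 2L) {
  stop_if(!identical(rownames(wt), rownames(mutant)),
          "wt and mutant must cover the same metabolites")
  all_missing <- rowSums(!is.na(wt)) == 0 | rowSums(!is.na(mutant)) == 0
  if (any(all_missing)) {
    warning("dropping all-missing metabolites: ",
            paste(rownames(wt)[all_missing], collapse = ", "))
    wt <- wt[!all_missing, , drop = FALSE]
    mutant <- mutant[!all_missing, , drop = FALSE]
  }
  stop_if(nrow(wt) == 0L, "no metabolites left to test")
  comb <- cbind(wt, mutant)
  gl <- glog(comb)
  if (any(is.na(gl))) gl <- svd_impute(gl, rank = impute_rank)
  iw <- seq_len(ncol(wt))
  res <- lapply(seq_len(nrow(gl)), function(i) {
    a <- gl[i, iw]; b <- gl[i, -iw]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      tt <- list(statistic = c(t = 0),
                 p.value = if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    } else {
      tt <- stats::t.test(b, a, var.equal = FALSE)
    }
    data.frame(metabolite = rownames(gl)[i],
               mean_wt = mean(wt[i, ], na.rm = TRUE),
               mean_mutant = mean(mutant[i, ], na.rm = TRUE),
               log2_change = log2(mean(mutant[i, ], na.rm = TRUE) /
                                    mean(wt[i, ], na.rm = TRUE)),
               t = unname(tt$statistic), p = tt$p.value)
  })
  out <- do.call(rbind, res)
  out$fdr <- benjamini_hochberg(out$p)
  out$significant <- out$fdr < alpha
  out$direction <- sign(out$mean_mutant - out$mean_wt)
  out
}

#' Quantify a full peak table against its calibration standards
#'
#' Runs QC, fits one calibration curve per metabolite, inverts sample
#' ratios and normalizes to biomass. Non-quantifiable peaks yield `NA`
#' concentrations.
#'
#' @param peaks `data.frame` with columns `metabolite`, `strain`,
#'   `bio_rep`, `tech_rep`, `h12`, `h13`, `sn`, `ppm`.
#' @param calibration `data.frame` with columns `metabolite`, `conc_uM`,
#'   `ratio`.
#' @param extract_volume Extraction volume (L).
#' @param biomass_gdcw Harvested biomass (gDCW) per sample.
#' @param range Calibration range (uM).
#' @return The peak table with added `conc_uM`, `out_of_range`,
#'   `below_loq`, `conc_gdcw` columns.
#' @export
quantify_metabolites <- function(peaks, calibration, extract_volume,
                                 biomass_gdcw, range = c(0.781, 50)) {
  peaks <- qc_filter(peaks)
  peaks$conc_uM <- NA_real_
  peaks$out_of_range <- NA
  peaks$below_loq <- NA
  for (m in unique(peaks$metabolite)) {
    cal <- calibration[calibration$metabolite == m, ]
    stop_if(nrow(cal) == 0L, "no calibration standards for '%s'", m)
    curve <- fit_calibration(cal$conc_uM, cal$ratio, range = range)
    sel <- peaks$metabolite == m & peaks$quantifiable
    if (!any(sel)) next
    inv <- invert_calibration(curve, peaks$ratio[sel], sn = peaks$sn[sel])
    peaks$conc_uM[sel] <- inv$conc_uM
    peaks$out_of_range[sel] <- inv$out_of_range
    peaks$below_loq[sel] <- inv$below_loq
  }
  peaks$conc_gdcw <- normalize_to_biomass(peaks$conc_uM, extract_volume,
                                          biomass_gdcw)
  peaks
}
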