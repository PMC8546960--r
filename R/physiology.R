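# Growth physiology: growth rates, biomass, uptake/secretion rates, yields.

#' Fit an exponential growth rate from an OD time course
#'
#' Ordinary least-squares slope of `ln(OD600)` versus time (h) over the
#' exponential window, the standard estimator for balanced growth.
#'
#' @param time Numeric vector of times (h).
#' @param od Numeric vector of OD600 readings, strictly positive.
#' @param window Optional `c(t_min, t_max)` bounds of the exponential phase;
#'   `NULL` (default) uses all points. Use [find_exponential_window()] for an
#'   automatic choice.
#' @return A list with `lambda` (1/h), `se`, `r_squared`, `n`, `od0`
#'   (back-extrapolated OD at t = 0 of the window fit).
#' @export
fit_growth_rate <- function(time, od, window = NULL) {
  stop_if(length(time) != length(od), "'time' and 'od' lengths differ")
  stop_if(any(!is.finite(od)) || any(od <= 0),
          "all OD values must be finite and > 0")
  if (!is.null(window)) {
    keep <- time >= window[1] & time <= window[2]
    time <- time[keep]; od <- od[keep]
  }
  stop_if(length(time) < 3L, "need at least 3 points in the window")
  fit <- stats::lm(log(od) ~ time)
  sm <- suppressWarnings(summary(fit))  # silence exact-fit notes
  list(lambda = unname(stats::coef(fit)[2]),
       se = sm$coefficients[2, 2],
       r_squared = sm$r.squared,
       n = length(time),
       od0 = exp(unname(stats::coef(fit)[1])))
}

#' Pick the exponential-phase window automatically
#'
#' Scans contiguous sub-series (>= `min_points` points) and returns the time
#' bounds of the longest span whose `ln(OD)`-vs-time fit has
#' R^2 >= `r2_min`.
#'
#' @param time,od As in [fit_growth_rate()].
#' @param r2_min Minimum R^2 of the log-linear fit (default 0.99).
#' @param min_points Minimum number of points in a window (default 4).
#' @return `c(t_min, t_max)`, or an error if no window qualifies.
#' @export
find_exponential_window <- function(time, od, r2_min = 0.99, min_points = 4L) {
  stop_if(any(od <= 0), "all OD values must be > 0")
  ord <- order(time); time <- time[ord]; od <- od[ord]
  n <- length(time)
  stop_if(n < min_points, "fewer than %d points", min_points)
  best <- NULL; best_len <- -Inf
  for (i in seq_len(n - min_points + 1L)) {
    for (j in seq(i + min_points - 1L, n)) {
      r2 <- suppressWarnings(
        summary(stats::lm(log(od[i:j]) ~ time[i:j])))$r.squared
      span <- time[j] - time[i]
      if (r2 >= r2_min && span > best_len) {
        best <- c(time[i], time[j]); best_len <- span
      }
    }
  }
  stop_if(is.null(best), "no window reaches R^2 >= %g", r2_min)
  best
}

#' Convert OD600 to biomass concentration
#'
#' @param od OD600 reading(s), >= 0.
#' @param dcw_factor Gram dry cell weight per liter per OD unit
#'   (default 0.44).
#' @return Biomass in g DCW / L.
#' @export
od_to_dcw <- function(od, dcw_factor = 0.44) {
  stop_if(any(od < 0), "OD must be >= 0")
  assert_number(dcw_factor, "dcw_factor", lower = 0, strict_lower = TRUE)
  od * dcw_factor
}

#' Biomass-specific uptake or secretion rate
#'
#' For balanced exponential growth, substrate concentration is linear in
#' biomass concentration; the specific rate is `q = lambda * |dS/dX|`
#' converted to molar units: `q = lambda * |slope| / molar_mass * 1000`
#' (mmol/gDCW/h) where slope is in g substrate per g DCW.
#'
#' @param substrate Substrate (or product) concentrations, g/L, sampled over
#'   the exponential window.
#' @param biomass Biomass concentrations g DCW/L at the same time points.
#' @param lambda Growth rate (1/h), > 0.
#' @param molar_mass Substrate molar mass, g/mol.
#' @return A list: `rate` (mmol/gDCW/h, positive for both consumed and
#'   produced species), `rate_mass` (g/gDCW/h), `slope` (signed dS/dX, g/g;
#'   negative for consumed species), `direction` (`"uptake"` or
#'   `"secretion"`).
#' @export
specific_rate <- function(substrate, biomass, lambda, molar_mass) {
  stop_if(length(substrate) != length(biomass),
          "substrate and biomass series must cover the same points")
  stop_if(length(substrate) < 2L, "need at least 2 paired points")
  assert_number(lambda, "lambda", lower = 0, strict_lower = TRUE)
  assert_number(molar_mass, "molar_mass", lower = 0, strict_lower = TRUE)
  slope <- unname(stats::coef(stats::lm(substrate ~ biomass))[2])
  rate_mass <- lambda * abs(slope)
  list(rate = rate_mass / molar_mass * 1000,
       rate_mass = rate_mass,
       slope = slope,
       direction = if (slope <= 0) "uptake" else "secretion")
}

#' Product yields on glucose
#'
#' Mass-based secretion rates normalized by the mass-based glucose uptake
#' rate, g product per g glucose.
#'
#' @param secretion_rates Named numeric vector of secretion rates
#'   (g/gDCW/h), >= 0.
#' @param q_glc_mass Glucose uptake rate in the same mass units, > 0.
#' @return Named numeric vector of yields (g/g glucose).
#' @export
compute_yields <- function(secretion_rates, q_glc_mass) {
  assert_number(q_glc_mass, "q_glc_mass", lower = 0, strict_lower = TRUE)
  stop_if(any(secretion_rates < 0), "secretion rates must be >= 0")
  secretion_rates / q_glc_mass
}

#' Full physiological characterization of one strain replicate
#'
#' Convenience wrapper: fits the growth rate from the OD series, converts OD
#' to biomass, regresses each concentration series against biomass for
#' specific rates and computes product yields on glucose.
#'
#' @param od_series `data.frame` with columns `time`, `od`.
#' @param conc_series `data.frame` with columns `time`, `species`,
#'   `concentration` (g/L). Must contain a `glucose` species.
#' @param molar_masses Named vector of molar masses (g/mol) per species.
#' @param window Optional exponential window passed to [fit_growth_rate()].
#' @param dcw_factor g DCW/L per OD (default 0.44).
#' @return A list: `lambda`, `lambda_se`, `r_squared`, `q_glc`
#'   (mmol/gDCW/h), `rates` (per-species mmol/gDCW/h), `yields` (g/g
#'   glucose for secreted species).
#' @export
characterize_physiology <- function(od_series, conc_series, molar_masses,
                                    window = NULL, dcw_factor = 0.44) {
  gr <- fit_growth_rate(od_series$time, od_series$od, window = window)
  stop_if(!"glucose" %in% conc_series$species,
          "conc_series must include a 'glucose' species")
  species <- unique(conc_series$species)
  stop_if(!all(species %in% names(molar_masses)),
          "missing molar mass for: %s",
          paste(setdiff(species, names(molar_masses)), collapse = ", "))
  # interpolate biomass at the concentration sampling times
  od_at <- stats::approx(od_series$time, od_series$od,
                         xout = conc_series$time, rule = 2)$y
  biomass <- od_to_dcw(od_at, dcw_factor)
  rates <- list()
  for (sp in species) {
    sel <- conc_series$species == sp
    rates[[sp]] <- specific_rate(conc_series$concentration[sel],
                                 biomass[sel], gr$lambda, molar_masses[[sp]])
  }
  q_glc_mass <- rates$glucose$rate_mass
  secreted <- vapply(rates, function(r) r$direction == "secretion",
                     logical(1))
  sec_mass <- vapply(rates[secreted], `[[`, numeric(1), "rate_mass")
  yields <- if (length(sec_mass)) compute_yields(sec_mass, q_glc_mass)
            else numeric(0)
  list(lambda = gr$lambda, lambda_se = gr$se, r_squared = gr$r_squared,
       q_glc = rates$glucose$rate,
       rates = vapply(rates, `[[`, numeric(1), "rate"),
       yields = yields)
}
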