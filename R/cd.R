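#' Convert raw ellipticity to mean residue ellipticity
#'
#' `MRE = raw_mdeg * MRW / (10 * path_cm * conc_g_per_L)` in
#' deg cm^2 dmol^-1, where MRW is the mean residue weight.
#'
#' @param raw raw ellipticity, mdeg (vector).
#' @param concentration protein concentration, g/L.
#' @param path cuvette path length, cm.
#' @param n_res number of residues (kept for record; the mean residue
#'   weight already normalizes per residue).
#' @param mean_residue_weight g/mol per residue (default 110).
#' @return Numeric MRE vector.
#' @export
to_mre <- function(raw, concentration, path, n_res,
                   mean_residue_weight = 110) {
  if (missing(concentration) || missing(path) || missing(n_res) ||
      is.null(concentration) || is.null(path) || is.null(n_res))
    stop("acquisition metadata (concentration, path, n_res) required")
  stopifnot(concentration > 0, path > 0, n_res > 0)
  raw * mean_residue_weight / (10 * path * concentration)
}

#' Percent helical content from the 222 nm mean residue ellipticity
#'
#' Uses a fully-helical reference magnitude of 36,000 deg cm^2 dmol^-1 at
#' 222 nm: `percent = 100 * |MRE222| / 36000`, clipped to [0, 120] with a
#' warning above 100.
#'
#' @param mre_222 MRE at 222 nm (sign ignored; helical minima are
#'   negative).
#' @param reference fully-helical reference magnitude.
#' @return Percent helical content.
#' @export
helical_content <- function(mre_222, reference = 36000) {
  stopifnot(is.finite(mre_222))
  pct <- 100 * abs(mre_222) / reference
  if (pct > 100) warning("helical content above 100% (", round(pct, 1),
                         "%); clipped at 120")
  min(pct, 120)
}

#' The 222/208 nm ellipticity ratio
#'
#' `MRE(222) / MRE(208)`, each value read at the nearest sampled
#' wavelength (linear interpolation when the grid point is more than half
#' a step away).  A ratio above 1 is the classic coiled-coil signature.
#'
#' @param wavelength wavelengths, nm (must cover 205-225 nm).
#' @param mre MRE values.
#' @return The dimensionless 222/208 ratio.
#' @export
ratio_222_208 <- function(wavelength, mre) {
  stopifnot(length(wavelength) == length(mre),
            min(wavelength) <= 205, max(wavelength) >= 225)
  read_at <- function(w0) {
    i <- which.min(abs(wavelength - w0))
    if (abs(wavelength[i] - w0) < 0.5) mre[i]
    else stats::approx(wavelength, mre, xout = w0)$y
  }
  m208 <- read_at(208)
  if (abs(m208) < 1e-9) stop("undefined ratio: MRE(208) is ~0")
  read_at(222) / m208
}

#' Normalize a thermal melt to percent folded
#'
#' Affine map anchoring the signal at 10 C to 100% folded and the signal
#' at 80 C to 0% folded.
#'
#' @param temperature temperatures, C (must span 10-80).
#' @param signal melt signal (e.g. MRE at 222 nm).
#' @return data.frame `temperature`, `fraction_folded` (percent).
#' @export
normalize_melt <- function(temperature, signal) {
  stopifnot(length(temperature) == length(signal),
            min(temperature) <= 10, max(temperature) >= 80)
  s10 <- stats::approx(temperature, signal, xout = 10)$y
  s80 <- stats::approx(temperature, signal, xout = 80)$y
  if (abs(s10 - s80) < 1e-12)
    stop("degenerate melt: signal at 10 C equals signal at 80 C")
  data.frame(temperature = temperature,
             fraction_folded = 100 * (signal - s80) / (s10 - s80))
}

#' Fit the melting midpoint of a normalized melt curve
#'
#' Two-state logistic fit `f(T) = 100 / (1 + exp((T - Tm) / w))` by
#' nonlinear least squares.
#'
#' @param temperature temperatures, C (>= 10 points spanning the
#'   transition).
#' @param fraction_folded normalized percent-folded values.
#' @return list(`tm`, `width`, `fitted`, `rss`).
#' @export
fit_melt <- function(temperature, fraction_folded) {
  stopifnot(length(temperature) >= 10,
            length(temperature) == length(fraction_folded))
  # midpoint start: temperature where the signal crosses 50%
  below <- which(fraction_folded <= 50)
  t0 <- if (length(below)) temperature[below[1]] else stats::median(temperature)
  fit <- try(stats::nls(
    fraction_folded ~ 100 / (1 + exp((temperature - tm) / w)),
    start = list(tm = t0, w = 3), algorithm = "port",
    lower = c(tm = min(temperature), w = 1e-3),
    upper = c(tm = max(temperature), w = 50),
    control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("melt fit did not converge: ", attr(fit, "condition")$message)
  cf <- stats::coef(fit)
  list(tm = unname(cf["tm"]), width = unname(cf["w"]),
       fitted = stats::fitted(fit), rss = sum(stats::resid(fit)^2))
}
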