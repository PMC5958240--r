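#' Scenario presets for the synthetic-data generators
#'
#' One row (list entry) per construct scenario.  Filament length/width
#' population parameters, bundling probabilities, end-to-end targets and
#' melting midpoints are the study's printed summary statistics; CD helix
#' fractions and sarcomere amplitudes encode the reported qualitative
#' orderings (wild type most helical, mutants accumulating at the M-line,
#' K1617del with reduced peak intensity and the shorter peak spacing).
#' Mixture scenarios (50:50 molar) use the printed intermediate values and
#' are drawn from a single intermediate population.
#'
#' @return Named list of per-scenario parameter lists.
#' @export
scenario_presets <- function() {
  list(
    WT = list(
      mutation = "", filament_length = c(mean = 431, sem = 34, n = 34),
      filament_width = c(mean = 18.4, sem = 0.4, n = 72),
      bundle_p = 0.19, ee_nm = c(mean = 23.9, sd = 0.5),
      helix_fraction = 0.95, tm = 48, melt_width = 3,
      solubility_mid_mM = 250,
      sarcomere = c(peak_amplitude = 1.0, m_line_amplitude = 0.1)),
    A1603P = list(
      mutation = "A1603P", filament_length = c(mean = 208, sem = 16, n = 24),
      filament_width = c(mean = 25, sem = 1, n = 31),
      bundle_p = 0.30, ee_nm = c(mean = 23.8, sd = 0.5),
      helix_fraction = 0.55, tm = 50, melt_width = 3,
      solubility_mid_mM = 150,
      sarcomere = c(peak_amplitude = 1.0, m_line_amplitude = 0.3)),
    K1617del = list(
      mutation = "K1617del", filament_length = c(mean = 300, sem = 25, n = 30),
      filament_width = c(mean = 23, sem = 1, n = 30),
      bundle_p = 0.70, ee_nm = c(mean = 23.4, sd = 0.5),
      helix_fraction = 0.75, tm = 50, melt_width = 3,
      solubility_mid_mM = 250,
      sarcomere = c(peak_amplitude = 0.7, m_line_amplitude = 0.35)),
    `K1617del-c` = list(
      mutation = "K1617del", filament_length = c(mean = 300, sem = 25, n = 30),
      filament_width = c(mean = 23, sem = 1, n = 30),
      bundle_p = 0.70, ee_nm = c(mean = 23.7, sd = 0.4),
      helix_fraction = 0.75, tm = 50, melt_width = 3,
      solubility_mid_mM = 250,
      sarcomere = c(peak_amplitude = 0.7, m_line_amplitude = 0.35)),
    `WT:A1603P` = list(
      mutation = "", filament_length = c(mean = 390, sem = 30, n = 30),
      filament_width = c(mean = 22, sem = 1, n = 30),
      bundle_p = 0.25, ee_nm = c(mean = 23.85, sd = 0.5),
      helix_fraction = 0.75, tm = 49, melt_width = 3,
      solubility_mid_mM = 200,
      sarcomere = c(peak_amplitude = 1.0, m_line_amplitude = 0.2)),
    `WT:K1617del` = list(
      mutation = "", filament_length = c(mean = 370, sem = 30, n = 30),
      filament_width = c(mean = 21, sem = 1, n = 30),
      bundle_p = 0.45, ee_nm = c(mean = 23.65, sd = 0.5),
      helix_fraction = 0.85, tm = 49, melt_width = 3,
      solubility_mid_mM = 250,
      sarcomere = c(peak_amplitude = 0.85, m_line_amplitude = 0.22))
  )
}

rodrigues <- function(xyz, axis, angle_rad, pivot) {
  axis <- axis / sqrt(sum(axis^2))
  v <- sweep(xyz, 2, pivot)
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
  sweep(v %*% t(R), 2, pivot, "+")
}

#' Generate a synthetic conformational ensemble from a built model
#'
#' Stands in for a molecular-dynamics trajectory: per frame, the model's
#' distal half (residues beyond the hinge) is rigidly rotated about a
#' random axis perpendicular to the supercoil (z) axis through the hinge
#' Calpha midpoint, then isotropic Gaussian jitter is added to all atoms.
#' In `"bend"` mode the bend angle is drawn from
#' `Normal(bend_mean_deg, bend_sd_deg)`; in `"end-to-end-target"` mode the
#' angle is solved by bisection so each frame's end-to-end distance
#' matches a draw from `Normal(ee_mean_nm, ee_sd_nm)` (draws above the
#' straight length are clamped to straight).
#'
#' @param model a `cc_model` built in the canonical frame (supercoil axis
#'   along z).
#' @param hinge_residue wild-type residue number of the hinge.
#' @param mode `"bend"` or `"end-to-end-target"`.
#' @param bend_mean_deg,bend_sd_deg bend-angle distribution, degrees.
#' @param ee_mean_nm,ee_sd_nm end-to-end target distribution, nm.
#' @param jitter_sd isotropic atomic jitter, A (default 0.15).
#' @param n_frames number of frames.
#' @param dt_ns time per frame, ns.
#' @param seed RNG seed (full determinism for a given seed).
#' @return A [cc_ensemble]; the truth parameters are in `$meta$truth`.
#' @export
gen_ensemble <- function(model, hinge_residue = 1603L,
                         mode = c("bend", "end-to-end-target"),
                         bend_mean_deg = 10, bend_sd_deg = 5,
                         ee_mean_nm = 23.9, ee_sd_nm = 0.5,
                         jitter_sd = 0.15, n_frames = 100, dt_ns = 0.2,
                         seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "cc_model"), n_frames >= 1)
  set.seed(seed)
  a <- model$atoms
  xyz0 <- as.matrix(a[, c("x", "y", "z")])
  caA <- model_ca(model, "A"); caB <- model_ca(model, "B")
  ends0 <- function(m) {
    e1 <- (m[[1]][1, ] + m[[2]][1, ]) / 2
    e2 <- (m[[1]][nrow(m[[1]]), ] + m[[2]][nrow(m[[2]]), ]) / 2
    list(e1, e2)
  }
  hA <- caA[rownames(caA) == as.character(hinge_residue), , drop = FALSE]
  hB <- caB[rownames(caB) == as.character(hinge_residue), , drop = FALSE]
  if (!nrow(hA) || !nrow(hB)) stop("hinge residue not in model")
  pivot <- as.numeric((hA + hB) / 2)
  distal <- a$resno > hinge_residue
  ee <- ends0(list(caA, caB))
  arm1 <- sqrt(sum((ee[[1]] - pivot)^2))
  arm2 <- sqrt(sum((ee[[2]] - pivot)^2))
  straight_nm <- sqrt(sum((ee[[1]] - ee[[2]])^2)) / 10
  if (mode == "end-to-end-target" && ee_mean_nm > straight_nm)
    stop(sprintf("unachievable end-to-end target: %.2f nm > straight %.2f nm",
                 ee_mean_nm, straight_nm))
  # end-to-end (nm) as a function of the distal-arm bend angle
  cos0 <- sum((ee[[1]] - pivot) * (ee[[2]] - pivot)) / (arm1 * arm2)
  ee_of <- function(gamma) {
    th0 <- acos(max(-1, min(1, cos0)))
    sqrt(arm1^2 + arm2^2 - 2 * arm1 * arm2 * cos(th0 + gamma)) / 10
  }
  solve_gamma <- function(target_nm) {
    lo <- 0; hi <- pi / 2
    if (target_nm >= ee_of(0)) return(0)
    while (ee_of(hi) > target_nm && hi < pi - 1e-6) hi <- min(pi, hi * 1.5)
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (ee_of(mid) > target_nm) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  # a bend can only shorten the rod, so per-frame targets above the
  # straight length are clamped; recentre the draw distribution so the
  # delivered ensemble mean still equals the requested mean
  ee_mu <- ee_mean_nm
  if (mode == "end-to-end-target" && ee_sd_nm > 0) {
    clipped_mean <- function(m) {
      d <- (straight_nm - m) / ee_sd_nm
      m - ee_sd_nm * (stats::dnorm(d) - d * (1 - stats::pnorm(d)))
    }
    if (clipped_mean(ee_mean_nm) < ee_mean_nm - 1e-9)
      ee_mu <- stats::uniroot(function(m) clipped_mean(m) - ee_mean_nm,
                              c(ee_mean_nm, straight_nm + 5 * ee_sd_nm),
                              extendInt = "upX", tol = 1e-9)$root
  }
  nat <- nrow(xyz0)
  frames <- matrix(NA_real_, n_frames, 3 * nat)
  for (f in seq_len(n_frames)) {
    beta <- stats::runif(1, 0, 2 * pi)
    axis <- c(cos(beta), sin(beta), 0)
    gamma <- if (mode == "bend") {
      stats::rnorm(1, bend_mean_deg, bend_sd_deg) * pi / 180
    } else {
      solve_gamma(min(stats::rnorm(1, ee_mu, ee_sd_nm), straight_nm))
    }
    xyz <- xyz0
    if (abs(gamma) > 0)
      xyz[distal, ] <- rodrigues(xyz0[distal, , drop = FALSE], axis,
                                 gamma, pivot)
    if (jitter_sd > 0)
      xyz <- xyz + matrix(stats::rnorm(3 * nat, 0, jitter_sd), nat, 3)
    frames[f, ] <- as.vector(t(xyz))
  }
  cc_ensemble(a[, c("elety", "resid", "chain", "resno", "elesy")], frames,
              time_ns = seq(0, by = dt_ns, length.out = n_frames),
              meta = list(source = "gen_ensemble", seed = seed,
                          truth = list(mode = mode, hinge = hinge_residue,
                                       bend_mean_deg = bend_mean_deg,
                                       bend_sd_deg = bend_sd_deg,
                                       ee_mean_nm = ee_mean_nm,
                                       ee_sd_nm = ee_sd_nm,
                                       jitter_sd = jitter_sd,
                                       straight_nm = straight_nm)))
}

# helix and coil basis spectra (MRE, deg cm^2 dmol^-1) on a wavelength
# grid; the helix basis is scaled to exactly -36000 at 222 nm
cd_basis <- function(wavelength) {
  helix <- -36000 * (exp(-(wavelength - 222)^2 / (2 * 6^2)) +
                       0.88 * exp(-(wavelength - 208)^2 / (2 * 5^2))) +
    65000 * exp(-(wavelength - 193)^2 / (2 * 4.5^2))
  helix <- helix * 36000 / abs(helix[which.min(abs(wavelength - 222))])
  coil <- -20000 * exp(-(wavelength - 198)^2 / (2 * 7^2)) +
    1500 * exp(-(wavelength - 218)^2 / (2 * 9^2))
  list(helix = helix, coil = coil)
}

#' Generate a synthetic CD spectrum
#'
#' Linear mixture of a helix basis (constrained to MRE(222) = -36000 and
#' a 222/208 ratio above 1, the coiled-coil signature) and a coil basis
#' (minimum near 198 nm), plus Gaussian noise.
#'
#' @param helix_fraction fraction of helix basis in [0, 1].
#' @param noise_sd Gaussian noise SD in MRE units.
#' @param seed RNG seed.
#' @param wavelength wavelength grid, nm.
#' @return data.frame `wavelength`, `mre`; truth parameters in
#'   `attr(, "truth")`.
#' @export
gen_cd <- function(helix_fraction, noise_sd = 0, seed = 1,
                   wavelength = 190:260) {
  stopifnot(helix_fraction >= 0, helix_fraction <= 1)
  set.seed(seed)
  b <- cd_basis(wavelength)
  mre <- helix_fraction * b$helix + (1 - helix_fraction) * b$coil +
    stats::rnorm(length(wavelength), 0, noise_sd)
  out <- data.frame(wavelength = wavelength, mre = mre)
  attr(out, "truth") <- list(helix_fraction = helix_fraction,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Generate a synthetic thermal melt curve
#'
#' Two-state sigmoid `100 / (1 + exp((T - Tm) / width))` on a 1 C grid
#' from 10 to 85 C, plus Gaussian noise (percent points).
#'
#' @param tm melting midpoint, C (between 10 and 80).
#' @param width transition width, C.
#' @param noise_sd noise SD, percent points.
#' @param seed RNG seed.
#' @return data.frame `temperature`, `fraction_folded`; truth in
#'   `attr(, "truth")`.
#' @export
gen_melt <- function(tm, width = 2, noise_sd = 0, seed = 1) {
  stopifnot(tm >= 10, tm <= 80, width > 0)
  set.seed(seed)
  temperature <- 10:85
  f <- 100 / (1 + exp((temperature - tm) / width)) +
    stats::rnorm(length(temperature), 0, noise_sd)
  out <- data.frame(temperature = temperature, fraction_folded = f)
  attr(out, "truth") <- list(tm = tm, width = width, noise_sd = noise_sd,
                             seed = seed)
  out
}

#' Generate synthetic filament measurement tables
#'
#' Lengths and widths are drawn per scenario from
#' `Normal(mean, SEM * sqrt(n))` truncated above zero (SD recovered from
#' the reported SEM via SD = SEM x sqrt(n)); image-field bundling flags
#' are Bernoulli draws at the scenario bundling probability.  Mixture
#' scenarios draw from a single intermediate population.
#'
#' @param scenarios character vector of preset names (see
#'   [scenario_presets()]).
#' @param n_fields bundled-flag fields per scenario (default 200).
#' @param seed RNG seed.
#' @return list: `measurements` (data.frame `group`, `length_nm`,
#'   `width_nm`, one non-NA variable per row) and `fields` (`group`,
#'   `field_id`, `bundled`); truth in `attr(, "truth")`.
#' @export
gen_filaments <- function(scenarios = c("WT", "A1603P", "K1617del"),
                          n_fields = 200, seed = 1) {
  presets <- scenario_presets()
  stopifnot(all(scenarios %in% names(presets)))
  set.seed(seed)
  meas <- list(); fields <- list()
  # zero-truncated normal, recentred so the truncated mean equals `mean`
  rtnorm <- function(n, mean, sd) {
    tmean <- function(m) m + sd * stats::dnorm(m / sd) / stats::pnorm(m / sd)
    m <- if (tmean(mean) > mean + 1e-9)
      stats::uniroot(function(m) tmean(m) - mean,
                     c(mean - 3 * sd, mean), extendInt = "upX",
                     tol = 1e-9)$root else mean
    x <- stats::rnorm(n, m, sd)
    while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), m, sd)
    x
  }
  for (g in scenarios) {
    p <- presets[[g]]
    ln <- p$filament_length; wd <- p$filament_width
    lv <- rtnorm(ln[["n"]], ln[["mean"]], ln[["sem"]] * sqrt(ln[["n"]]))
    wv <- rtnorm(wd[["n"]], wd[["mean"]], wd[["sem"]] * sqrt(wd[["n"]]))
    meas[[g]] <- rbind(
      data.frame(group = g, length_nm = lv, width_nm = NA_real_),
      data.frame(group = g, length_nm = NA_real_, width_nm = wv))
    fields[[g]] <- data.frame(
      group = g, field_id = paste0(g, "_f", seq_len(n_fields)),
      bundled = stats::runif(n_fields) < p$bundle_p)
  }
  out <- list(measurements = do.call(rbind, c(meas, make.row.names = FALSE)),
              fields = do.call(rbind, c(fields, make.row.names = FALSE)))
  attr(out, "truth") <- list(presets = presets[scenarios], seed = seed,
                             n_fields = n_fields)
  out
}

#' Generate synthetic solubility assay points
#'
#' Logistic salt dependence of the soluble fraction with midpoint
#' `mid_mM` (fraction soluble rises with NaCl, as for rod constructs that
#' polymerize at low ionic strength), sampled at the assay's five salt
#' concentrations with Gaussian noise.
#'
#' @param scenarios preset names.
#' @param NaCl_mM salt grid, mM.
#' @param total total protein concentration (arbitrary units).
#' @param noise_sd fractional noise SD.
#' @param seed RNG seed.
#' @return data.frame `group`, `NaCl_mM`, `supernatant`, `total`.
#' @export
gen_solubility <- function(scenarios = c("WT", "A1603P", "K1617del"),
                           NaCl_mM = c(50, 150, 250, 350, 500),
                           total = 1, noise_sd = 0.02, seed = 1) {
  presets <- scenario_presets()
  stopifnot(all(scenarios %in% names(presets)))
  set.seed(seed)
  out <- do.call(rbind, lapply(scenarios, function(g) {
    mid <- presets[[g]]$solubility_mid_mM
    fr <- 1 / (1 + exp((mid - NaCl_mM) / 50)) +
      stats::rnorm(length(NaCl_mM), 0, noise_sd)
    data.frame(group = g, NaCl_mM = NaCl_mM,
               supernatant = pmin(pmax(fr, 0), 1) * total, total = total)
  }))
  attr(out, "truth") <- list(mid = vapply(scenarios, function(g)
    presets[[g]]$solubility_mid_mM, numeric(1)), seed = seed)
  out
}

#' Generate synthetic sarcomere intensity line scans
#'
#' Each sarcomere contributes two Gaussian intensity peaks flanking the
#' M-line at `M +/- peak_separation / 2` plus a central Gaussian of
#' amplitude `m_line_amplitude` at the M-line (the M-line accumulation
#' term, elevated in the mutant presets) on a constant baseline; the
#' intensity minima at the sarcomere boundaries are the deepest minima of
#' the scan.  Gaussian noise is added per pixel.
#'
#' @param n_myofibrils number of myofibrils (one scan each).
#' @param n_sarcomeres sarcomeres per scan.
#' @param sarcomere_length period, um.
#' @param peak_separation distance between the two peaks flanking the
#'   M-line, um.
#' @param peak_amplitude,peak_sigma peak height and width, um.
#' @param m_line_amplitude,m_sigma M-line accumulation term.
#' @param baseline constant background.
#' @param noise_sd additive noise SD.
#' @param pixel_size sampling step, um.
#' @param seed RNG seed.
#' @return list of line-scan data.frames (`position`, `intensity`) with a
#'   `myofibril` attribute each; truth in `attr(, "truth")`.
#' @export
gen_linescans <- function(n_myofibrils = 12, n_sarcomeres = 4,
                          sarcomere_length = 2.0, peak_separation = 0.7,
                          peak_amplitude = 1.0, peak_sigma = 0.2,
                          m_line_amplitude = 0.1, m_sigma = 0.2,
                          baseline = 0.2, noise_sd = 0.02,
                          pixel_size = 0.02, seed = 1) {
  stopifnot(peak_separation < sarcomere_length, n_sarcomeres >= 2)
  set.seed(seed)
  scans <- lapply(seq_len(n_myofibrils), function(mf) {
    phase <- stats::runif(1, 0, sarcomere_length)
    pos <- seq(0, (n_sarcomeres + 1) * sarcomere_length, by = pixel_size)
    m_centres <- phase + sarcomere_length * (0:(n_sarcomeres + 1)) -
      sarcomere_length / 2
    y <- rep(baseline, length(pos))
    for (m in m_centres) {
      y <- y + peak_amplitude *
        (exp(-(pos - m + peak_separation / 2)^2 / (2 * peak_sigma^2)) +
           exp(-(pos - m - peak_separation / 2)^2 / (2 * peak_sigma^2))) +
        m_line_amplitude * exp(-(pos - m)^2 / (2 * m_sigma^2))
    }
    y <- y + stats::rnorm(length(pos), 0, noise_sd)
    out <- data.frame(position = pos, intensity = y)
    attr(out, "myofibril") <- mf
    attr(out, "m_centres") <- m_centres
    out
  })
  attr(scans, "truth") <- list(
    sarcomere_length = sarcomere_length, peak_separation = peak_separation,
    peak_amplitude = peak_amplitude, peak_sigma = peak_sigma,
    m_line_amplitude = m_line_amplitude, m_sigma = m_sigma,
    baseline = baseline, noise_sd = noise_sd, pixel_size = pixel_size,
    seed = seed)
  scans
}
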