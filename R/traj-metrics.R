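#' @title Per-residue ensemble metrics
#' @description Helpers shared by the per-residue metric functions: each
#'   returns a `residue_profile` data.frame (`chain`, `resno`, `mean`,
#'   `sd`, and `gap` where a window crosses the numbering gap left by a
#'   deletion), with the metric name and units in attributes.  All metrics
#'   use physical (sequential) neighbours for windows and report against
#'   wild-type numbering.
#' @name residue_profile
NULL

col_sd <- function(vals) {
  if (nrow(vals) < 2) rep(0, ncol(vals)) else apply(vals, 2, stats::sd)
}

residue_profile <- function(df, metric, units, n_frames) {
  rownames(df) <- NULL
  class(df) <- c("residue_profile", "data.frame")
  attr(df, "metric") <- metric
  attr(df, "units") <- units
  attr(df, "n_frames") <- n_frames
  df
}

# sliding window mean of an n x 3 coordinate block, width w (= 2h+1)
roll_centroid <- function(m, w) {
  cs <- apply(rbind(0, m), 2, cumsum)
  (cs[(w + 1):nrow(cs), , drop = FALSE] -
     cs[1:(nrow(cs) - w), , drop = FALSE]) / w
}

#' Inter-helix distance profile (D_com)
#'
#' For each residue, the distance between the centroids of the seven
#' Calpha atoms (three N-terminal and three C-terminal neighbours plus the
#' residue itself) of chain A and of chain B, averaged over frames.
#' Undefined at the three terminal residues of each end.
#'
#' @param ens a [cc_ensemble] with chains A and B.
#' @param window window width in residues (odd; default 7).
#' @return A `residue_profile` (`chain` is `"AB"`).
#' @export
dcom_profile <- function(ens, window = 7) {
  stopifnot(inherits(ens, "cc_ensemble"), window %% 2 == 1)
  h <- (window - 1) / 2
  selA <- atom_sel(ens, elety = "CA", chain = "A")
  selB <- atom_sel(ens, elety = "CA", chain = "B")
  resA <- ens$atoms$resno[selA]
  resB <- ens$atoms$resno[selB]
  common <- intersect(resA, resB)
  selA <- selA[match(common, resA)]
  selB <- selB[match(common, resB)]
  n <- length(common)
  if (n < window) stop("too few residues for the window")
  nf <- n_frames(ens)
  vals <- matrix(NA_real_, nf, n - window + 1)
  for (f in seq_len(nf)) {
    cA <- roll_centroid(frame_xyz(ens, f, selA), window)
    cB <- roll_centroid(frame_xyz(ens, f, selB), window)
    vals[f, ] <- sqrt(rowSums((cA - cB)^2))
  }
  idx <- (1 + h):(n - h)
  gap <- vapply(idx, function(i)
    common[i + h] - common[i - h] != window - 1, logical(1))
  residue_profile(
    data.frame(chain = "AB", resno = common[idx],
               mean = colMeans(vals), sd = col_sd(vals),
               gap = gap),
    "D_com", "angstrom", nf)
}

#' Heptad length profile
#'
#' Distance between the averaged Calpha position of window `{i-3..i+3}`
#' and that of the register-equivalent window `{i+4..i+10}` (the default
#' windowed-positions method), or the window-averaged `i` to `i+7`
#' Calpha-Calpha distance (`method = "distances"`).  About 10.5 A for a
#' straight helix with a 1.5 A rise.
#'
#' @param ens a [cc_ensemble].
#' @param method `"positions"` (default) or `"distances"`.
#' @return A `residue_profile` with per-chain rows.
#' @export
heptad_length_profile <- function(ens, method = c("positions", "distances")) {
  method <- match.arg(method)
  stopifnot(inherits(ens, "cc_ensemble"))
  nf <- n_frames(ens)
  out <- list()
  for (ch in unique(ens$atoms$chain)) {
    sel <- atom_sel(ens, elety = "CA", chain = ch)
    res <- ens$atoms$resno[sel]
    n <- length(sel)
    if (n < 14) next
    idx <- 4:(n - 10)                       # window centres
    vals <- matrix(NA_real_, nf, length(idx))
    for (f in seq_len(nf)) {
      xyz <- frame_xyz(ens, f, sel)
      if (method == "positions") {
        cen <- roll_centroid(xyz, 7)        # rows: centres 4..n-3
        m <- nrow(cen) - 7
        vals[f, ] <- sqrt(rowSums((cen[8:(m + 7), , drop = FALSE] -
                                     cen[1:m, , drop = FALSE])^2))
      } else {
        d7 <- sqrt(rowSums((xyz[8:n, , drop = FALSE] -
                              xyz[1:(n - 7), , drop = FALSE])^2))
        cs <- cumsum(c(0, d7))
        vals[f, ] <- (cs[idx + 4] - cs[idx - 3]) / 7
      }
    }
    gap <- vapply(idx, function(i) res[i + 10] - res[i - 3] != 13, logical(1))
    out[[ch]] <- data.frame(chain = ch, resno = res[idx],
                            mean = colMeans(vals),
                            sd = col_sd(vals), gap = gap)
  }
  residue_profile(do.call(rbind, out), "heptad_length", "angstrom", nf)
}

#' Inter-heptad angle profile
#'
#' Interior angle at residue `i` between the vectors pointing to the
#' Calpha atoms of residues `i - 7` and `i + 7` (physical neighbours).
#' Straight geometry gives 180 degrees; local bends reduce it.
#'
#' @param ens a [cc_ensemble].
#' @return A `residue_profile` with per-chain rows, degrees.
#' @export
inter_heptad_angle_profile <- function(ens) {
  stopifnot(inherits(ens, "cc_ensemble"))
  nf <- n_frames(ens)
  out <- list()
  for (ch in unique(ens$atoms$chain)) {
    sel <- atom_sel(ens, elety = "CA", chain = ch)
    res <- ens$atoms$resno[sel]
    n <- length(sel)
    if (n < 15) next
    idx <- 8:(n - 7)
    vals <- matrix(NA_real_, nf, length(idx))
    for (f in seq_len(nf)) {
      xyz <- frame_xyz(ens, f, sel)
      v1 <- xyz[idx - 7, , drop = FALSE] - xyz[idx, , drop = FALSE]
      v2 <- xyz[idx + 7, , drop = FALSE] - xyz[idx, , drop = FALSE]
      l1 <- sqrt(rowSums(v1^2)); l2 <- sqrt(rowSums(v2^2))
      if (any(l1 < 1e-12) || any(l2 < 1e-12))
        stop("zero-length inter-heptad vector")
      cth <- pmax(-1, pmin(1, rowSums(v1 * v2) / (l1 * l2)))
      vals[f, ] <- acos(cth) * 180 / pi
    }
    gap <- vapply(idx, function(i) res[i + 7] - res[i - 7] != 14, logical(1))
    out[[ch]] <- data.frame(chain = ch, resno = res[idx],
                            mean = colMeans(vals),
                            sd = col_sd(vals), gap = gap)
  }
  residue_profile(do.call(rbind, out), "inter_heptad_angle", "degree", nf)
}

# torsion angle (deg) of four points given as rows
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Backbone dihedral helicity
#'
#' Fraction of (residue, frame) pairs whose backbone dihedrals fall inside
#' the alpha-helical windows.  Residues lacking a phi or psi dihedral
#' (chain termini) are excluded from the denominator.
#'
#' @param ens a [cc_ensemble] with N, CA and C atoms.
#' @param phi_window,psi_window numeric length-2 windows in degrees.
#' @return A list: `overall` fraction, `per_chain` named fractions.
#' @export
helicity <- function(ens, phi_window = c(-100, -30),
                     psi_window = c(-80, -5)) {
  stopifnot(inherits(ens, "cc_ensemble"))
  nf <- n_frames(ens)
  hel <- tot <- stats::setNames(numeric(0), character(0))
  for (ch in unique(ens$atoms$chain)) {
    selN <- atom_sel(ens, elety = "N", chain = ch)
    selCA <- atom_sel(ens, elety = "CA", chain = ch)
    selC <- atom_sel(ens, elety = "C", chain = ch)
    n <- length(selCA)
    if (length(selN) != n || length(selC) != n)
      stop("N/CA/C atoms required for helicity in chain ", ch)
    nh <- nt <- 0
    for (f in seq_len(nf)) {
      Nx <- frame_xyz(ens, f, selN)
      CAx <- frame_xyz(ens, f, selCA)
      Cx <- frame_xyz(ens, f, selC)
      for (i in 2:(n - 1)) {
        phi <- dihedral4(Cx[i - 1, ], Nx[i, ], CAx[i, ], Cx[i, ])
        psi <- dihedral4(Nx[i, ], CAx[i, ], Cx[i, ], Nx[i + 1, ])
        nt <- nt + 1
        if (phi >= phi_window[1] && phi <= phi_window[2] &&
            psi >= psi_window[1] && psi <= psi_window[2]) nh <- nh + 1
      }
    }
    hel[ch] <- nh; tot[ch] <- nt
  }
  list(overall = sum(hel) / sum(tot), per_chain = hel / tot)
}

#' Ensemble end-to-end distance
#'
#' Per frame, the distance between the midpoint of the two chains' first
#' Calpha atoms and the midpoint of their last Calpha atoms, in nm.
#'
#' @param ens a [cc_ensemble] with chains A and B.
#' @return list(`mean_nm`, `sd_nm`, `per_frame_nm`).
#' @export
end_to_end <- function(ens) {
  stopifnot(inherits(ens, "cc_ensemble"))
  selA <- atom_sel(ens, elety = "CA", chain = "A")
  selB <- atom_sel(ens, elety = "CA", chain = "B")
  ends <- c(selA[1], selB[1], selA[length(selA)], selB[length(selB)])
  d <- vapply(seq_len(n_frames(ens)), function(f) {
    xyz <- frame_xyz(ens, f, ends)
    sqrt(sum((colMeans(xyz[1:2, ]) - colMeans(xyz[3:4, ]))^2))
  }, numeric(1))
  d <- d / 10  # angstrom -> nm
  list(mean_nm = mean(d), sd_nm = if (length(d) > 1) stats::sd(d) else 0,
       per_frame_nm = d)
}
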