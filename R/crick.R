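#' Crick parameters for the coiled-coil backbone generator
#'
#' Defaults are the values used to build the 164-residue rod models:
#' 3.617 residues per turn of helix, an axial translation of 1.495 A per
#' residue, a strand phase of 210 degrees, a major (supercoil) radius of
#' 4.9 A, and a smoothing parameter b = 0.03 for blending the per-motif
#' phase rates.  The minor radius (2.26 A) is the Calpha radius of an
#' ideal alpha-helix.
#'
#' @param residues_per_turn intrinsic helix periodicity (> 3).
#' @param rise_per_residue axial translation per residue, A.
#' @param strand_phase helix self-rotation phase, degrees in [0, 360).
#' @param major_radius supercoil radius, A.
#' @param minor_radius helix (Calpha) radius, A.
#' @param smoothing_b dimensionless width factor for blending motif phase
#'   rates (ramp width = `smoothing_b` x motif length, residues).
#' @return A list of class `crick_params`.
#' @export
crick_params <- function(residues_per_turn = 3.617, rise_per_residue = 1.495,
                         strand_phase = 210, major_radius = 4.9,
                         minor_radius = 2.26, smoothing_b = 0.03) {
  stopifnot(residues_per_turn > 3, rise_per_residue > 0,
            strand_phase >= 0, strand_phase < 360,
            major_radius > 0, minor_radius > 0, smoothing_b > 0)
  structure(list(residues_per_turn = residues_per_turn,
                 rise_per_residue = rise_per_residue,
                 strand_phase = strand_phase,
                 major_radius = major_radius,
                 minor_radius = minor_radius,
                 smoothing_b = smoothing_b),
            class = "crick_params")
}

# place atom D from A-B-C with bond |CD|, angle B-C-D (deg), torsion
# A-B-C-D (deg); standard internal-to-Cartesian (NeRF) step
nerf_place <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- pracma_cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# ideal alpha-helix backbone from internal coordinates (phi -57.8, psi -47)
# returns list of n x 3 matrices N, CA, C, O
ideal_helix_backbone <- function(n = 24, phi = -57.8, psi = -47.0) {
  b_NCA <- 1.458; b_CAC <- 1.525; b_CN <- 1.329; b_CO <- 1.231
  a_NCAC <- 111.2; a_CACN <- 116.2; a_CNCA <- 121.7; a_CACO <- 120.5
  N <- CA <- C <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b_NCA, 0, 0)
  C[1, ] <- nerf_place(c(0, 1, 0), N[1, ], CA[1, ], b_CAC, a_NCAC, phi + 60)
  for (i in 2:n) {
    N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ], b_CN, a_CACN, psi)
    CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ], b_NCA, a_CNCA, 180)
    C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ], b_CAC, a_NCAC, phi)
  }
  O <- matrix(NA_real_, n, 3)
  for (i in 1:(n - 1))
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], b_CO, a_CACO, psi + 180)
  O[n, ] <- nerf_place(N[n, ], CA[n, ], C[n, ], b_CO, a_CACO, psi + 180)
  list(N = N, CA = CA, C = C, O = O)
}

#' Fit local helix parameters to a point trace
#'
#' Closed-form, per-residue helix fit used as the builder's self-check and
#' by the analysis drivers.  For each interior point the inward bisector of
#' the two neighbouring virtual bonds gives the exact radial direction of
#' an ideal helix; the local axis direction, twist per residue, axial rise
#' and radius then follow in closed form.
#'
#' @param xyz n x 3 matrix of ordered points (e.g. a Calpha trace).
#' @return A data.frame with one row per interior point: `twist_deg`
#'   (signed; positive = right-handed), `rise`, `radius`, plus the local
#'   axis point (`ax_x,ax_y,ax_z`) and axis direction (`tx,ty,tz`).
#' @export
fit_local_helix <- function(xyz) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(n >= 4, ncol(xyz) == 3)
  unit <- function(v) v / sqrt(sum(v^2))
  u <- matrix(NA_real_, n, 3)
  for (i in 2:(n - 1))
    u[i, ] <- -unit((xyz[i - 1, ] - xyz[i, ]) + (xyz[i + 1, ] - xyz[i, ]))
  out <- vector("list", n - 3)
  for (i in 2:(n - 2)) {
    t_dir <- pracma_cross(u[i, ], u[i + 1, ])
    step <- xyz[i + 1, ] - xyz[i, ]
    if (sqrt(sum(t_dir^2)) < 1e-12) {      # locally straight
      out[[i - 1]] <- data.frame(twist_deg = 0, rise = sqrt(sum(step^2)),
                                 radius = 0, ax_x = xyz[i, 1],
                                 ax_y = xyz[i, 2], ax_z = xyz[i, 3],
                                 tx = NA, ty = NA, tz = NA)
      next
    }
    t_dir <- unit(t_dir)
    if (sum(t_dir * step) < 0) t_dir <- -t_dir
    d <- sum(step * t_dir)
    cth <- max(-1, min(1, sum(u[i, ] * u[i + 1, ])))
    th <- acos(cth)
    sgn <- sign(sum(pracma_cross(u[i, ], u[i + 1, ]) * t_dir))
    ch2 <- sum(step^2) - d^2
    r <- if (th > 1e-9) sqrt(ch2) / (2 * sin(th / 2)) else 0
    ax <- xyz[i, ] - r * u[i, ]
    out[[i - 1]] <- data.frame(twist_deg = sgn * th * 180 / pi, rise = d,
                               radius = r, ax_x = ax[1], ax_y = ax[2],
                               ax_z = ax[3], tx = t_dir[1], ty = t_dir[2],
                               tz = t_dir[3])
  }
  cbind(i = 2:(n - 2), do.call(rbind, out))
}

# cylindrical offsets of N, C, O relative to the Calpha helix of an ideal
# alpha-helix: radius, phase offset (deg, about the local axis, relative to
# the Calpha phase) and axial offset (A).  Computed once from internal
# coordinates and cached.
.ccrod_cache <- new.env(parent = emptyenv())

ideal_backbone_offsets <- function() {
  if (!is.null(.ccrod_cache$offsets)) return(.ccrod_cache$offsets)
  bb <- ideal_helix_backbone(n = 24)
  fit <- fit_local_helix(bb$CA)
  mid <- 8:16                       # interior residues, away from ends
  offs <- list()
  for (atom in c("N", "C", "O")) {
    vals <- t(vapply(mid, function(i) {
      f <- fit[fit$i == i, ]
      ax <- c(f$ax_x, f$ax_y, f$ax_z)
      t_dir <- c(f$tx, f$ty, f$tz)
      u <- (bb$CA[i, ] - ax)
      u <- u - sum(u * t_dir) * t_dir
      u <- u / sqrt(sum(u^2))
      w <- pracma_cross(t_dir, u)
      v <- bb[[atom]][i, ] - ax
      z <- sum(v * t_dir)
      p <- v - z * t_dir
      r <- sqrt(sum(p^2))
      phi <- atan2(sum(p * w), sum(p * u)) * 180 / pi
      c(r = r, dphi = phi, dz = z)
    }, numeric(3)))
    offs[[atom]] <- colMeans(vals)
  }
  fitm <- fit[fit$i %in% mid, ]
  offs$CA <- c(r = mean(fitm$radius), dphi = 0, dz = 0)
  offs$twist <- mean(fitm$twist_deg)
  offs$rise <- mean(fitm$rise)
  .ccrod_cache$offsets <- offs
  offs
}
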