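#' Van der Waals radii for solvent accessibility
#'
#' Chothia-style element radii (A) used by the Shrake-Rupley engine.
#'
#' @return Named numeric vector of radii by element symbol.
#' @export
vdw_radii <- function() {
  c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, H = 1.00, P = 1.90)
}

# quasi-uniform unit sphere points (golden-section spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley accessible surface area
#'
#' Per-atom solvent-accessible surface area: test points on each atom's
#' solvent-expanded sphere are counted accessible when outside every other
#' atom's expanded sphere.
#'
#' @param xyz n x 3 coordinate matrix.
#' @param radii numeric vector of van der Waals radii (length n).
#' @param probe probe radius, A (default 1.4).
#' @param n_points test points per atom (default 960).
#' @return Numeric vector of per-atom SASA, A^2.
#' @export
sasa_atoms <- function(xyz, radii, probe = 1.4, n_points = 960) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(length(radii) == n, probe >= 0)
  sp <- sphere_points(n_points)
  er <- radii + probe
  out <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(sp * er[i], 2, xyz[i, ], "+")
    # neighbours whose expanded sphere can reach atom i's surface
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ], "-")^2)
    nb <- which(d2 < (er + er[i])^2 & seq_len(n) != i)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- rowSums(sweep(pts[acc, , drop = FALSE], 2, xyz[j, ], "-")^2)
      acc[acc] <- dj > er[j]^2
    }
    out[i] <- 4 * pi * er[i]^2 * sum(acc) / n_points
  }
  out
}

# radii for an atom table, with a configurable default for unknown elements
atom_radii <- function(atoms, default_radius = 1.8) {
  r <- vdw_radii()[atoms$elesy]
  if (anyNA(r)) {
    warning("unknown element(s) ",
            paste(unique(atoms$elesy[is.na(r)]), collapse = ","),
            "; using default radius ", default_radius)
    r[is.na(r)] <- default_radius
  }
  unname(r)
}

# extended Gly-X-Gly reference SASA for one residue's side-chain atom set
# (side chain includes CA).  The residue's own atoms are transplanted
# rigidly (superposed on N/CA/C, or recentred on CA when backbone is
# incomplete) into an extended Gly-X-Gly backbone built from ideal internal
# coordinates, and the same engine is run, making the reference
# self-consistent by construction.
gxg_reference_sasa <- function(res_atoms, res_xyz, probe = 1.4,
                               n_points = 960, default_radius = 1.8) {
  bb <- ideal_helix_backbone(n = 3, phi = -120, psi = 120)
  tri <- rbind(bb$N[1, ], bb$CA[1, ], bb$C[1, ], bb$O[1, ],
               bb$N[2, ], bb$CA[2, ], bb$C[2, ], bb$O[2, ],
               bb$N[3, ], bb$CA[3, ], bb$C[3, ], bb$O[3, ])
  tri_el <- c("N", "C", "C", "O", "N", "C", "C", "O", "N", "C", "C", "O")
  bb_i <- match(c("N", "CA", "C"), res_atoms$elety)
  sc <- which(!(res_atoms$elety %in% c("N", "C", "O")))
  if (!length(sc)) return(NA_real_)
  if (!anyNA(bb_i)) {
    fit <- kabsch_transform(rbind(bb$N[2, ], bb$CA[2, ], bb$C[2, ]),
                            res_xyz[bb_i, , drop = FALSE])
    moved <- sweep(res_xyz %*% fit$R, 2, fit$t, "+")
  } else {
    ca <- match("CA", res_atoms$elety)
    if (is.na(ca)) return(NA_real_)
    moved <- sweep(res_xyz, 2, bb$CA[2, ] - res_xyz[ca, ], "+")
  }
  # central residue contributes its side-chain set; flanking Gly keep
  # backbone only (plus the central residue's own backbone N/C/O)
  keep_bb <- setdiff(seq_len(nrow(res_atoms)), sc)
  allxyz <- rbind(tri[-c(5:8), , drop = FALSE], moved[keep_bb, , drop = FALSE],
                  moved[sc, , drop = FALSE])
  el <- c(tri_el[-c(5:8)], res_atoms$elesy[keep_bb], res_atoms$elesy[sc])
  r <- vdw_radii()[el]
  r[is.na(r)] <- default_radius
  s <- sasa_atoms(allxyz, unname(r), probe, n_points)
  sum(s[(nrow(allxyz) - length(sc) + 1):nrow(allxyz)])
}

# least-squares rigid transform mapping Q onto P (rows are points)
kabsch_transform <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(Q, 2, cq)) %*% sweep(P, 2, cp)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, t = cp - cq %*% R)
}

#' Relative solvent accessibility profile
#'
#' Shrake-Rupley accessible surface of each residue's side-chain atom set
#' (Calpha included as part of the side chain, backbone N/C/O excluded),
#' normalized by the residue's maximum accessibility in an extended
#' Gly-X-Gly tripeptide computed with the same engine, and averaged over
#' frames sampled at a fixed interval.  Values slightly above 1 are
#' permitted for distorted conformers.
#'
#' @param ens a [cc_ensemble].
#' @param probe probe radius, A.
#' @param n_sphere_points test points per atom.
#' @param stride frame subsampling stride; default samples every 10 ps
#'   when frame times allow, else every frame.
#' @param default_radius radius for unknown elements.
#' @return A `residue_profile` with per-chain rows (`mean`, `sd` of RSA).
#' @export
rsa_profile <- function(ens, probe = 1.4, n_sphere_points = 960,
                        stride = NULL, default_radius = 1.8) {
  stopifnot(inherits(ens, "cc_ensemble"))
  if (is.null(stride)) {
    dt <- if (n_frames(ens) > 1) diff(ens$time_ns[1:2]) else NA
    stride <- if (!is.na(dt) && dt > 0) max(1L, round(0.01 / dt)) else 1L
  }
  frames <- seq(1, n_frames(ens), by = stride)
  a <- ens$atoms
  radii <- atom_radii(a, default_radius)
  key <- paste(a$chain, a$resno)
  res_keys <- unique(key)
  sc_mask <- !(a$elety %in% c("N", "C", "O"))
  # reference from the first sampled frame's conformation
  ref <- vapply(res_keys, function(k) {
    ii <- which(key == k)
    gxg_reference_sasa(a[ii, , drop = FALSE],
                       frame_xyz(ens, frames[1], ii), probe,
                       n_sphere_points, default_radius)
  }, numeric(1))
  vals <- matrix(NA_real_, length(frames), length(res_keys))
  for (fi in seq_along(frames)) {
    s <- sasa_atoms(frame_xyz(ens, frames[fi], seq_len(nrow(a))),
                    radii, probe, n_sphere_points)
    vals[fi, ] <- vapply(seq_along(res_keys), function(ri) {
      ii <- which(key == res_keys[ri] & sc_mask)
      if (!length(ii)) NA_real_ else sum(s[ii])
    }, numeric(1)) / ref
  }
  parts <- strsplit(res_keys, " ")
  residue_profile(
    data.frame(chain = vapply(parts, `[`, "", 1),
               resno = as.integer(vapply(parts, `[`, "", 2)),
               mean = colMeans(vals),
               sd = apply(vals, 2, function(x)
                 if (length(x) > 1) stats::sd(x) else 0),
               gap = FALSE),
    "relative_solvent_accessibility", "fraction", length(frames))
}
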