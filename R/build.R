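#' Build an idealized two-chain coiled-coil backbone model
#'
#' Generates a parallel two-chain coiled coil from a generalized Crick
#' parameterization driven by a motif schedule.  Inside a motif of length
#' `L` containing `N` helical turns, the helix phase advances at
#' `360 N / L` degrees per residue in the supercoil frame; the intrinsic
#' helix rate is `360 / residues_per_turn`; the difference is absorbed as
#' supercoil twist, so a canonical 7/2 motif gives the usual left-handed
#' supercoil while a 29/8 skip motif locally unwinds it.  Transitions
#' between motif phase rates are blended with a logistic ramp of width
#' `smoothing_b` x motif length.  The supercoil axis is the z axis; the
#' two chains are placed antipodally (180 degrees apart) about it and share
#' the helix self-phase `strand_phase`, so equal sequences give an exactly
#' C2-symmetric dimer.  Backbone N, C and O atoms are placed from ideal
#' alpha-helix internal geometry in the local helix frame.
#'
#' @param seqA,seqB [cc_sequence] objects for the two chains (chain B
#'   defaults to chain A).
#' @param schedule a [motif_schedule] tiling the chains.
#' @param params a [crick_params] object.
#' @return An object of class `cc_model`: list with `atoms` (a bio3d-style
#'   data.frame: `elety`, `resid`, `chain`, `resno`, `x`, `y`, `z`,
#'   `elesy`), `seqA`, `seqB`, `schedule`, `params`.
#' @examples
#' seq <- lmm_wt_sequence(1526, 1560)  # short canonical stretch
#' reg <- assign_heptad_register(seq, c("1526" = "a"))
#' mod <- build_coiled_coil(seq, schedule = make_motif_schedule(reg))
#' range(dist(model_ca(mod)[1:2, ]))  # consecutive Calpha distance
#' @export
build_coiled_coil <- function(seqA, seqB = seqA, schedule,
                              params = crick_params()) {
  stopifnot(inherits(seqA, "cc_sequence"), inherits(seqB, "cc_sequence"),
            inherits(schedule, "motif_schedule"),
            inherits(params, "crick_params"))
  n <- sum(schedule$length)
  if (length(seqA) != n || length(seqB) != n)
    stop("schedule (", n, " residues) does not tile the sequences (",
         length(seqA), "/", length(seqB), ")")

  rate <- motif_rate_profile(schedule, params$smoothing_b)
  w_alpha <- 360 / params$residues_per_turn
  w0 <- w_alpha - rate                    # supercoil twist, deg/residue
  offs <- ideal_backbone_offsets()
  rshift <- params$minor_radius - offs$CA[["r"]]

  chains <- list(A = 0, B = 180)
  seqs <- list(A = seqA, B = seqB)
  rows <- vector("list", 2L * n)
  k <- 0L
  for (ch in names(chains)) {
    th0 <- chains[[ch]] * pi / 180
    ph1 <- params$strand_phase * pi / 180
    z <- 0
    sq <- seqs[[ch]]
    for (j in seq_len(n)) {
      ax <- c(params$major_radius * cos(th0),
              params$major_radius * sin(th0), z)
      dth <- w0[j] * pi / 180
      tang <- c(-params$major_radius * sin(th0) * dth,
                params$major_radius * cos(th0) * dth,
                params$rise_per_residue)
      tang <- tang / sqrt(sum(tang^2))
      u <- c(cos(th0), sin(th0), 0)
      w <- pracma_cross(tang, u)
      place <- function(off) {
        phi <- ph1 + off[["dphi"]] * pi / 180
        r <- off[["r"]] + rshift
        ax + off[["dz"]] * tang + r * (cos(phi) * u + sin(phi) * w)
      }
      for (atom in c("N", "CA", "C", "O")) {
        p <- place(offs[[atom]])
        k <- k + 1L
        rows[[k]] <- data.frame(
          elety = atom, resid = aa1to3(sq$aa[j]), chain = ch,
          resno = sq$resno[j], x = p[1], y = p[2], z = p[3],
          elesy = substr(atom, 1, 1), stringsAsFactors = FALSE)
      }
      th0 <- th0 + dth
      ph1 <- ph1 + rate[j] * pi / 180
      z <- z + params$rise_per_residue
    }
  }
  atoms <- do.call(rbind, rows)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite geometry generated")
  structure(list(atoms = atoms, seqA = seqA, seqB = seqB,
                 schedule = schedule, params = params),
            class = "cc_model")
}

# per-residue helix phase rate (deg/residue) from a motif schedule, with
# logistic blending at motif boundaries; partial motifs run canonical
motif_rate_profile <- function(schedule, smoothing_b) {
  len <- schedule$length
  N <- schedule$turns_N
  r <- ifelse(is.na(N), 360 * 2 / 7, 360 * N / len)
  n <- sum(len)
  j <- seq_len(n)
  rate <- rep(r[1], n)
  p <- cumsum(len)
  if (length(r) > 1) {
    for (k in seq_len(length(r) - 1)) {
      wdt <- smoothing_b * max(len[k], len[k + 1])
      rate <- rate + (r[k + 1] - r[k]) * stats::plogis((j - (p[k] + 0.5)) / wdt)
    }
  }
  rate
}

aa1to3 <- function(aa) {
  tab <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  out <- tab[aa]
  if (any(is.na(out))) stop("unknown amino acid code")
  unname(out)
}

#' @export
print.cc_model <- function(x, ...) {
  cat(sprintf("cc_model: 2 x %d residues (%d atoms), mode %s\n",
              length(x$seqA), nrow(x$atoms), attr(x$schedule, "mode")))
  invisible(x)
}

#' Extract the Calpha trace of one chain of a model
#'
#' @param model a `cc_model`.
#' @param chain `"A"` or `"B"`.
#' @return n x 3 coordinate matrix, rownames = wild-type residue numbers.
#' @export
model_ca <- function(model, chain = "A") {
  a <- model$atoms
  sel <- a$elety == "CA" & a$chain == chain
  m <- as.matrix(a[sel, c("x", "y", "z")])
  rownames(m) <- a$resno[sel]
  m
}

#' Supercoil twist profile of a model-frame Calpha trace
#'
#' Diagnostic for built models (whose supercoil axis is z): the azimuthal
#' advance per residue of seven-residue windowed Calpha centroids, which
#' track the local helix axis.  Negative values are left-handed.
#'
#' @param ca n x 3 Calpha matrix in the builder frame.
#' @param window centroid window (odd), default 7.
#' @param lag residue lag over which the azimuthal advance is averaged;
#'   the default 7 spans two full minor-helix periods, cancelling the
#'   period-7 ripple the helix imprints on the centroid track.
#' @return data.frame `i` (window-centre index at the start of the lag),
#'   `twist_deg` (per residue).
#' @export
supercoil_twist_profile <- function(ca, window = 7, lag = 7) {
  stopifnot(window %% 2 == 1, nrow(ca) > window + lag)
  h <- (window - 1) / 2
  n <- nrow(ca)
  idx <- (1 + h):(n - h)
  cen <- t(vapply(idx, function(i) colMeans(ca[(i - h):(i + h), , drop = FALSE]),
                  numeric(3)))
  az <- atan2(cen[, 2], cen[, 1])
  m <- length(az) - lag
  d <- az[(1 + lag):length(az)] - az[1:m]
  d <- atan2(sin(d), cos(d)) * 180 / pi / lag   # wrap, per residue
  data.frame(i = idx[1:m], twist_deg = d)
}
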