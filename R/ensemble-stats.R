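#' RMSD of each frame from the initial structure
#'
#' Optimal-superposition (Kabsch) Calpha RMSD of every frame with respect
#' to the first retained frame.
#'
#' @param ens a [cc_ensemble].
#' @param elety atom selection (default `"CA"`).
#' @return data.frame `frame`, `time_ns`, `rmsd` (A); first frame is 0.
#' @export
rmsd_vs_initial <- function(ens, elety = "CA") {
  stopifnot(inherits(ens, "cc_ensemble"))
  sel <- atom_sel(ens, elety = elety)
  if (!length(sel)) stop("no atoms matching selection")
  inds <- bio3d::atom2xyz(sel)
  r <- fit_rmsd(ens$xyz[1, inds], ens$xyz[, inds, drop = FALSE])
  data.frame(frame = seq_len(n_frames(ens)), time_ns = ens$time_ns,
             rmsd = r)
}

# Kabsch-superposed RMSD of each row of xyz against the reference vector,
# without the printed-precision rounding of bio3d::rmsd()
fit_rmsd <- function(ref, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  fitted <- bio3d::fit.xyz(ref, xyz, fixed.inds = seq_along(ref),
                           mobile.inds = seq_along(ref))
  if (is.null(dim(fitted))) fitted <- matrix(fitted, nrow = 1)
  apply(fitted, 1, function(v)
    sqrt(mean(rowSums(matrix((v - ref)^2, ncol = 3, byrow = TRUE)))))
}

#' Per-residue root mean square fluctuation
#'
#' Frames are superposed iteratively onto their running mean structure
#' until the mean changes by less than `tol` (A); RMSF is then the root
#' mean squared deviation of each atom from the converged mean.
#'
#' @param ens a [cc_ensemble] with at least 2 frames.
#' @param elety atom selection (default `"CA"`).
#' @param fit superpose frames before measuring (default TRUE); disable
#'   only for toy geometries in a common frame.
#' @param tol convergence tolerance on the mean structure, A.
#' @param max_iter maximum superposition iterations.
#' @return A `residue_profile` (`mean` = RMSF, `sd` = NA).
#' @export
rmsf <- function(ens, elety = "CA", fit = TRUE, tol = 1e-4, max_iter = 100) {
  stopifnot(inherits(ens, "cc_ensemble"), n_frames(ens) >= 2)
  sel <- atom_sel(ens, elety = elety)
  inds <- bio3d::atom2xyz(sel)
  xyz <- ens$xyz[, inds, drop = FALSE]
  if (fit) {
    mean_xyz <- xyz[1, ]
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      xyz <- bio3d::fit.xyz(mean_xyz, xyz,
                            fixed.inds = seq_along(mean_xyz),
                            mobile.inds = seq_along(mean_xyz))
      new_mean <- colMeans(xyz)
      delta <- sqrt(max(rowSums(matrix((new_mean - mean_xyz)^2,
                                       ncol = 3, byrow = TRUE))))
      mean_xyz <- new_mean
      if (delta < tol) { conv <- TRUE; break }
    }
    if (!conv) stop("mean-structure superposition did not converge in ",
                    max_iter, " iterations")
  }
  mu <- colMeans(xyz)
  dev2 <- sweep(xyz, 2, mu)^2
  per_atom <- matrix(colMeans(dev2), ncol = 3, byrow = TRUE)
  val <- sqrt(rowSums(per_atom))
  residue_profile(
    data.frame(chain = ens$atoms$chain[sel], resno = ens$atoms$resno[sel],
               mean = val, sd = NA_real_, gap = FALSE),
    "RMSF", "angstrom", n_frames(ens))
}

#' Leader clustering of ensemble structures
#'
#' Deterministic streaming clustering on Calpha RMSD: in time order, each
#' frame joins the first existing cluster whose representative (founding
#' frame) lies within `cutoff`, else it founds a new cluster.
#'
#' @param ens a [cc_ensemble].
#' @param cutoff RMSD cutoff, A (default 8).
#' @param elety atom selection (default `"CA"`).
#' @return A list of class `cluster_result`: `labels` (per frame),
#'   `populations` (% of frames per cluster), `representatives` (founding
#'   frame indices), `cutoff`.
#' @export
cluster_structures <- function(ens, cutoff = 8, elety = "CA") {
  stopifnot(inherits(ens, "cc_ensemble"), cutoff > 0)
  sel <- atom_sel(ens, elety = elety)
  inds <- bio3d::atom2xyz(sel)
  nf <- n_frames(ens)
  labels <- integer(nf)
  reps <- integer(0)
  for (f in seq_len(nf)) {
    assigned <- FALSE
    for (k in seq_along(reps)) {
      r <- fit_rmsd(ens$xyz[reps[k], inds], ens$xyz[f, inds])
      if (r < cutoff) { labels[f] <- k; assigned <- TRUE; break }
    }
    if (!assigned) {
      reps <- c(reps, f)
      labels[f] <- length(reps)
    }
  }
  pop <- 100 * tabulate(labels, nbins = length(reps)) / nf
  structure(list(labels = labels, populations = pop,
                 representatives = reps, cutoff = cutoff),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d clusters (cutoff %.3g A)\n",
              length(x$populations), x$cutoff))
  for (k in seq_along(x$populations))
    cat(sprintf("  cluster %d: %.1f%% (representative frame %d)\n",
                k, x$populations[k], x$representatives[k]))
  invisible(x)
}
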