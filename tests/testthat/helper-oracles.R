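# Independent oracles and toy-fixture builders used across the suite.
# These deliberately re-derive quantities from first principles (SVD
# Kabsch, O(n^2) enumeration, direct formulas) so that the package
# implementations are checked against something they do not share code
# with.

# --- rigid superposition (Kabsch via SVD) ---------------------------------
oracle_kabsch <- function(P, Q) {
  # returns rotation R, translation t mapping Q onto P, and the rmsd
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(Q, 2, cq)) %*% sweep(P, 2, cp)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  Qf <- sweep(sweep(Q, 2, cq) %*% R, 2, cp, "+")
  list(R = R, rmsd = sqrt(mean(rowSums((Qf - P)^2))), fitted = Qf)
}

# --- leader clustering, direct pass ---------------------------------------
oracle_leader <- function(xyz_frames, cutoff) {
  reps <- integer(0)
  labels <- integer(nrow(xyz_frames))
  for (f in seq_len(nrow(xyz_frames))) {
    labels[f] <- 0L
    for (k in seq_along(reps)) {
      P <- matrix(xyz_frames[reps[k], ], ncol = 3, byrow = TRUE)
      Q <- matrix(xyz_frames[f, ], ncol = 3, byrow = TRUE)
      if (oracle_kabsch(P, Q)$rmsd < cutoff) { labels[f] <- k; break }
    }
    if (labels[f] == 0L) { reps <- c(reps, f); labels[f] <- length(reps) }
  }
  list(labels = labels, representatives = reps)
}

# --- RMSF by the direct two-pass definition (no superposition) ------------
oracle_rmsf <- function(xyz_frames) {
  mu <- colMeans(xyz_frames)
  dev2 <- sweep(xyz_frames, 2, mu)^2
  per_atom <- matrix(colMeans(dev2), ncol = 3, byrow = TRUE)
  sqrt(rowSums(per_atom))
}

# --- salt bridges by all-pairs enumeration --------------------------------
oracle_salt_bridges <- function(ens, cutoff = 4) {
  a <- ens$atoms
  centre <- function(frame, chain, resno) {
    ii <- which(a$chain == chain & a$resno == resno)
    resid <- a$resid[ii[1]]
    nm <- switch(resid, LYS = "NZ", ARG = c("NH1", "NH2"),
                 ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
    sel <- ii[a$elety[ii] %in% nm]
    colMeans(matrix(ens$xyz[frame, as.vector(rbind(3 * sel - 2, 3 * sel - 1,
                                                   3 * sel))],
                    ncol = 3, byrow = TRUE))
  }
  res <- unique(a[a$resid %in% c("LYS", "ARG", "ASP", "GLU"),
                  c("chain", "resno", "resid")])
  basics <- res[res$resid %in% c("LYS", "ARG"), ]
  acids <- res[res$resid %in% c("ASP", "GLU"), ]
  occ <- matrix(0, nrow(basics), nrow(acids))
  counts <- integer(nrow(ens$xyz))
  for (f in seq_len(nrow(ens$xyz))) {
    for (i in seq_len(nrow(basics))) for (j in seq_len(nrow(acids))) {
      d <- sqrt(sum((centre(f, basics$chain[i], basics$resno[i]) -
                       centre(f, acids$chain[j], acids$resno[j]))^2))
      if (d < cutoff) { occ[i, j] <- occ[i, j] + 1; counts[f] <- counts[f] + 1 }
    }
  }
  list(occ = occ / nrow(ens$xyz), counts = counts,
       basics = basics, acids = acids)
}

# --- toy ensemble builders ------------------------------------------------
# two straight parallel CA chains, n residues, 'sep' apart, spacing 'dz'
toy_parallel_chains <- function(n = 20, sep = 10, dz = 1.5, frames = 1) {
  atoms <- data.frame(
    elety = "CA", resid = "ALA",
    chain = rep(c("A", "B"), each = n),
    resno = rep(seq_len(n) + 1000L, 2),
    elesy = "C", stringsAsFactors = FALSE)
  xyzA <- cbind(0, 0, dz * (seq_len(n) - 1))
  xyzB <- cbind(sep, 0, dz * (seq_len(n) - 1))
  v <- as.vector(t(rbind(xyzA, xyzB)))
  cc_ensemble(atoms, matrix(rep(v, frames), nrow = frames, byrow = TRUE))
}

# single-chain CA trace ensemble from an n x 3 matrix (or list of them)
toy_ca_ensemble <- function(xyz, chain = "A") {
  if (!is.list(xyz)) xyz <- list(xyz)
  n <- nrow(xyz[[1]])
  atoms <- data.frame(elety = "CA", resid = "ALA", chain = chain,
                      resno = seq_len(n), elesy = "C",
                      stringsAsFactors = FALSE)
  cc_ensemble(atoms, t(vapply(xyz, function(m) as.vector(t(m)),
                              numeric(3 * n))))
}

# ideal straight alpha-helix CA trace (rise d, twist deg/res, radius r)
ideal_ca_helix <- function(n, twist = 100, rise = 1.5, radius = 2.3) {
  th <- (seq_len(n) - 1) * twist * pi / 180
  cbind(radius * cos(th), radius * sin(th), rise * (seq_len(n) - 1))
}

# charged-residue toy: LYS NZ and GLU OE1/OE2 point charges at given
# centre separation, one pair per chain label given
toy_salt_pair <- function(dist_frames, chainK = "A", chainE = "A") {
  atoms <- data.frame(
    elety = c("NZ", "OE1", "OE2"),
    resid = c("LYS", "GLU", "GLU"),
    chain = c(chainK, chainE, chainE),
    resno = c(1L, 2L, 2L), elesy = c("N", "O", "O"),
    stringsAsFactors = FALSE)
  xyz <- t(vapply(dist_frames, function(d)
    as.vector(t(rbind(c(0, 0, 0), c(d, 0.5, 0), c(d, -0.5, 0)))),
    numeric(9)))
  cc_ensemble(atoms, xyz)
}

# standard-region fixtures
wt_register <- function() {
  assign_heptad_register(lmm_wt_sequence(), c("1604" = "d"), 1582L)
}

small_wt_model <- function() {
  build_scenario_model("WT")
}
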