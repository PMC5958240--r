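jittered_frames <- function(n_frames = 5, n_atoms = 9, sd = 0.8, seed = 3) {
  set.seed(seed)
  base <- matrix(stats::runif(n_atoms * 3, -5, 5), n_atoms, 3)
  t(vapply(seq_len(n_frames), function(f)
    as.vector(t(base + matrix(stats::rnorm(n_atoms * 3, 0, sd),
                              n_atoms, 3))),
    numeric(3 * n_atoms)))
}

as_toy_ens <- function(xyz) {
  n <- ncol(xyz) / 3
  atoms <- data.frame(elety = "CA", resid = "ALA", chain = "A",
                      resno = seq_len(n), elesy = "C")
  cc_ensemble(atoms, xyz)
}

test_that("RMSD vs initial is zero for identical or rigidly moved frames", {
  xyz <- jittered_frames(1)
  ens <- as_toy_ens(rbind(xyz, xyz, xyz))
  r <- rmsd_vs_initial(ens)
  expect_true(all(r$rmsd < 1e-6))

  # rigid translation and rotation are absorbed by the superposition
  m <- matrix(xyz[1, ], ncol = 3, byrow = TRUE)
  th <- 0.9
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- sweep(m %*% R, 2, c(5, 5, 5), "+")
  ens2 <- as_toy_ens(rbind(xyz, matrix(as.vector(t(moved)), 1)))
  expect_lt(rmsd_vs_initial(ens2)$rmsd[2], 1e-6)
})

test_that("RMSD agrees with the hand-written Kabsch oracle", {
  xyz <- jittered_frames(4)
  ens <- as_toy_ens(xyz)
  r <- rmsd_vs_initial(ens)
  P <- matrix(xyz[1, ], ncol = 3, byrow = TRUE)
  for (f in 2:4) {
    Q <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    expect_equal(r$rmsd[f], oracle_kabsch(P, Q)$rmsd, tolerance = 1e-6)
  }
})

test_that("a radial single-atom displacement leaves the rotation null", {
  # equilateral triangle, one vertex displaced outward along its own
  # radial direction: the optimal rotation is the identity and the
  # fitted RMSD follows from the translation-corrected deviations
  d <- 0.9
  P <- rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0), c(-0.5, -sqrt(3) / 2, 0))
  Q <- P
  Q[1, ] <- Q[1, ] + d * c(1, 0, 0)
  o <- oracle_kabsch(P, Q)
  expect_equal(o$R, diag(3), tolerance = 1e-9)
  expect_equal(o$rmsd, d * sqrt(2) / 3, tolerance = 1e-9)
  ens <- as_toy_ens(rbind(as.vector(t(P)), as.vector(t(Q))))
  expect_equal(rmsd_vs_initial(ens)$rmsd[2], o$rmsd, tolerance = 1e-6)
  # without translation removal the displacement spreads as d / sqrt(3)
  expect_equal(sqrt(mean(rowSums((Q - P)^2))), d / sqrt(3))
})

test_that("RMSF matches the direct-definition oracle", {
  # static ensemble: zero everywhere
  xyz1 <- jittered_frames(1)
  ens0 <- as_toy_ens(rbind(xyz1, xyz1, xyz1))
  expect_true(all(rmsf(ens0)$mean < 1e-9))

  # one atom alternating +/- a along x, superposition disabled
  a <- 0.7
  base <- matrix(c(0, 0, 0, 3, 0, 0, 0, 3, 0, 0, 0, 3), 4, 3, byrow = TRUE)
  f1 <- base; f1[1, 1] <- a
  f2 <- base; f2[1, 1] <- -a
  ens1 <- as_toy_ens(rbind(as.vector(t(f1)), as.vector(t(f2))))
  r1 <- rmsf(ens1, fit = FALSE)
  expect_equal(r1$mean[1], a)
  expect_true(all(r1$mean[-1] < 1e-12))

  # random 5-frame toy equals the brute-force two-pass formula
  xyz <- jittered_frames(5)
  expect_equal(rmsf(as_toy_ens(xyz), fit = FALSE)$mean, oracle_rmsf(xyz))
})

test_that("RMSF is invariant under a global rigid transform", {
  xyz <- jittered_frames(5)
  th <- 1.3
  R <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
  moved <- t(apply(xyz, 1, function(v) {
    m <- sweep(matrix(v, ncol = 3, byrow = TRUE) %*% R, 2, c(9, -4, 2), "+")
    as.vector(t(m))
  }))
  expect_equal(rmsf(as_toy_ens(moved))$mean, rmsf(as_toy_ens(xyz))$mean,
               tolerance = 1e-6)
})

test_that("leader clustering reproduces the direct pass", {
  # two conformers differing by a large internal deformation, interleaved
  set.seed(7)
  A <- matrix(stats::runif(30, -5, 5), 10, 3)
  B <- A
  B[1:5, ] <- B[1:5, ] + 25          # half the atoms displaced
  frames <- t(vapply(1:6, function(f) {
    m <- (if (f %% 2 == 1) A else B) +
      matrix(stats::rnorm(30, 0, 0.3), 10, 3)
    as.vector(t(m))
  }, numeric(30)))
  ens <- as_toy_ens(frames)
  cl <- cluster_structures(ens, cutoff = 8)
  expect_equal(length(cl$populations), 2L)
  expect_equal(cl$labels, rep(c(1L, 2L), 3))
  expect_equal(cl$populations, c(50, 50))

  # all frames identical: a single cluster holding 100%
  one <- as_toy_ens(frames[c(1, 1, 1), ])
  c1 <- cluster_structures(one, 8)
  expect_equal(c1$populations, 100)

  # 50-frame toy against the independent leader oracle
  set.seed(21)
  drift <- t(vapply(1:50, function(f) {
    m <- A + matrix(stats::rnorm(30, 0, 4), 10, 3)
    as.vector(t(m))
  }, numeric(30)))
  ens50 <- as_toy_ens(drift)
  cl50 <- cluster_structures(ens50, cutoff = 5)
  orc <- oracle_leader(drift, 5)
  expect_equal(cl50$labels, orc$labels)
  expect_equal(cl50$representatives, orc$representatives)
  expect_equal(sum(cl50$populations), 100, tolerance = 1e-9)
  # every member lies within the cutoff of its representative
  for (f in seq_len(50)) {
    rep_f <- cl50$representatives[cl50$labels[f]]
    P <- matrix(drift[rep_f, ], ncol = 3, byrow = TRUE)
    Q <- matrix(drift[f, ], ncol = 3, byrow = TRUE)
    expect_lt(oracle_kabsch(P, Q)$rmsd, 5)
  }
})
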