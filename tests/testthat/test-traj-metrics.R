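test_that("D_com on straight parallel chains equals the separation", {
  ens <- toy_parallel_chains(n = 20, sep = 10, frames = 3)
  p <- dcom_profile(ens)
  expect_equal(nrow(p), 20 - 6)       # undefined at 3 terminal residues
  expect_true(all(abs(p$mean - 10) < 1e-9))
  expect_true(all(p$sd < 1e-12))
})

test_that("D_com on a built model tracks twice the major radius", {
  mod <- small_wt_model()
  p <- dcom_profile(as_ensemble(mod))
  interior <- p$mean[10:(nrow(p) - 10)]
  expect_true(all(abs(interior - 2 * 4.9) < 1))
  expect_true(all(p$sd == 0))         # single frame: SD 0 everywhere
})

test_that("heptad length matches the closed-form oracle on ideal traces", {
  # straight line of points 1.5 A apart: exactly 10.5 by collinearity
  line <- cbind(0, 0, 1.5 * (0:24))
  p <- heptad_length_profile(toy_ca_ensemble(line))
  expect_true(all(abs(p$mean - 10.5) < 1e-9))

  # ideal straight alpha-helix: chord + axial rise closed form on the
  # 7-residue windowed centroids
  hx <- ideal_ca_helix(30)
  twist <- 100 * pi / 180
  # centroid track: radius shrinks by the Dirichlet window factor
  rc <- 2.3 * abs(sum(cos((-3:3) * twist))) / 7
  chord <- 2 * rc * abs(sin(7 * twist / 2))
  expected <- sqrt((7 * 1.5)^2 + chord^2)
  p2 <- heptad_length_profile(toy_ca_ensemble(hx))
  expect_true(all(abs(p2$mean - expected) < 1e-9))
  expect_equal(mean(p2$mean), 10.5, tolerance = 1e-3)

  # homogeneity: scaling coordinates by 2 doubles all heptad lengths
  p3 <- heptad_length_profile(toy_ca_ensemble(2 * hx))
  expect_equal(p3$mean, 2 * p2$mean)

  # windowed-distances variant agrees on the straight line
  p4 <- heptad_length_profile(toy_ca_ensemble(line), method = "distances")
  expect_true(all(abs(p4$mean - 10.5) < 1e-9))
})

test_that("inter-heptad angles read 180 minus the local direction change", {
  line <- cbind(0, 0, 1.5 * (0:24))
  p <- inter_heptad_angle_profile(toy_ca_ensemble(line))
  expect_true(all(abs(p$mean - 180) < 1e-9))

  # 30-degree direction change at a vertex gives a 150-degree angle
  bend <- 30 * pi / 180
  arm2 <- cbind(sin(bend) * 1.5 * (0:12), 0, cos(bend) * 1.5 * (0:12))
  pts <- rbind(cbind(0, 0, -1.5 * (12:1)), arm2)
  pb <- inter_heptad_angle_profile(toy_ca_ensemble(pts))
  vertex <- pb[pb$resno == 13, ]     # the bend point
  expect_equal(vertex$mean, 150, tolerance = 1e-6)

  # ideal helix: constant interior value slightly below 180 (brute force)
  hx <- ideal_ca_helix(30)
  i <- 15
  v1 <- hx[i - 7, ] - hx[i, ]; v2 <- hx[i + 7, ] - hx[i, ]
  brute <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  ph <- inter_heptad_angle_profile(toy_ca_ensemble(hx))
  expect_true(all(abs(ph$mean - brute) < 1e-9))
  expect_lt(brute, 180)
  expect_gt(brute, 175)
})

test_that("dihedral helicity counts residues inside the alpha windows", {
  # all residues at canonical helical dihedrals
  mod <- small_wt_model()
  expect_equal(helicity(as_ensemble(mod))$overall, 1.0)

  # extended chain: 0%
  bb <- ccrod:::ideal_helix_backbone(n = 12, phi = -120, psi = 120)
  atoms <- data.frame(elety = rep(c("N", "CA", "C"), 12),
                      resid = "ALA", chain = "A",
                      resno = rep(1:12, each = 3), elesy = c("N", "C", "C"))
  xyz <- matrix(as.vector(t(do.call(rbind, lapply(1:12, function(i)
    rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ]))))), nrow = 1)
  expect_equal(helicity(cc_ensemble(atoms, xyz))$overall, 0)
})

test_that("end-to-end distance follows midpoint geometry", {
  ens <- toy_parallel_chains(n = 21, sep = 10, dz = 1.5, frames = 2)
  L <- 20 * 1.5 / 10   # nm
  ee <- end_to_end(ens)
  expect_equal(ee$mean_nm, L)
  expect_equal(ee$sd_nm, 0)

  # rigid transform invariance
  ens2 <- ens
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  for (f in 1:2) {
    m <- matrix(ens$xyz[f, ], ncol = 3, byrow = TRUE) %*% R
    ens2$xyz[f, ] <- as.vector(t(sweep(m, 2, c(5, -3, 11), "+")))
  }
  expect_equal(end_to_end(ens2)$mean_nm, L)

  # 90-degree rigid bend at the midpoint shortens the rod to L / sqrt(2)
  n <- 21
  half <- 11:21
  bent <- cbind(0, 0, 1.5 * (0:20))
  bent[half, ] <- cbind(1.5 * (0:10), 0, 1.5 * 10)
  atoms <- data.frame(elety = "CA", resid = "ALA",
                      chain = rep(c("A", "B"), each = n),
                      resno = rep(1:n, 2), elesy = "C")
  xyz <- matrix(as.vector(t(rbind(bent, bent))), nrow = 1)
  ee_b <- end_to_end(cc_ensemble(atoms, xyz))
  expect_equal(ee_b$mean_nm, L / sqrt(2), tolerance = 1e-9)
})

test_that("profile metrics on one frame equal their means with SD 0", {
  mod <- small_wt_model()
  ens1 <- as_ensemble(mod)
  for (p in list(dcom_profile(ens1), heptad_length_profile(ens1),
                 inter_heptad_angle_profile(ens1)))
    expect_true(all(p$sd == 0))
})

test_that("metrics are invariant under rigid transforms of each frame", {
  mod <- small_wt_model()
  ens <- gen_ensemble(mod, n_frames = 3, seed = 2, mode = "bend",
                      bend_mean_deg = 8, bend_sd_deg = 3)
  ens2 <- ens
  th <- -1.1
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  for (f in seq_len(nrow(ens$xyz))) {
    m <- matrix(ens$xyz[f, ], ncol = 3, byrow = TRUE) %*% R
    ens2$xyz[f, ] <- as.vector(t(sweep(m, 2, c(-8, 2, 30), "+")))
  }
  expect_equal(dcom_profile(ens2)$mean, dcom_profile(ens)$mean,
               tolerance = 1e-9)
  expect_equal(heptad_length_profile(ens2)$mean,
               heptad_length_profile(ens)$mean, tolerance = 1e-9)
  expect_equal(inter_heptad_angle_profile(ens2)$mean,
               inter_heptad_angle_profile(ens)$mean, tolerance = 1e-9)
  expect_equal(end_to_end(ens2)$per_frame_nm, end_to_end(ens)$per_frame_nm,
               tolerance = 1e-9)
})
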