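test_that("Shrake-Rupley SASA matches closed forms", {
  # isolated atom: 4 pi (r + probe)^2 exactly
  r <- 1.8
  expect_equal(sasa_atoms(matrix(0, 1, 3), r), 4 * pi * (r + 1.4)^2)
  # atom fully enclosed by a shell of overlapping atoms: 0
  shell <- 2 * rbind(diag(3), -diag(3))
  s <- sasa_atoms(rbind(c(0, 0, 0), shell), c(1.5, rep(2.5, 6)))
  expect_equal(s[1], 0)
  # two half-buried equal atoms are symmetric up to test-point placement
  two <- sasa_atoms(rbind(c(0, 0, 0), c(2, 0, 0)), c(1.7, 1.7))
  expect_equal(two[1], two[2], tolerance = 0.01)
  expect_lt(two[1], 4 * pi * 3.1^2)
})

test_that("RSA of X in an extended Gly-X-Gly input is 1 by construction", {
  bb <- ccrod:::ideal_helix_backbone(n = 3, phi = -120, psi = 120)
  cb <- bb$CA[2, ] + c(0.5, 1.3, 0.3)
  atoms <- data.frame(
    elety = c("N", "CA", "C", "O", "N", "CA", "C", "O", "CB",
              "N", "CA", "C", "O"),
    resid = c(rep("GLY", 4), rep("ALA", 5), rep("GLY", 4)),
    chain = "A", resno = rep(1:3, c(4, 5, 4)),
    elesy = c("N", "C", "C", "O", "N", "C", "C", "O", "C",
              "N", "C", "C", "O"))
  xyz <- rbind(bb$N[1, ], bb$CA[1, ], bb$C[1, ], bb$O[1, ],
               bb$N[2, ], bb$CA[2, ], bb$C[2, ], bb$O[2, ], cb,
               bb$N[3, ], bb$CA[3, ], bb$C[3, ], bb$O[3, ])
  ens <- cc_ensemble(atoms, matrix(as.vector(t(xyz)), 1))
  p <- rsa_profile(ens)
  expect_equal(p$mean[p$resno == 2], 1.0, tolerance = 1e-12)
})

test_that("core heptad positions of a built model are more buried", {
  mod <- small_wt_model()
  p <- rsa_profile(as_ensemble(mod), n_sphere_points = 240)
  reg <- wt_register()
  p$letter <- reg$letter[match(p$resno, reg$resno)]
  interior <- p[p$resno > 1535 & p$resno < 1680 & p$chain == "A", ]
  core <- interior$mean[interior$letter %in% c("a", "d")]
  shell <- interior$mean[interior$letter %in% c("b", "c", "f")]
  expect_lt(mean(core), mean(shell))
  # interior RSA stays within the physically sensible band
  expect_true(all(interior$mean >= 0 & interior$mean <= 1.25))
})

test_that("unknown elements fall back to the default radius with warning", {
  atoms <- data.frame(elety = "X1", resid = "ALA", chain = "A",
                      resno = 1L, elesy = "X")
  expect_warning(r <- ccrod:::atom_radii(atoms, default_radius = 2),
                 "unknown element")
  expect_equal(r, 2)
})

test_that("salt-bridge occupancy matches direct geometry", {
  # static frame: NZ 3.5 A from the carboxylate midpoint -> occupancy 1
  ens <- toy_salt_pair(3.5)
  out <- salt_bridge_occupancy(ens)
  expect_equal(nrow(out$bridges), 1L)
  expect_equal(out$bridges$occupancy, 1.0)
  expect_true(out$bridges$intra)
  # centres at 6 A in all frames: pair absent
  far <- salt_bridge_occupancy(toy_salt_pair(c(6, 6, 6)))
  expect_equal(nrow(far$bridges), 0L)
  # fractional occupancy counts bridged frames
  mix <- salt_bridge_occupancy(toy_salt_pair(c(3, 5, 3, 3)))
  expect_equal(mix$bridges$occupancy, 0.75)
  expect_equal(mix$per_frame_count$counts, c(1L, 0L, 1L, 1L))
})

test_that("occupancies equal the brute-force all-pairs oracle", {
  # 10-frame toy with several charged residues in two chains
  set.seed(11)
  mk_res <- function(resid, chain, resno, base) {
    elety <- switch(resid, LYS = "NZ", ARG = c("NH1", "NH2"),
                    ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
    data.frame(elety = elety, resid = resid, chain = chain, resno = resno,
               elesy = substr(elety, 1, 1),
               x = base[1] + stats::runif(length(elety), -0.5, 0.5),
               y = base[2] + stats::runif(length(elety), -0.5, 0.5),
               z = base[3] + stats::runif(length(elety), -0.5, 0.5))
  }
  spec <- list(list("LYS", "A", 1L, c(0, 0, 0)),
               list("GLU", "A", 2L, c(3, 1, 0)),
               list("ARG", "A", 3L, c(7, 0, 0)),
               list("ASP", "B", 4L, c(1, 3, 1)),
               list("GLU", "B", 5L, c(8, 2, 0)),
               list("LYS", "B", 6L, c(4, 4, 2)))
  a0 <- do.call(rbind, lapply(spec, function(s) do.call(mk_res, s)))
  xyz <- t(vapply(1:10, function(f) {
    m <- as.matrix(a0[, c("x", "y", "z")]) +
      matrix(stats::rnorm(nrow(a0) * 3, 0, 0.8), nrow(a0), 3)
    as.vector(t(m))
  }, numeric(3 * nrow(a0))))
  ens <- cc_ensemble(a0[, c("elety", "resid", "chain", "resno", "elesy")],
                     xyz)
  out <- salt_bridge_occupancy(ens, cutoff = 4)
  orc <- oracle_salt_bridges(ens, cutoff = 4)
  expect_equal(out$per_frame_count$counts, orc$counts)
  for (k in seq_len(nrow(out$bridges))) {
    b <- out$bridges[k, ]
    i <- which(orc$basics$chain == b$donor_chain &
                 orc$basics$resno == b$donor_resno)
    j <- which(orc$acids$chain == b$acceptor_chain &
                 orc$acids$resno == b$acceptor_resno)
    expect_equal(b$occupancy, orc$occ[i, j])
  }
  expect_equal(sum(out$bridges$occupancy) * 10, sum(orc$occ) * 10)
})

test_that("residues with missing charged-group atoms are excluded", {
  ens <- toy_salt_pair(3.5)
  ens$atoms$elety[1] <- "CB"    # LYS loses its NZ
  expect_warning(out <- salt_bridge_occupancy(ens), "missing")
  expect_equal(nrow(out$bridges), 0L)
})
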