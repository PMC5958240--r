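test_that("filament summary statistics follow their definitions", {
  rec <- data.frame(group = c("WT", "WT", "WT"), length_nm = c(1, 2, 3))
  out <- filament_stats(rec)
  len <- out[out$variable == "length_nm", ]
  expect_equal(len$mean, 2)
  expect_equal(len$sem, stats::sd(1:3) / sqrt(3))
  expect_equal(len$n, 3L)
})

test_that("identical groups show no significant difference", {
  rec <- data.frame(group = rep(c("WT", "MUT"), each = 10),
                    length_nm = rep(c(100, 110, 120, 130, 140), 4))
  out <- filament_stats(rec)
  p <- out$p_vs_ref[out$group == "MUT"]
  expect_gt(p, 0.05)
  expect_equal(out$stars[out$group == "MUT"], "")
})

test_that("Welch p-values agree with a permutation oracle", {
  set.seed(5)
  x <- stats::rnorm(15, 10, 2)
  y <- stats::rnorm(15, 12, 3)
  rec <- data.frame(group = rep(c("WT", "MUT"), each = 15),
                    length_nm = c(x, y))
  p_welch <- filament_stats(rec)$p_vs_ref
  p_welch <- p_welch[!is.na(p_welch)]
  # permutation test on the mean difference, 1e4 resamples
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  set.seed(99)
  perm <- mean(replicate(1e4, {
    idx <- sample(30, 15)
    abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12
  }))
  expect_lt(abs(p_welch - perm), 3 * sqrt(perm * (1 - perm) / 1e4) + 0.01)
})

test_that("synthetic populations recover the preset means", {
  fil <- gen_filaments(c("WT", "A1603P"), seed = 1)
  out <- filament_stats(fil$measurements)
  wt_len <- out[out$group == "WT" & out$variable == "length_nm", ]
  expect_equal(wt_len$n, 34L)
  expect_lt(abs(wt_len$mean - 431), 2 * 34)
  a_len <- out[out$group == "A1603P" & out$variable == "length_nm", ]
  expect_equal(a_len$n, 24L)
  expect_lt(abs(a_len$mean - 208), 2 * 16)
  # sample SEM consistent with the SD = SEM * sqrt(n) construction
  expect_lt(abs(wt_len$sem - 34) / 34, 0.45)
})

test_that("bundle fractions count fields once and bound the estimate", {
  rec <- data.frame(group = "G", field_id = rep(1:10, each = 2),
                    bundled = rep(c(TRUE, FALSE), each = 10))
  out <- bundle_fraction(rec)
  expect_equal(out$n_fields, 10L)
  expect_equal(out$percent_bundled, 50)
  all_b <- bundle_fraction(data.frame(group = "G", field_id = 1:5,
                                      bundled = TRUE))
  expect_equal(all_b$percent_bundled, 100)
  none <- bundle_fraction(data.frame(group = "G", field_id = 1:5,
                                     bundled = FALSE))
  expect_equal(none$percent_bundled, 0)
  # Bernoulli(0.7) draws land inside the binomial interval of the truth
  fil <- gen_filaments("K1617del", n_fields = 200, seed = 4)
  bf <- bundle_fraction(fil$fields)
  expect_gt(70, bf$ci_lo)
  expect_lt(70, bf$ci_hi)
})

test_that("solubility fractions are clipped and midpoints recovered", {
  pts <- data.frame(NaCl_mM = c(50, 150, 250, 350, 500),
                    supernatant = c(0, 0.2, 0.5, 0.9, 1.0), total = 1)
  out <- solubility_curve(pts)
  expect_equal(out$fraction_soluble, pts$supernatant)
  over <- pts; over$supernatant[5] <- 1.2
  expect_warning(oc <- solubility_curve(over), "clipped")
  expect_equal(oc$fraction_soluble[5], 1)
  expect_true(all(oc$fraction_soluble >= 0 & oc$fraction_soluble <= 1))

  # logistic synthetic curve: midpoint within 10 mM of truth
  sol <- gen_solubility("WT", NaCl_mM = seq(25, 500, by = 25),
                        noise_sd = 0.01, seed = 2)
  fit <- solubility_curve(sol)
  expect_lt(abs(attr(fit, "midpoints")[["WT"]] - 250), 10)

  # the A1603P preset stays soluble at lower salt than WT
  both <- solubility_curve(gen_solubility(c("WT", "A1603P"), seed = 3))
  mids <- attr(both, "midpoints")
  expect_lt(mids[["A1603P"]], mids[["WT"]])
})

test_that("integration scoring sums to 100% and flags unknown labels", {
  sc <- data.frame(group = "WT", experiment = 1,
                   cell_id = 1:30,
                   category = rep(c("integrated", "partial", "aggregated"),
                                  c(15, 10, 5)))
  out <- integration_summary(sc)
  expect_equal(sum(out$per_experiment$percent), 100, tolerance = 1e-9)
  expect_equal(out$per_experiment$percent,
               c(50, 100 * 10 / 30, 100 * 5 / 30))
  all_int <- data.frame(group = "WT", experiment = 1, cell_id = 1:30,
                        category = "integrated")
  expect_equal(integration_summary(all_int)$per_experiment$percent,
               c(100, 0, 0))
  bad <- sc; bad$category[1] <- "odd"
  expect_error(integration_summary(bad), "unknown category")
  small <- sc[1:10, ]
  expect_warning(integration_summary(small), "only 10 cells")
})

test_that("multinomial scoring recovers the generating probabilities", {
  set.seed(12)
  probs <- list(WT = c(0.8, 0.15, 0.05), MUT = c(0.3, 0.3, 0.4))
  cats <- c("integrated", "partial", "aggregated")
  sc <- do.call(rbind, lapply(names(probs), function(g)
    do.call(rbind, lapply(1:3, function(e)
      data.frame(group = g, experiment = e, cell_id = 1:40,
                 category = sample(cats, 40, TRUE, probs[[g]]))))))
  out <- integration_summary(sc)
  for (g in names(probs)) for (k in seq_along(cats)) {
    row <- out$summary[out$summary$group == g &
                         out$summary$category == cats[k], ]
    expect_lt(abs(row$mean - 100 * probs[[g]][k]),
              max(2 * row$sd, 15))
  }
  expect_equal(sum(out$per_experiment$percent), 600, tolerance = 1e-9)
})
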