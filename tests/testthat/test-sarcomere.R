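test_that("segmentation finds the generator's sarcomeres", {
  scans <- gen_linescans(n_myofibrils = 1, n_sarcomeres = 5, noise_sd = 0.01,
                         seed = 3)
  s <- scans[[1]]
  wins <- segment_sarcomeres(s$position, s$intensity)
  expect_true(length(wins) %in% 4:6)
  expect_equal(attr(wins, "period"), 2.0, tolerance = 0.05)
  # detected M positions sit at generator M-line centres
  truth <- attr(s, "m_centres")
  for (w in wins) {
    m <- attr(w, "m_position")
    expect_lt(min(abs(truth - m)), 0.05)
  }
})

test_that("degenerate scans raise segmentation errors", {
  pos <- seq(0, 10, by = 0.02)
  expect_error(segment_sarcomeres(pos, rep(1, length(pos))), "flat")
  expect_error(segment_sarcomeres(pos[1:60], sin(pos[1:60] * 0.1)),
               "segmentation error")
})

test_that("window count is stable under scan phase shifts", {
  base <- gen_linescans(n_myofibrils = 2, n_sarcomeres = 5, noise_sd = 0.01,
                        seed = 11)
  counts <- vapply(base, function(s)
    length(segment_sarcomeres(s$position, s$intensity)), integer(1))
  expect_lte(max(counts) - min(counts), 1L)
})

test_that("aligned averages centre the minimum at offset zero", {
  scans <- gen_linescans(n_myofibrils = 1, n_sarcomeres = 5, noise_sd = 0,
                         seed = 2)
  s <- scans[[1]]
  wins <- segment_sarcomeres(s$position, s$intensity)
  prof <- align_average(wins, myofibril = rep(1, length(wins)))
  i0 <- which.min(abs(prof$offset))
  expect_equal(prof$intensity[i0], min(
    prof$intensity[abs(prof$offset) < 0.5]), tolerance = 1e-9)
  # identical windows average to any single window
  w <- wins[[2]]
  same <- align_average(list(w, w, w), myofibril = c(1, 2, 3))
  ref <- align_average(list(w), myofibril = 1)
  expect_equal(same$intensity, ref$intensity, tolerance = 1e-12)
})

test_that("two-level averaging weights myofibrils, not sarcomeres", {
  # myofibril 1 contributes two identical bright windows, myofibril 2 one
  # dim window: the two-level mean is the midpoint of the two myofibril
  # means, not the pooled mean
  pos <- seq(-1, 1, by = 0.02)
  shape <- 1 - exp(-pos^2 / 0.02)      # central dip
  mk <- function(scale) {
    w <- data.frame(position = pos, intensity = scale * shape + 0.1)
    attr(w, "m_position") <- 0
    w
  }
  prof2 <- align_average(list(mk(2), mk(2), mk(1)), myofibril = c(1, 1, 2))
  pooled <- align_average(list(mk(2), mk(2), mk(1)), myofibril = c(1, 1, 2),
                          level = "pooled")
  mid <- which.min(abs(prof2$offset - 0.5))
  expect_equal(prof2$intensity[mid], 1.5 * shape[pos == 0.5] + 0.1,
               tolerance = 1e-9)
  expect_gt(pooled$intensity[mid], prof2$intensity[mid])
})

test_that("profile metrics follow their arithmetic definitions", {
  off <- seq(-1, 1, by = 0.01)
  y <- 1 + exp(-(off - 0.35)^2 / (2 * 0.05^2)) +
    exp(-(off + 0.35)^2 / (2 * 0.05^2))
  prof <- data.frame(offset = off, intensity = y)
  m <- profile_metrics(prof)
  expect_equal(m$peak_to_min_ratio, 2.0, tolerance = 1e-3)
  expect_equal(m$peak_peak_distance_um, 0.70, tolerance = 1e-3)
  expect_equal(m$mean_peak_value, 2.0, tolerance = 1e-3)
  # adding a constant offset c maps the ratio to (p + c) / (m + c)
  prof2 <- prof; prof2$intensity <- prof2$intensity + 3
  m2 <- profile_metrics(prof2)
  expect_equal(m2$peak_to_min_ratio,
               (m$mean_peak_value + 3) / (m$min_value + 3), tolerance = 1e-3)
  # scaling intensity leaves the ratio unchanged; shifting positions
  # leaves the distance unchanged
  prof3 <- prof; prof3$intensity <- 7 * prof3$intensity
  expect_equal(profile_metrics(prof3)$peak_to_min_ratio,
               m$peak_to_min_ratio, tolerance = 1e-9)
  expect_error(profile_metrics(data.frame(offset = off[off >= -0.01],
                                          intensity = y[off >= -0.01])),
               "single peak")
})

test_that("recovered peak separation matches the generator parameter", {
  # pure two-peak scans (no M-line term, which deliberately biases the
  # extrema inward when present)
  scans <- gen_linescans(n_myofibrils = 6, m_line_amplitude = 0,
                         noise_sd = 0.02, seed = 13)
  met <- sarcomere_metrics_by_myofibril(scans, "WT")
  # within one grid sample of the 0.7 um separation at this SNR
  expect_lt(abs(mean(met$peak_peak_distance_um) - 0.7), 0.02)
  # the bare-zone-width configuration resolves a 0.16 um separation
  nz <- gen_linescans(n_myofibrils = 4, peak_separation = 0.16,
                      peak_sigma = 0.05, m_line_amplitude = 0.05,
                      noise_sd = 0.01, seed = 17)
  mnz <- sarcomere_metrics_by_myofibril(nz, "WT")
  expect_lt(abs(mean(mnz$peak_peak_distance_um) - 0.16), 0.02)
})

test_that("group comparisons separate the construct presets", {
  pre <- scenario_presets()
  mets <- list()
  for (g in c("WT", "K1617del")) {
    p <- pre[[g]]$sarcomere
    scans <- gen_linescans(n_myofibrils = 12,
                           peak_amplitude = p[["peak_amplitude"]],
                           m_line_amplitude = p[["m_line_amplitude"]],
                           seed = 31 + match(g, names(pre)))
    mets[[g]] <- sarcomere_metrics_by_myofibril(scans, g)
  }
  met <- do.call(rbind, c(mets, make.row.names = FALSE))
  cmp <- compare_profile_groups(met)
  ratio_row <- cmp[cmp$group == "K1617del" &
                     cmp$metric == "peak_to_min_ratio", ]
  wt_row <- cmp[cmp$group == "WT" & cmp$metric == "peak_to_min_ratio", ]
  expect_lt(ratio_row$mean, wt_row$mean)
  expect_lt(ratio_row$p_vs_ref, 0.05)
  # identical groups give no significance
  met2 <- mets[["WT"]]
  met2b <- met2; met2b$group <- "COPY"
  cmp2 <- compare_profile_groups(rbind(met2, met2b))
  expect_gt(cmp2$p_vs_ref[cmp2$group == "COPY" &
                            cmp2$metric == "peak_to_min_ratio"], 0.05)
  # a single-myofibril group is rejected
  expect_error(compare_profile_groups(rbind(met2, data.frame(
    group = "ONE", myofibril = 1, peak_to_min_ratio = 1,
    mean_peak_value = 1, peak_peak_distance_um = 0.7))), ">= 2 myofibrils")
})

test_that("mutant presets reduce the peak/min ratio for every seed", {
  pre <- scenario_presets()
  for (seed in 1:20) {
    wt <- gen_linescans(n_myofibrils = 1, n_sarcomeres = 3,
                        peak_amplitude = 1, m_line_amplitude = 0.1,
                        noise_sd = 0.02, seed = seed)
    kd <- gen_linescans(n_myofibrils = 1, n_sarcomeres = 3,
                        peak_amplitude = 0.7, m_line_amplitude = 0.35,
                        noise_sd = 0.02, seed = seed + 1000)
    rw <- sarcomere_metrics_by_myofibril(wt, "WT")$peak_to_min_ratio
    rk <- sarcomere_metrics_by_myofibril(kd, "K")$peak_to_min_ratio
    expect_gt(rw, rk)
  }
})
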