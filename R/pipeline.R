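#' Pipeline run configuration
#'
#' Collects every stage parameter with the study defaults: analysis
#' window 7 residues, clustering cutoff 8 A, solvent probe 1.4 A,
#' salt-bridge cutoff 4 A with a 70% occupancy call, 10 ns equilibration
#' discard, melt normalization anchors at 10 and 80 C.
#'
#' @param scenarios preset names to run (see [scenario_presets()]).
#' @param out_dir output directory.
#' @param seed root seed; every stage derives its stream from it.
#' @param region wild-type numbering bounds of the modeled rod segment.
#' @param n_frames synthetic ensemble frames per scenario.
#' @param stages character vector of stage toggles.
#' @param window,cluster_cutoff,probe,salt_cutoff,salt_occupancy,equil_ns,melt_anchors
#'   stage parameters (defaults above).
#' @return list of class `run_config`.
#' @export
run_config <- function(scenarios = c("WT", "A1603P", "K1617del"),
                       out_dir = tempfile("ccrod_run_"), seed = 1,
                       region = c(1526L, 1689L), n_frames = 50,
                       stages = c("model", "ensemble", "trajectory",
                                  "cd", "morphometry", "sarcomere"),
                       window = 7, cluster_cutoff = 8, probe = 1.4,
                       salt_cutoff = 4, salt_occupancy = 0.7,
                       equil_ns = 10, melt_anchors = c(10, 80)) {
  stopifnot(all(scenarios %in% names(scenario_presets())), seed == floor(seed))
  structure(list(scenarios = scenarios, out_dir = out_dir, seed = as.integer(seed),
                 region = as.integer(region), n_frames = n_frames,
                 stages = stages, window = window,
                 cluster_cutoff = cluster_cutoff, probe = probe,
                 salt_cutoff = salt_cutoff, salt_occupancy = salt_occupancy,
                 equil_ns = equil_ns, melt_anchors = melt_anchors),
            class = "run_config")
}

config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL          # the output path is not a scientific parameter
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  v <- utf8ToInt(as.character(s))
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2^28
  sprintf("%07x", h)
}

#' Build the model for one scenario
#'
#' Wild-type sequence, register propagated from the E1604 = "d" anchor
#' across the E1582 skip, scenario mutation applied, and the motif
#' schedule in skip-del mode (or canonical-throughout for the
#' quasi-canonical deletion scenario `K1617del-c`).
#'
#' @param scenario preset name.
#' @param region wild-type numbering bounds.
#' @param params [crick_params].
#' @return A `cc_model`.
#' @export
build_scenario_model <- function(scenario, region = c(1526L, 1689L),
                                 params = crick_params()) {
  p <- scenario_presets()[[scenario]]
  if (is.null(p)) stop("unknown scenario: ", scenario)
  wt <- lmm_wt_sequence(region[1], region[2])
  seq <- mutate_sequence(wt, p$mutation)
  skips <- intersect(1582L, seq$resno)
  # register anchored at E1604 = "d"; for regions not containing 1604 the
  # anchor is transferred to the region's first non-skip residue via the
  # full-length register
  full <- assign_heptad_register(lmm_wt_sequence(), c("1604" = "d"), 1582L)
  a0 <- wt$resno[!(wt$resno %in% 1582L)][1]
  anchors <- stats::setNames(full$letter[full$resno == a0],
                             as.character(a0))
  reg <- assign_heptad_register(wt, anchors, skips)
  dels <- setdiff(wt$resno, seq$resno)
  mode <- if (identical(scenario, "K1617del-c")) "canonical" else "skip-del"
  sch <- make_motif_schedule(reg, deletions = dels, mode = mode)
  build_coiled_coil(seq, schedule = sch, params = params)
}

write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Per scenario: build the coiled-coil model, generate a synthetic
#' ensemble in end-to-end-target mode at the scenario preset, compute the
#' trajectory metrics (inter-helix distance, heptad length, inter-heptad
#' angle, dihedral helicity, end-to-end distance), the ensemble statistics
#' (RMSD vs the initial structure, RMSF, leader clustering), and the CD
#' quantities (helical content, 222/208 ratio, melt fit).  Morphometry and
#' sarcomere profiling run across scenarios.  A scenario stage failure is
#' logged and the remaining scenarios continue.  Outputs (tidy CSV per
#' metric plus a JSON report stamped with the config hash and seed) are
#' written under `config$out_dir`.
#'
#' @param config a [run_config].
#' @return The report list, invisibly; also written as `report.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_lines <- c(sprintf("ccrod %s | config %s | seed %d | %s",
                         as.character(utils::packageVersion("ccrod")),
                         hash, config$seed, format(Sys.time())))
  report <- list(config_hash = hash, seed = config$seed,
                 parameters = unclass(config), scenarios = list())
  dcom_store <- list()

  for (si in seq_along(config$scenarios)) {
    sc <- config$scenarios[si]
    seed_sc <- config$seed + 1000L * si
    res <- tryCatch({
      out <- list()
      p <- scenario_presets()[[sc]]
      if ("model" %in% config$stages) {
        model <- build_scenario_model(sc, config$region)
        write_ensemble(model, file.path(config$out_dir,
                                        paste0("model_", sc, ".pdb")),
                       remarks = c(paste("SCENARIO", sc),
                                   paste("CONFIG", hash)))
        out$model_residues <- length(model$seqA)
      }
      if ("ensemble" %in% config$stages) {
        ens <- gen_ensemble(model, hinge_residue = 1603L,
                            mode = "end-to-end-target",
                            ee_mean_nm = p$ee_nm[["mean"]],
                            ee_sd_nm = p$ee_nm[["sd"]],
                            n_frames = config$n_frames, seed = seed_sc)
      }
      if ("trajectory" %in% config$stages) {
        dc <- dcom_profile(ens, config$window)
        dcom_store[[sc]] <- dc
        hl <- heptad_length_profile(ens)
        ia <- inter_heptad_angle_profile(ens)
        write_profile_csv(dc, file.path(config$out_dir,
                                        paste0("dcom_", sc, ".csv")))
        write_profile_csv(hl, file.path(config$out_dir,
                                        paste0("heptad_length_", sc, ".csv")))
        write_profile_csv(ia, file.path(config$out_dir,
                                        paste0("inter_heptad_angle_", sc,
                                               ".csv")))
        hel <- helicity(ens)
        ee <- end_to_end(ens)
        rm <- rmsd_vs_initial(ens)
        rf <- rmsf(ens, max_iter = 1000)
        cl <- cluster_structures(ens, config$cluster_cutoff)
        utils::write.csv(
          data.frame(rm, cluster = cl$labels),
          file.path(config$out_dir, paste0("frames_", sc, ".csv")),
          row.names = FALSE)
        write_profile_csv(rf, file.path(config$out_dir,
                                        paste0("rmsf_", sc, ".csv")))
        out$helicity_percent <- 100 * hel$overall
        out$end_to_end_nm <- c(mean = ee$mean_nm, sd = ee$sd_nm)
        out$cluster_populations <- cl$populations
        out$dcom_mean <- mean(dc$mean)
      }
      if ("cd" %in% config$stages) {
        cd <- gen_cd(p$helix_fraction, noise_sd = 200, seed = seed_sc + 1)
        melt <- gen_melt(p$tm, p$melt_width, noise_sd = 1,
                         seed = seed_sc + 2)
        nm <- normalize_melt(melt$temperature, melt$fraction_folded)
        fit <- fit_melt(nm$temperature, nm$fraction_folded)
        out$helical_content <- helical_content(
          cd$mre[cd$wavelength == 222])
        out$ratio_222_208 <- ratio_222_208(cd$wavelength, cd$mre)
        out$tm <- fit$tm
        utils::write.csv(cd, file.path(config$out_dir,
                                       paste0("cd_", sc, ".csv")),
                         row.names = FALSE)
        utils::write.csv(nm, file.path(config$out_dir,
                                       paste0("melt_", sc, ".csv")),
                         row.names = FALSE)
      }
      log_lines <- c(log_lines, sprintf("scenario %s: ok", sc))
      out
    }, error = function(e) {
      log_lines <<- c(log_lines,
                      sprintf("scenario %s: FAILED (%s)", sc,
                              conditionMessage(e)))
      list(error = conditionMessage(e))
    })
    report$scenarios[[sc]] <- res
  }

  # per-residue inter-helix distance differences against the reference
  if (length(dcom_store) > 1 && "WT" %in% names(dcom_store)) {
    ref <- dcom_store[["WT"]]
    report$delta_dcom <- list()
    for (sc in setdiff(names(dcom_store), "WT")) {
      d <- dcom_store[[sc]]
      common <- intersect(ref$resno, d$resno)
      delta <- data.frame(
        resno = common,
        delta_dcom = d$mean[match(common, d$resno)] -
          ref$mean[match(common, ref$resno)])
      utils::write.csv(delta, file.path(config$out_dir,
                                        paste0("delta_dcom_", sc, ".csv")),
                       row.names = FALSE)
      report$delta_dcom[[sc]] <- delta
    }
  }

  if ("morphometry" %in% config$stages) {
    fil <- gen_filaments(config$scenarios, seed = config$seed + 77L)
    fs <- filament_stats(fil$measurements)
    bf <- bundle_fraction(fil$fields)
    sol <- solubility_curve(gen_solubility(config$scenarios,
                                           seed = config$seed + 78L))
    utils::write.csv(fs, file.path(config$out_dir, "filament_stats.csv"),
                     row.names = FALSE)
    utils::write.csv(bf, file.path(config$out_dir, "bundle_fraction.csv"),
                     row.names = FALSE)
    report$morphometry <- list(filaments = fs, bundles = bf,
                               solubility_mid = attr(sol, "midpoints"))
  }
  if ("sarcomere" %in% config$stages) {
    met <- list()
    for (si in seq_along(config$scenarios)) {
      sc <- config$scenarios[si]
      p <- scenario_presets()[[sc]]$sarcomere
      scans <- gen_linescans(n_myofibrils = 12,
                             peak_amplitude = p[["peak_amplitude"]],
                             m_line_amplitude = p[["m_line_amplitude"]],
                             seed = config$seed + 200L + si)
      met[[sc]] <- sarcomere_metrics_by_myofibril(scans, group = sc)
    }
    met <- do.call(rbind, c(met, make.row.names = FALSE))
    cmp <- compare_profile_groups(met)
    utils::write.csv(cmp, file.path(config$out_dir, "sarcomere_groups.csv"),
                     row.names = FALSE)
    report$sarcomere <- list(metrics = met, comparison = cmp)
  }

  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

#' Per-myofibril sarcomere profile metrics for a set of line scans
#'
#' Segments each scan, aligns and averages its sarcomere windows, and
#' extracts the peak metrics, one row per myofibril.
#'
#' @param scans list of line-scan data.frames (`position`, `intensity`)
#'   as from [gen_linescans()].
#' @param group group label attached to the rows.
#' @return data.frame `group`, `myofibril`, `peak_to_min_ratio`,
#'   `mean_peak_value`, `peak_peak_distance_um`.
#' @export
sarcomere_metrics_by_myofibril <- function(scans, group = "WT") {
  rows <- lapply(seq_along(scans), function(i) {
    s <- scans[[i]]
    wins <- segment_sarcomeres(s$position, s$intensity)
    prof <- align_average(wins, myofibril = rep(i, length(wins)))
    m <- profile_metrics(prof)
    data.frame(group = group, myofibril = i,
               peak_to_min_ratio = m$peak_to_min_ratio,
               mean_peak_value = m$mean_peak_value,
               peak_peak_distance_um = m$peak_peak_distance_um)
  })
  do.call(rbind, rows)
}
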