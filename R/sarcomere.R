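#' Segment a myofibril line scan into sarcomere windows
#'
#' Cuts a periodic intensity scan into one window per sarcomere.  The
#' deepest local minima at approximately periodic spacing are taken as the
#' sarcomere boundaries; within each window the alignment (M-line)
#' minimum is the deepest local minimum of the central half, matching a
#' motor-domain-tagged signal where intensity drops both at the sarcomere
#' boundary and in the central bare zone, with the boundary minima the
#' darker of the two.  Setting `m_line = "deepest"` instead treats the
#' deepest periodic minima themselves as M-lines (for stains whose
#' dominant minimum is the M-line) and bounds the windows midway between
#' them.
#'
#' @param position positions, um, uniformly spaced.
#' @param intensity intensities (same length).
#' @param min_period smallest credible sarcomere period, um (default 1).
#' @param m_line `"central"` (default) or `"deepest"`.
#' @return List of windows, each a data.frame (`position`, `intensity`)
#'   with the alignment position in `attr(, "m_position")`; the estimated
#'   period is attached to the list as `attr(, "period")`.
#' @export
segment_sarcomeres <- function(position, intensity, min_period = 1,
                               m_line = c("central", "deepest")) {
  m_line <- match.arg(m_line)
  stopifnot(length(position) == length(intensity), length(position) > 10)
  dx <- diff(position)
  if (max(dx) - min(dx) > 1e-6 * stats::median(dx))
    stop("non-uniform sampling")
  dx <- stats::median(dx)
  n <- length(intensity)
  if (stats::sd(intensity) < 1e-12 * max(abs(intensity), 1))
    stop("segmentation error: flat profile")
  # period from the autocorrelation peak
  ac <- stats::acf(intensity - mean(intensity), lag.max = floor(n / 2),
                   plot = FALSE, demean = TRUE)$acf[-1]
  lag0 <- max(2, round(min_period / dx))
  if (lag0 >= length(ac))
    stop("segmentation error: scan shorter than one period")
  lag <- (lag0:length(ac))[which.max(ac[lag0:length(ac)])]
  if (ac[lag] < 0.2) stop("segmentation error: no periodicity detected")
  period <- lag * dx
  mins <- which(diff(sign(diff(intensity))) > 0) + 1L
  if (length(mins) < 2) stop("segmentation error: fewer than 2 minima")
  # boundary detection runs on a smoothed copy (quarter-period running
  # mean) so flat noisy stretches between sarcomeres yield one
  # well-defined minimum; window contents and the alignment minimum are
  # taken from the raw data
  k <- max(3L, as.integer(lag / 4))
  if (k %% 2 == 0) k <- k + 1L
  sm <- as.numeric(stats::filter(intensity, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- intensity[is.na(sm)]
  smins <- which(diff(sign(diff(sm))) > 0) + 1L
  if (!length(smins)) smins <- mins
  # deepest periodic minima: anchor at the global deepest, march by one
  # period, snapping to the deepest smoothed minimum within +/- period/3
  anchor <- smins[which.min(sm[smins])]
  snap <- function(i0) {
    cand <- smins[abs(smins - i0) <= lag / 3]
    if (!length(cand)) return(NA_integer_)
    cand[which.min(sm[cand])]
  }
  deep <- anchor
  i <- anchor
  repeat {
    i <- i + lag
    if (i > n + lag / 3) break
    s <- snap(i)
    if (is.na(s)) break
    deep <- c(deep, s); i <- s
  }
  i <- anchor
  repeat {
    i <- i - lag
    if (i < 1 - lag / 3) break
    s <- snap(i)
    if (is.na(s)) break
    deep <- c(s, deep); i <- s
  }
  deep <- sort(unique(deep))
  if (length(deep) < 2) stop("segmentation error: fewer than 2 periods")

  if (m_line == "central") {
    lo <- deep[-length(deep)]
    hi <- deep[-1]
  } else {
    bounds <- round((deep[-1] + deep[-length(deep)]) / 2)
    lo <- c(max(1, deep[1] - round(lag / 2)), bounds)
    hi <- c(bounds, min(n, deep[length(deep)] + round(lag / 2)))
  }
  out <- lapply(seq_along(lo), function(k) {
    ii <- lo[k]:hi[k]
    w <- data.frame(position = position[ii], intensity = intensity[ii])
    if (m_line == "central") {
      # the M-line minimum is the deepest point between the two principal
      # intensity peaks of the sarcomere (the bright block's central dip),
      # located by bracketing with the outermost prominent local maxima
      yw <- intensity[ii]
      thr <- min(yw) + 0.5 * (max(yw) - min(yw))
      lm <- which(diff(sign(diff(yw))) < 0) + 1L
      big <- lm[yw[lm] >= thr]
      mi <- if (length(big) >= 2) {
        span <- min(big):max(big)
        ii[span[which.min(yw[span])]]
      } else {
        span4 <- hi[k] - lo[k]
        ctr <- which(ii >= lo[k] + span4 / 4 & ii <= hi[k] - span4 / 4)
        wm <- mins[mins %in% ii[ctr]]
        if (length(wm)) wm[which.min(intensity[wm])]
        else ii[ctr][which.min(intensity[ii[ctr]])]
      }
      attr(w, "m_position") <- position[mi]
    } else {
      attr(w, "m_position") <- position[deep[k]]
    }
    w
  })
  attr(out, "period") <- period
  out
}

# parabolic sub-sample refinement around index i: least-squares quadratic
# over up to +/- halfwin samples, falling back to the raw sample when the
# vertex is not a genuine extremum nearby
parab_refine <- function(x, y, i, halfwin = 3L) {
  n <- length(y)
  h <- min(halfwin, i - 1L, n - i)
  if (h < 1) return(c(x = x[i], y = y[i]))
  ii <- (i - h):(i + h)
  fit <- stats::lm.fit(cbind(1, x[ii] - x[i], (x[ii] - x[i])^2), y[ii])
  cf <- fit$coefficients
  if (!is.finite(cf[3]) || abs(cf[3]) < 1e-300) return(c(x = x[i], y = y[i]))
  d <- unname(-cf[2] / (2 * cf[3]))
  dx <- x[2] - x[1]
  if (abs(d) > (h + 0.5) * dx) return(c(x = x[i], y = y[i]))
  c(x = x[i] + d, y = unname(cf[1] - cf[2]^2 / (4 * cf[3])))
}

#' Align sarcomere windows on their central minimum and average
#'
#' Two-level averaging matching the measurement design: every window is
#' aligned on its central (M-line) minimum and interpolated onto a common
#' offset grid; windows are first averaged within each myofibril, then the
#' per-myofibril averages are averaged across myofibrils.  A pooled mode
#' (all sarcomeres weighted equally) is available but never the default.
#'
#' @param windows list of windows as returned by [segment_sarcomeres()];
#'   each must carry a `myofibril` attribute (or use `myofibril` to supply
#'   ids in parallel).
#' @param myofibril vector of myofibril ids, one per window.
#' @param level `"myofibril"` (two-level, default) or `"pooled"`.
#' @param grid_step offset grid spacing, um (default: the windows' pixel
#'   size).
#' @return A data.frame of class `sarcomere_profile`: `offset`,
#'   `intensity`; attributes `n_sarcomeres`, `n_myofibrils`.
#' @export
align_average <- function(windows, myofibril = NULL,
                          level = c("myofibril", "pooled"),
                          grid_step = NULL) {
  level <- match.arg(level)
  if (!length(windows)) stop("empty input")
  if (is.null(myofibril))
    myofibril <- vapply(windows, function(w) {
      m <- attr(w, "myofibril")
      if (is.null(m)) "1" else as.character(m)
    }, character(1))
  stopifnot(length(myofibril) == length(windows))
  dx <- if (is.null(grid_step))
    stats::median(diff(windows[[1]]$position)) else grid_step
  # offsets of each window about its refined central minimum
  aligned <- lapply(windows, function(w) {
    m_pos <- attr(w, "m_position")
    if (is.null(m_pos)) {
      ctr <- which(abs(w$position - stats::median(w$position)) <=
                     diff(range(w$position)) / 4)
      i <- ctr[which.min(w$intensity[ctr])]
    } else i <- which.min(abs(w$position - m_pos))
    ref <- parab_refine(w$position, w$intensity, i)
    data.frame(offset = w$position - ref[["x"]], intensity = w$intensity)
  })
  half <- min(vapply(aligned, function(a) min(-min(a$offset), max(a$offset)),
                     numeric(1)))
  grid <- seq(-floor(half / dx) * dx, floor(half / dx) * dx, by = dx)
  mat <- t(vapply(aligned, function(a)
    stats::approx(a$offset, a$intensity, xout = grid)$y,
    numeric(length(grid))))
  prof <- if (level == "pooled") colMeans(mat) else {
    per_mf <- rowsum(mat, myofibril)
    cnt <- table(myofibril)
    colMeans(per_mf / as.vector(cnt[rownames(per_mf)]))
  }
  out <- data.frame(offset = grid, intensity = prof)
  class(out) <- c("sarcomere_profile", "data.frame")
  attr(out, "n_sarcomeres") <- length(windows)
  attr(out, "n_myofibrils") <- length(unique(myofibril))
  out
}

#' Peak metrics of an averaged sarcomere profile
#'
#' The largest local maximum on each side of the central minimum (within
#' `half_period` of it), refined to sub-sample precision by a parabolic
#' fit.  Reports the mean of the two peak values, their ratio to the
#' central minimum value, and the peak-to-peak distance.
#'
#' @param profile a `sarcomere_profile` (columns `offset`, `intensity`).
#' @param half_period search range either side of the minimum, um
#'   (default: the profile half-width).
#' @return list(`peak_to_min_ratio`, `mean_peak_value`,
#'   `peak_peak_distance_um`, `min_value`, `peak_positions`, `capped`).
#' @export
profile_metrics <- function(profile, half_period = NULL) {
  off <- profile$offset; y <- profile$intensity
  if (is.null(half_period)) half_period <- max(abs(off))
  i0 <- which.min(abs(off))
  mref <- parab_refine(off, y, i0)
  find_peak <- function(side) {
    sel <- which(if (side < 0) off < 0 & off >= -half_period
                 else off > 0 & off <= half_period)
    if (length(sel) < 3) stop("single peak: no samples on one side")
    ys <- y[sel]
    loc <- which(diff(sign(diff(ys))) < 0) + 1L
    i <- if (length(loc)) sel[loc[which.max(ys[loc])]]
    else sel[which.max(ys)]
    parab_refine(off, y, i)
  }
  pL <- find_peak(-1); pR <- find_peak(+1)
  if (abs(pL[["x"]] - pR[["x"]]) < 1e-9) stop("single peak detected")
  mn <- mref[["y"]]
  capped <- FALSE
  ratio <- if (abs(mn) < 1e-12) { capped <- TRUE; Inf }
  else mean(c(pL[["y"]], pR[["y"]])) / mn
  list(peak_to_min_ratio = ratio,
       mean_peak_value = mean(c(pL[["y"]], pR[["y"]])),
       peak_peak_distance_um = pR[["x"]] - pL[["x"]],
       min_value = mn,
       peak_positions = c(pL[["x"]], pR[["x"]]),
       capped = capped)
}

#' Compare per-myofibril sarcomere metrics between groups
#'
#' Two-tailed Welch t-tests of each metric against the reference group,
#' one observation per myofibril, with stars at p < 0.05, < 0.001,
#' < 1e-4.
#'
#' @param metrics data.frame with columns `group`, `myofibril` and one
#'   column per metric (e.g. `peak_to_min_ratio`, `mean_peak_value`,
#'   `peak_peak_distance_um`).
#' @param reference reference group (default `"WT"`).
#' @return data.frame `group`, `metric`, `n`, `mean`, `sd`, `p_vs_ref`,
#'   `stars`.
#' @export
compare_profile_groups <- function(metrics, reference = "WT") {
  stopifnot(all(c("group", "myofibril") %in% names(metrics)))
  vars <- setdiff(names(metrics), c("group", "myofibril"))
  out <- list()
  for (v in vars) for (g in unique(metrics$group)) {
    x <- metrics[metrics$group == g, v]
    if (length(x) < 2) stop("need >= 2 myofibrils per group (", g, ")")
    p <- NA_real_
    if (g != reference) {
      rx <- metrics[metrics$group == reference, v]
      p <- stats::t.test(x, rx, var.equal = FALSE)$p.value
    }
    out[[length(out) + 1L]] <- data.frame(
      group = g, metric = v, n = length(x), mean = mean(x),
      sd = stats::sd(x), p_vs_ref = p,
      stars = star_band(p, c(0.05, 0.001, 1e-4)), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
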