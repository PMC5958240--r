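star_band <- function(p, bands = c(0.01, 0.001, 1e-4),
                      stars = c("*", "**", "***")) {
  if (is.na(p)) return(NA_character_)
  k <- sum(p < bands)
  if (k == 0) "" else stars[k]
}

#' Filament length/width population statistics
#'
#' Per-group mean, SD, SEM and n for filament lengths and widths, with
#' pairwise two-tailed Welch t-tests of each group against the reference
#' group (WT).  Stars follow the usual bands (p < 0.01, < 0.001, < 1e-4).
#'
#' @param records data.frame with columns `group`, `length_nm` and/or
#'   `width_nm` (NA entries are dropped per variable).
#' @param reference reference group label (default `"WT"`).
#' @return data.frame with one row per group x variable: `group`,
#'   `variable`, `n`, `mean`, `sd`, `sem`, `p_vs_ref`, `stars`.
#' @export
filament_stats <- function(records, reference = "WT") {
  stopifnot(is.data.frame(records), "group" %in% names(records))
  vars <- intersect(c("length_nm", "width_nm"), names(records))
  if (!length(vars)) stop("no length_nm/width_nm columns")
  out <- list()
  for (v in vars) {
    for (g in unique(records$group)) {
      x <- records[records$group == g, v]
      x <- x[!is.na(x)]
      if (!length(x)) { warning("empty group ", g, " for ", v); next }
      p <- NA_real_
      if (g != reference && length(x) >= 2) {
        refx <- stats::na.omit(records[records$group == reference, v])
        if (length(refx) >= 2)
          p <- stats::t.test(x, refx, var.equal = FALSE)$p.value
      }
      out[[length(out) + 1L]] <- data.frame(
        group = g, variable = v, n = length(x), mean = mean(x),
        sd = stats::sd(x), sem = stats::sd(x) / sqrt(length(x)),
        p_vs_ref = p, stars = star_band(p), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Fraction of image fields containing filament bundles
#'
#' Percentage of image fields flagged as bundled per group, with an exact
#' binomial 95% confidence interval.
#'
#' @param records data.frame with columns `group`, `field_id`, `bundled`
#'   (logical, constant within a field).
#' @return data.frame `group`, `n_fields`, `percent_bundled`, `ci_lo`,
#'   `ci_hi` (percent).
#' @export
bundle_fraction <- function(records) {
  stopifnot(all(c("group", "field_id", "bundled") %in% names(records)))
  out <- lapply(unique(records$group), function(g) {
    d <- records[records$group == g, ]
    fields <- !duplicated(d$field_id)
    x <- sum(d$bundled[fields])
    n <- sum(fields)
    ci <- stats::binom.test(x, n)$conf.int
    data.frame(group = g, n_fields = n, percent_bundled = 100 * x / n,
               ci_lo = 100 * ci[1], ci_hi = 100 * ci[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Salt-dependent solubility curve
#'
#' Fraction soluble (supernatant / total) per salt concentration, clipped
#' to [0, 1] with a warning, plus an optional logistic fit for the
#' half-solubility salt concentration.
#'
#' @param points data.frame with columns `NaCl_mM`, `supernatant`,
#'   `total`, optionally `group`.
#' @param fit_midpoint logistic-fit the half-solubility point per group.
#' @return data.frame of the points with `fraction_soluble`; when
#'   `fit_midpoint` the result carries a `midpoints` attribute (named
#'   numeric, mM).
#' @export
solubility_curve <- function(points, fit_midpoint = TRUE) {
  stopifnot(all(c("NaCl_mM", "supernatant", "total") %in% names(points)),
            all(points$total > 0))
  fr <- points$supernatant / points$total
  if (any(fr > 1)) {
    warning("supernatant above total; fraction clipped to 1")
    fr <- pmin(fr, 1)
  }
  fr <- pmax(fr, 0)
  out <- points
  out$fraction_soluble <- fr
  if (fit_midpoint) {
    grp <- if ("group" %in% names(out)) out$group else rep("all", nrow(out))
    mids <- vapply(unique(grp), function(g) {
      d <- out[grp == g, ]
      f <- try(stats::nls(fraction_soluble ~ 1 / (1 + exp((NaCl_mM - m) / s)),
                          data = d, start = list(m = stats::median(d$NaCl_mM),
                                                 s = -50),
                          algorithm = "port",
                          control = stats::nls.control(maxiter = 200,
                                                       warnOnly = TRUE)),
               silent = TRUE)
      if (inherits(f, "try-error")) NA_real_ else stats::coef(f)[["m"]]
    }, numeric(1))
    attr(out, "midpoints") <- mids
  }
  out
}

#' Cardiomyocyte integration scoring summary
#'
#' Percentage of cells per category (`integrated`, `partial`,
#' `aggregated`) within each experiment, the mean and SD across
#' experiments, and Welch t-tests of each category against the reference
#' group across experiments.
#'
#' @param scores data.frame with columns `group`, `experiment`, `cell_id`,
#'   `category`.
#' @param reference reference group (default `"WT"`).
#' @param min_cells warn when an experiment scored fewer cells (default
#'   30).
#' @return list: `per_experiment` (percentages summing to 100 per
#'   experiment), `summary` (mean +/- SD per group x category with
#'   `p_vs_ref` and `stars`).
#' @export
integration_summary <- function(scores, reference = "WT", min_cells = 30) {
  cats <- c("integrated", "partial", "aggregated")
  stopifnot(all(c("group", "experiment", "cell_id", "category")
                %in% names(scores)))
  if (!all(scores$category %in% cats))
    stop("unknown category label(s): ",
         paste(setdiff(unique(scores$category), cats), collapse = ","))
  per <- list()
  for (g in unique(scores$group)) for (e in unique(scores$experiment)) {
    d <- scores[scores$group == g & scores$experiment == e, ]
    if (!nrow(d)) next
    if (nrow(d) < min_cells)
      warning("only ", nrow(d), " cells for ", g, " experiment ", e)
    tab <- table(factor(d$category, levels = cats))
    per[[length(per) + 1L]] <- data.frame(
      group = g, experiment = e, category = cats,
      percent = 100 * as.numeric(tab) / nrow(d), n_cells = nrow(d),
      stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, per)
  summ <- list()
  for (g in unique(per$group)) for (ct in cats) {
    x <- per$percent[per$group == g & per$category == ct]
    p <- NA_real_
    if (g != reference && length(x) >= 2) {
      rx <- per$percent[per$group == reference & per$category == ct]
      if (length(rx) >= 2 && (stats::sd(x) > 0 || stats::sd(rx) > 0))
        p <- stats::t.test(x, rx, var.equal = FALSE)$p.value
    }
    summ[[length(summ) + 1L]] <- data.frame(
      group = g, category = ct, mean = mean(x),
      sd = if (length(x) > 1) stats::sd(x) else 0,
      n_experiments = length(x), p_vs_ref = p,
      stars = star_band(p, c(0.05, 0.001, 1e-4)), stringsAsFactors = FALSE)
  }
  list(per_experiment = per, summary = do.call(rbind, summ))
}
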