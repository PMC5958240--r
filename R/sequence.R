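#' Residue sequences with wild-type rod numbering
#'
#' A `cc_sequence` couples one-letter amino-acid codes to the residue
#' numbering of the intact wild-type rod.  Deletions keep the wild-type
#' numbers of the surviving residues, so a single-residue deletion leaves a
#' gap in `resno` rather than renumbering: all downstream per-residue
#' profiles index by these numbers.
#'
#' @param aa character vector of one-letter codes.
#' @param resno integer vector of wild-type residue numbers, strictly
#'   increasing, same length as `aa`.
#' @return An object of class `cc_sequence`: a list with elements `aa` and
#'   `resno`.
#' @export
cc_sequence <- function(aa, resno) {
  aa <- as.character(aa)
  resno <- as.integer(resno)
  stopifnot(length(aa) == length(resno), !is.unsorted(resno, strictly = TRUE))
  if (!all(aa %in% LETTERS)) stop("'aa' must be one-letter amino-acid codes")
  structure(list(aa = aa, resno = resno), class = "cc_sequence")
}

#' @export
length.cc_sequence <- function(x) length(x$aa)

#' @export
print.cc_sequence <- function(x, ...) {
  cat(sprintf("cc_sequence: %d residues, numbered %d-%d", length(x$aa),
              min(x$resno), max(x$resno)))
  gaps <- setdiff(seq(min(x$resno), max(x$resno)), x$resno)
  if (length(gaps)) cat(sprintf(" (gap at %s)", paste(gaps, collapse = ",")))
  cat("\n")
  invisible(x)
}

#' Synthetic stand-in sequence for the beta-MHC rod segment 1526-1689
#'
#' The 164-residue stretch of the human beta-cardiac myosin rod that spans
#' both Laing distal myopathy sites studied here (A1603P, K1617del) and the
#' third skip residue (E1582).  No sequence record is bundled with the
#' package, so this is a *synthetic* stand-in: every residue identity that
#' the analyses depend on is fixed to its true value (F1565, E1582, V1594,
#' L1601, A1603, E1604, S1607, R1608, V1614, K1615, K1616, K1617, E1619,
#' D1621, L1629) and all remaining positions are filled with an idealized
#' coiled-coil pattern consistent with the heptad register propagated from
#' the E1604 = "d" anchor across the E1582 skip (hydrophobic a/d core,
#' charged/polar b,c,e,f,g shell).
#'
#' @param start,end first and last wild-type residue numbers (defaults give
#'   the 164-residue modeled region).
#' @return A [cc_sequence].
#' @export
lmm_wt_sequence <- function(start = 1526L, end = 1689L) {
  stopifnot(start >= 1526L, end <= 1689L, start < end)
  resno <- seq(1526L, 1689L)
  reg <- assign_heptad_register(
    cc_sequence(rep("A", length(resno)), resno),
    anchors = c("1604" = "d"), skip_positions = 1582L)
  # idealized pattern per register position; skip residue handled below
  fill <- c(a = "L", b = "E", c = "A", d = "L", e = "K", f = "Q", g = "S")
  aa <- unname(fill[reg$letter])
  aa[reg$letter == "skip"] <- "E"
  fixed <- c(`1565` = "F", `1582` = "E", `1594` = "V", `1601` = "L",
             `1603` = "A", `1604` = "E", `1607` = "S", `1608` = "R",
             `1614` = "V", `1615` = "K", `1616` = "K", `1617` = "K",
             `1619` = "E", `1621` = "D", `1629` = "L")
  aa[match(as.integer(names(fixed)), resno)] <- fixed
  keep <- resno >= start & resno <= end
  cc_sequence(aa[keep], resno[keep])
}

#' Apply a point mutation or single-residue deletion
#'
#' Mutation specs use the conventional `<wt><position><new>` /
#' `<wt><position>del` notation, e.g. `"A1603P"` or `"K1617del"`.  A
#' substitution preserves length; a deletion removes the residue but keeps
#' wild-type numbering for all remaining residues, so the deletion site
#' stays visible as a numbering gap.
#'
#' @param seq a [cc_sequence].
#' @param spec character mutation spec, or `""`/`NULL` for no change.
#' @return A [cc_sequence].
#' @examples
#' wt <- lmm_wt_sequence()
#' mutate_sequence(wt, "A1603P")
#' mutate_sequence(wt, "K1617del")
#' @export
mutate_sequence <- function(seq, spec) {
  stopifnot(inherits(seq, "cc_sequence"))
  if (is.null(spec) || !nzchar(spec)) return(seq)
  m <- regmatches(spec, regexec("^([A-Z])([0-9]+)(del|[A-Z])$", spec))[[1]]
  if (length(m) != 4) stop("malformed mutation spec: ", spec)
  wt_aa <- m[2]; pos <- as.integer(m[3]); new <- m[4]
  i <- match(pos, seq$resno)
  if (is.na(i)) stop("position ", pos, " not present in sequence")
  if (seq$aa[i] != wt_aa)
    stop(sprintf("residue %d is %s, not %s", pos, seq$aa[i], wt_aa))
  if (new == "del") {
    cc_sequence(seq$aa[-i], seq$resno[-i])
  } else {
    aa <- seq$aa
    aa[i] <- new
    cc_sequence(aa, seq$resno)
  }
}
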