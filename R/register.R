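#' Assign the heptad register of a coiled-coil sequence
#'
#' Propagates the cyclic a-g register from one or more anchor residues.
#' Skip residues (extra residues inserted into the heptad pattern, such as
#' E1582 in the myosin rod) pause the propagation for one step: the skip
#' residue itself is labelled `"skip"` and the next residue resumes the
#' cycle where it would otherwise have been, so the register downstream of
#' a skip is offset by one sequence position.
#'
#' @param seq a [cc_sequence].
#' @param anchors named character vector mapping residue numbers to letters,
#'   e.g. `c("1604" = "d")`.  All anchors must agree under cyclic
#'   propagation or a register-conflict error is raised.
#' @param skip_positions integer residue numbers of skip residues.
#' @return A data.frame of class `heptad_assignment` with columns `resno`,
#'   `aa`, `letter` (one of a-g or `"skip"`); skip positions are kept in
#'   `attr(, "skips")`.
#' @examples
#' reg <- assign_heptad_register(lmm_wt_sequence(), c("1604" = "d"), 1582L)
#' reg$letter[reg$resno == 1615]  # "a": the core role K1615 plays
#' @export
assign_heptad_register <- function(seq, anchors, skip_positions = integer()) {
  stopifnot(inherits(seq, "cc_sequence"), length(anchors) >= 1)
  letters7 <- c("a", "b", "c", "d", "e", "f", "g")
  apos <- as.integer(names(anchors))
  if (any(is.na(apos)) || !all(apos %in% seq$resno))
    stop("anchor positions must name residues present in the sequence")
  if (!all(anchors %in% letters7)) stop("anchor letters must be a-g")
  skip_positions <- as.integer(skip_positions)
  if (!all(skip_positions %in% seq$resno))
    stop("skip positions must lie inside the sequence")
  if (any(apos %in% skip_positions)) stop("anchors cannot be skip residues")

  is_skip <- seq$resno %in% skip_positions
  # cumulative count of register-advancing residues
  adv <- cumsum(!is_skip)
  i0 <- match(apos[1], seq$resno)
  base0 <- match(anchors[1], letters7) - 1L
  idx <- (base0 + adv - adv[i0]) %% 7L
  # verify remaining anchors under the same propagation
  for (k in seq_along(anchors)[-1]) {
    i <- match(apos[k], seq$resno)
    if (letters7[idx[i] + 1L] != anchors[k])
      stop(sprintf(
        "register conflict: anchor %d=%s contradicts propagation (got %s)",
        apos[k], anchors[k], letters7[idx[i] + 1L]))
  }
  letter <- letters7[idx + 1L]
  letter[is_skip] <- "skip"
  out <- data.frame(resno = seq$resno, aa = seq$aa, letter = letter,
                    stringsAsFactors = FALSE)
  class(out) <- c("heptad_assignment", "data.frame")
  attr(out, "skips") <- skip_positions
  out
}

#' Build a motif schedule for a coiled-coil model
#'
#' The backbone builder describes a coiled coil as a tiling of "motifs",
#' each linking register-equivalent residues and carrying an integer number
#' of helical turns `N`.  A canonical coiled coil is tiled by 7-residue
#' motifs with N = 2.  In `"skip-del"` mode, a skip residue is absorbed by
#' replacing four canonical motifs with a single 29-residue motif
#' (4 x 7 + 1) and a single-residue deletion by a 27-residue motif
#' (4 x 7 - 1), both still containing N = 8 helical turns so the coiled
#' coil stays left-handed overall while the local supercoil twist is
#' redistributed.  In `"canonical"` mode only 7-residue motifs are emitted:
#' the register shift introduced by a skip and that of a downstream
#' deletion then cancel, which is how the quasi-canonical deletion model
#' (K1617del-c) is produced.
#'
#' @param assignment a [heptad_assignment] covering the modeled region.
#' @param deletions integer wild-type residue numbers deleted from the
#'   chain (e.g. `1617L` for K1617del).  Must be present in `assignment`
#'   (wild-type numbering is retained; the builder drops them).
#' @param mode `"skip-del"` or `"canonical"`.
#' @return A data.frame of class `motif_schedule` with one row per motif:
#'   `start`, `end` (wild-type numbers), `length` (physical residues),
#'   `turns_N`, `kind` (canonical / skip / deletion / partial) and a
#'   `mode` attribute.
#' @examples
#' seq <- lmm_wt_sequence(1565, 1594)
#' reg <- assign_heptad_register(seq, c("1565" = "a"), 1582L)
#' make_motif_schedule(reg)  # one 29-residue skip motif
#' @export
make_motif_schedule <- function(assignment, deletions = integer(),
                                mode = c("skip-del", "canonical")) {
  mode <- match.arg(mode)
  stopifnot(inherits(assignment, "heptad_assignment"))
  deletions <- as.integer(deletions)
  if (!all(deletions %in% assignment$resno))
    stop("deletions must lie inside the modeled region")
  skips <- attr(assignment, "skips")
  resno <- setdiff(assignment$resno, deletions)  # physical residues
  n <- length(resno)

  rows <- list()
  emit <- function(start_i, len, N, kind) {
    rows[[length(rows) + 1L]] <<- data.frame(
      start = resno[start_i], end = resno[start_i + len - 1L],
      length = len, turns_N = N, kind = kind, stringsAsFactors = FALSE)
  }

  if (mode == "skip-del" && length(skips) && length(deletions) &&
      min(abs(outer(skips, deletions, "-"))) < 29L)
    stop("unsupported schedule: skip and deletion within one motif span")

  i <- 1L
  while (i <= n) {
    left <- n - i + 1L
    if (mode == "skip-del") {
      if (left >= 29L) {
        win <- resno[i:(i + 28L)]
        sk <- intersect(skips, win)
        # emit the 29-residue motif once a full heptad flanks the skip
        if (length(sk) && match(sk[1], win) >= 8L && match(sk[1], win) <= 22L) {
          emit(i, 29L, 8L, "skip"); i <- i + 29L; next
        }
      }
      if (left >= 27L) {
        win <- resno[i:(i + 26L)]
        # a deletion lies in a window if the numbering gap it leaves does
        del <- deletions[deletions > win[1] & deletions < win[27]]
        if (length(del)) {
          o <- match(max(win[win < del[1]]), win)
          if (o >= 7L && o <= 20L) {
            emit(i, 27L, 8L, "deletion"); i <- i + 27L; next
          }
        }
      }
      if (left >= 7L && any(skips %in% resno[i:(i + 6L)]))
        stop("unsupported schedule: skip too close to a region boundary")
    }
    if (left >= 7L) {
      emit(i, 7L, 2L, "canonical"); i <- i + 7L
    } else {
      emit(i, left, NA_integer_, "partial"); i <- n + 1L
    }
  }
  out <- do.call(rbind, rows)
  stopifnot(sum(out$length) == n)
  class(out) <- c("motif_schedule", "data.frame")
  attr(out, "mode") <- if (mode == "skip-del") "skip-del" else
    "canonical-throughout"
  attr(out, "deletions") <- deletions
  attr(out, "skips") <- skips
  out
}
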