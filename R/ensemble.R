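#' Conformational ensembles
#'
#' A `cc_ensemble` holds ordered coordinate frames over a fixed atom table.
#' Coordinates follow the bio3d layout: one row per frame of length
#' `3 * n_atoms` (x1,y1,z1,x2,...).  Residues carry wild-type numbering;
#' a deletion is a gap in `resno`, never a renumbering.
#'
#' @param atoms data.frame with columns `elety` (atom name), `resid`
#'   (3-letter residue), `chain`, `resno` (wild-type number), `elesy`
#'   (element symbol).
#' @param xyz numeric matrix, frames x (3 * n_atoms).
#' @param time_ns numeric frame times in ns, strictly increasing.
#' @param meta optional named list (source, seed, ...).
#' @return Object of class `cc_ensemble`.
#' @export
cc_ensemble <- function(atoms, xyz, time_ns = NULL, meta = list()) {
  xyz <- as.matrix(xyz)
  if (is.null(dim(xyz)) || ncol(xyz) != 3L * nrow(atoms))
    stop("xyz must be frames x (3 * n_atoms)")
  if (is.null(time_ns)) time_ns <- seq_len(nrow(xyz)) - 1
  stopifnot(length(time_ns) == nrow(xyz),
            !is.unsorted(time_ns, strictly = TRUE))
  structure(list(atoms = atoms, xyz = xyz, time_ns = as.numeric(time_ns),
                 meta = meta),
            class = "cc_ensemble")
}

#' @export
print.cc_ensemble <- function(x, ...) {
  cat(sprintf("cc_ensemble: %d frames x %d atoms (%.3g-%.3g ns)\n",
              nrow(x$xyz), nrow(x$atoms), min(x$time_ns), max(x$time_ns)))
  invisible(x)
}

n_frames <- function(ens) nrow(ens$xyz)

#' Convert a built model into a single-frame ensemble
#'
#' @param model a `cc_model`.
#' @param time_ns frame time stamp.
#' @return A [cc_ensemble] with one frame.
#' @export
as_ensemble <- function(model, time_ns = 0) {
  stopifnot(inherits(model, "cc_model"))
  a <- model$atoms
  xyz <- matrix(t(as.matrix(a[, c("x", "y", "z")])), nrow = 1)
  cc_ensemble(a[, c("elety", "resid", "chain", "resno", "elesy")], xyz,
              time_ns = time_ns, meta = list(source = "cc_model"))
}

# index helpers -------------------------------------------------------------

atom_sel <- function(ens, elety = NULL, chain = NULL, resno = NULL) {
  a <- ens$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  which(keep)
}

# n x 3 coordinates of selected atoms in one frame
frame_xyz <- function(ens, frame, sel) {
  idx <- as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel))
  matrix(ens$xyz[frame, idx], ncol = 3, byrow = TRUE)
}

#' Drop equilibration frames from an ensemble
#'
#' Frames earlier than `t_cut` are removed before analysis; the cut is
#' recorded in the ensemble metadata.
#'
#' @param ens a [cc_ensemble].
#' @param t_cut time cutoff in ns (default 10).
#' @return The truncated [cc_ensemble].
#' @export
discard_equilibration <- function(ens, t_cut = 10) {
  stopifnot(inherits(ens, "cc_ensemble"), t_cut >= 0)
  keep <- ens$time_ns >= t_cut
  if (!any(keep)) stop("all frames removed by equilibration cut at ",
                       t_cut, " ns")
  out <- cc_ensemble(ens$atoms, ens$xyz[keep, , drop = FALSE],
                     ens$time_ns[keep], ens$meta)
  out$meta$equilibration_cut_ns <- t_cut
  out
}

# I/O -----------------------------------------------------------------------

#' Write an ensemble as a multi-model PDB file
#'
#' One MODEL block per frame, chains A/B, standard ATOM records with
#' occupancy 1.00 and B-factor 0.00.  Frame time stamps and any `remarks`
#' are echoed as REMARK lines so a round trip through [read_ensemble()]
#' preserves them.
#'
#' @param ens a [cc_ensemble] (or `cc_model`, written as one MODEL).
#' @param path output file.
#' @param remarks optional character vector of extra REMARK payload lines.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path, remarks = NULL) {
  if (inherits(ens, "cc_model")) ens <- as_ensemble(ens)
  stopifnot(inherits(ens, "cc_ensemble"))
  a <- ens$atoms
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(remarks))
    writeLines(sprintf("REMARK   6 CCROD %s", remarks), con)
  writeLines(sprintf("REMARK   6 CCROD TIME_NS %s",
                     paste(format(ens$time_ns, trim = TRUE), collapse = " ")),
             con)
  # PDB atom names: pad to 4 starting at column 14 for 1-3 char names
  nm <- ifelse(nchar(a$elety) < 4, sprintf(" %-3s", a$elety),
               sprintf("%-4s", a$elety))
  for (f in seq_len(n_frames(ens))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_xyz(ens, f, seq_len(nrow(a)))
    writeLines(sprintf(
      "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)), nm, a$resid, a$chain, a$resno,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$elesy), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file as an ensemble
#'
#' Parsing is delegated to [bio3d::read.pdb()] (`multi = TRUE`); before
#' that, the MODEL blocks are scanned so that an inconsistent atom count is
#' reported with the offending model index.  Frame times are taken from a
#' `REMARK 6 CCROD TIME_NS` line when present, else frame indices are used.
#'
#' @param path PDB file.
#' @return A [cc_ensemble].
#' @export
read_ensemble <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  if (length(starts) > 1) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(starts)) stop("truncated MODEL block near line ",
                                             utils::tail(starts, 1))
    counts <- mapply(function(s, e) sum(grepl("^ATOM|^HETATM",
                                              lines[s:e])), starts, ends)
    if (length(unique(counts)) != 1)
      stop("inconsistent atom count in MODEL ",
           which(counts != counts[1])[1], " (", counts[which(counts != counts[1])[1]],
           " vs ", counts[1], ")")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- data.frame(elety = pdb$atom$elety, resid = pdb$atom$resid,
                      chain = pdb$atom$chain, resno = pdb$atom$resno,
                      elesy = ifelse(is.na(pdb$atom$elesy) | pdb$atom$elesy == "",
                                     substr(pdb$atom$elety, 1, 1),
                                     pdb$atom$elesy),
                      stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  tm <- grep("^REMARK   6 CCROD TIME_NS", lines, value = TRUE)
  time_ns <- if (length(tm) == 1) {
    as.numeric(strsplit(sub("^REMARK   6 CCROD TIME_NS ", "", tm[1]),
                        " +")[[1]])
  } else NULL
  if (!is.null(time_ns) && length(time_ns) != nrow(xyz)) time_ns <- NULL
  cc_ensemble(atoms, xyz, time_ns, meta = list(source = path))
}

#' Read / write the plain-CSV Calpha trace dialect
#'
#' Columns: `frame`, `chain`, `resid` (wild-type residue number), `x`,
#' `y`, `z`.  Intended for toy inputs and tests.
#'
#' @param path CSV file.
#' @return [read_ca_csv()]: a [cc_ensemble] of CA atoms.
#' @export
read_ca_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("frame", "chain", "resid", "x", "y", "z") %in% names(d)))
  d <- d[order(d$frame, d$chain, d$resid), ]
  f1 <- d[d$frame == d$frame[1], ]
  atoms <- data.frame(elety = "CA", resid = "ALA", chain = f1$chain,
                      resno = f1$resid, elesy = "C", stringsAsFactors = FALSE)
  frames <- unique(d$frame)
  xyz <- t(vapply(frames, function(f) {
    di <- d[d$frame == f, ]
    if (nrow(di) != nrow(atoms)) stop("inconsistent atoms in frame ", f)
    as.vector(t(as.matrix(di[, c("x", "y", "z")])))
  }, numeric(3 * nrow(atoms))))
  cc_ensemble(atoms, xyz, meta = list(source = path))
}

#' @rdname read_ca_csv
#' @param ens a [cc_ensemble] (CA atoms are written).
#' @export
write_ca_csv <- function(ens, path) {
  sel <- atom_sel(ens, elety = "CA")
  out <- do.call(rbind, lapply(seq_len(n_frames(ens)), function(f) {
    xyz <- frame_xyz(ens, f, sel)
    data.frame(frame = f, chain = ens$atoms$chain[sel],
               resid = ens$atoms$resno[sel],
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
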