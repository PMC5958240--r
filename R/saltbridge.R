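#' Salt-bridge occupancy over an ensemble
#'
#' A basic (Lys/Arg) and acidic (Asp/Glu) residue pair is bridged in a
#' frame when their charge centres lie closer than `cutoff`.  Charge
#' centres: Lys NZ; Arg the NH1/NH2 midpoint; Asp the OD1/OD2 midpoint;
#' Glu the OE1/OE2 midpoint.  Residues missing their charged-group atoms
#' are excluded with a warning.  Pairs never bridged in any frame are
#' omitted from the output.
#'
#' @param ens a [cc_ensemble] with side-chain atoms for charged residues.
#' @param cutoff distance cutoff, A (default 4).
#' @return A list with `bridges` (data.frame: donor/acceptor chain+resno,
#'   `intra` flag, `occupancy`) and `per_frame_count` (list `mean`, `sd`,
#'   `counts`: total bridged pairs per frame, intra- plus inter-helical).
#' @export
salt_bridge_occupancy <- function(ens, cutoff = 4) {
  stopifnot(inherits(ens, "cc_ensemble"))
  a <- ens$atoms
  centre_atoms <- list(LYS = "NZ", ARG = c("NH1", "NH2"),
                       ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  key <- paste(a$chain, a$resno)
  charged <- unique(key[a$resid %in% names(centre_atoms)])
  info <- lapply(charged, function(k) {
    ii <- which(key == k)
    resid <- a$resid[ii[1]]
    need <- centre_atoms[[resid]]
    sel <- ii[match(need, a$elety[ii])]
    if (anyNA(sel)) {
      warning("charged-group atoms missing for ", resid, " ", k,
              "; residue excluded")
      return(NULL)
    }
    list(key = k, chain = a$chain[ii[1]], resno = a$resno[ii[1]],
         resid = resid, basic = resid %in% c("LYS", "ARG"), sel = sel)
  })
  info <- Filter(Negate(is.null), info)
  basics <- Filter(function(x) x$basic, info)
  acids <- Filter(function(x) !x$basic, info)
  nf <- n_frames(ens)
  if (!length(basics) || !length(acids))
    return(list(bridges = data.frame(), per_frame_count =
                  list(mean = 0, sd = 0, counts = rep(0, nf))))

  centres <- function(frame, group) {
    t(vapply(group, function(x)
      colMeans(frame_xyz(ens, frame, x$sel)), numeric(3)))
  }
  hits <- matrix(0L, length(basics), length(acids))
  counts <- integer(nf)
  for (f in seq_len(nf)) {
    cb <- centres(f, basics)
    ca <- centres(f, acids)
    d2 <- outer(rowSums(cb^2), rowSums(ca^2), "+") - 2 * cb %*% t(ca)
    br <- d2 < cutoff^2
    hits <- hits + br
    counts[f] <- sum(br)
  }
  occ <- hits / nf
  keep <- which(occ > 0, arr.ind = TRUE)
  bridges <- do.call(rbind, lapply(seq_len(nrow(keep)), function(r) {
    b <- basics[[keep[r, 1]]]; ac <- acids[[keep[r, 2]]]
    data.frame(donor_chain = b$chain, donor_resno = b$resno,
               donor_resid = b$resid, acceptor_chain = ac$chain,
               acceptor_resno = ac$resno, acceptor_resid = ac$resid,
               intra = b$chain == ac$chain,
               occupancy = occ[keep[r, 1], keep[r, 2]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(bridges)) bridges <- data.frame()
  list(bridges = bridges,
       per_frame_count = list(mean = mean(counts),
                              sd = if (nf > 1) stats::sd(counts) else 0,
                              counts = counts))
}
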