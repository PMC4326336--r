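# Brute-force reference scanner. Deliberately simple: slides a window over
# both strands of every chromosome and tests the full contract directly
# (PAM match, Hamming distance, seed agreement). No index is involved; only
# the base encoding and PAM primitives are shared with the indexed path, so
# agreement between the two is evidence of correctness, not tautology.

# windows qualifying on one strand's sequence; returns 0-based starts in
# that sequence's coordinates plus capture codes
.brute_scan_strand <- function(seq, guide_digits, pat, max_mm, seed) {
  n <- nchar(seq)
  W <- .GUIDE_LEN + pat$length
  empty <- list(start0 = numeric(0), capture = numeric(0))
  if (n < W) return(empty)
  d <- seq_to_digits(seq)
  isN <- is.na(d)
  d0 <- d
  d0[isN] <- 0
  csN <- c(0, cumsum(isN))
  ns <- n - W + 1L
  ok <- (csN[(W + 1L):(n + 1L)] - csN[1L:ns]) == 0
  mm <- 0
  seed_viol <- 0
  for (j in seq_len(.GUIDE_LEN)) {
    diffj <- d0[j:(ns + j - 1L)] != guide_digits[j]
    mm <- mm + diffj
    if ((j - 1L) %in% seed) seed_viol <- seed_viol + diffj
  }
  ok <- ok & mm <= max_mm & seed_viol == 0
  for (t in seq_len(pat$length)) {
    b <- d0[(.GUIDE_LEN + t):(ns + .GUIDE_LEN + t - 1L)]
    fx <- pat$digits[t]
    if (!is.na(fx)) {
      ok <- ok & (b == fx)
    } else if (pat$is_r[t]) {
      ok <- ok & (b == 0 | b == 2)
    }
  }
  starts <- which(ok)
  if (length(starts) == 0L) return(empty)
  capt <- 0
  for (k in seq_along(pat$unspec_pos)) {
    capt <- capt + d0[starts + .GUIDE_LEN + pat$unspec_pos[k]] * 4^(k - 1)
  }
  list(start0 = starts - 1,
       capture = if (length(pat$unspec_pos)) capt else rep(0, length(starts)))
}

#' Brute-force off-target scan (reference implementation)
#'
#' Naive sliding-window scan of both strands of the genome: a window is
#' reported iff the PAM pattern matches immediately 3' of it, its Hamming
#' distance to the guide is at most `max_mm`, and it agrees with the guide
#' at every seed position. Used as ground truth in the test suite; output
#' format and sort order are identical to [find_offtargets()].
#'
#' @inheritParams find_offtargets
#' @param g a [genome()].
#' @return hit data.frame (see [find_offtargets()]).
#' @export
brute_force_offtargets <- function(g, guide, pam, max_mm, seed = NULL) {
  stopifnot(inherits(g, "genome"))
  guide <- .check_guide(guide)
  max_mm <- .check_max_mm(max_mm)
  pat <- if (inherits(pam, "pam_pattern")) pam else parse_pam(pam, pam_id = 0L)
  seed <- parse_seed_mask(seed)
  gd <- seq_to_digits(guide)

  parts <- vector("list", 2L * length(g$seqs))
  for (ci in seq_along(g$seqs)) {
    s <- g$seqs[[ci]]
    n <- nchar(s)
    f <- .brute_scan_strand(s, gd, pat, max_mm, seed)
    rc <- reverse_complement(s)
    r <- .brute_scan_strand(rc, gd, pat, max_mm, seed)
    parts[[2L * ci - 1L]] <- data.frame(
      chrom_id = rep(ci - 1L, length(f$start0)),
      strand01 = rep(0L, length(f$start0)),
      position = f$start0,
      sequence = if (length(f$start0)) substring(s, f$start0 + 1L, f$start0 + .GUIDE_LEN) else character(0),
      capture = f$capture
    )
    parts[[2L * ci]] <- data.frame(
      chrom_id = rep(ci - 1L, length(r$start0)),
      strand01 = rep(1L, length(r$start0)),
      position = n - .GUIDE_LEN - r$start0,
      sequence = if (length(r$start0)) substring(rc, r$start0 + 1L, r$start0 + .GUIDE_LEN) else character(0),
      capture = r$capture
    )
  }
  all <- do.call(rbind, parts)
  if (nrow(all) == 0L) return(.empty_hits())
  .make_hits(
    chrom_id = all$chrom_id,
    strand01 = all$strand01,
    position = all$position,
    sequences = all$sequence,
    pam_instance = .codes_to_pam_instances(all$capture, pat),
    guide = guide,
    chrom_names = names(g$seqs)
  )
}
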