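# On-line stage: enumerate the Hamming neighborhood of the guide's 16-mer
# prefix (respecting the seed mask), follow Table A pointers into Table B,
# reconstitute candidate 20-mers from prefix + stored tail, and filter on
# total mismatch count, seed agreement, and requested PAM.

#' Parse a seed mask specification
#'
#' The seed is the user-chosen subset of the 20 guide positions that must
#' match the genomic site exactly. Position 0 is the 5'-most guide base.
#' Accepted forms: an integer vector of 0-based positions; a comma-separated
#' string like `"12,15,19"`; the shorthand `"3prime:k"` for the k PAM-proximal
#' positions `{20-k..19}`; `NULL` or `""` for no constraint.
#'
#' @param seed mask specification (see above).
#' @return sorted integer vector of 0-based positions (possibly empty).
#' @export
parse_seed_mask <- function(seed) {
  if (is.null(seed)) return(integer(0))
  if (is.character(seed)) {
    stopifnot(length(seed) == 1L)
    seed <- trimws(seed)
    if (!nzchar(seed)) return(integer(0))
    if (grepl("^3prime:", seed)) {
      k <- suppressWarnings(as.integer(sub("^3prime:", "", seed)))
      if (is.na(k) || k < 0L || k > .GUIDE_LEN) {
        stop("input error: seed shorthand '3prime:k' needs k in 0..", .GUIDE_LEN)
      }
      return(if (k == 0L) integer(0) else (.GUIDE_LEN - k):(.GUIDE_LEN - 1L))
    }
    seed <- suppressWarnings(as.integer(strsplit(seed, ",", fixed = TRUE)[[1L]]))
    if (anyNA(seed)) stop("input error: seed positions must be integers")
  }
  seed <- as.integer(seed)
  if (any(seed < 0L | seed >= .GUIDE_LEN)) {
    stop("input error: seed positions must lie in 0..", .GUIDE_LEN - 1L)
  }
  sort(unique(seed))
}

# Code-level neighborhood enumeration for find_offtargets: all 16-mer codes
# within Hamming distance max_mm of the prefix, substituting only at
# positions outside seed_prefix (0-based). Returns list(code, mm).
.enumerate_prefix_variant_codes <- function(prefix_digits, max_mm, seed_prefix) {
  w <- 4^((.PREFIX_LEN - 1L):0)
  code0 <- sum(prefix_digits * w)
  free <- setdiff(0:(.PREFIX_LEN - 1L), seed_prefix)
  codes <- list(code0)
  mms <- list(0L)
  if (max_mm > 0L && length(free) > 0L) {
    # delta[p, a]: code change from substituting alternative a at position p
    delta <- matrix(0, nrow = .PREFIX_LEN, ncol = 3L)
    for (p in seq_len(.PREFIX_LEN)) {
      alts <- setdiff(0:3, prefix_digits[p])
      delta[p, ] <- (alts - prefix_digits[p]) * w[p]
    }
    for (i in seq_len(min(max_mm, length(free)))) {
      idx <- utils::combn(seq_along(free), i)
      combs <- matrix(free[idx], nrow = i)          # i x C, 0-based positions
      tup <- as.matrix(expand.grid(rep(list(1:3), i)))   # 3^i x i
      total <- matrix(0, nrow = ncol(combs), ncol = nrow(tup))
      for (k in seq_len(i)) {
        dk <- delta[combs[k, ] + 1L, , drop = FALSE]     # C x 3
        total <- total + dk[, tup[, k], drop = FALSE]
      }
      codes[[i + 1L]] <- code0 + as.vector(total)
      mms[[i + 1L]] <- rep(i, ncol(combs) * nrow(tup))
    }
  }
  list(code = unlist(codes), mm = unlist(mms))
}

#' Enumerate the seed-constrained Hamming neighborhood of a 16-mer prefix
#'
#' Every distinct 16-mer within Hamming distance `max_mm` of `prefix`, with
#' substitutions only at positions outside the seed mask (positions 0..15 of
#' the mask apply; higher positions concern the guide tail). The original
#' prefix is included with distance 0; each variant appears exactly once,
#' with its exact distance. With an empty seed the count is
#' \eqn{\sum_{i=0}^{M} \binom{16}{i} 3^i}.
#'
#' @param prefix a 16-mer over {A,C,G,T}.
#' @param max_mm maximum Hamming distance, 0..5.
#' @param seed seed mask (see [parse_seed_mask()]).
#' @return data.frame with columns `variant` (16-mer) and `mm` (exact distance).
#' @export
enumerate_prefix_variants <- function(prefix, max_mm, seed = NULL) {
  stopifnot(nchar(prefix) == .PREFIX_LEN)
  max_mm <- .check_max_mm(max_mm)
  d <- seq_to_digits(toupper(prefix))
  if (anyNA(d)) stop("input error: prefix must be over {A,C,G,T}")
  seed <- parse_seed_mask(seed)
  v <- .enumerate_prefix_variant_codes(d, max_mm, seed[seed < .PREFIX_LEN])
  data.frame(variant = .codes_to_kmers(v$code, .PREFIX_LEN), mm = v$mm)
}

.check_max_mm <- function(max_mm) {
  if (length(max_mm) != 1L || is.na(max_mm) || max_mm < 0 || max_mm > 5 ||
      max_mm != trunc(max_mm)) {
    stop("input error: max_mm must be an integer in 0..5")
  }
  as.integer(max_mm)
}

.check_guide <- function(guide) {
  stopifnot(is.character(guide), length(guide) == 1L)
  guide <- toupper(guide)
  if (nchar(guide) != .GUIDE_LEN || grepl("[^ACGT]", guide)) {
    stop("input error: guide must be a ", .GUIDE_LEN,
         "-mer over {A,C,G,T}, got '", guide, "'")
  }
  guide
}

# resolve a pattern argument against an index's pam table
.resolve_pam <- function(index, pam) {
  text <- if (inherits(pam, "pam_pattern")) pam$text else toupper(as.character(pam))
  texts <- vapply(index$pam_table, `[[`, character(1), "text")
  i <- match(text, texts)
  if (is.na(i)) {
    stop("input error: PAM '", text, "' is not in this index; available: ",
         paste(texts, collapse = ", "))
  }
  index$pam_table[[i]]
}

.HIT_COLS <- c("chrom", "strand", "position", "sequence", "mismatch_count",
               "mismatch_positions", "pam", "gc")

.empty_hits <- function() {
  data.frame(chrom = character(0), strand = character(0), position = numeric(0),
             sequence = character(0), mismatch_count = integer(0),
             mismatch_positions = character(0), pam = character(0),
             gc = numeric(0))
}

# assemble a sorted hit table from parallel field vectors
.make_hits <- function(chrom_id, strand01, position, sequences, pam_instance,
                       guide, chrom_names) {
  if (length(position) == 0L) return(.empty_hits())
  gchars <- strsplit(guide, "", fixed = TRUE)[[1L]]
  mat <- matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
                ncol = .GUIDE_LEN, byrow = TRUE)
  diffm <- mat != matrix(gchars, nrow = nrow(mat), ncol = .GUIDE_LEN, byrow = TRUE)
  mm_count <- as.integer(rowSums(diffm))
  mm_pos <- vapply(seq_len(nrow(mat)), function(i) {
    paste(which(diffm[i, ]) - 1L, collapse = ",")
  }, character(1))
  gc <- (.GUIDE_LEN - nchar(gsub("[GC]", "", sequences))) / .GUIDE_LEN
  out <- data.frame(
    chrom = chrom_names[chrom_id + 1L],
    strand = c("+", "-")[strand01 + 1L],
    position = position,
    sequence = sequences,
    mismatch_count = mm_count,
    mismatch_positions = mm_pos,
    pam = pam_instance,
    gc = gc
  )
  out <- out[order(chrom_id, out$position, strand01), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find all off-target sites of a guide RNA using the index
#'
#' Enumerates the seed-constrained Hamming neighborhood of the guide's
#' 16-mer prefix, follows the Table A pointer of each variant to its Table B
#' group, reconstitutes each stored site's 20-mer (variant prefix + decoded
#' tail), and reports every site whose total mismatch count (prefix + tail)
#' is at most `max_mm`, whose mismatches avoid the seed positions, and whose
#' stored PAM id matches the requested pattern. The result is exhaustive:
#' it equals the brute-force scan ([brute_force_offtargets()]) as a set.
#'
#' @param index an `offtarget_index`.
#' @param guide the 20-mer guide sequence (protospacer, 5'->3', PAM not
#'   included).
#' @param pam the PAM pattern to report against (string or `pam_pattern`);
#'   must be one of the patterns the index was built with.
#' @param max_mm maximum number of mismatches, 0..5.
#' @param seed seed mask (see [parse_seed_mask()]); seed positions must match
#'   exactly and never count toward `max_mm` (they cannot mismatch).
#' @return data.frame of hits sorted by (chrom, position, strand) with
#'   columns `chrom`, `strand` (+/-), `position` (0-based forward-strand
#'   leftmost base of the 20-mer), `sequence` (reconstituted 20-mer),
#'   `mismatch_count`, `mismatch_positions` (comma-joined 0-based),
#'   `pam` (dereferenced PAM instance), `gc` (G+C fraction of the 20-mer).
#' @export
find_offtargets <- function(index, guide, pam, max_mm, seed = NULL) {
  stopifnot(inherits(index, "offtarget_index"))
  guide <- .check_guide(guide)
  max_mm <- .check_max_mm(max_mm)
  pat <- .resolve_pam(index, pam)
  seed <- parse_seed_mask(seed)
  gd <- seq_to_digits(guide)
  seed_prefix <- seed[seed < .PREFIX_LEN]
  seed_tail <- seed[seed >= .PREFIX_LEN] - .PREFIX_LEN

  v <- .enumerate_prefix_variant_codes(gd[1:.PREFIX_LEN], max_mm, seed_prefix)
  m <- match(v$code, index$prefix_codes)
  sel <- which(!is.na(m))
  if (length(sel) == 0L) return(.empty_hits())
  grp <- m[sel]
  lens <- index$offsets[grp + 1L] - index$offsets[grp]
  nz <- lens > 0
  grp <- grp[nz]; lens <- lens[nz]; sel <- sel[nz]
  if (length(grp) == 0L) return(.empty_hits())

  rec_idx <- sequence(as.integer(lens), from = as.integer(index$offsets[grp] + 1L))
  vcode <- rep(v$code[sel], lens)
  vmm <- rep(v$mm[sel], lens)
  word <- index$table_b[rec_idx]

  pam_id <- word %/% .B_PAMID %% 8
  keep <- pam_id == pat$pam_id
  if (!any(keep)) return(.empty_hits())
  word <- word[keep]; vcode <- vcode[keep]; vmm <- vmm[keep]

  tail_code <- word %/% .B_TAIL %% 256
  tm <- .codes_to_digit_matrix(tail_code, .TAIL_LEN)
  gt <- gd[(.PREFIX_LEN + 1L):.GUIDE_LEN]
  tdiff <- tm != matrix(gt, nrow = nrow(tm), ncol = .TAIL_LEN, byrow = TRUE)
  tail_mm <- rowSums(tdiff)
  ok <- (vmm + tail_mm) <= max_mm
  if (length(seed_tail) > 0L) {
    ok <- ok & rowSums(tdiff[, seed_tail + 1L, drop = FALSE]) == 0
  }
  if (!any(ok)) return(.empty_hits())
  word <- word[ok]; vcode <- vcode[ok]; tail_code <- tail_code[ok]

  sequences <- paste0(.codes_to_kmers(vcode, .PREFIX_LEN),
                      .codes_to_kmers(tail_code, .TAIL_LEN))
  capture <- word %/% .B_CAPT %% 256
  .make_hits(
    chrom_id = as.integer(word %/% .B_CHROM %% 32),
    strand01 = as.integer(word %/% .B_STRAND %% 2),
    position = word %% .B_STRAND,
    sequences = sequences,
    pam_instance = .codes_to_pam_instances(capture, pat),
    guide = guide,
    chrom_names = index$chrom_names
  )
}

#' Histogram of off-target counts by mismatch number
#'
#' @param hits a hit table from [find_offtargets()] or
#'   [brute_force_offtargets()].
#' @param max_mm largest mismatch count to tabulate.
#' @return integer vector of length `max_mm + 1`; element `i+1` is the number
#'   of hits with exactly `i` mismatches.
#' @export
mismatch_histogram <- function(hits, max_mm) {
  max_mm <- .check_max_mm(max_mm)
  counts <- integer(max_mm + 1L)
  if (nrow(hits) > 0L) {
    tab <- tabulate(hits$mismatch_count + 1L, nbins = max_mm + 1L)
    counts <- as.integer(tab)
  }
  stats::setNames(counts, paste0("mm", 0:max_mm))
}

#' GC content of a protospacer sequence
#'
#' Fraction of G or C bases.
#'
#' @param seq character vector of sequences over {A,C,G,T}.
#' @return numeric vector of G+C fractions.
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq))
  up <- toupper(seq)
  if (any(grepl("[^ACGT]", up))) {
    stop("input error: sequence must be over {A,C,G,T}")
  }
  (nchar(up) - nchar(gsub("[GC]", "", up))) / nchar(up)
}

#' Extract candidate guides from a target sequence
#'
#' Scans both strands of a target region (21 to 500 nt) for every 20-mer
#' window immediately followed (3' on its strand) by a PAM-matching window.
#' Offsets are 0-based coordinates of the window's leftmost base on the
#' forward strand of the input, regardless of strand.
#'
#' @param target_seq the target sequence (forward strand).
#' @param pam a PAM pattern string or [parse_pam()] object.
#' @return data.frame with columns `guide` (20-mer as read on its strand),
#'   `strand` (+/-), `offset`.
#' @export
extract_guides <- function(target_seq, pam) {
  stopifnot(is.character(target_seq), length(target_seq) == 1L)
  pat <- if (inherits(pam, "pam_pattern")) pam else parse_pam(pam, pam_id = 0L)
  target_seq <- toupper(target_seq)
  if (grepl("[^ACGTN]", target_seq)) {
    stop("input error: target sequence must be over {A,C,G,T,N}")
  }
  n <- nchar(target_seq)
  if (n > 500L) {
    stop("input error: target sequence is ", n, " nt; at most 500 nt allowed")
  }
  if (n < .GUIDE_LEN + pat$length) {
    stop("input error: target sequence is ", n, " nt; at least ",
         .GUIDE_LEN + pat$length, " nt (guide + PAM) required")
  }
  tab <- list(pat)
  fwd <- .scan_strand(target_seq, tab)
  rev <- .scan_strand(reverse_complement(target_seq), tab)
  out <- data.frame(
    guide = c(
      if (nrow(fwd)) substring(target_seq, fwd$start0 + 1L,
                               fwd$start0 + .GUIDE_LEN) else character(0),
      if (nrow(rev)) substring(reverse_complement(target_seq),
                               rev$start0 + 1L, rev$start0 + .GUIDE_LEN)
      else character(0)
    ),
    strand = c(rep("+", nrow(fwd)), rep("-", nrow(rev))),
    offset = c(fwd$start0, n - .GUIDE_LEN - rev$start0)
  )
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
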