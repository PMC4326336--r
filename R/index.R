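# Off-line stage: scan the genome for PAM-adjacent 20-mers and build the
# prefix-hash index — Table A (16-mer prefix -> offset range, stored sparse)
# over Table B (flat array of bit-packed 64-bit site records).
#
# Record layout within the 64-bit word (low to high):
#   bits 0-27  position (0-based, forward-strand leftmost base of the 20-mer)
#   bit  28    strand (0 forward, 1 reverse)
#   bits 29-33 chromosome id (0-based FASTA ordinal, <= 31)
#   bits 34-36 PAM id
#   bits 37-44 captured unspecified PAM bases (2 bits each, pattern order,
#              low bits first)
#   bits 45-52 tail 4-mer code (guide bases 17-20)
# The full layout spans bits 0..52, so every packed word is < 2^53 and is
# held exactly in an R double.

.GUIDE_LEN <- 20L
.PREFIX_LEN <- 16L
.TAIL_LEN <- 4L
.POS_BITS <- 28
.MAX_CHROMS <- 32L

.B_STRAND <- 2^28
.B_CHROM  <- 2^29
.B_PAMID  <- 2^34
.B_CAPT   <- 2^37
.B_TAIL   <- 2^45

# Scan one strand's sequence for PAM-adjacent 20-mers. Returns a data.frame
# with 0-based window starts in THIS sequence's coordinates; the caller maps
# reverse-strand starts back to forward coordinates.
.scan_strand <- function(seq, pam_table) {
  n <- nchar(seq)
  empty <- data.frame(prefix_code = numeric(0), tail_code = numeric(0),
                      pam_id = integer(0), capture_code = numeric(0),
                      start0 = numeric(0))
  if (n < .GUIDE_LEN + min(vapply(pam_table, `[[`, numeric(1), "length"))) {
    return(empty)
  }
  d <- seq_to_digits(seq)
  isN <- is.na(d)
  d0 <- d
  d0[isN] <- 0
  csN <- c(0, cumsum(isN))

  # rolling polynomial codes for every 16-mer and 4-mer window
  npfx <- n - .PREFIX_LEN + 1L
  P <- 0
  for (j in 0:(.PREFIX_LEN - 1L)) {
    P <- P + d0[(1L + j):(npfx + j)] * 4^(.PREFIX_LEN - 1L - j)
  }
  ntl <- n - .TAIL_LEN + 1L
  Tl <- 0
  for (j in 0:(.TAIL_LEN - 1L)) {
    Tl <- Tl + d0[(1L + j):(ntl + j)] * 4^(.TAIL_LEN - 1L - j)
  }

  out <- vector("list", length(pam_table))
  for (pi in seq_along(pam_table)) {
    pat <- pam_table[[pi]]
    W <- .GUIDE_LEN + pat$length
    if (n < W) next
    ns <- n - W + 1L                       # number of candidate starts
    ok <- (csN[(W + 1L):(n + 1L)] - csN[1L:ns]) == 0   # no N in 20-mer + PAM
    for (t in seq_len(pat$length)) {       # PAM position t (1-based)
      b <- d0[(.GUIDE_LEN + t):(ns + .GUIDE_LEN + t - 1L)]
      fx <- pat$digits[t]
      if (!is.na(fx)) {
        ok <- ok & (b == fx)
      } else if (pat$is_r[t]) {
        ok <- ok & (b == 0 | b == 2)       # purine: A or G
      }                                    # N: any base (genomic N caught above)
    }
    starts <- which(ok)
    if (length(starts) == 0L) next
    capt <- 0
    for (k in seq_along(pat$unspec_pos)) {
      u <- pat$unspec_pos[k]               # 0-based within PAM
      capt <- capt + d0[starts + .GUIDE_LEN + u] * 4^(k - 1)
    }
    out[[pi]] <- data.frame(
      prefix_code = P[starts],
      tail_code = Tl[starts + .PREFIX_LEN],
      pam_id = rep(pat$pam_id, length(starts)),
      capture_code = if (length(pat$unspec_pos)) capt else rep(0, length(starts)),
      start0 = starts - 1
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) empty else do.call(rbind, out)
}

#' Enumerate all PAM-adjacent 20-mer sites in a genome
#'
#' Scans both strands of every chromosome for 20-mer windows immediately
#' followed (3') by a window matching one of the PAM patterns. Windows whose
#' 20-mer or PAM region contains `N` are skipped. A site matching several
#' patterns is emitted once per pattern. Positions are always the 0-based
#' forward-strand coordinate of the leftmost base of the 20-mer, regardless
#' of strand.
#'
#' @param g a [genome()].
#' @param pam_table list of [parse_pam()] patterns with assigned ids
#'   (see [builtin_pams()]), or a character vector of pattern strings.
#' @return data.frame with columns `prefix_code` (16-mer code), `tail_code`
#'   (4-mer code), `pam_id`, `capture_code`, `chrom` (0-based id), `strand`
#'   (0 forward / 1 reverse), `position`.
#' @export
scan_pam_sites <- function(g, pam_table) {
  stopifnot(inherits(g, "genome"))
  if (is.character(pam_table)) pam_table <- make_pam_table(pam_table)
  if (length(g$seqs) > .MAX_CHROMS) {
    stop("capacity error: ", length(g$seqs), " chromosomes exceed the ",
         .MAX_CHROMS, "-sequence limit of the 5-bit chromosome field")
  }
  lens <- nchar(g$seqs)
  if (any(lens > 2^.POS_BITS)) {
    stop("capacity error: chromosome '",
         names(g$seqs)[which.max(lens)], "' exceeds the 2^", .POS_BITS,
         " nt limit of the ", .POS_BITS, "-bit position field")
  }
  res <- vector("list", 2L * length(g$seqs))
  for (ci in seq_along(g$seqs)) {
    s <- g$seqs[[ci]]
    n <- nchar(s)
    fwd <- .scan_strand(s, pam_table)
    fwd$chrom <- rep(ci - 1L, nrow(fwd))
    fwd$strand <- rep(0L, nrow(fwd))
    fwd$position <- fwd$start0
    rev <- .scan_strand(reverse_complement(s), pam_table)
    rev$chrom <- rep(ci - 1L, nrow(rev))
    rev$strand <- rep(1L, nrow(rev))
    rev$position <- n - .GUIDE_LEN - rev$start0
    res[[2L * ci - 1L]] <- fwd
    res[[2L * ci]] <- rev
  }
  out <- do.call(rbind, res)
  out$start0 <- NULL
  rownames(out) <- NULL
  out
}

#' Pack a site record into a 64-bit word
#'
#' Fields are validated against their declared bit widths and packed in the
#' fixed layout documented for [build_index()] (position low, tail code high).
#'
#' @param r list with fields `tail_code` (0..255), `pam_id` (0..7),
#'   `pam_bases` (character vector of captured bases, pattern order; or a
#'   numeric 8-bit capture code), `chrom` (0..31), `strand` (0/1),
#'   `position` (0..2^28-1).
#' @return the packed word as a double.
#' @export
pack_record <- function(r) {
  capt <- r$pam_bases %||% 0
  capt <- if (is.character(capt)) capture_to_code(capt) else
    if (length(capt) == 0L) 0 else as.numeric(capt)
  chk <- function(v, lo, hi, field) {
    if (is.null(v) || is.na(v) || v < lo || v > hi || v != trunc(v)) {
      stop("packing error: field '", field, "' = ", v,
           " outside ", lo, "..", hi)
    }
    as.numeric(v)
  }
  pos    <- chk(r$position, 0, 2^.POS_BITS - 1, "position")
  strand <- chk(r$strand, 0, 1, "strand")
  chrom  <- chk(r$chrom, 0, 31, "chrom")
  pam_id <- chk(r$pam_id, 0, 7, "pam_id")
  capt   <- chk(capt, 0, 255, "pam_bases")
  tail   <- chk(r$tail_code, 0, 255, "tail_code")
  pos + strand * .B_STRAND + chrom * .B_CHROM + pam_id * .B_PAMID +
    capt * .B_CAPT + tail * .B_TAIL
}

#' Unpack a 64-bit site record word
#'
#' Inverse of [pack_record()]. Vectorized over `word`.
#'
#' @param word numeric vector of packed words.
#' @param pam_table optional list of patterns (id-ordered as in an index); when
#'   given, the captured PAM bases are decoded to letters per record.
#' @return data.frame with columns `tail_code`, `pam_id`, `capture_code`,
#'   `chrom`, `strand`, `position`, and `pam_bases` (comma-joined captured
#'   bases) when `pam_table` is supplied.
#' @export
unpack_record <- function(word, pam_table = NULL) {
  word <- as.numeric(word)
  out <- data.frame(
    tail_code    = word %/% .B_TAIL %% 256,
    pam_id       = as.integer(word %/% .B_PAMID %% 8),
    capture_code = word %/% .B_CAPT %% 256,
    chrom        = as.integer(word %/% .B_CHROM %% 32),
    strand       = as.integer(word %/% .B_STRAND %% 2),
    position     = word %% .B_STRAND
  )
  if (!is.null(pam_table)) {
    ids <- vapply(pam_table, `[[`, integer(1), "pam_id")
    out$pam_bases <- vapply(seq_len(nrow(out)), function(i) {
      pat <- pam_table[[match(out$pam_id[i], ids)]]
      paste(code_to_capture(out$capture_code[i], length(pat$unspec_pos)),
            collapse = ",")
    }, character(1))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the off-target index for a genome
#'
#' Two-pass construction: pass 1 counts PAM-adjacent 20-mer sites per 16-mer
#' prefix and initializes the Table A offsets from the cumulative counts;
#' pass 2 places each bit-packed record into its prefix group (counting
#' sort). Within a group, records are ordered by (chrom, position, strand,
#' pam_id). Table A is stored sparsely: only occupied prefixes are kept, as
#' a sorted code vector plus an offset vector of length `n+1` whose
#' consecutive differences are exactly the per-prefix site counts.
#'
#' @param g a [genome()].
#' @param pams character vector of PAM pattern strings (or a pre-built
#'   pattern list); built-in patterns NGG, NAG, NNNNACA, NNGRRT keep their
#'   reserved ids 0-3, others are assigned 4 upward (at most 8 total).
#' @return object of class `offtarget_index` with fields `prefix_codes`,
#'   `offsets` (0-based into `table_b`, length `length(prefix_codes)+1`),
#'   `table_b` (packed words), `pam_table`, `chrom_names`, `chrom_lengths`.
#' @export
build_index <- function(g, pams) {
  stopifnot(inherits(g, "genome"))
  pam_table <- if (is.character(pams)) make_pam_table(pams) else pams
  sites <- scan_pam_sites(g, pam_table)

  # pass 1: per-prefix counts -> offset initialization
  prefix_codes <- sort(unique(sites$prefix_code))
  grp <- match(sites$prefix_code, prefix_codes)
  counts <- tabulate(grp, nbins = length(prefix_codes))
  offsets <- c(0, cumsum(counts))

  # pass 2: counting-sort placement, deterministic within-group order
  ord <- order(grp, sites$chrom, sites$position, sites$strand, sites$pam_id)
  s <- sites[ord, , drop = FALSE]
  table_b <- s$position + s$strand * .B_STRAND + s$chrom * .B_CHROM +
    s$pam_id * .B_PAMID + s$capture_code * .B_CAPT + s$tail_code * .B_TAIL

  structure(list(
    prefix_codes = prefix_codes,
    offsets = offsets,
    table_b = table_b,
    pam_table = pam_table,
    chrom_names = names(g$seqs),
    chrom_lengths = unname(nchar(g$seqs))
  ), class = "offtarget_index")
}

#' Per-prefix group sizes of an index
#'
#' The consecutive Table A offset differences: for each occupied 16-mer
#' prefix, the number of Table B records in its group.
#'
#' @param index an `offtarget_index`.
#' @return named numeric vector (names = prefix codes).
#' @export
prefix_group_sizes <- function(index) {
  stats::setNames(diff(index$offsets), format(index$prefix_codes, scientific = FALSE, trim = TRUE))
}

#' @export
print.offtarget_index <- function(x, ...) {
  cat("<offtarget_index>\n")
  cat("  genome:   ", length(x$chrom_names), " chromosome(s), ",
      format(sum(x$chrom_lengths), big.mark = ","), " nt\n", sep = "")
  cat("  PAMs:     ",
      paste(vapply(x$pam_table, function(p) sprintf("%s(id %d)", p$text, p$pam_id),
                   character(1)), collapse = ", "), "\n", sep = "")
  cat("  Table A:  ", format(length(x$prefix_codes), big.mark = ","),
      " occupied 16-mer prefixes (sparse)\n", sep = "")
  cat("  Table B:  ", format(length(x$table_b), big.mark = ","),
      " packed site records\n", sep = "")
  invisible(x)
}

#' @export
summary.offtarget_index <- function(object, ...) {
  rec <- unpack_record(object$table_b)
  per_chrom <- tabulate(rec$chrom + 1L, nbins = length(object$chrom_names))
  out <- data.frame(chrom = object$chrom_names,
                    length = object$chrom_lengths,
                    sites = per_chrom)
  class(out) <- c("summary.offtarget_index", "data.frame")
  out
}
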