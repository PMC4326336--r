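# Nucleotide <-> integer encoding, the polynomial k-mer hash, and FASTA
# ingestion. All codes are carried as doubles: a 16-mer code can reach
# 4^16 - 1 = 4,294,967,295, which exceeds R's 32-bit integer range but is
# exactly representable in a double.

# digit lookup: A->0, C->1, G->2, T->3; N and everything else -> NA
.DIGIT_LUT <- local({
  lut <- rep(NA_real_, 127L)
  lut[utf8ToInt("A")] <- 0
  lut[utf8ToInt("C")] <- 1
  lut[utf8ToInt("G")] <- 2
  lut[utf8ToInt("T")] <- 3
  lut
})

.BASES <- c("A", "C", "G", "T")

#' Convert a nucleotide string to integer digits
#'
#' Internal: maps A,C,G,T to 0..3 and N (or any other character) to NA,
#' one element per base.
#' @param seq single nucleotide string.
#' @return numeric vector of digits, length `nchar(seq)`.
#' @keywords internal
#' @noRd
seq_to_digits <- function(seq) {
  .DIGIT_LUT[utf8ToInt(seq)]
}

digits_to_seq <- function(digits) {
  paste(.BASES[digits + 1L], collapse = "")
}

#' Encode a k-mer as its polynomial hash value
#'
#' Maps a k-mer over {A,C,G,T} to the integer
#' \eqn{\sum_{j=0}^{k-1} d_j \, 4^{k-1-j}} with A=0, C=1, G=2, T=3 and the
#' leftmost base most significant. The mapping is a bijection between k-mers
#' and `0..4^k-1`, so it doubles as both a hash (collision-free) and a
#' 2-bit-per-base packing. For k = 16 the value range is 0 to 4,294,967,295.
#'
#' @param seq a single k-mer over {A,C,G,T}; `N` is rejected.
#' @param k expected k-mer length; defaults to `nchar(seq)`.
#' @return an object of class `kmer_code`: a double with attribute `k`.
#' @seealso [code_to_kmer()] for the inverse.
#' @examples
#' kmer_to_code("AACTCCTGACCTCAGA")  # 123606856
#' @export
kmer_to_code <- function(seq, k = nchar(seq)) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) != k) {
    stop("encoding error: sequence length ", nchar(seq), " does not match k = ", k)
  }
  d <- seq_to_digits(toupper(seq))
  if (anyNA(d)) {
    stop("encoding error: sequence contains characters outside {A,C,G,T}: ", seq)
  }
  value <- sum(d * 4^((k - 1):0))
  structure(value, k = k, class = "kmer_code")
}

#' Decode a polynomial hash value back to its k-mer
#'
#' Inverts [kmer_to_code()] by repeated division: the code is read as a k-digit
#' base-4 number, most significant digit first.
#'
#' @param code the integer code (a `kmer_code`, or a bare number with `k` given).
#' @param k the k-mer length; taken from the `k` attribute when present.
#' @return the k-mer as a character string.
#' @examples
#' code_to_kmer(123606856, k = 16)
#' @export
code_to_kmer <- function(code, k = attr(code, "k")) {
  if (is.null(k)) stop("domain error: k not supplied and not carried by code")
  value <- as.numeric(code)
  stopifnot(length(value) == 1L)
  if (is.na(value) || value < 0 || value >= 4^k || value != trunc(value)) {
    stop("domain error: code ", value, " outside 0..4^", k, "-1")
  }
  digits_to_seq(.codes_to_digit_matrix(value, k)[1L, ])
}

# vectorized decode: one row per code, k columns of digits 0..3
.codes_to_digit_matrix <- function(codes, k) {
  out <- matrix(0, nrow = length(codes), ncol = k)
  v <- codes
  for (j in k:1) {
    out[, j] <- v %% 4
    v <- v %/% 4
  }
  out
}

# vectorized decode straight to strings
.codes_to_kmers <- function(codes, k) {
  if (length(codes) == 0L) return(character(0))
  m <- .codes_to_digit_matrix(codes, k)
  cols <- lapply(seq_len(k), function(j) .BASES[m[, j] + 1L])
  do.call(paste0, cols)
}

#' Reverse complement of a nucleotide string
#'
#' Watson-Crick complement, reversed; `N` is its own complement. Works on a
#' character vector element-wise.
#'
#' @param seq character vector over {A,C,G,T,N} (case-insensitive).
#' @return character vector of reverse complements, uppercase.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  up <- toupper(seq)
  if (any(grepl("[^ACGTN]", up))) {
    stop("encoding error: sequence contains characters outside {A,C,G,T,N}")
  }
  comp <- chartr("ACGTN", "TGCAN", up)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a genome object
#'
#' A genome is an ordered set of named chromosome sequences over {A,C,G,T,N}.
#' Chromosome ids are the 0-based ordinals of the input order (the order of
#' records in the source FASTA).
#'
#' @param seqs named character vector of chromosome sequences.
#' @return object of class `genome`.
#' @export
genome <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("format error: every chromosome needs a name")
  }
  if (anyDuplicated(names(seqs))) {
    stop("format error: duplicate chromosome names: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  seqs <- toupper(seqs)
  seqs <- gsub("[^ACGTN]", "N", seqs)  # IUPAC ambiguity codes and gaps -> N
  structure(list(seqs = seqs), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome> ", length(x$seqs), " chromosome(s), ",
      format(sum(nchar(x$seqs)), big.mark = ","), " nt total\n", sep = "")
  for (i in seq_along(x$seqs)) {
    cat(sprintf("  [%d] %s  %s nt\n", i - 1L, names(x$seqs)[i],
                format(nchar(x$seqs[i]), big.mark = ",")))
  }
  invisible(x)
}

#' Chromosome names of a genome
#' @param g a `genome`.
#' @return character vector in chromosome-id order.
#' @export
chrom_names <- function(g) names(g$seqs)

#' Chromosome id lookup (0-based, FASTA order)
#' @param g a `genome`.
#' @return named integer vector mapping name to 0-based ordinal.
#' @export
chrom_ids <- function(g) {
  stats::setNames(seq_along(g$seqs) - 1L, names(g$seqs))
}

#' Read a genome from a FASTA file
#'
#' Multi-record FASTA, wrapped or unwrapped. Sequences are uppercased;
#' IUPAC ambiguity codes and gap characters are folded to `N` (a window
#' containing `N` is never indexed, so the fold is conservative). Record
#' order in the file fixes the chromosome ids.
#'
#' @param path path to a FASTA file.
#' @return a [genome()] object.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  lines <- readLines(path, n = 100L, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("format error: empty FASTA file: ", path)
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("format error: line ", first, " of ", path,
         " does not start a FASTA record ('>' expected)")
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("format error: cannot parse FASTA ", path, ": ",
                             conditionMessage(e))
  )
  if (length(set) == 0L) stop("format error: no records in FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(set))  # name = first whitespace-separated token
  genome(stats::setNames(as.character(set), nm))
}
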