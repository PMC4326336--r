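# Shared helpers: random inputs, an independent per-prefix site counter
# (string-based, no shared arithmetic with the scanner), and hit-set
# comparison.

BASES <- c("A", "C", "G", "T")

rand_guide <- function() {
  paste(sample(BASES, 20, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# does `window` match `pam_text` (over A,C,G,T,N,R)? string comparison only
pam_ok_str <- function(window, pam_text) {
  wc <- strsplit(window, "")[[1]]
  pc <- strsplit(pam_text, "")[[1]]
  if (any(!wc %in% BASES)) return(FALSE)
  all(mapply(function(w, p) {
    switch(p, N = TRUE, R = w %in% c("A", "G"), w == p)
  }, wc, pc))
}

# independent per-prefix site counts: substring-based window walk over both
# strands; returns a named vector (prefix 16-mer -> count of (site, PAM)
# tuples whose 20-mer starts with it)
naive_prefix_counts <- function(g, pam_texts) {
  counts <- new.env(parent = emptyenv())
  bump <- function(p) assign(p, (mget(p, counts, ifnotfound = 0)[[1]]) + 1, counts)
  for (s in g$seqs) {
    for (str_seq in c(s, revcomp_chr(s))) {
      n <- nchar(str_seq)
      for (pam in pam_texts) {
        L <- nchar(pam)
        if (n < 20 + L) next
        for (i in 1:(n - 20 - L + 1)) {
          w20 <- substring(str_seq, i, i + 19)
          if (grepl("N", w20, fixed = TRUE)) next
          if (pam_ok_str(substring(str_seq, i + 20, i + 19 + L), pam)) {
            bump(substring(w20, 1, 16))
          }
        }
      }
    }
  }
  unlist(as.list(counts))
}

hits_key <- function(h) {
  paste(h$chrom, h$strand, h$position, h$sequence, h$mismatch_count,
        h$mismatch_positions, h$pam, sprintf("%.6f", h$gc), sep = "|")
}

expect_same_hits <- function(a, b) {
  expect_identical(hits_key(a), hits_key(b))
}

# a random seed mask spec in one of the accepted forms
rand_seed_spec <- function() {
  switch(sample(3, 1),
         NULL,
         paste0("3prime:", sample(0:8, 1)),
         paste(sort(sample(0:19, sample(1:6, 1))), collapse = ","))
}

ALL_PAMS <- c("NGG", "NAG", "NNNNACA", "NNGRRT")

`%||%` <- function(a, b) if (is.null(a)) b else a
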