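# Synthetic genomes and planted off-target fixtures with machine-readable
# ground truth. The generator emulates background sequence as i.i.d. bases
# with a tunable GC fraction; planted sites are guide copies mutated at
# exactly the requested positions and followed by a concrete PAM instance.

#' Generate a synthetic genome
#'
#' Chromosomes of i.i.d. bases with P(G) = P(C) = `gc_bias/2` and
#' P(A) = P(T) = `(1-gc_bias)/2`. Reproducible for a fixed `rng_seed`.
#'
#' @param length chromosome length in nt (each chromosome; >= 30).
#' @param num_chroms number of chromosomes (named chr1, chr2, ...).
#' @param gc_bias target G+C fraction in (0, 1).
#' @param rng_seed integer seed; when given, `set.seed()` is called.
#' @return a [genome()].
#' @export
synth_genome <- function(length, num_chroms = 1L, gc_bias = 0.5, rng_seed = NULL) {
  if (length < 30L) {
    stop("input error: chromosome length must be >= 30 nt, got ", length)
  }
  if (num_chroms < 1L) stop("input error: need at least one chromosome")
  if (gc_bias <= 0 || gc_bias >= 1) {
    stop("input error: gc_bias must be in (0, 1)")
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  probs <- c((1 - gc_bias) / 2, gc_bias / 2, gc_bias / 2, (1 - gc_bias) / 2)
  seqs <- vapply(seq_len(num_chroms), function(i) {
    paste(sample(.BASES, length, replace = TRUE, prob = probs), collapse = "")
  }, character(1))
  genome(stats::setNames(seqs, paste0("chr", seq_len(num_chroms))))
}

# draw a concrete PAM instance consistent with the pattern
.random_pam_instance <- function(pat) {
  chars <- strsplit(pat$text, "", fixed = TRUE)[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "N") chars[i] <- sample(.BASES, 1L)
    else if (chars[i] == "R") chars[i] <- sample(c("A", "G"), 1L)
  }
  paste(chars, collapse = "")
}

.replace_substr <- function(s, start0, replacement) {
  # overwrite bases at 0-based start0 with replacement
  paste0(substring(s, 1L, start0),
         replacement,
         substring(s, start0 + nchar(replacement) + 1L, nchar(s)))
}

#' Plant off-target sites into a genome
#'
#' Each requested site overwrites a genomic window with the guide mutated at
#' exactly the given positions (mutated bases are drawn to differ from the
#' guide base) followed by a concrete PAM instance; on the reverse strand
#' the reverse complement is written so the protospacer reads as specified
#' on that strand. Ground truth lists each planted site in the hit-table
#' format of [find_offtargets()]. The background sequence may contain
#' additional chance hits, so ground truth is a subset of the full hit set;
#' use `verify_background = TRUE` (with a `max_mm`) to reject backgrounds
#' with chance hits and obtain exact-set semantics.
#'
#' @param g a [genome()].
#' @param guide the 20-mer guide the sites imitate.
#' @param sites data.frame with columns `chrom` (name or 0-based id),
#'   `position` (0-based forward-strand leftmost base of the 20-mer),
#'   `strand` (+/-), `mismatches` (comma-separated 0-based positions, or ""
#'   for an exact copy; at most 5 per site); optional `pam_instance`.
#' @param pam the PAM pattern (string or [parse_pam()] object).
#' @param rng_seed integer seed for mutation/PAM draws; when given,
#'   `set.seed()` is called.
#' @param verify_background if `TRUE`, error when the pre-planting genome
#'   already contains a hit for `guide` at `max_mm` mismatches.
#' @param max_mm mismatch budget used for `verify_background`.
#' @return list with `genome` (modified) and `truth` (hit data.frame).
#' @export
plant_offtargets <- function(g, guide, sites, pam, rng_seed = NULL,
                             verify_background = FALSE, max_mm = 5L) {
  stopifnot(inherits(g, "genome"), is.data.frame(sites))
  guide <- .check_guide(guide)
  pat <- if (inherits(pam, "pam_pattern")) pam else parse_pam(pam, pam_id = 0L)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (is.null(sites$mismatches)) sites$mismatches <- rep("", nrow(sites))
  if (verify_background) {
    bg <- brute_force_offtargets(g, guide, pat, max_mm = max_mm)
    if (nrow(bg) > 0L) {
      stop("input error: background genome already contains ", nrow(bg),
           " chance hit(s) for this guide at max_mm = ", max_mm)
    }
  }
  gchars <- strsplit(guide, "", fixed = TRUE)[[1L]]
  L <- pat$length
  seqs <- g$seqs
  ids <- chrom_ids(g)
  footprints <- list()
  truth <- vector("list", nrow(sites))

  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]
    ci <- if (is.numeric(chrom)) as.integer(chrom) + 1L else unname(ids[as.character(chrom)]) + 1L
    if (is.na(ci) || ci < 1L || ci > length(seqs)) {
      stop("input error: unknown chromosome '", chrom, "' in site ", i)
    }
    pos <- as.numeric(sites$position[i])
    strand <- as.character(sites$strand[i])
    mmspec <- sites$mismatches[i]
    mmpos <- if (is.na(mmspec) || !nzchar(trimws(mmspec))) integer(0) else
      sort(unique(as.integer(strsplit(as.character(mmspec), ",", fixed = TRUE)[[1L]])))
    if (any(mmpos < 0L | mmpos >= .GUIDE_LEN)) {
      stop("input error: mismatch positions must lie in 0..19 (site ", i, ")")
    }
    if (length(mmpos) > 5L) {
      stop("input error: at most 5 mismatches per planted site (site ", i, ")")
    }
    n <- nchar(seqs[[ci]])
    # footprint on the forward strand: protospacer plus PAM
    fp <- if (strand == "+") c(pos, pos + .GUIDE_LEN + L) else c(pos - L, pos + .GUIDE_LEN)
    if (fp[1] < 0 || fp[2] > n) {
      stop("input error: site ", i, " (position ", pos,
           ", strand ", strand, ") does not fit chromosome of ", n, " nt")
    }
    for (other in footprints) {
      if (other$chrom == ci && fp[1] < other$fp[2] && other$fp[1] < fp[2]) {
        stop("input error: planted sites overlap (site ", i, ")")
      }
    }
    footprints[[length(footprints) + 1L]] <- list(chrom = ci, fp = fp)

    mutated <- gchars
    for (p in mmpos) {
      mutated[p + 1L] <- sample(setdiff(.BASES, gchars[p + 1L]), 1L)
    }
    mutated <- paste(mutated, collapse = "")
    pam_inst <- if (!is.null(sites$pam_instance) && !is.na(sites$pam_instance[i]) &&
                    nzchar(sites$pam_instance[i])) {
      inst <- toupper(as.character(sites$pam_instance[i]))
      if (is.null(pam_match(inst, pat))) {
        stop("input error: pam_instance '", inst, "' does not match pattern ",
             pat$text, " (site ", i, ")")
      }
      inst
    } else {
      .random_pam_instance(pat)
    }
    if (strand == "+") {
      seqs[[ci]] <- .replace_substr(seqs[[ci]], pos, paste0(mutated, pam_inst))
    } else {
      seqs[[ci]] <- .replace_substr(seqs[[ci]], pos - L,
                                    reverse_complement(paste0(mutated, pam_inst)))
    }
    truth[[i]] <- data.frame(
      chrom_id = ci - 1L,
      strand01 = if (strand == "+") 0L else 1L,
      position = pos,
      sequence = mutated,
      capture = capture_to_code(
        strsplit(pam_inst, "", fixed = TRUE)[[1L]][pat$unspec_pos + 1L])
    )
  }
  tr <- do.call(rbind, truth)
  truth_hits <- if (is.null(tr) || nrow(tr) == 0L) .empty_hits() else .make_hits(
    chrom_id = tr$chrom_id, strand01 = tr$strand01, position = tr$position,
    sequences = tr$sequence,
    pam_instance = .codes_to_pam_instances(tr$capture, pat),
    guide = guide, chrom_names = names(seqs)
  )
  list(genome = genome(seqs), truth = truth_hits)
}

#' Write a fixture to disk as FASTA plus ground-truth TSV
#'
#' @param g a [genome()].
#' @param truth hit data.frame (e.g. from [plant_offtargets()]).
#' @param dir output directory (created if needed).
#' @param name basename for the two files (`<name>.fa`, `<name>.truth.tsv`).
#' @return named character vector of the two paths, invisibly.
#' @export
write_fixture <- function(g, truth, dir, name = "fixture") {
  stopifnot(inherits(g, "genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(name, ".fa"))
  lines <- character(0)
  for (i in seq_along(g$seqs)) {
    lines <- c(lines, paste0(">", names(g$seqs)[i]), g$seqs[[i]])
  }
  writeLines(lines, fa)
  tsv <- file.path(dir, paste0(name, ".truth.tsv"))
  utils::write.table(truth, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, truth = tsv))
}
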