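# Optional annotation stage: tag hits with overlapping gene/transcript
# features from a GTF or BED file. Intervals are kept per chromosome,
# 0-based half-open internally; overlap requires >= 1 bp and ignores
# feature strand.

.FEATURE_CLASS_MAP <- c(
  five_prime_utr = "5UTR",
  CDS = "CDS",
  three_prime_utr = "3UTR",
  exon = "exon"
)

# line-numbered structural validation before handing the file to the parser
.prevalidate_annotation <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || startsWith(ln, "#") ||
        (format == "bed" && (startsWith(ln, "track") || startsWith(ln, "browser")))) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (format == "gtf") {
      if (length(f) < 9L) {
        stop("format error: line ", i, " of ", path,
             ": GTF needs 9 tab-separated fields, found ", length(f))
      }
      if (is.na(suppressWarnings(as.numeric(f[4]))) ||
          is.na(suppressWarnings(as.numeric(f[5])))) {
        stop("format error: line ", i, " of ", path,
             ": non-numeric GTF coordinates")
      }
    } else {
      if (length(f) < 3L) {
        stop("format error: line ", i, " of ", path,
             ": BED needs at least 3 tab-separated fields, found ", length(f))
      }
      if (is.na(suppressWarnings(as.numeric(f[2]))) ||
          is.na(suppressWarnings(as.numeric(f[3])))) {
        stop("format error: line ", i, " of ", path,
             ": non-numeric BED coordinates")
      }
    }
  }
  invisible(TRUE)
}

#' Load a feature index from a GTF or BED annotation file
#'
#' GTF coordinates (1-based inclusive) and BED coordinates (0-based
#' half-open) are both converted to 0-based half-open internally. Feature
#' classes are derived from the GTF feature column (`five_prime_utr` ->
#' `5UTR`, `CDS` -> `CDS`, `three_prime_utr` -> `3UTR`, `exon` -> `exon`);
#' rows whose feature column does not map take class `lincRNA` when their
#' transcript (or gene) biotype is lincRNA, and `other` otherwise. BED rows
#' get class `other` with the name column as gene id.
#'
#' @param path annotation file; format inferred from the extension
#'   (`.gtf`/`.gff` vs `.bed`) unless given.
#' @param format `"gtf"`, `"bed"`, or `NULL` to infer.
#' @return object of class `feature_index`: per-chromosome sorted interval
#'   lists with gene/transcript metadata.
#' @export
load_annotation <- function(path, format = NULL) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed" else "gtf"
  }
  format <- match.arg(format, c("gtf", "bed"))
  .prevalidate_annotation(path, format)
  n_content <- sum(vapply(readLines(path, warn = FALSE), function(ln) {
    nzchar(trimws(ln)) && !startsWith(ln, "#") &&
      !startsWith(ln, "track") && !startsWith(ln, "browser")
  }, logical(1)))
  if (n_content == 0L) {
    df <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                     gene_id = character(0), transcript_id = character(0),
                     gene_name = character(0), class = character(0))
    return(structure(list(features = df, by_chrom = list()),
                     class = "feature_index"))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) stop("format error: cannot parse ", format, " file ",
                             path, ": ", conditionMessage(e))
  )
  mc <- S4Vectors::mcols(gr)
  getcol <- function(nm) {
    if (nm %in% colnames(mc)) as.character(mc[[nm]]) else rep(NA_character_, length(gr))
  }
  if (format == "gtf") {
    type <- getcol("type")
    cls <- unname(.FEATURE_CLASS_MAP[type])
    biotype <- getcol("transcript_biotype")
    gbio <- getcol("gene_biotype")
    biotype[is.na(biotype)] <- gbio[is.na(biotype)]
    cls[is.na(cls)] <- ifelse(!is.na(biotype[is.na(cls)]) &
                                biotype[is.na(cls)] == "lincRNA",
                              "lincRNA", "other")
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,          # to 0-based half-open
      end = as.numeric(GenomicRanges::end(gr)),
      gene_id = getcol("gene_id"),
      transcript_id = getcol("transcript_id"),
      gene_name = getcol("gene_name"),
      class = cls
    )
  } else {
    nm <- getcol("name")
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,
      end = as.numeric(GenomicRanges::end(gr)),
      gene_id = nm,
      transcript_id = NA_character_,
      gene_name = nm,
      class = "other"
    )
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  by_chrom <- lapply(split(seq_len(nrow(df)), df$chrom), function(ix) {
    list(rows = ix,
         ranges = IRanges::IRanges(start = df$start[ix] + 1L, end = df$end[ix]))
  })
  structure(list(features = df, by_chrom = by_chrom), class = "feature_index")
}

#' @export
print.feature_index <- function(x, ...) {
  cat("<feature_index> ", nrow(x$features), " feature(s) on ",
      length(x$by_chrom), " chromosome(s)\n", sep = "")
  if (nrow(x$features)) print(table(x$features$class))
  invisible(x)
}

#' Features overlapping a single hit
#'
#' All features overlapping the hit's 20-nt window `[position, position+20)`
#' by at least 1 bp, regardless of feature strand. A chromosome absent from
#' the annotation yields an empty result (annotation may cover a subset of
#' the genome).
#'
#' @param hit one row of a hit data.frame (needs `chrom` and `position`).
#' @param idx a [load_annotation()] index.
#' @return data.frame of overlapping features (0 rows = intergenic).
#' @export
annotate_hit <- function(hit, idx) {
  stopifnot(inherits(idx, "feature_index"))
  bc <- idx$by_chrom[[as.character(hit$chrom)]]
  if (is.null(bc)) return(idx$features[integer(0), , drop = FALSE])
  q <- IRanges::IRanges(start = as.numeric(hit$position) + 1L,
                        width = .GUIDE_LEN)
  ov <- IRanges::findOverlaps(q, bc$ranges, minoverlap = 1L)
  rows <- bc$rows[S4Vectors::subjectHits(ov)]
  idx$features[rows, , drop = FALSE]
}

#' Annotate a hit table with overlapping features
#'
#' Adds `gene_ids`, `transcript_ids`, and `feature_classes` columns
#' (comma-joined unique labels per hit; empty string = intergenic).
#'
#' @param hits hit data.frame from [find_offtargets()].
#' @param idx a [load_annotation()] index.
#' @return the hit table with three annotation columns appended.
#' @export
annotate_hits <- function(hits, idx) {
  stopifnot(inherits(idx, "feature_index"))
  join <- function(v) paste(unique(v[!is.na(v) & nzchar(v)]), collapse = ",")
  ann <- lapply(seq_len(nrow(hits)), function(i) {
    f <- annotate_hit(hits[i, ], idx)
    c(gene_ids = join(f$gene_id),
      transcript_ids = join(f$transcript_id),
      feature_classes = join(f$class))
  })
  hits$gene_ids <- vapply(ann, `[[`, character(1), "gene_ids")
  hits$transcript_ids <- vapply(ann, `[[`, character(1), "transcript_ids")
  hits$feature_classes <- vapply(ann, `[[`, character(1), "feature_classes")
  hits
}
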