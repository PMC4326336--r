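# PAM (protospacer adjacent motif) patterns: parsing, matching, capture of
# unspecified bases, and dereferencing. Patterns are strings over
# {A,C,G,T,N,R}; N matches any base, R matches a purine (A or G). Each
# unspecified position (N or R) has its concrete genomic base captured as a
# 2-bit digit so a site's fully dereferenced PAM can be reported later.

#' Parse a PAM pattern string
#'
#' @param text pattern over {A,C,G,T,N,R}, e.g. `"NGG"` or `"NNGRRT"`.
#' @param pam_id integer id 0..7 used inside an index; `NA` until registered.
#' @return object of class `pam_pattern` with fields `text`, `length`,
#'   `digits` (fixed-base digits, NA at unspecified positions),
#'   `unspec_pos` (0-based positions whose concrete base is stored),
#'   `is_r` (logical per position: purine-restricted), `pam_id`.
#' @export
parse_pam <- function(text, pam_id = NA_integer_) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- toupper(text)
  if (!nzchar(text)) stop("pattern error: empty PAM pattern")
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N", "R"))
  if (length(bad) > 0L) {
    stop("pattern error: illegal symbol(s) ", paste(bad, collapse = ", "),
         " in PAM pattern '", text, "' (allowed: A,C,G,T,N,R)")
  }
  fixed <- chars %in% c("A", "C", "G", "T")
  digits <- rep(NA_real_, length(chars))
  digits[fixed] <- .DIGIT_LUT[utf8ToInt(paste(chars[fixed], collapse = ""))]
  structure(list(
    text = text,
    length = length(chars),
    digits = digits,
    unspec_pos = which(!fixed) - 1L,
    is_r = chars == "R",
    pam_id = as.integer(pam_id)
  ), class = "pam_pattern")
}

#' @export
print.pam_pattern <- function(x, ...) {
  cat("<pam_pattern> ", x$text,
      if (!is.na(x$pam_id)) paste0(" (id ", x$pam_id, ")"),
      ", ", length(x$unspec_pos), " unspecified position(s)\n", sep = "")
  invisible(x)
}

#' Built-in PAM patterns
#'
#' The four patterns used by common Cas nucleases, registered with stable ids:
#' NGG (0), NAG (1), NNNNACA (2), NNGRRT (3). User-supplied patterns in an
#' index take ids from 4 upward.
#'
#' @return named list of `pam_pattern` objects.
#' @export
builtin_pams <- function() {
  texts <- c("NGG", "NAG", "NNNNACA", "NNGRRT")
  stats::setNames(
    lapply(seq_along(texts), function(i) parse_pam(texts[i], pam_id = i - 1L)),
    texts
  )
}

# Build the pam table for an index from pattern strings (or pam_pattern
# objects): built-ins keep their reserved ids 0-3, other patterns take the
# next free id; at most 8 patterns fit the 3-bit id field.
make_pam_table <- function(pams) {
  if (length(pams) == 0L) stop("pattern error: at least one PAM required")
  texts <- unname(vapply(pams, function(p) {
    if (inherits(p, "pam_pattern")) p$text else toupper(as.character(p))
  }, character(1)))
  if (anyDuplicated(texts)) stop("pattern error: duplicate PAM patterns")
  builtin <- vapply(builtin_pams(), `[[`, character(1), "text")
  ids <- match(texts, builtin) - 1L           # reserved ids 0..3
  free <- setdiff(0:7, ids)
  free <- free[free >= 4L]                    # user patterns start at 4
  need <- sum(is.na(ids))
  if (need > length(free)) {
    stop("pattern error: at most 8 PAM patterns per index (3-bit id)")
  }
  ids[is.na(ids)] <- free[seq_len(need)]
  tab <- lapply(seq_along(texts), function(i) parse_pam(texts[i], pam_id = ids[i]))
  tab[order(ids)]
}

#' Match a genomic window against a PAM pattern
#'
#' A window matches iff every fixed pattern position carries exactly that
#' base, every N position carries one of A,C,G,T, and every R position
#' carries A or G. Windows containing `N` in the genome never match.
#'
#' @param window nucleotide string, same length as the pattern.
#' @param pattern a [parse_pam()] object.
#' @return on match, a `pam_capture`: list with `pam_id` and `bases`
#'   (character vector of the concrete bases at the pattern's unspecified
#'   positions, in pattern order); `NULL` on no-match.
#' @export
pam_match <- function(window, pattern) {
  stopifnot(inherits(pattern, "pam_pattern"))
  if (nchar(window) != pattern$length) {
    stop("contract error: window length ", nchar(window),
         " != pattern length ", pattern$length)
  }
  d <- seq_to_digits(toupper(window))
  if (anyNA(d)) return(NULL)                       # genomic N never matches
  fixed <- !is.na(pattern$digits)
  if (any(d[fixed] != pattern$digits[fixed])) return(NULL)
  if (any(pattern$is_r & !(d %in% c(0, 2)))) return(NULL)
  structure(list(
    pam_id = pattern$pam_id,
    bases = .BASES[d[pattern$unspec_pos + 1L] + 1L]
  ), class = "pam_capture")
}

#' Reconstruct the concrete PAM instance from a capture
#'
#' Fills the pattern's unspecified positions with the captured bases,
#' yielding the fully dereferenced PAM as it occurs in the genome.
#'
#' @param capture a `pam_capture` (or bare character vector of bases).
#' @param pattern the [parse_pam()] pattern the capture belongs to.
#' @return the dereferenced PAM string.
#' @export
dereference_pam <- function(capture, pattern) {
  stopifnot(inherits(pattern, "pam_pattern"))
  bases <- if (inherits(capture, "pam_capture")) capture$bases else toupper(capture)
  if (length(bases) != length(pattern$unspec_pos)) {
    stop("contract error: capture has ", length(bases), " base(s), pattern '",
         pattern$text, "' has ", length(pattern$unspec_pos), " unspecified position(s)")
  }
  if (any(!bases %in% .BASES)) stop("contract error: captured bases must be A/C/G/T")
  r_pos <- pattern$is_r[pattern$unspec_pos + 1L]
  if (any(r_pos & !bases %in% c("A", "G"))) {
    stop("contract error: capture inconsistent with R (purine) position")
  }
  chars <- strsplit(pattern$text, "", fixed = TRUE)[[1L]]
  chars[pattern$unspec_pos + 1L] <- bases
  paste(chars, collapse = "")
}

# capture code: 2 bits per unspecified base, pattern order, low bits first
capture_to_code <- function(bases) {
  if (length(bases) == 0L) return(0)
  d <- match(bases, .BASES) - 1
  sum(d * 4^(seq_along(d) - 1))
}

code_to_capture <- function(code, n_unspec) {
  if (n_unspec == 0L) return(character(0))
  d <- numeric(n_unspec)
  v <- code
  for (i in seq_len(n_unspec)) {
    d[i] <- v %% 4
    v <- v %/% 4
  }
  .BASES[d + 1L]
}

# vectorized dereference for a vector of capture codes under one pattern
.codes_to_pam_instances <- function(codes, pattern) {
  n <- length(pattern$unspec_pos)
  chars <- strsplit(pattern$text, "", fixed = TRUE)[[1L]]
  if (n == 0L || length(codes) == 0L) {
    return(rep(pattern$text, length(codes)))
  }
  cols <- rep(list(NULL), pattern$length)
  for (j in seq_len(pattern$length)) cols[[j]] <- rep(chars[j], length(codes))
  v <- codes
  for (i in seq_len(n)) {
    cols[[pattern$unspec_pos[i] + 1L]] <- .BASES[(v %% 4) + 1L]
    v <- v %/% 4
  }
  do.call(paste0, cols)
}
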