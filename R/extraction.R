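#' Compile a framing-anchor search pattern
#'
#' A selection campaign's region of interest is located by two constant
#' framing nucleotide sequences (anchors) that flank the randomized insert,
#' equivalent to the regular expression `LEFT(.+?)RIGHT` with non-greedy,
#' first-match semantics. Anchors must be plain A/C/G/T and are stored
#' uppercase.
#'
#' @param left_anchor,right_anchor Anchor nucleotide sequences (A/C/G/T).
#' @param label Optional label used when persisting the pattern.
#' @return An object of class `search_pattern`.
#' @examples
#' compile_pattern("GATTCCAGG", "TACGACCCG")
#' @export
compile_pattern <- function(left_anchor, right_anchor, label = NULL) {
  validate_anchor(left_anchor, "left_anchor")
  validate_anchor(right_anchor, "right_anchor")
  structure(
    list(left_anchor = toupper(left_anchor),
         right_anchor = toupper(right_anchor),
         label = label),
    class = "search_pattern"
  )
}

validate_anchor <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(what, " must be a non-empty nucleotide string", call. = FALSE)
  }
  up <- toupper(x)
  chars <- strsplit(up, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T"))
  if (length(bad)) {
    stop(what, " contains invalid character(s): ",
         paste(sQuote(bad), collapse = ", "),
         " (anchors must be A/C/G/T only)", call. = FALSE)
  }
  invisible(up)
}

#' @export
print.search_pattern <- function(x, ...) {
  cat("<search_pattern> ", x$left_anchor, "(.+?)", x$right_anchor,
      if (!is.null(x$label)) paste0("  [", x$label, "]"), "\n", sep = "")
  invisible(x)
}

#' Extract the insert between the framing anchors
#'
#' For each read, finds the first occurrence of the left anchor and the
#' nearest occurrence of the right anchor starting after it, and returns the
#' intervening insert (non-greedy first-match semantics: each read yields at
#' most one insert). Anchors may be directly adjacent, giving an empty
#' insert. Matching is exact; a point mutation in an anchor makes the read a
#' no-match (see [enumerate_anchor_variants()]).
#'
#' @param sequence Character vector of read sequences (uppercase A/C/G/T plus
#'   any other symbols, which never match an anchor).
#' @param pattern A `search_pattern`.
#' @return Character vector of inserts, `NA` where the read has no match.
#' @export
extract_insert <- function(sequence, pattern) {
  stopifnot(inherits(pattern, "search_pattern"))
  if (length(sequence) == 0L) return(character())
  left <- pattern$left_anchor
  right <- pattern$right_anchor
  out <- rep(NA_character_, length(sequence))

  li <- regexpr(left, sequence, fixed = TRUE)
  hit <- which(li > 0L)
  if (length(hit)) {
    # right-anchor search starts immediately after the left anchor ends,
    # so overlapping anchors can never match
    tails <- substring(sequence[hit], li[hit] + nchar(left))
    ri <- regexpr(right, tails, fixed = TRUE)
    ok <- ri > 0L
    out[hit[ok]] <- substr(tails[ok], 1L, ri[ok] - 1L)
  }
  out
}

#' Extract and frame-check a whole selection round
#'
#' Runs [extract_insert()] over every read of a round and partitions the
#' reads three ways: inserts whose length is divisible by 3 (translatable),
#' frame failures (a match whose length indicates a frame-breaking indel),
#' and misses (no anchor match). The partition is exhaustive:
#' `length(inserts) + length(frame_failures) + miss_count == total_reads`.
#'
#' @param records A data.frame from [read_fastq()], or a path to a FASTQ
#'   file.
#' @param pattern A `search_pattern`; a single pattern is used for the whole
#'   round.
#' @return An object of class `extraction_result`: a list with `inserts`,
#'   `frame_failures` (both character vectors of DNA), `miss_count`,
#'   `total_reads`, and `misses` (the unmatched read sequences, kept so that
#'   anchor-variant re-search can revisit them).
#' @export
extract_round <- function(records, pattern) {
  if (is.character(records)) records <- read_fastq(records)
  stopifnot(is.data.frame(records), "sequence" %in% names(records))
  ins <- extract_insert(records$sequence, pattern)
  missed <- is.na(ins)
  matched <- ins[!missed]
  in_frame <- nchar(matched) %% 3L == 0L
  structure(
    list(inserts = matched[in_frame],
         frame_failures = matched[!in_frame],
         miss_count = sum(missed),
         total_reads = nrow(records),
         misses = records$sequence[missed]),
    class = "extraction_result"
  )
}

#' @export
print.extraction_result <- function(x, ...) {
  cat("<extraction_result> ", x$total_reads, " reads: ",
      length(x$inserts), " in-frame inserts, ",
      length(x$frame_failures), " frame failures (",
      sprintf("%.2f%%", 100 * length(x$frame_failures) /
                max(1L, x$total_reads)),
      "), ", x$miss_count, " without anchor match\n", sep = "")
  invisible(x)
}

#' Enumerate all single-point-mutation anchor variants
#'
#' Reads carrying a point mutation inside a framing region are missed by
#' exact anchor matching. This generates every pattern obtained by
#' substituting exactly one position of exactly one anchor with one of the
#' three alternative bases — `3 * (nchar(left) + nchar(right))` patterns, the
#' original excluded — so missed reads can be re-searched.
#'
#' @param pattern A `search_pattern`.
#' @return List of `search_pattern` objects, each labelled with the mutated
#'   side, position and base (e.g. `"left:3:G"`).
#' @export
enumerate_anchor_variants <- function(pattern) {
  stopifnot(inherits(pattern, "search_pattern"))
  bases <- c("A", "C", "G", "T")
  variants <- list()
  for (side in c("left", "right")) {
    anchor <- if (side == "left") pattern$left_anchor else pattern$right_anchor
    for (pos in seq_len(nchar(anchor))) {
      orig <- substr(anchor, pos, pos)
      for (b in setdiff(bases, orig)) {
        mut <- anchor
        substr(mut, pos, pos) <- b
        variants[[length(variants) + 1L]] <- if (side == "left") {
          compile_pattern(mut, pattern$right_anchor,
                          label = paste("left", pos, b, sep = ":"))
        } else {
          compile_pattern(pattern$left_anchor, mut,
                          label = paste("right", pos, b, sep = ":"))
        }
      }
    }
  }
  variants
}
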