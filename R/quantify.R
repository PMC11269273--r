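#' Tally (dna, peptide) pairs at the DNA level
#'
#' Counts exact DNA strings: synonymous inserts (different codons, same
#' peptide) remain distinct rows, so several rows may share a peptide with
#' different frequencies.
#'
#' @param pairs data.frame with columns `dna`, `peptide` (from
#'   [translate_round()]).
#' @return data.frame with columns `dna`, `peptide`, `raw_count`, one row per
#'   distinct DNA string, in order of first appearance.
#' @export
tally <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("dna", "peptide") %in% names(pairs)))
  if (nrow(pairs) == 0L) {
    return(data.frame(dna = character(), peptide = character(),
                      raw_count = integer(), stringsAsFactors = FALSE))
  }
  u <- unique(pairs$dna)
  idx <- match(pairs$dna, u)
  data.frame(dna = u,
             peptide = pairs$peptide[match(u, pairs$dna)],
             raw_count = tabulate(idx, nbins = length(u)),
             stringsAsFactors = FALSE)
}

#' Add parts-per-million frequencies
#'
#' ppm = raw_count / total * 1e6. The denominator is the total number of
#' successfully extracted, frame-valid inserts of the round — exactly the
#' sequences that appear as rows — so the ppm column of every round sums to
#' one million and rounds of different sequencing depth are directly
#' comparable.
#'
#' @param counts data.frame from [tally()].
#' @param total Total counted inserts; must equal `sum(counts$raw_count)`.
#' @return `counts` with a numeric `ppm` column appended.
#' @export
normalize_ppm <- function(counts, total = sum(counts$raw_count)) {
  stopifnot(is.data.frame(counts), "raw_count" %in% names(counts))
  if (total < 1L) stop("no extractable reads in round", call. = FALSE)
  if (total != sum(counts$raw_count)) {
    stop("total (", total, ") does not equal the sum of raw counts (",
         sum(counts$raw_count), ")", call. = FALSE)
  }
  counts$ppm <- counts$raw_count / total * 1e6
  counts
}

#' Build the per-round count table
#'
#' Convenience constructor running transform/translate, DNA-level tallying
#' and ppm normalization on an extraction result, and attaching the
#' provenance fields that are persisted with the round (selection name, user,
#' processing date).
#'
#' @param extraction An `extraction_result` from [extract_round()].
#' @param mode One of [TRANSLATION_MODES].
#' @param selection_name Name of the selection round (e.g. `"target3"`).
#' @param user Analyst name recorded with the round.
#' @param drop_stop Passed to [translate_round()].
#' @param processed_date Date recorded with the round (ISO-8601).
#' @return An object of class `count_table`: a list with `selection_name`,
#'   `user`, `rows` (data.frame `dna`, `peptide`, `raw_count`, `ppm`),
#'   `total_counted`, `frame_fail_count`, `miss_count`, `processed_date`.
#' @export
count_round <- function(extraction, mode = "forward", selection_name,
                        user = Sys.getenv("USER", "unknown"),
                        drop_stop = FALSE,
                        processed_date = format(Sys.Date())) {
  stopifnot(inherits(extraction, "extraction_result"))
  pairs <- translate_round(extraction$inserts, mode, drop_stop = drop_stop)
  rows <- normalize_ppm(tally(pairs))
  count_table(rows, selection_name = selection_name, user = user,
              frame_fail_count = length(extraction$frame_failures),
              miss_count = extraction$miss_count,
              processed_date = processed_date)
}

#' Construct a count_table from normalized rows
#'
#' @param rows data.frame with columns `dna`, `peptide`, `raw_count`, `ppm`.
#' @param selection_name,user,processed_date Provenance fields.
#' @param frame_fail_count,miss_count Read-accounting context from
#'   extraction.
#' @return A `count_table` object.
#' @export
count_table <- function(rows, selection_name, user = "unknown",
                        frame_fail_count = 0L, miss_count = 0L,
                        processed_date = format(Sys.Date())) {
  stopifnot(is.data.frame(rows),
            all(c("dna", "peptide", "raw_count", "ppm") %in% names(rows)))
  if (!is.character(selection_name) || !nzchar(selection_name)) {
    stop("selection_name must be a non-empty string", call. = FALSE)
  }
  total <- sum(rows$raw_count)
  structure(
    list(selection_name = selection_name,
         user = user,
         rows = rows[, c("dna", "peptide", "raw_count", "ppm")],
         total_counted = as.integer(total),
         frame_fail_count = as.integer(frame_fail_count),
         miss_count = as.integer(miss_count),
         processed_date = processed_date),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat("<count_table> '", x$selection_name, "' (", x$user, ", ",
      x$processed_date, "): ", nrow(x$rows), " distinct sequences / ",
      x$total_counted, " inserts; ", x$frame_fail_count, " frame failures, ",
      x$miss_count, " unmatched reads\n", sep = "")
  if (nrow(x$rows)) {
    top <- utils::head(x$rows[order(-x$rows$raw_count), ], 5L)
    print(top, row.names = FALSE)
  }
  invisible(x)
}

#' Look up ppm frequencies of sequences in a count table
#'
#' @param table A `count_table` (or `NULL`).
#' @param dna Character vector of DNA sequences.
#' @return Numeric ppm vector; 0 for sequences absent from the table, `NA`
#'   if `table` is `NULL`.
#' @export
ppm_of <- function(table, dna) {
  if (is.null(table)) return(rep(NA_real_, length(dna)))
  stopifnot(inherits(table, "count_table"))
  i <- match(dna, table$rows$dna)
  ifelse(is.na(i), 0, table$rows$ppm[i])
}
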