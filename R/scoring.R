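#' Enrichment score of a sequence
#'
#' Ratio of a sequence's normalized frequency in the final target selection
#' round to its frequency in the naive library:
#' `target3_ppm / max(library_ppm, floor)`. A sequence never observed in the
#' library has a zero denominator; the configurable ppm floor (default 0.5,
#' half the smallest observable frequency at the 1e6 scale) keeps such
#' "never seen in control" sequences finite and ranked strongest rather than
#' dropped.
#'
#' @param target3_ppm,library_ppm Numeric ppm frequencies (vectorized).
#' @param floor Positive ppm floor applied to the denominator.
#' @return Numeric score vector.
#' @examples
#' enrichment_score(200, 4)   # 50
#' enrichment_score(200, 0)   # 400 with the default 0.5 floor
#' @export
enrichment_score <- function(target3_ppm, library_ppm, floor = 0.5) {
  check_floor(floor)
  target3_ppm / pmax(library_ppm, floor)
}

#' Empty score of a sequence
#'
#' Ratio of a sequence's normalized frequency in the final target selection
#' round to its frequency in the final empty-selection round (a selection run
#' entirely without target): `target3_ppm / max(empty3_ppm, floor)`. The
#' empty score is the primary ranking key — it demotes target-independent
#' sequences (plastic binders, amplification-advantaged phages) that enrich
#' equally well without a target.
#'
#' @param target3_ppm,empty3_ppm Numeric ppm frequencies (vectorized).
#' @param floor Positive ppm floor applied to the denominator.
#' @return Numeric score vector.
#' @examples
#' empty_score(200, 10)  # 20
#' empty_score(50, 50)   # 1
#' @export
empty_score <- function(target3_ppm, empty3_ppm, floor = 0.5) {
  check_floor(floor)
  target3_ppm / pmax(empty3_ppm, floor)
}

check_floor <- function(floor) {
  if (!is.numeric(floor) || length(floor) != 1L || is.na(floor) ||
      floor <= 0) {
    stop("floor must be a single positive ppm value", call. = FALSE)
  }
  invisible(floor)
}

#' Assemble the labeled rounds of one selection campaign
#'
#' @param targets List of up to three target-round `count_table`s, in round
#'   order (round 1 first).
#' @param library Optional `count_table` of the naive library sequenced
#'   before selection (required for the enrichment score).
#' @param empties Optional list of empty-selection `count_table`s, in round
#'   order (the final one is required for the empty score).
#' @param direct_controls Optional list of direct-control `count_table`s
#'   (target selection continued one round without target); reported as a
#'   specificity ratio column.
#' @return An object of class `round_set`.
#' @export
round_set <- function(targets, library = NULL, empties = NULL,
                      direct_controls = NULL) {
  as_table_list <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (inherits(x, "count_table")) x <- list(x)
    ok <- vapply(x, inherits, logical(1L), "count_table")
    if (!length(x) || !all(ok)) {
      stop(what, " must be a count_table or a list of count_tables",
           call. = FALSE)
    }
    x
  }
  targets <- as_table_list(targets, "targets")
  if (is.null(targets)) stop("at least one target round is required",
                             call. = FALSE)
  if (length(targets) > 3L) {
    stop("at most three target rounds are supported", call. = FALSE)
  }
  if (!is.null(library)) stopifnot(inherits(library, "count_table"))
  structure(
    list(targets = targets,
         library = library,
         empties = as_table_list(empties, "empties"),
         direct_controls = as_table_list(direct_controls, "direct_controls")),
    class = "round_set"
  )
}

#' @export
print.round_set <- function(x, ...) {
  nm <- function(l) if (is.null(l)) "none" else
    paste(vapply(l, `[[`, "", "selection_name"), collapse = ", ")
  cat("<round_set>\n",
      "  targets:         ", nm(x$targets), "\n",
      "  library:         ", if (is.null(x$library)) "none" else
        x$library$selection_name, "\n",
      "  empties:         ", nm(x$empties), "\n",
      "  direct controls: ", nm(x$direct_controls), "\n", sep = "")
  invisible(x)
}

#' Score and rank the sequences of a campaign
#'
#' Produces one record per DNA sequence present in the final target round,
#' with its per-round ppm frequencies, enrichment score and empty score, and
#' orders the table by empty score (descending). Ties are broken by
#' enrichment score, then final-target ppm, then lexicographic DNA, making
#' the ranking a deterministic total order. All calculations use normalized
#' ppm values so rounds of different depth compare without bias. Optional
#' filters (applied after scoring) drop low-frequency sequences, weak
#' enrichers, and sequences that accumulate in the direct control.
#'
#' @param rounds A `round_set`.
#' @param floor Positive ppm floor for zero denominators (see
#'   [enrichment_score()]).
#' @param min_target_ppm Keep sequences with final-target ppm >= this.
#' @param min_enrichment Keep sequences with enrichment score >= this.
#' @param max_direct_ratio Keep sequences whose direct-control ratio
#'   `direct_ppm / max(target_ppm, floor)` is <= this; default `Inf` (the
#'   ratio is reported but never filtered on unless requested).
#' @param scores Which scores to compute; the corresponding control rounds
#'   must be present. Ordering uses the empty score when computed, otherwise
#'   the enrichment score.
#' @return data.frame of class `evaluation`: columns `rank`, `dna`,
#'   `peptide`, `target<i>_ppm` for each provided target round,
#'   `library_ppm`, `empty_ppm`, `direct_ppm`, `direct_ratio` (when controls
#'   are present), `enrichment_score`, `empty_score`, sorted best-first.
#' @export
evaluate <- function(rounds, floor = 0.5, min_target_ppm = 0,
                     min_enrichment = 0, max_direct_ratio = Inf,
                     scores = c("enrichment", "empty")) {
  stopifnot(inherits(rounds, "round_set"))
  check_floor(floor)
  scores <- match.arg(scores, c("enrichment", "empty"), several.ok = TRUE)
  want_enrich <- "enrichment" %in% scores
  want_empty <- "empty" %in% scores
  if (want_enrich && is.null(rounds$library)) {
    stop("enrichment score requested but no library round provided",
         call. = FALSE)
  }
  if (want_empty && is.null(rounds$empties)) {
    stop("empty score requested but no empty-selection round provided",
         call. = FALSE)
  }

  final <- rounds$targets[[length(rounds$targets)]]
  dna <- final$rows$dna
  out <- data.frame(dna = dna, peptide = final$rows$peptide,
                    stringsAsFactors = FALSE)
  for (i in seq_along(rounds$targets)) {
    out[[paste0("target", i, "_ppm")]] <- ppm_of(rounds$targets[[i]], dna)
  }
  target_ppm <- ppm_of(final, dna)
  out$library_ppm <- ppm_of(rounds$library, dna)
  out$empty_ppm <- if (is.null(rounds$empties)) NA_real_ else
    ppm_of(rounds$empties[[length(rounds$empties)]], dna)
  if (!is.null(rounds$direct_controls)) {
    dc <- rounds$direct_controls[[length(rounds$direct_controls)]]
    out$direct_ppm <- ppm_of(dc, dna)
    out$direct_ratio <- out$direct_ppm / pmax(target_ppm, floor)
  }
  out$enrichment_score <- if (want_enrich) {
    enrichment_score(target_ppm, out$library_ppm, floor)
  } else NA_real_
  out$empty_score <- if (want_empty) {
    empty_score(target_ppm, out$empty_ppm, floor)
  } else NA_real_

  # filters are applied after scoring, never silently during it
  keep <- target_ppm >= min_target_ppm
  if (want_enrich) keep <- keep & out$enrichment_score >= min_enrichment
  if (!is.null(out$direct_ratio) && is.finite(max_direct_ratio)) {
    keep <- keep & out$direct_ratio <= max_direct_ratio
  }
  out <- out[keep, , drop = FALSE]
  target_ppm <- target_ppm[keep]

  primary <- if (want_empty) out$empty_score else out$enrichment_score
  secondary <- if (want_enrich) out$enrichment_score else target_ppm
  ord <- order(-primary, -secondary, -target_ppm, out$dna, method = "radix")
  out <- out[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("evaluation", "data.frame")
  out
}

#' Export an evaluation table as TSV/CSV
#'
#' Writes the ranked table with its fixed, documented column order.
#'
#' @param records An `evaluation` data.frame from [evaluate()].
#' @param path Output path.
#' @param sep Field separator, `"\t"` (default) or `","`.
#' @return Invisibly, the path written.
#' @export
write_evaluation <- function(records, path, sep = "\t") {
  stopifnot(is.data.frame(records))
  utils::write.table(records, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
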