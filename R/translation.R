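#' @importFrom Biostrings GENETIC_CODE
NULL

#' The four insert transformation modes
#'
#' Before translation an extracted insert can be used as read (`forward`),
#' base-complemented in place (`forward_complement`), character-reversed
#' (`reverse`), or reverse-complemented (`reverse_complement`) — the choice
#' depends on how the randomized region is oriented relative to the
#' sequencing primer.
#'
#' @format Character vector of the four mode names.
#' @export
TRANSLATION_MODES <- c("forward", "forward_complement",
                       "reverse", "reverse_complement")

check_mode <- function(mode) {
  if (!is.character(mode) || length(mode) != 1L ||
      !mode %in% TRANSLATION_MODES) {
    stop("mode must be one of: ", paste(TRANSLATION_MODES, collapse = ", "),
         call. = FALSE)
  }
  mode
}

dna_complement <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

dna_reverse <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1L),
         USE.NAMES = FALSE)
}

#' Transform an insert according to the translation mode
#'
#' @param insert Character vector of frame-valid DNA inserts (length
#'   divisible by 3).
#' @param mode One of [TRANSLATION_MODES].
#' @return Character vector of transformed inserts, same lengths.
#' @examples
#' transform_insert("AAATTTGGG", "reverse_complement")  # "CCCAAATTT"
#' @export
transform_insert <- function(insert, mode) {
  check_mode(mode)
  if (length(insert) == 0L) return(character())
  if (any(nchar(insert) %% 3L != 0L)) {
    stop("insert length not divisible by 3; frame failures must be filtered ",
         "before transformation", call. = FALSE)
  }
  switch(mode,
         forward = insert,
         forward_complement = dna_complement(insert),
         reverse = dna_reverse(insert),
         reverse_complement = dna_reverse(dna_complement(insert)))
}

#' Translate DNA with the standard genetic code
#'
#' Codon-by-codon translation under NCBI translation table 1
#' (`Biostrings::GENETIC_CODE`). Stop codons emit `*` and are retained; any
#' codon containing a symbol outside A/C/G/T (e.g. an `N` call) emits `X`
#' rather than discarding the sequence — the only read-discarding rule in the
#' pipeline is the frame check.
#'
#' @param dna Character vector of DNA strings with lengths divisible by 3.
#' @return Character vector of peptides (length = nchar(dna)/3; empty input
#'   string gives the empty peptide).
#' @examples
#' translate_dna("AAATTTGGG")  # "KFG"
#' @export
translate_dna <- function(dna) {
  if (length(dna) == 0L) return(character())
  n <- nchar(dna)
  if (any(n %% 3L != 0L)) {
    stop("DNA length not divisible by 3", call. = FALSE)
  }
  vapply(dna, function(s) {
    len <- nchar(s)
    if (len == 0L) return("")
    codons <- substring(s, seq.int(1L, len, by = 3L), seq.int(3L, len, by = 3L))
    aa <- unname(GENETIC_CODE[codons])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Transform and translate a round's inserts
#'
#' Applies the selected mode and translates each insert, returning
#' (dna, peptide) pairs in input order. The DNA key kept alongside each
#' peptide is the ORIGINAL extracted insert, not the transformed strand:
#' counting downstream is at the DNA level of the extracted information,
#' which keeps count tables comparable across modes and preserves
#' synonymous-sequence resolution (distinct DNA, same peptide).
#'
#' @param inserts Character vector of frame-valid DNA inserts.
#' @param mode One of [TRANSLATION_MODES].
#' @param drop_stop If `TRUE`, pairs whose peptide contains a stop (`*`) are
#'   dropped. Default `FALSE`: stops are retained as information.
#' @return data.frame with character columns `dna` and `peptide`.
#' @export
translate_round <- function(inserts, mode = "forward", drop_stop = FALSE) {
  check_mode(mode)
  # transform/translate unique sequences once, then map back
  u <- unique(inserts)
  pep_u <- translate_dna(transform_insert(u, mode))
  peptide <- pep_u[match(inserts, u)]
  out <- data.frame(dna = as.character(inserts), peptide = peptide,
                    stringsAsFactors = FALSE)
  if (isTRUE(drop_stop)) out <- out[!grepl("*", out$peptide, fixed = TRUE), ]
  rownames(out) <- NULL
  out
}
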