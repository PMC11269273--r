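# shared fixture builders; all data are generated in code at test time

PAPER_LEFT <- "GATTCCAGG"
PAPER_RIGHT <- "TACGACCCG"

paper_pattern <- function() compile_pattern(PAPER_LEFT, PAPER_RIGHT)

rand_dna_string <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# reads mixing every structural case the extractor must handle: no anchors,
# one clean pair, adjacent anchors, duplicated right anchor, right-before-left,
# left-only, two full anchor pairs, duplicated left anchor
random_mixed_reads <- function(n, left = PAPER_LEFT, right = PAPER_RIGHT) {
  r <- function(len) rand_dna_string(len)
  vapply(seq_len(n), function(i) {
    switch((i %% 8L) + 1L,
      r(sample(30:80, 1L)),
      paste0(r(sample(0:10, 1L)), left, r(sample(0:30, 1L)), right,
             r(sample(0:10, 1L))),
      paste0(r(3L), left, right, r(3L)),
      paste0(r(5L), left, r(9L), right, r(4L), right, r(5L)),
      paste0(r(5L), right, r(9L), left, r(5L)),
      paste0(r(5L), left, r(20L)),
      paste0(r(5L), left, r(6L), right, r(4L), left, r(6L), right),
      paste0(r(3L), left, r(2L), left, r(9L), right, r(3L))
    )
  }, character(1L))
}

fastq_frame <- function(ids, seqs) {
  data.frame(read_id = ids, sequence = seqs,
             quality = strrep("I", nchar(seqs)), stringsAsFactors = FALSE)
}

write_fastq_lines <- function(lines) {
  tmp <- tempfile(fileext = ".fastq")
  writeLines(lines, tmp)
  tmp
}

# small campaign with both corruption processes, cached per test run
small_corrupt_campaign <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- campaign_spec(n_library_sequences = 300L,
                            reads_per_round = 10000L,
                            anchor_mutation_rate = 0.05,
                            frameshift_rate = 0.02,
                            with_direct = TRUE, seed = 7L)
      dir <- file.path(tempdir(), "phagerank-corrupt-campaign")
      cache <<- c(generate_campaign(spec, dir), list(spec = spec))
    }
    cache
  }
})
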