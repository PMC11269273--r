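test_that("a fixed seed reproduces the campaign byte for byte", {
  spec <- campaign_spec(n_library_sequences = 50L, reads_per_round = 500L,
                       anchor_mutation_rate = 0.03, frameshift_rate = 0.02,
                       seed = 13L)
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  s1 <- generate_campaign(spec, d1)
  s2 <- generate_campaign(spec, d2)
  for (role in names(s1$files)) {
    expect_identical(readLines(s1$files[[role]]),
                     readLines(s2$files[[role]]), info = role)
  }
  expect_identical(readLines(s1$manifest_path), readLines(s2$manifest_path))
})

test_that("with no corruption, extraction recovers the manifest exactly", {
  spec <- campaign_spec(n_library_sequences = 80L, reads_per_round = 2000L,
                        rounds = 2L, seed = 21L)
  sim <- generate_campaign(spec, file.path(tempdir(), "clean"))
  for (role in names(sim$files)) {
    ex <- extract_round(sim$files[[role]], spec$pattern)
    expect_identical(length(ex$inserts), spec$reads_per_round, info = role)
    expect_identical(ex$miss_count, 0L, info = role)
    expect_length(ex$frame_failures, 0L)
    got <- tally(translate_round(ex$inserts, "forward"))
    want <- sim$manifest$rounds[[role]]$counts
    expect_identical(got$raw_count[match(want$dna, got$dna)],
                     want$multiplicity, info = role)
    expect_identical(sum(got$raw_count), sum(want$multiplicity))
  }
})

test_that("planted corruption counts match the manifest exactly", {
  sim <- small_corrupt_campaign()
  for (role in c("target3", "library")) {
    ex <- extract_round(sim$files[[role]], sim$spec$pattern)
    m <- sim$manifest$rounds[[role]]
    expect_identical(ex$miss_count, m$n_snv, info = role)
    expect_identical(length(ex$frame_failures), m$n_frameshift, info = role)
    expect_identical(
      length(ex$inserts) + length(ex$frame_failures) + ex$miss_count,
      ex$total_reads, info = role)
    # clean multiplicities still recovered exactly
    got <- tally(translate_round(ex$inserts, "forward"))
    want <- m$counts
    expect_identical(got$raw_count[match(want$dna, got$dna)],
                     want$multiplicity, info = role)
  }
})

test_that("background abundances follow the specified law", {
  # library round is a plain multinomial draw from the background; a
  # goodness-of-fit test against the Zipf probabilities should not reject
  for (s in c(31L, 32L, 33L)) {
    spec <- campaign_spec(n_library_sequences = 100L,
                          reads_per_round = 20000L,
                          n_binders = 0L, with_empty = FALSE, seed = s)
    sim <- generate_campaign(spec, file.path(tempdir(), paste0("gof", s)))
    lib <- sim$manifest$library_sequences
    p <- seq_along(lib)^(-1.1)
    p <- p / sum(p)
    counts <- sim$manifest$rounds$library$counts
    obs <- counts$multiplicity[match(lib, counts$dna)]
    obs[is.na(obs)] <- 0L
    # collapse any low-expectation tail so the chi-square approximation holds
    keep <- p * spec$reads_per_round >= 5
    obs2 <- obs[keep]
    p2 <- p[keep]
    if (any(!keep)) {
      obs2 <- c(obs2, sum(obs[!keep]))
      p2 <- c(p2, sum(p[!keep]))
    }
    expect_gt(stats::chisq.test(obs2, p = p2)$p.value, 0.01)
  }
})

test_that("anchor SNVs hit inserts independently of their identity", {
  # frequency distribution among SNV-carrying reads mirrors the clean reads
  spec <- campaign_spec(n_library_sequences = 100L,
                        reads_per_round = 40000L, n_binders = 0L,
                        rounds = 1L, with_empty = FALSE, with_library = FALSE,
                        anchor_mutation_rate = 0.2, seed = 55L)
  sim <- generate_campaign(spec, file.path(tempdir(), "snvdist"))
  ex <- extract_round(sim$files[["target1"]], spec$pattern)
  variants <- enumerate_anchor_variants(spec$pattern)
  recovered <- character(0L)
  for (v in variants) {
    ins <- extract_insert(ex$misses, v)
    recovered <- c(recovered, ins[!is.na(ins)])
  }
  recovered <- recovered[nchar(recovered) %% 3L == 0L]
  clean <- tally(translate_round(ex$inserts, "forward"))
  snv <- tally(translate_round(recovered, "forward"))
  common <- intersect(clean$dna, snv$dna)
  expect_gt(length(common), 50L)
  rho <- stats::cor(clean$raw_count[match(common, clean$dna)],
                    snv$raw_count[match(common, snv$dna)],
                    method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("contradictory specs are rejected", {
  expect_error(campaign_spec(insert_length_nt = 10L), "divisible by 3")
  expect_error(campaign_spec(rounds = 4L), "between 1 and 3")
  expect_error(campaign_spec(anchor_mutation_rate = 1.2), "\\[0, 1\\)")
  spec <- campaign_spec(
    n_library_sequences = 20L, reads_per_round = 100L,
    planted_binders = data.frame(dna = "AAACCCGGGAAACCCGGGAAACCCGGG",
                                 factor = 10))
  expect_error(generate_campaign(spec, tempdir()), "absent from the library")
})
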