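# build a count_table directly from named raw counts
mk_table <- function(counts, name, user = "t") {
  rows <- normalize_ppm(data.frame(dna = names(counts),
                                   peptide = strrep("X", 2L),
                                   raw_count = as.integer(counts),
                                   stringsAsFactors = FALSE))
  count_table(rows, selection_name = name, user = user)
}

test_that("score formulas reproduce the hand-checkable ratios", {
  expect_identical(enrichment_score(200, 4), 50)
  expect_identical(enrichment_score(0, 4), 0)
  expect_identical(enrichment_score(200, 0, floor = 0.5), 400)
  expect_identical(empty_score(200, 10), 20)
  expect_identical(empty_score(50, 50), 1)
  expect_identical(empty_score(200, 0, floor = 0.5), 400)
  expect_error(enrichment_score(1, 1, floor = 0), "positive")
  expect_error(empty_score(1, 1, floor = -1), "positive")
})

test_that("evaluation orders by empty score with the full tie-break chain", {
  # per 1000 reads, ppm = count * 1000
  target3 <- mk_table(c(AAA = 200, CCC = 200, GGG = 10, TTT = 590), "target3")
  library_ <- mk_table(c(AAA = 1, CCC = 400, GGG = 1, TTT = 598), "library")
  empty3 <- mk_table(c(AAA = 10, CCC = 10, GGG = 970, TTT = 10), "empty3")
  ev <- evaluate(round_set(list(target3), library = library_,
                           empties = list(empty3)))
  # AAA and CCC tie on empty score (20); AAA wins on enrichment (200 vs 0.5)
  expect_identical(ev$dna, c("TTT", "AAA", "CCC", "GGG"))
  expect_identical(ev$rank, 1:4)
  expect_equal(ev$empty_score[ev$dna == "AAA"], 20)
  expect_equal(ev$empty_score[ev$dna == "CCC"], 20)
  expect_gt(ev$enrichment_score[ev$dna == "AAA"],
            ev$enrichment_score[ev$dna == "CCC"])
})

test_that("a sequence absent from a control is floored, not dropped", {
  target3 <- mk_table(c(AAA = 200, CCC = 800), "target3")
  library_ <- mk_table(c(CCC = 1000), "library")
  empty3 <- mk_table(c(CCC = 1000), "empty3")
  ev <- evaluate(round_set(list(target3), library = library_,
                           empties = list(empty3)))
  aaa <- ev[ev$dna == "AAA", ]
  expect_equal(aaa$enrichment_score, 200000 / 0.5)
  expect_equal(aaa$empty_score, 200000 / 0.5)
  expect_identical(ev$dna[1], "AAA")
})

test_that("identical target and empty frequencies give empty score one", {
  t3 <- mk_table(c(AAA = 300, CCC = 700), "target3")
  e3 <- mk_table(c(AAA = 300, CCC = 700), "empty3")
  l0 <- mk_table(c(AAA = 500, CCC = 500), "library")
  ev <- evaluate(round_set(list(t3), library = l0, empties = list(e3)))
  expect_equal(ev$empty_score, c(1, 1))
})

test_that("scores are invariant to rescaling any single round's counts", {
  t3 <- mk_table(c(AAA = 20, CCC = 30, GGG = 50), "target3")
  lib <- mk_table(c(AAA = 5, CCC = 90, GGG = 5), "library")
  e3 <- mk_table(c(AAA = 2, CCC = 49, GGG = 49), "empty3")
  lib7 <- mk_table(7L * c(AAA = 5, CCC = 90, GGG = 5), "library")
  a <- evaluate(round_set(list(t3), library = lib, empties = list(e3)))
  b <- evaluate(round_set(list(t3), library = lib7, empties = list(e3)))
  expect_equal(a, b)
})

test_that("missing control rounds are configuration errors", {
  t3 <- mk_table(c(AAA = 1000), "target3")
  expect_error(evaluate(round_set(list(t3), empties = list(t3)),
                        scores = c("enrichment", "empty")),
               "no library round")
  expect_error(evaluate(round_set(list(t3), library = t3),
                        scores = c("enrichment", "empty")),
               "no empty-selection round")
  # enrichment-only scoring works without an empty round
  ev <- evaluate(round_set(list(t3), library = t3), scores = "enrichment")
  expect_true(is.na(ev$empty_score))
})

test_that("earlier target rounds appear as context columns", {
  t1 <- mk_table(c(AAA = 100, CCC = 900), "target1")
  t3 <- mk_table(c(AAA = 600, CCC = 400), "target3")
  lib <- mk_table(c(AAA = 500, CCC = 500), "library")
  e3 <- mk_table(c(AAA = 500, CCC = 500), "empty3")
  ev <- evaluate(round_set(list(t1, t3), library = lib, empties = list(e3)))
  expect_equal(ev$target1_ppm[ev$dna == "AAA"], 1e5)
  expect_equal(ev$target2_ppm[ev$dna == "AAA"], 6e5)  # final round is 2nd
})

test_that("filters drop rows after scoring, per configuration", {
  t3 <- mk_table(c(AAA = 500, CCC = 499, GGG = 1), "target3")
  lib <- mk_table(c(AAA = 1, CCC = 998, GGG = 1), "library")
  e3 <- mk_table(c(AAA = 1, CCC = 1, GGG = 998), "empty3")
  dc <- mk_table(c(CCC = 1000), "direct")
  rs <- round_set(list(t3), library = lib, empties = list(e3),
                  direct_controls = list(dc))
  all_rows <- evaluate(rs)
  expect_identical(nrow(all_rows), 3L)  # no filter by default
  expect_true(all(c("direct_ppm", "direct_ratio") %in% names(all_rows)))
  expect_identical(evaluate(rs, min_target_ppm = 2000)$dna %in% "GGG",
                   logical(2L))
  expect_false("CCC" %in% evaluate(rs, min_enrichment = 10)$dna)
  expect_false("CCC" %in% evaluate(rs, max_direct_ratio = 1)$dna)
})

test_that("the evaluation table round-trips through TSV export", {
  t3 <- mk_table(c(AAA = 200, CCC = 800), "target3")
  lib <- mk_table(c(AAA = 100, CCC = 900), "library")
  e3 <- mk_table(c(AAA = 50, CCC = 950), "empty3")
  ev <- evaluate(round_set(list(t3), library = lib, empties = list(e3)))
  path <- tempfile(fileext = ".tsv")
  write_evaluation(ev, path)
  back <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_identical(back$dna, ev$dna)
  expect_equal(back$empty_score, ev$empty_score)
  expect_identical(names(back), names(ev))
})
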