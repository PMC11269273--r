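# Independent oracles, written deliberately unlike the package internals:
# position-scanning loops instead of vectorized regex/substring arithmetic.

# all (possibly overlapping) start positions of fixed pattern `pat` in `s`
find_all_occurrences <- function(s, pat) {
  hits <- integer(0L)
  from <- 1L
  repeat {
    i <- regexpr(pat, substring(s, from), fixed = TRUE)
    if (i < 0L) break
    hits <- c(hits, from + i - 1L)
    from <- from + i
  }
  hits
}

# brute-force insert extraction: scan every occurrence of both anchors and
# take the substring between the first left occurrence and the nearest right
# occurrence that starts after it
oracle_extract <- function(sequence, left, right) {
  vapply(sequence, function(s) {
    lpos <- find_all_occurrences(s, left)
    if (!length(lpos)) return(NA_character_)
    start <- lpos[1L] + nchar(left)
    rpos <- find_all_occurrences(s, right)
    rpos <- rpos[rpos >= start]
    if (!length(rpos)) return(NA_character_)
    substr(s, start, rpos[1L] - 1L)
  }, character(1L), USE.NAMES = FALSE)
}

# hand-coded standard genetic code (NCBI translation table 1)
HAND_GENETIC_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

oracle_complement <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(x, function(s) {
    paste(comp[strsplit(s, "", fixed = TRUE)[[1L]]], collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

oracle_reverse <- function(x) {
  vapply(x, function(s) {
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1L), USE.NAMES = FALSE)
}

oracle_translate <- function(x) {
  vapply(x, function(s) {
    n <- nchar(s)
    if (n == 0L) return("")
    aa <- character(n %/% 3L)
    for (k in seq_along(aa)) {
      codon <- substr(s, 3L * k - 2L, 3L * k)
      aa[k] <- if (codon %in% names(HAND_GENETIC_CODE)) {
        HAND_GENETIC_CODE[[codon]]
      } else "X"
    }
    paste(aa, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# every DNA string of length `len`
all_kmers <- function(len) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), len),
                              stringsAsFactors = FALSE))
}
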