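#' Specify a synthetic selection campaign
#'
#' Describes a complete phage-display selection campaign for the simulator:
#' a naive library with skewed abundances, up to three target rounds in
#' which planted binders gain a multiplicative advantage per round, parallel
#' empty-selection rounds without that advantage, an optional direct
#' control, and two read-corruption processes (anchor point mutations and
#' frame-breaking 1-nt deletions).
#'
#' Defaults describe a small but realistic campaign: 1,000 distinct library
#' sequences with Zipf-distributed abundances (exponent 1.1, the skew of a
#' naive display library after amplification), 5 planted binders with a
#' 10-fold per-round advantage, 50,000 reads per round, 27-nt inserts
#' (9-mer peptides) framed by 9-nt anchors.
#'
#' @param n_library_sequences Number of distinct library inserts.
#' @param insert_length_nt Insert length in nt; must be divisible by 3.
#' @param rounds Number of target selection rounds (1-3).
#' @param n_binders Number of binders to plant when `planted_binders` is not
#'   given explicitly.
#' @param enrichment_factor Per-round multiplicative advantage of each
#'   auto-planted binder.
#' @param planted_binders Optional data.frame with columns `dna`, `factor`;
#'   every `dna` must be a member of `library_sequences`.
#' @param library_sequences Optional character vector of library inserts; by
#'   default they are generated randomly (anchor-free, unique).
#' @param background Abundance law of the naive library:
#'   `list(law = "zipf", exponent = ...)` or
#'   `list(law = "lognormal", meanlog = ..., sdlog = ...)`.
#' @param reads_per_round Reads sequenced per round.
#' @param pattern `search_pattern` giving the framing anchors.
#' @param anchor_mutation_rate Fraction of reads in `[0, 1)` receiving one
#'   random point mutation inside an anchor (these reads are unfindable by
#'   exact matching).
#' @param frameshift_rate Fraction of reads in `[0, 1)` receiving a 1-nt
#'   deletion inside the insert (these become frame failures).
#' @param with_empty,with_direct,with_library Which control selections to
#'   generate.
#' @param pad_range Integer range of random padding lengths flanking the
#'   anchored construct on each side.
#' @param seed Integer RNG seed; a fixed seed gives byte-identical output.
#' @return An object of class `campaign_spec`.
#' @export
campaign_spec <- function(n_library_sequences = 1000L,
                          insert_length_nt = 27L,
                          rounds = 3L,
                          n_binders = 5L,
                          enrichment_factor = 10,
                          planted_binders = NULL,
                          library_sequences = NULL,
                          background = list(law = "zipf", exponent = 1.1),
                          reads_per_round = 50000L,
                          pattern = compile_pattern("GATTCCAGG", "TACGACCCG"),
                          anchor_mutation_rate = 0,
                          frameshift_rate = 0,
                          with_empty = TRUE,
                          with_direct = FALSE,
                          with_library = TRUE,
                          pad_range = c(5L, 15L),
                          seed = 1L) {
  stopifnot(inherits(pattern, "search_pattern"))
  if (insert_length_nt %% 3L != 0L) {
    stop("insert_length_nt must be divisible by 3", call. = FALSE)
  }
  if (rounds < 1L || rounds > 3L) {
    stop("rounds must be between 1 and 3", call. = FALSE)
  }
  for (r in c(anchor_mutation_rate, frameshift_rate)) {
    if (!is.numeric(r) || r < 0 || r >= 1) {
      stop("corruption rates must lie in [0, 1)", call. = FALSE)
    }
  }
  if (anchor_mutation_rate + frameshift_rate >= 1) {
    stop("combined corruption rates must stay below 1", call. = FALSE)
  }
  if (!background$law %in% c("zipf", "lognormal")) {
    stop("background$law must be 'zipf' or 'lognormal'", call. = FALSE)
  }
  if (!is.null(planted_binders)) {
    stopifnot(is.data.frame(planted_binders),
              all(c("dna", "factor") %in% names(planted_binders)))
  }
  structure(
    list(n_library_sequences = as.integer(n_library_sequences),
         insert_length_nt = as.integer(insert_length_nt),
         rounds = as.integer(rounds),
         n_binders = as.integer(n_binders),
         enrichment_factor = enrichment_factor,
         planted_binders = planted_binders,
         library_sequences = library_sequences,
         background = background,
         reads_per_round = as.integer(reads_per_round),
         pattern = pattern,
         anchor_mutation_rate = anchor_mutation_rate,
         frameshift_rate = frameshift_rate,
         with_empty = with_empty,
         with_direct = with_direct,
         with_library = with_library,
         pad_range = as.integer(pad_range),
         seed = as.integer(seed)),
    class = "campaign_spec"
  )
}

random_dna <- function(n, len) {
  if (n == 0L) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# library inserts must not interact with the anchors: each candidate is
# checked by extracting it back out of a minimal anchored construct, so no
# insert can contain (or form at a junction) a spurious anchor occurrence
generate_library_sequences <- function(n, len, pattern) {
  out <- character(0L)
  while (length(out) < n) {
    cand <- unique(random_dna(2L * (n - length(out)), len))
    cand <- setdiff(cand, out)
    probe <- paste0(pattern$left_anchor, cand, pattern$right_anchor)
    ok <- !is.na(extract_insert(probe, pattern)) &
      extract_insert(probe, pattern) == cand
    out <- c(out, cand[ok])
  }
  out[seq_len(n)]
}

background_probs <- function(spec) {
  n <- spec$n_library_sequences
  law <- spec$background
  w <- switch(law$law,
              zipf = seq_len(n)^(-law$exponent),
              lognormal = stats::rlnorm(n, law$meanlog, law$sdlog))
  w / sum(w)
}

#' Generate a synthetic selection campaign
#'
#' Writes one FASTQ file per simulated round into `dir` plus a ground-truth
#' manifest (`manifest.json`). Target-round abundances follow the background
#' law with each planted binder's weight multiplied by `factor^round`; empty
#' rounds resample the background without the binder advantage; the direct
#' control applies the advantage through round `rounds - 1` and then one
#' neutral round; the library round samples the background directly. Each
#' read is `left pad + left anchor + insert + right anchor + right pad` with
#' random pad lengths. A fraction `anchor_mutation_rate` of reads receives
#' one anchor point mutation (and is verified to be unmatchable), a fraction
#' `frameshift_rate` a 1-nt deletion inside the insert (verified to extract
#' as a frame failure); all remaining reads are verified to extract to
#' exactly their intended insert, so the manifest is exact ground truth. A
#' fixed seed gives byte-identical FASTQ output.
#'
#' @param spec A `campaign_spec`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `files` (named FASTQ paths), `manifest`
#'   (the in-memory manifest), and `manifest_path`.
#' @export
generate_campaign <- function(spec, dir) {
  stopifnot(inherits(spec, "campaign_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)

  lib <- spec$library_sequences
  if (is.null(lib)) {
    lib <- generate_library_sequences(spec$n_library_sequences,
                                      spec$insert_length_nt, spec$pattern)
  } else {
    if (length(unique(lib)) != spec$n_library_sequences) {
      stop("library_sequences must hold n_library_sequences unique inserts",
           call. = FALSE)
    }
  }
  p <- background_probs(spec)

  binders <- spec$planted_binders
  if (is.null(binders)) {
    idx <- sample(spec$n_library_sequences, spec$n_binders)
    binders <- data.frame(dna = lib[idx],
                          factor = rep(spec$enrichment_factor,
                                       spec$n_binders),
                          stringsAsFactors = FALSE)
  }
  bidx <- match(binders$dna, lib)
  if (anyNA(bidx)) {
    stop("planted binder sequence(s) absent from the library: ",
         paste(utils::head(binders$dna[is.na(bidx)], 3L), collapse = ", "),
         call. = FALSE)
  }

  weights_for <- function(advantage_rounds) {
    w <- p
    w[bidx] <- w[bidx] * binders$factor^advantage_rounds
    w / sum(w)
  }

  role_weights <- list()
  for (r in seq_len(spec$rounds)) {
    role_weights[[paste0("target", r)]] <- weights_for(r)
    if (spec$with_empty) role_weights[[paste0("empty", r)]] <- weights_for(0)
  }
  if (spec$with_direct) {
    role_weights[["direct"]] <- weights_for(spec$rounds - 1L)
  }
  if (spec$with_library) role_weights[["library"]] <- weights_for(0)

  files <- character(0L)
  manifest_rounds <- list()
  for (role in names(role_weights)) {
    sim <- simulate_round(role, role_weights[[role]], lib, spec)
    path <- file.path(dir, paste0(role, ".fastq"))
    write_fastq(sim$records, path)
    files[[role]] <- path
    manifest_rounds[[role]] <- sim$manifest
  }

  manifest <- list(
    seed = spec$seed,
    insert_length_nt = spec$insert_length_nt,
    reads_per_round = spec$reads_per_round,
    anchor_mutation_rate = spec$anchor_mutation_rate,
    frameshift_rate = spec$frameshift_rate,
    left_anchor = spec$pattern$left_anchor,
    right_anchor = spec$pattern$right_anchor,
    binders = binders,
    library_sequences = lib,
    rounds = manifest_rounds
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(files = files, manifest = manifest,
                 manifest_path = manifest_path))
}

# draw one round: multinomial insert counts, planted corruptions, padded
# assembly, and rejection-verification of every read's extraction outcome
simulate_round <- function(role, weights, lib, spec) {
  n <- spec$reads_per_round
  counts <- as.integer(stats::rmultinom(1L, n, weights))
  insert_idx <- rep.int(seq_along(lib), counts)
  insert_idx <- sample(insert_idx)  # shuffle read order
  insert <- lib[insert_idx]

  n_snv <- stats::rbinom(1L, n, spec$anchor_mutation_rate)
  n_fs <- stats::rbinom(1L, n, spec$frameshift_rate)
  corrupted <- sample(n, n_snv + n_fs)
  snv_i <- corrupted[seq_len(n_snv)]
  fs_i <- corrupted[n_snv + seq_len(n_fs)]

  left <- rep.int(spec$pattern$left_anchor, n)
  la_len <- nchar(spec$pattern$left_anchor)
  ra_len <- nchar(spec$pattern$right_anchor)
  right <- rep.int(spec$pattern$right_anchor, n)

  # anchor SNV: one random position of one random anchor flips to another base
  if (n_snv > 0L) {
    side_left <- sample(c(TRUE, FALSE), n_snv, replace = TRUE)
    for (k in seq_len(n_snv)) {
      i <- snv_i[k]
      if (side_left[k]) {
        left[i] <- mutate_one_base(left[i], sample.int(la_len, 1L))
      } else {
        right[i] <- mutate_one_base(right[i], sample.int(ra_len, 1L))
      }
    }
  }
  # frameshift: delete one random nt inside the insert
  if (n_fs > 0L) {
    pos <- sample.int(spec$insert_length_nt, n_fs, replace = TRUE)
    insert[fs_i] <- paste0(substr(insert[fs_i], 1L, pos - 1L),
                           substring(insert[fs_i], pos + 1L))
  }

  pat <- spec$pattern
  want_match <- rep.int(TRUE, n)
  want_match[snv_i] <- FALSE

  pads <- function(m) {
    lens <- sample(seq.int(spec$pad_range[1L], spec$pad_range[2L]), m,
                   replace = TRUE)
    full <- random_dna(m, spec$pad_range[2L])
    substr(full, 1L, lens)
  }
  lpad <- pads(n)
  rpad <- pads(n)
  reads <- paste0(lpad, left, insert, right, rpad)

  # rejection step: pads (or, for stubborn reads, the whole read context)
  # must not create spurious anchor occurrences that change the outcome
  for (iter in seq_len(50L)) {
    got <- extract_insert(reads, pat)
    ok <- ifelse(want_match, !is.na(got) & got == insert, is.na(got))
    bad <- which(!ok)
    if (!length(bad)) break
    if (iter == 50L) {
      stop("could not realize a conflict-free read layout after 50 attempts",
           call. = FALSE)
    }
    lpad[bad] <- pads(length(bad))
    rpad[bad] <- pads(length(bad))
    if (iter > 5L) {
      # a stubborn SNV read can contain the intact anchor across a junction;
      # re-draw its mutation
      stubborn_snv <- intersect(bad, snv_i)
      for (i in stubborn_snv) {
        left[i] <- pat$left_anchor
        right[i] <- pat$right_anchor
        if (stats::runif(1L) < 0.5) {
          left[i] <- mutate_one_base(left[i], sample.int(la_len, 1L))
        } else {
          right[i] <- mutate_one_base(right[i], sample.int(ra_len, 1L))
        }
      }
    }
    reads[bad] <- paste0(lpad[bad], left[bad], insert[bad], right[bad],
                         rpad[bad])
  }

  ids <- paste0(role, "_", seq_len(n))
  records <- data.frame(read_id = ids, sequence = reads,
                        quality = strrep("I", nchar(reads)),
                        stringsAsFactors = FALSE)

  clean <- setdiff(seq_len(n), corrupted)
  mult <- tabulate(insert_idx[clean], nbins = length(lib))
  keep <- mult > 0L
  list(records = records,
       manifest = list(
         n_reads = n,
         counts = data.frame(dna = lib[keep], multiplicity = mult[keep],
                             stringsAsFactors = FALSE),
         snv_read_ids = ids[sort(snv_i)],
         frameshift_read_ids = ids[sort(fs_i)],
         n_snv = n_snv,
         n_frameshift = n_fs))
}

mutate_one_base <- function(anchor, pos) {
  orig <- substr(anchor, pos, pos)
  alt <- sample(setdiff(c("A", "C", "G", "T"), orig), 1L)
  substr(anchor, pos, pos) <- alt
  anchor
}
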