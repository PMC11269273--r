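#' Read a strict 4-line FASTQ file
#'
#' Reads a UTF-8 FASTQ file in the strict 4-line-per-record layout (header,
#' sequence, separator, quality) and returns one row per read. Wrapped
#' (multi-line) FASTQ is rejected. Gzip-compressed files are decompressed
#' transparently. Sequence letters are uppercased on ingest so that downstream
#' anchor matching is case-insensitive; quality strings are validated for
#' length only and never used analytically.
#'
#' @param path Path to a FASTQ or FASTQ.gz file.
#' @return A data.frame with character columns `read_id`, `sequence`,
#'   `quality`, one row per read, in file order. An empty file yields zero
#'   rows.
#' @examples
#' tmp <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), tmp)
#' read_fastq(tmp)
#' @export
read_fastq <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0L) return(empty_fastq_frame())
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ '", basename(path), "': ", length(lines),
         " lines is not a multiple of 4 (wrapped records are not supported)",
         call. = FALSE)
  }
  idx <- seq.int(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]

  bad <- which(substr(hdr, 1L, 1L) != "@")
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1L],
         ": header line does not start with '@'", call. = FALSE)
  }
  bad <- which(substr(plus, 1L, 1L) != "+")
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1L],
         ": separator line does not start with '+'", call. = FALSE)
  }
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1L], ": quality length (",
         nchar(qual[bad[1L]]), ") differs from sequence length (",
         nchar(seqs[bad[1L]]), ")", call. = FALSE)
  }
  ids <- substring(hdr, 2L)
  bad <- which(!nzchar(ids))
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1L], ": empty read id", call. = FALSE)
  }
  data.frame(read_id = ids, sequence = toupper(seqs), quality = qual,
             stringsAsFactors = FALSE)
}

#' Write records as 4-line FASTQ
#'
#' Inverse of [read_fastq()]: writes one 4-line record per row. Paths ending
#' in `.gz` are gzip-compressed.
#'
#' @param records data.frame with columns `read_id`, `sequence`, `quality`
#'   (quality defaults to a constant 'I' string if the column is absent).
#' @param path Output path.
#' @return Invisibly, the number of records written.
#' @export
write_fastq <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("read_id", "sequence") %in% names(records)))
  if (is.null(records$quality)) {
    records$quality <- strrep("I", nchar(records$sequence))
  }
  if (any(nchar(records$quality) != nchar(records$sequence))) {
    stop("quality/sequence length mismatch in records to write", call. = FALSE)
  }
  if (any(!nzchar(records$read_id))) {
    stop("empty read id in records to write", call. = FALSE)
  }
  n <- nrow(records)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (n > 0L) {
    lines <- character(4L * n)
    lines[seq.int(1L, by = 4L, length.out = n)] <- paste0("@", records$read_id)
    lines[seq.int(2L, by = 4L, length.out = n)] <- records$sequence
    lines[seq.int(3L, by = 4L, length.out = n)] <- "+"
    lines[seq.int(4L, by = 4L, length.out = n)] <- records$quality
    writeLines(lines, con)
  }
  invisible(n)
}

empty_fastq_frame <- function() {
  data.frame(read_id = character(), sequence = character(),
             quality = character(), stringsAsFactors = FALSE)
}
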