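#' Open (or create) a campaign database
#'
#' All long-term storage lives in a single SQLite file that the user can
#' place anywhere (local disk or network share). After a complete analysis
#' the database holds one table per provided selection round (targets,
#' direct controls, empties, library), a table of saved search patterns, and
#' — once scoring has been run — an evaluation table. Round tables are never
#' mutated by evaluation, so the original extracted data survive an
#' unexpected scoring outcome. Schema is documented in the README so the
#' file can be queried with any external SQLite client.
#'
#' @param path Path to the SQLite database file (created if absent).
#' @return An object of class `campaign_db` holding the path; connections
#'   are opened per operation.
#' @export
campaign_db <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  db <- structure(list(path = path), class = "campaign_db")
  con <- db_connect(db)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbExecute(con, "
    CREATE TABLE IF NOT EXISTS rounds_meta (
      selection_name TEXT PRIMARY KEY,
      table_name     TEXT NOT NULL,
      user           TEXT,
      total_counted  INTEGER,
      frame_fail_count INTEGER,
      miss_count     INTEGER,
      processed_date TEXT
    )")
  DBI::dbExecute(con, "
    CREATE TABLE IF NOT EXISTS search_patterns (
      label        TEXT PRIMARY KEY,
      left_anchor  TEXT NOT NULL,
      right_anchor TEXT NOT NULL
    )")
  db
}

#' @export
print.campaign_db <- function(x, ...) {
  cat("<campaign_db> ", x$path, "\n  rounds: ",
      paste(list_rounds(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

db_connect <- function(db) {
  stopifnot(inherits(db, "campaign_db"))
  DBI::dbConnect(RSQLite::SQLite(), db$path)
}

# SQL identifier for a round table: non-alphanumerics become '_'
round_table_name <- function(selection_name) {
  paste0("round_", gsub("[^A-Za-z0-9]", "_", selection_name))
}

#' Persist a per-round count table
#'
#' Stores one row per distinct DNA sequence with the provenance columns
#' (selection name, user, sequence, peptide, raw count, ppm, processing
#' date). Re-storing an existing selection name with `overwrite = TRUE`
#' replaces it atomically; without the flag it is a conflict error.
#'
#' @param table A `count_table`.
#' @param db A `campaign_db`.
#' @param overwrite Replace an existing round of the same name.
#' @return Invisibly, the number of rows written.
#' @export
store_round <- function(table, db, overwrite = FALSE) {
  stopifnot(inherits(table, "count_table"))
  con <- db_connect(db)
  on.exit(DBI::dbDisconnect(con))
  tbl <- round_table_name(table$selection_name)
  known <- DBI::dbGetQuery(con,
    "SELECT selection_name FROM rounds_meta WHERE selection_name = ?",
    params = list(table$selection_name))
  if (nrow(known) && !overwrite) {
    stop("selection '", table$selection_name,
         "' already stored; use overwrite = TRUE to replace it",
         call. = FALSE)
  }
  rows <- data.frame(selection_name = table$selection_name,
                     user = table$user,
                     dna = table$rows$dna,
                     peptide = table$rows$peptide,
                     raw_count = table$rows$raw_count,
                     ppm = table$rows$ppm,
                     processed_date = as.character(table$processed_date),
                     stringsAsFactors = FALSE)
  DBI::dbWithTransaction(con, {
    if (DBI::dbExistsTable(con, tbl)) DBI::dbRemoveTable(con, tbl)
    DBI::dbWriteTable(con, tbl, rows)
    DBI::dbExecute(con,
      "INSERT OR REPLACE INTO rounds_meta
       (selection_name, table_name, user, total_counted, frame_fail_count,
        miss_count, processed_date) VALUES (?, ?, ?, ?, ?, ?, ?)",
      params = list(table$selection_name, tbl, table$user,
                    table$total_counted, table$frame_fail_count,
                    table$miss_count, as.character(table$processed_date)))
  })
  invisible(nrow(rows))
}

#' Reload a stored selection round
#'
#' @param selection_name Name the round was stored under.
#' @param db A `campaign_db`.
#' @return The reconstructed `count_table`.
#' @export
load_round <- function(selection_name, db) {
  con <- db_connect(db)
  on.exit(DBI::dbDisconnect(con))
  meta <- DBI::dbGetQuery(con,
    "SELECT * FROM rounds_meta WHERE selection_name = ?",
    params = list(selection_name))
  if (!nrow(meta)) {
    stop("no stored round named '", selection_name, "'", call. = FALSE)
  }
  rows <- DBI::dbGetQuery(con, paste0(
    "SELECT dna, peptide, raw_count, ppm FROM ",
    DBI::dbQuoteIdentifier(con, meta$table_name), " ORDER BY rowid"))
  count_table(rows, selection_name = meta$selection_name, user = meta$user,
              frame_fail_count = meta$frame_fail_count,
              miss_count = meta$miss_count,
              processed_date = meta$processed_date)
}

#' List stored selection rounds
#'
#' @param db A `campaign_db`.
#' @return Character vector of stored selection names.
#' @export
list_rounds <- function(db) {
  con <- db_connect(db)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbGetQuery(con,
    "SELECT selection_name FROM rounds_meta ORDER BY selection_name"
  )$selection_name
}

#' Persist the ranked evaluation table
#'
#' Writes the filtered, ordered scoring results to the `evaluation` table.
#' Round tables are left untouched — the evaluation is derived data and the
#' original per-round counts remain the reference.
#'
#' @param records An `evaluation` data.frame from [evaluate()].
#' @param db A `campaign_db`.
#' @param name Table name (default `"evaluation"`).
#' @param overwrite Replace an existing evaluation table.
#' @return Invisibly, the number of rows written.
#' @export
store_evaluation <- function(records, db, name = "evaluation",
                             overwrite = TRUE) {
  stopifnot(is.data.frame(records))
  con <- db_connect(db)
  on.exit(DBI::dbDisconnect(con))
  if (DBI::dbExistsTable(con, name) && !overwrite) {
    stop("evaluation table '", name, "' already exists; ",
         "use overwrite = TRUE to replace it", call. = FALSE)
  }
  DBI::dbWithTransaction(con, {
    if (DBI::dbExistsTable(con, name)) DBI::dbRemoveTable(con, name)
    DBI::dbWriteTable(con, name, as.data.frame(records))
  })
  invisible(nrow(records))
}

#' Reload a stored evaluation table
#'
#' @param db A `campaign_db`.
#' @param name Table name (default `"evaluation"`).
#' @return The `evaluation` data.frame in stored (ranked) order.
#' @export
load_evaluation <- function(db, name = "evaluation") {
  con <- db_connect(db)
  on.exit(DBI::dbDisconnect(con))
  if (!DBI::dbExistsTable(con, name)) {
    stop("no evaluation table named '", name, "'", call. = FALSE)
  }
  out <- DBI::dbGetQuery(con, paste0(
    "SELECT * FROM ", DBI::dbQuoteIdentifier(con, name), " ORDER BY rank"))
  class(out) <- c("evaluation", "data.frame")
  out
}

#' Save / reload a search pattern by label
#'
#' Framing-anchor patterns can be kept in the database for fast reuse in
#' later sessions.
#'
#' @param pattern A `search_pattern` with a non-`NULL` label.
#' @param db A `campaign_db`.
#' @param overwrite Replace an existing pattern of the same label.
#' @return `store_pattern`: invisibly, the label. `load_pattern`: the
#'   `search_pattern`. `list_patterns`: character vector of labels.
#' @export
store_pattern <- function(pattern, db, overwrite = FALSE) {
  stopifnot(inherits(pattern, "search_pattern"))
  if (is.null(pattern$label) || !nzchar(pattern$label)) {
    stop("pattern must carry a label to be stored", call. = FALSE)
  }
  con <- db_connect(db)
  on.exit(DBI::dbDisconnect(con))
  known <- DBI::dbGetQuery(con,
    "SELECT label FROM search_patterns WHERE label = ?",
    params = list(pattern$label))
  if (nrow(known) && !overwrite) {
    stop("pattern label '", pattern$label, "' already stored; ",
         "use overwrite = TRUE to replace it", call. = FALSE)
  }
  DBI::dbExecute(con,
    "INSERT OR REPLACE INTO search_patterns
     (label, left_anchor, right_anchor) VALUES (?, ?, ?)",
    params = list(pattern$label, pattern$left_anchor, pattern$right_anchor))
  invisible(pattern$label)
}

#' @rdname store_pattern
#' @param label Label the pattern was stored under.
#' @export
load_pattern <- function(label, db) {
  con <- db_connect(db)
  on.exit(DBI::dbDisconnect(con))
  row <- DBI::dbGetQuery(con,
    "SELECT * FROM search_patterns WHERE label = ?", params = list(label))
  if (!nrow(row)) stop("no stored pattern labelled '", label, "'",
                       call. = FALSE)
  compile_pattern(row$left_anchor, row$right_anchor, label = row$label)
}

#' @rdname store_pattern
#' @export
list_patterns <- function(db) {
  con <- db_connect(db)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbGetQuery(con,
    "SELECT label FROM search_patterns ORDER BY label")$label
}
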