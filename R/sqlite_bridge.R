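# SQLite persistence without RSQLite: the store schema is fixed (three
# tables), so reads and writes are delegated to the python sqlite3 stdlib
# through short generated scripts exchanging CSV via temp files. `python`
# ships in the same environment as R here; the bridge fails loudly if it is
# absent.

sqlite_python <- function() {
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  ct_error("SQLite support needs a 'python' executable on PATH (sqlite3 stdlib)")
}

SQLITE_SCHEMA <- c(
  predictions = paste(
    "CREATE TABLE IF NOT EXISTS predictions (",
    "image_id TEXT NOT NULL, model_id TEXT NOT NULL, rank INTEGER NOT NULL,",
    "synset_id TEXT NOT NULL, confidence REAL NOT NULL,",
    "PRIMARY KEY (image_id, model_id, rank))"),
  truth = paste(
    "CREATE TABLE IF NOT EXISTS truth (",
    "image_id TEXT PRIMARY KEY, is_positive INTEGER NOT NULL,",
    "camera_id TEXT, timestamp TEXT)"),
  models = paste(
    "CREATE TABLE IF NOT EXISTS models (",
    "model_id TEXT PRIMARY KEY, full_name TEXT, input_size_px INTEGER,",
    "top1_imagenet REAL, top5_imagenet REAL, origin_library TEXT,",
    "n_params INTEGER, flop_millions REAL, img_per_s REAL)")
)

run_python <- function(code, args = character()) {
  script <- tempfile(fileext = ".py")
  on.exit(unlink(script))
  writeLines(code, script)
  out <- suppressWarnings(
    system2(sqlite_python(), c(script, shQuote(args)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    ct_error("sqlite bridge failed (exit %d): %s", status,
             paste(out, collapse = " | "))
  }
  invisible(out)
}

# replace the named table's contents with the CSV payload
sqlite_write_table <- function(db_path, table, dt) {
  stopifnot(table %in% names(SQLITE_SCHEMA))
  payload <- tempfile(fileext = ".csv")
  on.exit(unlink(payload))
  fwrite(dt, payload)
  ncol <- length(names(dt))
  code <- c(
    "import csv, sqlite3, sys",
    "db, table, payload = sys.argv[1:4]",
    sprintf("schemas = %s", py_dict(SQLITE_SCHEMA)),
    "con = sqlite3.connect(db)",
    "cur = con.cursor()",
    "for ddl in schemas.values():",
    "    cur.execute(ddl)",
    "with open(payload, newline='') as fh:",
    "    rows = list(csv.reader(fh))",
    "header, body = rows[0], rows[1:]",
    "cur.execute('DELETE FROM ' + table)",
    "cols = ','.join(header)",
    "ph = ','.join('?' * len(header))",
    "cur.executemany(f'INSERT INTO {table} ({cols}) VALUES ({ph})', body)",
    "con.commit()",
    "con.close()")
  run_python(code, c(db_path, table, payload))
  invisible(db_path)
}

sqlite_read_table <- function(db_path, table) {
  stopifnot(table %in% names(SQLITE_SCHEMA))
  if (!file.exists(db_path)) ct_error("no such file: %s", db_path)
  out_csv <- tempfile(fileext = ".csv")
  on.exit(unlink(out_csv))
  code <- c(
    "import csv, sqlite3, sys",
    "db, table, out = sys.argv[1:4]",
    "con = sqlite3.connect(db)",
    "cur = con.execute('SELECT * FROM ' + table)",
    "cols = [d[0] for d in cur.description]",
    "with open(out, 'w', newline='') as fh:",
    "    w = csv.writer(fh)",
    "    w.writerow(cols)",
    "    for row in cur:",
    "        w.writerow([repr(v) if isinstance(v, float) else v for v in row])",
    "con.close()")
  run_python(code, c(db_path, table, out_csv))
  fread(out_csv, colClasses = list(character = intersect(
    c("image_id", "model_id", "synset_id", "camera_id", "timestamp",
      "full_name", "origin_library"),
    names(fread(out_csv, nrows = 0L)))))
}

#' List the tables present in an SQLite results store
#' @param db_path path to the database file.
#' @return character vector of table names.
#' @export
sqlite_store_tables <- function(db_path) {
  if (!file.exists(db_path)) ct_error("no such file: %s", db_path)
  out_csv <- tempfile(fileext = ".csv")
  on.exit(unlink(out_csv))
  code <- c(
    "import sqlite3, sys",
    "db, out = sys.argv[1:3]",
    "con = sqlite3.connect(db)",
    "rows = con.execute(\"SELECT name FROM sqlite_master WHERE type='table' ORDER BY name\").fetchall()",
    "open(out, 'w').write('\\n'.join(r[0] for r in rows) + '\\n')",
    "con.close()")
  run_python(code, c(db_path, out_csv))
  readLines(out_csv)
}

#' Write a complete SQLite results store
#'
#' Creates (or refreshes) the three-table store: `predictions`, `truth`
#' and `models`, mirroring the workflow where top-5 inference results and
#' human labels live in one queryable database.
#'
#' @param db_path destination database file.
#' @param predictions prediction records (may be `NULL` to leave the table
#'   empty).
#' @param truth truth table (optional).
#' @param models model catalog (optional; defaults to the bundled catalog).
#' @return invisibly `db_path`.
#' @export
write_results_store <- function(db_path, predictions = NULL, truth = NULL,
                                models = load_model_catalog()) {
  empty_pred <- data.table(image_id = character(), model_id = character(),
                           rank = integer(), synset_id = character(),
                           confidence = numeric())
  sqlite_write_table(db_path, "predictions",
                     if (is.null(predictions)) empty_pred
                     else validate_predictions(predictions))
  tr <- if (is.null(truth)) {
    data.table(image_id = character(), is_positive = integer())
  } else {
    t2 <- copy(validate_truth(truth))
    t2[, is_positive := as.integer(is_positive)][]
  }
  sqlite_write_table(db_path, "truth", tr)
  if (!is.null(models)) sqlite_write_table(db_path, "models", models)
  invisible(db_path)
}

py_dict <- function(named) {
  entries <- vapply(names(named), function(k)
    sprintf("'%s': \"%s\"", k, gsub('"', '\\\\"', named[[k]])), character(1))
  paste0("{", paste(entries, collapse = ", "), "}")
}
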