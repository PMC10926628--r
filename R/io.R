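#' Read a per-user search-history export
#'
#' Accepts either a Google Takeout "My Activity" Search export (a JSON
#' array of activity objects with a `title` like `"Searched for ..."` and
#' an ISO-8601 `time`) or the package's line-delimited fixture dialect
#' (one JSON object per line with keys `user_id`, `timestamp`, `text`).
#' Non-search activity entries (e.g. `"Visited ..."`) are skipped.
#'
#' @param path path to the JSON / JSONL file.
#' @param user_id identifier to assign to the records.  Required for
#'   Takeout input; for the JSONL dialect it overrides the per-line
#'   `user_id` when given.
#' @return a tibble of query records (`user_id`, `timestamp` as UTC
#'   `POSIXct`, `text`), sorted ascending by timestamp, with empty-text
#'   records dropped.
#' @export
read_takeout <- function(path, user_id = NULL) {
  first <- trimws(paste(readLines(path, n = 5L, warn = FALSE), collapse = ""))
  if (startsWith(first, "[")) {
    recs <- parse_takeout_json(path, user_id)
  } else {
    recs <- parse_fixture_jsonl(path, user_id)
  }
  recs <- recs[nzchar(trimws(recs$text)), ]
  dplyr::arrange(recs, .data$timestamp)
}

parse_takeout_json <- function(path, user_id) {
  if (is.null(user_id))
    qs_stop("user_id is required for Takeout input", "qs_format_error")
  entries <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) qs_stop(
      paste0("unparseable Takeout JSON in '", path, "': ",
             conditionMessage(e)), "qs_format_error"))
  is_search <- vapply(entries, function(e) {
    !is.null(e$title) && startsWith(e$title, "Searched for ")
  }, logical(1))
  entries <- entries[is_search]
  if (length(entries) == 0L)
    return(tibble::tibble(user_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                          text = character()))
  times <- vapply(entries, function(e) {
    if (is.null(e$time))
      qs_stop("Takeout record missing 'time' field", "qs_format_error")
    e$time
  }, character(1))
  tibble::tibble(
    user_id = user_id,
    timestamp = parse_iso8601(times, path),
    text = vapply(entries, function(e) sub("^Searched for ", "", e$title),
                  character(1)))
}

parse_fixture_jsonl <- function(path, user_id) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(tibble::tibble(user_id = character(),
                          timestamp = as.POSIXct(character(), tz = "UTC"),
                          text = character()))
  recs <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) qs_stop(
                      paste0("unparseable JSON at line ", i, " of '", path,
                             "': ", conditionMessage(e)), "qs_format_error"))
    if (is.null(obj$timestamp))
      qs_stop(paste0("record at line ", i, " is missing a timestamp"),
              "qs_format_error")
    if (is.null(obj$text))
      qs_stop(paste0("record at line ", i, " is missing text"),
              "qs_format_error")
    tibble::tibble(user_id = user_id %||% obj$user_id %||% NA_character_,
                   time_raw = as.character(obj$timestamp),
                   text = as.character(obj$text))
  })
  recs <- dplyr::bind_rows(recs)
  tibble::tibble(user_id = recs$user_id,
                 timestamp = parse_iso8601(recs$time_raw, path),
                 text = recs$text)
}

parse_iso8601 <- function(x, path) {
  x <- sub("Z$", "", x)
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  date_only <- is.na(out)
  out[date_only] <- as.POSIXct(x[date_only], format = "%Y-%m-%d", tz = "UTC")
  if (anyNA(out)) {
    bad <- x[which(is.na(out))[1]]
    qs_stop(paste0("unparseable timestamp '", bad, "' in '", path, "'"),
            "qs_format_error")
  }
  out
}

#' Write query records in the JSONL fixture dialect
#'
#' One JSON object per line with keys `user_id`, `timestamp` (ISO-8601
#' UTC) and `text`; [read_takeout()] reads the result back losslessly.
#'
#' @param records tibble with `user_id`, `timestamp` (`POSIXct`) and
#'   `text` columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_records_jsonl <- function(records, path) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    jsonlite::toJSON(list(
      user_id = records$user_id[[i]],
      timestamp = format(records$timestamp[[i]], "%Y-%m-%dT%H:%M:%S",
                         tz = "UTC"),
      text = records$text[[i]]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write / read a cohort as line-delimited JSON
#'
#' One JSON object per user per line: `user_id`, `referral_date`,
#' `outcome`, `queries` (array of `{date, text}`) and optionally
#' `questionnaire` (map of symptom name to 0/1).  Intermediate pipeline
#' artifacts use this format so every stage is inspectable with standard
#' tools.
#'
#' @param cohort a `qs_cohort`.
#' @param path file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a `qs_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  qs <- split(cohort$queries[c("date", "text")], cohort$queries$user_id)
  qn <- cohort$questionnaire
  lines <- vapply(seq_len(nrow(cohort$users)), function(i) {
    u <- cohort$users[i, ]
    uq <- qs[[u$user_id]]
    obj <- list(user_id = u$user_id,
                referral_date = format(u$referral_date),
                outcome = u$outcome,
                queries = if (is.null(uq)) list() else
                  list(date = format(uq$date), text = uq$text))
    if (!is.null(qn)) {
      row <- qn[qn$user_id == u$user_id, setdiff(names(qn), "user_id")]
      if (nrow(row) == 1L) obj$questionnaire <- as.list(row)
    }
    jsonlite::toJSON(obj, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  objs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  users <- dplyr::bind_rows(lapply(objs, function(o)
    tibble::tibble(user_id = o$user_id, referral_date = o$referral_date,
                   outcome = o$outcome)))
  queries <- dplyr::bind_rows(lapply(objs, function(o) {
    if (length(o$queries) == 0L || length(o$queries$date) == 0L)
      return(NULL)
    tibble::tibble(user_id = o$user_id, date = as.Date(o$queries$date),
                   text = o$queries$text)
  }))
  if (nrow(queries) == 0L)
    queries <- tibble::tibble(user_id = character(), date = as.Date(character()),
                              text = character())
  qn <- NULL
  if (!is.null(objs[[1]]$questionnaire)) {
    qn <- dplyr::bind_rows(lapply(objs, function(o)
      tibble::as_tibble(c(list(user_id = o$user_id), o$questionnaire))))
  }
  cohort(users, queries, qn)
}

#' Read a clinical questionnaire table
#'
#' Expects a delimited table with a `user_id` column and one binary column
#' per configured symptom (the 20 questionnaire symptoms by default).
#' Unknown or missing symptom columns, non-binary cells and duplicated
#' users are rejected rather than silently coerced.
#'
#' @param path CSV file path.
#' @param symptoms character vector of expected symptom column names;
#'   defaults to the bundled 20-symptom set ([questionnaire_symptoms()]).
#' @return tibble with `user_id` and one integer 0/1 column per symptom.
#' @export
read_questionnaire <- function(path, symptoms = questionnaire_symptoms()) {
  df <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE,
                                          stringsAsFactors = FALSE))
  if (!"user_id" %in% names(df))
    qs_stop("questionnaire is missing a user_id column", "qs_format_error")
  extra <- setdiff(names(df), c("user_id", symptoms))
  if (length(extra) > 0L)
    qs_stop(paste0("unknown symptom column(s): ",
                   paste(extra, collapse = ", ")), "qs_format_error")
  missing <- setdiff(symptoms, names(df))
  if (length(missing) > 0L)
    qs_stop(paste0("missing symptom column(s): ",
                   paste(missing, collapse = ", ")), "qs_format_error")
  if (anyDuplicated(df$user_id))
    qs_stop(paste0("duplicate user_id row(s): ",
                   paste(unique(df$user_id[duplicated(df$user_id)]),
                         collapse = ", ")), "qs_format_error")
  for (s in symptoms) {
    bad <- which(!(df[[s]] %in% c(0L, 1L)))
    if (length(bad) > 0L)
      qs_stop(paste0("non-binary value in column '", s, "', row ", bad[1]),
              "qs_value_error")
    df[[s]] <- as.integer(df[[s]])
  }
  df[c("user_id", symptoms)]
}
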