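#' Assemble a study cohort
#'
#' Bundles per-user referral dates and outcome labels with the pooled query
#' log (and, optionally, questionnaire responses) into the container the
#' rest of the pipeline operates on.  Day 0 of every user's timeline is
#' their GP referral date; all downstream windowing is expressed in whole
#' days before that date, so time of day is dropped at assembly.
#'
#' @param users data frame with columns `user_id`, `referral_date` (`Date`
#'   or parseable string) and `outcome` (`"benign"` or `"malignant"`).
#' @param queries data frame with columns `user_id`, `text` and either
#'   `date` (`Date`) or `timestamp` (`POSIXct`); every `user_id` must
#'   appear in `users`.
#' @param questionnaire optional data frame as returned by
#'   [read_questionnaire()].
#' @return an object of class `qs_cohort`: a list with tibbles `users`,
#'   `queries` (columns `user_id`, `date`, `text`, sorted by user then
#'   date) and `questionnaire` (or `NULL`).
#' @export
cohort <- function(users, queries, questionnaire = NULL) {
  users <- tibble::as_tibble(users)
  stopifnot(all(c("user_id", "referral_date", "outcome") %in% names(users)))
  users$referral_date <- as.Date(users$referral_date)
  if (anyNA(users$referral_date))
    qs_stop("unparseable referral_date", "qs_format_error")
  if (anyDuplicated(users$user_id))
    qs_stop("duplicate user_id in users table", "qs_format_error")
  if (!all(users$outcome %in% c("benign", "malignant")))
    qs_stop("outcome must be 'benign' or 'malignant'", "qs_format_error")

  queries <- tibble::as_tibble(queries)
  if (!"date" %in% names(queries)) {
    stopifnot("timestamp" %in% names(queries))
    queries$date <- as.Date(queries$timestamp, tz = "UTC")
  }
  stopifnot(all(c("user_id", "date", "text") %in% names(queries)))
  if (!all(queries$user_id %in% users$user_id))
    qs_stop("queries reference user_id absent from users table",
            "qs_format_error")
  queries <- dplyr::arrange(queries[c("user_id", "date", "text")],
                            .data$user_id, .data$date)

  if (!is.null(questionnaire)) {
    questionnaire <- tibble::as_tibble(questionnaire)
    stopifnot("user_id" %in% names(questionnaire))
  }
  structure(list(users = users, queries = queries,
                 questionnaire = questionnaire),
            class = "qs_cohort")
}

#' @export
print.qs_cohort <- function(x, ...) {
  tab <- table(x$users$outcome)
  cat("<qs_cohort> ", nrow(x$users), " users (",
      paste(names(tab), tab, sep = " = ", collapse = ", "), "), ",
      nrow(x$queries), " queries", if (!is.null(x$questionnaire))
        paste0(", questionnaire (", nrow(x$questionnaire), " rows)"),
      "\n", sep = "")
  invisible(x)
}

#' Number of users in a cohort
#' @param x a `qs_cohort`.
#' @return integer count.
#' @export
n_users <- function(x) nrow(x$users)

# queries joined with referral dates, plus day offset (days before referral)
query_offsets <- function(cohort) {
  q <- dplyr::left_join(cohort$queries,
                        cohort$users[c("user_id", "referral_date")],
                        by = "user_id")
  q$offset <- as.integer(q$referral_date - q$date)
  q
}

# replace the queries table, preserving users/questionnaire
set_queries <- function(cohort, queries) {
  cohort$queries <- queries[c("user_id", "date", "text")]
  cohort
}

# subset a cohort to the given users (order of `ids` respected)
subset_users <- function(cohort, ids) {
  cohort$users <- cohort$users[match(ids, cohort$users$user_id), ]
  cohort$queries <- cohort$queries[cohort$queries$user_id %in% ids, ]
  if (!is.null(cohort$questionnaire))
    cohort$questionnaire <-
      cohort$questionnaire[cohort$questionnaire$user_id %in% ids, ]
  cohort
}

#' Restrict each history to a pre-referral lookback period
#'
#' Keeps records whose day offset `d = referral_date - record date` lies in
#' `[1, lookback_days]`.  The referral date itself (day 0) is excluded:
#' searches on the day of referral are taken to reflect the GP
#' consultation, not the pre-referral state.
#'
#' @param records data frame of query records with a `date` (or
#'   `timestamp`) column.
#' @param referral_date `Date` scalar; day 0 of the offset axis.
#' @param lookback_days positive integer; default 730 (24 months).
#' @return the subsequence of `records` with offsets in
#'   `[1, lookback_days]`.
#' @export
truncate_history <- function(records, referral_date, lookback_days = 730) {
  stopifnot(lookback_days >= 1)
  records <- tibble::as_tibble(records)
  if (!"date" %in% names(records))
    records$date <- as.Date(records$timestamp, tz = "UTC")
  d <- as.integer(as.Date(referral_date) - records$date)
  records[d >= 1 & d <= lookback_days, ]
}

#' Apply the lookback truncation to every user of a cohort
#'
#' @param cohort a `qs_cohort`.
#' @param lookback_days positive integer; default 730.
#' @return the cohort with each user's queries restricted to day offsets
#'   `[1, lookback_days]` before their own referral date.
#' @export
truncate_cohort <- function(cohort, lookback_days = 730) {
  q <- query_offsets(cohort)
  set_queries(cohort, q[q$offset >= 1 & q$offset <= lookback_days, ])
}
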