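#' Pre-referral evaluation window
#'
#' A window selects queries made between `start_days_before` (T1, the far
#' edge) and `end_days_before` (T2, the near edge) days before referral,
#' both inclusive.  Day offsets are stored as positive days-before; day 0
#' (the referral date) can never fall inside a window.
#'
#' @param start_days_before integer T1; farther from referral, at most 700.
#' @param end_days_before integer T2; nearer referral, at least 1 and
#'   strictly less than T1.
#' @return an object of class `qs_window`.
#' @export
#' @examples
#' window(630, 60)
window <- function(start_days_before, end_days_before) {
  if (!(is.numeric(start_days_before) && is.numeric(end_days_before) &&
        start_days_before > end_days_before && end_days_before >= 1 &&
        start_days_before <= 700))
    qs_stop("invalid window: need 700 >= start_days_before > end_days_before >= 1",
            "qs_value_error")
  structure(list(t1 = as.integer(start_days_before),
                 t2 = as.integer(end_days_before)),
            class = "qs_window")
}

#' @export
print.qs_window <- function(x, ...) {
  cat("<qs_window> days", x$t1, "to", x$t2, "before referral\n")
  invisible(x)
}

#' Select the queries inside a window
#'
#' @param cohort a `qs_cohort` (truncated and filtered).
#' @param win a [window()].
#' @return the cohort with queries restricted to day offsets
#'   `[end_days_before, start_days_before]`; users are kept even when
#'   left with no in-window query (they featurize to zero vectors).
#' @export
select_window <- function(cohort, win) {
  stopifnot(inherits(win, "qs_window"))
  q <- query_offsets(cohort)
  set_queries(cohort, q[q$offset >= win$t2 & q$offset <= win$t1, ])
}

# long table of (user_id, term, n) for unigrams and consecutive-word
# bigrams over the in-window queries; bigrams never span query boundaries
user_term_long <- function(cohort, win) {
  q <- select_window(cohort, win)$queries
  utext <- unique(normalize_text(q$text))
  uterms <- lapply(tokenize(utext), function(tok) {
    if (length(tok) >= 2L)
      c(tok, paste(tok[-length(tok)], tok[-1L]))
    else tok
  })
  idx <- match(normalize_text(q$text), utext)
  reps <- lengths(uterms)[idx]
  long <- tibble::tibble(
    user_id = rep(q$user_id, reps),
    term = as.character(unlist(uterms[idx], use.names = FALSE)))
  dplyr::count(long, .data$user_id, .data$term)
}

#' Build the terms vocabulary for a window
#'
#' The vocabulary contains every unigram and consecutive-word bigram used
#' in-window by at least `min_patients` distinct patients, in fixed
#' lexicographic order for reproducibility.
#'
#' @param cohort a `qs_cohort` (inside cross-validation, the training fold
#'   only — the held-out patient must not contribute).
#' @param win a [window()].
#' @param min_patients document-frequency cutoff (default 5 patients).
#' @return tibble with columns `term` and `df` (number of distinct
#'   patients using the term), sorted by term.
#' @export
build_vocabulary <- function(cohort, win, min_patients = 5) {
  long <- user_term_long(cohort, win)
  df <- dplyr::count(long, .data$term, name = "df")
  df <- df[df$df >= min_patients, ]
  dplyr::arrange(df, .data$term)
}

#' Count vector-space features against a vocabulary
#'
#' Entry `(u, t)` is the total number of occurrences of term `t` across
#' user `u`'s in-window queries; out-of-vocabulary terms are ignored.
#'
#' @param cohort a `qs_cohort`.
#' @param win a [window()].
#' @param vocab tibble from [build_vocabulary()] (or any tibble with a
#'   `term` column).
#' @return integer matrix, one row per cohort user (rownames = user ids),
#'   one column per vocabulary term.
#' @export
vectorize_terms <- function(cohort, win, vocab) {
  long <- user_term_long(cohort, win)
  count_matrix(long, cohort$users$user_id, vocab$term)
}

count_matrix <- function(long, user_ids, terms) {
  x <- matrix(0L, nrow = length(user_ids), ncol = length(terms),
              dimnames = list(user_ids, terms))
  long <- long[long$term %in% terms & long$user_id %in% user_ids, ]
  if (nrow(long) > 0L)
    x[cbind(match(long$user_id, user_ids), match(long$term, terms))] <-
      long$n
  x
}

#' Count queries per symptom category in a window
#'
#' Entry `(u, c)` is the number of query-category assignments of user
#' `u`'s in-window queries to category `c`; a multi-category query
#' increments each of its categories.
#'
#' @param cohort a `qs_cohort`.
#' @param win a [window()].
#' @param lexicon a `qs_lexicon`.
#' @return integer matrix, one row per user, one column per category.
#' @export
vectorize_categories <- function(cohort, win, lexicon) {
  q <- select_window(cohort, win)$queries
  cats <- assign_categories(q$text, lexicon)
  long <- dplyr::count(
    tibble::tibble(user_id = rep(q$user_id, lengths(cats)),
                   term = as.character(unlist(cats, use.names = FALSE))),
    .data$user_id, .data$term)
  count_matrix(long, cohort$users$user_id, lexicon$categories)
}

# ---- feature-set container -------------------------------------------------

new_features <- function(user_ids, labels, representation, static_x = NULL,
                         user_terms = NULL, min_patients = NULL,
                         provenance = NULL) {
  structure(list(user_ids = user_ids, labels = labels,
                 representation = representation, static_x = static_x,
                 user_terms = user_terms, min_patients = min_patients,
                 provenance = provenance),
            class = "qs_features")
}

#' @export
print.qs_features <- function(x, ...) {
  cat("<qs_features> ", length(x$user_ids), " users, representation = ",
      x$representation, ", ", ncol(features_matrix(x)), " features\n",
      sep = "")
  invisible(x)
}

#' Terms (vector-space) feature set
#'
#' Bag of unigrams and consecutive bigrams with a document-frequency
#' cutoff.  The returned object carries each user's raw term counts so
#' that cross-validation can rebuild the vocabulary inside every training
#' fold — a term used only by the held-out patient never enters that
#' fold's feature space.
#'
#' @param cohort a filtered `qs_cohort` with outcome labels.
#' @param win a [window()].
#' @param min_patients document-frequency cutoff (default 5).
#' @param binary if `TRUE`, clip counts to presence/absence (default
#'   `FALSE`, raw counts).
#' @return a `qs_features` object; use [features_matrix()] to materialize
#'   the full-data matrix.
#' @export
terms_features <- function(cohort, win, min_patients = 5, binary = FALSE) {
  long <- user_term_long(cohort, win)
  if (binary) long$n <- pmin(long$n, 1L)
  user_terms <- lapply(split(long, factor(long$user_id,
                                          levels = cohort$users$user_id)),
                       function(d) stats::setNames(d$n, d$term))
  new_features(user_ids = cohort$users$user_id,
               labels = as.integer(cohort$users$outcome == "malignant"),
               representation = "terms",
               user_terms = user_terms, min_patients = min_patients)
}

#' Category feature set
#'
#' 14-dimensional count representation over the curated symptom
#' categories.
#'
#' @inheritParams terms_features
#' @param lexicon a `qs_lexicon`.
#' @return a `qs_features` object.
#' @export
category_features <- function(cohort, win, lexicon) {
  x <- vectorize_categories(cohort, win, lexicon)
  new_features(user_ids = cohort$users$user_id,
               labels = as.integer(cohort$users$outcome == "malignant"),
               representation = "categories", static_x = x,
               provenance = rep("categories", ncol(x)))
}

#' Materialize the feature matrix of a feature set
#'
#' For terms(-bearing) representations the vocabulary is built from all
#' users in the set (appropriate outside cross-validation, e.g. when
#' training the full-cohort model applied to external controls).
#'
#' @param features a `qs_features` object.
#' @param vocab optional fixed vocabulary (tibble with a `term` column)
#'   for the terms block, bypassing vocabulary construction.
#' @return numeric matrix, one row per user.
#' @export
features_matrix <- function(features, vocab = NULL) {
  blocks <- list()
  if (!is.null(features$user_terms)) {
    terms <- if (!is.null(vocab)) vocab$term else
      vocab_from_user_terms(features$user_terms, features$min_patients)
    blocks$terms <- user_terms_matrix(features$user_terms, terms)
  }
  if (!is.null(features$static_x)) blocks$static <- features$static_x
  x <- do.call(cbind, unname(blocks))
  rownames(x) <- features$user_ids
  x
}

vocab_from_user_terms <- function(user_terms, min_patients) {
  df <- table(unlist(lapply(user_terms, names), use.names = FALSE))
  sort(names(df)[df >= min_patients])
}

user_terms_matrix <- function(user_terms, terms) {
  x <- matrix(0L, nrow = length(user_terms), ncol = length(terms),
              dimnames = list(names(user_terms), terms))
  for (i in seq_along(user_terms)) {
    ut <- user_terms[[i]]
    hit <- names(ut) %in% terms
    if (any(hit)) x[i, names(ut)[hit]] <- unname(ut[hit])
  }
  x
}
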