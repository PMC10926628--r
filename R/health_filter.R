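#' Two-stage health filter with consecutive-duplicate removal
#'
#' Reduces a raw query log to the health-related analysis set in three
#' ordered stages:
#'
#' 1. *Inclusion*: keep queries sharing at least one normalized word with
#'    the medical terms list.  Each word of a multi-word medical phrase
#'    matches independently, so a phrase like "club foot" deliberately lets
#'    "club music tonight" through to the next stage.
#' 2. *Exclusion*: drop queries matching an exclusion pattern — either a
#'    (trigger, context) word pair such as (cat, bleeding), mechanizing the
#'    manual removal of pet and irrelevant-organ queries, or a standalone
#'    stop phrase.
#' 3. *Dedup*: drop a query whose normalized text equals that of the
#'    immediately preceding retained query from the same user, whatever
#'    the time gap (verbatim repeats in consecutive searches).
#'
#' @param queries tibble of query records (`user_id`, `date` or
#'   `timestamp`, `text`), time-sorted within user.
#' @param lexicon a `qs_lexicon`.
#' @return a list with `queries` (the retained subsequence) and `report`,
#'   a one-row tibble of stage counts (`n_input`, `n_after_inclusion`,
#'   `n_after_exclusion`, `n_after_dedup`).
#' @export
filter_health <- function(queries, lexicon) {
  stopifnot(inherits(lexicon, "qs_lexicon"))
  if (length(lexicon$medical_words) == 0L)
    qs_stop("lexicon inclusion word set is empty", "qs_config_error")
  queries <- tibble::as_tibble(queries)
  n_input <- nrow(queries)
  norm <- normalize_text(queries$text)

  # all text-level predicates computed once per distinct normalized text
  utext <- unique(norm)
  utok <- tokenize(utext)
  keep_u <- vapply(utok, function(t) any(t %in% lexicon$medical_words),
                   logical(1))
  excl_u <- rep(FALSE, length(utext))
  if (nrow(lexicon$exclusion_pairs) > 0L) {
    words <- unique(c(lexicon$exclusion_pairs$trigger,
                      lexicon$exclusion_pairs$context))
    has <- vapply(words, function(w)
      vapply(utok, function(t) w %in% t, logical(1)),
      logical(length(utext)))
    has <- matrix(has, nrow = length(utext),
                  dimnames = list(NULL, words))
    for (i in seq_len(nrow(lexicon$exclusion_pairs))) {
      excl_u <- excl_u | (has[, lexicon$exclusion_pairs$trigger[i]] &
                          has[, lexicon$exclusion_pairs$context[i]])
    }
  }
  excl_u <- excl_u | contains_phrase(utext, lexicon$exclusion_phrases)

  idx <- match(norm, utext)
  stage1 <- keep_u[idx]
  n_after_inclusion <- sum(stage1)
  stage2 <- stage1 & !excl_u[idx]
  n_after_exclusion <- sum(stage2)

  kept <- which(stage2)
  if (length(kept) > 1L) {
    same_user <- queries$user_id[kept[-1]] == queries$user_id[kept[-length(kept)]]
    same_text <- norm[kept[-1]] == norm[kept[-length(kept)]]
    kept <- kept[c(TRUE, !(same_user & same_text))]
  }
  report <- tibble::tibble(n_input = n_input,
                           n_after_inclusion = n_after_inclusion,
                           n_after_exclusion = n_after_exclusion,
                           n_after_dedup = length(kept))
  list(queries = queries[kept, ], report = report)
}

#' Drop users whose filtered history is empty
#'
#' Users with no query surviving the health filter carry no usable signal
#' and are excluded from the analysis cohort; both partitions are returned
#' so the enrolment accounting can report the exclusion.
#'
#' @param cohort a `qs_cohort` whose queries have already been filtered.
#' @return list with `cohort` (retained users) and `excluded` (character
#'   vector of excluded user ids).
#' @export
exclude_empty_users <- function(cohort) {
  active <- unique(cohort$queries$user_id)
  excluded <- setdiff(cohort$users$user_id, active)
  list(cohort = subset_users(cohort, setdiff(cohort$users$user_id, excluded)),
       excluded = excluded)
}

#' Filter a cohort end to end
#'
#' Convenience wrapper: truncates each history to the lookback period,
#' applies [filter_health()], and removes users left with an empty
#' history.
#'
#' @param cohort a `qs_cohort`.
#' @param lexicon a `qs_lexicon`.
#' @param lookback_days lookback period in days before referral
#'   (default 730); `NULL` to skip truncation.
#' @return list with `cohort` (filtered), `report` (stage counts) and
#'   `excluded` (user ids dropped for an empty filtered history).
#' @export
filter_cohort <- function(cohort, lexicon, lookback_days = 730) {
  if (!is.null(lookback_days))
    cohort <- truncate_cohort(cohort, lookback_days)
  fh <- filter_health(cohort$queries, lexicon)
  out <- exclude_empty_users(set_queries(cohort, fh$queries))
  list(cohort = out$cohort, report = fh$report, excluded = out$excluded)
}
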