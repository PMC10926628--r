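#' Control population container
#'
#' Wraps the query log of an external (non-referred) population together
#' with its fixed data period and post-period lookahead.  The end of the
#' data period plays the role of "the day before referral": scoring maps
#' the last in-period day to day offset 1.
#'
#' @param queries tibble with `user_id`, `date` (`Date`), `text`.
#' @param period_start,period_end first and last day of the data period.
#' @param lookahead_end last day of the post-period lookahead used by the
#'   exclusion rule (default three months after `period_end`).
#' @return an object of class `qs_controls`.
#' @export
controls <- function(queries, period_start, period_end,
                     lookahead_end = as.Date(period_end) + 92) {
  queries <- tibble::as_tibble(queries)
  stopifnot(all(c("user_id", "date", "text") %in% names(queries)))
  period_start <- as.Date(period_start)
  period_end <- as.Date(period_end)
  lookahead_end <- as.Date(lookahead_end)
  stopifnot(period_start < period_end, period_end < lookahead_end)
  if (any(queries$date < period_start | queries$date > lookahead_end))
    qs_stop("control queries outside the data period and lookahead",
            "qs_value_error")
  structure(list(queries = dplyr::arrange(queries, .data$user_id,
                                          .data$date),
                 period_start = period_start, period_end = period_end,
                 lookahead_end = lookahead_end),
            class = "qs_controls")
}

#' @export
print.qs_controls <- function(x, ...) {
  cat("<qs_controls> ", length(unique(x$queries$user_id)), " users, ",
      nrow(x$queries), " queries, period ", format(x$period_start), " to ",
      format(x$period_end), " (+lookahead to ",
      format(x$lookahead_end), ")\n", sep = "")
  invisible(x)
}

#' Exclude controls with repeated gynaecological-cancer queries
#'
#' Drops control users who queried gynaecological-cancer terms
#' `threshold` or more times, to guard against including people with a
#' pre-existing or imminent diagnosis.  By default the data period and
#' the lookahead are counted jointly; `rule = "either"` excludes when
#' either period alone reaches the threshold.
#'
#' @param ctl a [controls()] object.
#' @param lexicon a `qs_lexicon` with non-empty `gynae_terms`.
#' @param threshold exclusion count (default 10).
#' @param rule `"joint"` (default) or `"either"`.
#' @return list with `controls` (retained) and `excluded` (user ids).
#' @export
exclude_flagged_controls <- function(ctl, lexicon, threshold = 10,
                                     rule = c("joint", "either")) {
  rule <- match.arg(rule)
  stopifnot(inherits(ctl, "qs_controls"),
            length(lexicon$gynae_terms) > 0L)
  q <- ctl$queries
  hit <- contains_phrase(normalize_text(q$text), lexicon$gynae_terms)
  in_period <- q$date <= ctl$period_end
  count_of <- function(keep) {
    tab <- table(q$user_id[hit & keep])
    ids <- unique(q$user_id)
    stats::setNames(as.integer(tab[match(ids, names(tab))]), ids) |>
      (\(v) { v[is.na(v)] <- 0L; v })()
  }
  excluded <- if (rule == "joint") {
    counts <- count_of(rep(TRUE, nrow(q)))
    names(counts)[counts >= threshold]
  } else {
    a <- count_of(in_period)
    b <- count_of(!in_period)
    names(a)[a >= threshold | b >= threshold]
  }
  retained <- ctl
  retained$queries <- q[!(q$user_id %in% excluded), ]
  list(controls = retained, excluded = excluded)
}

#' Score a control population with a cohort-trained model
#'
#' Featurizes each control's queries exactly as a patient window ending
#' one day before a pseudo-referral placed the day after the period end,
#' then applies the trained model.  Controls should have been passed
#' through [filter_health()] with the same lexicon as the cohort.
#' Controls with no in-window vocabulary terms are scored from a zero
#' vector (flagged, not dropped).
#'
#' @param model a `qs_model` from [fit_cohort_model()].
#' @param ctl a [controls()] object.
#' @return tibble with `user_id`, `score`, `n_queries` (in-window query
#'   count) and `zero_vector` flag.
#' @export
score_controls <- function(model, ctl) {
  stopifnot(inherits(model, "qs_model"), inherits(ctl, "qs_controls"))
  pseudo_referral <- ctl$period_end + 1
  q <- ctl$queries[ctl$queries$date <= ctl$period_end, ]
  ids <- unique(ctl$queries$user_id)
  pseudo <- cohort(
    users = tibble::tibble(user_id = ids,
                           referral_date = pseudo_referral,
                           outcome = "benign"),  # placeholder label
    queries = q)
  win <- model$window
  x <- if (model$representation == "terms")
    vectorize_terms(pseudo, win, model$vocab)
  else
    vectorize_categories(pseudo, win, model$lexicon)
  scores <- predict_gbm(model$booster, x)
  n_inwin <- rowSums(x)
  tibble::tibble(user_id = ids, score = scores,
                 n_queries = as.integer(n_inwin),
                 zero_vector = n_inwin == 0)
}

#' Histogram of classification scores by population
#'
#' Equal-width bins over `[0, 1]` (right-inclusive last bin; a score of
#' exactly 1 lands in the top bin), with per-population counts and
#' frequencies.
#'
#' @param populations named list of numeric score vectors in `[0, 1]`
#'   (e.g. `list(control = ..., benign = ..., malignant = ...)`).
#' @param bins number of bins (default 10).
#' @return tibble with `population`, `bin`, `lower`, `upper`, `count`,
#'   `frequency`.
#' @export
score_histogram <- function(populations, bins = 10) {
  stopifnot(is.list(populations), length(names(populations)) > 0L)
  edges <- seq(0, 1, length.out = bins + 1)
  rows <- lapply(names(populations), function(nm) {
    s <- populations[[nm]]
    if (length(s) == 0L)
      qs_stop(paste0("empty population: ", nm), "qs_value_error")
    stopifnot(all(s >= 0 & s <= 1))
    bin <- pmin(pmax(ceiling(s * bins), 1L), bins)
    counts <- tabulate(bin, nbins = bins)
    tibble::tibble(population = nm, bin = seq_len(bins),
                   lower = edges[-length(edges)], upper = edges[-1],
                   count = counts, frequency = counts / length(s))
  })
  dplyr::bind_rows(rows)
}
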