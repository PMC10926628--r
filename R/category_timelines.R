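#' Assign queries to symptom categories
#'
#' A query belongs to every category that any of its normalized tokens
#' maps to in the lexicon's keyword-category map; categories are not
#' mutually exclusive and a query with no category keyword gets none.
#'
#' @param text character vector of query strings.
#' @param lexicon a `qs_lexicon` with a non-empty `category_map`.
#' @return a list, one character vector of category names per query.
#' @export
#' @examples
#' lex <- default_lexicon()
#' assign_categories(c("stomach bloating remedies", "best pizza near me"), lex)
assign_categories <- function(text, lexicon) {
  stopifnot(inherits(lexicon, "qs_lexicon"),
            length(lexicon$category_map) > 0L)
  utext <- unique(normalize_text(text))
  utok <- tokenize(utext)
  ucat <- lapply(utok, function(t) {
    hits <- lexicon$category_map[intersect(t, names(lexicon$category_map))]
    sort(unique(as.character(unlist(hits, use.names = FALSE))))
  })
  ucat[match(normalize_text(text), utext)]
}

#' Outcome-stratified weekly category time series
#'
#' Bins each categorized query into weeks before referral (week `k` covers
#' day offsets `[7k-6, 7k]`, so week 1 is the last pre-referral week),
#' sums counts per (outcome stratum, category, week), divides by the
#' number of users in the stratum to give queries per patient, and
#' smooths with a trailing moving average whose window covers the current
#' week and the `smooth_weeks - 1` weeks further from referral (the
#' window shrinks at the far end of the series; no post-referral bin is
#' ever used).
#'
#' @param cohort a filtered `qs_cohort` with outcome labels.
#' @param lexicon a `qs_lexicon`.
#' @param horizon_days horizon in days before referral (default 490, i.e.
#'   70 weeks).
#' @param smooth_weeks moving-average window in weeks (default 4; use 1
#'   for the raw series).
#' @return tibble with columns `stratum`, `category`, `week_offset`
#'   (weeks before referral, descending toward referral) and `value`
#'   (smoothed mean queries per patient per week).
#' @export
weekly_category_series <- function(cohort, lexicon, horizon_days = 490,
                                   smooth_weeks = 4) {
  stopifnot(horizon_days >= 7, smooth_weeks >= 1)
  n_weeks <- ceiling(horizon_days / 7)
  strata <- c("benign", "malignant")
  n_by_stratum <- table(factor(cohort$users$outcome, levels = strata))
  if (any(n_by_stratum == 0))
    qs_stop(paste0("empty stratum: ",
                   paste(strata[n_by_stratum == 0], collapse = ", ")),
            "qs_value_error")

  q <- query_offsets(cohort)
  q <- q[q$offset >= 1 & q$offset <= n_weeks * 7, ]
  cats <- assign_categories(q$text, lexicon)
  reps <- lengths(cats)
  long <- tibble::tibble(
    user_id = rep(q$user_id, reps),
    week = rep(ceiling(q$offset / 7), reps),
    category = unlist(cats, use.names = FALSE))
  long <- dplyr::left_join(long, cohort$users[c("user_id", "outcome")],
                           by = "user_id")

  counts <- dplyr::count(long, .data$outcome, .data$category, .data$week)
  grid <- tidyr::expand_grid(stratum = strata,
                             category = lexicon$categories,
                             week_offset = seq_len(n_weeks))
  grid <- dplyr::left_join(
    grid, dplyr::rename(counts, stratum = "outcome", week_offset = "week"),
    by = c("stratum", "category", "week_offset"))
  grid$n <- ifelse(is.na(grid$n), 0L, grid$n)
  grid$raw <- grid$n / as.numeric(n_by_stratum[grid$stratum])

  grid <- dplyr::group_by(grid, .data$stratum, .data$category)
  grid <- dplyr::arrange(grid, .data$week_offset, .by_group = TRUE)
  grid <- dplyr::mutate(grid, value = trailing_mean(.data$raw, smooth_weeks))
  grid <- dplyr::ungroup(grid)
  dplyr::arrange(grid[c("stratum", "category", "week_offset", "value")],
                 .data$stratum, .data$category,
                 dplyr::desc(.data$week_offset))
}

# trailing moving average toward larger week offsets (further from
# referral); the window shrinks where it would run past the series start
trailing_mean <- function(x, width) {
  if (width == 1L) return(x)
  n <- length(x)
  vapply(seq_len(n), function(k) mean(x[k:min(k + width - 1L, n)]),
         numeric(1))
}

#' Estimate per-category symptom onset from a weekly series
#'
#' For each category, forms the malignant-minus-benign difference of the
#' per-patient weekly series and fits a two-segment constant model: a
#' baseline level for weeks further from referral than a change-point and
#' an elevated level from the change-point onwards.  The change-point
#' minimizing the residual sum of squares is reported as the onset.
#'
#' @param series tibble from [weekly_category_series()] containing both
#'   strata (an unsmoothed series, `smooth_weeks = 1`, gives the sharpest
#'   change-points).
#' @return tibble with `category`, `onset_week` (weeks before referral)
#'   and `onset_days` (`7 * onset_week`).
#' @export
estimate_onsets <- function(series) {
  wide <- tidyr::pivot_wider(series, names_from = "stratum",
                             values_from = "value")
  out <- lapply(split(wide, wide$category), function(d) {
    d <- d[order(d$week_offset), ]  # week 1 first
    diff <- d$malignant - d$benign
    cp <- changepoint_week(diff)
    tibble::tibble(category = d$category[1], onset_week = cp,
                   onset_days = 7L * cp)
  })
  dplyr::bind_rows(out)
}

# least-squares two-segment constant fit on x ordered week 1..K; returns
# the change-point c such that weeks 1..c form the elevated segment
changepoint_week <- function(x) {
  K <- length(x)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  sse <- vapply(seq_len(K - 1L), function(c) {
    s1 <- cs[c]; s2 <- cs[K] - cs[c]
    q1 <- cs2[c]; q2 <- cs2[K] - cs2[c]
    (q1 - s1^2 / c) + (q2 - s2^2 / (K - c))
  }, numeric(1))
  which.min(sse)
}
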