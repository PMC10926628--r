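#' Enrolment flow counts
#'
#' Records the patient accounting of a recruitment flowchart: how many
#' individuals were approached, met the eligibility criteria (held a
#' Google account), consented, completed enrolment (takeout file plus
#' questionnaire), were excluded for insufficient post-filter search data,
#' and remained in the final cohort, together with optional breakdowns of
#' the incomplete-enrolment group and malignancy counts.
#'
#' @param approached,eligible,consented,complete,excluded_insufficient,final
#'   non-negative integer counts, with
#'   `final <= complete <= consented <= eligible <= approached`.
#' @param final_malignant malignant diagnoses in the final cohort.
#' @param excluded_total,excluded_malignant size of, and malignant count
#'   in, the incomplete-enrolment group.
#' @param technical,withdrew,not_tracking breakdown of incomplete
#'   enrolment: takeout export failures, withdrawals, search tracking
#'   disabled.
#' @param non_health_searchers users in the final cohort who queried none
#'   of the listed medical conditions; the remainder form the
#'   health-engaged subcohort.
#' @param engaged_malignant malignant diagnoses among health-engaged users.
#' @return an object of class `qs_enrolment_flow` (named list of counts,
#'   `NA` where not supplied).
#' @export
enrolment_flow <- function(approached, eligible, consented, complete,
                           excluded_insufficient, final,
                           final_malignant = NA, excluded_total = NA,
                           excluded_malignant = NA, technical = NA,
                           withdrew = NA, not_tracking = NA,
                           non_health_searchers = NA,
                           engaged_malignant = NA) {
  counts <- c(approached = approached, eligible = eligible,
              consented = consented, complete = complete,
              excluded_insufficient = excluded_insufficient, final = final,
              final_malignant = final_malignant,
              excluded_total = excluded_total,
              excluded_malignant = excluded_malignant,
              technical = technical, withdrew = withdrew,
              not_tracking = not_tracking,
              non_health_searchers = non_health_searchers,
              engaged_malignant = engaged_malignant)
  if (any(counts < 0, na.rm = TRUE))
    qs_stop("enrolment counts must be non-negative", "qs_value_error")
  if (!(final <= complete && complete <= consented &&
        consented <= eligible && eligible <= approached))
    qs_stop("enrolment counts must be nested: final <= complete <= consented <= eligible <= approached",
            "qs_value_error")
  structure(as.list(counts), class = "qs_enrolment_flow")
}

#' Enrolment and malignancy-rate accounting
#'
#' Recomputes every reported percentage of the enrolment flowchart from
#' its numerator/denominator pair, rounding half-up to one decimal the way
#' the percentages are conventionally printed.  Ratios whose inputs were
#' not supplied are omitted; a requested ratio with a zero denominator is
#' an error.
#'
#' @param flow a [enrolment_flow()] object.
#' @return tibble with columns `metric`, `numerator`, `denominator`,
#'   `percent`.
#' @export
#' @examples
#' flow <- enrolment_flow(approached = 844, eligible = 652, consented = 392,
#'                        complete = 255, excluded_insufficient = 20,
#'                        final = 235, final_malignant = 61)
#' enrolment_accounting(flow)
enrolment_accounting <- function(flow) {
  stopifnot(inherits(flow, "qs_enrolment_flow"))
  f <- flow
  engaged <- if (!is.na(f$non_health_searchers))
    f$final - f$non_health_searchers else NA
  specs <- list(
    eligible_of_approached = c(f$eligible, f$approached),
    consented_of_eligible = c(f$consented, f$eligible),
    complete_of_consented = c(f$complete, f$consented),
    excluded_insufficient_of_complete = c(f$excluded_insufficient, f$complete),
    malignant_of_final = c(f$final_malignant, f$final),
    incomplete_of_consented = c(f$consented - f$complete, f$consented),
    technical_of_consented = c(f$technical, f$consented),
    withdrew_of_consented = c(f$withdrew, f$consented),
    not_tracking_of_consented = c(f$not_tracking, f$consented),
    malignant_of_excluded = c(f$excluded_malignant, f$excluded_total),
    non_health_of_final = c(f$non_health_searchers, f$final),
    malignant_of_engaged = c(f$engaged_malignant, engaged),
    benign_of_engaged = c(engaged - f$engaged_malignant, engaged))
  keep <- vapply(specs, function(x) !anyNA(x), logical(1))
  specs <- specs[keep]
  num <- vapply(specs, `[`, numeric(1), 1)
  den <- vapply(specs, `[`, numeric(1), 2)
  if (any(den == 0))
    qs_stop(paste0("undefined ratio (zero denominator): ",
                   paste(names(specs)[den == 0], collapse = ", ")),
            "qs_value_error")
  tibble::tibble(metric = names(specs), numerator = unname(num),
                 denominator = unname(den),
                 percent = unname(round_half_up(100 * num / den, 1)))
}

#' Mean queries per user, as printed in cohort summaries
#'
#' Integer part (floor) of `total_queries / n_users`; cohort summaries
#' print this as a whole number of searches per patient.
#'
#' @param total_queries total query count.
#' @param n_users number of users; must be positive.
#' @return integer.
#' @export
#' @examples
#' mean_queries_per_user(519048, 235)  # 2208
mean_queries_per_user <- function(total_queries, n_users) {
  if (n_users <= 0)
    qs_stop("n_users must be positive", "qs_value_error")
  as.integer(floor(total_queries / n_users))
}
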