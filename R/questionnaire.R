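#' Symptom-to-query-term map
#'
#' Maps each questionnaire symptom to the query terms taken to indicate
#' that the patient searched for it.  The bundled map is a synthetic
#' stand-in covering the 20 questionnaire symptoms; supply your own YAML
#' (symptom name -> list of terms) to override.
#'
#' @param path YAML file path.
#' @return named list: symptom name -> character vector of terms.
#' @export
read_symptom_map <- function(path) {
  m <- yaml::read_yaml(path)
  lapply(m, as.character)
}

#' @rdname read_symptom_map
#' @export
default_symptom_map <- function() {
  read_symptom_map(system.file("extdata", "lexicon", "symptom_map.yaml",
                               package = "querysift"))
}

#' The configured questionnaire symptom names
#' @return character vector of the 20 symptom names.
#' @export
questionnaire_symptoms <- function() names(default_symptom_map())

#' Questionnaire-versus-search contingency tests
#'
#' For each symptom, cross-tabulates whether a patient flagged the
#' symptom on the questionnaire against whether they searched for it
#' (at least one filtered query over the full lookback containing a
#' mapped term), and applies Pearson's chi-squared test without
#' continuity correction.  Significance is reported at the
#' Bonferroni-adjusted threshold `alpha / n_symptoms`.  Tables with a
#' zero margin are marked not evaluable.
#'
#' @param cohort a filtered `qs_cohort` with a questionnaire.
#' @param map symptom-term map (default [default_symptom_map()]).
#' @param alpha family-wise significance level (default 0.05).
#' @return tibble with columns `symptom`, the 2x2 counts `n_yy`, `n_yn`,
#'   `n_ny`, `n_nn` (questionnaire yes/no x searched yes/no), `chi2`,
#'   `p_value`, `evaluable`, `significant_bonferroni`, and `low_expected`
#'   (any expected cell count below 5, reported as a caveat).
#' @export
symptom_search_contingency <- function(cohort, map = default_symptom_map(),
                                       alpha = 0.05) {
  qn <- cohort$questionnaire
  if (is.null(qn))
    qs_stop("cohort has no questionnaire", "qs_value_error")
  symptoms <- intersect(names(map), names(qn))
  if (length(symptoms) == 0L)
    qs_stop("no mapped symptom appears in the questionnaire",
            "qs_value_error")
  norm <- normalize_text(cohort$queries$text)
  threshold <- alpha / length(symptoms)
  rows <- lapply(symptoms, function(s) {
    hit <- contains_phrase(norm, map[[s]])
    searched_ids <- unique(cohort$queries$user_id[hit])
    searched <- qn$user_id %in% searched_ids
    flagged <- qn[[s]] == 1L
    tab <- table(factor(flagged, levels = c(TRUE, FALSE)),
                 factor(searched, levels = c(TRUE, FALSE)))
    evaluable <- all(rowSums(tab) > 0) && all(colSums(tab) > 0)
    if (evaluable) {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      chi2 <- unname(ct$statistic)
      p <- unname(ct$p.value)
      low_expected <- any(ct$expected < 5)
    } else {
      chi2 <- NA_real_; p <- NA_real_; low_expected <- NA
    }
    tibble::tibble(symptom = s,
                   n_yy = tab[1, 1], n_yn = tab[1, 2],
                   n_ny = tab[2, 1], n_nn = tab[2, 2],
                   chi2 = chi2, p_value = p, evaluable = evaluable,
                   significant_bonferroni = evaluable && !is.na(p) &&
                     p < threshold,
                   low_expected = low_expected)
  })
  dplyr::bind_rows(rows)
}

#' Questionnaire feature set
#'
#' Binary indicator matrix over the questionnaire symptoms, one column
#' per symptom.
#'
#' @param cohort a `qs_cohort` whose every user has a questionnaire row.
#' @return a `qs_features` object with representation `"questionnaire"`.
#' @export
questionnaire_features <- function(cohort) {
  qn <- cohort$questionnaire
  if (is.null(qn))
    qs_stop("cohort has no questionnaire", "qs_value_error")
  missing <- setdiff(cohort$users$user_id, qn$user_id)
  if (length(missing) > 0L)
    qs_stop(paste0("missing questionnaire for user(s): ",
                   paste(missing, collapse = ", ")), "qs_value_error")
  qn <- qn[match(cohort$users$user_id, qn$user_id), ]
  x <- as.matrix(qn[setdiff(names(qn), "user_id")])
  rownames(x) <- cohort$users$user_id
  new_features(user_ids = cohort$users$user_id,
               labels = as.integer(cohort$users$outcome == "malignant"),
               representation = "questionnaire", static_x = x,
               provenance = rep("questionnaire", ncol(x)))
}

#' Combine two feature sets column-wise
#'
#' Concatenates a search-based and a questionnaire feature set over the
#' same users (same order); per-column provenance is retained.  If the
#' first set carries raw term counts, fold-wise vocabulary rebuilding is
#' preserved for its block under cross-validation.
#'
#' @param search,questionnaire `qs_features` objects with identical user
#'   vectors.
#' @return a `qs_features` object with representation `"combined"`.
#' @export
combined_features <- function(search, questionnaire) {
  if (!identical(search$user_ids, questionnaire$user_ids) ||
      !identical(search$labels, questionnaire$labels))
    qs_stop("feature sets cover different users", "qs_value_error")
  static <- list()
  prov <- character(0)
  if (!is.null(search$static_x)) {
    static$a <- search$static_x
    prov <- c(prov, rep(search$representation, ncol(search$static_x)))
  }
  if (!is.null(questionnaire$static_x)) {
    static$b <- questionnaire$static_x
    prov <- c(prov,
              rep(questionnaire$representation,
                  ncol(questionnaire$static_x)))
  }
  static_x <- if (length(static)) do.call(cbind, unname(static)) else NULL
  new_features(user_ids = search$user_ids, labels = search$labels,
               representation = "combined", static_x = static_x,
               user_terms = search$user_terms,
               min_patients = search$min_patients,
               provenance = prov)
}
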