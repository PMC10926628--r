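# Shared fixtures and independent oracles.  The lexicon is loaded once per
# test run; simulated cohorts are built in code at reduced query volume so
# the suite stays fast while keeping the default outcome structure.

test_lexicon <- default_lexicon()

# small filtered synthetic cohort; volume scaled down, structure default
small_sim <- function(n_users = 80, seed = 1, ...) {
  cfg <- sim_config(n_users = n_users, mean_health_queries = 300,
                    decoy_rate = 0.3, seed = seed, ...)
  sim <- simulate_cohort(cfg, test_lexicon)
  fc <- filter_cohort(sim$cohort, test_lexicon)
  list(cohort = fc$cohort, raw = sim$cohort, truth = sim$truth,
       report = fc$report, config = cfg)
}

# hand-built cohort: explicit queries at given day offsets before a fixed
# referral date
offset_cohort <- function(..., outcome = NULL, referral = as.Date("2022-06-01"),
                          questionnaire = NULL) {
  users_q <- list(...)
  ids <- names(users_q)
  queries <- dplyr::bind_rows(lapply(ids, function(id) {
    q <- users_q[[id]]
    tibble::tibble(user_id = id, date = referral - q$offset, text = q$text)
  }))
  if (is.null(outcome))
    outcome <- rep(c("benign", "malignant"), length.out = length(ids))
  cohort(tibble::tibble(user_id = ids, referral_date = referral,
                        outcome = outcome),
         queries, questionnaire)
}

q_at <- function(offset, text) list(offset = offset, text = text)

subset_users_for_test <- function(co, ids) {
  co$users <- co$users[co$users$user_id %in% ids, ]
  co$queries <- co$queries[co$queries$user_id %in% ids, ]
  if (!is.null(co$questionnaire))
    co$questionnaire <-
      co$questionnaire[co$questionnaire$user_id %in% ids, ]
  co
}

set_queries_for_test <- function(co, q) {
  co$queries <- tibble::as_tibble(q)[c("user_id", "date", "text")]
  co
}

# brute-force AUC oracle: concordant-pair counting with half credit for ties
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# closed-form Pearson chi-squared for a 2x2 table [[a, b], [c, d]]
chi2_closed <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# cohort realizing a prescribed 2x2 table for one symptom:
# a = flagged & searched, b = flagged & not, c = unflagged & searched,
# d = unflagged & not
contingency_cohort <- function(a, b, c, d, symptom = "bloating",
                               term = "bloating") {
  n <- a + b + c + d
  ids <- sprintf("u%03d", seq_len(n))
  flagged <- c(rep(1L, a + b), rep(0L, c + d))
  searched <- c(rep(TRUE, a), rep(FALSE, b), rep(TRUE, c), rep(FALSE, d))
  referral <- as.Date("2022-06-01")
  queries <- tibble::tibble(
    user_id = ids,
    date = referral - 30,
    text = ifelse(searched, term, "weather tomorrow"))
  qn <- tibble::as_tibble(c(list(user_id = ids),
                            stats::setNames(list(flagged), symptom)))
  cohort(tibble::tibble(user_id = ids, referral_date = referral,
                        outcome = rep(c("benign", "malignant"),
                                      length.out = n)),
         queries, qn)
}
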