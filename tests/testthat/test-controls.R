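make_controls <- function(per_user_texts, period_start = "2021-10-01",
                          period_end = "2022-06-30",
                          lookahead_end = "2022-09-30") {
  queries <- dplyr::bind_rows(lapply(names(per_user_texts), function(id) {
    spec <- per_user_texts[[id]]
    tibble::tibble(user_id = id, date = as.Date(spec$date),
                   text = spec$text)
  }))
  controls(queries, period_start, period_end, lookahead_end)
}

test_that("the gynae-query exclusion rule counts periods jointly by default", {
  in_p <- as.Date("2022-01-10") + 0:9
  ahead <- as.Date("2022-07-10") + 0:9
  ctl <- make_controls(list(
    ten = list(date = in_p, text = rep("ovarian cancer symptoms", 10)),
    nine = list(date = in_p[1:9], text = rep("ovarian cancer symptoms", 9)),
    split = list(date = c(in_p[1:6], ahead[1:4]),
                 text = rep("endometrial cancer", 10)),
    clean = list(date = in_p[1:3],
                 text = c("pelvic pain", "bloating", "weather"))))
  res <- exclude_flagged_controls(ctl, test_lexicon)
  expect_setequal(res$excluded, c("ten", "split"))
  expect_setequal(unique(res$controls$queries$user_id),
                  c("nine", "clean"))

  # either-period semantics: 6 + 4 no longer trips the rule
  res_either <- exclude_flagged_controls(ctl, test_lexicon,
                                         rule = "either")
  expect_setequal(res_either$excluded, "ten")

  # monotone in threshold
  res_high <- exclude_flagged_controls(ctl, test_lexicon, threshold = 11)
  expect_true(all(res_high$excluded %in% res$excluded))
  res_zero <- exclude_flagged_controls(ctl, test_lexicon, threshold = 1)
  expect_true(all(res$excluded %in% res_zero$excluded))
})

test_that("score histogram bins [0,1] with a right-inclusive top bin", {
  h <- score_histogram(list(a = rep(0.05, 7)))
  expect_equal(h$count[h$bin == 1], 7L)
  expect_equal(sum(h$count), 7L)

  h2 <- score_histogram(list(a = c(0, 1, 0.999, 0.1, 0.10001)))
  expect_equal(h2$count[h2$bin == 10], 2L)  # 1 and 0.999
  expect_equal(h2$count[h2$bin == 1], 2L)   # 0 and 0.1
  expect_equal(h2$count[h2$bin == 2], 1L)   # 0.10001

  set.seed(2)
  h3 <- score_histogram(list(u = runif(1000)))
  expect_equal(sum(h3$frequency), 1)
  expect_true(all(abs(h3$frequency - 0.1) < 0.04))

  expect_error(score_histogram(list(a = numeric(0))),
               class = "qs_value_error")
})

test_that("control scoring is deterministic and flags zero-vector users", {
  sim <- small_sim(n_users = 40, seed = 51)
  model <- fit_cohort_model(sim$cohort, window(270, 1), "terms",
                            cfg = model_config(seed = 2))
  ctl_sim <- simulate_controls(sim$config, n_controls = 30,
                               flagged_fraction = 0, lexicon = test_lexicon)
  filtered <- filter_health(ctl_sim$controls$queries, test_lexicon)
  ctl <- ctl_sim$controls
  ctl$queries <- filtered$queries
  s1 <- score_controls(model, ctl)
  s2 <- score_controls(model, ctl)
  expect_identical(s1, s2)
  expect_true(all(s1$score >= 0 & s1$score <= 1))
  # zero-vector users share one constant score
  if (any(s1$zero_vector))
    expect_length(unique(s1$score[s1$zero_vector]), 1L)
})

test_that("patients pushed through the control path get their direct scores", {
  # users sharing one referral date can be re-expressed as controls whose
  # period ends the day before that referral
  referral <- as.Date("2022-07-01")
  sim <- small_sim(n_users = 30, seed = 61)
  co <- sim$cohort
  # align all users on one referral date, preserving each query's offset
  shift <- as.integer(
    referral -
      co$users$referral_date[match(co$queries$user_id,
                                   co$users$user_id)])
  co$queries$date <- co$queries$date + shift
  co$users$referral_date <- referral
  co <- querysift::truncate_cohort(co, 730)
  w <- window(270, 1)
  model <- fit_cohort_model(co, w, "terms", cfg = model_config(seed = 3))
  direct <- querysift:::predict_gbm(
    model$booster, vectorize_terms(co, w, model$vocab))

  keep <- co$queries$date >= referral - 270 & co$queries$date <= referral - 1
  ctl <- controls(co$queries[keep, ], period_start = referral - 270,
                  period_end = referral - 1)
  via_controls <- score_controls(model, ctl)
  expect_equal(
    via_controls$score[match(co$users$user_id, via_controls$user_id)],
    unname(direct))
})

test_that("simulated controls satisfy their activity constraints", {
  cfg <- sim_config(n_users = 10, mean_health_queries = 300,
                    decoy_rate = 0.3, seed = 71)
  ctl_sim <- simulate_controls(cfg, n_controls = 40,
                               flagged_fraction = 0.25,
                               lexicon = test_lexicon)
  q <- ctl_sim$controls$queries
  months <- unique(format(seq(as.Date("2021-10-01"), as.Date("2022-09-30"),
                              by = "day"), "%Y-%m"))
  for (id in unique(q$user_id)) {
    expect_setequal(unique(format(q$date[q$user_id == id], "%Y-%m")),
                    months)
  }
  # flagged users (and only plausibly they) trip the exclusion rule
  res <- exclude_flagged_controls(ctl_sim$controls, test_lexicon)
  expect_setequal(res$excluded,
                  ctl_sim$truth$user_id[ctl_sim$truth$flagged])

  none <- simulate_controls(cfg, n_controls = 15, flagged_fraction = 0,
                            lexicon = test_lexicon)
  expect_length(
    exclude_flagged_controls(none$controls, test_lexicon)$excluded, 0L)
})
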