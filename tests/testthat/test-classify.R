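test_that("rank-based AUC matches hand-derived and degenerate cases", {
  expect_equal(auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(auc(c(3, 2, 1), c("malignant", "benign", "malignant")), 0.5)
  expect_error(auc(c(0.1, 0.2), c(1, 1)), class = "qs_eval_error")
})

test_that("AUC equals brute-force pair counting and is rank-invariant", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    s <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    expect_equal(auc(s, y), brute_auc(s, y))
    expect_equal(auc(qlogis(pmin(pmax(s, 0.01), 0.99)), y),
                 auc(pmin(pmax(s, 0.01), 0.99), y))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.3))
    s <- round(runif(n), 2)
    expect_equal(auc(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("LOOCV separates a perfectly separable synthetic cohort", {
  # every malignant user shares a marker term benign users never use
  referral <- as.Date("2022-06-01")
  ids <- sprintf("u%02d", 1:14)
  outcome <- rep(c("malignant", "benign"), 7)
  queries <- dplyr::bind_rows(lapply(seq_along(ids), function(i) {
    text <- if (outcome[i] == "malignant")
      c("ovarian cyst pain", "bloating") else c("indigestion", "fatigue")
    tibble::tibble(user_id = ids[i], date = referral - c(30, 60),
                   text = text)
  }))
  co <- cohort(tibble::tibble(user_id = ids, referral_date = referral,
                              outcome = outcome), queries)
  feats <- terms_features(co, window(630, 1), min_patients = 5)
  scores <- loocv_scores(feats, model_config())
  expect_true(all(scores >= 0 & scores <= 1))
  expect_equal(auc(scores, feats$labels), 1)
})

test_that("LOOCV guards degenerate inputs", {
  f <- querysift:::new_features(user_ids = c("a", "b"), labels = c(0L, 1L),
                                representation = "categories",
                                static_x = matrix(1:2, 2, 1))
  expect_error(loocv_scores(f), class = "qs_eval_error")
  f2 <- querysift:::new_features(
    user_ids = letters[1:6], labels = rep(0:1, 3),
    representation = "categories",
    static_x = matrix(0, 6, 0))
  expect_error(loocv_scores(f2), class = "qs_eval_error")
})

test_that("empty fold vocabularies fall back to the training prevalence", {
  co <- offset_cohort(
    a = q_at(10, "pelvic pain"), b = q_at(10, "bloating"),
    c = q_at(10, "nausea"), d = q_at(10, "fatigue"),
    outcome = c("malignant", "benign", "malignant", "benign"))
  feats <- terms_features(co, window(630, 1), min_patients = 5)
  scores <- loocv_scores(feats, model_config())
  # each fold's score is the mean label of the other three users
  expect_equal(unname(scores), c(1, 2, 1, 2) / 3)
})

test_that("operating points maximize TPR subject to the FPR budget", {
  pts <- roc_operating_points(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0),
                              fpr_targets = c(0, 1))
  expect_equal(pts$tpr[pts$fpr_target == 0], 0.5)
  expect_equal(pts$threshold[pts$fpr_target == 0], 0.9)
  expect_equal(pts$fpr[pts$fpr_target == 0], 0)
  expect_equal(pts$tpr[pts$fpr_target == 1], 1)  # accept-all

  perfect <- roc_operating_points(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 0)
  expect_equal(perfect$tpr, 1)
  expect_error(roc_operating_points(1:3, c(1, 1, 1), 0.1),
               class = "qs_eval_error")
})

test_that("sample-size regression recovers a closed-form line", {
  curve <- fit_sample_curve(c(50, 100, 150), c(0.6, 0.7, 0.8),
                            reference_n = 235)
  expect_equal(curve$slope, 0.002)
  expect_equal(curve$intercept, 0.5)
  expect_error(fit_sample_curve(c(100, 100), c(0.6, 0.7), 235),
               class = "qs_value_error")
})

test_that("the sample-size correction is an identity at the reference size", {
  set.seed(7)
  for (i in 1:20) {
    curve <- fit_sample_curve(c(60, 120, 180),
                              0.5 + runif(3, 0, 0.3), reference_n = 200)
    raw <- runif(1, 0.4, 0.9)
    expect_equal(corrected_auc(raw, 200, curve), raw)
    flat <- curve; flat$slope <- 0
    expect_equal(corrected_auc(raw, 60, flat), raw)
  }
  curve <- fit_sample_curve(c(50, 100, 150), c(0.55, 0.6, 0.65), 150)
  expect_equal(corrected_auc(0.70, 100, curve), 0.75)
  high <- fit_sample_curve(c(10, 150), c(0.2, 0.99), 150)
  expect_lte(corrected_auc(0.99, 10, high), 1)  # clipped
})

test_that("auc_sample_curve subsamples without replacement and fits", {
  sim <- small_sim(n_users = 50, seed = 6)
  feats <- category_features(sim$cohort, window(630, 60), test_lexicon)
  curve <- auc_sample_curve(feats, model_config(), subset_sizes = c(25, 40),
                            replicates = 2, seed = 3)
  expect_equal(nrow(curve$auc_by_size), 2L)
  expect_true(is.finite(curve$slope))
  expect_equal(curve$reference_n, 50)
  expect_error(auc_sample_curve(feats, model_config(), subset_sizes = 40,
                                replicates = 2, seed = 3),
               class = "qs_value_error")
})

test_that("cohort models score deterministically", {
  sim <- small_sim(n_users = 30, seed = 8)
  m1 <- fit_cohort_model(sim$cohort, window(270, 1), "categories",
                         lexicon = test_lexicon)
  m2 <- fit_cohort_model(sim$cohort, window(270, 1), "categories",
                         lexicon = test_lexicon)
  x <- vectorize_categories(sim$cohort, window(270, 1), test_lexicon)
  expect_equal(querysift:::predict_gbm(m1$booster, x),
               querysift:::predict_gbm(m2$booster, x))
})
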