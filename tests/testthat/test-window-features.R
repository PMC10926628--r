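test_that("window validation and boundary selection are inclusive", {
  expect_error(window(60, 630), class = "qs_value_error")
  expect_error(window(630, 0), class = "qs_value_error")
  expect_error(window(701, 1), class = "qs_value_error")

  co <- offset_cohort(
    a = q_at(c(59, 60, 630, 631),
             c("pelvic pain", "bloating", "ovarian cyst", "fatigue")),
    b = q_at(5, "nausea"))
  sel <- select_window(co, window(630, 60))
  expect_setequal(sel$queries$text[sel$queries$user_id == "a"],
                  c("bloating", "ovarian cyst"))
  # monotone: a nested window selects a subset
  inner <- select_window(co, window(400, 100))
  outer <- select_window(co, window(630, 60))
  expect_true(all(inner$queries$text %in% outer$queries$text))
  # empty history stays empty
  expect_equal(nrow(select_window(co, window(700, 640))$queries[
    select_window(co, window(700, 640))$queries$user_id == "b", ]), 0L)
})

test_that("vocabulary applies the distinct-patient cutoff to words and bigrams", {
  mk <- function(id, texts) q_at(seq_along(texts) + 10, texts)
  co <- offset_cohort(
    p1 = mk("p1", "bloating ascites"),
    p2 = mk("p2", "bloating remedies"),
    p3 = mk("p3", "bloating"),
    p4 = mk("p4", "bloating ascites"),
    p5 = mk("p5", "bloating"),
    p6 = mk("p6", "stomach ache"))
  v <- build_vocabulary(co, window(630, 1), min_patients = 5)
  expect_true("bloating" %in% v$term)     # 5 patients
  expect_false("ascites" %in% v$term)     # 2 patients
  expect_equal(v$df[v$term == "bloating"], 5L)
  expect_equal(v$term, sort(v$term))

  # unigrams and consecutive bigrams from a single query
  co1 <- offset_cohort(a = q_at(10, "pelvic pain relief"),
                       b = q_at(10, "x"))
  v1 <- build_vocabulary(co1, window(630, 1), min_patients = 1)
  expect_setequal(setdiff(v1$term, "x"),
                  c("pelvic", "pain", "relief", "pelvic pain",
                    "pain relief"))
})

test_that("term vectors count occurrences and ignore out-of-vocabulary tokens", {
  co <- offset_cohort(
    a = q_at(c(10, 40), c("pelvic pain", "pelvic pain")),
    b = q_at(10, "bloating nausea"))
  vocab <- tibble::tibble(term = c("bloating", "pain", "pelvic",
                                   "pelvic pain"))
  x <- vectorize_terms(co, window(630, 1), vocab)
  expect_equal(x["a", ], c(bloating = 0L, pain = 2L, pelvic = 2L,
                           `pelvic pain` = 2L))
  expect_equal(x["b", "bloating"], 1L)
  # no in-window queries -> zero vector
  x2 <- vectorize_terms(co, window(700, 650), vocab)
  expect_true(all(x2 == 0L))
  # unigram totals match a brute-force recount
  sim <- small_sim(n_users = 15, seed = 2)
  w <- window(630, 60)
  v <- build_vocabulary(sim$cohort, w, min_patients = 3)
  xs <- vectorize_terms(sim$cohort, w, v)
  uni <- v$term[!grepl(" ", v$term)]
  q <- select_window(sim$cohort, w)$queries
  toks <- tokenize(q$text)
  for (u in sample(rownames(xs), 5)) {
    all_tok <- unlist(toks[q$user_id == u])
    expect_equal(sum(xs[u, uni]), sum(all_tok %in% uni))
  }
})

test_that("category vectors count multi-category assignments per query", {
  co <- offset_cohort(
    a = q_at(10, "pelvic pain bleeding"),
    b = q_at(c(10, 20, 30), rep("period pain", 3)))
  x <- vectorize_categories(co, window(630, 1), test_lexicon)
  expect_equal(unname(x["a", c("pain", "bleeding")]), c(1L, 1L))
  expect_equal(unname(x["b", "pain"]), 3L)
  expect_equal(ncol(x), 14L)
  x0 <- vectorize_categories(co, window(700, 650), test_lexicon)
  expect_true(all(x0 == 0L))
})

test_that("vocabulary construction is deterministic and leakage-free per fold", {
  sim <- small_sim(n_users = 20, seed = 4)
  w <- window(630, 60)
  v1 <- build_vocabulary(sim$cohort, w, min_patients = 3)
  v2 <- build_vocabulary(sim$cohort, w, min_patients = 3)
  expect_identical(v1, v2)

  # a term used by exactly min_patients users disappears from the
  # vocabulary of any training fold excluding one of those users
  feats <- terms_features(sim$cohort, w, min_patients = 3)
  df_all <- table(unlist(lapply(feats$user_terms, names)))
  marginal <- names(df_all)[df_all == 3]
  expect_true(length(marginal) > 0)
  t0 <- marginal[[1]]
  carrier <- which(vapply(feats$user_terms,
                          function(ut) t0 %in% names(ut), logical(1)))[1]
  ids <- sim$cohort$users$user_id
  fold <- subset_users_for_test(sim$cohort, ids[-carrier])
  v_fold <- build_vocabulary(fold, w, min_patients = 3)
  expect_false(t0 %in% v_fold$term)
  expect_true(t0 %in% build_vocabulary(sim$cohort, w, min_patients = 3)$term)
})

test_that("features_matrix honours binary mode and user order", {
  co <- offset_cohort(
    a = q_at(c(10, 40), c("pelvic pain", "pelvic pain")),
    b = q_at(10, "pelvic pain"))
  f_counts <- terms_features(co, window(630, 1), min_patients = 2)
  f_bin <- terms_features(co, window(630, 1), min_patients = 2,
                          binary = TRUE)
  expect_equal(unname(features_matrix(f_counts)["a", "pelvic pain"]), 2L)
  expect_equal(unname(features_matrix(f_bin)["a", "pelvic pain"]), 1L)
  expect_equal(rownames(features_matrix(f_counts)), c("a", "b"))
})
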