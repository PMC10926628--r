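test_that("read_takeout handles the Takeout export, skipping non-search entries", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    list(header = "Search", title = "Searched for ovarian cyst",
         time = "2022-05-22T10:30:00Z"),
    list(header = "Search", title = "Visited some website",
         time = "2022-05-23T09:00:00Z"),
    list(header = "Search", title = "Searched for pelvic pain",
         time = "2022-05-27T18:00:00Z")), auto_unbox = TRUE), path)
  recs <- read_takeout(path, user_id = "u1")
  expect_equal(nrow(recs), 2L)
  expect_equal(recs$text, c("ovarian cyst", "pelvic pain"))
  expect_true(all(diff(recs$timestamp) >= 0))
  expect_equal(unique(recs$user_id), "u1")
})

test_that("read_takeout handles the JSONL fixture dialect and edge cases", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"user_id":"u1","timestamp":"2022-05-27T08:00:00","text":"pelvic pain"}',
    '{"user_id":"u1","timestamp":"2022-05-22T08:00:00","text":"ovarian cyst"}'),
    path)
  recs <- read_takeout(path)
  expect_equal(recs$text, c("ovarian cyst", "pelvic pain"))  # sorted

  empty <- withr::local_tempfile(fileext = ".json")
  writeLines("[]", empty)
  expect_equal(nrow(read_takeout(empty, user_id = "u1")), 0L)

  bad <- withr::local_tempfile(fileext = ".jsonl")
  writeLines('{"user_id":"u1","timestamp":"not-a-date","text":"x"}', bad)
  expect_error(read_takeout(bad), class = "qs_format_error")

  miss <- withr::local_tempfile(fileext = ".jsonl")
  writeLines('{"user_id":"u1","text":"x"}', miss)
  expect_error(read_takeout(miss), class = "qs_format_error")

  notjson <- withr::local_tempfile(fileext = ".jsonl")
  writeLines('{"user_id": oops', notjson)
  expect_error(read_takeout(notjson), regexp = "line 1",
               class = "qs_format_error")
})

test_that("fixture dialect round-trips records losslessly", {
  recs <- tibble::tibble(
    user_id = "u9",
    timestamp = as.POSIXct(c("2021-01-02 10:00:00", "2021-03-04 23:59:59"),
                           tz = "UTC"),
    text = c("douleur pelvienne", "ca125 blood test"))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_records_jsonl(recs, path)
  back <- read_takeout(path)
  expect_equal(back$text, recs$text)
  expect_equal(back$timestamp, recs$timestamp)
  expect_equal(back$user_id, recs$user_id)
})

test_that("truncate_history keeps exactly day offsets 1..lookback", {
  referral <- as.Date("2022-06-01")
  recs <- tibble::tibble(date = referral - c(0, 1, 365, 730, 731),
                         text = letters[1:5])
  kept <- truncate_history(recs, referral)
  expect_equal(as.integer(referral - kept$date), c(1, 365, 730))
  # enumerated interval check
  kept2 <- truncate_history(
    tibble::tibble(date = referral - c(0, 1, 365, 731), text = letters[1:4]),
    referral)
  expect_equal(as.integer(referral - kept2$date), c(1, 365))
})

test_that("cohort JSONL round-trips users, queries and questionnaire", {
  sim <- small_sim(n_users = 8, seed = 3)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_cohort(sim$cohort, path)
  back <- read_cohort(path)
  expect_equal(back$users, sim$cohort$users)
  expect_equal(back$queries, sim$cohort$queries)
  expect_equal(back$questionnaire, sim$cohort$questionnaire)
})

test_that("read_questionnaire validates shape and values", {
  symptoms <- questionnaire_symptoms()
  expect_length(symptoms, 20L)
  path <- withr::local_tempfile(fileext = ".csv")
  row0 <- stats::setNames(as.list(rep(0L, 20)), symptoms)
  row1 <- row0; row1[["pelvic pain"]] <- 1L; row1[["bloating"]] <- 1L
  df <- dplyr::bind_rows(
    tibble::as_tibble(c(list(user_id = "a"), row0)),
    tibble::as_tibble(c(list(user_id = "b"), row1)))
  utils::write.csv(df, path, row.names = FALSE)
  qn <- read_questionnaire(path)
  expect_equal(sum(unlist(qn[1, -1])), 0L)
  expect_equal(names(qn)[-1][unlist(qn[2, -1]) == 1L],
               c("pelvic pain", "bloating"))

  dup <- dplyr::bind_rows(df, df[1, ])
  utils::write.csv(dup, path, row.names = FALSE)
  expect_error(read_questionnaire(path), class = "qs_format_error")

  bad <- df; bad[["bloating"]][1] <- 2L
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_questionnaire(path), regexp = "bloating",
               class = "qs_value_error")

  unknown <- df; unknown$mystery <- 0L
  utils::write.csv(unknown, path, row.names = FALSE)
  expect_error(read_questionnaire(path), regexp = "mystery",
               class = "qs_format_error")
})

test_that("enrolment accounting recomputes percentages with half-up rounding", {
  flow <- enrolment_flow(approached = 844, eligible = 652, consented = 392,
                         complete = 255, excluded_insufficient = 20,
                         final = 235, final_malignant = 61)
  acc <- enrolment_accounting(flow)
  expect_equal(acc$percent[acc$metric == "eligible_of_approached"], 77.3)
  expect_equal(acc$percent[acc$metric == "malignant_of_final"], 26.0)
  # half-up, not banker's: 1/16 = 6.25% -> 6.3
  flow2 <- enrolment_flow(approached = 16, eligible = 1, consented = 1,
                          complete = 1, excluded_insufficient = 0, final = 1)
  acc2 <- enrolment_accounting(flow2)
  expect_equal(acc2$percent[acc2$metric == "eligible_of_approached"], 6.3)
  # zero numerator is fine, zero denominator is not
  flow3 <- enrolment_flow(approached = 100, eligible = 80, consented = 60,
                          complete = 40, excluded_insufficient = 0,
                          final = 40, final_malignant = 0)
  acc3 <- enrolment_accounting(flow3)
  expect_equal(acc3$percent[acc3$metric == "malignant_of_final"], 0)
  flow0 <- enrolment_flow(approached = 0, eligible = 0, consented = 0,
                          complete = 0, excluded_insufficient = 0, final = 0)
  expect_error(enrolment_accounting(flow0), class = "qs_value_error")
  expect_error(enrolment_flow(approached = 10, eligible = 20, consented = 5,
                              complete = 5, excluded_insufficient = 0,
                              final = 5),
               class = "qs_value_error")
})

test_that("mean queries per user floors the ratio", {
  expect_equal(mean_queries_per_user(519048, 235), 2208L)
  expect_equal(mean_queries_per_user(100, 100), 1L)
  expect_equal(mean_queries_per_user(7, 2), 3L)
  expect_error(mean_queries_per_user(10, 0), class = "qs_value_error")
})

test_that("pseudo-anonymisation is deterministic, salted and collision-free here", {
  ids <- sprintf("patient%03d@example.org", 1:50)
  h1 <- anonymise_user_ids(ids, salt = "s1")
  expect_equal(h1, anonymise_user_ids(ids, salt = "s1"))
  expect_equal(anyDuplicated(h1), 0L)
  expect_false(any(h1 == anonymise_user_ids(ids, salt = "s2")))
  expect_false(any(ids %in% h1))
})
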