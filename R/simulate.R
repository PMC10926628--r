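#' Synthetic cohort configuration
#'
#' Parameters of the generative model used to exercise the pipeline
#' without patient data.  Defaults emulate the study conditions: 235
#' users, 26% malignant prevalence, ~65% of users engaging in
#' health-condition search, heavy-tailed per-user query volume averaging
#' ~2208 health queries over the 24-month lookback, and
#' outcome-dependent category query-rate onsets (gastrointestinal and
#' pain ~365 days before referral, urinary and bleeding ~140 days,
#' bloating / gynaecological / menopause ~70 days) absent in benign
#' users.
#'
#' @param n_users cohort size (default 235).
#' @param malignant_prevalence probability of a malignant outcome
#'   (default 0.26).
#' @param engagement_rate probability a user makes medical-condition
#'   queries at all (default 0.65).
#' @param mean_health_queries target mean health-related queries per user
#'   over the lookback (default 2208); the condition-query rate of
#'   engaged users is tuned so the cohort mean meets this target.
#' @param rate_sigma log-scale standard deviation of the per-user
#'   condition-query rate (lognormal heterogeneity; default 0.75).
#' @param symptom_rate baseline per-category symptom-query rate,
#'   queries/user/day (default 0.02).
#' @param onset_schedule named list: category -> `c(onset, mult)`, the
#'   day offset at which a malignant user's rate for that category
#'   switches from `symptom_rate` to `symptom_rate * mult`.
#' @param benign_signal multiplier on benign users' (time-constant)
#'   symptom rate — benign patients are symptomatic referrals, not
#'   healthy controls (default 1).
#' @param decoy_rate non-medical queries/user/day (default 1); decoys are
#'   removed by the health filter.
#' @param questionnaire_noise probability a questionnaire flag is flipped
#'   relative to the latent symptom exposure (default 0.1).
#' @param lookback_days history length before referral (default 730).
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @return an object of class `qs_sim_config`.
#' @export
sim_config <- function(n_users = 235, malignant_prevalence = 0.26,
                       engagement_rate = 0.65, mean_health_queries = 2208,
                       rate_sigma = 0.75, symptom_rate = 0.02,
                       onset_schedule = default_onset_schedule(),
                       benign_signal = 1, decoy_rate = 1,
                       questionnaire_noise = 0.1, lookback_days = 730,
                       seed = 1) {
  stopifnot(n_users >= 1,
            malignant_prevalence >= 0, malignant_prevalence <= 1,
            engagement_rate >= 0, engagement_rate <= 1,
            questionnaire_noise >= 0, questionnaire_noise <= 1,
            symptom_rate > 0, mean_health_queries > 0, lookback_days >= 1)
  onsets <- vapply(onset_schedule, `[`, numeric(1), 1)
  if (any(onsets < 1 | onsets > lookback_days))
    qs_stop("onset days must lie within [1, lookback_days]",
            "qs_value_error")
  structure(list(n_users = as.integer(n_users),
                 malignant_prevalence = malignant_prevalence,
                 engagement_rate = engagement_rate,
                 mean_health_queries = mean_health_queries,
                 rate_sigma = rate_sigma, symptom_rate = symptom_rate,
                 onset_schedule = onset_schedule,
                 benign_signal = benign_signal, decoy_rate = decoy_rate,
                 questionnaire_noise = questionnaire_noise,
                 lookback_days = as.integer(lookback_days),
                 seed = as.integer(seed)),
            class = "qs_sim_config")
}

#' @rdname sim_config
#' @export
default_onset_schedule <- function() {
  list(gastrointestinal = c(onset = 365, mult = 3),
       pain = c(onset = 365, mult = 3),
       urinary = c(onset = 140, mult = 3),
       bleeding = c(onset = 140, mult = 3),
       bloating = c(onset = 70, mult = 3),
       gynaecological = c(onset = 70, mult = 3),
       menopause = c(onset = 70, mult = 3))
}

# query-text pools derived from the lexicon; conditions whose words
# collide with category keywords are dropped so the engagement channel
# stays orthogonal to the symptom-category channel
sim_text_pools <- function(lexicon) {
  cat_words <- names(lexicon$category_map)
  # keywords that are themselves listed conditions (e.g. "cystitis") are
  # kept out of the symptom pools: a symptom query must never read as a
  # condition query, or the engagement channel loses its ground truth
  single_conditions <- lexicon$conditions[
    lengths(tokenize(lexicon$conditions)) == 1L]
  fillers <- c("", "causes", "remedies", "nhs", "treatment", "why")
  cat_pool <- lapply(lexicon$categories, function(cn) {
    kws <- names(lexicon$category_map)[
      vapply(lexicon$category_map, function(v) cn %in% v, logical(1))]
    kws <- setdiff(kws, single_conditions)
    as.vector(outer(kws, fillers, function(k, f) trimws(paste(k, f))))
  })
  names(cat_pool) <- lexicon$categories
  neutral <- lexicon$conditions[
    !vapply(tokenize(lexicon$conditions),
            function(t) any(t %in% cat_words), logical(1))]
  cond_fillers <- c("", "nhs", "treatment", "medication", "guidelines")
  cond_pool <- as.vector(outer(neutral, cond_fillers,
                               function(k, f) trimws(paste(k, f))))
  decoy_pool <- c("weather tomorrow", "football scores today",
                  "cheap flights to rome", "pizza near me",
                  "new series to watch", "bus times city centre",
                  "cat bleeding pain", "dog pain limping",
                  "club music tonight", "second hand cars",
                  "birthday gift ideas", "how to fix a bike puncture")
  list(category = cat_pool, condition = cond_pool, decoy = decoy_pool)
}

# internal map from questionnaire symptom to the category whose elevation
# makes the symptom "truly present"
symptom_category_link <- function() {
  c("pelvic pain" = "pain", "bloating" = "bloating",
    "post-menopausal bleeding" = "bleeding",
    "irregular bleeding" = "bleeding", "heavy periods" = "bleeding",
    "dyspareunia" = "pain", "weight loss" = "nutrition",
    "appetite loss" = "nutrition", "constipation" = "gastrointestinal",
    "diarrhoea" = "gastrointestinal", "nausea" = "gastrointestinal",
    "urgency" = "urinary", "frequency" = "urinary",
    "incontinence" = "urinary", "fatigue" = "fatigue",
    "back pain" = "pain", "abdominal swelling" = "bloating",
    "early satiety" = "gastrointestinal",
    "vaginal discharge" = "vagina or pelvic organs",
    "hot flushes" = "menopause")
}

#' Simulate a patient cohort
#'
#' Draws outcomes, engagement flags, and per-user query streams from an
#' inhomogeneous Poisson model: engaged users emit medical-condition
#' queries at a heavy-tailed (lognormal) individual rate; every user
#' emits baseline symptom-category queries; malignant users' scheduled
#' categories switch to an elevated rate at their configured onset;
#' decoy (non-medical) queries are layered on top and questionnaire
#' flags equal latent symptom exposure XOR noise.  Fully deterministic
#' given the configuration.
#'
#' @param cfg a [sim_config()].
#' @param lexicon a `qs_lexicon` supplying the query-text pools
#'   (default [default_lexicon()]).
#' @return list with `cohort` (a raw, unfiltered `qs_cohort` with
#'   questionnaire), `truth` (per-user latent variables: `engaged`,
#'   `cond_rate`, and `condition_days`, a list column of day offsets of
#'   the condition-bearing queries) and `config`.
#' @export
simulate_cohort <- function(cfg, lexicon = default_lexicon()) {
  stopifnot(inherits(cfg, "qs_sim_config"))
  set.seed(cfg$seed)
  pools <- sim_text_pools(lexicon)
  L <- cfg$lookback_days
  n <- cfg$n_users
  ids <- sprintf("sim%04d", seq_len(n))
  referral <- as.Date("2021-06-01") +
    sample.int(366, n, replace = TRUE) - 1L

  outcome <- ifelse(stats::rbinom(n, 1, cfg$malignant_prevalence) == 1,
                    "malignant", "benign")
  engaged <- stats::rbinom(n, 1, cfg$engagement_rate) == 1
  # engaged users' condition-query rate: lognormal with mean tuned so the
  # cohort-wide mean health-query count hits the configured target
  n_symptom_expected <- 14 * cfg$symptom_rate * L
  mean_cond_rate <- max(
    (cfg$mean_health_queries - n_symptom_expected) /
      max(cfg$engagement_rate, 1e-9) / L, 1e-6)
  cond_rate <- stats::rlnorm(n, log(mean_cond_rate) - cfg$rate_sigma^2 / 2,
                             cfg$rate_sigma)
  cond_rate[!engaged] <- 0

  sched <- cfg$onset_schedule
  sched_onset <- vapply(sched, `[`, numeric(1), 1)
  sched_mult <- vapply(sched, `[`, numeric(1), 2)

  all_q <- vector("list", n)
  cond_days_list <- vector("list", n)
  qn_rows <- vector("list", n)
  link <- symptom_category_link()

  for (i in seq_len(n)) {
    offs <- integer(0); texts <- character(0)
    # condition-bearing (engagement) queries
    n_cond <- stats::rpois(1, cond_rate[i] * L)
    if (n_cond > 0) {
      d <- sample.int(L, n_cond, replace = TRUE)
      offs <- c(offs, d)
      texts <- c(texts, sample(pools$condition, n_cond, replace = TRUE))
      cond_days_list[[i]] <- sort(d)
    } else cond_days_list[[i]] <- integer(0)
    # symptom-category queries
    for (cn in names(pools$category)) {
      if (length(pools$category[[cn]]) == 0L) next
      base <- cfg$symptom_rate *
        (if (outcome[i] == "benign") cfg$benign_signal else 1)
      if (outcome[i] == "malignant" && cn %in% names(sched)) {
        onset <- sched_onset[[cn]]; mult <- sched_mult[[cn]]
        n_pre <- stats::rpois(1, base * (L - onset))
        n_post <- stats::rpois(1, base * mult * onset)
        d <- c(if (n_pre > 0) onset + sample.int(L - onset, n_pre,
                                                 replace = TRUE),
               if (n_post > 0) sample.int(onset, n_post, replace = TRUE))
      } else {
        n_c <- stats::rpois(1, base * L)
        d <- if (n_c > 0) sample.int(L, n_c, replace = TRUE) else integer(0)
      }
      if (length(d) > 0) {
        offs <- c(offs, d)
        texts <- c(texts, sample(pools$category[[cn]], length(d),
                                 replace = TRUE))
      }
    }
    # decoys
    n_dec <- stats::rpois(1, cfg$decoy_rate * L)
    if (n_dec > 0) {
      offs <- c(offs, sample.int(L, n_dec, replace = TRUE))
      texts <- c(texts, sample(pools$decoy, n_dec, replace = TRUE))
    }
    all_q[[i]] <- tibble::tibble(user_id = ids[i],
                                 date = referral[i] - offs, text = texts)
    # questionnaire: latent exposure XOR noise
    elevated <- if (outcome[i] == "malignant") names(sched) else character(0)
    exposure <- ifelse(link %in% elevated, 0.6, 0.3)
    true_flag <- stats::rbinom(length(link), 1, exposure)
    flip <- stats::rbinom(length(link), 1, cfg$questionnaire_noise)
    qn_rows[[i]] <- tibble::as_tibble(
      c(list(user_id = ids[i]),
        stats::setNames(as.list(as.integer(xor(true_flag, flip))),
                        names(link))))
  }

  users <- tibble::tibble(user_id = ids, referral_date = referral,
                          outcome = outcome)
  queries <- dplyr::bind_rows(all_q)
  truth <- tibble::tibble(user_id = ids, outcome = outcome,
                          engaged = engaged, cond_rate = cond_rate,
                          condition_days = cond_days_list)
  list(cohort = cohort(users, queries, dplyr::bind_rows(qn_rows)),
       truth = truth, config = cfg)
}

#' Simulate an external control population
#'
#' Benign-like users over a fixed data period plus lookahead: baseline
#' symptom-category queries (no onsets), condition queries at the
#' engaged-user rate, and decoys, constrained to at least one query in
#' every calendar month and at least one medical keyword overall.  A
#' configurable fraction is given ten-plus gynaecological-cancer queries
#' to exercise the exclusion rule.
#'
#' @param cfg a [sim_config()] (rates and seed are reused; `n_users` is
#'   ignored).
#' @param n_controls number of control users.
#' @param flagged_fraction fraction given >= 10 gynae-cancer queries
#'   (default 0.02).
#' @param period_start,period_end data period (defaults 2021-10-01 to
#'   2022-06-30).
#' @param lookahead_end end of the post-period lookahead (default
#'   2022-09-30).
#' @param lexicon a `qs_lexicon`.
#' @return list with `controls` (a [controls()] object) and `truth`
#'   (tibble with `user_id`, `flagged`).
#' @export
simulate_controls <- function(cfg, n_controls, flagged_fraction = 0.02,
                              period_start = "2021-10-01",
                              period_end = "2022-06-30",
                              lookahead_end = "2022-09-30",
                              lexicon = default_lexicon()) {
  stopifnot(inherits(cfg, "qs_sim_config"))
  set.seed(cfg$seed + 1L)
  pools <- sim_text_pools(lexicon)
  period_start <- as.Date(period_start)
  period_end <- as.Date(period_end)
  lookahead_end <- as.Date(lookahead_end)
  span <- as.integer(lookahead_end - period_start) + 1L
  months <- unique(format(seq(period_start, lookahead_end, by = "day"),
                          "%Y-%m"))
  ids <- sprintf("ctl%04d", seq_len(n_controls))
  flagged <- stats::rbinom(n_controls, 1, flagged_fraction) == 1

  n_symptom_expected <- 14 * cfg$symptom_rate * cfg$lookback_days
  mean_cond_rate <- max(
    (cfg$mean_health_queries - n_symptom_expected) /
      max(cfg$engagement_rate, 1e-9) / cfg$lookback_days, 1e-6)

  all_q <- vector("list", n_controls)
  for (i in seq_len(n_controls)) {
    offs <- integer(0); texts <- character(0)
    rate <- stats::rlnorm(1, log(mean_cond_rate) - cfg$rate_sigma^2 / 2,
                          cfg$rate_sigma)
    n_cond <- stats::rpois(1, rate * span)
    if (n_cond > 0) {
      offs <- c(offs, sample.int(span, n_cond, replace = TRUE))
      texts <- c(texts, sample(pools$condition, n_cond, replace = TRUE))
    }
    for (cn in names(pools$category)) {
      n_c <- stats::rpois(1, cfg$symptom_rate * span)
      if (n_c > 0) {
        offs <- c(offs, sample.int(span, n_c, replace = TRUE))
        texts <- c(texts, sample(pools$category[[cn]], n_c,
                                 replace = TRUE))
      }
    }
    n_dec <- stats::rpois(1, cfg$decoy_rate * span)
    if (n_dec > 0) {
      offs <- c(offs, sample.int(span, n_dec, replace = TRUE))
      texts <- c(texts, sample(pools$decoy, n_dec, replace = TRUE))
    }
    if (flagged[i]) {
      n_g <- 10L + sample.int(6L, 1) - 1L
      offs <- c(offs, sample.int(span, n_g, replace = TRUE))
      texts <- c(texts, sample(lexicon$gynae_terms, n_g, replace = TRUE))
    }
    dates <- period_start + offs - 1L
    # monthly-activity constraint: top up empty calendar months
    missing <- setdiff(months, unique(format(dates, "%Y-%m")))
    for (m in missing) {
      day1 <- as.Date(paste0(m, "-01"))
      last <- min(seq(day1, by = "month", length.out = 2)[2] - 1,
                  lookahead_end)
      d <- day1 + sample.int(as.integer(last - day1) + 1L, 1) - 1L
      dates <- c(dates, d)
      texts <- c(texts, sample(pools$decoy, 1))
    }
    # medical-keyword constraint
    if (n_cond == 0 && !flagged[i]) {
      dates <- c(dates, period_start + sample.int(span, 1) - 1L)
      texts <- c(texts, sample(pools$condition, 1))
    }
    all_q[[i]] <- tibble::tibble(user_id = ids[i], date = dates,
                                 text = texts)
  }
  list(controls = controls(dplyr::bind_rows(all_q), period_start,
                           period_end, lookahead_end),
       truth = tibble::tibble(user_id = ids, flagged = flagged))
}
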