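#' Default T1/T2 window grid
#'
#' Start times T1 step from 30 to `t1_max` days before referral in
#' `step`-day increments; for each T1, end times T2 are 1 day plus the
#' multiples of `step` strictly below T1.
#'
#' @param step grid step in days (default 30).
#' @param t1_max largest start time (default 700).
#' @return tibble with columns `t1`, `t2`.
#' @export
default_window_grid <- function(step = 30, t1_max = 700) {
  t1s <- seq(step, t1_max, by = step)
  dplyr::bind_rows(lapply(t1s, function(t1) {
    t2s <- c(1, if (t1 > step) seq(step, t1 - step, by = step))
    t2s <- unique(t2s[t2s < t1])
    tibble::tibble(t1 = t1, t2 = t2s)
  }))
}

#' Sweep evaluation windows
#'
#' For each (T1, T2) window: restricts the cohort to users with at least
#' one in-window query, runs leave-one-out cross-validation `n_repeats`
#' times with seeds `seed, seed + 1, ...`, and records the mean and
#' standard deviation of the AUC.  Windows leaving fewer than two users
#' in either class are flagged unevaluable rather than failing the sweep.
#'
#' @param cohort a filtered `qs_cohort`.
#' @param representation `"terms"` or `"categories"`.
#' @param lexicon a `qs_lexicon` (required for `"categories"`).
#' @param grid tibble with `t1`, `t2` columns
#'   (default [default_window_grid()]).
#' @param cfg a [model_config()].
#' @param min_patients vocabulary cutoff for the terms representation.
#' @return tibble with columns `t1`, `t2`, `n_users`, `auc_mean`,
#'   `auc_sd`, `evaluable`.
#' @export
sweep_windows <- function(cohort, representation = c("terms", "categories"),
                          lexicon = NULL, grid = default_window_grid(),
                          cfg = model_config(), min_patients = 5) {
  representation <- match.arg(representation)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    win <- window(grid$t1[k], grid$t2[k])
    inwin <- select_window(cohort, win)
    active <- unique(inwin$queries$user_id)
    sub <- subset_users(cohort, active)
    classes <- table(factor(sub$users$outcome,
                            levels = c("benign", "malignant")))
    if (any(classes < 2L))
      return(tibble::tibble(t1 = win$t1, t2 = win$t2,
                            n_users = length(active), auc_mean = NA_real_,
                            auc_sd = NA_real_, evaluable = FALSE))
    feats <- switch(representation,
      terms = terms_features(sub, win, min_patients),
      categories = category_features(sub, win, lexicon))
    aucs <- vapply(seq_len(cfg$n_repeats), function(r) {
      cfg_r <- cfg
      cfg_r$seed <- cfg$seed + r - 1L
      auc(loocv_scores(feats, cfg_r), feats$labels)
    }, numeric(1))
    tibble::tibble(t1 = win$t1, t2 = win$t2, n_users = length(active),
                   auc_mean = mean(aucs),
                   auc_sd = if (length(aucs) > 1L) stats::sd(aucs) else 0,
                   evaluable = TRUE)
  })
  dplyr::bind_rows(rows)
}

#' Compare two representations across a window sweep
#'
#' Pairs the two sweep tables window by window, reports the mean AUC
#' difference (first minus second), an exact two-sided sign test on the
#' paired differences (ties dropped), and the mean difference restricted
#' to windows where the first representation's AUC exceeds `auc_floor`.
#'
#' @param sweep_a,sweep_b tibbles from [sweep_windows()] over the same
#'   grid (e.g. terms and categories).
#' @param auc_floor restriction threshold (default 0.55).
#' @return list with `mean_diff`, `p_value`, `restricted_mean_diff`,
#'   `n_windows`, `n_restricted`.
#' @export
compare_representations <- function(sweep_a, sweep_b, auc_floor = 0.55) {
  key_a <- paste(sweep_a$t1, sweep_a$t2)
  key_b <- paste(sweep_b$t1, sweep_b$t2)
  if (!identical(sort(key_a), sort(key_b)))
    qs_stop("sweeps cover different windows", "qs_value_error")
  m <- dplyr::inner_join(sweep_a, sweep_b, by = c("t1", "t2"),
                         suffix = c("_a", "_b"))
  m <- m[m$evaluable_a & m$evaluable_b, ]
  d <- m$auc_mean_a - m$auc_mean_b
  n_pos <- sum(d > 0)
  n_nonzero <- sum(d != 0)
  p <- if (n_nonzero == 0L) 1 else
    stats::binom.test(n_pos, n_nonzero, p = 0.5,
                      alternative = "two.sided")$p.value
  restricted <- d[m$auc_mean_a > auc_floor]
  list(mean_diff = mean(d), p_value = p,
       restricted_mean_diff = if (length(restricted)) mean(restricted)
         else NA_real_,
       n_windows = length(d), n_restricted = length(restricted))
}

#' Fit the AUC-versus-sample-size regression
#'
#' Ordinary least squares of AUC on subset size, the relationship used to
#' correct AUCs measured on reduced cohorts back to a reference size.
#'
#' @param sizes numeric vector of subset sizes (at least two distinct).
#' @param aucs numeric vector of AUCs, same length.
#' @param reference_n reference (full) cohort size.
#' @return an object of class `qs_sample_curve` with `slope`,
#'   `intercept`, `reference_n` and the per-size mean table
#'   `auc_by_size`.
#' @export
#' @examples
#' fit_sample_curve(c(50, 100, 150), c(0.6, 0.7, 0.8), reference_n = 235)
fit_sample_curve <- function(sizes, aucs, reference_n) {
  if (length(unique(sizes)) < 2L)
    qs_stop("sample-size regression needs at least two distinct sizes",
            "qs_value_error")
  stopifnot(length(sizes) == length(aucs))
  fit <- stats::lm(aucs ~ sizes)
  by_size <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(size = sizes, auc = aucs), .data$size),
    auc_mean = mean(.data$auc), .groups = "drop")
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 reference_n = reference_n, auc_by_size = by_size),
            class = "qs_sample_curve")
}

#' Measure the AUC-versus-sample-size curve by subsampling
#'
#' Draws `replicates` random patient subsets (without replacement) at each
#' size, runs leave-one-out cross-validation on each subset, and fits the
#' linear AUC ~ size model over all replicate AUCs.
#'
#' @param features a `qs_features` object for the full cohort.
#' @param cfg a [model_config()].
#' @param subset_sizes integer vector of subset sizes (each at most the
#'   cohort size; at least two distinct sizes).
#' @param replicates random subsets per size (default 5).
#' @param seed integer seed for the subset draws.
#' @param max_redraws bounded retries when a draw lands in one class.
#' @return a `qs_sample_curve` (see [fit_sample_curve()]).
#' @export
auc_sample_curve <- function(features, cfg = model_config(), subset_sizes,
                             replicates = 5, seed = 1, max_redraws = 20) {
  n <- length(features$user_ids)
  stopifnot(max(subset_sizes) <= n)
  if (length(unique(subset_sizes)) < 2L)
    qs_stop("sample-size regression needs at least two distinct sizes",
            "qs_value_error")
  set.seed(seed)
  rows <- list()
  for (size in subset_sizes) {
    for (r in seq_len(replicates)) {
      for (attempt in seq_len(max_redraws)) {
        idx <- sort(sample.int(n, size))
        if (length(unique(features$labels[idx])) == 2L &&
            min(table(features$labels[idx])) >= 2L) break
        if (attempt == max_redraws)
          qs_stop("could not draw a two-class subset", "qs_eval_error")
      }
      sub <- subset_features(features, idx)
      rows[[length(rows) + 1L]] <-
        tibble::tibble(size = size,
                       auc = auc(loocv_scores(sub, cfg), sub$labels))
    }
  }
  obs <- dplyr::bind_rows(rows)
  fit_sample_curve(obs$size, obs$auc, reference_n = n)
}

subset_features <- function(features, idx) {
  f <- features
  f$user_ids <- features$user_ids[idx]
  f$labels <- features$labels[idx]
  if (!is.null(f$static_x)) f$static_x <- f$static_x[idx, , drop = FALSE]
  if (!is.null(f$user_terms)) f$user_terms <- f$user_terms[idx]
  f
}

#' Sample-size-corrected AUC
#'
#' Shifts an AUC measured on `n` patients along the fitted AUC ~ size
#' line to the curve's reference cohort size:
#' `raw_auc + slope * (reference_n - n)`, clipped to `[0, 1]`.  At
#' `n = reference_n`, or with a flat curve, the AUC is unchanged.
#'
#' @param raw_auc AUC measured on the reduced cohort.
#' @param n size of the reduced cohort (at most `curve$reference_n`).
#' @param curve a `qs_sample_curve`.
#' @return corrected AUC in `[0, 1]`.
#' @export
corrected_auc <- function(raw_auc, n, curve) {
  stopifnot(inherits(curve, "qs_sample_curve"), n <= curve$reference_n)
  min(1, max(0, raw_auc + curve$slope * (curve$reference_n - n)))
}

#' Remove users without condition queries in the first half-window
#'
#' Health-engagement filter: within evaluation window `(T1, T2)`, a user
#' is retained only if at least one of their queries in the *first half*
#' of the window — day offsets from T1 down to the midpoint
#' `T1 - floor((T1 - T2) / 2)`, inclusive — mentions a listed medical
#' condition.  Only the first half is used so that filtering near the
#' referral date cannot preferentially remove benign patients.
#'
#' @param cohort a filtered `qs_cohort`.
#' @param win a [window()].
#' @param lexicon a `qs_lexicon` with a non-empty conditions list.
#' @return list with `cohort` (retained users) and `removed` (character
#'   vector of user ids).
#' @export
engagement_filter <- function(cohort, win, lexicon) {
  stopifnot(inherits(win, "qs_window"),
            length(lexicon$conditions) > 0L)
  midpoint <- win$t1 - floor((win$t1 - win$t2) / 2)
  q <- query_offsets(cohort)
  q <- q[q$offset >= midpoint & q$offset <= win$t1, ]
  hit <- contains_phrase(normalize_text(q$text), lexicon$conditions)
  engaged <- unique(q$user_id[hit])
  retained <- cohort$users$user_id[cohort$users$user_id %in% engaged]
  list(cohort = subset_users(cohort, retained),
       removed = setdiff(cohort$users$user_id, retained))
}

#' ROC operating points at target false-positive rates
#'
#' For each target FPR, scans the thresholds induced by the score set
#' (classifying `score >= threshold` as positive) and reports the
#' operating point with the highest true-positive rate among those whose
#' empirical FPR does not exceed the target.
#'
#' @param scores numeric classification scores.
#' @param labels binary labels (see [auc()]).
#' @param fpr_targets numeric vector of admissible false-positive rates.
#' @return tibble with columns `fpr_target`, `threshold`, `tpr`, `fpr`.
#' @export
roc_operating_points <- function(scores, labels, fpr_targets) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L)
    qs_stop("operating points need both classes present", "qs_eval_error")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[y == 1L] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[y == 0L] >= t), numeric(1))
  dplyr::bind_rows(lapply(fpr_targets, function(target) {
    ok <- which(fpr <= target)
    best <- ok[which.max(tpr[ok])]
    tibble::tibble(fpr_target = target, threshold = thr[best],
                   tpr = tpr[best], fpr = fpr[best])
  }))
}
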