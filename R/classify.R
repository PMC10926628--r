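#' Gradient-boosting model configuration
#'
#' The classifier is gradient boosting with 50 weak learners; tree depth,
#' learning rate and the random seed are exposed here so every run is
#' fully specified.  `n_repeats` controls how many times window
#' evaluations are repeated (with seeds `seed, seed + 1, ...`) when
#' averaging AUCs.
#'
#' @param n_weak_learners boosting rounds (default 50).
#' @param max_depth tree depth (default 3).
#' @param learning_rate shrinkage (default 0.1).
#' @param subsample row subsampling fraction per round (default 1, i.e.
#'   deterministic boosting).
#' @param seed integer seed.
#' @param n_repeats repeats for window evaluation (default 10).
#' @return an object of class `qs_model_config`.
#' @export
model_config <- function(n_weak_learners = 50, max_depth = 3,
                         learning_rate = 0.1, subsample = 1, seed = 1,
                         n_repeats = 10) {
  stopifnot(n_weak_learners >= 1, n_repeats >= 1, learning_rate > 0,
            subsample > 0, subsample <= 1)
  structure(list(n_weak_learners = as.integer(n_weak_learners),
                 max_depth = as.integer(max_depth),
                 learning_rate = learning_rate, subsample = subsample,
                 seed = as.integer(seed),
                 n_repeats = as.integer(n_repeats)),
            class = "qs_model_config")
}

fit_gbm <- function(x, y, cfg) {
  if (length(unique(y)) < 2L)
    qs_stop("single-class training fold: cannot fit classifier",
            "qs_eval_error")
  if (cfg$subsample < 1) {
    # stochastic boosting draws from the R RNG: seed it locally without
    # disturbing the caller's random stream
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(cfg$seed)
  }
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = cfg$max_depth, eta = cfg$learning_rate,
                  subsample = cfg$subsample, nthread = 1,
                  seed = cfg$seed),
    data = dtrain, nrounds = cfg$n_weak_learners, verbose = 0)
}

predict_gbm <- function(booster, x) {
  as.numeric(predict(booster, xgboost::xgb.DMatrix(x, nthread = 1)))
}

#' Leave-one-out cross-validated classification scores
#'
#' Scores every user with a gradient-boosting model trained on all other
#' users.  For the terms (and combined) representation the vocabulary is
#' rebuilt inside each training fold, so terms used only by the held-out
#' patient never leak into that fold's feature space.  A fold whose
#' feature space is empty falls back to the training-fold prevalence as
#' the score.
#'
#' @param features a `qs_features` object with at least two users per
#'   class.
#' @param cfg a [model_config()].
#' @return numeric vector of scores in `[0, 1]`, one per user, named by
#'   user id.
#' @export
loocv_scores <- function(features, cfg = model_config()) {
  y <- features$labels
  n <- length(y)
  if (min(table(factor(y, levels = 0:1))) < 2L)
    qs_stop("leave-one-out needs at least two users per class",
            "qs_eval_error")
  rebuild <- !is.null(features$user_terms)
  if (!rebuild) {
    x <- features_matrix(features)
    if (ncol(x) == 0L)
      qs_stop("empty feature set", "qs_eval_error")
  } else {
    all_terms <- lapply(features$user_terms, names)
    df_all <- table(unlist(all_terms, use.names = FALSE))
  }
  scores <- numeric(n)
  for (i in seq_len(n)) {
    if (rebuild) {
      df_fold <- df_all
      held <- all_terms[[i]]
      if (length(held) > 0L) df_fold[held] <- df_fold[held] - 1L
      vocab <- sort(names(df_fold)[df_fold >= features$min_patients])
      xtr_terms <- user_terms_matrix(features$user_terms[-i], vocab)
      xte_terms <- user_terms_matrix(features$user_terms[i], vocab)
      if (!is.null(features$static_x)) {
        xtr <- cbind(xtr_terms, features$static_x[-i, , drop = FALSE])
        xte <- cbind(xte_terms, features$static_x[i, , drop = FALSE])
      } else {
        xtr <- xtr_terms
        xte <- xte_terms
      }
    } else {
      xtr <- x[-i, , drop = FALSE]
      xte <- x[i, , drop = FALSE]
    }
    if (ncol(xtr) == 0L) {
      scores[i] <- mean(y[-i])
    } else {
      booster <- fit_gbm(xtr, y[-i], cfg)
      scores[i] <- predict_gbm(booster, xte)
    }
  }
  stats::setNames(scores, features$user_ids)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' positive scores above a randomly chosen negative, with ties counting
#' one half.
#'
#' @param scores numeric scores, higher meaning more likely positive.
#' @param labels binary labels (0/1, logical, or `"benign"`/
#'   `"malignant"`).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))  # 0.75
auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  stopifnot(length(scores) == length(y))
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L)
    qs_stop("AUC needs both classes present", "qs_eval_error")
  r <- rank(scores)
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    stopifnot(all(labels %in% c("benign", "malignant")))
    as.integer(labels == "malignant")
  } else {
    y <- as.integer(labels)
    stopifnot(all(y %in% c(0L, 1L)))
    y
  }
}

#' Train a full-cohort model (no cross-validation)
#'
#' Fits the gradient-boosting classifier once on every cohort user, as
#' used when scoring an external control population.  For the terms
#' representation the vocabulary is built on all patients (controls are
#' out-of-sample, so there is no leakage concern).
#'
#' @param cohort a filtered `qs_cohort`.
#' @param win the [window()] to featurize (e.g. `window(270, 1)`).
#' @param representation `"terms"` or `"categories"`.
#' @param lexicon a `qs_lexicon` (required for `"categories"`).
#' @param cfg a [model_config()].
#' @param min_patients vocabulary document-frequency cutoff for terms.
#' @return an object of class `qs_model` carrying the booster, the frozen
#'   vocabulary (terms) or lexicon (categories), the window and the
#'   configuration.
#' @export
fit_cohort_model <- function(cohort, win,
                             representation = c("terms", "categories"),
                             lexicon = NULL, cfg = model_config(),
                             min_patients = 5) {
  representation <- match.arg(representation)
  if (representation == "terms") {
    vocab <- build_vocabulary(cohort, win, min_patients)
    x <- vectorize_terms(cohort, win, vocab)
  } else {
    stopifnot(inherits(lexicon, "qs_lexicon"))
    vocab <- NULL
    x <- vectorize_categories(cohort, win, lexicon)
  }
  y <- as.integer(cohort$users$outcome == "malignant")
  booster <- fit_gbm(x, y, cfg)
  structure(list(booster = booster, representation = representation,
                 vocab = vocab, lexicon = lexicon, window = win,
                 cfg = cfg, feature_names = colnames(x)),
            class = "qs_model")
}

#' @export
print.qs_model <- function(x, ...) {
  cat("<qs_model> ", x$representation, " representation, ",
      length(x$feature_names), " features, window (", x$window$t1, ", ",
      x$window$t2, ")\n", sep = "")
  invisible(x)
}
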