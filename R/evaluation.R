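# Group-constrained repeated nested cross-validation, support-weighted
# metrics, vote aggregation and the corrected McNemar comparison.

#' Runner roster of a window set or session list
#'
#' @param x A window set or a list of sessions.
#' @return Data frame with columns `runner_id`, `group`.
#' @export
runner_roster <- function(x) {
  if (inherits(x, "exertr_window_set")) {
    df <- unique(x$meta[, c("runner_id", "group")])
  } else {
    df <- data.frame(runner_id = vapply(x, `[[`, character(1), "runner_id"),
                     group = vapply(x, `[[`, character(1), "group"))
  }
  rownames(df) <- NULL
  df[order(df$group, df$runner_id), , drop = FALSE]
}

#' Draw one group-constrained fold plan
#'
#' Partitions the runners into `k` folds of two, each containing exactly
#' one trained and one untrained runner. The pairing of untrained to
#' trained runners is drawn uniformly at random, so there are `n!` distinct
#' plans for `n` runners per group.
#'
#' @param roster Data frame with `runner_id`, `group` (equal group sizes).
#' @param seed Integer seed.
#' @return Object of class `"exertr_fold_plan"`: list of character vectors
#'   of runner ids.
#' @export
make_fold_plan <- function(roster, seed = 1L) {
  tr <- sort(roster$runner_id[roster$group == "trained"])
  un <- sort(roster$runner_id[roster$group == "untrained"])
  if (length(tr) != length(un) || length(tr) == 0L) {
    stop("fold construction requires equal, nonzero group sizes", call. = FALSE)
  }
  set.seed(seed)
  perm <- sample(length(un))
  plan <- lapply(seq_along(tr), function(i) c(tr[i], un[perm[i]]))
  structure(plan, class = "exertr_fold_plan", k = length(tr))
}

#' Number of distinct constrained fold plans
#'
#' With folds identified by their trained member, a plan is a bijection
#' from trained to untrained runners, so there are `n!` plans for `n`
#' runners per group (720 for the 6 + 6 cohort).
#'
#' @param n_per_group Runners per group.
#' @return Integer count.
#' @export
count_fold_plans <- function(n_per_group) {
  stopifnot(n_per_group >= 1)
  factorial(n_per_group)
}

# Draw n distinct constrained plans without replacement, seeded.
sample_fold_plans <- function(roster, n, seed) {
  total <- count_fold_plans(sum(roster$group == "trained"))
  if (n > total) stop("asked for more distinct fold plans than exist (", total, ")", call. = FALSE)
  plans <- list()
  seen <- character(0)
  s <- seed
  while (length(plans) < n) {
    p <- make_fold_plan(roster, seed = s)
    key <- paste(vapply(p, paste, character(1), collapse = "+"), collapse = "|")
    if (!key %in% seen) {
      seen <- c(seen, key)
      plans[[length(plans) + 1L]] <- p
    }
    s <- s + 1L
  }
  plans
}

sample_hyperparams <- function(space, n_iter, seed) {
  set.seed(seed)
  lapply(seq_len(n_iter), function(i) {
    draw <- lapply(space, function(dim) {
      if (is.list(dim) && !is.null(dim$log_uniform)) {
        rng <- log(dim$log_uniform)
        exp(stats::runif(1, rng[1], rng[2]))
      } else {
        dim[[sample.int(length(dim), 1)]]
      }
    })
    names(draw) <- names(space)
    draw
  })
}

search_space_size <- function(space) {
  if (length(space) == 0L) return(0L)
  sizes <- vapply(space, function(dim) {
    if (is.list(dim) && !is.null(dim$log_uniform)) Inf else length(dim)
  }, numeric(1))
  prod(sizes)
}

#' Nested random hyperparameter search with constrained inner folds
#'
#' Samples `n_iter` hyperparameter draws from the search space and scores
#' each by constrained k-fold cross-validation over the training runners
#' (inner `k` equals the per-group runner count of the training split, 5
#' when the outer split leaves 5 + 5). The score is the mean window-level
#' accuracy across inner folds; ties go to the first-sampled draw. A
#' single-point space is returned immediately without data evaluation.
#'
#' @param name Classifier name.
#' @param train Window set of the training runners.
#' @param space Search space as in [default_search_space()].
#' @param n_iter Number of random draws.
#' @param seed Integer seed.
#' @return Named list of chosen hyperparameters (possibly empty).
#' @export
nested_random_search <- function(name, train, space = default_search_space(name),
                                 n_iter = 10L, seed = 1L) {
  if (search_space_size(space) <= 1L) {
    return(lapply(space, function(dim) if (is.list(dim)) dim$log_uniform[1] else dim[[1]]))
  }
  roster <- runner_roster(train)
  if (!all(table(roster$group) >= 2L)) {
    stop("inner fold construction impossible: need at least 2 runners per group", call. = FALSE)
  }
  draws <- sample_hyperparams(space, n_iter, seed)
  inner_plan <- make_fold_plan(roster, seed = seed + 1L)
  scores <- vapply(draws, function(hp) {
    accs <- vapply(inner_plan, function(fold) {
      te <- train$meta$runner_id %in% fold
      if (!any(te) || all(te)) return(NA_real_)
      tr_ws <- subset_windows(train, which(!te))
      te_ws <- subset_windows(train, which(te))
      if (length(unique(tr_ws$meta$label)) < 2L && !name %in% c("majority", "borg")) {
        return(NA_real_)
      }
      spec <- do.call(classifier_spec, c(list(name = name), hp))
      if (name == "knn_dtw" && hp$k > n_windows(tr_ws)) return(NA_real_)
      model <- fit_classifier(spec, tr_ws, seed = seed)
      mean(predict_classifier(model, te_ws) == te_ws$meta$label)
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }, numeric(1))
  draws[[which.max(scores)]]   # which.max takes the first maximum
}

#' Repeated group-constrained nested cross-validation
#'
#' Runs `n_repetitions` (odd) rounds of constrained k-fold CV, the fold
#' plans drawn without replacement from the `n!` admissible pairings. For
#' each test fold, hyperparameters are chosen by [nested_random_search()]
#' on the remaining runners only, a model is fitted on all their windows,
#' and every window of the test fold is predicted. Window-level
#' predictions are reduced to one prediction per original (runner, marker)
#' label by majority over that label's windows (ties to `"non_exerted"`).
#'
#' @param windows Window set of the full cohort.
#' @param name Classifier name.
#' @param n_repetitions Odd number of CV repetitions (the study uses 15).
#' @param seed Integer seed.
#' @param space Hyperparameter search space (see
#'   [default_search_space()]); a single-point or empty space skips the
#'   inner search.
#' @param n_iter Random-search draws per test fold.
#' @return Data frame of per-label predictions with columns `runner_id`,
#'   `marker_t`, `group`, `repetition`, `classifier`, `true_class`,
#'   `predicted_class`.
#' @export
run_repeated_cv <- function(windows, name, n_repetitions = 15L, seed = 1L,
                            space = default_search_space(name), n_iter = 10L) {
  if (n_repetitions %% 2L == 0L) {
    stop("n_repetitions must be odd to avoid vote ties", call. = FALSE)
  }
  roster <- runner_roster(windows)
  plans <- sample_fold_plans(roster, n_repetitions, seed = seed * 1000L + 17L)
  out <- list()
  for (rep_i in seq_len(n_repetitions)) {
    plan <- plans[[rep_i]]
    for (fold in plan) {
      te <- windows$meta$runner_id %in% fold
      tr_ws <- subset_windows(windows, which(!te))
      te_ws <- subset_windows(windows, which(te))
      if (n_windows(te_ws) == 0L) next
      # leakage guard: no test runner's window may enter the fit
      stopifnot(!any(tr_ws$meta$runner_id %in% fold))
      hp <- nested_random_search(name, tr_ws, space = space, n_iter = n_iter,
                                 seed = seed + 31L * rep_i)
      spec <- do.call(classifier_spec, c(list(name = name), hp))
      model <- fit_classifier(spec, tr_ws, seed = seed + 31L * rep_i)
      pred <- predict_classifier(model, te_ws)
      agg <- reduce_windows_to_labels(te_ws$meta, pred)
      agg$repetition <- rep_i
      agg$classifier <- name
      out[[length(out) + 1L]] <- agg
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "fold_plans") <- plans
  res
}

# Majority vote over a label's windows; ties resolve to non_exerted.
reduce_windows_to_labels <- function(meta, pred) {
  key <- paste(meta$runner_id, meta$marker_t, sep = "\r")
  rows <- lapply(split(seq_along(key), key), function(idx) {
    n_ex <- sum(pred[idx] == "exerted")
    data.frame(runner_id = meta$runner_id[idx[1]],
               marker_t = meta$marker_t[idx[1]],
               group = meta$group[idx[1]],
               true_class = meta$label[idx[1]],
               predicted_class = if (n_ex > length(idx) / 2) "exerted" else "non_exerted")
  })
  out <- do.call(rbind, rows)
  out[order(out$runner_id, out$marker_t), , drop = FALSE]
}

#' Aggregate repeated-CV predictions into consensus predictions
#'
#' For each (runner, marker) label, the modal predicted class across the
#' odd number of repetitions becomes the consensus ("real") prediction;
#' with an odd count no tie is possible.
#'
#' @param preds Prediction data frame from [run_repeated_cv()].
#' @return Data frame with one consensus row per label.
#' @export
aggregate_votes <- function(preds) {
  key <- paste(preds$runner_id, preds$marker_t, sep = "\r")
  rows <- lapply(split(seq_len(nrow(preds)), key), function(idx) {
    if (length(idx) %% 2L == 0L) {
      stop("even repetition count per label; vote could tie", call. = FALSE)
    }
    n_ex <- sum(preds$predicted_class[idx] == "exerted")
    data.frame(runner_id = preds$runner_id[idx[1]],
               marker_t = preds$marker_t[idx[1]],
               group = preds$group[idx[1]],
               classifier = preds$classifier[idx[1]],
               true_class = preds$true_class[idx[1]],
               predicted_class = if (n_ex > length(idx) / 2) "exerted" else "non_exerted")
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$runner_id, out$marker_t), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Confusion matrix and support-weighted classification metrics
#'
#' Computes the 2x2 confusion matrix (rows = true class, columns =
#' predicted class), per-class precision, recall and F1, overall accuracy,
#' and the support-weighted averages (each class's metric weighted by its
#' true-label count). Weighted recall is algebraically identical to
#' accuracy. A class never predicted gets precision 0.
#'
#' @param truth,pred Character vectors of true and predicted classes, or a
#'   prediction data frame with `true_class`/`predicted_class` in `truth`.
#' @return List with `confusion`, `per_class` (data frame), `accuracy`,
#'   and `weighted` (named vector: precision, recall, f1).
#' @export
compute_metrics <- function(truth, pred = NULL) {
  if (is.data.frame(truth)) {
    pred <- truth$predicted_class
    truth <- truth$true_class
  }
  stopifnot(length(truth) == length(pred), length(truth) > 0)
  lv <- exertion_levels()
  cm <- table(factor(truth, levels = lv), factor(pred, levels = lv))
  cm <- matrix(as.numeric(cm), 2, 2, dimnames = list(true = lv, predicted = lv))
  support <- rowSums(cm)
  total <- sum(cm)
  per_class <- do.call(rbind, lapply(seq_along(lv), function(i) {
    tp <- cm[i, i]
    prec <- if (sum(cm[, i]) > 0) tp / sum(cm[, i]) else 0
    rec <- if (support[i] > 0) tp / support[i] else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = lv[i], support = support[i], precision = prec,
               recall = rec, f1 = f1)
  }))
  rownames(per_class) <- NULL
  w <- support / total
  weighted <- c(precision = sum(w * per_class$precision),
                recall = sum(w * per_class$recall),
                f1 = sum(w * per_class$f1))
  list(confusion = cm, per_class = per_class,
       accuracy = sum(diag(cm)) / total, weighted = weighted)
}

#' Round half away from zero
#'
#' Table-formatting rounding (so 54.55 prints as 54.6, not banker's 54.5).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Paired 2x2 contingency table for two classifiers
#'
#' Cell semantics: `C00` both correct, `C11` both incorrect, `C01` only
#' classifier 1 correct, `C10` only classifier 2 correct. Both consensus
#' prediction sets must cover the identical (runner, marker) label set.
#'
#' @param cons1,cons2 Consensus prediction data frames from
#'   [aggregate_votes()].
#' @return Named numeric vector `c(C00, C01, C10, C11)`.
#' @export
mcnemar_table <- function(cons1, cons2) {
  k1 <- paste(cons1$runner_id, cons1$marker_t, sep = "\r")
  k2 <- paste(cons2$runner_id, cons2$marker_t, sep = "\r")
  if (length(k1) != length(k2) || !setequal(k1, k2) || anyDuplicated(k1)) {
    stop("the two classifiers must cover the identical label set", call. = FALSE)
  }
  cons2 <- cons2[match(k1, k2), , drop = FALSE]
  ok1 <- cons1$predicted_class == cons1$true_class
  ok2 <- cons2$predicted_class == cons2$true_class
  c(C00 = sum(ok1 & ok2), C01 = sum(ok1 & !ok2),
    C10 = sum(!ok1 & ok2), C11 = sum(!ok1 & !ok2))
}

#' Continuity-corrected McNemar test
#'
#' Edwards' corrected statistic
#' `Z = (|C01 - C10| - 1)^2 / (C01 + C10)` compared against the
#' chi-squared quantile with one degree of freedom (3.841459 at
#' alpha = 0.05). If the classifiers disagree nowhere (`C01 + C10 = 0`)
#' the result is defined as `Z = 0`, no rejection, with a warning.
#'
#' @param tab Contingency vector from [mcnemar_table()].
#' @param alpha Significance level.
#' @return List with `Z`, `critical`, `alpha`, `reject`.
#' @export
mcnemar_test <- function(tab, alpha = 0.05) {
  b <- tab[["C01"]]; c_ <- tab[["C10"]]
  critical <- stats::qchisq(1 - alpha, df = 1)
  if (b + c_ == 0) {
    warning("classifiers disagree on no label; McNemar statistic defined as 0", call. = FALSE)
    return(list(Z = 0, critical = critical, alpha = alpha, reject = FALSE))
  }
  Z <- (abs(b - c_) - 1)^2 / (b + c_)
  list(Z = Z, critical = critical, alpha = alpha, reject = Z > critical)
}
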