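test_that("fold plans pair one trained with one untrained runner", {
  plan <- make_fold_plan(mk_roster(6), seed = 1)
  expect_length(plan, 6)
  for (fold in plan) {
    expect_length(fold, 2)
    expect_equal(sum(startsWith(fold, "T")), 1)
    expect_equal(sum(startsWith(fold, "U")), 1)
  }
  expect_setequal(unlist(plan), mk_roster(6)$runner_id)
  # the 1+1 cohort has exactly one admissible plan
  expect_length(make_fold_plan(mk_roster(1), seed = 3), 1)
  expect_identical(make_fold_plan(mk_roster(6), seed = 8),
                   make_fold_plan(mk_roster(6), seed = 8))
  expect_false(identical(make_fold_plan(mk_roster(6), seed = 8),
                         make_fold_plan(mk_roster(6), seed = 9)))
  bad <- mk_roster(3)[-1, ]
  expect_error(make_fold_plan(bad, seed = 1), "equal")
})

test_that("the constraint holds across thousands of seeded draws", {
  roster <- mk_roster(6)
  for (s in 1:2000) {
    plan <- make_fold_plan(roster, seed = s)
    ok <- vapply(plan, function(f) {
      sum(startsWith(f, "T")) == 1 && sum(startsWith(f, "U")) == 1
    }, logical(1))
    expect_true(all(ok))
  }
})

test_that("the number of admissible plans is n!, matching enumeration", {
  expect_equal(count_fold_plans(6), 720)
  expect_equal(count_fold_plans(1), 1)
  for (n in 2:5) {
    expect_equal(count_fold_plans(n), length(enumerate_fold_plans(n)))
  }
  # sampled plans without replacement are distinct
  plans <- exertr:::sample_fold_plans(mk_roster(6), 15, seed = 4)
  keys <- vapply(plans, function(p) paste(vapply(p, paste, character(1),
                                                collapse = "+"), collapse = "|"),
                 character(1))
  expect_equal(anyDuplicated(keys), 0)
  expect_error(exertr:::sample_fold_plans(mk_roster(2), 3, seed = 1), "more distinct")
})

test_that("nested random search returns single points untouched and picks the better draw", {
  ws <- borg_exact_windows(seed = 7, stride = 60)
  single <- nested_random_search("knn_dtw", ws,
                                 space = list(k = 3L, neighbor_weighting = "uniform"),
                                 n_iter = 5, seed = 1)
  expect_equal(single, list(k = 3L, neighbor_weighting = "uniform"))
  # two-point space: k = 1 separates the noiseless cohort; a k as large as
  # the training set collapses to the majority vote and misses one class
  n_tr <- exertr:::n_windows(ws)
  best <- nested_random_search("knn_dtw", ws,
                               space = list(k = c(1L, as.integer(floor(n_tr * 0.5))),
                                            neighbor_weighting = c("uniform")),
                               n_iter = 4, seed = 2)
  expect_equal(best$k, 1L)
  # seeded: identical draws across runs
  expect_identical(exertr:::sample_hyperparams(default_search_space("svm"), 5, 9),
                   exertr:::sample_hyperparams(default_search_space("svm"), 5, 9))
})

test_that("repeated CV produces one prediction per label and repetition, without leakage", {
  ws <- borg_exact_windows(seed = 7, stride = 60)
  n_labels <- nrow(unique(ws$meta[, c("runner_id", "marker_t")]))
  expect_error(run_repeated_cv(ws, "majority", n_repetitions = 4, seed = 1), "odd")
  p <- run_repeated_cv(ws, "majority", n_repetitions = 3, seed = 1)
  expect_equal(nrow(p), 3 * n_labels)
  expect_equal(sort(unique(p$repetition)), 1:3)
  # every drawn plan satisfies the one-per-group constraint
  for (plan in attr(p, "fold_plans")) {
    for (fold in plan) {
      expect_equal(sum(startsWith(fold, "T")), 1)
      expect_equal(sum(startsWith(fold, "U")), 1)
    }
  }
  # majority prediction equals the training majority class everywhere
  expect_true(all(p$predicted_class == "non_exerted") ||
                all(tapply(p$predicted_class, p$repetition,
                           function(x) length(unique(x))) == 1))
})

test_that("the Borg classifier is exact on the calibrated noiseless cohort", {
  ws <- borg_exact_windows(seed = 7, stride = 60)
  p <- run_repeated_cv(ws, "borg", n_repetitions = 3, seed = 2)
  cons <- aggregate_votes(p)
  expect_equal(mean(cons$predicted_class == cons$true_class), 1)
})

test_that("vote aggregation takes the mode and refuses even counts", {
  votes <- data.frame(runner_id = "a", marker_t = 100, group = "trained",
                      classifier = "x", true_class = "exerted",
                      repetition = 1:15,
                      predicted_class = rep(c("exerted", "non_exerted"),
                                            times = c(8, 7)))
  cons <- aggregate_votes(votes)
  expect_equal(cons$predicted_class, "exerted")
  expect_equal(aggregate_votes(transform(votes, predicted_class = "non_exerted"))$predicted_class,
               "non_exerted")
  expect_error(aggregate_votes(votes[1:4, ]), "even")
  # counting oracle on random vote sets
  set.seed(31)
  for (i in 1:25) {
    n <- sample(c(3, 5, 7, 15), 1)
    pv <- sample(exertion_levels(), n, replace = TRUE)
    df <- data.frame(runner_id = "r", marker_t = 1, group = "trained",
                     classifier = "x", true_class = "exerted",
                     repetition = seq_len(n), predicted_class = pv)
    expected <- names(which.max(table(factor(pv, levels = exertion_levels()))))
    expect_equal(aggregate_votes(df)$predicted_class, expected)
  }
})

test_that("metrics reproduce hand-computed confusion arithmetic", {
  # counts (56, 10; 7, 39): overall accuracy 84.8, precisions 88.9/79.6
  truth <- rep(exertion_levels(), times = c(66, 46))
  pred <- c(rep("non_exerted", 56), rep("exerted", 10),
            rep("non_exerted", 7), rep("exerted", 39))
  m <- compute_metrics(truth, pred)
  expect_equal(round_half_away(100 * m$accuracy), 84.8)
  expect_equal(round_half_away(100 * m$per_class$precision), c(88.9, 79.6))
  expect_equal(round_half_away(100 * m$per_class$recall), c(84.8, 84.8))
  # constant predictor on the 66/46 label split
  m2 <- compute_metrics(truth, rep("non_exerted", 112))
  expect_equal(round_half_away(100 * m2$accuracy), 58.9)
  expect_equal(round_half_away(100 * m2$weighted[["precision"]]), 34.7)
  expect_equal(round_half_away(100 * m2$weighted[["f1"]]), 43.7)
  # perfect predictions
  m3 <- compute_metrics(truth, truth)
  expect_equal(m3$accuracy, 1)
  expect_equal(unname(m3$weighted), c(1, 1, 1))
})

test_that("weighted recall is identically accuracy", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    truth <- sample(exertion_levels(), n, replace = TRUE, prob = c(0.6, 0.4))
    pred <- sample(exertion_levels(), n, replace = TRUE)
    m <- compute_metrics(truth, pred)
    expect_equal(m$weighted[["recall"]], m$accuracy, tolerance = 1e-12)
  }
})

test_that("contingency tables count paired correctness as specified", {
  mkcons <- function(pred, truth) {
    data.frame(runner_id = "r", marker_t = seq_along(pred), group = "trained",
               classifier = "x", true_class = truth, predicted_class = pred)
  }
  truth <- rep(exertion_levels(), 5)
  same <- mkcons(truth, truth)
  tab <- mcnemar_table(same, same)
  expect_equal(tab[["C01"]], 0)
  expect_equal(tab[["C10"]], 0)
  expect_equal(tab[["C00"]], 10)
  allwrong <- mkcons(rev(truth), truth)
  tab2 <- mcnemar_table(same, allwrong)
  expect_equal(unname(tab2), c(0, 10, 0, 0))
  # brute-force tally on random vectors
  set.seed(23)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    tr <- sample(exertion_levels(), n, replace = TRUE)
    p1 <- sample(exertion_levels(), n, replace = TRUE)
    p2 <- sample(exertion_levels(), n, replace = TRUE)
    tab <- mcnemar_table(mkcons(p1, tr), mkcons(p2, tr))
    ok1 <- p1 == tr; ok2 <- p2 == tr
    expect_equal(unname(tab), c(sum(ok1 & ok2), sum(ok1 & !ok2),
                                sum(!ok1 & ok2), sum(!ok1 & !ok2)))
    expect_equal(sum(tab), n)
  }
  mismatch <- mkcons(truth[1:8], truth[1:8])
  expect_error(mcnemar_table(same, mismatch), "identical label set")
})

test_that("the corrected McNemar statistic behaves as the chi-squared reference demands", {
  res <- mcnemar_test(c(C00 = 10, C01 = 15, C10 = 5, C11 = 3))
  expect_equal(res$Z, (10 - 1)^2 / 20)       # 4.05
  expect_true(res$reject)
  expect_equal(res$critical, 3.841459, tolerance = 1e-6)
  # direction cross-check with an exact binomial test on the discordant cells
  expect_lt(stats::binom.test(15, 20, 0.5)$p.value, 0.05)
  # symmetric discordance never rejects at alpha = 0.05
  for (b in c(1, 5, 20)) {
    r <- mcnemar_test(c(C00 = 0, C01 = b, C10 = b, C11 = 0))
    expect_lte(r$Z, 0.5)
    expect_false(r$reject)
  }
  # statistic is symmetric in classifier order
  r1 <- mcnemar_test(c(C00 = 1, C01 = 12, C10 = 4, C11 = 2))
  r2 <- mcnemar_test(c(C00 = 1, C01 = 4, C10 = 12, C11 = 2))
  expect_equal(r1$Z, r2$Z)
  # no disagreement: defined degenerate result with a warning
  expect_warning(r0 <- mcnemar_test(c(C00 = 9, C01 = 0, C10 = 0, C11 = 1)),
                 "disagree")
  expect_equal(r0$Z, 0)
  expect_false(r0$reject)
})
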