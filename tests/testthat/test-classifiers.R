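make_separable_set <- function(n_per_class = 6, L = 20, seed = 1) {
  set.seed(seed)
  mats <- c(
    lapply(seq_len(n_per_class), function(i) {
      cbind(seq(-1, 0, length.out = L), rnorm(L, 0, 0.05), rnorm(L, 0, 0.05))
    }),
    lapply(seq_len(n_per_class), function(i) {
      cbind(seq(1, 2, length.out = L), rnorm(L, 0, 0.05), rnorm(L, 0, 0.05))
    })
  )
  toy_window_set(mats, rep(exertion_levels(), each = n_per_class))
}

test_that("majority baseline predicts the most frequent class, ties to non_exerted", {
  # 66 non-exerted + 46 exerted windows, as in the study's label counts
  mats <- replicate(112, matrix(0, 4, 3), simplify = FALSE)
  ws <- toy_window_set(mats, rep(exertion_levels(), times = c(66, 46)))
  m <- fit_classifier(classifier_spec("majority"), ws)
  expect_true(all(predict_classifier(m, ws) == "non_exerted"))
  # exact tie resolves to the lower class level
  ws_tie <- toy_window_set(mats[1:4], rep(exertion_levels(), each = 2))
  m_tie <- fit_classifier(classifier_spec("majority"), ws_tie)
  expect_equal(predict_classifier(m_tie, ws_tie)[1], "non_exerted")
  # tolerates a single-class training set
  ws_one <- toy_window_set(mats[1:3], rep("exerted", 3))
  expect_true(all(predict_classifier(fit_classifier(classifier_spec("majority"), ws_one),
                                     ws_one) == "exerted"))
})

test_that("the Borg rule thresholds mean raw heart rate over ten, strictly", {
  expect_equal(predict_borg(rep(140, 60)), "non_exerted")  # score 14
  expect_equal(predict_borg(rep(170, 60)), "exerted")      # score 17
  expect_equal(predict_borg(rep(155, 60)), "exerted")      # score 15.5 > 15
  expect_equal(predict_borg(rep(150, 60)), "non_exerted")  # boundary: 15 is not > 15
  # depends only on the heart-rate channel
  ws <- make_separable_set()
  m <- fit_classifier(classifier_spec("borg"), ws)
  base <- predict_classifier(m, ws)
  ws2 <- ws
  ws2$values[, , 2:3] <- ws2$values[, , 2:3] + 100  # perturb cadence/velocity
  expect_identical(predict_classifier(m, ws2), base)
})

test_that("kNN under DTW votes as specified", {
  ws <- make_separable_set()
  m1 <- fit_classifier(classifier_spec("knn_dtw", k = 1), ws)
  # a training window's nearest neighbour is itself
  expect_identical(predict_classifier(m1, ws), ws$meta$label)
  # k = |train| with uniform weights reduces to the majority baseline
  ws_unbal <- make_separable_set(n_per_class = 4)
  ws_unbal <- exertr:::subset_windows(ws_unbal, 1:7)  # 4 non, 3 exerted
  mall <- fit_classifier(classifier_spec("knn_dtw", k = 7), ws_unbal)
  q <- make_separable_set(seed = 2)
  expect_true(all(predict_classifier(mall, q) == "non_exerted"))
  # inverse-distance weights: two nearer points outvote a distant one
  mats3 <- list(matrix(c(0, 0), 2, 3), matrix(c(0.1, 0.1), 2, 3),
                matrix(c(5, 5), 2, 3))
  ws3 <- toy_window_set(mats3, c("exerted", "exerted", "non_exerted"))
  m3 <- fit_classifier(classifier_spec("knn_dtw", k = 3,
                                       neighbor_weighting = "inverse_distance"), ws3)
  query <- toy_window_set(list(matrix(c(0.05, 0.05), 2, 3)), "exerted")
  expect_equal(predict_classifier(m3, query), "exerted")
  expect_error(predict_classifier(fit_classifier(classifier_spec("knn_dtw", k = 99), ws), ws),
               "exceeds")
})

test_that("SVM separates separable windows and underfits with tiny C", {
  ws <- make_separable_set()
  big <- fit_classifier(classifier_spec("svm", C = 1000), ws)
  expect_equal(mean(predict_classifier(big, ws) == ws$meta$label), 1)
  tiny <- fit_classifier(classifier_spec("svm", C = 1e-3), ws)
  expect_lte(mean(predict_classifier(tiny, ws) == ws$meta$label),
             mean(predict_classifier(big, ws) == ws$meta$label))
  # XOR-like layout needs the RBF kernel
  xor_mats <- list(matrix(c(0, 0), 2, 3), matrix(c(1, 1), 2, 3),
                   matrix(c(0, 1), 2, 3), matrix(c(1, 0), 2, 3))
  # flatten: first two have HR (0,0)/(1,1), labels by parity
  xw <- toy_window_set(xor_mats, c("non_exerted", "non_exerted",
                                   "exerted", "exerted"))
  mx <- fit_classifier(classifier_spec("svm", C = 100, gamma = 1), xw)
  expect_identical(predict_classifier(mx, xw), xw$meta$label)
  # single-class training set errors, naming the class
  ws_one <- exertr:::subset_windows(ws, which(ws$meta$label == "exerted"))
  expect_error(fit_classifier(classifier_spec("svm"), ws_one), "exerted")
})

test_that("classifiers are pure at predict time", {
  ws <- make_separable_set()
  for (name in c("majority", "borg", "knn_dtw", "svm", "sfa")) {
    m <- suppressWarnings(fit_classifier(classifier_spec(name), ws, seed = 3))
    expect_identical(predict_classifier(m, ws), predict_classifier(m, ws))
  }
})
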