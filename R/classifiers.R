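# The classifier roster behind one fit/predict contract.

#' Classifier specification
#'
#' Names one of the seven classifiers and carries its hyperparameters.
#' Unspecified hyperparameters take the declared defaults from
#' [default_hyperparams()].
#'
#' @param name One of `"majority"`, `"borg"`, `"sfa"`, `"knn_dtw"`,
#'   `"svm"`, `"cnn"`, `"gru"`.
#' @param ... Hyperparameter overrides (e.g. `k = 3`, `C = 10`).
#' @return Object of class `"exertr_classifier_spec"`.
#' @export
classifier_spec <- function(name = c("majority", "borg", "sfa", "knn_dtw",
                                     "svm", "cnn", "gru"), ...) {
  name <- match.arg(name)
  hp <- utils::modifyList(default_hyperparams(name), list(...))
  validate_hyperparams(name, hp)
  structure(list(name = name, hyperparams = hp),
            class = "exertr_classifier_spec")
}

#' Default hyperparameters per classifier
#'
#' @param name Classifier name.
#' @return Named list of hyperparameter defaults.
#' @export
default_hyperparams <- function(name) {
  switch(name,
    majority = list(),
    borg = list(),
    knn_dtw = list(k = 5L, neighbor_weighting = "uniform"),
    svm = list(C = 1, kernel = "radial", gamma = NA_real_),
    sfa = list(MinF = 2L, MaxF = 4L, MaxS = 4L, lambda = 1e-3),
    cnn = list(n_filters = 32L, n_conv_layers = 2L, activation = "relu",
               kernel_width = 5L, learning_rate = 1e-3, max_epochs = 100L,
               patience = 10L, batch_size = 32L),
    gru = list(n_units = 32L, dropout = 0.2, recurrent_dropout = 0,
               learning_rate = 1e-3, max_epochs = 100L, patience = 10L,
               batch_size = 32L),
    stop("unknown classifier: ", name, call. = FALSE)
  )
}

validate_hyperparams <- function(name, hp) {
  if (name == "knn_dtw") {
    stopifnot(hp$k >= 1, hp$neighbor_weighting %in% c("uniform", "inverse_distance"))
  }
  if (name == "svm") stopifnot(hp$C > 0)
  if (name == "sfa") stopifnot(hp$MinF <= hp$MaxF, hp$MaxS >= 2)
  if (name == "gru") stopifnot(hp$dropout >= 0, hp$dropout < 1,
                               hp$recurrent_dropout >= 0, hp$recurrent_dropout < 1)
  if (name == "cnn") stopifnot(hp$n_filters >= 1, hp$n_conv_layers >= 1,
                               hp$activation %in% c("relu", "selu"))
  invisible(TRUE)
}

#' Default random-search spaces
#'
#' The hyperparameter spaces sampled by [nested_random_search()]. Discrete
#' dimensions are given as value vectors; `C` and `gamma` are drawn
#' log-uniformly from the stated decade ranges.
#'
#' @param name Classifier name.
#' @return Named list describing the search space (empty for the
#'   hyperparameter-free baselines).
#' @export
default_search_space <- function(name) {
  switch(name,
    majority = list(),
    borg = list(),
    knn_dtw = list(k = c(1L, 3L, 5L, 7L),
                   neighbor_weighting = c("uniform", "inverse_distance")),
    svm = list(C = list(log_uniform = c(1e-2, 1e3)),
               gamma = list(log_uniform = c(1e-4, 1e1))),
    sfa = list(MaxF = c(4L, 6L), MaxS = c(4L, 8L)),
    cnn = list(n_filters = c(16L, 32L, 64L), n_conv_layers = c(2L, 3L),
               activation = c("relu", "selu")),
    gru = list(n_units = c(16L, 32L, 64L),
               dropout = c(0, 0.2, 0.5), recurrent_dropout = c(0, 0.2, 0.5)),
    stop("unknown classifier: ", name, call. = FALSE)
  )
}

check_two_classes <- function(train, name) {
  present <- unique(train$meta$label)
  if (length(present) < 2L) {
    stop(sprintf("cannot fit discriminative classifier '%s': training set contains only class '%s'",
                 name, present), call. = FALSE)
  }
}

#' Fit a classifier on a set of labeled windows
#'
#' @param spec A [classifier_spec()].
#' @param train A window set ([window_set()]); must contain both classes
#'   except for the majority baseline.
#' @param seed Integer seed for the stochastic fits (SFA optimizer split,
#'   SVM, neural networks). Majority, Borg and kNN are deterministic.
#' @return A fitted model of class `"exertr_model"`.
#' @export
fit_classifier <- function(spec, train, seed = 1L) {
  stopifnot(inherits(spec, "exertr_classifier_spec"),
            inherits(train, "exertr_window_set"))
  if (n_windows(train) == 0L && spec$name != "borg") {
    stop("training window set is empty", call. = FALSE)
  }
  fit <- switch(spec$name,
    majority = fit_majority(train),
    borg = list(),
    knn_dtw = fit_knn(train),
    svm = fit_svm(spec$hyperparams, train, seed),
    sfa = fit_sfa_classifier(spec$hyperparams, train, seed),
    cnn = ,
    gru = fit_nn(spec, train, seed)
  )
  structure(list(spec = spec, fit = fit), class = "exertr_model")
}

#' Predict exertion classes for a set of windows
#'
#' Pure at predict time: repeated calls on the same input agree. All
#' tie-breaks resolve to `"non_exerted"` unless documented otherwise
#' (kNN ties go to the single nearest neighbour's label).
#'
#' @param model A fitted `"exertr_model"`.
#' @param windows A window set.
#' @return Character vector of predicted classes, one per window.
#' @export
predict_classifier <- function(model, windows) {
  stopifnot(inherits(model, "exertr_model"),
            inherits(windows, "exertr_window_set"))
  if (n_windows(windows) == 0L) return(character(0))
  switch(model$spec$name,
    majority = rep(model$fit$label, n_windows(windows)),
    borg = predict_borg(windows$raw_hr),
    knn_dtw = predict_knn(model$fit, windows$values,
                          k = model$spec$hyperparams$k,
                          weighting = model$spec$hyperparams$neighbor_weighting),
    svm = predict_svm(model$fit, windows),
    sfa = predict_sfa(model$fit, windows),
    cnn = ,
    gru = predict_nn(model$fit, windows)
  )
}

# --- majority vote ---------------------------------------------------------

fit_majority <- function(train) {
  counts <- table(factor(train$meta$label, levels = exertion_levels()))
  # ties resolve to the first (lower) class level
  list(label = exertion_levels()[which.max(counts)])
}

# --- Borg heart-rate rule --------------------------------------------------

#' Borg baseline prediction from raw heart rate
#'
#' Implements the RPE ~ HR/10 rule of the Borg 6--20 scale: the mean raw
#' heart rate (bpm) of the window is divided by ten and compared to the
#' class boundary. The comparison is continuous (no rounding) and strict:
#' a window is `"exerted"` iff `mean(HR)/10 > 15`, mirroring the
#' RPE <= 15 convention of [binarize_rpe()].
#'
#' @param raw_hr Numeric matrix of un-normalized heart rate, one window per
#'   row, or a single numeric vector.
#' @return Character vector of predicted classes.
#' @export
predict_borg <- function(raw_hr) {
  if (is.vector(raw_hr)) raw_hr <- matrix(raw_hr, nrow = 1)
  score <- rowMeans(raw_hr) / 10
  ifelse(score > 15, "exerted", "non_exerted")
}

# --- k-nearest neighbours under DTW ----------------------------------------

fit_knn <- function(train) {
  check_two_classes(train, "knn_dtw")
  list(values = train$values, labels = train$meta$label)
}

#' k-nearest-neighbour prediction under multivariate DTW
#'
#' Votes among the `k` training windows nearest to each query under
#' [dtw_distance()]. With `weighting = "inverse_distance"` each neighbour's
#' vote is weighted by the reciprocal of its distance (a zero-distance
#' neighbour dominates). Vote ties are broken towards the label of the
#' single nearest neighbour. With `k` equal to the training-set size and
#' uniform weights the classifier reduces to the majority-vote baseline.
#'
#' @param fit List with `values` (n x L x 3 array) and `labels` from the
#'   training windows.
#' @param query_values Query windows as an n x L x 3 array.
#' @param k Neighbour count; must not exceed the training-set size.
#' @param weighting `"uniform"` or `"inverse_distance"`.
#' @return Character vector of predicted classes.
#' @export
predict_knn <- function(fit, query_values, k, weighting = "uniform") {
  n_train <- dim(fit$values)[1]
  if (k > n_train) stop("k (", k, ") exceeds training-set size (", n_train, ")", call. = FALSE)
  d <- dtw_cross(query_values, fit$values)
  lv <- exertion_levels()
  apply_vote <- function(di) {
    ord <- order(di)
    nn <- ord[seq_len(k)]
    w <- if (weighting == "inverse_distance") 1 / pmax(di[nn], 1e-12) else rep(1, k)
    votes <- vapply(lv, function(cl) sum(w[fit$labels[nn] == cl]), numeric(1))
    if (votes[1] == votes[2]) fit$labels[ord[1]] else lv[which.max(votes)]
  }
  vapply(seq_len(nrow(d)), function(i) apply_vote(d[i, ]), character(1))
}

# --- support vector machine ------------------------------------------------

flatten_windows <- function(windows) {
  v <- windows$values
  dim(v) <- c(dim(v)[1], dim(v)[2] * dim(v)[3])
  v
}

fit_svm <- function(hp, train, seed) {
  check_two_classes(train, "svm")
  x <- flatten_windows(train)
  y <- factor(train$meta$label, levels = exertion_levels())
  gamma <- if (is.na(hp$gamma)) 1 / ncol(x) else hp$gamma
  set.seed(seed)
  list(model = e1071::svm(x = x, y = y, kernel = hp$kernel, cost = hp$C,
                          gamma = gamma, scale = FALSE))
}

predict_svm <- function(fit, windows) {
  as.character(stats::predict(fit$model, flatten_windows(windows)))
}
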