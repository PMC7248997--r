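# Symbolic Fourier approximation (SFA) bag-of-words classifier.
#
# Each channel of a window is summarized by the real/imaginary parts of its
# first non-DC Fourier coefficients (an implicit low-pass filter), and each
# part is quantized into a small alphabet using equi-depth bin edges learned
# on training data only (multiple coefficient binning, MCB). Channel-tagged
# words over several word lengths form a bag-of-words feature vector fed to
# a linear classifier trained with cross-entropy loss. This is a
# single-word-length simplification of the WEASEL+MUSE family: no bi-grams,
# no chi-squared feature selection, no window-size ensembling.

# Real/imaginary parts of the first ceil(n_vals/2) non-DC DFT coefficients,
# interleaved Re, Im, truncated to n_vals values.
sfa_coefficients <- function(x, n_vals) {
  n_coef <- ceiling(n_vals / 2)
  if (n_coef + 1 > length(x)) {
    stop("word length exceeds available Fourier coefficients", call. = FALSE)
  }
  co <- stats::fft(x)[2:(n_coef + 1)]
  out <- as.vector(rbind(Re(co), Im(co)))
  out[seq_len(n_vals)]
}

#' Quantize one window channel into an SFA word
#'
#' @param x Numeric vector: one channel of one window.
#' @param word_length Number of symbols in the word (number of Fourier
#'   coefficient components used).
#' @param bins List of numeric break vectors, one per coefficient
#'   component, as learned by the training-data binning.
#' @return Integer vector of symbol indices in `1..(length(breaks)+1)`.
#' @export
sfa_transform <- function(x, word_length, bins) {
  vals <- sfa_coefficients(x, word_length)
  vapply(seq_len(word_length), function(p) {
    findInterval(vals[p], bins[[p]]) + 1L
  }, integer(1))
}

# Learn equi-depth (quantile) bin edges per channel and coefficient
# component from training windows only.
sfa_fit_bins <- function(values, max_word_length, MaxS) {
  n <- dim(values)[1]; n_ch <- dim(values)[3]
  probs <- seq_len(MaxS - 1) / MaxS
  lapply(seq_len(n_ch), function(ch) {
    coefs <- t(vapply(seq_len(n),
                      function(i) sfa_coefficients(values[i, , ch], max_word_length),
                      numeric(max_word_length)))
    lapply(seq_len(max_word_length), function(p) {
      unname(stats::quantile(coefs[, p], probs = probs, type = 7))
    })
  })
}

sfa_words_for_window <- function(x_window, bins, word_lengths) {
  words <- character(0)
  for (ch in seq_along(bins)) {
    for (f in word_lengths) {
      sym <- sfa_transform(x_window[, ch], f, bins[[ch]])
      words <- c(words, sprintf("c%d|f%d|%s", ch, f, paste(sym, collapse = ".")))
    }
  }
  words
}

sfa_feature_matrix <- function(windows, bins, word_lengths, vocab = NULL) {
  n <- n_windows(windows)
  all_words <- lapply(seq_len(n), function(i) {
    sfa_words_for_window(windows$values[i, , ], bins, word_lengths)
  })
  if (is.null(vocab)) vocab <- sort(unique(unlist(all_words)))
  x <- matrix(0, n, length(vocab), dimnames = list(NULL, vocab))
  for (i in seq_len(n)) {
    w <- all_words[[i]]
    w <- w[w %in% vocab]
    tab <- table(w)
    x[i, names(tab)] <- as.numeric(tab)
  }
  x
}

fit_sfa_classifier <- function(hp, train, seed) {
  check_two_classes(train, "sfa")
  word_lengths <- seq.int(hp$MinF, hp$MaxF)
  bins <- sfa_fit_bins(train$values, max(word_lengths), hp$MaxS)
  x <- sfa_feature_matrix(train, bins, word_lengths)
  y <- factor(train$meta$label, levels = exertion_levels())
  set.seed(seed)
  if (ncol(x) < 2L) x <- cbind(x, `..pad` = 0)  # glmnet needs >= 2 columns
  model <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = hp$lambda, standardize = FALSE)
  list(bins = bins, word_lengths = word_lengths, vocab = colnames(x),
       model = model)
}

predict_sfa <- function(fit, windows) {
  x <- sfa_feature_matrix(windows, fit$bins, fit$word_lengths,
                          vocab = fit$vocab)
  p <- as.numeric(stats::predict(fit$model, x, type = "response"))
  # p is P(exerted); strict > so an exact tie resolves to non_exerted
  ifelse(p > 0.5, "exerted", "non_exerted")
}
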