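# Compact neural-network engine for the CNN and GRU classifiers.
#
# Architectures follow the study design: the CNN stacks 1D convolutions,
# each followed by batch normalization and a ReLU or SeLU activation, then
# global MAX pooling over time and a dense softmax over the two classes;
# the GRU is a single recurrent layer with linear (input) and recurrent
# dropout feeding a dense softmax. Both are trained with Adam (lr 1e-3) on
# categorical cross-entropy, early stopping with patience 10 on a 10%
# stratified validation split, for at most 100 epochs. Everything runs in
# plain R matrix arithmetic; the analytic gradients are verified against
# numerical differentiation in the test suite.

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772
BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

glorot_mat <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

nn_activate <- function(x, activation) {
  if (activation == "relu") pmax(x, 0)
  else SELU_LAMBDA * ifelse(x > 0, x, SELU_ALPHA * (exp(x) - 1))
}

nn_activate_grad <- function(x, activation) {
  if (activation == "relu") (x > 0) * 1
  else SELU_LAMBDA * ifelse(x > 0, 1, SELU_ALPHA * exp(x))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# --- CNN -------------------------------------------------------------------

cnn_init <- function(hp, L, n_ch) {
  layers <- list()
  t_len <- L
  c_in <- n_ch
  for (l in seq_len(hp$n_conv_layers)) {
    kw <- min(hp$kernel_width, t_len)
    layers[[l]] <- list(
      W = glorot_mat(kw * c_in, hp$n_filters),
      b = numeric(hp$n_filters),
      gamma = rep(1, hp$n_filters), beta = numeric(hp$n_filters),
      run_mean = numeric(hp$n_filters), run_var = rep(1, hp$n_filters),
      kw = kw, c_in = c_in)
    t_len <- t_len - kw + 1
    c_in <- hp$n_filters
    if (t_len < 1) stop("window too short for the configured CNN depth", call. = FALSE)
  }
  list(layers = layers,
       Wd = glorot_mat(hp$n_filters, 2), bd = numeric(2),
       activation = hp$activation)
}

im2col <- function(X, kw) {
  n <- dim(X)[1]; t_in <- dim(X)[2]; c_in <- dim(X)[3]
  t_out <- t_in - kw + 1
  P <- matrix(0, n * t_out, kw * c_in)
  for (w in seq_len(kw)) {
    for (c in seq_len(c_in)) {
      P[, (w - 1) * c_in + c] <- as.vector(X[, w:(w + t_out - 1), c])
    }
  }
  P
}

col2im_add <- function(dP, n, t_in, c_in, kw) {
  t_out <- t_in - kw + 1
  dX <- array(0, dim = c(n, t_in, c_in))
  for (w in seq_len(kw)) {
    for (c in seq_len(c_in)) {
      dX[, w:(w + t_out - 1), c] <- dX[, w:(w + t_out - 1), c] +
        matrix(dP[, (w - 1) * c_in + c], n, t_out)
    }
  }
  dX
}

cnn_forward <- function(params, X, train = FALSE) {
  n <- dim(X)[1]
  caches <- list()
  A <- X
  for (l in seq_along(params$layers)) {
    ly <- params$layers[[l]]
    t_in <- dim(A)[2]
    t_out <- t_in - ly$kw + 1
    P <- im2col(A, ly$kw)
    Z <- sweep(P %*% ly$W, 2, ly$b, "+")
    if (train) {
      mu <- colMeans(Z)
      v <- colMeans(Z^2) - mu^2
    } else {
      mu <- ly$run_mean
      v <- ly$run_var
    }
    s <- sqrt(v + BN_EPS)
    xhat <- sweep(sweep(Z, 2, mu, "-"), 2, s, "/")
    Zbn <- sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
    Aout <- nn_activate(Zbn, params$activation)
    caches[[l]] <- list(A_in = A, P = P, xhat = xhat, s = s, Zbn = Zbn,
                        t_out = t_out, mu = mu, v = v)
    A <- array(Aout, dim = c(n, t_out, dim(Z)[2]))
  }
  # global max pooling over time
  n_f <- dim(A)[3]
  H <- matrix(0, n, n_f)
  arg <- matrix(0L, n, n_f)
  for (f in seq_len(n_f)) {
    Af <- A[, , f, drop = TRUE]
    if (is.null(dim(Af))) Af <- matrix(Af, n, dim(A)[2])
    arg[, f] <- max.col(Af, ties.method = "first")
    H[, f] <- Af[cbind(seq_len(n), arg[, f])]
  }
  logits <- sweep(H %*% params$Wd, 2, params$bd, "+")
  list(logits = logits, H = H, arg = arg, caches = caches,
       pooled_dim = dim(A))
}

bn_backward <- function(dY, xhat, s, gamma) {
  n <- nrow(dY)
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, gamma, "*")
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dZ <- sweep(sweep(sweep(dxhat, 2, m1, "-") - sweep(xhat, 2, m2, "*"),
                    2, s, "/"), 2, 1, "*")
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

cnn_backward <- function(params, fwd, X, y_onehot) {
  n <- nrow(y_onehot)
  probs <- softmax_rows(fwd$logits)
  dlogits <- (probs - y_onehot) / n
  grads <- list(Wd = t(fwd$H) %*% dlogits, bd = colSums(dlogits),
                layers = vector("list", length(params$layers)))
  dH <- dlogits %*% t(params$Wd)
  # max-pool backward
  pd <- fwd$pooled_dim
  dA <- array(0, dim = pd)
  for (f in seq_len(pd[3])) {
    dAf <- matrix(0, pd[1], pd[2])
    dAf[cbind(seq_len(pd[1]), fwd$arg[, f])] <- dH[, f]
    dA[, , f] <- dAf
  }
  for (l in rev(seq_along(params$layers))) {
    ly <- params$layers[[l]]
    cc <- fwd$caches[[l]]
    dAmat <- matrix(dA, nrow = n * cc$t_out)
    dZbn <- dAmat * nn_activate_grad(cc$Zbn, params$activation)
    bn <- bn_backward(dZbn, cc$xhat, cc$s, ly$gamma)
    dW <- t(cc$P) %*% bn$dZ
    db <- colSums(bn$dZ)
    dP <- bn$dZ %*% t(ly$W)
    grads$layers[[l]] <- list(W = dW, b = db, gamma = bn$dgamma, beta = bn$dbeta)
    dA <- col2im_add(dP, n, dim(cc$A_in)[2], ly$c_in, ly$kw)
  }
  grads
}

cnn_update_running_stats <- function(params, X) {
  fwd <- NULL
  A <- X
  for (l in seq_along(params$layers)) {
    ly <- params$layers[[l]]
    P <- im2col(A, ly$kw)
    Z <- sweep(P %*% ly$W, 2, ly$b, "+")
    mu <- colMeans(Z); v <- colMeans(Z^2) - mu^2
    params$layers[[l]]$run_mean <- BN_MOMENTUM * ly$run_mean + (1 - BN_MOMENTUM) * mu
    params$layers[[l]]$run_var <- BN_MOMENTUM * ly$run_var + (1 - BN_MOMENTUM) * v
    s <- sqrt(v + BN_EPS)
    xhat <- sweep(sweep(Z, 2, mu, "-"), 2, s, "/")
    Zbn <- sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
    Aout <- nn_activate(Zbn, params$activation)
    t_out <- dim(A)[2] - ly$kw + 1
    A <- array(Aout, dim = c(dim(A)[1], t_out, ncol(Z)))
  }
  params
}

# --- GRU -------------------------------------------------------------------

gru_init <- function(hp, n_ch) {
  U <- hp$n_units
  list(Wz = glorot_mat(n_ch, U), Uz = glorot_mat(U, U), bz = numeric(U),
       Wr = glorot_mat(n_ch, U), Ur = glorot_mat(U, U), br = numeric(U),
       Wc = glorot_mat(n_ch, U), Uc = glorot_mat(U, U), bc = numeric(U),
       Wd = glorot_mat(U, 2), bd = numeric(2), n_units = U)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

gru_forward <- function(params, X, dropout = 0, recurrent_dropout = 0,
                        train = FALSE) {
  n <- dim(X)[1]; T_len <- dim(X)[2]; U <- params$n_units
  # inverted-dropout masks, shared across timesteps (variational style)
  mx <- if (train && dropout > 0) {
    matrix(stats::rbinom(n * dim(X)[3], 1, 1 - dropout), n) / (1 - dropout)
  } else NULL
  mh <- if (train && recurrent_dropout > 0) {
    matrix(stats::rbinom(n * U, 1, 1 - recurrent_dropout), n) / (1 - recurrent_dropout)
  } else NULL
  h <- matrix(0, n, U)
  steps <- vector("list", T_len)
  for (t in seq_len(T_len)) {
    x <- X[, t, , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, n)
    if (!is.null(mx)) x <- x * mx
    hd <- if (!is.null(mh)) h * mh else h
    z <- sigmoid(sweep(x %*% params$Wz + hd %*% params$Uz, 2, params$bz, "+"))
    r <- sigmoid(sweep(x %*% params$Wr + hd %*% params$Ur, 2, params$br, "+"))
    cc <- tanh(sweep(x %*% params$Wc + (r * hd) %*% params$Uc, 2, params$bc, "+"))
    h_new <- (1 - z) * h + z * cc
    steps[[t]] <- list(x = x, h_prev = h, hd = hd, z = z, r = r, c = cc)
    h <- h_new
  }
  logits <- sweep(h %*% params$Wd, 2, params$bd, "+")
  list(logits = logits, h = h, steps = steps, mx = mx, mh = mh)
}

gru_backward <- function(params, fwd, y_onehot) {
  n <- nrow(y_onehot)
  probs <- softmax_rows(fwd$logits)
  dlogits <- (probs - y_onehot) / n
  g <- list(Wz = 0 * params$Wz, Uz = 0 * params$Uz, bz = 0 * params$bz,
            Wr = 0 * params$Wr, Ur = 0 * params$Ur, br = 0 * params$br,
            Wc = 0 * params$Wc, Uc = 0 * params$Uc, bc = 0 * params$bc,
            Wd = t(fwd$h) %*% dlogits, bd = colSums(dlogits))
  dh <- dlogits %*% t(params$Wd)
  for (t in rev(seq_along(fwd$steps))) {
    st <- fwd$steps[[t]]
    dz <- dh * (st$c - st$h_prev)
    dc <- dh * st$z
    dh_prev <- dh * (1 - st$z)
    da_c <- dc * (1 - st$c^2)
    g$Wc <- g$Wc + t(st$x) %*% da_c
    g$Uc <- g$Uc + t(st$r * st$hd) %*% da_c
    g$bc <- g$bc + colSums(da_c)
    drh <- da_c %*% t(params$Uc)
    dr <- drh * st$hd
    dhd <- drh * st$r
    da_r <- dr * st$r * (1 - st$r)
    g$Wr <- g$Wr + t(st$x) %*% da_r
    g$Ur <- g$Ur + t(st$hd) %*% da_r
    g$br <- g$br + colSums(da_r)
    dhd <- dhd + da_r %*% t(params$Ur)
    da_z <- dz * st$z * (1 - st$z)
    g$Wz <- g$Wz + t(st$x) %*% da_z
    g$Uz <- g$Uz + t(st$hd) %*% da_z
    g$bz <- g$bz + colSums(da_z)
    dhd <- dhd + da_z %*% t(params$Uz)
    if (!is.null(fwd$mh)) dhd <- dhd * fwd$mh
    dh <- dh_prev + dhd
  }
  g
}

# --- shared training harness ----------------------------------------------

flatten_params <- function(p) {
  out <- list()
  walk <- function(x, prefix) {
    keys <- if (is.null(names(x))) as.character(seq_along(x)) else names(x)
    for (i in seq_along(x)) {
      nm <- keys[i]
      v <- x[[i]]
      if (is.list(v)) walk(v, paste0(prefix, nm, "."))
      else if (is.numeric(v) && !nm %in% c("kw", "c_in", "n_units") &&
               !startsWith(nm, "run_")) {
        out[[paste0(prefix, nm)]] <<- v
      }
    }
  }
  walk(p, "")
  out
}

set_in <- function(p, path, value) {
  if (length(path) == 1L) {
    k <- suppressWarnings(as.integer(path))
    if (!is.na(k)) p[[k]] <- value else p[[path]] <- value
  } else {
    k <- suppressWarnings(as.integer(path[1]))
    key <- if (!is.na(k)) k else path[1]
    p[[key]] <- set_in(p[[key]], path[-1], value)
  }
  p
}

unflatten_params <- function(p, flat) {
  for (nm in names(flat)) {
    p <- set_in(p, strsplit(nm, ".", fixed = TRUE)[[1]], flat[[nm]])
  }
  p
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) 0 * x),
       v = lapply(flat, function(x) 0 * x), t = 0)
}

adam_step <- function(flat, grads_flat, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(flat)) {
    gch <- grads_flat[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gch
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gch^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(flat = flat, state = state)
}

ce_loss <- function(logits, y_idx) {
  probs <- softmax_rows(logits)
  -mean(log(pmax(probs[cbind(seq_along(y_idx), y_idx)], 1e-12)))
}

stratified_val_split <- function(y_idx, frac = 0.1) {
  val <- integer(0)
  for (cl in unique(y_idx)) {
    idx <- which(y_idx == cl)
    n_val <- max(1L, floor(frac * length(idx)))
    if (length(idx) > n_val) val <- c(val, sample(idx, n_val))
  }
  sort(val)
}

fit_nn <- function(spec, train, seed) {
  check_two_classes(train, spec$name)
  hp <- spec$hyperparams
  X <- train$values
  y_idx <- match(train$meta$label, exertion_levels())
  set.seed(seed)
  params <- if (spec$name == "cnn") cnn_init(hp, dim(X)[2], dim(X)[3])
            else gru_init(hp, dim(X)[3])
  val_idx <- stratified_val_split(y_idx)
  tr_idx <- setdiff(seq_along(y_idx), val_idx)
  if (length(val_idx) == 0L) { val_idx <- tr_idx }  # degenerate tiny sets
  Xtr <- X[tr_idx, , , drop = FALSE]; ytr <- y_idx[tr_idx]
  Xval <- X[val_idx, , , drop = FALSE]; yval <- y_idx[val_idx]
  flat <- flatten_params(params)
  opt <- adam_init(flat)
  best <- list(params = params, loss = Inf, epoch = 0)
  wait <- 0
  n_tr <- length(ytr)
  for (epoch in seq_len(hp$max_epochs)) {
    ord <- sample(n_tr)
    batches <- split(ord, ceiling(seq_along(ord) / hp$batch_size))
    for (bi in batches) {
      Xb <- Xtr[bi, , , drop = FALSE]
      yb <- ytr[bi]
      y1h <- matrix(0, length(yb), 2); y1h[cbind(seq_along(yb), yb)] <- 1
      if (spec$name == "cnn") {
        fwd <- cnn_forward(params, Xb, train = TRUE)
        grads <- cnn_backward(params, fwd, Xb, y1h)
        params <- cnn_update_running_stats(params, Xb)
      } else {
        fwd <- gru_forward(params, Xb, dropout = hp$dropout,
                           recurrent_dropout = hp$recurrent_dropout,
                           train = TRUE)
        grads <- gru_backward(params, fwd, y1h)
      }
      loss <- ce_loss(fwd$logits, yb)
      if (!is.finite(loss)) stop("non-finite training loss", call. = FALSE)
      res <- adam_step(flatten_params(params), flatten_params(grads),
                       opt, hp$learning_rate)
      opt <- res$state
      params <- unflatten_params(params, res$flat)
    }
    val_logits <- if (spec$name == "cnn") cnn_forward(params, Xval)$logits
                  else gru_forward(params, Xval)$logits
    val_loss <- ce_loss(val_logits, yval)
    if (!is.finite(val_loss)) stop("non-finite validation loss", call. = FALSE)
    if (val_loss < best$loss - 1e-9) {
      best <- list(params = params, loss = val_loss, epoch = epoch)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= hp$patience) break
    }
  }
  list(params = best$params, name = spec$name, hp = hp)
}

predict_nn <- function(fit, windows) {
  X <- windows$values
  logits <- if (fit$name == "cnn") cnn_forward(fit$params, X)$logits
            else gru_forward(fit$params, X)$logits
  probs <- softmax_rows(logits)
  # strict >: an exact tie resolves to non_exerted
  ifelse(probs[, 2] > probs[, 1], "exerted", "non_exerted")
}
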