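# Minimal neural-network engine used by the feature encoders and the fusion
# grading head: dense layers, batch normalization, ReLU, dropout, linear
# residual projections, AdamW, class-weighted cross-entropy and MSE losses,
# mini-batch training with early stopping. Matrices are n x d (rows =
# samples); all heavy products go through BLAS.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- fully connected stacks (encoder feature stages) -----------------------

# fc: list of list(W, b); ReLU between layers, linear output.
fc_forward <- function(fc, X) {
  h <- X
  for (i in seq_along(fc)) {
    h <- sweep(h %*% fc[[i]]$W, 2, fc[[i]]$b, "+")
    if (i < length(fc)) h <- relu(h)
  }
  h
}

fc_init <- function(dims, seed) {
  with_seed(seed, lapply(seq_len(length(dims) - 1L), function(i) {
    list(W = matrix(stats::rnorm(dims[i] * dims[i + 1], 0, sqrt(2 / dims[i])),
                    nrow = dims[i], ncol = dims[i + 1]),
         b = rep(0, dims[i + 1]))
  }))
}

# ---- AdamW -----------------------------------------------------------------

adamw_init <- function(params) {
  list(m = rapply(params, function(p) p * 0, how = "replace"),
       v = rapply(params, function(p) p * 0, how = "replace"),
       t = 0L)
}

# params/grads/state$m/state$v share the same nested list structure
adamw_step <- function(params, grads, state, lr, weight_decay = 1e-4,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + weight_decay * p)
    list(p = p, m = m, v = v)
  }
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(rec, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      walk(p, g, m, v)
    }
  }
  out <- rec(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}

# ---- MSE training of an fc stack with an auxiliary readout -----------------

# Trains fc (ReLU-separated linear layers) plus a linear readout on top,
# minimizing MSE between readout and targets. Returns the trained fc stack
# (readout discarded unless keep_aux) and a history.
train_fc_mse <- function(fc, X, Y, Xval = NULL, Yval = NULL,
                         epochs = 30L, lr = 1e-3, batch_size = 128L,
                         patience = 5L, weight_decay = 1e-4, seed = 1L,
                         keep_aux = FALSE) {
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
  if (!is.null(Yval) && is.null(dim(Yval))) Yval <- matrix(Yval, ncol = 1)
  d_feat <- ncol(fc[[length(fc)]]$W)
  aux <- fc_init(c(d_feat, ncol(Y)), seed + 97L)[[1]]
  params <- list(fc = fc, aux = aux)
  state <- adamw_init(params)
  n <- nrow(X)

  fwd <- function(params, X) {
    hs <- list(X)
    h <- X
    for (i in seq_along(params$fc)) {
      z <- sweep(h %*% params$fc[[i]]$W, 2, params$fc[[i]]$b, "+")
      h <- if (i < length(params$fc)) relu(z) else z
      hs[[i + 1]] <- h
    }
    pred <- sweep(h %*% params$aux$W, 2, params$aux$b, "+")
    list(hs = hs, pred = pred)
  }

  val_loss <- function(params) {
    if (is.null(Xval)) return(NA_real_)
    mean((fwd(params, Xval)$pred - Yval)^2)
  }

  history <- data.frame(epoch = integer(), train_mse = numeric(), val_mse = numeric())
  best <- list(loss = Inf, params = params, epoch = 0L)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      losses <- numeric(0)
      for (bi in batches) {
        f <- fwd(params, X[bi, , drop = FALSE])
        err <- f$pred - Y[bi, , drop = FALSE]
        losses <- c(losses, mean(err^2))
        m <- length(bi) * ncol(Y)
        dpred <- 2 * err / m
        g_aux <- list(W = crossprod(f$hs[[length(f$hs)]], dpred), b = colSums(dpred))
        dh <- tcrossprod(dpred, params$aux$W)
        g_fc <- vector("list", length(params$fc))
        for (i in rev(seq_along(params$fc))) {
          if (i < length(params$fc)) dh <- dh * (f$hs[[i + 1]] > 0)
          g_fc[[i]] <- list(W = crossprod(f$hs[[i]], dh), b = colSums(dh))
          if (i > 1) dh <- tcrossprod(dh, params$fc[[i]]$W)
        }
        upd <- adamw_step(params, list(fc = g_fc, aux = g_aux), state, lr, weight_decay)
        params <- upd$params
        state <- upd$state
      }
      tl <- mean(losses)
      if (!is.finite(tl))
        stop_plum("plum_training_error", "training diverged at epoch %d", ep)
      vl <- val_loss(params)
      history <- rbind(history, data.frame(epoch = ep, train_mse = tl, val_mse = vl))
      monitor <- if (is.na(vl)) tl else vl
      if (monitor < best$loss - 1e-12) {
        best <- list(loss = monitor, params = params, epoch = ep)
      } else if (ep - best$epoch > patience) {
        break
      }
    }
  })
  out <- best$params
  list(fc = out$fc, aux = if (keep_aux) out$aux else NULL, history = history,
       stop_epoch = best$epoch)
}

# ---- grading head ----------------------------------------------------------

head_init <- function(d_in, hidden, n_classes, use_residual, seed) {
  dims <- c(d_in, hidden)
  with_seed(seed, {
    blocks <- lapply(seq_along(hidden), function(i) {
      di <- dims[i]; do <- dims[i + 1]
      list(W = matrix(stats::rnorm(di * do, 0, sqrt(2 / di)), di, do),
           b = rep(0, do),
           gamma = rep(1, do), beta = rep(0, do),
           P = if (use_residual)
             matrix(stats::rnorm(di * do, 0, sqrt(1 / di)), di, do) else NULL)
    })
    out <- list(W = matrix(stats::rnorm(hidden[length(hidden)] * n_classes, 0,
                                        sqrt(2 / hidden[length(hidden)])),
                           hidden[length(hidden)], n_classes),
                b = rep(0, n_classes))
    list(blocks = blocks, out = out)
  })
}

head_params <- function(model) {
  list(blocks = lapply(model$blocks, function(bl)
         Filter(Negate(is.null), bl[c("W", "b", "gamma", "beta", "P")])),
       out = model$out)
}

head_set_params <- function(model, params) {
  for (i in seq_along(model$blocks)) {
    for (nm in names(params$blocks[[i]])) model$blocks[[i]][[nm]] <- params$blocks[[i]][[nm]]
  }
  model$out <- params$out
  model
}

bcast <- function(v, M) matrix(v, nrow(M), ncol(M), byrow = TRUE)

head_forward <- function(model, X, training = FALSE, dropout = 0) {
  h <- X
  caches <- list()
  bn_updates <- list()
  for (i in seq_along(model$blocks)) {
    bl <- model$blocks[[i]]
    z <- sweep(h %*% bl$W, 2, bl$b, "+")
    if (training) {
      mu <- colMeans(z)
      va <- colMeans(z^2) - mu^2
      bn_updates[[i]] <- list(mu = mu, va = va)
    } else {
      mu <- model$bn[[i]]$mean
      va <- model$bn[[i]]$var
    }
    invstd <- 1 / sqrt(va + 1e-5)
    xhat <- sweep(z, 2, mu, "-") * bcast(invstd, z)
    y <- sweep(xhat * bcast(bl$gamma, xhat), 2, bl$beta, "+")
    a <- relu(y)
    if (training && dropout > 0) {
      mask <- matrix(stats::runif(length(a)) >= dropout, nrow(a), ncol(a)) / (1 - dropout)
      d <- a * mask
    } else {
      mask <- NULL
      d <- a
    }
    o <- if (!is.null(bl$P)) d + h %*% bl$P else d
    caches[[i]] <- list(h = h, xhat = xhat, invstd = invstd, y = y, mask = mask)
    h <- o
  }
  logits <- sweep(h %*% model$out$W, 2, model$out$b, "+")
  list(logits = logits, probs = softmax_rows(logits), h_last = h,
       caches = caches, bn_updates = bn_updates)
}

# Backward pass for the head under class-weighted cross-entropy.
# y_int: integer class codes; w: per-class weights.
head_backward <- function(model, fwd, X, y_int, w, dropout) {
  n <- nrow(X)
  wi <- w[y_int]
  sw <- sum(wi)
  onehot <- matrix(0, n, ncol(fwd$probs))
  onehot[cbind(seq_len(n), y_int)] <- 1
  dlogits <- (fwd$probs - onehot) * (wi / sw)
  g_out <- list(W = crossprod(fwd$h_last, dlogits), b = colSums(dlogits))
  dh <- tcrossprod(dlogits, model$out$W)
  g_blocks <- vector("list", length(model$blocks))
  for (i in rev(seq_along(model$blocks))) {
    bl <- model$blocks[[i]]
    ca <- caches_i <- fwd$caches[[i]]
    gP <- NULL
    dh_res <- 0
    if (!is.null(bl$P)) {
      gP <- crossprod(ca$h, dh)
      dh_res <- tcrossprod(dh, bl$P)
    }
    dd <- dh
    da <- if (!is.null(ca$mask)) dd * ca$mask else dd
    dy <- da * (ca$y > 0)
    dgamma <- colSums(dy * ca$xhat)
    dbeta <- colSums(dy)
    dxhat <- dy * bcast(bl$gamma, dy)
    m <- nrow(dy)
    dz <- (bcast(ca$invstd, dy) / m) *
      (m * dxhat - bcast(colSums(dxhat), dxhat) -
         ca$xhat * bcast(colSums(dxhat * ca$xhat), dxhat))
    g <- list(W = crossprod(ca$h, dz), b = colSums(dz),
              gamma = dgamma, beta = dbeta)
    if (!is.null(gP)) g$P <- gP
    g_blocks[[i]] <- g
    dh <- tcrossprod(dz, bl$W) + dh_res
  }
  list(blocks = g_blocks, out = g_out)
}

weighted_ce <- function(probs, y_int, w) {
  wi <- w[y_int]
  p <- pmax(probs[cbind(seq_along(y_int), y_int)], 1e-12)
  sum(wi * -log(p)) / sum(wi)
}
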