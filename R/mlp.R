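# Minimal dense neural network: one hidden layer, softmax output,
# cross-entropy loss, Adam or Adamax optimizer. This is the built-in reference
# backend for the two neural-network classifiers; the dense-nn configuration
# is fixed at 6 inputs -> 6 sigmoid units -> 2 softmax units with Adamax.

act_fun <- function(name) {
  switch(name,
    sigmoid = list(f = function(z) 1 / (1 + exp(-z)),
                   df = function(z, a) a * (1 - a)),
    relu = list(f = function(z) pmax(z, 0),
                df = function(z, a) (z > 0) + 0),
    stop_domain("unknown activation '%s'", name))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_init <- function(n_in, hidden, n_out, init_sd) {
  # small fixed-scale init: raw 8-bit color features are fed unscaled, so
  # weights must start small enough to keep pre-activations out of saturation
  list(W1 = matrix(rnorm(n_in * hidden, 0, init_sd), n_in, hidden),
       b1 = numeric(hidden),
       W2 = matrix(rnorm(hidden * n_out, 0, init_sd), hidden, n_out),
       b2 = numeric(n_out))
}

opt_state_like <- function(params) lapply(params, function(p) {
  list(m = p * 0, v = p * 0)
})

opt_update <- function(params, grads, state, t, optimizer, lr, beta1, beta2,
                       eps = 1e-7) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    if (optimizer == "adamax") {
      st$v <- pmax(beta2 * st$v, abs(g))
      params[[nm]] <- params[[nm]] - (lr / (1 - beta1^t)) * st$m / (st$v + eps)
    } else { # adam
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

mlp_train <- function(X, y, hidden, activation, optimizer, lr,
                      epochs = 100L, batch_size = 256L, seed = 0L,
                      beta1 = 0.9, beta2 = 0.999, init_sd = 0.01) {
  stopifnot(is.matrix(X), all(y %in% c(0L, 1L)))
  n <- nrow(X)
  Y <- cbind(1 - y, y)  # column 1 = class 0, column 2 = class 1
  act <- act_fun(activation)
  with_seed(seed, {
    params <- mlp_init(ncol(X), hidden, 2L, init_sd)
    state <- opt_state_like(params)
    t <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
        Z1 <- sweep(Xb %*% params$W1, 2, params$b1, "+")
        A1 <- act$f(Z1)
        Z2 <- sweep(A1 %*% params$W2, 2, params$b2, "+")
        P <- softmax_rows(Z2)
        dZ2 <- (P - Yb) / nrow(Xb)           # softmax + cross-entropy gradient
        grads <- list(
          W1 = NULL, b1 = NULL,
          W2 = crossprod(A1, dZ2), b2 = colSums(dZ2))
        dA1 <- dZ2 %*% t(params$W2)
        dZ1 <- dA1 * act$df(Z1, A1)
        grads$W1 <- crossprod(Xb, dZ1)
        grads$b1 <- colSums(dZ1)
        t <- t + 1L
        upd <- opt_update(params, grads, state, t, optimizer, lr, beta1, beta2)
        params <- upd$params; state <- upd$state
      }
    }
    structure(list(params = params, activation = activation,
                   hidden = hidden,
                   n_parameters = sum(vapply(params, length, 1L))),
              class = "steatoquant_mlp")
  })
}

# class-1 probability for each row of X
mlp_predict_prob <- function(model, X) {
  act <- act_fun(model$activation)
  A1 <- act$f(sweep(X %*% model$params$W1, 2, model$params$b1, "+"))
  P <- softmax_rows(sweep(A1 %*% model$params$W2, 2, model$params$b2, "+"))
  P[, 2]
}
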