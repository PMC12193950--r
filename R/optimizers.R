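# The six first-order optimizers of the refinement protocol. Each update
# function maps (weights, gradient, state, step) -> (weights, state) for a
# single leaf (matrix or vector); .applyUpdate walks the nested parameter
# list so the same code serves every layer.

.optimizerDefaults <- list(
  sgd = 0.01, rmsprop = 0.001, adam = 0.001, adagrad = 0.001,
  nadam = 0.001, adamax = 0.001)

.makeOptimizer <- function(name, lr = NA_real_) {
  name <- match.arg(name, names(.optimizerDefaults))
  if (is.na(lr)) lr <- .optimizerDefaults[[name]]
  eps <- 1e-7; rho <- 0.9; b1 <- 0.9; b2 <- 0.999
  update <- switch(name,
    sgd = function(w, g, s, t) {
      list(w = w - lr * g, s = s)
    },
    rmsprop = function(w, g, s, t) {
      if (is.null(s)) s <- list(v = g * 0)
      s$v <- rho * s$v + (1 - rho) * g * g
      list(w = w - lr * g / (sqrt(s$v) + eps), s = s)
    },
    adagrad = function(w, g, s, t) {
      if (is.null(s)) s <- list(v = g * 0)
      s$v <- s$v + g * g
      list(w = w - lr * g / (sqrt(s$v) + eps), s = s)
    },
    adam = function(w, g, s, t) {
      if (is.null(s)) s <- list(m = g * 0, v = g * 0)
      s$m <- b1 * s$m + (1 - b1) * g
      s$v <- b2 * s$v + (1 - b2) * g * g
      mhat <- s$m / (1 - b1^t)
      vhat <- s$v / (1 - b2^t)
      list(w = w - lr * mhat / (sqrt(vhat) + eps), s = s)
    },
    nadam = function(w, g, s, t) {
      if (is.null(s)) s <- list(m = g * 0, v = g * 0)
      s$m <- b1 * s$m + (1 - b1) * g
      s$v <- b2 * s$v + (1 - b2) * g * g
      mhat <- s$m / (1 - b1^t)
      vhat <- s$v / (1 - b2^t)
      mbar <- b1 * mhat + (1 - b1) * g / (1 - b1^t)
      list(w = w - lr * mbar / (sqrt(vhat) + eps), s = s)
    },
    adamax = function(w, g, s, t) {
      if (is.null(s)) s <- list(m = g * 0, u = g * 0)
      s$m <- b1 * s$m + (1 - b1) * g
      s$u <- pmax(b2 * s$u, abs(g))
      list(w = w - (lr / (1 - b1^t)) * s$m / (s$u + eps), s = s)
    })
  list(name = name, lr = lr, update = update)
}

# params/grads: parallel nested lists with numeric leaves; state mirrors the
# structure (NULL until first use)
.applyUpdate <- function(params, grads, state, opt, t) {
  if (is.list(params)) {
    if (is.null(state)) state <- vector("list", length(params))
    for (i in seq_along(params)) {
      res <- .applyUpdate(params[[i]], grads[[i]], state[[i]], opt, t)
      params[[i]] <- res$params
      state[i] <- list(res$state)   # keep NULL states from shrinking the list
    }
    return(list(params = params, state = state))
  }
  res <- opt$update(params, grads, state, t)
  list(params = res$w, state = res$s)
}
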