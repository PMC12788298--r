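# AdamW (decoupled weight decay) and global gradient-norm clipping over
# arbitrary named lists of tensors (matrices, vectors, or lists of
# matrices for convolution taps).

flatten_grads <- function(g) {
  unlist(lapply(g, function(x) if (is.list(x)) unlist(x) else as.numeric(x)),
         use.names = FALSE)
}

clip_global_norm <- function(grads, max_norm) {
  total <- sqrt(sum(flatten_grads(grads)^2))
  if (is.finite(total) && total > max_norm) {
    scale <- max_norm / total
    grads <- rapply(grads, function(x) x * scale, how = "replace")
  }
  grads
}

adamw_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0)
}

adamw_step <- function(params, grads, state, lr = 1e-3, weight_decay = 1e-2,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + weight_decay * p)
    list(p = p, m = m, v = v)
  }
  for (nm in names(params)) {
    if (is.list(params[[nm]])) {
      for (j in seq_along(params[[nm]])) {
        r <- upd(params[[nm]][[j]], grads[[nm]][[j]],
                 state$m[[nm]][[j]], state$v[[nm]][[j]])
        params[[nm]][[j]] <- r$p
        state$m[[nm]][[j]] <- r$m
        state$v[[nm]][[j]] <- r$v
      }
    } else {
      r <- upd(params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]])
      params[[nm]] <- r$p
      state$m[[nm]] <- r$m
      state$v[[nm]] <- r$v
    }
  }
  list(params = params, state = state)
}
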