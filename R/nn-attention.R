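# Multi-head scaled dot-product attention (audio queries, projected IMU
# keys/values). The per-(sample, head) attention loops run in compiled
# code (src/nn_kernels.cpp); the learned projections stay here. Attention
# weight dropout is applied after the row softmax when training.

mha_fwd <- function(Qin, KVin, T_len, B, params, heads, p_drop, train,
                    single = TRUE) {
  q <- sweep(Qin %*% params$x_q_W, 2, params$x_q_b, "+")
  k <- sweep(KVin %*% params$x_k_W, 2, params$x_k_b, "+")
  v <- sweep(KVin %*% params$x_v_W, 2, params$x_v_b, "+")
  core <- .mha_fwd_cpp(q, k, v, T_len, B, heads, p_drop, train, single)
  out <- sweep(core$O %*% params$x_o_W, 2, params$x_o_b, "+")
  list(Y = out, Qin = Qin, KVin = KVin, q = q, k = k, v = v, O = core$O,
       P = core$P, M = core$M, T_len = T_len, B = B, heads = heads,
       single = single)
}

mha_bwd <- function(cache, dY, params) {
  dWo <- crossprod(cache$O, dY)
  dbo <- colSums(dY)
  dO <- dY %*% t(params$x_o_W)
  core <- .mha_bwd_cpp(dO, cache$q, cache$k, cache$v, cache$P, cache$M,
                       cache$T_len, cache$B, cache$heads, cache$single)
  dq <- core$dq; dk <- core$dk; dv <- core$dv
  list(dQin = dq %*% t(params$x_q_W),
       dKVin = dk %*% t(params$x_k_W) + dv %*% t(params$x_v_W),
       grads = list(x_q_W = crossprod(cache$Qin, dq), x_q_b = colSums(dq),
                    x_k_W = crossprod(cache$KVin, dk), x_k_b = colSums(dk),
                    x_v_W = crossprod(cache$KVin, dv), x_v_b = colSums(dv),
                    x_o_W = dWo, x_o_b = dbo))
}

# Row-softmax attention probabilities for one (sample, head) cell,
# recomputed in R for inspection and testing.
attention_probs <- function(q_rows, k_rows) {
  S <- q_rows %*% t(k_rows) / sqrt(ncol(q_rows))
  S <- S - apply(S, 1, max)
  P <- exp(S)
  P / rowSums(P)
}
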