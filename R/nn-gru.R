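# Bidirectional GRU with backpropagation through time. The per-timestep
# recursion (forward and backward) runs in compiled code
# (src/gru_kernels.cpp); these wrappers manage caches and the two
# directions.
#
# Gate convention (r = reset, z = update, n = candidate):
#   r_t = sigmoid(W_r x_t + U_r h_{t-1} + b_r + c_r)
#   z_t = sigmoid(W_z x_t + U_z h_{t-1} + b_z + c_z)
#   n_t = tanh(W_n x_t + b_n + r_t * (U_n h_{t-1} + c_n))
#   h_t = (1 - z_t) * n_t + z_t * h_{t-1}
# Wx stacks [W_r W_z W_n] (D x 3H); Wh stacks [U_r U_z U_n] (H x 3H);
# bx and bh are the separate input/recurrent bias stacks (the recurrent
# candidate bias sits inside the reset-gate product).

gru_dir_fwd <- function(X, T_len, B, Wx, Wh, bx, bh, reverse = FALSE,
                        single = TRUE, keep = TRUE) {
  .gru_fwd_cpp(X, Wx, Wh, bx, bh, T_len, B, reverse, single, keep)
}

gru_dir_bwd <- function(cache, dY, Wx, Wh) {
  out <- .gru_bwd_cpp(cache$ptr, dY, Wx, Wh)
  list(dX = out$dX, dWx = out$dWx, dbx = as.numeric(out$dbx),
       dWh = out$dWh, dbh = as.numeric(out$dbh))
}

bigru_fwd <- function(X, T_len, B, params, single = TRUE, keep = TRUE) {
  fw <- gru_dir_fwd(X, T_len, B, params$gf_Wx, params$gf_Wh,
                    params$gf_bx, params$gf_bh, reverse = FALSE,
                    single = single, keep = keep)
  bw <- gru_dir_fwd(X, T_len, B, params$gb_Wx, params$gb_Wh,
                    params$gb_bx, params$gb_bh, reverse = TRUE,
                    single = single, keep = keep)
  list(Y = cbind(fw$Y, bw$Y), fw = fw, bw = bw)
}

bigru_bwd <- function(cache, dY, params) {
  H <- ncol(cache$fw$Y)
  gf <- gru_dir_bwd(cache$fw, dY[, 1:H, drop = FALSE],
                    params$gf_Wx, params$gf_Wh)
  gb <- gru_dir_bwd(cache$bw, dY[, H + 1:H, drop = FALSE],
                    params$gb_Wx, params$gb_Wh)
  list(dX = gf$dX + gb$dX,
       grads = list(gf_Wx = gf$dWx, gf_Wh = gf$dWh, gf_bx = gf$dbx,
                    gf_bh = gf$dbh, gb_Wx = gb$dWx, gb_Wh = gb$dWh,
                    gb_bx = gb$dbx, gb_bh = gb$dbh))
}
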