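# Model assembly: modality encoders, fusion variants, shared BiGRU
# backbone and classifier head, capacity-matched across variants.

FUSION_VARIANTS <- c("audio_only", "imu_only", "early_concat",
                     "gated_early", "mid_xattn")

#' Model configuration
#'
#' Architecture widths shared by all five fusion variants. Defaults are the
#' working configuration (embedding H = 96, four attention heads so
#' d_head = 24, BiGRU with 128 units per direction, 256 -> 128 -> 1 head);
#' smaller widths are accepted for testing.
#'
#' @param variant One of `audio_only`, `imu_only`, `early_concat`,
#'   `gated_early`, `mid_xattn`.
#' @param H Embedding width (divisible by `heads`).
#' @param H_gru Recurrent width per direction.
#' @param heads Attention heads (cross-attention variant).
#' @param conv_kernel Audio encoder kernel size (odd).
#' @param dropout_head Dropout rate in the classifier head.
#' @param dropout_fusion Dropout rate in the gate hidden layer and on
#'   attention weights.
#' @param n_mel,n_imu Input feature widths (56 log-mel bins, 6 IMU axes).
#' @param precision `"single"` (the training compute precision) or
#'   `"double"` (used for gradient verification).
#' @return An object of class `model_config`.
#' @export
model_config <- function(variant, H = 96, H_gru = 128, heads = 4,
                         conv_kernel = 5, dropout_head = 0.20,
                         dropout_fusion = 0.10, n_mel = 56, n_imu = 6,
                         precision = c("single", "double")) {
  precision <- match.arg(precision)
  stop_if(!variant %in% FUSION_VARIANTS,
          paste("unknown variant:", variant, "- must be one of",
                paste(FUSION_VARIANTS, collapse = ", ")))
  stop_if(H %% heads != 0, "H must be divisible by heads")
  stop_if(H <= 0 || H_gru <= 0, "widths must be positive")
  stop_if(conv_kernel %% 2 != 1, "conv_kernel must be odd")
  structure(list(variant = variant, H = H, H_gru = H_gru, heads = heads,
                 d_head = H %/% heads, conv_kernel = conv_kernel,
                 dropout_head = dropout_head, dropout_fusion = dropout_fusion,
                 n_mel = n_mel, n_imu = n_imu, single = precision == "single",
                 D = if (variant %in% c("early_concat", "gated_early")) 2 * H else H),
            class = "model_config")
}

#' Build a fusion model with randomly initialized weights
#'
#' Unimodal variants instantiate only their own encoder; the BiGRU backbone
#' and classifier head are constructed identically for every variant, so
#' their trainable-parameter count depends only on the fused width D.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return List with `config` and `params` (named list of weight tensors).
#' @export
build_model <- function(config, seed = 42) {
  stopifnot(inherits(config, "model_config"))
  H <- config$H; Hg <- config$H_gru; k <- config$conv_kernel
  v <- config$variant
  with_seed(seed, {
    p <- list()
    if (v != "imu_only") {
      p$a_conv1_W <- lapply(1:k, function(i) init_mat(config$n_mel, H, k * config$n_mel))
      p$a_conv1_b <- init_vec(H, k * config$n_mel)
      p$a_conv2_W <- lapply(1:k, function(i) init_mat(H, H, k * H))
      p$a_conv2_b <- init_vec(H, k * H)
    }
    if (v != "audio_only") {
      p$i_fc1_W <- init_mat(config$n_imu, H, config$n_imu)
      p$i_fc1_b <- init_vec(H, config$n_imu)
      p$i_fc2_W <- init_mat(H, H, H)
      p$i_fc2_b <- init_vec(H, H)
    }
    if (v == "gated_early") {
      p$g_fc1_W <- init_mat(2 * H, H, 2 * H)
      p$g_fc1_b <- init_vec(H, 2 * H)
      p$g_fc2_W <- init_mat(H, 2 * H, H)
      p$g_fc2_b <- init_vec(2 * H, H)
    }
    if (v == "mid_xattn") {
      p$x_phi_W <- init_mat(H, H, H)
      p$x_phi_b <- init_vec(H, H)
      for (nm in c("q", "k", "v", "o")) {
        p[[paste0("x_", nm, "_W")]] <- init_mat(H, H, H)
        p[[paste0("x_", nm, "_b")]] <- init_vec(H, H)
      }
      p$x_ln_gamma <- rep(1, H)
      p$x_ln_beta <- rep(0, H)
    }
    D <- config$D
    for (dir in c("gf", "gb")) {
      p[[paste0(dir, "_Wx")]] <- init_mat(D, 3 * Hg, Hg)
      p[[paste0(dir, "_Wh")]] <- init_mat(Hg, 3 * Hg, Hg)
      p[[paste0(dir, "_bx")]] <- init_vec(3 * Hg, Hg)
      p[[paste0(dir, "_bh")]] <- init_vec(3 * Hg, Hg)
    }
    p$h_fc1_W <- init_mat(2 * Hg, 128, 2 * Hg)
    p$h_fc1_b <- init_vec(128, 2 * Hg)
    p$h_fc2_W <- init_mat(128, 1, 128)
    p$h_fc2_b <- init_vec(1, 128)
    list(config = config, params = p)
  })
}

#' Count trainable parameters
#'
#' @param model Output of [build_model()].
#' @param which `"all"`, `"backbone_head"` (BiGRU + classifier only), or a
#'   character vector of parameter-name prefixes.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model, which = "all") {
  nms <- names(model$params)
  if (identical(which, "backbone_head")) {
    nms <- grep("^(gf_|gb_|h_)", nms, value = TRUE)
  } else if (!identical(which, "all")) {
    nms <- nms[grepl(paste0("^(", paste(which, collapse = "|"), ")"), nms)]
  }
  sum(vapply(model$params[nms], function(x)
    if (is.list(x)) sum(vapply(x, length, numeric(1))) else length(x),
    numeric(1)))
}

# Forward pass over a batch of aligned crops (all the same length T).
# Xa: (B*T) x n_mel or NULL; Xi: (B*T) x n_imu or NULL. `need_grad = FALSE`
# drops the compiled-side activation caches (inference-only forwards).
# Returns list(logit = numeric(B), cache).
model_forward <- function(model, Xa, Xi, T_len, B, train = FALSE,
                          need_grad = TRUE) {
  cfg <- model$config
  p <- model$params
  v <- cfg$variant
  pe <- positional_encoding(T_len, cfg$H)[rep(1:T_len, B), , drop = FALSE]
  cache <- list(T_len = T_len, B = B)

  A <- NULL; I <- NULL
  if (v != "imu_only") {
    stop_if(is.null(Xa), paste("variant", v, "requires audio input"))
    stop_if(ncol(Xa) != cfg$n_mel, "wrong audio feature width")
    c1 <- conv1d_fwd(Xa, p$a_conv1_W, p$a_conv1_b, T_len, B, cfg$single,
                     need_grad)
    r1 <- relu_fwd(c1$Y)
    c2 <- conv1d_fwd(r1$Y, p$a_conv2_W, p$a_conv2_b, T_len, B, cfg$single,
                     need_grad)
    r2 <- relu_fwd(c2$Y)
    A <- r2$Y + pe
    cache$a <- list(c1 = c1, r1 = r1, c2 = c2, r2 = r2)
  }
  if (v != "audio_only") {
    stop_if(is.null(Xi), paste("variant", v, "requires IMU input"))
    stop_if(ncol(Xi) != cfg$n_imu, "wrong IMU channel width")
    l1 <- linear_fwd(Xi, p$i_fc1_W, p$i_fc1_b)
    ri <- relu_fwd(l1$Y)
    l2 <- linear_fwd(ri$Y, p$i_fc2_W, p$i_fc2_b)
    I <- l2$Y + pe
    cache$i <- list(l1 = l1, ri = ri, l2 = l2)
  }
  if (!is.null(A) && !is.null(I)) stopifnot(nrow(A) == nrow(I))

  Z <- switch(v,
    audio_only = A,
    imu_only = I,
    early_concat = cbind(A, I),
    gated_early = {
      zt <- cbind(A, I)
      g1 <- linear_fwd(zt, p$g_fc1_W, p$g_fc1_b)
      gr <- relu_fwd(g1$Y)
      gd <- dropout_fwd(gr$Y, cfg$dropout_fusion, train)
      g2 <- linear_fwd(gd$Y, p$g_fc2_W, p$g_fc2_b)
      g <- sigmoid(g2$Y)
      cache$gate <- list(zt = zt, g1 = g1, gr = gr, gd = gd, g2 = g2, g = g)
      g * zt
    },
    mid_xattn = {
      phi <- linear_fwd(I, p$x_phi_W, p$x_phi_b)
      att <- mha_fwd(A, phi$Y, T_len, B, p, cfg$heads,
                     cfg$dropout_fusion, train, cfg$single)
      ln <- layernorm_fwd(A + att$Y, p$x_ln_gamma, p$x_ln_beta)
      cache$xattn <- list(phi = phi, att = att, ln = ln)
      ln$Y
    })

  gru <- bigru_fwd(Z, T_len, B, p, cfg$single, need_grad)
  cache$Z <- Z
  pool <- rowsum(gru$Y, rep(1:B, each = T_len)) / T_len
  h1 <- linear_fwd(pool, p$h_fc1_W, p$h_fc1_b)
  hr <- relu_fwd(h1$Y)
  hd <- dropout_fwd(hr$Y, cfg$dropout_head, train)
  h2 <- linear_fwd(hd$Y, p$h_fc2_W, p$h_fc2_b)
  cache$gru <- gru
  cache$head <- list(h1 = h1, hr = hr, hd = hd, h2 = h2)
  cache$pool <- pool
  list(logit = as.numeric(h2$Y), h_bar = pool, cache = cache)
}

# Backward pass; dlogit is a length-B vector. Returns the gradient list
# (same names/shapes as model$params).
model_backward <- function(model, cache, dlogit) {
  cfg <- model$config
  p <- model$params
  v <- cfg$variant
  T_len <- cache$T_len; B <- cache$B
  g <- list()

  hb <- linear_bwd(cache$head$h2, matrix(dlogit, ncol = 1), p$h_fc2_W)
  g$h_fc2_W <- hb$dW; g$h_fc2_b <- hb$db
  dhd <- dropout_bwd(cache$head$hd, hb$dX)
  dh1 <- relu_bwd(cache$head$hr, dhd)
  hb1 <- linear_bwd(cache$head$h1, dh1, p$h_fc1_W)
  g$h_fc1_W <- hb1$dW; g$h_fc1_b <- hb1$db

  dY <- hb1$dX[rep(1:B, each = T_len), , drop = FALSE] / T_len
  gb <- bigru_bwd(cache$gru, dY, p)
  g <- c(g, gb$grads)
  dZ <- gb$dX

  dA <- NULL; dI <- NULL
  if (v == "audio_only") dA <- dZ
  if (v == "imu_only") dI <- dZ
  if (v == "early_concat") {
    dA <- dZ[, 1:cfg$H, drop = FALSE]
    dI <- dZ[, cfg$H + 1:cfg$H, drop = FALSE]
  }
  if (v == "gated_early") {
    gc <- cache$gate
    dg <- dZ * gc$zt
    dzt <- dZ * gc$g
    dg2 <- dg * gc$g * (1 - gc$g)
    b2 <- linear_bwd(gc$g2, dg2, p$g_fc2_W)
    g$g_fc2_W <- b2$dW; g$g_fc2_b <- b2$db
    dgd <- dropout_bwd(gc$gd, b2$dX)
    dgr <- relu_bwd(gc$gr, dgd)
    b1 <- linear_bwd(gc$g1, dgr, p$g_fc1_W)
    g$g_fc1_W <- b1$dW; g$g_fc1_b <- b1$db
    dzt <- dzt + b1$dX
    dA <- dzt[, 1:cfg$H, drop = FALSE]
    dI <- dzt[, cfg$H + 1:cfg$H, drop = FALSE]
  }
  if (v == "mid_xattn") {
    xc <- cache$xattn
    lb <- layernorm_bwd(xc$ln, dZ, p$x_ln_gamma)
    g$x_ln_gamma <- lb$dgamma; g$x_ln_beta <- lb$dbeta
    ab <- mha_bwd(xc$att, lb$dX, p)
    g <- c(g, ab$grads)
    dA <- lb$dX + ab$dQin
    pb <- linear_bwd(xc$phi, ab$dKVin, p$x_phi_W)
    g$x_phi_W <- pb$dW; g$x_phi_b <- pb$db
    dI <- pb$dX
  }

  if (!is.null(dA)) {
    dr2 <- relu_bwd(cache$a$r2, dA)
    cb2 <- conv1d_bwd(cache$a$c2, dr2, p$a_conv2_W)
    g$a_conv2_W <- cb2$dW; g$a_conv2_b <- cb2$db
    dr1 <- relu_bwd(cache$a$r1, cb2$dX)
    cb1 <- conv1d_bwd(cache$a$c1, dr1, p$a_conv1_W)
    g$a_conv1_W <- cb1$dW; g$a_conv1_b <- cb1$db
  }
  if (!is.null(dI)) {
    ib2 <- linear_bwd(cache$i$l2, dI, p$i_fc2_W)
    g$i_fc2_W <- ib2$dW; g$i_fc2_b <- ib2$db
    dri <- relu_bwd(cache$i$ri, ib2$dX)
    ib1 <- linear_bwd(cache$i$l1, dri, p$i_fc1_W)
    g$i_fc1_W <- ib1$dW; g$i_fc1_b <- ib1$db
  }
  g[names(model$params)]
}
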