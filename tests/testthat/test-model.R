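# Fusion architectures: shape contracts, positional encoding, encoder
# behavior, fusion semantics, matched capacity, and gradient correctness.

pf <- asNamespace("parkfuse")

test_that("positional encoding matches its closed form and bounds", {
  pe <- positional_encoding(50, 96)
  expect_true(all(pe >= -1 & pe <= 1))
  expect_true(all(pe[1, seq(1, 95, by = 2)] == 0))  # sin(0)
  expect_true(all(pe[1, seq(2, 96, by = 2)] == 1))  # cos(0)
  expect_equal(pe[, 1], sin(0:49))                  # base dimension
  expect_error(positional_encoding(0, 4), ">= 1")
})

test_that("every variant produces a finite logit and a 256-wide pooling", {
  for (variant in c("audio_only", "imu_only", "early_concat",
                    "gated_early", "mid_xattn")) {
    cfg <- model_config(variant)
    expect_equal(cfg$d_head, 24)
    m <- build_model(cfg, seed = 1)
    for (T_len in c(1, 10, 120)) {
      set.seed(T_len)
      Xa <- if (variant != "imu_only") matrix(rnorm(T_len * 56), T_len, 56)
      Xi <- if (variant != "audio_only") matrix(rnorm(T_len * 6), T_len, 6)
      out <- pf$model_forward(m, Xa, Xi, T_len, 1L)
      expect_length(out$logit, 1)
      expect_true(is.finite(out$logit))
      expect_equal(ncol(out$h_bar), 256)
    }
  }
})

test_that("a 750-frame crop flows through the full-width fusion model", {
  m <- build_model(model_config("early_concat"), seed = 2)
  set.seed(7)
  out <- pf$model_forward(m, matrix(rnorm(750 * 56), 750, 56),
                          matrix(rnorm(750 * 6), 750, 6), 750L, 1L)
  expect_true(is.finite(out$logit))
  expect_equal(model_config("early_concat")$D, 192)
})

test_that("encoders reduce to the positional encoding on zero input", {
  for (variant in c("audio_only", "imu_only")) {
    m <- build_model(model_config(variant, H = 16, H_gru = 8, heads = 2),
                     seed = 4)
    for (nm in grep("_b$", names(m$params), value = TRUE))
      m$params[[nm]] <- m$params[[nm]] * 0
    T_len <- 12
    Xa <- if (variant == "audio_only") matrix(0, T_len, 56)
    Xi <- if (variant == "imu_only") matrix(0, T_len, 6)
    out <- pf$model_forward(m, Xa, Xi, T_len, 1L)
    # reconstruct the fused sequence fed to the GRU via its input cache
    Z <- out$cache$Z
    expect_equal(Z, positional_encoding(T_len, 16), tolerance = 1e-12)
  }
})

test_that("stacked kernel-5 convolutions see a 9-frame receptive field", {
  T_len <- 31
  W1 <- lapply(1:5, function(i) matrix(1, 1, 1))
  x <- matrix(0, T_len, 1)
  x[16, 1] <- 1
  y1 <- pf$conv1d_fwd(x, W1, 0, T_len, 1L)$Y
  y2 <- pf$conv1d_fwd(y1, W1, 0, T_len, 1L)$Y
  expect_equal(which(y2 != 0), 12:20)
})

test_that("the IMU encoder is a per-timestep map", {
  m <- build_model(model_config("imu_only", H = 16, H_gru = 8, heads = 2),
                   seed = 5)
  set.seed(5)
  Xi <- matrix(rnorm(10 * 6), 10, 6)
  enc <- function(X) {
    h <- pmax(sweep(X %*% m$params$i_fc1_W, 2, m$params$i_fc1_b, "+"), 0)
    sweep(h %*% m$params$i_fc2_W, 2, m$params$i_fc2_b, "+")
  }
  perm <- sample(10)
  expect_equal(enc(Xi)[perm, ], enc(Xi[perm, ]))
})

test_that("fusion variants have the documented output widths and gates", {
  T_len <- 20
  set.seed(6)
  Xa <- matrix(rnorm(T_len * 56), T_len, 56)
  Xi <- matrix(rnorm(T_len * 6), T_len, 6)

  m <- build_model(model_config("early_concat"), seed = 6)
  out <- pf$model_forward(m, Xa, Xi, T_len, 1L)
  expect_equal(ncol(out$cache$Z), 192)

  mg <- build_model(model_config("gated_early"), seed = 6)
  og <- pf$model_forward(mg, Xa, Xi, T_len, 1L)
  g <- og$cache$gate$g
  expect_true(all(g > 0 & g < 1))

  mx <- build_model(model_config("mid_xattn"), seed = 6)
  ox <- pf$model_forward(mx, Xa, Xi, T_len, 1L)
  expect_equal(ncol(ox$cache$Z), 96)
  # attention rows are probability distributions
  P <- ox$cache$xattn$att$P
  expect_true(all(abs(apply(P, 3, rowSums) - 1) < 1e-5))
})

test_that("constant queries give a timestep-invariant attention readout", {
  m <- build_model(model_config("mid_xattn", H = 8, heads = 2, H_gru = 4),
                   seed = 7)
  T_len <- 9
  set.seed(7)
  Qin <- matrix(rep(rnorm(8), each = T_len), T_len, 8)  # constant over t
  KVin <- matrix(rnorm(T_len * 8), T_len, 8)
  att <- pf$mha_fwd(Qin, KVin, T_len, 1L, m$params, heads = 2,
                    p_drop = 0, train = FALSE)
  expect_lt(max(abs(sweep(att$Y, 2, att$Y[1, ]))), 1e-10)
})

test_that("backbone and head capacity depends only on the fused width", {
  counts <- sapply(c("audio_only", "imu_only", "mid_xattn"), function(v)
    count_parameters(build_model(model_config(v), seed = 1), "backbone_head"))
  expect_equal(length(unique(counts)), 1)

  ce <- count_parameters(build_model(model_config("early_concat"), seed = 1))
  cg <- count_parameters(build_model(model_config("gated_early"), seed = 1))
  gate_params <- (192 * 96 + 96) + (96 * 192 + 192)
  expect_equal(cg - ce, gate_params)

  expect_error(model_config("late_fusion"), "unknown variant")
})

test_that("a gate forced open reproduces early concatenation exactly", {
  cfg_g <- model_config("gated_early")
  mg <- build_model(cfg_g, seed = 8)
  me <- build_model(model_config("early_concat"), seed = 9)
  shared <- intersect(names(me$params), names(mg$params))
  for (nm in shared) me$params[[nm]] <- mg$params[[nm]]
  mg$params$g_fc2_W <- mg$params$g_fc2_W * 0
  mg$params$g_fc2_b <- rep(40, length(mg$params$g_fc2_b))  # sigmoid -> 1
  T_len <- 25
  set.seed(10)
  Xa <- matrix(rnorm(T_len * 56), T_len, 56)
  Xi <- matrix(rnorm(T_len * 6), T_len, 6)
  lg <- pf$model_forward(mg, Xa, Xi, T_len, 1L)$logit
  le <- pf$model_forward(me, Xa, Xi, T_len, 1L)$logit
  expect_equal(lg, le, tolerance = 1e-10)
})

test_that("evaluation mode is deterministic", {
  m <- build_model(model_config("gated_early"), seed = 11)
  set.seed(11)
  Xa <- matrix(rnorm(30 * 56), 30, 56)
  Xi <- matrix(rnorm(30 * 6), 30, 6)
  l1 <- pf$model_forward(m, Xa, Xi, 30L, 1L)$logit
  l2 <- pf$model_forward(m, Xa, Xi, 30L, 1L)$logit
  expect_identical(l1, l2)
})

test_that("analytic gradients match finite differences for every variant", {
  for (variant in c("audio_only", "imu_only", "early_concat",
                    "gated_early", "mid_xattn")) {
    cfg <- model_config(variant, H = 8, H_gru = 5, heads = 2,
                        n_mel = 7, n_imu = 3, precision = "double")
    m <- build_model(cfg, seed = 3)
    T_len <- 6; B <- 2
    set.seed(11)
    Xa <- if (variant != "imu_only") matrix(rnorm(B * T_len * 7), B * T_len, 7)
    Xi <- if (variant != "audio_only") matrix(rnorm(B * T_len * 3), B * T_len, 3)
    y <- c(0, 1)
    loss_fn <- function(mm) {
      fw <- pf$model_forward(mm, Xa, Xi, T_len, B)
      mean(pf$softplus(fw$logit) - y * fw$logit)
    }
    fw <- pf$model_forward(m, Xa, Xi, T_len, B)
    gr <- pf$model_backward(m, fw$cache, (pf$sigmoid(fw$logit) - y) / B)
    eps <- 1e-5
    set.seed(99)
    for (i in 1:25) {
      nm <- sample(names(m$params), 1)
      j <- if (is.list(m$params[[nm]])) sample(length(m$params[[nm]]), 1) else NA
      tensor <- if (is.na(j)) m$params[[nm]] else m$params[[nm]][[j]]
      k <- sample(length(tensor), 1)
      bump <- function(delta) {
        m2 <- m
        if (is.na(j)) m2$params[[nm]][k] <- m2$params[[nm]][k] + delta
        else m2$params[[nm]][[j]][k] <- m2$params[[nm]][[j]][k] + delta
        m2
      }
      g_num <- (loss_fn(bump(eps)) - loss_fn(bump(-eps))) / (2 * eps)
      g_an <- if (is.na(j)) gr[[nm]][k] else gr[[nm]][[j]][k]
      expect_lt(abs(g_num - g_an) / max(1e-6, abs(g_num) + abs(g_an)), 1e-4)
    }
  }
})
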