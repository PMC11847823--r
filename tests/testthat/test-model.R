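test_that("dual self-attention reduces to zero on zero input with uniform maps", {
  Z <- spectral_self_attention(matrix(0, 4, 6))
  expect_equal(unclass(Z)[, ], matrix(0, 4, 6), ignore_attr = TRUE)
  expect_equal(attr(Z, "W_channels"), matrix(1 / 4, 4, 4))
  expect_equal(attr(Z, "W_frequency"), matrix(1 / 6, 6, 6))
})

test_that("attention maps are row-stochastic for arbitrary input", {
  set.seed(2)
  Z <- spectral_self_attention(matrix(rnorm(12), 3, 4))
  expect_equal(rowSums(attr(Z, "W_channels")), rep(1, 3))
  expect_equal(rowSums(attr(Z, "W_frequency")), rep(1, 4))
})

test_that("dual self-attention matches scalar arithmetic on a 2x2 toy", {
  X <- rbind(c(1, 0), c(0, 1))
  # channel map: softmax of XX'/2 rows; frequency map likewise
  sm <- function(v) exp(v) / sum(exp(v))
  P1 <- rbind(sm(c(0.5, 0)), sm(c(0, 0.5)))
  P2 <- P1                                  # X'X/2 equals XX'/2 here
  R <- P1 %*% X
  Q <- P2 %*% t(X)
  expected <- (R + X) + t(Q + t(X))
  Z <- spectral_self_attention(X)
  expect_equal(unclass(Z)[, ], expected, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("graph layer applies ELU(S Z W + b) with the expected shapes", {
  expect_equal(unclass(graph_layer(matrix(0, 3, 4), diag(3),
                                   matrix(1, 4, 5)))[, ],
               matrix(0, 3, 5), ignore_attr = TRUE)
  set.seed(3)
  Z <- matrix(rnorm(12), 3, 4)
  S <- tiny_S(3)
  W <- matrix(rnorm(4 * 5), 4, 5)
  b <- rnorm(5)
  M <- S %*% Z %*% W + matrix(b, 3, 5, byrow = TRUE)
  expected <- ifelse(M > 0, M, exp(M) - 1)
  expect_equal(unclass(graph_layer(Z, S, W, b))[, ], expected,
               tolerance = 1e-12, ignore_attr = TRUE)
  # identity adjacency with an identity-extended projection passes Z through
  W_id <- cbind(diag(4), matrix(0, 4, 1))
  out <- graph_layer(Z, diag(3), W_id)
  expect_equal(unclass(out)[, 1:4], ifelse(Z > 0, Z, exp(Z) - 1),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("spatial attention is a channel simplex, uniform for identical rows", {
  set.seed(4)
  Wb <- diag(3); cb <- numeric(3); ub <- c(1, 0, 0)
  H_same <- matrix(1, 62, 3)
  sa <- spatial_attention(H_same, Wb, cb, ub)
  expect_equal(sa$phi, rep(1 / 62, 62))
  H <- matrix(rnorm(5 * 3), 5, 3)
  sa2 <- spatial_attention(H, matrix(rnorm(9), 3), rnorm(3), rnorm(3))
  expect_equal(sum(sa2$phi), 1)
  expect_true(all(sa2$phi >= 0 & sa2$phi <= 1))
  expect_equal(sa2$V, H * sa2$phi)
})

test_that("spatial attention matches hand computation on a 2-channel toy", {
  H <- rbind(c(0.3, -0.2), c(-0.1, 0.5))
  Wb <- diag(2); cb <- c(0, 0); ub <- c(1, 0)
  u <- tanh(H)                      # Wb = I, cb = 0
  e <- u %*% ub
  phi <- exp(e) / sum(exp(e))
  sa <- spatial_attention(H, Wb, cb, ub)
  expect_equal(sa$phi, drop(phi), tolerance = 1e-12)
})

test_that("temporal attention is a window simplex with weighted-sum output", {
  set.seed(5)
  G_same <- matrix(1, 7, 4)
  ta <- temporal_attention(G_same, diag(4), numeric(4), rnorm(4))
  expect_equal(ta$psi, rep(1 / 7, 7))
  G <- matrix(rnorm(6 * 4), 6, 4)
  Wa <- matrix(rnorm(16), 4); ca <- rnorm(4); ua <- rnorm(4)
  ta2 <- temporal_attention(G, Wa, ca, ua)
  expect_equal(sum(ta2$psi), 1)
  expect_equal(ta2$t, drop(ta2$psi %*% G))
  # hand computation
  u <- tanh(sweep(G %*% Wa, 2, ca, `+`))
  e <- drop(u %*% ua)
  psi <- exp(e - max(e)) / sum(exp(e - max(e)))
  expect_equal(ta2$psi, psi, tolerance = 1e-12)
})

test_that("the BiLSTM outputs 2m units, bounded on zero input, with mirrored directions", {
  set.seed(6)
  cfg <- tiny_config(w = 3, K = 2, F = 3, U = 2, m = 4)
  params <- init_params(cfg)
  X <- matrix(rnorm(3 * 4), 3, 4)
  enc <- temporal_encode(X, params)
  expect_equal(dim(enc$G), c(3, 8))
  z <- temporal_encode(matrix(0, 3, 4), params)
  expect_true(all(abs(z$G) < 1))
  # reversing time swaps the roles of the two directions (shared weights)
  fwd_on_rev <- eegattn:::.lstm_dir(X[3:1, , drop = FALSE], params$Wx_f,
                                    params$Wh_f, params$b_f, reverse = FALSE)
  bwd_on_orig <- eegattn:::.lstm_dir(X, params$Wx_f, params$Wh_f, params$b_f,
                                     reverse = TRUE)
  expect_equal(fwd_on_rev$H, bwd_on_orig$H[3:1, , drop = FALSE],
               tolerance = 1e-12)
})

test_that("the heads output a class simplex and a domain probability", {
  set.seed(7)
  cfg <- tiny_config(C = 5, m = 3)
  params <- init_params(cfg)
  hd <- heads(rnorm(6), params)
  expect_length(hd$p_class, 5)
  expect_equal(sum(hd$p_class), 1)
  expect_true(hd$p_domain > 0 && hd$p_domain < 1)
})

test_that("the adversarial schedule starts at zero and increases monotonically", {
  expect_equal(lambda_schedule(0), 0)
  expect_equal(lambda_schedule(0.5), 2 / (1 + exp(-5)) - 1)
  p <- seq(0, 1, by = 0.01)
  expect_true(all(diff(lambda_schedule(p)) > 0))
  expect_true(all(lambda_schedule(p) >= 0 & lambda_schedule(p) < 1))
})

test_that("analytic backward pass matches finite differences", {
  set.seed(42)
  cfg <- tiny_config(w = 3, K = 3, F = 4, U = 3, m = 2, C = 2, seed = 7)
  params <- init_params(cfg)
  S <- tiny_S(3)
  X <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  y <- 2L
  lambda <- 0.37
  loss_y <- function(p) {
    f <- eegattn:::.forward_sample(X, p, cfg, S); -log(f$p_class[y])
  }
  loss_d <- function(p) {
    f <- eegattn:::.forward_sample(X, p, cfg, S); -log(f$p_domain)
  }
  fw <- eegattn:::.forward_sample(X, params, cfg, S)
  grad <- list2env(eegattn:::.zero_like(params))
  dly <- fw$p_class; dly[y] <- dly[y] - 1
  eegattn:::.backward_sample(fw, params, cfg, S, grad, dlogit_y = dly,
                             dlogit_d = fw$p_domain - 1, lambda = lambda)
  num_grad <- function(lossfn, nm, eps = 1e-6) {
    g <- params[[nm]] * 0
    for (i in seq_along(g)) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps; up <- lossfn(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps; dn <- lossfn(pp)
      g[i] <- (up - dn) / (2 * eps)
    }
    g
  }
  for (nm in names(params)) {
    gy <- num_grad(loss_y, nm)
    gd <- num_grad(loss_d, nm)
    expected <- if (nm %in% c("Wy", "by")) gy
      else if (nm %in% c("wd", "bd")) gd
      else gy - lambda * gd
    got <- get(nm, envir = grad)
    expect_equal(as.vector(got), as.vector(expected), tolerance = 1e-4,
                 label = paste("gradient of", nm))
  }
})

test_that("the compiled engine reproduces the R reference exactly", {
  for (abl in list(character(0), "spatial_attn", "bilstm")) {
    set.seed(99)
    cfg <- tiny_config(w = 4, K = 4, F = 5, U = 3, m = 2, C = 3,
                       ablate = abl, seed = 5)
    params <- init_params(cfg)
    S <- tiny_S(4)
    B <- 3
    Xb <- array(rnorm(B * 4 * 4 * 5), c(B, 4, 4, 5))
    y <- c(1L, 3L, 2L)
    Xt <- array(rnorm(2 * 4 * 4 * 5), c(2, 4, 4, 5))
    lambda <- 0.4
    grad <- list2env(eegattn:::.zero_like(params))
    for (b in 1:B) {
      fw <- eegattn:::.forward_sample(Xb[b, , , ], params, cfg, S)
      dly <- fw$p_class; dly[y[b]] <- dly[y[b]] - 1
      eegattn:::.backward_sample(fw, params, cfg, S, grad,
                                 dlogit_y = dly / B,
                                 dlogit_d = fw$p_domain / B, lambda = lambda)
    }
    for (b in 1:2) {
      fw <- eegattn:::.forward_sample(Xt[b, , , ], params, cfg, S)
      eegattn:::.backward_sample(fw, params, cfg, S, grad,
                                 dlogit_d = (fw$p_domain - 1) / 2,
                                 lambda = lambda)
    }
    res <- eegattn:::cpp_batch_grad(Xb, y, Xt, params, unclass(cfg), S, NULL,
                                    lambda, TRUE)
    for (nm in names(params))
      expect_equal(as.vector(res$grads[[nm]]),
                   as.vector(get(nm, envir = grad)), tolerance = 1e-12,
                   label = paste("cpp gradient of", nm, "ablate",
                                 paste(abl, collapse = "+")))
    pr <- eegattn:::cpp_predict(Xb, params, unclass(cfg), S)
    fw2 <- eegattn:::.forward_sample(Xb[2, , , ], params, cfg, S)
    expect_equal(pr$probabilities[2, ], fw2$p_class, tolerance = 1e-12)
    expect_equal(pr$Phi[2, , ], fw2$Phi, tolerance = 1e-12)
    expect_equal(pr$Psi[2, ], fw2$psi, tolerance = 1e-12)
  }
})

test_that("training is deterministic under a fixed seed", {
  set.seed(11)
  subs <- lapply(1:3, function(i)
    random_subject_tensor(c(1, 1, 2, 2, 3, 3), id = i))
  cfg <- tiny_config(epochs = 3, seed = 21)
  S <- tiny_S(4)
  f1 <- train_fold(subs[-1], subs[[1]], cfg, S)
  f2 <- train_fold(subs[-1], subs[[1]], cfg, S)
  expect_identical(f1$overall_accuracy, f2$overall_accuracy)
  expect_identical(f1$Phi, f2$Phi)
  expect_identical(f1$Psi, f2$Psi)
  expect_identical(f1$params, f2$params)
})

test_that("with lambda forced to zero the domain loss cannot touch the feature extractor", {
  set.seed(12)
  subs <- lapply(1:3, function(i)
    random_subject_tensor(c(1, 2, 3, 1, 2, 3), id = i))
  S <- tiny_S(4)
  adv0 <- train_fold(subs[-1], subs[[1]],
                     tiny_config(epochs = 4, seed = 5, lambda_scale = 0), S)
  plain <- train_fold(subs[-1], subs[[1]],
                      tiny_config(epochs = 4, seed = 5,
                                  use_domain_head = FALSE), S)
  feature_names <- setdiff(names(adv0$params), c("wd", "bd"))
  for (nm in feature_names)
    expect_identical(adv0$params[[nm]], plain$params[[nm]],
                     label = paste("parameter", nm))
  # the domain head itself did train in the adversarial run
  expect_false(identical(adv0$params$wd, plain$params$wd))
})

test_that("target-subject labels never influence training", {
  set.seed(13)
  subs <- lapply(1:3, function(i)
    random_subject_tensor(c(1, 2, 3, 1, 2, 3), id = i))
  S <- tiny_S(4)
  cfg <- tiny_config(epochs = 3, seed = 9)
  target <- subs[[1]]
  shuffled <- target
  shuffled$labels <- rev(target$labels)
  f1 <- train_fold(subs[-1], target, cfg, S)
  f2 <- train_fold(subs[-1], shuffled, cfg, S)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$predictions, f2$predictions)
  expect_identical(f1$Phi, f2$Phi)
})

test_that("training requires at least two source classes", {
  set.seed(14)
  subs <- lapply(1:2, function(i) random_subject_tensor(c(1, 1, 1), id = i))
  expect_error(train_fold(subs[1], subs[[2]], tiny_config(), tiny_S(4)),
               "at least 2 emotion classes")
})

test_that("ablations force uniform attention and mean pooling", {
  set.seed(15)
  cfg <- tiny_config(ablate = c("spatial_attn", "temporal_attn"), seed = 3)
  params <- init_params(cfg)
  S <- tiny_S(4)
  X <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  fw <- eegattn:::.forward_sample(X, params, cfg, S)
  expect_equal(fw$Phi, matrix(1 / 4, 3, 4))
  expect_equal(fw$psi, rep(1 / 3, 3))
  expect_equal(fw$t, colMeans(fw$enc$G))
  # shape preservation under every single ablation
  for (abl in c("channel_attn", "freq_attn", "spectral_block", "graph_layer",
                "bilstm")) {
    cfg_a <- tiny_config(ablate = abl, seed = 3)
    fw_a <- eegattn:::.forward_sample(X, init_params(cfg_a), cfg_a, S)
    expect_length(fw_a$t, 2 * cfg_a$lstm_units)
    expect_length(fw_a$p_class, 3)
  }
})

test_that("per-class accuracy averages to the macro accuracy", {
  acc <- per_class_accuracy(c(1, 1, 2, 3), c(1, 1, 2, 2), 3)
  expect_equal(unname(acc$per_class[1:2]), c(1, 0.5))
  expect_true(is.na(acc$per_class[3]))
  expect_equal(acc$overall, 0.75)
  perfect <- per_class_accuracy(c(1, 2, 3), c(1, 2, 3), 3)
  expect_equal(perfect$overall, 1)
  expect_equal(unname(perfect$per_class), rep(1, 3))
})

test_that("LOOCV holds each subject out exactly once and summarizes folds", {
  set.seed(16)
  subs <- lapply(1:3, function(i)
    random_subject_tensor(c(1, 2, 3, 1, 2, 3), id = i))
  cv <- loocv(subs, tiny_config(epochs = 2, seed = 2), tiny_S(4))
  expect_length(cv$folds, 3)
  expect_equal(sort(vapply(cv$folds, function(f) f$subject_id, numeric(1))),
               1:3)
  accs <- vapply(cv$folds, function(f) f$overall_accuracy, numeric(1))
  expect_equal(cv$summary$mean, mean(accs))
  expect_equal(cv$summary$n_folds, 3)
  expect_true(cv$summary$ci_lower <= cv$summary$mean &&
                cv$summary$mean <= cv$summary$ci_upper)
  # attention weights extracted for every held-out video form simplices
  for (f in cv$folds) {
    expect_true(all(abs(apply(f$Phi, c(1, 2), sum) - 1) < 1e-5))
    expect_true(all(abs(rowSums(f$Psi) - 1) < 1e-5))
    expect_true(all(f$history$simplex_dev < 1e-5))
  }
})
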