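#' The attention-DANN emotion-recognition network
#'
#' The network maps a padded per-video tensor (w windows x channels x
#' frequency bins) to an emotion class while exposing two simplex-normalized
#' attention maps: spatial weights phi over channels (one simplex per
#' window) and temporal weights psi over windows (one simplex per video).
#' Stages: per-channel layer normalization over the frequency axis; dual
#' self-attention over channels and over frequencies with residual fusion;
#' a graph layer over the montage adjacency; spatial attention; a
#' bidirectional LSTM over windows; temporal attention; and two heads — a
#' softmax emotion classifier and a sigmoid domain classifier behind a
#' gradient-reversal layer (domain-adversarial training). All forward and
#' backward passes are implemented explicitly in matrix code; gradients are
#' verified against finite differences in the test suite.
#'
#' @name attn_dann_model
NULL

.sigmoid <- function(x) 1 / (1 + exp(-x))

.row_softmax <- function(M) {
  M <- exp(M - apply(M, 1, max))
  M / rowSums(M)
}

.softmax <- function(v) {
  v <- exp(v - max(v))
  v / sum(v)
}

# backward through a row-wise softmax: given P = row_softmax(A) and dP,
# return dA
.row_softmax_back <- function(P, dP) {
  P * (dP - rowSums(dP * P))
}

.softmax_back <- function(p, dp) p * (dp - sum(dp * p))

.elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
.elu_grad <- function(x) ifelse(x > 0, 1, exp(x))

.glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Model configuration
#'
#' Defaults follow the reference training setup: 62 channels x 50 frequency
#' bins, a 128-unit graph layer, a BiLSTM with 64 units per direction,
#' dropout 0.7 before the label head, SGD with learning rate 0.01 for 100
#' epochs and batch size 64. Tests and the synthetic benchmark use smaller
#' values through the same interface.
#'
#' @param w padded window count per video.
#' @param n_classes number of emotion classes (>= 2).
#' @param n_channels,n_freqs input dimensions.
#' @param gnl_units graph-layer output units.
#' @param lstm_units LSTM units per direction (BiLSTM output is 2x this).
#' @param dropout_rate dropout rate before the label head, in [0, 1).
#' @param batch_size source-batch size per SGD step.
#' @param learning_rate SGD learning rate.
#' @param epochs training epochs; the adversarial weight lambda follows
#'   [lambda_schedule()] over the epoch fraction.
#' @param lambda_scale multiplier on the scheduled lambda (0 disconnects the
#'   domain gradient from the feature extractor).
#' @param use_domain_head if `FALSE` the domain classifier is skipped
#'   entirely (plain supervised training; target batches are still drawn so
#'   the random-number stream matches an adversarial run).
#' @param ablate character vector of components to remove, among
#'   `"channel_attn"`, `"freq_attn"`, `"spectral_block"`, `"graph_layer"`,
#'   `"spatial_attn"`, `"bilstm"`, `"temporal_attn"`. Removal preserves all
#'   shapes: dropped self-attention branches pass the input through, the
#'   graph layer becomes a per-channel dense projection, dropped attention
#'   weights are forced uniform, and the BiLSTM becomes a per-window dense
#'   projection.
#' @param seed RNG seed for initialization and batching.
#' @return A `model_config` list.
#' @export
model_config <- function(w, n_classes, n_channels = 62, n_freqs = 50,
                         gnl_units = 128, lstm_units = 64,
                         dropout_rate = 0.7, batch_size = 64,
                         learning_rate = 0.01, epochs = 100,
                         lambda_scale = 1, use_domain_head = TRUE,
                         ablate = character(0), seed = 1L) {
  known <- c("channel_attn", "freq_attn", "spectral_block", "graph_layer",
             "spatial_attn", "bilstm", "temporal_attn")
  if (length(bad <- setdiff(ablate, known)))
    stop("unknown ablation flag(s): ", paste(bad, collapse = ", "))
  stopifnot(n_classes >= 2, dropout_rate >= 0, dropout_rate < 1, w >= 1)
  structure(list(w = w, n_classes = n_classes, n_channels = n_channels,
                 n_freqs = n_freqs, gnl_units = gnl_units,
                 lstm_units = lstm_units, dropout_rate = dropout_rate,
                 batch_size = batch_size, learning_rate = learning_rate,
                 epochs = epochs, lambda_scale = lambda_scale,
                 use_domain_head = use_domain_head, ablate = ablate,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Adversarial weight schedule
#'
#' `lambda(p) = 2 / (1 + exp(-10 p)) - 1` for training progress `p` in
#' [0, 1]: zero at the start, saturating toward 1.
#'
#' @param p training progress (completed-epoch fraction).
#' @return lambda in [0, 1).
#' @export
lambda_schedule <- function(p) 2 / (1 + exp(-10 * p)) - 1

#' Initialize model parameters
#'
#' Glorot-uniform fan-based initialization for all dense maps; zero biases;
#' layer-norm gain 1 and bias 0. Uses the current RNG state.
#'
#' @param cfg a [model_config()].
#' @return Named list of parameter arrays.
#' @export
init_params <- function(cfg) {
  K <- cfg$n_channels; F <- cfg$n_freqs; U <- cfg$gnl_units
  m <- cfg$lstm_units; D <- K * U; C <- cfg$n_classes
  p <- list(
    ln_gamma = rep(1, F), ln_beta = rep(0, F),
    Wg = .glorot(F, U), bg = numeric(U),
    Wb = .glorot(U, U), cb = numeric(U), ub = .glorot(U, 1)[, 1],
    Wa = .glorot(2 * m, 2 * m), ca = numeric(2 * m),
    ua = .glorot(2 * m, 1)[, 1],
    Wy = .glorot(C, 2 * m), by = numeric(C),
    wd = .glorot(2 * m, 1)[, 1], bd = 0
  )
  if ("bilstm" %in% cfg$ablate) {
    p$Wl <- .glorot(2 * m, D); p$bl <- numeric(2 * m)
  } else {
    for (dir in c("f", "b")) {
      p[[paste0("Wx_", dir)]] <- .glorot(4 * m, D)
      p[[paste0("Wh_", dir)]] <- .glorot(4 * m, m)
      p[[paste0("b_", dir)]]  <- numeric(4 * m)
    }
  }
  p
}

.zero_like <- function(params) lapply(params, function(x) x * 0)

#' Per-channel layer normalization over the frequency axis
#'
#' Each row (channel) of a channels x freqs matrix is standardized over its
#' frequency bins and rescaled by a learnable per-frequency gain and bias.
#'
#' @param X channels x freqs matrix.
#' @param gamma,beta numeric vectors of length `ncol(X)`.
#' @param eps variance floor.
#' @return Normalized matrix (with cache attributes used by the backward
#'   pass).
#' @export
layer_norm <- function(X, gamma = rep(1, ncol(X)), beta = rep(0, ncol(X)),
                       eps = 1e-5) {
  mu <- rowMeans(X)
  v <- rowMeans((X - mu)^2)
  xhat <- (X - mu) / sqrt(v + eps)
  out <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  attr(out, "xhat") <- xhat
  out
}

#' Dual self-attention over channels and frequencies
#'
#' For a channels x freqs input X:
#' `R = softmax(X X' / n_freqs) X` (channel attention),
#' `Q = softmax(X' X / n_channels) X'` (frequency attention), fused with
#' residuals as `Z = (R + X) + (Q + X')'`. Ablation flags replace either
#' branch by a plain residual pass-through, or the whole block by X itself.
#'
#' @param X channels x freqs matrix (normalized upstream in the model).
#' @param ablate character vector, see [model_config()].
#' @return Z with the shape of X; attributes `W_channels` and `W_frequency`
#'   carry the row-stochastic attention maps.
#' @export
spectral_self_attention <- function(X, ablate = character(0)) {
  if ("spectral_block" %in% ablate) {
    Z <- X
    attr(Z, "W_channels") <- NULL
    return(Z)
  }
  K <- nrow(X); F <- ncol(X)
  P1 <- P2 <- NULL
  if (!("channel_attn" %in% ablate)) {
    P1 <- .row_softmax(tcrossprod(X) / F)    # K x K
    B1 <- P1 %*% X + X
  } else B1 <- X
  if (!("freq_attn" %in% ablate)) {
    P2 <- .row_softmax(crossprod(X) / K)     # F x F
    B2 <- t(P2 %*% t(X)) + X                 # (Q + X')' = Q' + X
  } else B2 <- X
  Z <- B1 + B2
  attr(Z, "W_channels") <- P1
  attr(Z, "W_frequency") <- P2
  Z
}

#' Graph layer over the montage adjacency
#'
#' `H = ELU(S Z W_graph + b)`, mixing each channel's spectral features with
#' its montage neighbours' before a dense projection to `gnl_units`
#' dimensions. With the `graph_layer` ablation the montage mixing is
#' dropped and the layer becomes a per-channel dense projection
#' `ELU(Z W_graph + b)`.
#'
#' @param Z channels x freqs matrix.
#' @param S normalized adjacency (channels x channels) or `NULL`/ablated.
#' @param W freqs x units weight matrix.
#' @param b units-length bias.
#' @param ablate character vector.
#' @return channels x units matrix.
#' @export
graph_layer <- function(Z, S, W, b = numeric(ncol(W)),
                        ablate = character(0)) {
  M <- if ("graph_layer" %in% ablate || is.null(S)) Z %*% W else S %*% Z %*% W
  M <- sweep(M, 2, b, `+`)
  out <- .elu(M)
  attr(out, "pre") <- M
  out
}

#' Spatial attention over channels
#'
#' `u_k = tanh(W_b h_k + c_b)`; `phi = softmax_k(u_k . u_b)`;
#' `v_k = phi_k h_k`. The weights phi form a simplex over channels. With the
#' `spatial_attn` ablation phi is forced uniform (1/K).
#'
#' @param H channels x units feature matrix.
#' @param Wb,cb,ub attention parameters (units x units, units, units).
#' @param ablate character vector.
#' @return List with `V` (channels x units, rows scaled by phi) and `phi`.
#' @export
spatial_attention <- function(H, Wb, cb, ub, ablate = character(0)) {
  K <- nrow(H)
  if ("spatial_attn" %in% ablate) {
    phi <- rep(1 / K, K)
    return(list(V = H / K, phi = phi, Uh = NULL))
  }
  Uh <- tanh(sweep(H %*% Wb, 2, cb, `+`))
  phi <- .softmax(drop(Uh %*% ub))
  list(V = H * phi, phi = phi, Uh = Uh)
}

#' Temporal attention over windows
#'
#' `a_w = tanh(W_a g_w + c_a)`; `psi = softmax_w(a_w . u_a)`;
#' `t = sum_w psi_w g_w`. The weights psi form a simplex over the padded
#' windows of a video. With the `temporal_attn` ablation psi is forced
#' uniform (mean pooling).
#'
#' @param G w x units matrix of BiLSTM outputs.
#' @param Wa,ca,ua attention parameters.
#' @param ablate character vector.
#' @return List with `t` (length units) and `psi` (length w).
#' @export
temporal_attention <- function(G, Wa, ca, ua, ablate = character(0)) {
  w <- nrow(G)
  if ("temporal_attn" %in% ablate) {
    psi <- rep(1 / w, w)
    return(list(t = colMeans(G), psi = psi, Ah = NULL))
  }
  Ah <- tanh(sweep(G %*% Wa, 2, ca, `+`))
  psi <- .softmax(drop(Ah %*% ua))
  list(t = drop(psi %*% G), psi = psi, Ah = Ah)
}

# ---- single-direction LSTM over a w x D input sequence --------------------
# gate order in the stacked 4m blocks: input, forget, cell, output
.lstm_dir <- function(Xseq, Wx, Wh, b, reverse = FALSE) {
  w <- nrow(Xseq); m <- length(b) / 4
  idx <- if (reverse) rev(seq_len(w)) else seq_len(w)
  h <- numeric(m); cc <- numeric(m)
  H <- matrix(0, w, m)
  cache <- vector("list", w)
  for (t in idx) {
    z <- drop(Wx %*% Xseq[t, ] + Wh %*% h + b)
    i <- .sigmoid(z[1:m]); f <- .sigmoid(z[(m + 1):(2 * m)])
    g <- tanh(z[(2 * m + 1):(3 * m)]); o <- .sigmoid(z[(3 * m + 1):(4 * m)])
    c_prev <- cc
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h <- o * tc
    H[t, ] <- h
    cache[[t]] <- list(i = i, f = f, g = g, o = o, c = cc, c_prev = c_prev,
                       tc = tc, x = Xseq[t, ])
  }
  list(H = H, cache = cache, idx = idx)
}

.lstm_dir_back <- function(dH, fwd, Wx, Wh) {
  w <- nrow(dH); m <- ncol(dH)
  dWx <- Wx * 0; dWh <- Wh * 0; db <- numeric(4 * m)
  dX <- matrix(0, w, ncol(Wx))
  dh_carry <- numeric(m); dc_carry <- numeric(m)
  for (t in rev(fwd$idx)) {
    cc <- fwd$cache[[t]]
    dh <- dH[t, ] + dh_carry
    do <- dh * cc$tc
    dtc <- dh * cc$o * (1 - cc$tc^2) + dc_carry
    di <- dtc * cc$g; df <- dtc * cc$c_prev; dg <- dtc * cc$i
    dc_carry <- dtc * cc$f
    dz <- c(di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
            dg * (1 - cc$g^2), do * cc$o * (1 - cc$o))
    # previous hidden state in iteration order
    pos <- match(t, fwd$idx)
    h_prev <- if (pos == 1) numeric(m) else fwd$H[fwd$idx[pos - 1], ]
    dWx <- dWx + tcrossprod(dz, cc$x)
    dWh <- dWh + tcrossprod(dz, h_prev)
    db <- db + dz
    dX[t, ] <- dX[t, ] + drop(crossprod(Wx, dz))
    dh_carry <- drop(crossprod(Wh, dz))
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

#' Bidirectional LSTM encoding of a window sequence
#'
#' Runs a forward and a backward LSTM (`lstm_units` each) over the per-window
#' feature vectors and concatenates their hidden states, giving one
#' `2 * lstm_units` vector per window. With the `bilstm` ablation the
#' sequence is encoded window-wise by a dense projection instead.
#'
#' @param Xseq w x D matrix (one flattened spatial feature vector per
#'   window, ascending time order).
#' @param params model parameters from [init_params()].
#' @param ablate character vector.
#' @return List with `G` (w x 2m) and internal caches.
#' @export
temporal_encode <- function(Xseq, params, ablate = character(0)) {
  if ("bilstm" %in% ablate) {
    G <- t(params$Wl %*% t(Xseq) + params$bl)
    return(list(G = G, fwd = NULL, bwd = NULL))
  }
  fwd <- .lstm_dir(Xseq, params$Wx_f, params$Wh_f, params$b_f, reverse = FALSE)
  bwd <- .lstm_dir(Xseq, params$Wx_b, params$Wh_b, params$b_b, reverse = TRUE)
  list(G = cbind(fwd$H, bwd$H), fwd = fwd, bwd = bwd)
}

#' Classifier and domain heads
#'
#' Label head: dropout (training only) then a dense layer with softmax over
#' the emotion classes. Domain head: gradient-reversal layer (identity
#' forward) then a single-unit dense layer with sigmoid; source domain is
#' class 0, target domain class 1.
#'
#' @param t feature vector (length `2 * lstm_units`).
#' @param params model parameters.
#' @param drop_mask optional 0/1 dropout mask already scaled by
#'   1/(1 - rate); `NULL` for inference.
#' @return List with `p_class` (simplex over classes) and `p_domain`
#'   (scalar in (0, 1)).
#' @export
heads <- function(t, params, drop_mask = NULL) {
  td <- if (is.null(drop_mask)) t else t * drop_mask
  p_class <- .softmax(drop(params$Wy %*% td + params$by))
  p_domain <- .sigmoid(sum(params$wd * t) + params$bd)
  list(p_class = p_class, p_domain = p_domain, td = td)
}

# ---- full forward pass over one video tensor ------------------------------
# X: w x K x F array. Returns feature vector t, attention maps, and caches.
.forward_sample <- function(X, params, cfg, S, drop_mask = NULL) {
  w <- dim(X)[1]; K <- dim(X)[2]; U <- cfg$gnl_units
  caches <- vector("list", w)
  Xseq <- matrix(0, w, K * U)
  Phi <- matrix(0, w, K)
  for (t in seq_len(w)) {
    X0 <- X[t, , , drop = TRUE]
    if (is.null(dim(X0))) X0 <- matrix(X0, K, cfg$n_freqs)
    N <- layer_norm(X0, params$ln_gamma, params$ln_beta)
    xhat <- attr(N, "xhat")
    Z <- spectral_self_attention(N, cfg$ablate)
    H <- graph_layer(Z, S, params$Wg, params$bg, cfg$ablate)
    sa <- spatial_attention(H, params$Wb, params$cb, params$ub, cfg$ablate)
    Xseq[t, ] <- as.vector(sa$V)
    Phi[t, ] <- sa$phi
    caches[[t]] <- list(xhat = xhat, N = N, Z = Z, H = H, sa = sa,
                        P1 = attr(Z, "W_channels"), P2 = attr(Z, "W_frequency"))
  }
  enc <- temporal_encode(Xseq, params, cfg$ablate)
  ta <- temporal_attention(enc$G, params$Wa, params$ca, params$ua, cfg$ablate)
  hd <- heads(ta$t, params, drop_mask)
  list(t = ta$t, psi = ta$psi, Phi = Phi, p_class = hd$p_class,
       p_domain = hd$p_domain, td = hd$td,
       caches = caches, Xseq = Xseq, enc = enc, ta = ta)
}

# ---- full backward pass for one sample ------------------------------------
# dlogit_y: gradient of the loss wrt label-head logits (NULL if no label
#   term); dlogit_d: scalar gradient wrt domain logit (NULL if none);
# lambda: gradient-reversal scale applied to the domain gradient entering
#   the feature extractor. Accumulates into `grad` (an environment of
#   parameter arrays).
.backward_sample <- function(fw, params, cfg, S, grad,
                             dlogit_y = NULL, dlogit_d = NULL,
                             drop_mask = NULL, lambda = 0) {
  m2 <- length(fw$t)
  dt <- numeric(m2)
  if (!is.null(dlogit_y)) {
    grad$Wy <- grad$Wy + tcrossprod(dlogit_y, fw$td)
    grad$by <- grad$by + dlogit_y
    dtd <- drop(crossprod(params$Wy, dlogit_y))
    dt <- dt + if (is.null(drop_mask)) dtd else dtd * drop_mask
  }
  if (!is.null(dlogit_d)) {
    grad$wd <- grad$wd + dlogit_d * fw$t
    grad$bd <- grad$bd + dlogit_d
    # gradient reversal: -lambda into the feature extractor
    dt <- dt - lambda * dlogit_d * params$wd
  }

  G <- fw$enc$G; w <- nrow(G)
  if ("temporal_attn" %in% cfg$ablate) {
    dG <- matrix(dt, w, m2, byrow = TRUE) / w
  } else {
    psi <- fw$ta$psi; Ah <- fw$ta$Ah
    dpsi <- drop(G %*% dt)
    dG <- tcrossprod(psi, dt)
    de <- .softmax_back(psi, dpsi)
    grad$ua <- grad$ua + drop(crossprod(Ah, de))
    dAh <- tcrossprod(de, params$ua)
    dApre <- dAh * (1 - Ah^2)
    grad$Wa <- grad$Wa + crossprod(G, dApre)
    grad$ca <- grad$ca + colSums(dApre)
    dG <- dG + dApre %*% t(params$Wa)
  }

  if ("bilstm" %in% cfg$ablate) {
    grad$Wl <- grad$Wl + crossprod(dG, fw$Xseq)
    grad$bl <- grad$bl + colSums(dG)
    dXseq <- dG %*% params$Wl
  } else {
    m <- cfg$lstm_units
    bf <- .lstm_dir_back(dG[, 1:m, drop = FALSE], fw$enc$fwd,
                         params$Wx_f, params$Wh_f)
    bb <- .lstm_dir_back(dG[, (m + 1):(2 * m), drop = FALSE], fw$enc$bwd,
                         params$Wx_b, params$Wh_b)
    grad$Wx_f <- grad$Wx_f + bf$dWx; grad$Wh_f <- grad$Wh_f + bf$dWh
    grad$b_f <- grad$b_f + bf$db
    grad$Wx_b <- grad$Wx_b + bb$dWx; grad$Wh_b <- grad$Wh_b + bb$dWh
    grad$b_b <- grad$b_b + bb$db
    dXseq <- bf$dX + bb$dX
  }

  K <- cfg$n_channels; U <- cfg$gnl_units; F <- cfg$n_freqs
  graph_ablate <- "graph_layer" %in% cfg$ablate
  for (t in seq_len(w)) {
    cc <- fw$caches[[t]]
    dV <- matrix(dXseq[t, ], K, U)
    H <- cc$H; phi <- cc$sa$phi
    if ("spatial_attn" %in% cfg$ablate) {
      dH <- dV / K
    } else {
      dH <- dV * phi
      dphi <- rowSums(dV * H)
      de <- .softmax_back(phi, dphi)
      Uh <- cc$sa$Uh
      grad$ub <- grad$ub + drop(crossprod(Uh, de))
      dUh <- tcrossprod(de, params$ub)
      dUpre <- dUh * (1 - Uh^2)
      grad$Wb <- grad$Wb + crossprod(H, dUpre)
      grad$cb <- grad$cb + colSums(dUpre)
      dH <- dH + dUpre %*% t(params$Wb)
    }
    dM <- dH * .elu_grad(attr(cc$H, "pre"))
    SZ <- if (graph_ablate) cc$Z else S %*% cc$Z
    grad$Wg <- grad$Wg + crossprod(SZ, dM)
    grad$bg <- grad$bg + colSums(dM)
    dZ <- dM %*% t(params$Wg)
    if (!graph_ablate) dZ <- S %*% dZ   # S symmetric
    dN <- .spectral_attention_back(dZ, cc, cfg$ablate)
    grad$ln_gamma <- grad$ln_gamma + colSums(dN * cc$xhat)
    grad$ln_beta <- grad$ln_beta + colSums(dN)
  }
  invisible(NULL)
}

.spectral_attention_back <- function(dZ, cc, ablate) {
  if ("spectral_block" %in% ablate) return(dZ)
  N <- cc$N; K <- nrow(N); F <- ncol(N)
  dN <- matrix(0, K, F)
  # channel branch: B1 = P1 N + N (or N)
  if (!("channel_attn" %in% ablate)) {
    P1 <- cc$P1
    dR <- dZ
    dN <- dN + dZ + crossprod(P1, dR)
    dP1 <- tcrossprod(dR, N)
    dA1 <- .row_softmax_back(P1, dP1)
    dN <- dN + (dA1 + t(dA1)) %*% N / F
  } else dN <- dN + dZ
  # frequency branch: B2 = (P2 N')' + N = N P2' + N (or N)
  if (!("freq_attn" %in% ablate)) {
    P2 <- cc$P2
    dQt <- dZ                      # gradient wrt Q' (K x F)
    dN <- dN + dZ + dQt %*% P2
    dP2 <- crossprod(dQt, N)       # dQ = dQt'; dP2 = dQ N (F x F)
    dA2 <- .row_softmax_back(P2, dP2)
    dN <- dN + N %*% (dA2 + t(dA2)) / K
  } else dN <- dN + dZ
  dN
}
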