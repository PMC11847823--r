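# Small fixtures shared across tests; everything is generated in code.

# montage of `n` channels on a line (distinct positions)
line_montage <- function(n, positions = seq_len(n)) {
  channel_montage(paste0("ch", seq_len(n)),
                  cbind(positions, 0, 0))
}

# tiny model configuration for structural tests
tiny_config <- function(w = 3, K = 4, F = 5, U = 3, m = 2, C = 3,
                        epochs = 3, ...) {
  model_config(w = w, n_classes = C, n_channels = K, n_freqs = F,
               gnl_units = U, lstm_units = m, dropout_rate = 0,
               batch_size = 4, learning_rate = 0.1, epochs = epochs, ...)
}

# random subject tensor with the given label sequence
random_subject_tensor <- function(labels, w = 3, K = 4, F = 5, id = 1) {
  videos <- lapply(labels, function(l) {
    wins <- lapply(seq_len(w), function(i) matrix(abs(rnorm(K * F)), K, F))
    assemble_video_tensor(wins, w, label = l)
  })
  assemble_subject_tensor(videos, subject_id = id)
}

# adjacency for the tiny montage sizes
tiny_S <- function(K) {
  set.seed(1234 + K)
  build_normalized_adjacency(
    channel_montage(paste0("c", seq_len(K)), matrix(stats::rnorm(3 * K), K)))$S
}

# brute-force Benjamini-Hochberg step-up (independent oracle)
bh_oracle <- function(p) {
  m <- length(p)
  adj <- rep(NA_real_, m)
  ord <- order(p)
  sorted <- p[ord]
  for (i in seq_len(m)) {
    cand <- sorted[i:m] * m / (i:m)
    adj[ord[i]] <- min(1, min(cand))
  }
  adj
}
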