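# build a (videos, w, K) Phi and (videos, w) Psi pair of valid simplices
random_attention <- function(n, w, K) {
  Phi <- array(abs(rnorm(n * w * K)) + 0.1, c(n, w, K))
  for (i in seq_len(n)) for (t in seq_len(w))
    Phi[i, t, ] <- Phi[i, t, ] / sum(Phi[i, t, ])
  Psi <- matrix(abs(rnorm(n * w)) + 0.1, n, w)
  Psi <- Psi / rowSums(Psi)
  list(Phi = Phi, Psi = Psi)
}

test_that("per-emotion averages equal inputs for a single video and stay uniform", {
  set.seed(1)
  att <- random_attention(2, 3, 4)
  stack <- emotion_attention_stack(att$Phi, att$Psi, labels = c(1, 2),
                                   subjects = c(1, 1))
  avg <- average_attention(stack)
  expect_equal(avg$emotion1$spatial, att$Phi[1, , ])
  expect_equal(avg$emotion1$temporal, att$Psi[1, ])
  u <- list(Phi = array(1 / 4, c(2, 3, 4)), Psi = matrix(1 / 3, 2, 3))
  ustack <- emotion_attention_stack(u$Phi, u$Psi, c(1, 1), c(1, 2))
  uavg <- average_attention(ustack)
  expect_equal(uavg$emotion1$spatial, matrix(1 / 4, 3, 4))
  expect_equal(uavg$emotion1$temporal, rep(1 / 3, 3))
})

test_that("two-subject averages match the element-wise mean", {
  set.seed(2)
  att <- random_attention(2, 3, 4)
  stack <- emotion_attention_stack(att$Phi, att$Psi, c(1, 1), c(1, 2))
  avg <- average_attention(stack)
  expect_equal(avg$emotion1$spatial, (att$Phi[1, , ] + att$Phi[2, , ]) / 2)
  expect_equal(avg$emotion1$temporal, colMeans(att$Psi))
})

test_that("aggregation has its closed forms under uniform and point-mass weights", {
  w <- 6; K <- 5; w_bar <- 4
  Phi <- array(1 / K, c(1, w, K))
  Psi <- matrix(1 / w, 1, w)
  expect_equal(aggregate_attention(Phi, Psi, w_bar)[1, ],
               rep(w_bar / (K * w), K))
  # point mass on window 3 <= w_bar recovers that window's spatial weights
  set.seed(3)
  att <- random_attention(1, w, K)
  point <- matrix(0, 1, w); point[1, 3] <- 1
  expect_equal(aggregate_attention(att$Phi, point, w_bar)[1, ],
               att$Phi[1, 3, ])
  expect_error(aggregate_attention(Phi, Psi, w + 1), "exceeds")
})

test_that("aggregation matches a scalar oracle on a 2-channel, 3-window toy", {
  Phi <- array(0, c(1, 3, 2))
  Phi[1, , ] <- rbind(c(0.7, 0.3), c(0.4, 0.6), c(0.9, 0.1))
  Psi <- matrix(c(0.5, 0.3, 0.2), 1, 3)
  # truncation at W-bar = 2: omega_k = 0.5*Phi[1,k] + 0.3*Phi[2,k]
  expect_equal(aggregate_attention(Phi, Psi, 2)[1, ],
               c(0.5 * 0.7 + 0.3 * 0.4, 0.5 * 0.3 + 0.3 * 0.6))
  # alternative scale reading multiplies the full-width sum by W-bar
  expect_equal(aggregate_attention(Phi, Psi, 2, scale = "multiply")[1, ],
               2 * c(0.5 * 0.7 + 0.3 * 0.4 + 0.2 * 0.9,
                     0.5 * 0.3 + 0.3 * 0.6 + 0.2 * 0.1))
})

test_that("aggregation is linear in the spatial weights for fixed temporal weights", {
  set.seed(4)
  a <- random_attention(2, 4, 3); b <- random_attention(2, 4, 3)
  Psi <- a$Psi
  lhs <- aggregate_attention(a$Phi + b$Phi, Psi, 3)
  rhs <- aggregate_attention(a$Phi, Psi, 3) + aggregate_attention(b$Phi, Psi, 3)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("the joint test family has one test per channel per emotion pair", {
  expect_equal(n_pairwise_tests(3), 186)
  expect_equal(n_pairwise_tests(4), 372)
  expect_equal(n_pairwise_tests(5), 620)
  expect_equal(n_pairwise_tests(3, n_channels = 8), 24)
})

test_that("BH adjustment inside the report matches a brute-force step-up oracle", {
  set.seed(5)
  omega <- list(A = matrix(rnorm(60, 10), 10, 6),
                B = matrix(rnorm(60, 10), 10, 6),
                C = matrix(rnorm(60, 10.8), 10, 6))
  rep_df <- pairwise_channel_tests(omega)
  expect_equal(nrow(rep_df), 3 * 6)
  expect_equal(rep_df$p_adj, bh_oracle(rep_df$p))
  expect_true(all(rep_df$p_adj >= rep_df$p - 1e-12))
  # toy vector: all four adjusted values collapse to 0.04
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
})

test_that("adjusted p-values are a monotone transform of raw p-values", {
  set.seed(6)
  omega <- list(A = matrix(rnorm(50, 5), 10, 5),
                B = matrix(rnorm(50, 5.5), 10, 5))
  rep_df <- pairwise_channel_tests(omega)
  ord <- order(rep_df$p)
  expect_true(all(diff(rep_df$p_adj[ord]) >= -1e-12))
})

test_that("identical distributions are rarely flagged at FDR 0.05", {
  set.seed(7)
  flagged <- 0; total <- 0
  for (r in 1:20) {
    omega <- list(A = matrix(rnorm(40, 8), 10, 4),
                  B = matrix(rnorm(40, 8), 10, 4))
    rep_df <- pairwise_channel_tests(omega)
    flagged <- flagged + sum(rep_df$significant)
    total <- total + nrow(rep_df)
  }
  expect_lte(flagged / total, 0.05 + 2 * sqrt(0.05 * 0.95 / total))
})

test_that("unequal group sizes fall back to the rank-sum test", {
  set.seed(8)
  omega <- list(A = matrix(rnorm(40, 8), 10, 4),
                B = matrix(rnorm(32, 9), 8, 4))
  rep_df <- pairwise_channel_tests(omega)
  expect_true(all(is.finite(rep_df$p)))
  # oracle: plain rank-sum on one channel
  ref <- stats::wilcox.test(omega$A[, 2], omega$B[, 2], exact = FALSE)$p.value
  expect_equal(rep_df$p[rep_df$channel == "ch2"], ref)
})

test_that("paired testing with too few observations is skipped with a warning", {
  omega <- list(A = matrix(1:8, 4, 2), B = matrix(c(2:5, 6:9), 4, 2))
  warns <- capture_warnings(rep_df <- pairwise_channel_tests(omega))
  expect_match(warns, "fewer than 5", all = TRUE)
  expect_length(warns, 2)
  expect_true(all(is.na(rep_df$p)))
  expect_true(all(!rep_df$significant))
})

test_that("directions point at the emotion with the larger median weight", {
  omega <- list(low = matrix(1, 6, 2), high = matrix(2, 6, 2) +
                  matrix(rnorm(12, 0, 1e-3), 6, 2))
  rep_df <- suppressWarnings(pairwise_channel_tests(omega, paired = FALSE))
  expect_true(all(rep_df$direction == "high"))
})

test_that("channel ranking is permutation-equivariant and ties under uniform weights", {
  set.seed(9)
  omega <- list(A = matrix(abs(rnorm(40)), 10, 4))
  r1 <- rank_channels(omega, channel_names = c("w", "x", "y", "z"))
  perm <- c(3, 1, 4, 2)
  omega_p <- list(A = omega$A[, perm])
  r2 <- rank_channels(omega_p, channel_names = c("w", "x", "y", "z")[perm])
  expect_equal(r1$A$channel, r2$A$channel)
  expect_equal(r1$A$mean_omega, r2$A$mean_omega)
  uni <- list(A = matrix(0.25, 5, 4))
  ru <- rank_channels(uni, uniform_ref = 0.25)
  expect_true(all(ru$A$mean_omega == 0.25))
  expect_true(all(!ru$A$above_uniform))
})
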