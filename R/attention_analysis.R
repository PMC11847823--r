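#' From attention weights to channel-relevance findings
#'
#' After LOOCV, every video carries spatial attention weights phi (one
#' simplex over channels per window) and temporal weights psi (one simplex
#' over windows). Per video, the spatial weights are aggregated over time as
#' a temporal-attention-weighted sum truncated at the dataset mean window
#' count W-bar:
#' `omega_{i,k} = sum_{t=1}^{W-bar} Phi[i,t,k] * Psi[i,t]`.
#' The per-emotion matrices Omega^e (videos x channels) are then compared
#' channel-wise between emotion pairs with Wilcoxon tests, the p-values
#' adjusted jointly by Benjamini-Hochberg, and channels ranked by mean
#' aggregated weight.
#'
#' @name attention_analysis
NULL

#' Group attention weights by emotion
#'
#' Orders videos by (subject, video index) within each emotion so paired
#' comparisons line up, and carries the aggregation horizon W-bar.
#'
#' @param Phi videos x w x channels array of spatial weights.
#' @param Psi videos x w matrix of temporal weights.
#' @param labels integer emotion labels per video.
#' @param subjects subject identifier per video.
#' @param w_bar dataset mean window count (aggregation horizon).
#' @return `emotion_attention_stack`: per-emotion list with `Phi`, `Psi`,
#'   `subjects`, plus `w_bar` and `w`.
#' @export
emotion_attention_stack <- function(Phi, Psi, labels, subjects,
                                    w_bar = dim(Psi)[2]) {
  w <- dim(Psi)[2]
  if (w_bar > w) stop("w_bar (", w_bar, ") exceeds the padded width ", w)
  per <- lapply(sort(unique(labels)), function(e) {
    sel <- which(labels == e)
    sel <- sel[order(subjects[sel], sel)]
    list(Phi = Phi[sel, , , drop = FALSE], Psi = Psi[sel, , drop = FALSE],
         subjects = subjects[sel])
  })
  names(per) <- paste0("emotion", sort(unique(labels)))
  structure(list(emotions = per, w_bar = w_bar, w = w),
            class = "emotion_attention_stack")
}

#' Average attention maps per emotion
#'
#' Element-wise mean of the spatial weights (windows x channels) and of the
#' temporal weights (windows) across all videos of each emotion — the
#' subject-averaged maps used to visualize which channels and which windows
#' the model attends to.
#'
#' @param stack an [emotion_attention_stack()].
#' @return Per-emotion list with `spatial` (w x channels) and `temporal`
#'   (length w).
#' @export
average_attention <- function(stack) {
  lapply(stack$emotions, function(e) {
    list(spatial = apply(e$Phi, c(2, 3), mean),
         temporal = colMeans(e$Psi))
  })
}

#' Aggregate spatial weights over time (per video)
#'
#' The temporal-weighted average of the spatial weights over the first
#' `w_bar` windows. Truncating at the dataset mean window count keeps the
#' comparison fair across videos of different lengths. `scale = "multiply"`
#' exposes the alternative reading in which the full-width weighted sum is
#' multiplied by `w_bar` instead of truncated.
#'
#' @param Phi videos x w x channels array.
#' @param Psi videos x w matrix.
#' @param w_bar aggregation horizon (<= w).
#' @param scale `"truncate"` (default) or `"multiply"`.
#' @return Omega: videos x channels matrix of nonnegative aggregated
#'   weights.
#' @export
aggregate_attention <- function(Phi, Psi, w_bar,
                                scale = c("truncate", "multiply")) {
  scale <- match.arg(scale)
  w <- dim(Psi)[2]
  if (w_bar > w) stop("w_bar (", w_bar, ") exceeds the padded width ", w)
  K <- dim(Phi)[3]
  n <- dim(Phi)[1]
  tsel <- if (scale == "truncate") seq_len(w_bar) else seq_len(w)
  Omega <- matrix(0, n, K)
  for (i in seq_len(n)) {
    Omega[i, ] <- drop(Psi[i, tsel] %*% Phi[i, tsel, ])
  }
  if (scale == "multiply") Omega <- Omega * w_bar
  Omega
}

#' Size of the joint multiple-testing family
#'
#' One Wilcoxon test per channel per unordered emotion pair:
#' `choose(n_classes, 2) * n_channels` (186, 372 and 620 for 3, 4 and 5
#' classes over 62 channels).
#'
#' @param n_classes number of emotion classes.
#' @param n_channels number of channels, default 62.
#' @return Integer test count.
#' @export
n_pairwise_tests <- function(n_classes, n_channels = 62) {
  choose(n_classes, 2) * n_channels
}

#' Channel-wise Wilcoxon tests between emotion pairs
#'
#' For every unordered emotion pair and every channel, compares the
#' aggregated weights Omega between the two emotions. The default is the
#' Wilcoxon signed-rank test on paired differences (pairing by position in
#' the subject-ordered stacks; zero differences dropped per the Wilcoxon
#' convention), used when both emotions have the same number of videos;
#' otherwise — or with `paired = FALSE` — the unpaired rank-sum test is
#' used. All p-values of the family are adjusted jointly with
#' Benjamini-Hochberg and flagged at the given false-discovery rate.
#' Directions come from the median difference. Pairs with fewer than 5
#' usable observations are skipped with a warning.
#'
#' @param omega_by_emotion named list of videos x channels Omega matrices.
#' @param paired prefer the paired signed-rank variant.
#' @param fdr false-discovery rate for significance flags, default 0.05.
#' @param channel_names optional channel labels.
#' @return `relevance_report` data.frame: `channel`, `pair`, `p`, `p_adj`,
#'   `direction` (name of the emotion with the larger weights, "none" on
#'   ties), `significant`.
#' @export
pairwise_channel_tests <- function(omega_by_emotion, paired = TRUE,
                                   fdr = 0.05, channel_names = NULL) {
  emos <- names(omega_by_emotion)
  if (is.null(emos)) emos <- paste0("emotion", seq_along(omega_by_emotion))
  K <- ncol(omega_by_emotion[[1]])
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(K))
  rows <- list()
  for (a in seq_along(emos)) for (b in seq_along(emos)) {
    if (b <= a) next
    Oa <- omega_by_emotion[[a]]; Ob <- omega_by_emotion[[b]]
    use_paired <- paired && nrow(Oa) == nrow(Ob)
    for (k in seq_len(K)) {
      x <- Oa[, k]; y <- Ob[, k]
      p <- NA_real_
      if (use_paired) {
        d <- x - y
        d <- d[d != 0]
        if (length(d) < 5) {
          warning("fewer than 5 paired observations for ", emos[a], " vs ",
                  emos[b], ", channel ", channel_names[k], "; test skipped")
        } else {
          p <- stats::wilcox.test(d, exact = FALSE)$p.value
        }
      } else {
        if (min(length(x), length(y)) < 5) {
          warning("fewer than 5 observations for ", emos[a], " vs ",
                  emos[b], ", channel ", channel_names[k], "; test skipped")
        } else {
          p <- stats::wilcox.test(x, y, exact = FALSE)$p.value
        }
      }
      md <- stats::median(x) - stats::median(y)
      rows[[length(rows) + 1]] <- data.frame(
        channel = channel_names[k],
        pair = paste0(emos[a], "_vs_", emos[b]),
        p = p,
        direction = if (md > 0) emos[a] else if (md < 0) emos[b] else "none",
        stringsAsFactors = FALSE)
    }
  }
  rep_df <- do.call(rbind, rows)
  rep_df$p_adj <- stats::p.adjust(rep_df$p, method = "BH")
  rep_df$significant <- !is.na(rep_df$p_adj) & rep_df$p_adj <= fdr
  rep_df <- rep_df[, c("channel", "pair", "p", "p_adj", "direction",
                       "significant")]
  class(rep_df) <- c("relevance_report", "data.frame")
  rep_df
}

#' Rank channels by mean aggregated attention
#'
#' Channels sorted by the mean of Omega over all videos of an emotion (and
#' overall). Under fully uniform attention the aggregated weight has the
#' closed form `w_bar / (n_channels * w)`; channels above that reference
#' are flagged when `uniform_ref` is supplied.
#'
#' @param omega_by_emotion named list of videos x channels Omega matrices.
#' @param channel_names optional channel labels.
#' @param uniform_ref optional numeric uniform-attention reference value.
#' @return List of data.frames (one per emotion plus `"overall"`), each
#'   with `channel`, `mean_omega`, `rank`, and `above_uniform` when a
#'   reference was given.
#' @export
rank_channels <- function(omega_by_emotion, channel_names = NULL,
                          uniform_ref = NULL) {
  K <- ncol(omega_by_emotion[[1]])
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(K))
  one <- function(M) {
    mu <- colMeans(M)
    out <- data.frame(channel = channel_names, mean_omega = mu,
                      stringsAsFactors = FALSE)
    out <- out[order(-out$mean_omega), ]
    out$rank <- seq_len(nrow(out))
    if (!is.null(uniform_ref)) out$above_uniform <- out$mean_omega > uniform_ref
    rownames(out) <- NULL
    out
  }
  res <- lapply(omega_by_emotion, one)
  res$overall <- one(do.call(rbind, omega_by_emotion))
  res
}
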