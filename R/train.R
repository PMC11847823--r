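#' Domain-adversarial training and leave-one-subject-out evaluation
#'
#' Training follows the DANN recipe: the label head sees only source-subject
#' videos (cross-entropy); the domain head sees source (class 0) and
#' held-out target (class 1) videos (binary cross-entropy) and its gradient
#' enters the shared feature extractor through a gradient-reversal layer
#' scaled by the schedule lambda(p). The target subject's emotion labels are
#' never used in training — they enter only the post-hoc accuracy
#' computation. Optimization is plain SGD.
#'
#' @name train
NULL

.stack_subject_tensors <- function(subjects) {
  d <- dim(subjects[[1]]$data)
  n <- sum(vapply(subjects, function(s) dim(s$data)[1], numeric(1)))
  arr <- array(0, c(n, d[2], d[3], d[4]))
  labels <- numeric(n)
  at <- 0
  for (s in subjects) {
    k <- dim(s$data)[1]
    arr[at + seq_len(k), , , ] <- s$data
    labels[at + seq_len(k)] <- s$labels
    at <- at + k
  }
  list(data = arr, labels = labels)
}

.sgd_update <- function(params, grad, lr) {
  for (nm in names(params)) {
    g <- if (is.environment(grad)) get(nm, envir = grad) else grad[[nm]]
    if (is.null(dim(params[[nm]]))) g <- as.vector(g)
    if (!all(is.finite(g))) stop("non-finite gradient in ", nm)
    params[[nm]] <- params[[nm]] - lr * g
  }
  params
}

#' Train one LOOCV fold
#'
#' Trains the network on all source subjects with the held-out target
#' subject's tensors participating only in the adversarial domain term,
#' then evaluates on the target subject and extracts its attention weights
#' in inference mode.
#'
#' @param source list of `subject_tensor` objects (training subjects).
#' @param target a single `subject_tensor` (held-out subject).
#' @param cfg a [model_config()].
#' @param S normalized adjacency matrix matching `cfg$n_channels` (from
#'   [build_normalized_adjacency()]), or `NULL` when the graph layer is
#'   ablated.
#' @param verbose print per-epoch losses.
#' @return A `fold_result`: list with `subject_id`, `per_class_accuracy`,
#'   `overall_accuracy` (macro average over classes), `predictions`,
#'   `labels`, `Phi` (videos x w x channels), `Psi` (videos x w), `history`
#'   (per-epoch label loss, domain loss, lambda, and worst simplex
#'   deviation), and the trained `params`.
#' @export
train_fold <- function(source, target, cfg, S = NULL, verbose = FALSE) {
  src <- .stack_subject_tensors(source)
  if (length(unique(src$labels)) < 2)
    stop("source set must contain at least 2 emotion classes")
  set.seed(cfg$seed)
  params <- init_params(cfg)
  n_s <- dim(src$data)[1]
  n_t <- dim(target$data)[1]
  B <- min(cfg$batch_size, n_s)
  n_steps <- ceiling(n_s / B)
  m2 <- 2 * cfg$lstm_units
  hist <- data.frame(epoch = seq_len(cfg$epochs), loss_y = NA_real_,
                     loss_d = NA_real_, lambda = NA_real_,
                     simplex_dev = NA_real_)

  for (epoch in seq_len(cfg$epochs)) {
    p <- (epoch - 1) / cfg$epochs          # completed-epoch fraction
    lambda <- lambda_schedule(p) * cfg$lambda_scale
    perm <- sample.int(n_s)
    ep_ly <- 0; ep_ld <- 0; ep_dev <- 0; n_ly <- 0
    for (step in seq_len(n_steps)) {
      idx <- perm[((step - 1) * B + 1):min(step * B, n_s)]
      tidx <- sample.int(n_t, length(idx), replace = TRUE)
      Bb <- length(idx)
      masks <- if (cfg$dropout_rate > 0)
        matrix((stats::runif(m2 * Bb) >= cfg$dropout_rate) /
                 (1 - cfg$dropout_rate), m2, Bb)
      else NULL
      res <- cpp_batch_grad(src$data[idx, , , , drop = FALSE],
                            as.integer(src$labels[idx]),
                            if (cfg$use_domain_head)
                              target$data[tidx, , , , drop = FALSE]
                            else numeric(0),
                            params, unclass(cfg), S, masks,
                            lambda, cfg$use_domain_head)
      ep_ly <- ep_ly + res$loss_y; n_ly <- n_ly + Bb
      ep_ld <- ep_ld + res$loss_d
      ep_dev <- max(ep_dev, res$simplex_dev)
      params <- .sgd_update(params, res$grads, cfg$learning_rate)
    }
    hist$loss_y[epoch] <- ep_ly / n_ly
    hist$loss_d[epoch] <- if (cfg$use_domain_head) ep_ld / (2 * n_ly) else NA
    hist$lambda[epoch] <- lambda
    hist$simplex_dev[epoch] <- ep_dev
    if (verbose)
      message(sprintf("epoch %d: L_y=%.4f L_d=%s lambda=%.3f", epoch,
                      hist$loss_y[epoch],
                      formatC(hist$loss_d[epoch], format = "f", digits = 4),
                      lambda))
  }

  ev <- predict_subject(params, cfg, S, target)
  acc <- per_class_accuracy(ev$predictions, target$labels, cfg$n_classes)
  structure(list(subject_id = target$subject_id,
                 per_class_accuracy = acc$per_class,
                 overall_accuracy = acc$overall,
                 predictions = ev$predictions, labels = target$labels,
                 Phi = ev$Phi, Psi = ev$Psi, history = hist, params = params),
            class = "fold_result")
}

#' Inference and attention extraction for one subject
#'
#' Runs the trained network over every video of a subject tensor in
#' inference mode (no dropout) and collects predictions together with the
#' spatial and temporal attention weights.
#'
#' @param params trained parameters.
#' @param cfg a [model_config()].
#' @param S normalized adjacency or `NULL`.
#' @param tensor a `subject_tensor`.
#' @return List with `predictions` (class indices), `probabilities`
#'   (videos x classes), `Phi` (videos x w x channels), `Psi` (videos x w).
#' @export
predict_subject <- function(params, cfg, S, tensor) {
  out <- cpp_predict(tensor$data, params, unclass(cfg), S)
  preds <- apply(out$probabilities, 1, which.max)
  list(predictions = preds, probabilities = out$probabilities,
       Phi = out$Phi, Psi = out$Psi, p_domain = out$p_domain)
}

#' Per-class and macro accuracy
#'
#' @param predictions,labels integer class indices in 1..n_classes.
#' @param n_classes class count.
#' @return List with `per_class` (named accuracy per class, NA for classes
#'   absent from `labels`) and `overall` (mean of per-class accuracies over
#'   the classes present).
#' @export
per_class_accuracy <- function(predictions, labels, n_classes) {
  per <- vapply(seq_len(n_classes), function(k) {
    sel <- labels == k
    if (!any(sel)) return(NA_real_)
    mean(predictions[sel] == k)
  }, numeric(1))
  names(per) <- paste0("class", seq_len(n_classes))
  list(per_class = per, overall = mean(per, na.rm = TRUE))
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject, each subject held out exactly once; the summary
#' reports the mean, standard deviation, and t-based 95% confidence
#' interval of fold overall accuracies across subjects.
#'
#' @param subjects list of `subject_tensor` objects.
#' @param cfg a [model_config()].
#' @param S normalized adjacency or `NULL`.
#' @param verbose print fold progress.
#' @return List with `folds` (list of `fold_result`) and `summary`
#'   (mean, sd, ci_lower, ci_upper, n_folds).
#' @export
loocv <- function(subjects, cfg, S = NULL, verbose = FALSE) {
  n <- length(subjects)
  if (n < 2) stop("LOOCV needs at least 2 subjects")
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    if (verbose) message("fold ", i, "/", n, " (held-out subject ",
                         subjects[[i]]$subject_id, ")")
    folds[[i]] <- train_fold(subjects[-i], subjects[[i]], cfg, S)
  }
  acc <- vapply(folds, function(f) f$overall_accuracy, numeric(1))
  se <- stats::sd(acc) / sqrt(n)
  tq <- stats::qt(0.975, df = n - 1)
  list(folds = folds,
       summary = list(mean = mean(acc), sd = stats::sd(acc),
                      ci_lower = mean(acc) - tq * se,
                      ci_upper = mean(acc) + tq * se, n_folds = n))
}
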