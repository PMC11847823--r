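#' Published per-recording window counts
#'
#' The SEED-family datasets report, for every recording and emotion class,
#' how many non-overlapping 4-second windows the video yielded. These counts
#' fix two bookkeeping quantities the rest of the pipeline depends on: the
#' per-dataset padding length `w` (the maximum count) and the dataset mean
#' window count used as the aggregation horizon of the channel-relevance
#' analysis. The tables ship with the package as plain-text fixtures.
#'
#' @param dataset one of "seed", "seediv", "seedv".
#' @return data.frame with a `recording` column and one integer column per
#'   emotion class.
#' @export
segment_count_table <- function(dataset = c("seed", "seediv", "seedv")) {
  dataset <- match.arg(dataset)
  path <- system.file("extdata",
                      paste0("segment_counts_", dataset, ".tsv"),
                      package = "eegattn", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Bookkeeping summary of a window-count table
#'
#' Computes per-class mean window counts, the overall dataset mean (floored
#' to an integer, the convention behind the published aggregation horizons
#' 56/34/40), and the padding length implied by the maximum count.
#'
#' @param counts a data.frame as returned by [segment_count_table()].
#' @return List with `class_means` (named numeric), `dataset_mean_windows`
#'   (integer floor of the grand mean), and `pad_length`
#'   (via [infer_pad_length()]).
#' @export
summarize_segment_counts <- function(counts) {
  cls <- counts[, setdiff(names(counts), "recording"), drop = FALSE]
  all_counts <- unlist(cls, use.names = FALSE)
  list(class_means = colMeans(cls),
       dataset_mean_windows = as.integer(floor(mean(all_counts))),
       pad_length = infer_pad_length(all_counts))
}
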