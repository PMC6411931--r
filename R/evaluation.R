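#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a random
#' positive scores above a random negative, with ties receiving half
#' credit.
#'
#' @param labels Binary vector (1 = positive, 0 = negative); both classes
#'   must be present.
#' @param scores Numeric scores, same length.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores) # midranks give the 0.5 tie credit
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Non-interpolated step rule: scores are swept in descending order, tied
#' scores processed as one group, and the area accumulated as
#' `sum (recall_i - recall_{i-1}) * precision_i` at each group boundary.
#' With constant scores this reduces to the prevalence
#' `n_pos / (n_pos + n_neg)`.
#'
#' @inheritParams roc_auc
#' @return AUPRC in `[0, 1]`.
#' @export
pr_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  bounds <- which(!duplicated(s, fromLast = TRUE)) # last index of each group
  tp <- cumsum(y)[bounds]
  n_at <- bounds
  prec <- tp / n_at
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Benchmark a model against fresh random negative sets
#'
#' Mirrors the evaluation protocol of pairing one positive set with
#' several independently drawn random negative sets: for each replicate,
#' negatives are regenerated (seeded), featurized, optionally
#' standardized, and the model's AUC/AUPRC on positives-vs-negatives is
#' recorded.
#'
#' @param model A `binding_model`.
#' @param pos_features `feature_matrix` of the positive sequences, in the
#'   model's standardization state.
#' @param spec A [synthetic_spec] describing the negative generator.
#' @param pwm The [pwm] used for featurization.
#' @param backend A [fold_backend].
#' @param stats `background_stats`, required when the model is
#'   standardized.
#' @param n_negative_replicates Number of fresh negative sets (default 5).
#' @param seed Master seed; replicate `i` uses a derived seed.
#' @param out_tsv Optional path to write the result table.
#' @return A `data.frame` with one row per replicate (`replicate`, `auc`,
#'   `auprc`, `n_pos`, `n_neg`) plus a `"summary"` attribute with mean/sd.
#' @export
run_benchmark <- function(model, pos_features, spec, pwm,
                          backend = fold_backend_internal(), stats = NULL,
                          n_negative_replicates = 5L, seed, out_tsv = NULL) {
  stopifnot(inherits(model, "binding_model"),
            inherits(pos_features, "feature_matrix"))
  if (model$standardized && is.null(stats))
    stop("standardized model needs background stats for the negatives")
  rows <- vector("list", n_negative_replicates)
  for (i in seq_len(n_negative_replicates)) {
    rep_spec <- spec
    rep_spec$seed <- derive_seed(seed, paste0("benchmark-neg-", i))
    negs <- generate_negative_set(rep_spec)
    nf <- featurize_set(negs, pwm, backend = backend)
    if (model$standardized) nf <- z_transform(nf, stats)
    ds <- labeled_dataset(pos_features, nf)
    votes <- rf_predict(model$forest, ds$x)
    rows[[i]] <- data.frame(
      model_id = model$model_id, replicate = i,
      auc = roc_auc(ds$labels, votes), auprc = pr_auc(ds$labels, votes),
      n_pos = sum(ds$labels == 1L), n_neg = sum(ds$labels == 0L),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  attr(res, "summary") <- data.frame(
    model_id = model$model_id,
    mean_auc = mean(res$auc), sd_auc = stats::sd(res$auc),
    mean_auprc = mean(res$auprc), sd_auprc = stats::sd(res$auprc))
  if (!is.null(out_tsv)) {
    con <- file(out_tsv, open = "wb")
    utils::write.table(res, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    close(con)
  }
  res
}
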