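#' Assemble a labeled training dataset
#'
#' Combines positive (target) and negative feature matrices for one PWM
#' into the labeled dataset the classifiers train on.
#'
#' @param pos,neg `feature_matrix` objects from [featurize_set()] (or
#'   [z_transform()]), same PWM and same standardization state.
#' @return An object of class `labeled_dataset` with elements `x` (matrix),
#'   `labels` (1 = target, 0 = negative), `ids`, `pwm_id`, `standardized`,
#'   `stats_pwm_id`.
#' @export
labeled_dataset <- function(pos, neg) {
  for (m in list(pos, neg)) stopifnot(inherits(m, "feature_matrix"))
  if (!identical(attr(pos, "pwm_id"), attr(neg, "pwm_id")))
    stop("positive and negative features come from different PWMs")
  if (!identical(isTRUE(attr(pos, "standardized")),
                 isTRUE(attr(neg, "standardized"))))
    stop("positive and negative features differ in standardization state")
  x <- rbind(unclass(pos), unclass(neg))
  labels <- c(rep(1L, nrow(pos)), rep(0L, nrow(neg)))
  if (anyNA(x)) stop("labeled dataset contains missing values")
  structure(list(x = x, labels = labels, ids = rownames(x),
                 pwm_id = attr(pos, "pwm_id"),
                 standardized = isTRUE(attr(pos, "standardized")),
                 stats_pwm_id = attr(pos, "stats_pwm_id")),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset>", x$pwm_id, "-", sum(x$labels == 1), "pos /",
      sum(x$labels == 0), "neg,",
      if (x$standardized) "standardized" else "raw", "\n")
  invisible(x)
}

new_binding_model <- function(kind, pwm_id, fit, x, y, ids, standardized,
                              backend_mode, model_id) {
  oob <- rf_oob_scores(fit)
  usable <- !is.na(oob)
  oob_auc <- if (length(unique(y[usable])) == 2L)
    roc_auc(y[usable], oob[usable]) else NA_real_
  structure(list(
    model_id = model_id, kind = kind, pwm_id = pwm_id,
    standardized = standardized, backend_mode = backend_mode,
    n_trees = fit$n_trees, mtry = fit$mtry, nodesize = fit$nodesize,
    seed = fit$seed,
    summary = list(n_pos = sum(y == 1L), n_neg = sum(y == 0L),
                   oob_auc = oob_auc),
    feature_names = colnames(x),
    forest = list(trees = fit$trees, inbag = fit$inbag,
                  oob_pos = fit$oob_pos, oob_total = fit$oob_total),
    train_x = x, train_y = y, train_ids = ids
  ), class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  cat("<binding_model>", x$model_id, "kind =", x$kind,
      "| trees =", x$n_trees, "mtry =", x$mtry,
    "| n =", x$summary$n_pos, "+", x$summary$n_neg,
      "| OOB AUC =", round(x$summary$oob_auc, 3),
      "|", if (x$standardized) "standardized" else "raw", "features\n")
  invisible(x)
}

#' Train an RBP-specific binding model
#'
#' One random forest per RBP:PWM combination, trained on that RBP's own
#' positive and negative sequences (raw, unstandardized features by
#' default). Out-of-bag votes are retained for evaluation and permutation
#' importance.
#'
#' @param data A [labeled_dataset] (raw features for the canonical
#'   specific model; a standardized dataset is accepted, e.g. for
#'   cross-RBP experiments, and the state is recorded on the model).
#' @param n_trees Number of trees (default 500).
#' @param mtry Features tried per split (default 6, about sqrt(40)).
#' @param nodesize Minimum node size (default 1: grow to purity).
#' @param seed Integer seed; required. Training is fully deterministic
#'   given `(data, params, seed)`.
#' @param model_id Identifier; default derived from the PWM id.
#' @return A `binding_model`.
#' @export
train_specific <- function(data, n_trees = 500L, mtry = 6L, nodesize = 1L,
                           seed, model_id = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  tab <- table(factor(data$labels, levels = c(0L, 1L)))
  if (any(tab == 0L)) stop("training data must contain both classes")
  if (any(tab < 10L))
    stop("need at least 10 sequences per class, got ",
         tab[["1"]], " positives / ", tab[["0"]], " negatives")
  fit <- rf_fit(data$x, data$labels, n_trees = n_trees, mtry = mtry,
                nodesize = nodesize, seed = seed)
  new_binding_model(kind = "specific", pwm_id = data$pwm_id, fit = fit,
                    x = data$x, y = data$labels, ids = data$ids,
                    standardized = data$standardized,
                    backend_mode = "mfe",
                    model_id = model_id %||% paste0("specific:", data$pwm_id))
}

#' Out-of-bag vote fractions of a trained model
#'
#' For each training row, the fraction of positive votes among only those
#' trees whose bootstrap sample excluded the row. Rows that were in-bag
#' in every tree get `NA` and are excluded from OOB AUC.
#'
#' @param model A `binding_model`.
#' @return Numeric vector (one entry per training row, `NA` if never
#'   out-of-bag), named by training ids.
#' @export
oob_scores <- function(model) {
  stopifnot(inherits(model, "binding_model"))
  if (is.null(model$forest$oob_total))
    stop("model has no out-of-bag bookkeeping")
  s <- ifelse(model$forest$oob_total > 0,
              model$forest$oob_pos / model$forest$oob_total, NA_real_)
  names(s) <- model$train_ids
  s
}

#' Train the pooled general binding model
#'
#' Standardized feature matrices from several RBPs are pooled: all
#' positives are kept and negatives are down-sampled (seeded, without
#' replacement when possible) to `neg_ratio` times the pooled positive
#' count (default 1:2 positive-negative), then a single forest is trained.
#' The resulting model applies to any RBP whose features are standardized
#' against its own background.
#'
#' @param datasets List of standardized [labeled_dataset] objects from at
#'   least two distinct PWMs.
#' @param neg_ratio Negatives per positive (default 2).
#' @param n_trees,mtry,nodesize Forest hyperparameters.
#' @param seed Integer seed (negative sampling and training).
#' @param model_id Identifier; default `"general"`.
#' @return A `binding_model` with `kind = "general"`.
#' @export
train_general <- function(datasets, neg_ratio = 2, n_trees = 500L, mtry = 6L,
                          nodesize = 1L, seed, model_id = "general") {
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  for (d in datasets) {
    stopifnot(inherits(d, "labeled_dataset"))
    if (!isTRUE(d$standardized))
      stop("general model requires standardized datasets; '", d$pwm_id,
           "' is raw")
    if (!is.null(d$stats_pwm_id) && !identical(d$stats_pwm_id, d$pwm_id))
      stop("dataset '", d$pwm_id, "' was standardized with stats for '",
           d$stats_pwm_id, "'")
  }
  pwm_ids <- vapply(datasets, function(d) d$pwm_id, character(1))
  if (length(unique(pwm_ids)) < 2L)
    stop("general model needs datasets from at least 2 distinct PWMs")
  if (neg_ratio <= 0) stop("neg_ratio must be positive")
  x <- do.call(rbind, lapply(datasets, function(d) d$x))
  y <- unlist(lapply(datasets, function(d) d$labels), use.names = FALSE)
  ids <- unlist(lapply(seq_along(datasets), function(i)
    paste0(pwm_ids[i], "/", datasets[[i]]$ids)), use.names = FALSE)
  pos_i <- which(y == 1L)
  neg_i <- which(y == 0L)
  n_neg <- round(neg_ratio * length(pos_i))
  sel <- with_seed(derive_seed(seed, "general-negatives"), {
    if (length(neg_i) >= n_neg) sample(neg_i, n_neg)
    else sample(neg_i, n_neg, replace = TRUE)
  })
  keep <- c(pos_i, sort(sel))
  fit <- rf_fit(x[keep, , drop = FALSE], y[keep], n_trees = n_trees,
                mtry = mtry, nodesize = nodesize, seed = seed)
  m <- new_binding_model(kind = "general", pwm_id = unique(pwm_ids),
                         fit = fit, x = x[keep, , drop = FALSE],
                         y = y[keep], ids = ids[keep],
                         standardized = TRUE, backend_mode = "mfe",
                         model_id = model_id)
  m
}

#' Predict binding for a feature matrix
#'
#' The vote fraction is the fraction of trees voting "target"; the binding
#' call is `vote_fraction >= call_threshold`. The standardization state of
#' the features must match the model's (no silent coercion).
#'
#' @param model A `binding_model`.
#' @param features A `feature_matrix` (raw or standardized, matching the
#'   model).
#' @param call_threshold Vote fraction at or above which a sequence is
#'   called bound (default 0.5).
#' @return A `data.frame` of prediction records: `seq_id`, `pwm_id`,
#'   `model_id`, `vote_fraction`, `binding_call`, `best_site_start`
#'   (1-based), `best_site_score`.
#' @export
predict_binding <- function(model, features, call_threshold = 0.5) {
  stopifnot(inherits(model, "binding_model"))
  if (!inherits(features, "feature_matrix"))
    stop("features must come from featurize_set()/z_transform()")
  if (!identical(isTRUE(attr(features, "standardized")), model$standardized))
    stop("standardization mismatch: model expects ",
         if (model$standardized) "standardized" else "raw",
         " features but got the opposite; apply (or skip) z_transform()")
  if (ncol(features) != length(model$feature_names))
    stop("feature arity mismatch")
  votes <- rf_predict(model$forest, features)
  data.frame(
    seq_id = rownames(features),
    pwm_id = attr(features, "pwm_id"),
    model_id = model$model_id,
    vote_fraction = votes,
    binding_call = votes >= call_threshold,
    best_site_start = attr(features, "best_start"),
    best_site_score = attr(features, "best_score"),
    stringsAsFactors = FALSE
  )
}

#' Permutation importance of the 40 features
#'
#' Out-of-bag permutation importance: for each tree and feature, the
#' feature column is permuted among the tree's out-of-bag rows and the
#' mean decrease in OOB accuracy is recorded (seeded, deterministic).
#' Ties rank by feature order.
#'
#' @param model A `binding_model`.
#' @param seed Seed for the permutations; defaults to the training seed.
#' @return A `data.frame` with `feature`, `importance`, ranked by
#'   decreasing importance.
#' @export
feature_importance <- function(model, seed = model$seed) {
  stopifnot(inherits(model, "binding_model"))
  if (is.null(model$forest$inbag)) stop("model has no out-of-bag bookkeeping")
  imp <- .rf_importance_cpp(model$forest$trees, model$forest$inbag,
                            model$train_x, as.integer(model$train_y),
                            as.double(seed))
  names(imp) <- model$feature_names
  ord <- order(-imp, seq_along(imp))
  data.frame(feature = names(imp)[ord], importance = unname(imp)[ord],
             stringsAsFactors = FALSE)
}

#' Cross-RBP prediction AUC
#'
#' Applies a model trained on one RBP's (standardized) data to another
#' RBP's standardized labeled data and returns the ROC AUC — the
#' experiment that justifies pooling RBPs into a general model.
#'
#' @param model A `binding_model` trained on standardized features.
#' @param data A standardized [labeled_dataset] for the other RBP.
#' @return The AUC of the model's vote fractions against `data$labels`.
#' @export
cross_predict <- function(model, data) {
  stopifnot(inherits(model, "binding_model"), inherits(data, "labeled_dataset"))
  if (!model$standardized)
    stop("cross-RBP prediction requires a model trained on standardized features")
  if (!isTRUE(data$standardized))
    stop("cross-RBP prediction requires standardized features, got raw")
  votes <- rf_predict(model$forest, data$x)
  roc_auc(data$labels, votes)
}
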