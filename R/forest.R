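# Thin R wrapper around the compiled CART random forest. Kept separate
# from the binding-model layer so the classifier can be tested on plain
# matrices against statistical oracles.

rf_fit <- function(x, y, n_trees = 500L, mtry = 6L, nodesize = 1L, seed) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0L, 1L)))
  if (n_trees < 1L) stop("n_trees must be >= 1")
  if (missing(seed)) stop("seed is required for reproducible training")
  fit <- .rf_fit_cpp(x, y, as.integer(n_trees), as.integer(mtry),
                     as.integer(nodesize), as.double(seed))
  fit$n_trees <- as.integer(n_trees)
  fit$mtry <- as.integer(mtry)
  fit$nodesize <- as.integer(nodesize)
  fit$seed <- as.numeric(seed)
  class(fit) <- "rbp_rf"
  fit
}

rf_predict <- function(fit, x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  .rf_predict_cpp(fit$trees, x)
}

# Per-row OOB positive-vote fraction; rows never out-of-bag are NA.
rf_oob_scores <- function(fit) {
  ifelse(fit$oob_total > 0, fit$oob_pos / fit$oob_total, NA_real_)
}

rf_importance <- function(fit, x, y, seed = fit$seed) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  imp <- .rf_importance_cpp(fit$trees, fit$inbag, x, as.integer(y),
                            as.double(seed))
  names(imp) <- colnames(x)
  imp
}
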