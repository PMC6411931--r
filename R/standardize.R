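#' Background feature distribution for one PWM
#'
#' Raw features depend strongly on the PWM, so feature values are not
#' comparable across RBPs. To pool training data across RBPs, each
#' feature column is z-standardized against its empirical distribution on
#' a background sequence set (3'-UTR-like sequences with no known relation
#' to the RBP): `z = (f - M_j) / S_j` with the per-column sample mean
#' `M_j` and sample standard deviation `S_j` (n-1 denominator).
#'
#' @param background List of [candidate_seq] objects (at least 2, each at
#'   least as long as the motif).
#' @param pwm An [pwm].
#' @param backend A [fold_backend]; default internal.
#' @param seed Optional seed recorded for provenance (the computation
#'   itself is deterministic).
#' @return An object of class `background_stats` with `pwm_id`,
#'   `n_background`, `mean` and `sd` (length-40 vectors), `backend_mode`,
#'   `seed`.
#' @export
compute_background_stats <- function(background, pwm,
                                     backend = fold_backend_internal(),
                                     seed = NULL) {
  if (length(background) < 2L)
    stop("need at least 2 background sequences, got ", length(background))
  x <- featurize_set(background, pwm, backend = backend)
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  structure(list(pwm_id = pwm$id, n_background = nrow(x),
                 mean = m, sd = s, backend_mode = backend$mode,
                 seed = seed),
            class = "background_stats")
}

#' @export
print.background_stats <- function(x, ...) {
  cat("<background_stats>", x$pwm_id, "- n =", x$n_background,
      "backend mode =", x$backend_mode, "\n")
  invisible(x)
}

#' z-standardize a feature matrix against background statistics
#'
#' Columns with zero background standard deviation (reachable, e.g. with a
#' uniform PWM where every matching score is constant) map to 0 rather
#' than NA or infinity, keeping vectors complete for the forest.
#'
#' @param x A `feature_matrix` (raw) from [featurize_set()], or a plain
#'   named numeric vector/matrix with the 40 feature columns.
#' @param stats A `background_stats` for the same PWM.
#' @return The standardized matrix, `standardized` attribute set to
#'   `TRUE` and `stats_pwm_id` recorded.
#' @export
z_transform <- function(x, stats) {
  stopifnot(inherits(stats, "background_stats"))
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, nrow = 1, dimnames = list(NULL, names(x))) else x
  pid <- attr(xm, "pwm_id")
  if (!is.null(pid) && !identical(pid, stats$pwm_id))
    stop("PWM mismatch: features computed for '", pid,
         "' but stats are for '", stats$pwm_id, "'")
  if (isTRUE(attr(xm, "standardized")))
    stop("features are already standardized")
  if (ncol(xm) != length(stats$mean))
    stop("feature arity mismatch: ", ncol(xm), " vs ", length(stats$mean))
  z <- sweep(xm, 2, stats$mean, "-")
  s <- stats$sd
  nz <- s > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2, s[nz], "/")
  z[, !nz] <- 0
  out <- structure(as.matrix(z), class = c("feature_matrix", "matrix", "array"),
                   pwm_id = pid %||% stats$pwm_id, standardized = TRUE,
                   stats_pwm_id = stats$pwm_id,
                   backend_mode = attr(xm, "backend_mode") %||% stats$backend_mode,
                   best_start = attr(xm, "best_start"),
                   best_score = attr(xm, "best_score"))
  if (vec) {
    v <- out[1, ]
    attributes(v) <- c(attributes(v),
                       list(pwm_id = attr(out, "pwm_id"), standardized = TRUE,
                            stats_pwm_id = stats$pwm_id))
    return(v)
  }
  out
}

#' Save / load background statistics as JSON
#'
#' All 80 numbers plus provenance (PWM id, background size, backend mode,
#' seed) are stored at full precision.
#'
#' @param stats A `background_stats` object.
#' @param path File path.
#' @return `path` / the loaded `background_stats`.
#' @export
save_background_stats <- function(stats, path) {
  stopifnot(inherits(stats, "background_stats"))
  payload <- list(format = "rbpforest-stats-1",
                  pwm_id = stats$pwm_id, n_background = stats$n_background,
                  feature_names = names(stats$mean),
                  mean = unname(stats$mean), sd = unname(stats$sd),
                  backend_mode = stats$backend_mode, seed = stats$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname save_background_stats
#' @export
load_background_stats <- function(path) {
  if (!file.exists(path)) stop("stats file not found: ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "rbpforest-stats-1"))
    stop("stats format version mismatch in ", path)
  m <- as.numeric(p$mean); s <- as.numeric(p$sd)
  names(m) <- names(s) <- p$feature_names
  structure(list(pwm_id = p$pwm_id, n_background = p$n_background,
                 mean = m, sd = s, backend_mode = p$backend_mode,
                 seed = p$seed),
            class = "background_stats")
}
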