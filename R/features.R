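#' Matching scores of every motif placement in a sequence
#'
#' The matching score of the k-mer starting at position `i` is the plain
#' sum over the k motif positions of the PWM frequency of the observed
#' base (no log-odds, no pseudocounts); an `N` contributes 0.25, the
#' expected frequency of a renormalized column. Scores lie in `[0, k]`.
#'
#' @param seq A [candidate_seq].
#' @param pwm An [pwm] object with motif length `k <= L`.
#' @return Numeric vector of `L - k + 1` scores; element `i` is the score
#'   of the placement starting at 0-based position `i - 1`.
#' @export
scan_matching_scores <- function(seq, pwm) {
  stopifnot(inherits(seq, "candidate_seq"), inherits(pwm, "rbp_pwm"))
  L <- seq$length
  k <- pwm$k
  if (L < k)
    stop("sequence '", seq$id, "' (L = ", L, ") is shorter than the motif (k = ", k, ")")
  codes <- match(strsplit(seq$bases, "")[[1]], c("A", "C", "G", "U"))
  n <- L - k + 1L
  scores <- numeric(n)
  for (j in seq_len(k)) {
    contrib <- pwm$freq[j, codes[j:(j + n - 1L)]]
    contrib[is.na(contrib)] <- 0.25 # N base
    scores <- scores + contrib
  }
  unname(scores)
}

#' Select the top putative binding sites
#'
#' The `n` best-scoring placements, sorted by score descending with ties
#' broken by the smaller start. If fewer than `n` placements exist the
#' list is padded with zero-score sites flagged `padded = TRUE` so that
#' downstream feature vectors always have a fixed arity.
#'
#' @param scores Score vector from [scan_matching_scores()].
#' @param n Number of sites (default 10).
#' @return A `data.frame` with columns `start` (0-based), `ms`, `rank`,
#'   `padded`.
#' @export
select_top_sites <- function(scores, n = 10L) {
  if (length(scores) == 0L) stop("empty score vector")
  ord <- order(-scores, seq_along(scores))
  take <- seq_len(min(n, length(scores)))
  real <- data.frame(start = ord[take] - 1L, ms = scores[ord[take]],
                     rank = take, padded = FALSE)
  if (length(scores) < n) {
    pad <- data.frame(start = NA_integer_,
                      ms = 0,
                      rank = (length(scores) + 1L):n,
                      padded = TRUE)
    real <- rbind(real, pad)
  }
  rownames(real) <- NULL
  real
}

#' Clustering score (CS) of a putative site
#'
#' Measures the clustering propensity of PWM matches around a site: inside
#' a 50-nt window centered on the site's midpoint, the five largest local
#' maxima of the matching-score profile are ranked and combined with
#' geometric weights, `CS = sum over r of 2^-r * S_r`. Local maxima are
#' taken on the windowed profile (window edges act one-sidedly); a plateau
#' counts once, at its leftmost position. Missing ranks contribute 0;
#' padded sites score 0.
#'
#' @param scores Full matching-score vector of the sequence.
#' @param site One row of [select_top_sites()] output.
#' @param k Motif length (placement width).
#' @param window_nt Window width in nucleotides (default 50).
#' @param n_peaks Number of ranked peaks (default 5).
#' @return The clustering score.
#' @export
clustering_score <- function(scores, site, k, window_nt = 50L, n_peaks = 5L) {
  if (isTRUE(site$padded)) return(0)
  n <- length(scores)
  L <- n + k - 1L
  mid <- site$start + k / 2
  lo <- max(0, mid - window_nt / 2)
  hi <- min(L, mid + window_nt / 2)
  # placements whose k-mer lies fully inside the clamped window
  starts <- which(seq_len(n) - 1L >= ceiling(lo - 1e-9) &
                  seq_len(n) - 1L + k <= floor(hi + 1e-9))
  if (length(starts) == 0L) starts <- site$start + 1L # degenerate k > window
  peaks <- local_maxima(scores[starts])
  if (length(peaks) == 0L) return(0)
  pk <- sort(scores[starts][peaks], decreasing = TRUE)
  r <- seq_len(min(n_peaks, length(pk)))
  sum(2^(-r) * pk[r])
}

# Local maxima of a vector with plateau handling: a maximal run of equal
# values is a local maximum if it exceeds both flanking values (one-sided
# at the vector boundaries); it is reported once, at its leftmost index.
local_maxima <- function(v) {
  n <- length(v)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- logical(length(r$values))
  for (i in seq_along(r$values)) {
    left_ok <- (i == 1L) || (r$values[i] > r$values[i - 1L])
    right_ok <- (i == length(r$values)) || (r$values[i] > r$values[i + 1L])
    keep[i] <- left_ok && right_ok
  }
  starts[keep]
}

#' Conservation score (Csrv) of a putative site
#'
#' The average conservation over ten consecutive positions starting at the
#' site (clamped at the sequence end; the mean is over the positions
#' actually available). Sequences without a track, and padded sites,
#' score 0.
#'
#' @param seq A [candidate_seq].
#' @param site One row of [select_top_sites()] output.
#' @param span Number of consecutive positions averaged (default 10).
#' @return The conservation score.
#' @export
conservation_score <- function(seq, site, span = 10L) {
  if (isTRUE(site$padded)) return(0)
  if (is.null(seq$track)) return(0)
  from <- site$start + 1L
  to <- min(site$start + span, seq$length)
  mean(seq$track[from:to])
}

.FEATURE_NAMES <- c(paste0("MS", 1:10), paste0("CS", 1:10),
                    paste0("Gacc", 1:10), paste0("Csrv", 1:10))

#' Encode one sequence as the 40-feature vector
#'
#' The ten best PWM placements ("putative binding sites") are located and
#' each contributes four features — matching score (MS), clustering score
#' (CS), structural accessibility (Gacc) and conservation (Csrv) — giving
#' a fixed-order vector `MS1..MS10, CS1..CS10, Gacc1..Gacc10,
#' Csrv1..Csrv10`. Feature index `i` refers to the rank-`i` site.
#'
#' @param seq A [candidate_seq].
#' @param pwm An [pwm].
#' @param backend A [fold_backend]; default internal.
#' @param n_sites Number of putative sites (default 10).
#' @return Named numeric vector of length `4 * n_sites` with attributes
#'   `seq_id`, `pwm_id`, `sites` (the site table).
#' @export
featurize <- function(seq, pwm, backend = fold_backend_internal(),
                      n_sites = 10L) {
  scores <- scan_matching_scores(seq, pwm)
  sites <- select_top_sites(scores, n = n_sites)
  ms <- sites$ms
  cs <- gacc <- csrv <- numeric(n_sites)
  for (i in seq_len(n_sites)) {
    site <- sites[i, ]
    cs[i] <- clustering_score(scores, site, k = pwm$k)
    gacc[i] <- accessibility_score(seq, site, backend = backend)
    csrv[i] <- conservation_score(seq, site)
  }
  fv <- c(ms, cs, gacc, csrv)
  names(fv) <- if (n_sites == 10L) .FEATURE_NAMES else
    c(paste0("MS", seq_len(n_sites)), paste0("CS", seq_len(n_sites)),
      paste0("Gacc", seq_len(n_sites)), paste0("Csrv", seq_len(n_sites)))
  stopifnot(all(is.finite(fv)))
  attr(fv, "seq_id") <- seq$id
  attr(fv, "pwm_id") <- pwm$id
  attr(fv, "sites") <- sites
  fv
}

#' Encode a set of sequences as a feature matrix
#'
#' @param seqs List of [candidate_seq] objects.
#' @param pwm An [pwm].
#' @param backend A [fold_backend]; default internal.
#' @return A numeric matrix (one row per sequence, 40 named columns) of
#'   class `feature_matrix`, with attributes `pwm_id`, `standardized`
#'   (`FALSE` for raw features), `backend_mode`, `best_start` (1-based
#'   start of each sequence's best site) and `best_score`.
#' @export
featurize_set <- function(seqs, pwm, backend = fold_backend_internal()) {
  stopifnot(length(seqs) > 0L)
  rows <- vector("list", length(seqs))
  best_start <- integer(length(seqs))
  best_score <- numeric(length(seqs))
  for (i in seq_along(seqs)) {
    fv <- featurize(seqs[[i]], pwm, backend = backend)
    rows[[i]] <- as.numeric(fv)
    sites <- attr(fv, "sites")
    best_start[i] <- sites$start[1L] + 1L # 1-based in outputs
    best_score[i] <- sites$ms[1L]
  }
  x <- do.call(rbind, rows)
  colnames(x) <- .FEATURE_NAMES
  rownames(x) <- vapply(seqs, function(s) s$id, character(1))
  structure(x, class = c("feature_matrix", "matrix", "array"),
            pwm_id = pwm$id, standardized = FALSE,
            backend_mode = backend$mode,
            best_start = best_start, best_score = best_score)
}
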