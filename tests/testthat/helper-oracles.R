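# Independent oracles, written before the implementations they check.
# Direct loops and exhaustive enumeration only; no shared code with R/.

# PWM matching score by per-position summation
naive_scan <- function(bases, freq) {
  chars <- strsplit(bases, "")[[1]]
  k <- nrow(freq)
  L <- length(chars)
  lut <- c(A = 1, C = 2, G = 3, U = 4)
  vapply(seq_len(L - k + 1), function(i) {
    s <- 0
    for (j in seq_len(k)) {
      b <- chars[i + j - 1]
      s <- s + if (b %in% names(lut)) freq[j, lut[[b]]] else 0.25
    }
    s
  }, numeric(1))
}

# Exhaustive enumeration of all nested structures (min hairpin loop 3,
# AU/GC/GU pairs, masked positions unpaired); returns the max pair count.
enum_max_pairs <- function(bases, mask = rep(FALSE, nchar(bases))) {
  chars <- strsplit(bases, "")[[1]]
  ok <- function(a, b) {
    p <- paste0(a, b)
    p %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  best <- function(i, j) {
    if (j - i < 4) return(0L)
    # enumerate choices for position i: unpaired, or paired with each l
    res <- best(i + 1L, j)
    for (l in (i + 4L):j) {
      if (mask[i] || mask[l]) next
      if (!ok(chars[i], chars[l])) next
      res <- max(res, 1L + best(i + 1L, l - 1L) + best(l + 1L, j))
    }
    res
  }
  n <- length(chars)
  if (n < 5) return(0L)
  best(1L, n)
}

# AUC by all-pairs counting
naive_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# AUPRC by explicit threshold sweep over distinct scores (step rule)
naive_auprc <- function(labels, scores) {
  ths <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1)
  prev_rec <- 0
  area <- 0
  for (t in ths) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / n1
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# two-pass mean/sd (n-1) per column
naive_colstats <- function(x) {
  m <- apply(x, 2, function(v) sum(v) / length(v))
  s <- apply(x, 2, function(v) sqrt(sum((v - sum(v) / length(v))^2) / (length(v) - 1)))
  list(mean = m, sd = s)
}

# Direct-loop reimplementation of the 40-feature encoding for small
# instances (uses enum_max_pairs for the accessibility term, so keep
# L <= 20). Mirrors the documented conventions, not the package code.
naive_featurize <- function(bases, freq, track = NULL) {
  k <- nrow(freq)
  L <- nchar(bases)
  scores <- naive_scan(bases, freq)
  np <- length(scores)
  ord <- order(-scores, seq_len(np))
  n_sites <- 10L
  ms <- cs <- gacc <- csrv <- numeric(n_sites)
  chars <- strsplit(bases, "")[[1]]
  for (r in seq_len(n_sites)) {
    if (r > np) next # padded: all zeros
    start0 <- ord[r] - 1L
    ms[r] <- scores[ord[r]]
    # clustering: local maxima of the windowed profile
    mid <- start0 + k / 2
    lo <- max(0, mid - 25)
    hi <- min(L, mid + 25)
    in_win <- which((seq_len(np) - 1) >= lo - 1e-9 &
                    (seq_len(np) - 1) + k <= hi + 1e-9)
    wv <- scores[in_win]
    peaks <- c()
    i <- 1
    while (i <= length(wv)) {
      j <- i
      while (j < length(wv) && wv[j + 1] == wv[i]) j <- j + 1
      left_ok <- i == 1 || wv[i] > wv[i - 1]
      right_ok <- j == length(wv) || wv[j] > wv[j + 1]
      if (left_ok && right_ok) peaks <- c(peaks, wv[i])
      i <- j + 1
    }
    if (length(peaks) > 0) {
      pk <- sort(peaks, decreasing = TRUE)
      for (rr in seq_len(min(5, length(pk)))) cs[r] <- cs[r] + 2^(-rr) * pk[rr]
    }
    # accessibility on clamped segment via exhaustive enumeration
    seg_lo <- max(0, start0 - 85); seg_hi <- min(L, start0 + 95)
    core_lo <- max(0, start0 - 15); core_hi <- min(L, start0 + 25)
    seg <- substr(bases, seg_lo + 1, seg_hi)
    msk <- rep(FALSE, seg_hi - seg_lo)
    msk[(core_lo - seg_lo + 1):(core_hi - seg_lo)] <- TRUE
    gacc[r] <- enum_max_pairs(seg) - enum_max_pairs(seg, msk)
    if (!is.null(track))
      csrv[r] <- mean(track[(start0 + 1):min(start0 + 10, L)])
  }
  c(ms, cs, gacc, csrv)
}
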