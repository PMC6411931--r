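#' Specification of a synthetic RBP-binding dataset
#'
#' Describes the "world" every generator draws from: an RBP's PWM (given
#' or generated), 3'-UTR-like background sequences, positives carrying
#' PWM-sampled motif instances at non-overlapping positions, and
#' phyloP-like conservation tracks elevated at the planted sites.
#'
#' Defaults model the conditions the method targets: 7-nt motifs (typical
#' RBP motif length), Dirichlet concentration 0.1 (an informative,
#' RNAcompete-like motif), 100 positives / 100 negatives, 300-nt
#' sequences (above the 150-nt length filter and long enough for interior
#' 180-nt folding segments), 1-2 planted sites per positive, uniform base
#' composition (an AU-rich preset is available via `base_comp`), standard
#' normal baseline conservation with planted sites shifted to mean 2.
#'
#' @param pwm Optional [pwm]; if `NULL`, one is generated from
#'   `(k, concentration, seed)`.
#' @param k Motif length for a generated PWM (default 7).
#' @param concentration Symmetric Dirichlet concentration for generated
#'   PWM rows (default 0.1; smaller = more informative).
#' @param n_pos,n_neg Numbers of positive / negative sequences.
#' @param seq_length Sequence length in nt (default 300).
#' @param sites_per_positive Integer range `c(min, max)` of motif
#'   instances planted per positive (default `c(1, 2)`).
#' @param base_comp Named background base probabilities
#'   (`A`, `C`, `G`, `U`).
#' @param conservation List with `baseline_mean`, `baseline_sd`,
#'   `site_mean`, `site_sd`.
#' @param seed Mandatory integer seed.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(pwm = NULL, k = 7L, concentration = 0.1,
                           n_pos = 100L, n_neg = 100L, seq_length = 300L,
                           sites_per_positive = c(1L, 2L),
                           base_comp = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                           conservation = list(baseline_mean = 0,
                                               baseline_sd = 1,
                                               site_mean = 2,
                                               site_sd = 0.5),
                           seed) {
  if (missing(seed)) stop("seed is mandatory for a synthetic_spec")
  stopifnot(n_pos >= 1L, n_neg >= 1L, seq_length >= 1L)
  stopifnot(length(sites_per_positive) == 2L,
            sites_per_positive[1] >= 1L,
            sites_per_positive[2] >= sites_per_positive[1])
  stopifnot(setequal(names(base_comp), c("A", "C", "G", "U")),
            all(base_comp >= 0), sum(base_comp) > 0)
  base_comp <- base_comp[c("A", "C", "G", "U")] / sum(base_comp)
  if (is.null(pwm)) pwm <- generate_pwm(k, concentration,
                                        derive_seed(seed, "pwm"))
  if (seq_length < pwm$k)
    stop("seq_length must be at least the motif length")
  structure(list(pwm = pwm, n_pos = as.integer(n_pos),
                 n_neg = as.integer(n_neg),
                 seq_length = as.integer(seq_length),
                 sites_per_positive = as.integer(sites_per_positive),
                 base_comp = base_comp, conservation = conservation,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' AU-rich 3'-UTR-like base composition preset
#'
#' @return Named probability vector (A .3, C .2, G .2, U .3).
#' @export
utr_base_comp <- function() c(A = 0.3, C = 0.2, G = 0.2, U = 0.3)

#' Generate a random PWM
#'
#' Each row is an independent draw from a symmetric Dirichlet: low
#' concentration gives informative (peaked) columns, high concentration
#' approaches the uniform matrix.
#'
#' @param k Motif length.
#' @param concentration Dirichlet concentration parameter (> 0).
#' @param seed Integer seed.
#' @param id PWM identifier; default encodes `k` and the seed.
#' @return An [pwm] object.
#' @export
generate_pwm <- function(k, concentration, seed,
                         id = sprintf("synthPWM_k%d_s%d", k, seed)) {
  stopifnot(k >= 1L, concentration > 0)
  freq <- with_seed(seed, {
    g <- matrix(stats::rgamma(4L * k, shape = concentration), nrow = k)
    g / rowSums(g)
  })
  colnames(freq) <- c("A", "C", "G", "U")
  pwm(freq, id = id)
}

random_bases <- function(n, comp) {
  paste(sample(names(comp), n, replace = TRUE, prob = comp), collapse = "")
}

sample_motif_instance <- function(pwm) {
  paste(vapply(seq_len(pwm$k), function(j)
    sample(colnames(pwm$freq), 1L, prob = pwm$freq[j, ]), character(1)),
    collapse = "")
}

# non-overlapping 0-based start positions for n_sites k-mers in [0, L-k]
place_sites <- function(L, k, n_sites, max_tries = 200L) {
  placed <- integer(0)
  for (s in seq_len(n_sites)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      cand <- sample.int(L - k + 1L, 1L) - 1L
      if (all(abs(cand - placed) >= k)) { placed <- c(placed, cand); ok <- TRUE; break }
    }
    if (!ok) stop("could not place ", n_sites,
                  " non-overlapping sites of length ", k, " in ", L, " nt")
  }
  sort(placed)
}

#' Generate planted-motif positive sequences
#'
#' Background bases are i.i.d. from the spec's composition; each positive
#' receives between `sites_per_positive[1]` and `[2]` motif instances,
#' sampled column-wise from the PWM, at non-overlapping uniform positions.
#'
#' @param spec A [synthetic_spec].
#' @return A list with `seqs` (list of [candidate_seq], ids `pos_1...`)
#'   and `annotations` (a `data.frame` of planted intervals: `seq_id`,
#'   `start` 0-based, `end` exclusive, `instance`).
#' @export
generate_positive_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(derive_seed(spec$seed, "positives"), {
    k <- spec$pwm$k
    seqs <- vector("list", spec$n_pos)
    ann <- list()
    for (i in seq_len(spec$n_pos)) {
      bases <- strsplit(random_bases(spec$seq_length, spec$base_comp), "")[[1]]
      n_range <- seq.int(spec$sites_per_positive[1], spec$sites_per_positive[2])
      n_sites <- n_range[sample.int(length(n_range), 1L)]
      starts <- place_sites(spec$seq_length, k, n_sites)
      id <- paste0("pos_", i)
      for (s in starts) {
        inst <- sample_motif_instance(spec$pwm)
        bases[(s + 1L):(s + k)] <- strsplit(inst, "")[[1]]
        ann[[length(ann) + 1L]] <-
          data.frame(seq_id = id, start = s, end = s + k, instance = inst)
      }
      seqs[[i]] <- candidate_seq(id, paste(bases, collapse = ""))
    }
    annotations <- do.call(rbind, ann)
    rownames(annotations) <- NULL
    list(seqs = stats::setNames(seqs, vapply(seqs, `[[`, "", "id")),
         annotations = annotations)
  })
}

#' Generate background-only negative sequences
#'
#' Pseudo-negatives are plain background sequences (random sequences
#' approximate experimental negatives well when none are available).
#' Optionally, sequences containing an exact match to the PWM consensus
#' can be rejected and resampled (off by default).
#'
#' @param spec A [synthetic_spec].
#' @param screen_consensus If `TRUE`, resample sequences containing the
#'   PWM consensus k-mer.
#' @return A list of [candidate_seq] with ids `neg_1...`.
#' @export
generate_negative_set <- function(spec, screen_consensus = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  consensus <- paste(colnames(spec$pwm$freq)[apply(spec$pwm$freq, 1, which.max)],
                     collapse = "")
  with_seed(derive_seed(spec$seed, "negatives"), {
    seqs <- vector("list", spec$n_neg)
    for (i in seq_len(spec$n_neg)) {
      repeat {
        b <- random_bases(spec$seq_length, spec$base_comp)
        if (!screen_consensus || !grepl(consensus, b, fixed = TRUE)) break
      }
      seqs[[i]] <- candidate_seq(paste0("neg_", i), b)
    }
    stats::setNames(seqs, vapply(seqs, `[[`, "", "id"))
  })
}

#' Generate phyloP-like conservation tracks
#'
#' Every position gets Gaussian baseline noise; positions inside planted
#' intervals are drawn from the elevated distribution instead.
#'
#' @param seqs List of [candidate_seq].
#' @param annotations Planted-interval table from
#'   [generate_positive_set()] (may cover only some sequences; pass
#'   `NULL` for none).
#' @param spec A [synthetic_spec] (its `conservation` block is used).
#' @param seed Optional override seed; defaults to one derived from the
#'   spec seed.
#' @return The sequences with `track` filled in.
#' @export
generate_conservation_tracks <- function(seqs, annotations, spec,
                                         seed = derive_seed(spec$seed, "tracks")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  cv <- spec$conservation
  with_seed(seed, {
    for (i in seq_along(seqs)) {
      s <- seqs[[i]]
      track <- stats::rnorm(s$length, cv$baseline_mean, cv$baseline_sd)
      if (!is.null(annotations)) {
        rows <- annotations[annotations$seq_id == s$id, , drop = FALSE]
        for (j in seq_len(nrow(rows))) {
          idx <- (rows$start[j] + 1L):rows$end[j]
          track[idx] <- stats::rnorm(length(idx), cv$site_mean, cv$site_sd)
        }
      }
      seqs[[i]]$track <- track
    }
    seqs
  })
}

#' Remove sequences shorter than a minimum length
#'
#' Reproduces the benchmark length filter: sequences strictly shorter
#' than `min_len` nucleotides are removed (a sequence of exactly
#' `min_len` is kept).
#'
#' @param seqs List of [candidate_seq].
#' @param min_len Minimum length (default 150).
#' @return The surviving sequences; the removed count is reported via
#'   `message()`, and an empty result triggers a warning.
#' @export
apply_length_filter <- function(seqs, min_len = 150L) {
  keep <- vapply(seqs, function(s) s$length >= min_len, logical(1))
  if (sum(!keep) > 0L)
    message("length filter removed ", sum(!keep), " of ", length(seqs),
            " sequences (< ", min_len, " nt)")
  out <- seqs[keep]
  if (length(out) == 0L) warning("length filter removed all sequences")
  out
}
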