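# Shared fixture builders (everything generated in code; no stored data).

uniform_pwm <- function(k = 4L, id = "uniform") {
  pwm(matrix(0.25, nrow = k, ncol = 4,
             dimnames = list(NULL, c("A", "C", "G", "U"))), id = id)
}

# deterministic PWM with all mass on the given consensus string
consensus_pwm <- function(consensus, id = paste0("cons_", consensus)) {
  chars <- strsplit(chartr("T", "U", consensus), "")[[1]]
  freq <- matrix(0, nrow = length(chars), ncol = 4,
                 dimnames = list(NULL, c("A", "C", "G", "U")))
  for (j in seq_along(chars)) freq[j, chars[j]] <- 1
  pwm(freq, id = id)
}

random_seq <- function(L, id = "r", comp = c(A = .25, C = .25, G = .25, U = .25)) {
  candidate_seq(id, paste(sample(names(comp), L, TRUE, prob = comp),
                          collapse = ""))
}

# a fake external folder: reads two stdin lines (sequence, constraint) and
# reports energies derived from them, RNAfold-style output
write_mock_folder <- function(dir = tempfile("mockfold")) {
  dir.create(dir, showWarnings = FALSE)
  exe <- file.path(dir, "mockfold")
  writeLines(c(
    "#!/bin/sh",
    "read seq",
    "read constraint",
    "# energy = -(0.1 * number of unconstrained positions), so adding",
    "# constraints raises the energy, as a real folder must",
    "free=$(printf %s \"$constraint\" | tr -cd '.' | wc -c)",
    "e=$(awk -v n=\"$free\" 'BEGIN{printf \"%.2f\", -0.1*n}')",
    "printf '%s\\n' \"$seq\"",
    "printf '....(((...))) (%s)\\n' \"$e\"",
    "printf ' free energy of ensemble = %s kcal/mol\\n' \"$e\""
  ), exe)
  Sys.chmod(exe, "0755")
  exe
}

# small end-to-end synthetic dataset, featurized; returns list(ds, pwm, spec)
make_planted_dataset <- function(seed, n_pos = 30L, n_neg = 30L, k = 7L,
                                 seq_length = 200L, concentration = 0.1,
                                 with_tracks = FALSE,
                                 backend = fold_backend_internal()) {
  spec <- synthetic_spec(k = k, concentration = concentration, n_pos = n_pos,
                         n_neg = n_neg, seq_length = seq_length, seed = seed)
  pos <- generate_positive_set(spec)
  neg <- generate_negative_set(spec)
  if (with_tracks) {
    pos$seqs <- generate_conservation_tracks(pos$seqs, pos$annotations, spec)
    neg <- generate_conservation_tracks(neg, NULL, spec,
                                        seed = derive_seed(spec$seed, "nt"))
  }
  pf <- featurize_set(pos$seqs, spec$pwm, backend = backend)
  nf <- featurize_set(neg, spec$pwm, backend = backend)
  list(ds = labeled_dataset(pf, nf), pwm = spec$pwm, spec = spec,
       pos = pos, neg = neg, pos_features = pf, neg_features = nf)
}

derive_seed <- rbpforest:::derive_seed
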