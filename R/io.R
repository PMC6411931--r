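#' Construct a candidate RNA sequence
#'
#' A candidate sequence is one RNA (or DNA) sequence to be scored against an
#' RBP's binding preference. Bases are normalized to the RNA alphabet
#' (uppercase, `T` mapped to `U`); `N` marks unresolved bases. An optional
#' per-position conservation track (phyloP-like, unitless) of exactly the
#' sequence length may be attached.
#'
#' @param id Sequence identifier (single non-empty string).
#' @param bases Sequence string; `T`/`t` are treated as `U`.
#' @param track Optional numeric vector of per-position conservation scores,
#'   length equal to the sequence length.
#' @return An object of class `candidate_seq` with elements `id`, `bases`,
#'   `length`, `track`.
#' @export
candidate_seq <- function(id, bases, track = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(bases), length(bases) == 1L)
  bases <- chartr("Tt", "Uu", bases)
  bases <- toupper(bases)
  if (!nzchar(bases)) stop("empty sequence for id '", id, "'")
  bad <- gsub("[ACGUN]", "", bases)
  if (nzchar(bad))
    stop("sequence '", id, "' contains invalid characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
  L <- nchar(bases)
  if (!is.null(track)) {
    track <- as.numeric(track)
    if (length(track) != L)
      stop("track for '", id, "' has length ", length(track),
           " but sequence has length ", L)
    if (anyNA(track)) stop("track for '", id, "' contains NA")
  }
  structure(list(id = id, bases = bases, length = L, track = track),
            class = "candidate_seq")
}

#' @export
print.candidate_seq <- function(x, ...) {
  cat("<candidate_seq>", x$id, "-", x$length, "nt,",
      if (is.null(x$track)) "no track" else "with track", "\n")
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' Bases are normalized (uppercased, `T` to `U`); record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A list of [candidate_seq] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  if (any(Biostrings::width(set) == 0L))
    stop("empty record(s) in ", path, ": ",
         paste(ids[Biostrings::width(set) == 0L], collapse = ", "))
  seqs <- unname(as.character(set))
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) out[[i]] <- candidate_seq(ids[i], seqs[i])
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs List of [candidate_seq] objects.
#' @param path Output path.
#' @param width Line width for wrapping; default 70.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, open = "wb") # binary mode: byte-identical across platforms
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$id), con, sep = "\n")
    starts <- seq(1L, s$length, by = width)
    writeLines(substring(s$bases, starts, pmin(starts + width - 1L, s$length)),
               con, sep = "\n")
  }
  invisible(path)
}

#' Construct a position weight matrix (PWM)
#'
#' Rows are motif positions, columns the RNA alphabet `A`, `C`, `G`, `U`;
#' each row is renormalized to sum to one at construction.
#'
#' @param freq Numeric matrix, `k` rows by 4 columns of non-negative
#'   frequencies; a `T` column name is accepted and relabeled `U`.
#' @param id PWM identifier.
#' @param rbp_name Name of the RBP the PWM belongs to; defaults to `id`.
#' @return An object of class `rbp_pwm` with elements `id`, `rbp_name`,
#'   `k`, `freq`.
#' @export
pwm <- function(freq, id, rbp_name = id) {
  freq <- as.matrix(freq)
  if (nrow(freq) < 1L) stop("PWM must have at least one position (k >= 1)")
  if (ncol(freq) != 4L) stop("PWM must have exactly 4 nucleotide columns")
  if (!is.null(colnames(freq))) {
    cn <- toupper(colnames(freq))
    cn[cn == "T"] <- "U"
    if (!setequal(cn, c("A", "C", "G", "U")))
      stop("PWM columns must be A, C, G, U (or T)")
    freq <- freq[, match(c("A", "C", "G", "U"), cn), drop = FALSE]
  }
  colnames(freq) <- c("A", "C", "G", "U")
  rownames(freq) <- NULL
  storage.mode(freq) <- "double"
  if (anyNA(freq) || any(freq < 0)) stop("PWM entries must be non-negative numbers")
  rs <- rowSums(freq)
  if (any(rs <= 0)) stop("PWM row(s) sum to zero: ", paste(which(rs <= 0), collapse = ", "))
  freq <- freq / rs
  structure(list(id = as.character(id), rbp_name = as.character(rbp_name),
                 k = nrow(freq), freq = freq),
            class = "rbp_pwm")
}

#' @export
print.rbp_pwm <- function(x, ...) {
  cat("<rbp_pwm>", x$id, "(", x$rbp_name, ") k =", x$k, "\n")
  print(round(x$freq, 3))
  invisible(x)
}

#' Read a PWM from a cisBP-RNA style tab-separated table
#'
#' Expects a header with a position column and columns `A`, `C`, `G`,
#' `U` (or `T`); one row per motif position. Rows are renormalized to sum
#' to one.
#'
#' @param path Path to the table.
#' @param id PWM identifier; defaults to the file name without extension.
#' @param rbp_name RBP name; defaults to `id`.
#' @return An [pwm] object.
#' @export
read_pwm_cisbp <- function(path, id = NULL, rbp_name = NULL) {
  if (!file.exists(path)) stop("PWM file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("PWM file has no positions (k = 0): ", path)
  cn <- toupper(names(tab))
  cn[cn == "T"] <- "U"
  need <- c("A", "C", "G", "U")
  if (!all(need %in% cn))
    stop("PWM file is missing nucleotide column(s): ",
         paste(setdiff(need, cn), collapse = ", "))
  freq <- as.matrix(tab[, match(need, cn), drop = FALSE])
  if (!is.numeric(freq)) stop("non-numeric cell in PWM file: ", path)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  if (is.null(rbp_name)) rbp_name <- id
  colnames(freq) <- need
  pwm(freq, id = id, rbp_name = rbp_name)
}

#' Read the first motif from a MEME-format file (letter-probability matrix)
#'
#' Minimal reader: locates the first `MOTIF` name and its
#' `letter-probability matrix` block; columns are assumed in MEME's
#' `A C G T` order and relabeled to the RNA alphabet.
#'
#' @param path Path to a MEME motif file.
#' @return An [pwm] object.
#' @export
read_pwm_meme <- function(path) {
  if (!file.exists(path)) stop("MEME file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  mline <- grep("^MOTIF\\s+", lines)
  if (length(mline) == 0L) stop("no MOTIF line in MEME file: ", path)
  name <- strsplit(trimws(lines[mline[1L]]), "\\s+")[[1L]][2L]
  lp <- grep("^letter-probability matrix", lines)
  lp <- lp[lp > mline[1L]]
  if (length(lp) == 0L) stop("no letter-probability matrix block in: ", path)
  rows <- list()
  i <- lp[1L] + 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!grepl("^[-0-9.eE+ \t]+$", ln) || !nzchar(ln)) break
    vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1L]]))
    if (length(vals) != 4L || anyNA(vals)) break
    rows[[length(rows) + 1L]] <- vals
    i <- i + 1L
  }
  if (length(rows) == 0L) stop("empty letter-probability matrix in: ", path)
  freq <- do.call(rbind, rows)
  colnames(freq) <- c("A", "C", "G", "U") # MEME order A C G T, T == U here
  pwm(freq, id = name, rbp_name = name)
}

#' Write a PWM as a cisBP-RNA style table
#'
#' @param x An [pwm] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm_cisbp <- function(x, path) {
  stopifnot(inherits(x, "rbp_pwm"))
  df <- data.frame(Pos = seq_len(x$k), x$freq, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Attach conservation tracks from a TSV file
#'
#' The file has columns `seq_id`, `pos` (1-based), `score`. Positions not
#' listed default to 0; every sequence receives a track (all-zero if the
#' file has no rows for it). Rows naming an unknown sequence are skipped
#' with a warning; positions outside the sequence are an error.
#'
#' @param path Path to the TSV file.
#' @param seqs List of [candidate_seq] objects.
#' @return The list with `track` filled in on every sequence.
#' @export
read_conservation_tsv <- function(path, seqs) {
  if (!file.exists(path)) stop("conservation file not found: ", path)
  ids <- vapply(seqs, function(s) s$id, character(1))
  for (i in seq_along(seqs)) seqs[[i]]$track <- rep(0, seqs[[i]]$length)
  info <- file.info(path)
  tab <- if (info$size == 0) NULL else
    utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(tab) && nrow(tab) > 0L) {
    need <- c("seq_id", "pos", "score")
    if (!all(need %in% names(tab)))
      stop("conservation file must have columns seq_id, pos, score")
    if (!is.numeric(tab$pos) || !is.numeric(tab$score) ||
        anyNA(tab$pos) || anyNA(tab$score))
      stop("malformed row(s) in conservation file: non-numeric pos or score")
    unknown <- setdiff(unique(tab$seq_id), ids)
    if (length(unknown) > 0L) {
      warning("conservation rows for unknown sequence id(s) skipped: ",
              paste(unknown, collapse = ", "))
      tab <- tab[tab$seq_id %in% ids, , drop = FALSE]
    }
    for (i in seq_along(seqs)) {
      rows <- tab[tab$seq_id == seqs[[i]]$id, , drop = FALSE]
      if (nrow(rows) == 0L) next
      if (any(rows$pos < 1 | rows$pos > seqs[[i]]$length))
        stop("conservation position out of range for '", seqs[[i]]$id,
             "' (L = ", seqs[[i]]$length, ")")
      seqs[[i]]$track[rows$pos] <- rows$score
    }
  }
  seqs
}

#' Write conservation tracks to a TSV file
#'
#' Only non-zero positions are written (the reader defaults to 0).
#'
#' @param seqs List of [candidate_seq] objects with tracks.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation_tsv <- function(seqs, path) {
  rows <- list()
  for (s in seqs) {
    if (is.null(s$track)) next
    nz <- which(s$track != 0)
    if (length(nz) == 0L) next
    rows[[length(rows) + 1L]] <-
      data.frame(seq_id = s$id, pos = nz, score = s$track[nz])
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_id = character(), pos = integer(), score = numeric())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Write prediction records to a TSV file
#'
#' Emits a header plus one row per (sequence, PWM, model) in the order of
#' the input records; byte-deterministic for identical inputs.
#'
#' @param records A `data.frame` of prediction records as returned by
#'   [predict_binding()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(records, path) {
  cols <- c("seq_id", "pwm_id", "model_id", "vote_fraction", "binding_call",
            "best_site_start", "best_site_score")
  if (is.null(records) || nrow(records) == 0L)
    records <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  if (!all(cols %in% names(records)))
    stop("records must have columns: ", paste(cols, collapse = ", "))
  records <- records[, cols, drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

.MODEL_FORMAT_VERSION <- "rbpforest-model-1"

#' Save a trained binding model to disk
#'
#' Models are serialized as full-precision JSON text (forest node tables,
#' in-bag counts, training matrix) with metadata (PWM id(s), seed,
#' hyperparameters, standardized flag, folding mode, format version).
#' Round-tripping preserves predictions bit-for-bit.
#'
#' @param model A `binding_model` from [train_specific()] or [train_general()].
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "binding_model"))
  payload <- list(
    format = .MODEL_FORMAT_VERSION,
    model_id = model$model_id,
    kind = model$kind,
    pwm_id = model$pwm_id,
    standardized = model$standardized,
    backend_mode = model$backend_mode,
    n_trees = model$n_trees,
    mtry = model$mtry,
    nodesize = model$nodesize,
    seed = model$seed,
    summary = model$summary,
    feature_names = model$feature_names,
    forest = list(
      trees = lapply(model$forest$trees, function(m) unname(as.matrix(m))),
      inbag = unname(model$forest$inbag),
      oob_pos = model$forest$oob_pos,
      oob_total = model$forest$oob_total
    ),
    train_x = unname(model$train_x),
    train_y = model$train_y,
    train_ids = model$train_ids
  )
  # I(17) significant digits: doubles survive the text round trip exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Load a trained binding model from disk
#'
#' @param path Path written by [save_model()].
#' @return A `binding_model` object.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) stop("corrupted model file: ",
                                               conditionMessage(e)))
  if (is.null(payload$format) || !identical(payload$format, .MODEL_FORMAT_VERSION))
    stop("model format version mismatch: expected '", .MODEL_FORMAT_VERSION,
         "', found '", payload$format %||% "<none>", "'")
  trees <- lapply(payload$forest$trees, function(m) {
    m <- as.matrix(m)
    colnames(m) <- c("feature", "threshold", "left", "right", "pred")
    m
  })
  forest <- list(trees = trees,
                 inbag = as.matrix(payload$forest$inbag),
                 oob_pos = as.numeric(payload$forest$oob_pos),
                 oob_total = as.numeric(payload$forest$oob_total))
  storage.mode(forest$inbag) <- "integer"
  x <- as.matrix(payload$train_x)
  colnames(x) <- payload$feature_names
  structure(list(
    model_id = payload$model_id, kind = payload$kind, pwm_id = payload$pwm_id,
    standardized = isTRUE(payload$standardized),
    backend_mode = payload$backend_mode,
    n_trees = payload$n_trees, mtry = payload$mtry,
    nodesize = payload$nodesize, seed = as.numeric(payload$seed),
    summary = payload$summary, feature_names = payload$feature_names,
    forest = forest, train_x = x, train_y = as.integer(payload$train_y),
    train_ids = payload$train_ids
  ), class = "binding_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
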