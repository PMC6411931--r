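#' Folding backends for the accessibility feature
#'
#' The spatial-accessibility score of a putative binding site is the
#' energetic cost of keeping its core single-stranded:
#' `Gacc = G(constrained) - G(unconstrained)` for a 180-nt segment around
#' the site, where the constrained fold forces a 40-nt core to stay
#' unpaired. Two backends satisfy the same contract (deterministic;
#' constrained energy never below unconstrained):
#'
#' * `fold_backend_internal()` — a self-contained Nussinov-style dynamic
#'   program maximizing nested canonical pairs (AU/GC/GU wobble, minimum
#'   hairpin loop 3, masked positions and `N` never pair); energy is the
#'   negated pair count, an MFE-like toy unit.
#' * `fold_backend_external()` — adapter around a user-configured folding
#'   executable (e.g. an RNAfold-compatible program). The segment and a
#'   constraint string (`.` free, `x` forced unpaired) are passed on stdin;
#'   the ensemble free energy (or MFE, per `mode`) is parsed from stdout.
#'   Failures raise errors; there is no silent fallback.
#'
#' @param exe Path to the external folding executable.
#' @param mode `"ensemble"` (default: parse the ensemble free-energy line)
#'   or `"mfe"` (parse the last `( -x.xx )` energy).
#' @param args Extra command-line arguments for the executable.
#' @return A `fold_backend` object.
#' @name fold_backend
NULL

#' @rdname fold_backend
#' @export
fold_backend_internal <- function() {
  structure(list(name = "internal", mode = "mfe"), class = "fold_backend")
}

#' @rdname fold_backend
#' @export
fold_backend_external <- function(exe, mode = c("ensemble", "mfe"),
                                  args = character()) {
  mode <- match.arg(mode)
  structure(list(name = "external", mode = mode, exe = exe, args = args),
            class = "fold_backend")
}

#' @export
print.fold_backend <- function(x, ...) {
  cat("<fold_backend>", x$name, "mode =", x$mode, "\n")
  invisible(x)
}

#' Free energy of a (possibly constrained) segment
#'
#' @param backend A [fold_backend] object.
#' @param segment RNA string over `A`, `C`, `G`, `U`, `N`.
#' @param unpaired_mask Logical vector, same length as `segment`; `TRUE`
#'   positions are forbidden to pair. Defaults to all-`FALSE`
#'   (unconstrained).
#' @return Free energy (internal backend: minus the maximum number of
#'   nested pairs; external backend: the program's reported energy).
#' @export
fold_energy <- function(backend, segment, unpaired_mask = NULL) {
  stopifnot(inherits(backend, "fold_backend"))
  n <- nchar(segment)
  if (is.null(unpaired_mask)) unpaired_mask <- rep(FALSE, n)
  if (length(unpaired_mask) != n)
    stop("unpaired_mask length (", length(unpaired_mask),
         ") must equal segment length (", n, ")")
  if (backend$name == "internal") {
    -as.numeric(.nussinov_pairs_cpp(segment, unpaired_mask))
  } else {
    fold_external(segment, unpaired_mask, backend)
  }
}

# Invoke the configured external folder; parse its reported energy.
fold_external <- function(segment, unpaired_mask, backend) {
  exe <- backend$exe
  if (is.null(exe) || !nzchar(Sys.which(exe)) && !file.exists(exe))
    stop("external folding executable not found: ", exe %||% "<unset>")
  constraint <- paste(ifelse(unpaired_mask, "x", "."), collapse = "")
  input <- c(segment, constraint)
  out <- suppressWarnings(
    system2(exe, args = backend$args, input = input,
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L)
    stop("external folder exited with status ", status, ": ",
         paste(out, collapse = " | "))
  parse_fold_output(out, backend$mode)
}

parse_fold_output <- function(lines, mode) {
  if (mode == "ensemble") {
    hit <- grep("free energy of ensemble", lines, value = TRUE)
    if (length(hit) == 0L)
      stop("could not parse ensemble free energy from folder output: ",
           paste(lines, collapse = " | "))
    m <- regmatches(hit[1L],
                    regexpr("-?[0-9]+\\.?[0-9]*(?=\\s*kcal)", hit[1L], perl = TRUE))
    if (length(m) == 0L)
      stop("unparsable ensemble energy line: ", hit[1L])
    as.numeric(m)
  } else {
    hit <- grep("\\(\\s*-?[0-9]+\\.?[0-9]*\\s*\\)\\s*$", lines, value = TRUE)
    if (length(hit) == 0L)
      stop("could not parse MFE from folder output: ",
           paste(lines, collapse = " | "))
    last <- hit[length(hit)]
    m <- regmatches(last, regexpr("-?[0-9]+\\.?[0-9]*(?=\\s*\\)\\s*$)",
                                  last, perl = TRUE))
    as.numeric(m)
  }
}

# Geometry of the accessibility segment: the site extent is taken as 10 nt
# from the match start (independent of motif length k); the core adds 15-nt
# immediate flanks (40 nt forced unpaired) and the segment adds 70-nt outer
# flanks (180 nt folded). Intervals are clamped to the sequence.
.SITE_EXTENT <- 10L
.CORE_FLANK <- 15L
.OUTER_FLANK <- 70L

#' Extract the folding segment and unpaired-core mask around a site
#'
#' For an interior site the segment is 180 nt
#' (site 10 + 2x15 immediate + 2x70 outer flanks) and the core forced to
#' stay unpaired is 40 nt (site + immediate flanks); both are clamped at
#' sequence boundaries.
#'
#' @param seq A [candidate_seq].
#' @param site One putative site (a row of [select_top_sites()] output).
#' @return A list with `segment` (string), `core_mask` (logical, relative
#'   to the segment), `seg_start` (0-based offset of the segment in the
#'   sequence).
#' @export
extract_segment <- function(seq, site) {
  stopifnot(inherits(seq, "candidate_seq"))
  if (isTRUE(site$padded)) stop("cannot extract a segment for a padded site")
  start <- as.integer(site$start) # 0-based
  L <- seq$length
  core_lo <- max(0L, start - .CORE_FLANK)
  core_hi <- min(L, start + .SITE_EXTENT + .CORE_FLANK)
  seg_lo <- max(0L, start - .CORE_FLANK - .OUTER_FLANK)
  seg_hi <- min(L, start + .SITE_EXTENT + .CORE_FLANK + .OUTER_FLANK)
  segment <- substr(seq$bases, seg_lo + 1L, seg_hi)
  mask <- rep(FALSE, seg_hi - seg_lo)
  mask[(core_lo - seg_lo + 1L):(core_hi - seg_lo)] <- TRUE
  list(segment = segment, core_mask = mask, seg_start = seg_lo)
}

#' Accessibility score (Gacc) of a putative site
#'
#' `Gacc = G(segment, core forced unpaired) - G(segment, unconstrained)`;
#' non-negative up to backend numerical noise because the constrained
#' structure space is a subset of the unconstrained one. Padded sites
#' score 0.
#'
#' @param seq A [candidate_seq].
#' @param site One putative site.
#' @param backend A [fold_backend]; default internal.
#' @return Non-negative accessibility score.
#' @export
accessibility_score <- function(seq, site, backend = fold_backend_internal()) {
  if (isTRUE(site$padded)) return(0)
  seg <- extract_segment(seq, site)
  g_uncon <- fold_energy(backend, seg$segment)
  g_con <- fold_energy(backend, seg$segment, seg$core_mask)
  gacc <- g_con - g_uncon
  if (gacc < -1e-6)
    stop("backend violated the constraint contract: Gacc = ", gacc)
  max(gacc, 0)
}
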