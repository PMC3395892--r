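# Feature encoding for pentamer pairs: global channels describing the whole
# wild-type protein, local sliding-window channels centered on the position
# of change, and wild-type/mutant difference channels encoded as
# (absolute difference, sign bit).

ALLOWED_WINDOWS <- c(1L, 5L, 9L, 13L, 17L, 21L)

# Per-position width of every known track channel. Three-state predictions
# (secondary structure helix/strand/other; accessibility buried/intermediate/
# exposed) carry 3 values per position, two-state predictions 2 mutually
# exclusive values, scalar tracks 1.
track_widths <- function() {
  w <- c(
    ss = 3L, acc = 3L, ss_raw = 3L, acc_raw = 3L,
    disorder = 2L, dna = 2L, isis = 2L,
    flexibility = 1L, info = 1L, psic = 1L, pfam_fit = 1L,
    disorder_short = 1L, disorder_long = 1L,
    pssm = 20L, freq = 20L
  )
  props <- setNames(rep(1L, 6L), paste0("prop_", names(propensity_scales())))
  c(w, props)
}

#' Build a feature descriptor
#'
#' A descriptor names one encodable channel: a `global` protein-level
#' summary, a `local` track windowed around the position of change, or a
#' `difference` channel comparing wild type and mutant. Width is derived
#' from the pinned per-channel encoding.
#'
#' @param name Descriptor identifier (unique within a descriptor list).
#' @param kind One of `"global"`, `"local"`, `"difference"`.
#' @param track Track name for local / track-based difference descriptors.
#' @param window Odd window length in `{1, 5, 9, 13, 17, 21}` (local only).
#' @param diff_kind For differences: `"track"` (per-channel value at the
#'   center of each chain), `"substitution"` (amino-acid-indexed matrix of
#'   the wild-type chain, wild-type vs mutant column), or `"scale"`
#'   (propensity scale lookup of the two center residues).
#' @param width Total numeric values contributed (computed by the builders).
#' @return A `feature_descriptor` object.
#' @export
feature_descriptor <- function(name, kind, track = NULL, window = NULL,
                               diff_kind = NULL, width) {
  kind <- match.arg(kind, c("global", "local", "difference"))
  if (kind == "local") {
    if (is.null(window) || !(window %in% ALLOWED_WINDOWS))
      stop("local descriptors need a window in {", paste(ALLOWED_WINDOWS, collapse = ","), "}")
  } else if (!is.null(window)) {
    stop("window only applies to local descriptors")
  }
  structure(list(name = name, kind = kind, track = track, window = window,
                 diff_kind = diff_kind, width = as.integer(width)),
            class = "feature_descriptor")
}

#' @rdname feature_descriptor
#' @param which Which global summary: length bins (4 values), amino acid
#'   composition (20), predicted secondary-structure content (3) or
#'   predicted accessibility content (3).
#' @export
global_descriptor <- function(which = c("length_bins", "composition",
                                        "ss_content", "acc_content")) {
  which <- match.arg(which)
  w <- switch(which, length_bins = 4L, composition = 20L,
              ss_content = 3L, acc_content = 3L)
  tr <- switch(which, ss_content = "ss", acc_content = "acc", NULL)
  feature_descriptor(which, "global", track = tr, width = w)
}

#' @rdname feature_descriptor
#' @export
local_descriptor <- function(track, window) {
  tw <- track_widths()
  if (!track %in% names(tw)) stop("unknown track: ", track)
  window <- as.integer(window)
  feature_descriptor(paste0(track, ":w", window), "local", track = track,
                     window = window, width = tw[[track]] * window)
}

#' @rdname feature_descriptor
#' @param property Difference property: a propensity scale name (`mass`,
#'   `volume`, `hydrophobicity`, `cbeta_branching`, `helix_breaker`,
#'   `charge`), a conservation score (`psic`, `pssm`, `freq`), a disorder
#'   score (`disorder_short`, `disorder_long`), or a single-sequence-mode
#'   prediction (`ss_raw`, `acc_raw`).
#' @export
diff_descriptor <- function(property) {
  scales <- names(propensity_scales())
  tw <- track_widths()
  if (property %in% scales) {
    feature_descriptor(paste0(property, "_diff"), "difference",
                       track = property, diff_kind = "scale", width = 2L)
  } else if (property %in% c("pssm", "freq")) {
    feature_descriptor(paste0(property, "_diff"), "difference",
                       track = property, diff_kind = "substitution", width = 2L)
  } else if (property %in% c("psic", "disorder_short", "disorder_long",
                             "ss_raw", "acc_raw")) {
    feature_descriptor(paste0(property, "_diff"), "difference",
                       track = property, diff_kind = "track",
                       width = 2L * tw[[property]])
  } else {
    stop("unknown difference property: ", property)
  }
}

#' @export
print.feature_descriptor <- function(x, ...) {
  cat(sprintf("<feature_descriptor> %s (%s, width %d)\n", x$name, x$kind, x$width))
  invisible(x)
}

#' Total width of a descriptor list
#'
#' @param descriptors List of `feature_descriptor` objects.
#' @return Integer: sum of the descriptor widths.
#' @export
feature_width <- function(descriptors) {
  sum(vapply(descriptors, function(d) d$width, integer(1)))
}

#' The nine forward-selected descriptors
#'
#' The descriptor set retained by the forward selection on the structural
#' pentamer data, in acceptance order: PSIC difference, predicted secondary
#' structure (w = 17), per-position alignment information (w = 21), predicted
#' flexibility (w = 21), PSSM difference, single-sequence secondary-structure
#' difference, Pfam fit (w = 13), interaction hotspots (w = 13) and residue
#' volume (w = 5). Under the pinned per-channel widths these contribute 147
#' numeric values in total.
#'
#' @return List of nine `feature_descriptor` objects.
#' @export
selected_descriptors <- function() {
  list(
    diff_descriptor("psic"),
    local_descriptor("ss", 17),
    local_descriptor("info", 21),
    local_descriptor("flexibility", 21),
    diff_descriptor("pssm"),
    diff_descriptor("ss_raw"),
    local_descriptor("pfam_fit", 13),
    local_descriptor("isis", 13),
    local_descriptor("prop_volume", 5)
  )
}

#' Full candidate descriptor set for forward selection
#'
#' Every global and difference descriptor plus every (local track, window)
#' combination over the allowed window lengths.
#'
#' @param tracks Character vector of local track names to include; defaults
#'   to every known track.
#' @return List of `feature_descriptor` objects, lexicographically ordered
#'   by name.
#' @export
default_descriptors <- function(tracks = names(track_widths())) {
  globals <- lapply(c("length_bins", "composition", "ss_content", "acc_content"),
                    global_descriptor)
  diffs <- lapply(c(names(propensity_scales()), "psic", "pssm", "freq",
                    "disorder_short", "disorder_long", "ss_raw", "acc_raw"),
                  diff_descriptor)
  locals <- list()
  for (tr in tracks) for (w in ALLOWED_WINDOWS)
    locals[[length(locals) + 1L]] <- local_descriptor(tr, w)
  all <- c(globals, diffs, locals)
  all[order(vapply(all, function(d) d$name, character(1)))]
}

#' Encode sequence length as four interval bins
#'
#' Bins cover 1-60, 61-120, 121-180 and 181-240 residues. The bin containing
#' the length is set to 0.5, bins below to 1, bins above to 0; lengths over
#' 240 set all four bins to 1.
#'
#' @param length Sequence length in residues (>= 1).
#' @return Numeric vector of length 4.
#' @export
encode_length_bins <- function(length) {
  if (length < 1) stop("length must be >= 1")
  upper <- c(60, 120, 180, 240)
  out <- as.numeric(length > upper)          # bins fully below the length
  bin <- which(length <= upper)
  if (length(bin) > 0L) out[bin[1L]] <- 0.5  # containing bin
  out
}

#' Amino acid composition
#'
#' Relative frequencies of the 20 standard amino acids in fixed alphabetical
#' one-letter order; 'X' positions are excluded from both numerator and
#' denominator.
#'
#' @param sequence Amino acid string.
#' @return Numeric vector of length 20 summing to 1 (all zeros if no
#'   standard residue is present).
#' @export
encode_composition <- function(sequence) {
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  ch <- strsplit(sequence, "")[[1]]
  ch <- ch[ch %in% AA_ALPHABET]
  counts <- table(factor(ch, levels = AA_ALPHABET))
  n <- sum(counts)
  if (n == 0L) return(setNames(rep(0, 20L), AA_ALPHABET))
  setNames(as.numeric(counts) / n, AA_ALPHABET)
}

#' Per-residue propensity track
#'
#' @param sequence Amino acid string.
#' @param scale A propensity scale name or a named numeric vector over the
#'   20 amino acids with values in `[0, 1]`.
#' @return n-by-1 numeric matrix; 'X' positions get 0.
#' @export
propensity_track <- function(sequence, scale) {
  if (is.character(scale) && length(scale) == 1L)
    scale <- propensity_scales()[[scale]]
  ch <- strsplit(sequence, "")[[1]]
  v <- unname(scale[ch])
  v[is.na(v)] <- 0
  matrix(v, ncol = 1L)
}

#' Window a track around a center position
#'
#' Concatenates the per-position tuples for positions
#' `center - (w-1)/2 ... center + (w-1)/2` in order; positions outside the
#' chain are zero-padded.
#'
#' @param track n-by-width numeric matrix.
#' @param center 1-based center residue index.
#' @param window Window length in `{1, 5, 9, 13, 17, 21}`.
#' @return Numeric vector of length `width * window`.
#' @export
encode_window <- function(track, center, window) {
  track <- as.matrix(track)
  if (!(window %in% ALLOWED_WINDOWS))
    stop("window must be one of ", paste(ALLOWED_WINDOWS, collapse = ", "))
  n <- nrow(track); w <- ncol(track)
  stopifnot(center >= 1L, center <= n)
  half <- (window - 1L) %/% 2L
  out <- matrix(0, window, w)
  pos <- (center - half):(center + half)
  inside <- pos >= 1L & pos <= n
  out[inside, ] <- track[pos[inside], , drop = FALSE]
  as.numeric(t(out))
}

#' Difference encoding of a wild-type/mutant score pair
#'
#' The difference `mut - wt` is represented by its absolute value and a sign
#' bit (1 for non-negative, 0 for negative). Inputs are expected on a
#' normalized `[0, 1]` scale so the magnitude stays in `[0, 1]`.
#'
#' @param wt,mut Finite scores (vectorized over channels).
#' @return Numeric vector `(|delta_1|, sign_1, |delta_2|, sign_2, ...)`.
#' @export
encode_difference <- function(wt, mut) {
  stopifnot(length(wt) == length(mut), all(is.finite(wt)), all(is.finite(mut)))
  delta <- mut - wt
  as.numeric(rbind(abs(delta), as.numeric(delta >= 0)))
}

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the `-Q`-style position-specific scoring matrix and returns three
#' per-position tracks: the 20 log-odds scores mapped affinely from
#' `[-16, 16]` to `[0, 1]` (clipped), the 20 relative frequencies in
#' `[0, 1]`, and the per-position information content capped at 2 bits and
#' scaled to `[0, 1]`. Columns are reordered to the fixed alphabetical
#' amino acid order.
#'
#' @param text PSSM file content as a character scalar.
#' @param sequence Optional chain sequence; a row-count mismatch is an error.
#' @return List with matrices `pssm` (n x 20), `freq` (n x 20), `info`
#'   (n x 1) and the string `sequence` read from the file.
#' @export
parse_pssm <- function(text, sequence = NULL) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  toks <- lapply(lines, function(l) strsplit(trimws(l), "[[:space:]]+")[[1]])
  hdr <- which(vapply(toks, function(t)
    length(t) >= 20L && all(t[1:20] %in% AA_ALPHABET), logical(1)))[1]
  if (is.na(hdr)) stop("no PSSM header line with 20 amino acid columns found")
  aa_order <- toks[[hdr]][1:20]
  rows <- toks[(hdr + 1L):length(toks)]
  rows <- rows[vapply(rows, function(t)
    length(t) >= 42L && grepl("^[0-9]+$", t[1]), logical(1))]
  if (length(rows) == 0L) stop("no PSSM data rows found")
  n <- length(rows)
  scores <- matrix(NA_real_, n, 20L, dimnames = list(NULL, aa_order))
  freqs <- matrix(NA_real_, n, 20L, dimnames = list(NULL, aa_order))
  info <- numeric(n)
  seq_chr <- character(n)
  for (i in seq_len(n)) {
    t <- rows[[i]]
    seq_chr[i] <- t[2]
    scores[i, ] <- as.numeric(t[3:22])
    freqs[i, ] <- as.numeric(t[23:42])
    info[i] <- if (length(t) >= 43L) as.numeric(t[43]) else 0
  }
  if (anyNA(scores) || anyNA(freqs) || anyNA(info))
    stop("malformed PSSM data row")
  if (!is.null(sequence) && nchar(sequence) != n)
    stop("PSSM has ", n, " rows but sequence has ", nchar(sequence), " residues")
  ord <- match(AA_ALPHABET, aa_order)
  pssm01 <- (scores[, ord, drop = FALSE] + 16) / 32
  pssm01[pssm01 < 0] <- 0
  pssm01[pssm01 > 1] <- 1
  colnames(pssm01) <- AA_ALPHABET
  freq01 <- freqs[, ord, drop = FALSE] / 100
  colnames(freq01) <- AA_ALPHABET
  list(pssm = pssm01, freq = freq01,
       info = matrix(pmin(info, 2) / 2, ncol = 1L),
       sequence = paste(seq_chr, collapse = ""))
}

#' Write a PSSM in PSI-BLAST ASCII layout
#'
#' Counterpart of [parse_pssm()] for building fixtures; takes raw (unscaled)
#' integer scores, percent frequencies and information content.
#'
#' @param sequence Amino acid string (row letters).
#' @param scores n x 20 integer log-odds matrix, alphabetical column order.
#' @param freqs n x 20 percent frequency matrix.
#' @param info Length-n information content vector (bits).
#' @return PSSM file content as a character scalar.
#' @export
write_pssm <- function(sequence, scores, freqs, info) {
  n <- nchar(sequence)
  stopifnot(nrow(scores) == n, nrow(freqs) == n, length(info) == n)
  ch <- strsplit(sequence, "")[[1]]
  out <- c("", "Last position-specific scoring matrix computed",
           paste0("            ", paste(sprintf("%3s", AA_ALPHABET), collapse = ""),
                  " ", paste(sprintf("%4s", AA_ALPHABET), collapse = "")))
  for (i in seq_len(n)) {
    out <- c(out, paste0(
      sprintf("%5d %s ", i, ch[i]),
      paste(sprintf("%3d", round(scores[i, ])), collapse = ""), " ",
      paste(sprintf("%4d", round(freqs[i, ])), collapse = ""),
      sprintf("  %.2f %.2f", info[i], 1.0)
    ))
  }
  paste(c(out, ""), collapse = "\n")
}

# Fetch a track matrix for a chain, deriving propensity tracks from the
# sequence on demand. Returns NULL when unavailable.
get_track <- function(tracks, chains, chain_ref, name) {
  tr <- tracks[[chain_ref]][[name]]
  if (!is.null(tr)) return(as.matrix(tr))
  if (startsWith(name, "prop_")) {
    ch <- chains[[chain_ref]]
    if (!is.null(ch))
      return(propensity_track(ch$sequence, sub("^prop_", "", name)))
  }
  NULL
}

scale_value <- function(scale_name, aa) {
  sc <- propensity_scales()[[scale_name]]
  v <- unname(sc[aa])
  if (is.na(v)) 0 else v
}

#' Assemble the feature vector for one pentamer pair
#'
#' Concatenates the configured descriptors in order. Global and local
#' channels are computed on the wild-type chain (window centered at the
#' wild-type fragment's central residue); difference channels compare the
#' wild-type and mutant center values. A missing optional track contributes
#' zeros with a warning, or an error under `on_missing = "error"`.
#'
#' @param pair One row of a labeled pair data.frame (with `wt_is_a` set).
#' @param descriptors List of `feature_descriptor` objects.
#' @param tracks Named list keyed by chain `source_id`; each element is a
#'   named list of n-by-width track matrices.
#' @param chains Named list of `protein_chain` objects keyed by `source_id`.
#' @param on_missing `"zero"` (default) or `"error"`.
#' @return List with `values` (numeric vector) and `layout` (data.frame of
#'   descriptor name, offset, width).
#' @export
assemble_vector <- function(pair, descriptors, tracks, chains,
                            on_missing = c("zero", "error")) {
  on_missing <- match.arg(on_missing)
  if (length(descriptors) == 0L) {
    return(list(values = numeric(0),
                layout = data.frame(name = character(0), offset = integer(0),
                                    width = integer(0), stringsAsFactors = FALSE)))
  }
  if (is.na(pair$wt_is_a)) stop("pair roles not designated; run designate_roles()")
  if (pair$wt_is_a) {
    wt_chain <- pair$chain_a; wt_start <- pair$start_a; wt_aa <- pair$center_a
    mu_chain <- pair$chain_b; mu_start <- pair$start_b; mu_aa <- pair$center_b
  } else {
    wt_chain <- pair$chain_b; wt_start <- pair$start_b; wt_aa <- pair$center_b
    mu_chain <- pair$chain_a; mu_start <- pair$start_a; mu_aa <- pair$center_a
  }
  wt_center <- wt_start + 2L
  mu_center <- mu_start + 2L
  wt_seq <- chains[[wt_chain]]$sequence

  missing_track <- function(d) {
    if (on_missing == "error") stop("track '", d$track, "' unavailable for ",
                                    wt_chain, " (descriptor ", d$name, ")")
    warning("track '", d$track, "' unavailable; descriptor ", d$name,
            " filled with zeros", call. = FALSE)
    rep(0, d$width)
  }

  parts <- vector("list", length(descriptors))
  for (k in seq_along(descriptors)) {
    d <- descriptors[[k]]
    vals <- switch(d$kind,
      global = {
        if (d$name == "length_bins") encode_length_bins(nchar(wt_seq))
        else if (d$name == "composition") unname(encode_composition(wt_seq))
        else {
          tr <- get_track(tracks, chains, wt_chain, d$track)
          if (is.null(tr)) missing_track(d)
          else {
            states <- max.col(tr, ties.method = "first")
            as.numeric(tabulate(states, nbins = ncol(tr))) / nrow(tr)
          }
        }
      },
      local = {
        tr <- get_track(tracks, chains, wt_chain, d$track)
        if (is.null(tr)) missing_track(d)
        else encode_window(tr, wt_center, d$window)
      },
      difference = {
        if (d$diff_kind == "scale") {
          encode_difference(scale_value(d$track, wt_aa), scale_value(d$track, mu_aa))
        } else if (d$diff_kind == "substitution") {
          tr <- get_track(tracks, chains, wt_chain, d$track)
          if (is.null(tr)) missing_track(d)
          else encode_difference(tr[wt_center, wt_aa], tr[wt_center, mu_aa])
        } else {
          trw <- get_track(tracks, chains, wt_chain, d$track)
          trm <- get_track(tracks, chains, mu_chain, d$track)
          if (is.null(trw) || is.null(trm)) missing_track(d)
          else encode_difference(trw[wt_center, ], trm[mu_center, ])
        }
      }
    )
    if (length(vals) != d$width)
      stop("descriptor ", d$name, " produced ", length(vals),
           " values, expected ", d$width)
    parts[[k]] <- vals
  }
  widths <- vapply(descriptors, function(d) d$width, integer(1))
  layout <- data.frame(
    name = vapply(descriptors, function(d) d$name, character(1)),
    offset = cumsum(c(0L, widths[-length(widths)])),
    width = widths,
    stringsAsFactors = FALSE
  )
  list(values = unlist(parts, use.names = FALSE), layout = layout)
}

#' Assemble the feature matrix for a pair table
#'
#' @inheritParams assemble_vector
#' @param pairs Labeled pair data.frame with roles designated.
#' @return Numeric matrix (pairs x features) with a `layout` attribute.
#' @export
assemble_matrix <- function(pairs, descriptors, tracks, chains,
                            on_missing = c("zero", "error")) {
  on_missing <- match.arg(on_missing)
  p <- feature_width(descriptors)
  X <- matrix(NA_real_, nrow(pairs), p)
  layout <- NULL
  for (i in seq_len(nrow(pairs))) {
    fv <- assemble_vector(pairs[i, , drop = FALSE], descriptors, tracks,
                          chains, on_missing)
    X[i, ] <- fv$values
    layout <- fv$layout
  }
  attr(X, "layout") <- layout
  X
}
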