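# Chopping chains into pentamers and building cross-set pairs that differ
# only at the central residue.

#' Extract clean pentamers from a chain
#'
#' Every window of five consecutive residues becomes a pentamer unless it
#' (i) spans a chain break, (ii) contains a non-standard residue, or
#' (iii) is missing a C-alpha atom.
#'
#' @param chain A `protein_chain`.
#' @param breaks Integer vector from [detect_chain_breaks()]; `i` in `breaks`
#'   means the bond between residues `i` and `i + 1` is broken.
#' @return A data.frame with columns `chain_ref`, `start` (1-based index of
#'   the first residue), `sequence` (5-letter string) and a list-column `ca`
#'   of 5x3 C-alpha coordinate matrices, ordered by `start`.
#' @export
extract_pentamers <- function(chain, breaks = detect_chain_breaks(chain)) {
  nres <- length(chain$name)
  empty <- data.frame(chain_ref = character(0), start = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  empty$ca <- list()
  if (nres < 5L) return(empty)
  ok_res <- !is.na(chain$one_letter) & !is.na(chain$ca[, 1L])
  starts <- integer(0)
  for (s in seq_len(nres - 4L)) {
    idx <- s:(s + 4L)
    if (!all(ok_res[idx])) next
    if (any(breaks %in% s:(s + 3L))) next
    starts <- c(starts, s)
  }
  if (length(starts) == 0L) return(empty)
  out <- data.frame(
    chain_ref = chain$source_id,
    start = starts,
    sequence = vapply(starts, function(s)
      substr(chain$sequence, s, s + 4L), character(1)),
    stringsAsFactors = FALSE
  )
  out$ca <- lapply(starts, function(s) chain$ca[s:(s + 4L), , drop = FALSE])
  out
}

#' Global pairwise percent sequence identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 10, gap extend 0.5)
#' via Biostrings; identity is 100 x identical aligned positions divided by
#' the full alignment length, gap columns included.
#'
#' @param seq_a,seq_b Non-empty amino acid strings ('X' allowed).
#' @return Percent identity in `[0, 100]`.
#' @export
global_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5, type = "global"
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  100 * sum(pa == ps & pa != "-") / length(pa)
}

#' Pair pentamers across two sets
#'
#' Emits every cross-set pair whose 5-letter sequences agree at the four
#' context positions and differ at the center, and whose source chains share
#' more than `min_identity` percent global sequence identity. Identity is
#' computed once per chain pair and cached. Duplicate
#' (chain_a, start_a, chain_b, start_b) combinations are dropped.
#'
#' @param set_a,set_b Pentamer data.frames from [extract_pentamers()]
#'   (possibly row-bound over chains).
#' @param chains Named list of `protein_chain` objects keyed by `source_id`,
#'   covering every chain referenced by the pentamers.
#' @param min_identity Identity threshold in percent; strict `>` (default 30).
#' @return A pair data.frame: `chain_a`, `start_a`, `seq_a`, `chain_b`,
#'   `start_b`, `seq_b`, `center_a`, `center_b`, `identity`, `wt_is_a`
#'   (`NA` until [designate_roles()]), with list-columns `ca_a`, `ca_b`.
#' @export
pair_pentamers <- function(set_a, set_b, chains, min_identity = 30) {
  empty <- empty_pairs()
  if (nrow(set_a) == 0L || nrow(set_b) == 0L) return(empty)
  ctx <- function(s) paste0(substr(s, 1L, 2L), substr(s, 4L, 5L))
  ctx_a <- ctx(set_a$sequence)
  ctx_b <- ctx(set_b$sequence)
  common <- intersect(ctx_a, ctx_b)
  if (length(common) == 0L) return(empty)
  id_cache <- new.env(parent = emptyenv())
  chain_identity <- function(ca, cb) {
    key <- paste(ca, cb, sep = "\r")
    if (!is.null(id_cache[[key]])) return(id_cache[[key]])
    v <- global_identity(chains[[ca]]$sequence, chains[[cb]]$sequence)
    id_cache[[key]] <- v
    v
  }
  rows <- list()
  seen <- new.env(parent = emptyenv())
  for (cx in common) {
    ia <- which(ctx_a == cx)
    ib <- which(ctx_b == cx)
    for (i in ia) for (j in ib) {
      cen_a <- substr(set_a$sequence[i], 3L, 3L)
      cen_b <- substr(set_b$sequence[j], 3L, 3L)
      if (cen_a == cen_b) next
      key <- paste(set_a$chain_ref[i], set_a$start[i],
                   set_b$chain_ref[j], set_b$start[j], sep = "\r")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      pid <- chain_identity(set_a$chain_ref[i], set_b$chain_ref[j])
      if (!(pid > min_identity)) next
      rows[[length(rows) + 1L]] <- list(
        chain_a = set_a$chain_ref[i], start_a = set_a$start[i],
        seq_a = set_a$sequence[i],
        chain_b = set_b$chain_ref[j], start_b = set_b$start[j],
        seq_b = set_b$sequence[j],
        center_a = cen_a, center_b = cen_b, identity = pid,
        ca_a = set_a$ca[[i]], ca_b = set_b$ca[[j]]
      )
    }
  }
  if (length(rows) == 0L) return(empty)
  pairs_from_rows(rows)
}

empty_pairs <- function() {
  out <- data.frame(
    chain_a = character(0), start_a = integer(0), seq_a = character(0),
    chain_b = character(0), start_b = integer(0), seq_b = character(0),
    center_a = character(0), center_b = character(0),
    identity = numeric(0), wt_is_a = logical(0), stringsAsFactors = FALSE
  )
  out$ca_a <- list()
  out$ca_b <- list()
  out
}

pairs_from_rows <- function(rows) {
  out <- data.frame(
    chain_a = vapply(rows, `[[`, character(1), "chain_a"),
    start_a = vapply(rows, `[[`, numeric(1), "start_a"),
    seq_a = vapply(rows, `[[`, character(1), "seq_a"),
    chain_b = vapply(rows, `[[`, character(1), "chain_b"),
    start_b = vapply(rows, `[[`, numeric(1), "start_b"),
    seq_b = vapply(rows, `[[`, character(1), "seq_b"),
    center_a = vapply(rows, `[[`, character(1), "center_a"),
    center_b = vapply(rows, `[[`, character(1), "center_b"),
    identity = vapply(rows, `[[`, numeric(1), "identity"),
    wt_is_a = NA,
    stringsAsFactors = FALSE
  )
  out$ca_a <- lapply(rows, `[[`, "ca_a")
  out$ca_b <- lapply(rows, `[[`, "ca_b")
  out
}

#' Drop pairs embedded in much larger identical fragments
#'
#' For each pair, the matched region is extended outward (left and right,
#' independently) while the flanking residues of the two source chains are
#' equal. Pairs whose total extension (left + right) exceeds `max_extension`
#' are removed: they sit inside a larger fragment that already fulfils the
#' pairing criteria, so the pentamer is not an isolated local match.
#'
#' @param pairs Pair data.frame from [pair_pentamers()].
#' @param chains Named list of `protein_chain` objects.
#' @param max_extension Maximum tolerated total flank extension in residues
#'   (default 4).
#' @return The filtered pair data.frame.
#' @export
maximal_fragment_filter <- function(pairs, chains, max_extension = 4) {
  if (nrow(pairs) == 0L) return(pairs)
  keep <- vapply(seq_len(nrow(pairs)), function(r) {
    sa <- chains[[pairs$chain_a[r]]]$sequence
    sb <- chains[[pairs$chain_b[r]]]$sequence
    ia <- pairs$start_a[r]; ib <- pairs$start_b[r]
    ext_l <- 0L
    while (ia - ext_l - 1L >= 1L && ib - ext_l - 1L >= 1L &&
           substr(sa, ia - ext_l - 1L, ia - ext_l - 1L) ==
           substr(sb, ib - ext_l - 1L, ib - ext_l - 1L)) {
      ext_l <- ext_l + 1L
    }
    ext_r <- 0L
    la <- nchar(sa); lb <- nchar(sb)
    while (ia + 4L + ext_r + 1L <= la && ib + 4L + ext_r + 1L <= lb &&
           substr(sa, ia + 4L + ext_r + 1L, ia + 4L + ext_r + 1L) ==
           substr(sb, ib + 4L + ext_r + 1L, ib + 4L + ext_r + 1L)) {
      ext_r <- ext_r + 1L
    }
    (ext_l + ext_r) <= max_extension
  }, logical(1))
  pairs[keep, , drop = FALSE]
}

#' Randomly designate wild-type and mutant fragments
#'
#' Seeded uniform coin per pair: `wt_is_a` is `TRUE` when fragment A plays
#' the wild-type role. Deterministic given seed and input order.
#'
#' @param pairs Pair data.frame.
#' @param seed Integer seed.
#' @return `pairs` with `wt_is_a` filled in.
#' @export
designate_roles <- function(pairs, seed) {
  if (nrow(pairs) == 0L) return(pairs)
  pairs$wt_is_a <- with_seed(seed, stats::runif(nrow(pairs)) < 0.5)
  pairs
}

#' Write pairs to TSV (coordinates omitted)
#'
#' @param pairs Pair data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  cols <- c("chain_a", "start_a", "seq_a", "chain_b", "start_b", "seq_b",
            "center_a", "center_b", "identity", "wt_is_a")
  extra <- intersect(c("rmsd", "label"), names(pairs))
  utils::write.table(pairs[, c(cols, extra), drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
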