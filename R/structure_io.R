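# PDB-format coordinate I/O with the residue-level filters needed for
# pentamer extraction: first MODEL only, first altloc per residue/atom,
# non-standard residues kept but flagged ('X' in the sequence).

#' Parse a PDB-format string into protein chains
#'
#' Fixed-column parsing of ATOM records (PDB v3.3 layout). HETATM records,
#' waters and chains without any C-alpha atom (e.g. nucleic acids) are
#' ignored. Only the first MODEL of a multi-model entry is read. For residues
#' with alternative locations, the first-encountered record per atom is
#' retained and the residue is flagged `had_altloc`. Missing backbone atoms
#' yield `NA` coordinates.
#'
#' @param text A character scalar with PDB-format content (ATOM/TER records).
#' @param structure_id Identifier prefixed to chain ids, e.g. a PDB code.
#'
#' @return A list of `protein_chain` objects, in file order. Each has:
#'   `source_id` (structure id + chain id), `name` (three-letter codes),
#'   `one_letter` (one-letter codes, `NA` for non-standard residues),
#'   `seq_id` (author residue number + insertion code), `had_altloc`,
#'   `ca`/`n`/`c` (length-n-by-3 coordinate matrices in Angstrom, `NA` rows
#'   for missing atoms) and `sequence` (one-letter string, 'X' at
#'   non-standard positions). Residues follow record order.
#' @export
parse_pdb <- function(text, structure_id = "STRUCT") {
  stopifnot(is.character(text), length(text) == 1L)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0L) return(list())

  rec <- substr(lines, 1L, 6L)
  # first model only
  endmdl <- which(rec == "ENDMDL")
  if (length(endmdl) > 0L) lines <- lines[seq_len(endmdl[1] - 1L)]
  rec <- substr(lines, 1L, 6L)
  atom_idx <- which(rec == "ATOM  ")
  if (length(atom_idx) == 0L) return(list())

  al <- lines[atom_idx]
  short <- nchar(al) < 54L
  if (any(short)) {
    stop("malformed ATOM record (line ", atom_idx[which(short)[1]],
         "): fewer than 54 columns")
  }
  atom_name <- trimws(substr(al, 13L, 16L))
  altloc    <- substr(al, 17L, 17L)
  res_name  <- trimws(substr(al, 18L, 20L))
  chain_id  <- substr(al, 22L, 22L)
  res_seq   <- trimws(substr(al, 23L, 26L))
  icode     <- trimws(substr(al, 27L, 27L))
  x <- suppressWarnings(as.numeric(substr(al, 31L, 38L)))
  y <- suppressWarnings(as.numeric(substr(al, 39L, 46L)))
  z <- suppressWarnings(as.numeric(substr(al, 47L, 54L)))
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0L) {
    stop("malformed ATOM record (line ", atom_idx[bad[1]],
         "): non-numeric coordinate field")
  }

  chains <- list()
  for (cid in unique(chain_id)) {
    sel <- chain_id == cid
    res_key <- paste0(res_seq[sel], "|", icode[sel])
    keys <- unique(res_key)  # first-encounter order
    nres <- length(keys)
    ca <- matrix(NA_real_, nres, 3L)
    nn <- matrix(NA_real_, nres, 3L)
    cc <- matrix(NA_real_, nres, 3L)
    nm <- character(nres)
    sid <- character(nres)
    alt <- logical(nres)
    an  <- atom_name[sel]
    alc <- altloc[sel]
    rn  <- res_name[sel]
    rs  <- res_seq[sel]
    ic  <- icode[sel]
    xs <- x[sel]; ys <- y[sel]; zs <- z[sel]
    ridx <- match(res_key, keys)
    for (j in seq_along(ridx)) {
      i <- ridx[j]
      if (nm[i] == "") {
        nm[i] <- rn[j]
        sid[i] <- paste0(rs[j], ic[j])
      }
      if (alc[j] != " " && alc[j] != "") alt[i] <- TRUE
      tgt <- switch(an[j], CA = "ca", N = "n", C = "c", NA_character_)
      if (!is.na(tgt)) {
        m <- switch(tgt, ca = ca, n = nn, c = cc)
        if (is.na(m[i, 1L])) {  # first record per residue/atom wins
          m[i, ] <- c(xs[j], ys[j], zs[j])
          if (tgt == "ca") ca <- m else if (tgt == "n") nn <- m else cc <- m
        }
      }
    }
    if (all(is.na(ca[, 1L]))) next  # not a protein chain
    one <- unname(AA_3TO1[nm])
    seq_chr <- ifelse(is.na(one), "X", one)
    chains[[length(chains) + 1L]] <- structure(
      list(
        source_id = paste0(structure_id, "_", cid),
        chain_id = cid,
        name = nm,
        one_letter = one,
        seq_id = sid,
        had_altloc = alt,
        ca = ca, n = nn, c = cc,
        sequence = paste(seq_chr, collapse = "")
      ),
      class = "protein_chain"
    )
  }
  chains
}

#' @export
print.protein_chain <- function(x, ...) {
  cat("<protein_chain> ", x$source_id, ": ", length(x$name), " residues, ",
      sum(is.na(x$one_letter)), " non-standard\n", sep = "")
  invisible(x)
}

#' @export
length.protein_chain <- function(x) length(x$name)

#' Write a chain back to PDB format
#'
#' Emits N/CA/C ATOM records (present atoms only) in residue order, suitable
#' for round-tripping through [parse_pdb()].
#'
#' @param chain A `protein_chain`.
#' @return A character scalar of PDB-format text.
#' @export
write_pdb <- function(chain) {
  stopifnot(inherits(chain, "protein_chain"))
  out <- character(0)
  serial <- 0L
  for (i in seq_along(chain$name)) {
    for (atom in c("N", "CA", "C")) {
      m <- switch(atom, N = chain$n, CA = chain$ca, C = chain$c)
      if (is.na(m[i, 1L])) next
      serial <- serial + 1L
      aname <- sprintf(" %-3s", atom)  # right-padded, col 13-16 convention
      out <- c(out, sprintf(
        "ATOM  %5d %s %3s %1s%4s    %8.3f%8.3f%8.3f  1.00  0.00",
        serial, aname, chain$name[i], chain$chain_id,
        substr(chain$seq_id[i], 1L, 4L), m[i, 1L], m[i, 2L], m[i, 3L]
      ))
    }
  }
  paste(c(out, "TER", ""), collapse = "\n")
}

#' Detect chain breaks from peptide bond geometry
#'
#' A peptide bond between residue `i` and `i + 1` counts as broken when the
#' C(i)-N(i+1) distance exceeds `max_bond` (strict inequality, DSSP
#' convention) or when either atom is missing.
#'
#' @param chain A `protein_chain`.
#' @param max_bond Maximum peptide C-N bond length in Angstrom (default 2.5).
#' @return Integer vector of 1-based indices `i` such that the bond after
#'   residue `i` is broken. Empty for chains with fewer than 2 residues.
#' @export
detect_chain_breaks <- function(chain, max_bond = 2.5) {
  nres <- length(chain$name)
  if (nres < 2L) return(integer(0))
  cmat <- chain$c[-nres, , drop = FALSE]
  nmat <- chain$n[-1L, , drop = FALSE]
  d2 <- rowSums((cmat - nmat)^2)
  broken <- is.na(d2) | d2 > max_bond^2
  which(broken)
}

#' Write chain sequences as FASTA
#'
#' @param chains List of `protein_chain` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chain_fasta <- function(chains, path) {
  txt <- unlist(lapply(chains, function(ch) c(paste0(">", ch$source_id), ch$sequence)))
  writeLines(txt, path)
  invisible(path)
}

#' Summarize chains as a table
#'
#' @param chains List of `protein_chain` objects.
#' @return data.frame with columns `source_id`, `length`, `n_breaks`.
#' @export
chain_table <- function(chains) {
  data.frame(
    source_id = vapply(chains, function(ch) ch$source_id, character(1)),
    length = vapply(chains, function(ch) length(ch$name), integer(1)),
    n_breaks = vapply(chains, function(ch) length(detect_chain_breaks(ch)), integer(1)),
    stringsAsFactors = FALSE
  )
}
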