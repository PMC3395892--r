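# Desk-scale synthetic inputs: toy PDB backbones with controlled
# perturbation, planted-signal feature matrices, and synthetic per-residue
# tracks for every provider slot. All randomness flows from explicit seeds.

toy_backbone <- function(length, geometry = c("extended", "helix")) {
  geometry <- match.arg(geometry)
  i <- seq_len(length) - 1L
  if (geometry == "extended") {
    ca <- cbind(3.8 * i, 0, 0)
  } else {
    # ideal alpha-helix: radius 2.3 A, rise 1.5 A, 100 degrees per residue
    ang <- 100 * pi / 180 * i
    ca <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
  }
  # N and C placed on the chords between consecutive C-alphas at a fraction
  # that leaves the inter-residue C-N gap at ~1.33 A
  f <- 0.325
  nmat <- matrix(NA_real_, length, 3L)
  cmat <- matrix(NA_real_, length, 3L)
  for (j in seq_len(length)) {
    prev <- if (j > 1L) ca[j - 1L, ] else 2 * ca[1L, ] - ca[2L, ]
    nxt <- if (j < length) ca[j + 1L, ] else 2 * ca[length, ] - ca[length - 1L, ]
    nmat[j, ] <- ca[j, ] + f * (prev - ca[j, ])
    cmat[j, ] <- ca[j, ] + f * (nxt - ca[j, ])
  }
  list(ca = ca, n = nmat, c = cmat)
}

toy_chain_object <- function(length, geometry, seed, perturbation_sd = 0,
                             sequence = NULL, chain_id = "A",
                             structure_id = "TOY") {
  stopifnot(length >= 5L, perturbation_sd >= 0)
  bb <- toy_backbone(length, geometry)
  with_seed(seed, {
    if (is.null(sequence)) {
      sequence <- paste(sample(AA_ALPHABET, length, replace = TRUE),
                        collapse = "")
    }
    if (perturbation_sd > 0) {
      bb$ca <- bb$ca + matrix(stats::rnorm(3 * length, 0, perturbation_sd), length, 3L)
      bb$n <- bb$n + matrix(stats::rnorm(3 * length, 0, perturbation_sd), length, 3L)
      bb$c <- bb$c + matrix(stats::rnorm(3 * length, 0, perturbation_sd), length, 3L)
    }
  })
  one <- strsplit(sequence, "")[[1]]
  three <- names(AA_3TO1)[match(one, AA_3TO1)]
  three[is.na(three)] <- "UNK"
  structure(list(
    source_id = paste0(structure_id, "_", chain_id), chain_id = chain_id,
    name = three, one_letter = ifelse(three == "UNK", NA_character_, one),
    seq_id = as.character(seq_len(length)),
    had_altloc = rep(FALSE, length),
    ca = bb$ca, n = bb$n, c = bb$c,
    sequence = paste(ifelse(three == "UNK", "X", one), collapse = "")
  ), class = "protein_chain")
}

#' Generate a toy PDB chain
#'
#' Idealized backbone (consecutive C-alpha spacing ~3.8 A, peptide C-N gaps
#' ~1.33 A) in extended or alpha-helical geometry, with optional seeded
#' Gaussian coordinate noise. At `perturbation_sd = 0` the chain parses with
#' zero chain breaks. Byte-identical output for identical arguments.
#'
#' @param length Number of residues (>= 5).
#' @param geometry `"extended"` or `"helix"`.
#' @param seed Integer seed (sequence sampling and noise).
#' @param perturbation_sd Gaussian noise SD in Angstrom applied to all
#'   backbone atoms (default 0).
#' @param sequence Optional fixed amino acid sequence.
#' @param structure_id,chain_id Identifiers used in the records.
#' @return PDB-format text (character scalar).
#' @export
make_toy_chain <- function(length, geometry = c("extended", "helix"),
                           seed = 1L, perturbation_sd = 0, sequence = NULL,
                           structure_id = "TOY", chain_id = "A") {
  write_pdb(toy_chain_object(length, match.arg(geometry), seed,
                             perturbation_sd, sequence, chain_id, structure_id))
}

#' Generate a mutated-and-perturbed chain pair fixture
#'
#' The second chain copies the first, renames the central residue to
#' `mutate_center`, and perturbs its C-alpha coordinates with seeded
#' Gaussian noise of scale `perturb`. The true post-superposition RMSD of
#' the central pentamer is computed internally and returned with the
#' resulting structural label.
#'
#' @param length Chain length (odd, >= 5; default 11).
#' @param geometry Backbone geometry (see [make_toy_chain()]).
#' @param mutate_center One-letter amino acid for the mutant center.
#' @param perturb Gaussian coordinate noise SD in Angstrom (>= 0).
#' @param seed Integer seed.
#' @param mutate_flanks When `TRUE`, residues at `center - 3` and
#'   `center + 3` (just outside the central pentamer) are also mutated, so
#'   the resulting pair is not embedded in a larger identical fragment and
#'   survives [maximal_fragment_filter()] at its default.
#' @return List: `pdb_a`, `pdb_b` (PDB texts), `center` (1-based central
#'   residue index), `rmsd` (central-pentamer C-alpha RMSD after optimal
#'   superposition), `label` (from [label_pair()]).
#' @export
make_pair_fixture <- function(length = 11L, geometry = "extended",
                              mutate_center = "A", perturb = 0, seed = 1L,
                              mutate_flanks = FALSE) {
  stopifnot(perturb >= 0, length >= 5L)
  seeds <- derive_seeds(seed, 4L)
  center <- (length + 1L) %/% 2L
  seq_a <- with_seed(seeds[1], {
    s <- sample(AA_ALPHABET, length, replace = TRUE)
    if (s[center] == mutate_center)  # force a central mismatch
      s[center] <- sample(setdiff(AA_ALPHABET, mutate_center), 1L)
    paste(s, collapse = "")
  })
  chain_a <- toy_chain_object(length, geometry, seeds[2], 0, seq_a,
                              chain_id = "A", structure_id = "FIXA")
  seq_b <- seq_a
  substr(seq_b, center, center) <- mutate_center
  if (mutate_flanks) {
    seq_b <- with_seed(seeds[4], {
      s <- strsplit(seq_b, "")[[1]]
      for (pos in c(center - 3L, center + 3L)) {
        if (pos >= 1L && pos <= length)
          s[pos] <- sample(setdiff(AA_ALPHABET, s[pos]), 1L)
      }
      paste(s, collapse = "")
    })
  }
  chain_b <- toy_chain_object(length, geometry, seeds[2], 0, seq_b,
                              chain_id = "B", structure_id = "FIXB")
  if (perturb > 0) {
    chain_b$ca <- chain_b$ca +
      with_seed(seeds[3], matrix(stats::rnorm(3 * length, 0, perturb), length, 3L))
  }
  idx <- (center - 2L):(center + 2L)
  rmsd <- superpose(chain_a$ca[idx, ], chain_b$ca[idx, ])$rmsd
  list(pdb_a = write_pdb(chain_a), pdb_b = write_pdb(chain_b),
       center = center, rmsd = rmsd, label = label_pair(rmsd))
}

#' Generate a planted-signal classification dataset
#'
#' The signal feature is drawn from unit-variance Gaussians with class means
#' 0 (neutral) and `d` (change); all other features are standard-normal
#' noise. With effect size `d` the analytic single-feature AUC is
#' `pnorm(d / sqrt(2))`.
#'
#' @param n Number of instances.
#' @param n_features Number of feature columns.
#' @param signal_feature Column index of the informative feature (default 1).
#' @param d Class-mean separation in SD units (>= 0; default 2).
#' @param class_balance Fraction of "change" instances (default 0.5).
#' @param seed Integer seed.
#' @return List: `X` (n x n_features matrix with a per-column layout
#'   attribute so each feature is a selectable descriptor), `y` (0/1 labels).
#' @export
make_planted_dataset <- function(n, n_features, signal_feature = 1L, d = 2,
                                 class_balance = 0.5, seed = 1L) {
  stopifnot(class_balance > 0, class_balance < 1, d >= 0,
            signal_feature >= 1L, signal_feature <= n_features)
  n1 <- round(n * class_balance)
  y <- c(rep(1, n1), rep(0, n - n1))
  X <- with_seed(seed, {
    m <- matrix(stats::rnorm(n * n_features), n, n_features)
    m[y == 1, signal_feature] <- m[y == 1, signal_feature] + d
    m
  })
  nm <- sprintf("f%02d", seq_len(n_features))
  attr(X, "layout") <- data.frame(name = nm,
                                  offset = seq_len(n_features) - 1L,
                                  width = 1L, stringsAsFactors = FALSE)
  colnames(X) <- nm
  list(X = X, y = y)
}

simplex_rows <- function(n, k) {
  m <- matrix(stats::rexp(n * k), n, k)
  m / rowSums(m)
}

onehot_rows <- function(n, k) {
  idx <- sample.int(k, n, replace = TRUE)
  m <- matrix(0, n, k)
  m[cbind(seq_len(n), idx)] <- 1
  m
}

#' Generate synthetic per-residue tracks for a chain
#'
#' Fills every provider slot consumed by the feature encoder with
#' range-respecting random tracks: three-state tracks are per-position
#' probability simplexes, two-state tracks mutually exclusive 1/0 pairs,
#' scalar tracks uniform in `[0, 1]`, and the 20-wide substitution tracks
#' uniform (`pssm`) or simplex (`freq`).
#'
#' @param chain A `protein_chain`.
#' @param seed Integer seed.
#' @return Named list of n-by-width matrices covering every name in the
#'   track registry except the sequence-derived propensity tracks.
#' @export
make_synthetic_tracks <- function(chain, seed = 1L) {
  n <- length(chain$name)
  with_seed(seed, {
    tr <- list(
      ss = simplex_rows(n, 3L), acc = simplex_rows(n, 3L),
      ss_raw = simplex_rows(n, 3L), acc_raw = simplex_rows(n, 3L),
      disorder = onehot_rows(n, 2L), dna = onehot_rows(n, 2L),
      isis = onehot_rows(n, 2L),
      flexibility = matrix(stats::runif(n), ncol = 1L),
      info = matrix(stats::runif(n), ncol = 1L),
      psic = matrix(stats::runif(n), ncol = 1L),
      pfam_fit = matrix(stats::runif(n), ncol = 1L),
      disorder_short = matrix(stats::runif(n), ncol = 1L),
      disorder_long = matrix(stats::runif(n), ncol = 1L),
      pssm = matrix(stats::runif(n * 20L), n, 20L,
                    dimnames = list(NULL, AA_ALPHABET)),
      freq = {
        f <- simplex_rows(n, 20L); colnames(f) <- AA_ALPHABET; f
      }
    )
    tr
  })
}

#' Generate a synthetic PSI-BLAST ASCII PSSM
#'
#' Random integer log-odds in `[-8, 8]`, percent frequency rows summing to
#' ~100, and information content in `[0, 2]` bits, formatted with
#' [write_pssm()] so it round-trips through [parse_pssm()].
#'
#' @param sequence Amino acid string.
#' @param seed Integer seed.
#' @return PSSM file content (character scalar).
#' @export
make_synthetic_pssm <- function(sequence, seed = 1L) {
  n <- nchar(sequence)
  with_seed(seed, {
    scores <- matrix(sample(-8:8, n * 20L, replace = TRUE), n, 20L)
    freqs <- round(100 * simplex_rows(n, 20L))
    info <- round(stats::runif(n, 0, 2), 2)
    write_pssm(sequence, scores, freqs, info)
  })
}
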