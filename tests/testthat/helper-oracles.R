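# Independent oracles and tiny fixture builders, deliberately implemented
# with different algorithms than the package code they check.

# One fixed-column ATOM record (PDB v3.3 layout).
pdb_atom_line <- function(serial, atom, resname, chain, resseq, x, y, z,
                          altloc = " ", icode = " ") {
  sprintf("ATOM  %5d %s%s%3s %s%4d%s   %8.3f%8.3f%8.3f  1.00  0.00",
          serial, sprintf(" %-3s", atom), altloc, resname, chain, resseq,
          icode, x, y, z)
}

# A residue's N/CA/C records on an ideal extended trace (C-N gap 1.33 A).
pdb_residue_lines <- function(serial0, resname, chain, resseq, i,
                              ca_shift = c(0, 0, 0)) {
  x0 <- 3.8 * i
  c(
    pdb_atom_line(serial0,     "N",  resname, chain, resseq, x0 - 1.235, 0.0, 0.0),
    pdb_atom_line(serial0 + 1, "CA", resname, chain, resseq,
                  x0 + ca_shift[1], ca_shift[2], ca_shift[3]),
    pdb_atom_line(serial0 + 2, "C",  resname, chain, resseq, x0 + 1.235, 0.0, 0.0)
  )
}

# Ideal extended test chain from a one-letter sequence; resnames looked up
# independently of the package tables.
AA_1TO3 <- c(A="ALA", R="ARG", N="ASN", D="ASP", C="CYS", Q="GLN", E="GLU",
             G="GLY", H="HIS", I="ILE", L="LEU", K="LYS", M="MET", F="PHE",
             P="PRO", S="SER", T="THR", W="TRP", Y="TYR", V="VAL")

pdb_fixture_text <- function(sequence, chain = "A") {
  ch <- strsplit(sequence, "")[[1]]
  lines <- character(0)
  for (i in seq_along(ch)) {
    rn <- if (ch[i] %in% names(AA_1TO3)) AA_1TO3[[ch[i]]] else "MSE"
    lines <- c(lines, pdb_residue_lines(3 * i - 2, rn, chain, i, i - 1))
  }
  paste(c(lines, "TER", ""), collapse = "\n")
}

# Mann-Whitney AUC by explicit pair counting, ties counted 1/2.
mw_auc_oracle <- function(probs, y) {
  pos <- probs[y == 1]
  neg <- probs[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Brute-force planar superposition oracle: for z = 0 point sets the optimal
# proper 3D rotation is either an in-plane rotation or an in-plane rotation
# composed with a y-flip (a proper rotation about the x axis). Scans a fine
# angle grid over both orientations.
grid_rmsd_oracle <- function(x, y, n_grid = 20000L) {
  q <- sweep(x, 2, colMeans(x))
  p0 <- sweep(y, 2, colMeans(y))
  best <- Inf
  for (flip in c(FALSE, TRUE)) {
    p <- p0
    if (flip) p[, 2] <- -p[, 2]
    for (th in seq(0, 2 * pi, length.out = n_grid)) {
      r <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
      d <- p %*% r - q
      best <- min(best, sqrt(mean(rowSums(d^2))))
    }
  }
  best
}

# Random proper rotation matrix (QR of a Gaussian matrix, det fixed to +1).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  r <- qr.Q(qr_)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# Penalized logistic objective used by the independent optim() oracle.
logreg_objective_factory <- function(X, y01, C) {
  Xa <- cbind(1, X)
  pen <- c(0, rep(1, ncol(X)))
  function(theta) {
    z <- drop(Xa %*% theta)
    0.5 * sum(pen * theta^2) +
      C * sum(pmax(z, 0) - y01 * z + log1p(exp(-abs(z))))
  }
}

# Shared smoke-scale end-to-end fixture: n_pairs fixtures, alternating
# unperturbed (neutral) and strongly perturbed (change) chains.
build_smoke_dataset <- function(n_pairs = 10, length = 15, seed = 100) {
  chains <- list()
  pairs <- NULL
  edges <- NULL
  for (i in seq_len(n_pairs)) {
    fx <- make_pair_fixture(length = length, perturb = if (i %% 2) 0 else 1.0,
                            seed = seed + i, mutate_flanks = TRUE)
    a <- parse_pdb(fx$pdb_a, paste0("P", i))[[1]]
    b <- parse_pdb(fx$pdb_b, paste0("Q", i))[[1]]
    chains[[a$source_id]] <- a
    chains[[b$source_id]] <- b
    pa <- extract_pentamers(a)
    pb <- extract_pentamers(b)
    pr <- pair_pentamers(pa, pb, chains, min_identity = 30)
    pr <- maximal_fragment_filter(pr, chains)
    pairs <- if (is.null(pairs)) pr else rbind(pairs, pr)
    edges <- rbind(edges, data.frame(a = a$source_id, b = b$source_id,
                                     stringsAsFactors = FALSE))
  }
  pairs <- designate_roles(label_pairs(pairs), seed = seed)
  tracks <- lapply(chains, function(ch)
    make_synthetic_tracks(ch, seed = seed + nchar(ch$source_id)))
  list(chains = chains, pairs = pairs, tracks = tracks, edges = edges)
}
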