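# Feature encoding: global channels, windows, differences, PSSM parsing,
# vector assembly.

test_that("length bins follow the 0.5/1/0 convention", {
  expect_equal(encode_length_bins(100), c(1, 0.5, 0, 0))
  expect_equal(encode_length_bins(30), c(0.5, 0, 0, 0))
  expect_equal(encode_length_bins(300), c(1, 1, 1, 1))
  expect_equal(encode_length_bins(60), c(0.5, 0, 0, 0))
  expect_equal(encode_length_bins(61), c(1, 0.5, 0, 0))
  expect_equal(encode_length_bins(240), c(1, 1, 1, 0.5))
  expect_error(encode_length_bins(0))
})

test_that("composition is a normalized count over standard residues", {
  comp <- encode_composition("AAAA")
  expect_equal(unname(comp["A"]), 1)
  expect_equal(sum(comp), 1)
  comp2 <- encode_composition("ACACAC")
  expect_equal(unname(comp2[c("A", "C")]), c(0.5, 0.5))
  expect_equal(encode_composition("XXX"), setNames(rep(0, 20), sort(names(comp))))
  # counting oracle on a random long sequence; X excluded from both sides
  set.seed(3)
  ch <- sample(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X"), 1000,
               replace = TRUE)
  comp3 <- encode_composition(paste(ch, collapse = ""))
  std <- ch[ch != "X"]
  for (aa in c("A", "K", "W")) {
    expect_equal(unname(comp3[aa]), sum(std == aa) / length(std))
  }
  expect_equal(sum(comp3), 1, tolerance = 1e-9)
})

test_that("window encoding slices and zero-pads correctly", {
  tr <- matrix(seq_len(20), 10, 2)  # 10 positions, width 2
  expect_equal(encode_window(tr, 4, 1), c(4, 14))
  expect_equal(encode_window(tr, 1, 5), c(0, 0, 0, 0, 1, 11, 2, 12, 3, 13))
  expect_equal(encode_window(tr, 5, 5),
               as.numeric(t(tr[3:7, ])))
  expect_equal(encode_window(tr, 10, 5), c(8, 18, 9, 19, 10, 20, 0, 0, 0, 0))
  expect_error(encode_window(tr, 4, 4))
  expect_error(encode_window(tr, 4, 7))   # odd but not in the allowed set
  expect_error(encode_window(tr, 0, 5))
})

test_that("window encoding never reads out of range (fuzzed)", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(1:30, 1)
    w <- sample(c(1L, 5L, 9L, 13L, 17L, 21L), 1)
    tr <- matrix(runif(n * 3), n, 3)
    center <- sample(n, 1)
    v <- encode_window(tr, center, w)
    expect_length(v, 3 * w)
    expect_true(all(is.finite(v)))
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("difference encoding produces |delta| and a >= 0 sign bit", {
  expect_equal(encode_difference(0.7, 0.4), c(0.3, 0))
  expect_equal(encode_difference(0.4, 0.7), c(0.3, 1))
  expect_equal(encode_difference(0.5, 0.5), c(0, 1))
  expect_equal(encode_difference(c(0.2, 0.9), c(0.5, 0.1)),
               c(0.3, 1, 0.8, 0))
})

test_that("propensity scales cover all 20 residues in [0,1]", {
  sc <- propensity_scales()
  expect_named(sc, c("mass", "volume", "hydrophobicity", "cbeta_branching",
                     "helix_breaker", "charge"))
  for (s in sc) {
    expect_length(s, 20)
    expect_true(all(s >= 0 & s <= 1))
  }
  expect_equal(unname(sc$mass["G"]), 0)
  expect_equal(unname(sc$mass["W"]), 1)
  expect_equal(unname(sc$helix_breaker["P"]), 1)
  expect_equal(sum(sc$helix_breaker), 1)
  expect_equal(unname(sc$charge[c("D", "K", "A")]), c(0, 1, 0.5))
  expect_equal(unname(sc$cbeta_branching[c("I", "T", "V", "L")]), c(1, 1, 1, 0))
})

test_that("propensity tracks map per position with 0 at X", {
  tr <- propensity_track("APA", "helix_breaker")
  expect_equal(as.numeric(tr), c(0, 1, 0))
  tr2 <- propensity_track("GXW", "mass")
  expect_equal(as.numeric(tr2), c(0, 0, 1))
})

test_that("synthetic PSSM round-trips through the parser", {
  seqs <- "ALKVGHIWDE"
  txt <- make_synthetic_pssm(seqs, seed = 8)
  parsed <- parse_pssm(txt, seqs)
  expect_equal(parsed$sequence, seqs)
  expect_equal(dim(parsed$pssm), c(10L, 20L))
  expect_true(all(parsed$pssm >= 0 & parsed$pssm <= 1))
  expect_true(all(parsed$freq >= 0 & parsed$freq <= 1))
  expect_true(all(parsed$info >= 0 & parsed$info <= 1))
  # affine map invertible on the raw integer scores
  raw <- round(parsed$pssm * 32 - 16)
  txt2 <- write_pssm(seqs, raw, parsed$freq * 100, parsed$info * 2)
  expect_equal(parse_pssm(txt2)$pssm, parsed$pssm)
  expect_error(parse_pssm(txt, "ALKVG"), "rows")
})

test_that("all-zero PSSM rows map to mid-scale 0.5", {
  n <- 4
  txt <- write_pssm("ALKV", matrix(0, n, 20), matrix(5, n, 20), rep(1, n))
  expect_true(all(parse_pssm(txt)$pssm == 0.5))
})

test_that("the nine selected descriptors cover 147 values", {
  desc <- selected_descriptors()
  expect_length(desc, 9)
  expect_equal(feature_width(desc), 147L)
  widths <- vapply(desc, function(d) d$width, integer(1))
  expect_equal(widths, c(2L, 51L, 21L, 21L, 2L, 6L, 13L, 26L, 5L))
})

test_that("descriptor builders validate windows and tracks", {
  expect_error(local_descriptor("ss", 4))
  expect_error(local_descriptor("nosuchtrack", 5))
  expect_error(diff_descriptor("nosuchproperty"))
  expect_equal(local_descriptor("pssm", 1)$width, 20L)
  expect_equal(diff_descriptor("ss_raw")$width, 6L)
  expect_equal(diff_descriptor("volume")$width, 2L)
})

# one assembled pair shared across the assembly tests
assembled_fixture <- local({
  fx <- make_pair_fixture(length = 25, perturb = 0.5, seed = 21,
                          mutate_flanks = TRUE)
  a <- parse_pdb(fx$pdb_a, "FA")[[1]]
  b <- parse_pdb(fx$pdb_b, "FB")[[1]]
  chains <- setNames(list(a, b), c(a$source_id, b$source_id))
  pr <- pair_pentamers(extract_pentamers(a), extract_pentamers(b), chains)
  pr <- designate_roles(label_pairs(pr), seed = 4)
  tracks <- setNames(list(make_synthetic_tracks(a, 1),
                          make_synthetic_tracks(b, 2)), names(chains))
  list(pair = pr[1, ], chains = chains, tracks = tracks)
})

test_that("assembled vectors conserve width and stay in [0,1]", {
  fx <- assembled_fixture
  desc_all <- c(list(global_descriptor("length_bins"),
                     global_descriptor("composition"),
                     global_descriptor("ss_content"),
                     global_descriptor("acc_content")),
                selected_descriptors(),
                list(diff_descriptor("charge"), local_descriptor("disorder", 9)))
  fv <- assemble_vector(fx$pair, desc_all, fx$tracks, fx$chains)
  expect_length(fv$values, feature_width(desc_all))
  expect_equal(sum(fv$layout$width), length(fv$values))
  expect_equal(fv$layout$offset, cumsum(c(0, fv$layout$width[-nrow(fv$layout)])))
  expect_true(all(fv$values >= 0 & fv$values <= 1))
  # empty descriptor list
  expect_length(assemble_vector(fx$pair, list(), fx$tracks, fx$chains)$values, 0)
})

test_that("global content features are argmax fractions", {
  fx <- assembled_fixture
  wt <- if (fx$pair$wt_is_a) fx$pair$chain_a else fx$pair$chain_b
  fv <- assemble_vector(fx$pair, list(global_descriptor("ss_content")),
                        fx$tracks, fx$chains)
  tr <- fx$tracks[[wt]]$ss
  states <- max.col(tr, ties.method = "first")
  expect_equal(fv$values, as.numeric(table(factor(states, 1:3))) / nrow(tr))
  expect_equal(sum(fv$values), 1)
})

test_that("local windows in the assembly equal direct slices of the track", {
  fx <- assembled_fixture
  wt <- if (fx$pair$wt_is_a) fx$pair$chain_a else fx$pair$chain_b
  wt_start <- if (fx$pair$wt_is_a) fx$pair$start_a else fx$pair$start_b
  fv <- assemble_vector(fx$pair, list(local_descriptor("flexibility", 5)),
                        fx$tracks, fx$chains)
  expect_equal(fv$values,
               encode_window(fx$tracks[[wt]]$flexibility, wt_start + 2, 5))
})

test_that("swapping roles preserves difference magnitudes and flips signs", {
  fx <- assembled_fixture
  # shared tracks make the substitution channel exactly antisymmetric too
  tracks <- fx$tracks
  tracks[[fx$pair$chain_b]] <- tracks[[fx$pair$chain_a]]
  desc <- list(diff_descriptor("psic"), diff_descriptor("ss_raw"),
               diff_descriptor("pssm"), diff_descriptor("mass"),
               diff_descriptor("charge"))
  p1 <- fx$pair; p1$wt_is_a <- TRUE
  p2 <- fx$pair; p2$wt_is_a <- FALSE
  # identical start offsets so center positions coincide under the swap
  p2$start_b <- p1$start_a
  p1$start_b <- p1$start_a
  p2$start_a <- p1$start_a
  v1 <- assemble_vector(p1, desc, tracks, fx$chains)$values
  v2 <- assemble_vector(p2, desc, tracks, fx$chains)$values
  mag <- seq(1, length(v1), by = 2)
  sgn <- mag + 1
  expect_equal(v1[mag], v2[mag], tolerance = 1e-12)
  nontie <- v1[mag] > 0
  expect_equal(v2[sgn][nontie], 1 - v1[sgn][nontie])
})

test_that("missing tracks warn and zero-fill, or error when strict", {
  fx <- assembled_fixture
  tracks <- fx$tracks
  tracks[[fx$pair$chain_a]]$psic <- NULL
  tracks[[fx$pair$chain_b]]$psic <- NULL
  desc <- list(diff_descriptor("psic"))
  expect_warning(fv <- assemble_vector(fx$pair, desc, tracks, fx$chains),
                 "unavailable")
  expect_equal(fv$values, c(0, 0))
  expect_error(assemble_vector(fx$pair, desc, tracks, fx$chains,
                               on_missing = "error"), "unavailable")
})

test_that("assemble_matrix stacks vectors with a layout attribute", {
  fx <- assembled_fixture
  pairs2 <- rbind(fx$pair, fx$pair)
  X <- assemble_matrix(pairs2, selected_descriptors(), fx$tracks, fx$chains)
  expect_equal(dim(X), c(2L, 147L))
  expect_equal(X[1, ], X[2, ])
  expect_equal(sum(attr(X, "layout")$width), 147L)
})
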