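# Optimal rigid-body superposition of pentamer C-alpha traces (Kabsch via
# SVD with reflection guard) and the three-way RMSD labeling.

#' Optimal superposition of two coordinate sets
#'
#' Least-squares rigid superposition of `y` onto `x` over paired points:
#' the returned proper rotation and translation minimize the sum of squared
#' distances, and `rmsd` is the root mean square residual distance in
#' Angstrom. Reflections are excluded by the determinant sign correction
#' (Kabsch), so a mirror image never superposes at RMSD 0.
#'
#' @param x,y Numeric n-by-3 matrices (same n, finite values). Rows are
#'   paired atoms, e.g. the five C-alpha positions of a pentamer.
#' @return An object of class `superposition`: list with `rotation`
#'   (3x3 proper orthogonal), `translation` (length 3) such that
#'   `y %*% t(rotation) + translation` best fits `x`, and `rmsd`.
#' @export
superpose <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(is.numeric(x), is.numeric(y), ncol(x) == 3L, ncol(y) == 3L,
            nrow(x) == nrow(y), nrow(x) >= 1L)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("coordinates must be finite")
  cx <- colMeans(x); cy <- colMeans(y)
  p <- sweep(y, 2L, cy)   # moving
  q <- sweep(x, 2L, cx)   # target
  h <- crossprod(p, q)    # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- p %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - q)^2)))
  structure(list(
    rotation = rot,
    translation = as.numeric(cx - drop(cy %*% t(rot))),
    rmsd = rmsd
  ), class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Three-way structural label from pentamer RMSD
#'
#' RMSD strictly below `t_neutral` is "neutral", strictly above `t_change`
#' is "change"; everything in between (boundaries included) is "excluded"
#' and dropped from the binary problem.
#'
#' @param rmsd Non-negative RMSD values in Angstrom (vectorized).
#' @param t_neutral Neutral threshold, default 0.2.
#' @param t_change Change threshold, default 0.4; must exceed `t_neutral`.
#' @return Character vector over `{"neutral", "excluded", "change"}`.
#' @export
label_pair <- function(rmsd, t_neutral = 0.2, t_change = 0.4) {
  if (!(t_neutral < t_change)) stop("t_neutral must be < t_change")
  stopifnot(all(rmsd >= 0))
  ifelse(rmsd < t_neutral, "neutral",
         ifelse(rmsd > t_change, "change", "excluded"))
}

#' Superpose and label a pair table
#'
#' Computes the C-alpha RMSD for every pair via [superpose()] and appends
#' `rmsd` and `label` columns.
#'
#' @param pairs Pair data.frame with `ca_a`/`ca_b` list-columns.
#' @inheritParams label_pair
#' @return `pairs` with `rmsd` and `label` columns added.
#' @export
label_pairs <- function(pairs, t_neutral = 0.2, t_change = 0.4) {
  if (nrow(pairs) == 0L) {
    pairs$rmsd <- numeric(0)
    pairs$label <- character(0)
    return(pairs)
  }
  pairs$rmsd <- vapply(seq_len(nrow(pairs)), function(i)
    superpose(pairs$ca_a[[i]], pairs$ca_b[[i]])$rmsd, numeric(1))
  pairs$label <- label_pair(pairs$rmsd, t_neutral, t_change)
  pairs
}
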