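# L2-regularized logistic regression (Newton with step halving on the
# LIBLINEAR-style primal objective), homology-aware fold assignment, and
# forward feature selection driven by cross-validated AUC.

#' Train an L2-regularized logistic regression model
#'
#' Minimizes `0.5 * ||w||^2 + C * sum_i log(1 + exp(-y_i z_i))` with
#' `z = X w + b` and unpenalized intercept `b`, by damped Newton iterations
#' until the gradient infinity-norm falls below `tol`. Deterministic given
#' the data.
#'
#' @param X Numeric matrix (instances x features), no `NA`.
#' @param y Binary labels: logical, 0/1, or a character/factor where the
#'   positive class is `"change"`.
#' @param reg_strength Loss weight `C` (LIBLINEAR convention); larger means
#'   weaker regularization. Default 1.
#' @param tol Gradient tolerance (default 1e-8).
#' @param max_iter Maximum Newton iterations.
#' @return A `logreg_model`: list with `weights`, `intercept`,
#'   `reg_strength` and the training `layout` attribute of `X` if present.
#' @export
train_logreg <- function(X, y, reg_strength = 1.0, tol = 1e-8, max_iter = 100L) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X contains NA")
  y01 <- as_binary01(y)
  if (length(unique(y01)) < 2L) stop("y must contain both classes")
  stopifnot(nrow(X) == length(y01), reg_strength > 0)
  n <- nrow(X); p <- ncol(X)
  Xa <- cbind(1, X)
  pen <- c(0, rep(1, p))
  theta <- rep(0, p + 1L)
  objective <- function(th) {
    z <- drop(Xa %*% th)
    # numerically stable log(1 + exp(z)) - y*z
    nll <- sum(pmax(z, 0) - y01 * z + log1p(exp(-abs(z))))
    0.5 * sum(pen * th^2) + reg_strength * nll
  }
  f <- objective(theta)
  for (it in seq_len(max_iter)) {
    z <- drop(Xa %*% theta)
    mu <- stats::plogis(z)
    grad <- pen * theta + reg_strength * drop(crossprod(Xa, mu - y01))
    if (max(abs(grad)) < tol) break
    wdiag <- pmax(mu * (1 - mu), 1e-10)
    H <- reg_strength * crossprod(Xa * wdiag, Xa)
    diag(H) <- diag(H) + pen
    step <- tryCatch(solve(H, grad), error = function(e) grad / max(diag(H)))
    # step halving keeps the damped Newton iteration monotone
    alpha <- 1
    repeat {
      cand <- theta - alpha * step
      fc <- objective(cand)
      if (fc <= f || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    theta <- cand
    f <- fc
  }
  structure(list(
    weights = theta[-1L], intercept = theta[1L],
    reg_strength = reg_strength, layout = attr(X, "layout")
  ), class = "logreg_model")
}

as_binary01 <- function(y) {
  if (is.logical(y)) return(as.numeric(y))
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) return(as.numeric(y == "change"))
  stopifnot(all(y %in% c(0, 1)))
  as.numeric(y)
}

#' @export
print.logreg_model <- function(x, ...) {
  cat(sprintf("<logreg_model> %d weights, intercept %.4f, C = %g\n",
              length(x$weights), x$intercept, x$reg_strength))
  invisible(x)
}

#' Predicted probability of structural change
#'
#' @param model A `logreg_model`.
#' @param X Numeric matrix with the same feature width the model was
#'   trained on.
#' @return Probabilities in `(0, 1)`.
#' @export
predict_proba <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$weights))
    stop("feature width mismatch: model has ", length(model$weights),
         ", data has ", ncol(X))
  stats::plogis(drop(X %*% model$weights) + model$intercept)
}

#' Serialize a trained model to JSON
#'
#' @param model A `logreg_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(weights = model$weights, intercept = model$intercept,
         reg_strength = model$reg_strength, layout = model$layout),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = as.numeric(obj$weights),
                 intercept = as.numeric(obj$intercept),
                 reg_strength = as.numeric(obj$reg_strength),
                 layout = obj$layout),
            class = "logreg_model")
}

# Union-find connected components over protein ids.
protein_components <- function(proteins, similarity_edges) {
  parent <- seq_along(proteins)
  names(parent) <- proteins
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (!is.null(similarity_edges) && nrow(similarity_edges) > 0L) {
    for (r in seq_len(nrow(similarity_edges))) {
      a <- match(similarity_edges[[1L]][r], proteins)
      b <- match(similarity_edges[[2L]][r], proteins)
      if (is.na(a) || is.na(b)) next
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_along(proteins), find, numeric(1))
  match(roots, unique(roots))
}

#' Homology-aware cross-validation folds
#'
#' Connected components of the protein-similarity graph are assigned
#' atomically to folds, largest component first (seeded shuffle breaks
#' ties), each to the currently smallest fold. Instances from similar
#' proteins therefore never straddle a train/test boundary.
#'
#' @param instances data.frame with columns `id` and `protein`.
#' @param similarity_edges data.frame with two columns of protein ids
#'   (pairs deemed similar, e.g. BLAST E-value <= 1e-3), or `NULL`.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return List with `fold_of` (named integer vector, instance id ->
#'   fold in `1..k`) and `k`.
#' @export
assign_folds <- function(instances, similarity_edges = NULL, k = 10L, seed = 1L) {
  stopifnot(all(c("id", "protein") %in% names(instances)))
  proteins <- unique(instances$protein)
  comp_of_protein <- protein_components(proteins, similarity_edges)
  comp <- comp_of_protein[match(instances$protein, proteins)]
  sizes <- tabulate(comp)
  ord <- with_seed(seed, {
    jitter <- stats::runif(length(sizes))
    order(-sizes, jitter)
  })
  if (max(sizes) > length(comp) / k)
    warning("a similarity component exceeds n/k instances; folds will be unbalanced")
  fold_sizes <- rep(0L, k)
  fold_of_comp <- integer(length(sizes))
  for (cmp in ord) {
    f <- which.min(fold_sizes)
    fold_of_comp[cmp] <- f
    fold_sizes[f] <- fold_sizes[f] + sizes[cmp]
  }
  list(fold_of = setNames(fold_of_comp[comp], instances$id), k = as.integer(k))
}

#' Similarity-respecting holdout split for feature selection
#'
#' Accumulates whole similarity components (seeded order) into the selection
#' set until it reaches at least `fraction` of the instances; no similarity
#' edge crosses the split.
#'
#' @inheritParams assign_folds
#' @param fraction Target selection-set fraction (default 1/5).
#' @return List with character vectors `selection` and `main` of instance
#'   ids.
#' @export
holdout_selection_split <- function(instances, similarity_edges = NULL,
                                    fraction = 1/5, seed = 1L) {
  proteins <- unique(instances$protein)
  comp_of_protein <- protein_components(proteins, similarity_edges)
  comp <- comp_of_protein[match(instances$protein, proteins)]
  n <- nrow(instances)
  ncomp <- max(comp)
  ord <- with_seed(seed, sample.int(ncomp))
  sizes <- tabulate(comp, nbins = ncomp)
  take <- logical(ncomp)
  got <- 0L
  for (cmp in ord) {
    if (got >= fraction * n) break
    take[cmp] <- TRUE
    got <- got + sizes[cmp]
  }
  if (got >= n)
    stop("holdout split impossible: selected components cover all instances ",
         "(similarity graph too connected)")
  list(selection = instances$id[take[comp]],
       main = instances$id[!take[comp]])
}

# Mean cross-validated AUC of a logistic model on the given columns.
cv_auc <- function(X, y01, cols, folds, k, reg_strength = 1.0) {
  aucs <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    te <- folds == f
    if (!any(te) || length(unique(y01[!te])) < 2L ||
        length(unique(y01[te])) < 2L) next
    m <- train_logreg(X[!te, cols, drop = FALSE], y01[!te],
                      reg_strength = reg_strength, tol = 1e-6)
    p <- predict_proba(m, X[te, cols, drop = FALSE])
    aucs[f] <- roc_auc(p, y01[te])$auc
  }
  aucs
}

#' Forward feature selection by cross-validated AUC
#'
#' Greedy forward search: at each round every remaining candidate descriptor
#' is appended to the accepted set, a full k-fold rotation of
#' train/test is run, and the candidate with the best mean test AUC is
#' accepted; the search stops when the best improvement over the current
#' mean AUC is `<= stop_delta`. Ties break lexicographically by descriptor
#' name (candidates are scanned in lexicographic order with a strict
#' improvement test). Folds are fixed once per run (seeded).
#'
#' @param X Feature matrix with a `layout` attribute mapping descriptor
#'   names to column blocks (from [assemble_matrix()]), or a plain matrix if
#'   `candidates` is a list mapping names to column indices.
#' @param y Binary labels (see [train_logreg()]).
#' @param candidates Character vector of descriptor names (resolved through
#'   the layout), or a named list of integer column vectors.
#' @param folds Optional fold id per row; when `NULL`, a seeded balanced
#'   assignment over `k` folds is drawn.
#' @param k Fold count (default 10).
#' @param stop_delta Minimum mean-AUC improvement to continue (default
#'   0.001).
#' @param seed Integer seed (fold assignment).
#' @param reg_strength Passed to [train_logreg()].
#' @return A `selection_trace`: list with `steps` (data.frame of accepted
#'   steps: name, mean_auc), `fold_aucs` (list of per-fold AUC vectors),
#'   `accepted` (character), `stopped_reason` (`"converged"` or
#'   `"exhausted"`).
#' @export
forward_select <- function(X, y, candidates, folds = NULL, k = 10L,
                           stop_delta = 0.001, seed = 1L, reg_strength = 1.0) {
  X <- as.matrix(X)
  y01 <- as_binary01(y)
  if (is.character(candidates)) {
    layout <- attr(X, "layout")
    if (is.null(layout)) stop("X has no layout attribute; pass candidate columns explicitly")
    candidates <- setNames(lapply(candidates, function(nm) {
      r <- layout[layout$name == nm, ]
      if (nrow(r) != 1L) stop("descriptor not in layout: ", nm)
      (r$offset + 1L):(r$offset + r$width)
    }), candidates)
  }
  if (length(candidates) == 0L) {
    return(structure(list(steps = data.frame(name = character(0),
                                             mean_auc = numeric(0)),
                          fold_aucs = list(), accepted = character(0),
                          stopped_reason = "exhausted"),
                     class = "selection_trace"))
  }
  candidates <- candidates[order(names(candidates))]
  if (is.null(folds)) {
    folds <- with_seed(seed, sample(rep_len(seq_len(k), nrow(X))))
  }
  accepted <- character(0)
  accepted_cols <- integer(0)
  best_mean <- 0.5  # chance-level baseline before any feature
  steps <- list()
  fold_aucs <- list()
  remaining <- names(candidates)
  stopped <- "exhausted"
  while (length(remaining) > 0L) {
    round_best <- -Inf
    round_name <- NA_character_
    round_aucs <- NULL
    for (nm in remaining) {  # lexicographic scan; strict > keeps first on ties
      aucs <- cv_auc(X, y01, c(accepted_cols, candidates[[nm]]), folds, k,
                     reg_strength)
      m <- mean(aucs, na.rm = TRUE)
      if (is.finite(m) && m > round_best) {
        round_best <- m
        round_name <- nm
        round_aucs <- aucs
      }
    }
    if (!is.finite(round_best) || round_best - best_mean <= stop_delta) {
      stopped <- "converged"
      break
    }
    accepted <- c(accepted, round_name)
    accepted_cols <- c(accepted_cols, candidates[[round_name]])
    best_mean <- round_best
    steps[[length(steps) + 1L]] <- data.frame(name = round_name,
                                              mean_auc = round_best,
                                              stringsAsFactors = FALSE)
    fold_aucs[[length(fold_aucs) + 1L]] <- round_aucs
    remaining <- setdiff(remaining, round_name)
  }
  structure(list(
    steps = if (length(steps)) do.call(rbind, steps)
            else data.frame(name = character(0), mean_auc = numeric(0)),
    fold_aucs = fold_aucs, accepted = accepted, stopped_reason = stopped
  ), class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace> ", nrow(x$steps), " accepted step(s), stopped: ",
      x$stopped_reason, "\n", sep = "")
  if (nrow(x$steps)) print(x$steps)
  invisible(x)
}
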