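#' Non-negative-loading PCA by expectation-maximization
#'
#' Fits successive principal components whose gene loadings are constrained
#' to be non-negative, on the gene-set restriction of the expression matrix
#' after centering each gene to zero mean. Each component is fitted by an
#' EM loop: the E-step projects the (deflated) data onto the current
#' loading, `y = X w`; the M-step minimizes `sum_n ||x_n - y_n w||^2`
#' subject to `w >= 0`, whose closed form is `w ∝ max(X^T y, 0)`, followed
#' by renormalization to unit length. Without the constraint this is the
#' classical EM formulation of PCA (power iteration on the covariance), so
#' the component variance ascends over iterations; the constraint only
#' activates when the unconstrained optimum has negative loadings.
#'
#' Because the loadings are non-negative but the input is centered, the
#' component scores can still be negative; they are reported as fitted,
#' without any post-hoc shifting or re-signing.
#'
#' Subsequent components are fitted after deflating the data in score
#' space, `X <- X - y (y^T X) / (y^T y)`, which makes the scores of
#' successive components exactly orthogonal by construction, also when the
#' non-negativity constraint is active.
#'
#' If at some iteration `X^T y` has no positive entry there is no feasible
#' positive direction; the component falls back to the single-gene axis
#' with the largest variance in the current deflated data (ties broken by a
#' seeded draw) and the EM loop continues from there.
#'
#' @param em lognorm-layer [expression_matrix] (centering is internal).
#' @param set [gene_set] restricting the genes used; at least one set gene
#'   must be present in the matrix.
#' @param n_components number of components, at most `min(cells - 1, genes)`.
#' @param tol convergence threshold on the infinity norm of the loading
#'   change (default 1e-6).
#' @param max_iter maximum EM iterations per component (default 500).
#' @param seed integer used only for the degenerate fallback tie-break.
#' @return An object of class `nnpca_model`: list with `gene_ids`,
#'   `loadings` (genes x components, non-negative, unit columns), `scores`
#'   (cells x components), `variance_explained` (fraction of the total
#'   variance of the centered restricted matrix, before any deflation),
#'   `objective_trace` (per-component variance over EM iterations),
#'   `n_iter`, `converged` and `total_variance`.
#' @export
nnpca_fit <- function(em, set, n_components = 5, tol = 1e-6, max_iter = 500,
                      seed = 1) {
  .assert_layer(em, "lognorm", "nnpca_fit")
  stopifnot(inherits(set, "gene_set"))
  keep <- toupper(em$gene_ids) %in% set$genes
  if (sum(keep) < 1)
    stop("gene set '", set$name, "' matches no matrix genes")
  X <- em$values[, keep, drop = FALSE]
  X <- sweep(X, 2, colMeans(X))
  n_cells <- nrow(X)
  n_genes <- ncol(X)
  if (n_components > min(n_cells - 1, n_genes))
    stop("n_components exceeds min(cells - 1, genes) = ",
         min(n_cells - 1, n_genes))
  total_var <- sum(apply(X, 2, stats::var))
  rng <- .seeded_rng(seed)

  loadings <- matrix(0, n_genes, n_components)
  scores <- matrix(0, n_cells, n_components)
  n_iter <- integer(n_components)
  converged <- logical(n_components)
  traces <- vector("list", n_components)

  for (k in seq_len(n_components)) {
    # deterministic init: |leading right singular vector| of deflated data
    sv <- svd(X, nu = 0, nv = 1)
    w <- abs(sv$v[, 1])
    if (sum(w) == 0) w <- rep(1, n_genes)
    w <- w / sqrt(sum(w^2))
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      y <- drop(X %*% w)
      trace <- c(trace, stats::var(y))
      w_new <- pmax(drop(crossprod(X, y)), 0)
      if (sum(w_new) == 0) {
        # no feasible positive direction: best single-gene axis
        gvar <- apply(X, 2, stats::var)
        best <- which(gvar == max(gvar))
        pick <- if (length(best) > 1) best[[.rng_pick(rng, length(best))]]
                else best[[1]]
        message("nnpca_fit: component ", k,
                " fell back to single-gene axis '", colnames(X)[pick], "'")
        w_new <- rep(0, n_genes)
        w_new[pick] <- 1
      }
      w_new <- w_new / sqrt(sum(w_new^2))
      delta <- max(abs(w_new - w))
      w <- w_new
      if (delta < tol) break
    }
    n_iter[k] <- it
    converged[k] <- delta < tol
    if (!converged[k])
      message("nnpca_fit: component ", k, " did not converge in ",
              max_iter, " iterations (delta = ", signif(delta, 3), ")")
    y <- drop(X %*% w)
    trace <- c(trace, stats::var(y))
    loadings[, k] <- w
    scores[, k] <- y
    traces[[k]] <- trace
    yss <- sum(y^2)
    if (yss > 0) X <- X - outer(y, drop(crossprod(X, y)) / yss)
  }
  rownames(loadings) <- em$gene_ids[keep]
  rownames(scores) <- em$cell_ids
  structure(list(
    gene_ids = em$gene_ids[keep],
    loadings = loadings,
    scores = scores,
    cell_ids = em$cell_ids,
    variance_explained = apply(scores, 2, stats::var) / total_var,
    objective_trace = traces,
    n_iter = n_iter,
    converged = converged,
    total_variance = total_var
  ), class = "nnpca_model")
}

#' @export
print.nnpca_model <- function(x, ...) {
  cat(sprintf("<nnpca_model> %d genes, %d components; variance explained: %s\n",
              length(x$gene_ids), ncol(x$loadings),
              paste(signif(x$variance_explained, 3), collapse = ", ")))
  invisible(x)
}

# stateless helpers keeping the fallback tie-break reproducible without
# touching the global RNG stream
.seeded_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$seed <- as.integer(seed)
  env
}

.rng_pick <- function(rng, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(rng$seed)
  rng$seed <- rng$seed + 1L
  sample.int(n, 1)
}

#' Rank components by the two-criterion EMT selection rule
#'
#' First the `n_candidates` components with the highest variance explained
#' are kept; among those, components are re-ranked by the variance of the
#' per-subtype mean scores, descending — the component that best separates
#' the subtype centroids comes first. Ties in the subtype-mean variance are
#' broken by higher variance explained, then by lower component index.
#'
#' @param model an `nnpca_model`.
#' @param labels subtype label per cell (same order as the fitted cells);
#'   at least two distinct subtypes are required. `NA` labels are dropped.
#' @param n_candidates number of top-variance candidates (default 5).
#' @return Integer vector of component indices, best first.
#' @export
select_em_pcs <- function(model, labels, n_candidates = 5) {
  stopifnot(inherits(model, "nnpca_model"))
  labels <- as.character(labels)
  if (length(labels) != nrow(model$scores))
    stop("labels must have one entry per fitted cell")
  use <- !is.na(labels)
  if (length(unique(labels[use])) < 2)
    stop("at least two subtypes are required to rank components")
  k <- ncol(model$scores)
  cand <- order(-model$variance_explained)[seq_len(min(n_candidates, k))]
  subtype_var <- vapply(cand, function(j) {
    mu <- tapply(model$scores[use, j], labels[use], mean)
    stats::var(as.numeric(mu))
  }, numeric(1))
  cand[order(-subtype_var, -model$variance_explained[cand], cand)]
}
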