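# Independent oracles and small fixture builders used across the suite.

# Brute-force ssGSEA running sum: direct position-by-position enumeration of
# the two empirical CDFs, written without reference to the package internals.
# alpha = 0 only, no ties.
oracle_ssgsea_alpha0 <- function(expr, in_set) {
  stopifnot(!anyDuplicated(expr))
  ord <- order(expr, decreasing = TRUE)
  hits <- in_set[ord]
  n_in <- sum(in_set)
  n_out <- length(in_set) - n_in
  total <- 0
  seen_in <- 0
  seen_out <- 0
  for (i in seq_along(hits)) {
    if (hits[i]) seen_in <- seen_in + 1 else seen_out <- seen_out + 1
    total <- total + seen_in / n_in - seen_out / n_out
  }
  total
}

# lognorm-layer matrix from explicit values (bypassing the count chain) for
# unit tests of scoring operations
lognorm_em <- function(values, cell_ids = NULL, gene_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(cell_ids)) cell_ids <- rownames(values)
  if (is.null(gene_ids)) gene_ids <- colnames(values)
  if (is.null(cell_ids)) cell_ids <- paste0("c", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(values)))
  expression_matrix(values, cell_ids = cell_ids, gene_ids = gene_ids,
                    layer = "lognorm")
}

raw_em <- function(values, ...) {
  em <- lognorm_em(values, ...) # reuses the id defaulting
  expression_matrix(em$values, cell_ids = em$cell_ids,
                    gene_ids = em$gene_ids, layer = "raw")
}

# small, fast synthetic configuration for tests that only need structure,
# not the full default study conditions
small_config <- function(seed = 11, ...) {
  args <- list(
    n_cells_per_subtype = c(A = 60, A2 = 60, N = 60, P = 60, Y = 60),
    n_genes_background = 150, e_set_size = 40, m1_set_size = 20,
    m2_set_size = 20, sclc_sig_size = 30, overlap_genes = 8, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthetic_config, args)
}

# non-negative data with one dominant positive factor, so the centered
# leading eigenvector is itself non-negative, the constraint is inactive and
# the unconstrained SVD is a valid oracle for the non-negative fit
positive_factor_matrix <- function(n = 50, p = 20, n_factors = 3) {
  loads <- matrix(runif(p * n_factors, 0, 0.3), p, n_factors)
  loads[, 1] <- runif(p, 0.5, 1.5)
  scores <- cbind(rexp(n, rate = 1 / 3),
                  matrix(rexp(n * (n_factors - 1)), n))
  scores %*% t(loads) + matrix(runif(n * p, 0, 0.05), n)
}

leading_right_singular <- function(X) {
  v <- svd(sweep(X, 2, colMeans(X)), nu = 0, nv = 1)$v[, 1]
  if (sum(v) < 0) -v else v
}
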