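#' Mann-Whitney U test between two groups
#'
#' Rank-sum comparison with midrank tie handling. The reported `u` is the
#' U statistic of `x` (rank sum of `x` minus its minimum), so swapping the
#' groups maps `u` to `n1 * n2 - u`. Following the convention of the
#' subtype contrasts in this package, `alternative = "greater"` tests
#' whether `y` tends to be larger than `x` (and `"less"` the reverse). The
#' p-value comes from [stats::wilcox.test()], which enumerates the exact
#' null when the samples are small and tie-free and otherwise uses the
#' tie-corrected normal approximation.
#'
#' @param x,y numeric vectors, each non-empty.
#' @param alternative `"two.sided"` (default), `"greater"` (`y > x`) or
#'   `"less"` (`y < x`).
#' @return List with `u` (U statistic of `x`) and `p`.
#' @export
mw_test <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  p <- suppressWarnings(
    stats::wilcox.test(y, x, alternative = alternative, exact = NULL)$p.value
  )
  list(u = unname(u), p = p)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Step-up adjusted values in input order.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Classify mesenchymal genes into divergent M1/M2 programs
#'
#' For every mesenchymal signature gene present in the matrix, computes the
#' difference in mean log-normalized expression between the neuroendocrine
#' class (`n_class`, e.g. `"N"` or the merged `"A/N"`) and the `"Y"` class,
#' a two-sided Mann-Whitney p-value, and a Benjamini-Hochberg q-value
#' across the M set. Genes with `q < fdr_cut` are called `M1` when the
#' class difference is positive (higher in the NE class, the ZEB1-like
#' pattern) and `M2` when negative (higher in Y, the VIM-like pattern);
#' everything else is `unclassified`.
#'
#' @param em lognorm-layer [expression_matrix].
#' @param labels named character vector, cell_id -> subtype label.
#' @param m_set mesenchymal [gene_set]; genes absent from the matrix are
#'   skipped with a message.
#' @param n_class,y_class labels of the contrasted classes (defaults
#'   `"N"`, `"Y"`); each must have at least 3 cells.
#' @param fdr_cut FDR gate for the M1/M2 call (default 0.05).
#' @return `data.frame` with columns `gene`, `mean_diff`, `u_stat`, `p`,
#'   `q`, `m_class`.
#' @export
classify_m_genes <- function(em, labels, m_set, n_class = "N", y_class = "Y",
                             fdr_cut = 0.05) {
  .assert_layer(em, "lognorm", "classify_m_genes")
  stopifnot(inherits(m_set, "gene_set"))
  labels <- labels[!is.na(labels)]
  n_cells <- names(labels)[labels == n_class]
  y_cells <- names(labels)[labels == y_class]
  if (!length(n_cells)) stop("class '", n_class, "' absent from labels")
  if (!length(y_cells)) stop("class '", y_class, "' absent from labels")
  if (length(n_cells) < 3 || length(y_cells) < 3)
    stop("both classes need at least 3 cells")
  n_cells <- intersect(n_cells, em$cell_ids)
  y_cells <- intersect(y_cells, em$cell_ids)
  present <- m_set$genes[m_set$genes %in% toupper(em$gene_ids)]
  missing <- setdiff(m_set$genes, present)
  if (length(missing))
    message("classify_m_genes: skipping ", length(missing),
            " M genes absent from the matrix")
  if (!length(present)) stop("no M set genes present in the matrix")
  gidx <- match(present, toupper(em$gene_ids))
  xn <- em$values[n_cells, gidx, drop = FALSE]
  xy <- em$values[y_cells, gidx, drop = FALSE]
  stats_list <- lapply(seq_along(present), function(j)
    mw_test(xn[, j], xy[, j], alternative = "two.sided"))
  out <- data.frame(
    gene = em$gene_ids[gidx],
    mean_diff = colMeans(xn) - colMeans(xy),
    u_stat = vapply(stats_list, `[[`, numeric(1), "u"),
    p = vapply(stats_list, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE
  )
  out$q <- bh_adjust(out$p)
  out$m_class <- ifelse(out$q < fdr_cut & out$mean_diff > 0, "M1",
                        ifelse(out$q < fdr_cut & out$mean_diff < 0, "M2",
                               "unclassified"))
  rownames(out) <- NULL
  out
}

#' Pearson correlation of N-Y divergence across two datasets
#'
#' Correlates the per-gene N-minus-Y mean differences of two
#' [classify_m_genes()] tables over their shared genes — the cross-dataset
#' consistency check for the divergent mesenchymal programs.
#'
#' @param table_a,table_b `data.frame`s with columns `gene` and `mean_diff`.
#' @return List with `x_name`, `y_name`, `r` (Pearson), `p`, `n` (shared
#'   genes, at least 3).
#' @export
cross_dataset_correlation <- function(table_a, table_b) {
  stopifnot(all(c("gene", "mean_diff") %in% names(table_a)),
            all(c("gene", "mean_diff") %in% names(table_b)))
  shared <- intersect(toupper(table_a$gene), toupper(table_b$gene))
  if (length(shared) < 3)
    stop("need at least 3 shared genes; got ", length(shared))
  a <- table_a$mean_diff[match(shared, toupper(table_a$gene))]
  b <- table_b$mean_diff[match(shared, toupper(table_b$gene))]
  ct <- stats::cor.test(a, b, method = "pearson")
  list(x_name = "mean_diff_a", y_name = "mean_diff_b",
       r = unname(ct$estimate), p = ct$p.value, n = length(shared))
}

#' Cells positive for a marker gene
#'
#' Positivity is any detected transcript: log-normalized expression strictly
#' above `threshold` (default 0).
#'
#' @param em lognorm-layer [expression_matrix].
#' @param gene marker symbol (matched uppercased).
#' @param threshold positivity threshold on lognorm expression (default 0).
#' @return Character vector of positive cell IDs.
#' @export
marker_positive <- function(em, gene, threshold = 0) {
  .assert_layer(em, "lognorm", "marker_positive")
  j <- match(toupper(gene), toupper(em$gene_ids))
  if (is.na(j)) stop("marker gene '", gene, "' not in the matrix")
  em$cell_ids[em$values[, j] > threshold]
}

#' Spearman correlation between scores or gene expression, by stratum
#'
#' Correlates two per-cell quantities — each either a column of the score
#' table or a gene's log-normalized expression — within each requested cell
#' stratum (e.g. all cells, ASCL1-positive cells, untreated cells). Strata
#' with fewer than 3 cells are skipped with a message.
#'
#' @param scores `data.frame` with `cell_id` and score columns.
#' @param x,y score column names or gene symbols.
#' @param em optional lognorm [expression_matrix], required when `x` or `y`
#'   is a gene symbol.
#' @param strata named list of cell-ID vectors defining the strata; default
#'   a single `all` stratum of every scored cell.
#' @return `data.frame` with columns `x_name`, `y_name`, `stratum`, `sr`
#'   (Spearman), `p`, `n`.
#' @export
score_correlation <- function(scores, x, y, em = NULL, strata = NULL) {
  stopifnot(is.data.frame(scores), "cell_id" %in% names(scores))
  resolve <- function(nm) {
    if (nm %in% names(scores))
      return(stats::setNames(scores[[nm]], scores$cell_id))
    if (!is.null(em)) {
      j <- match(toupper(nm), toupper(em$gene_ids))
      if (!is.na(j)) {
        .assert_layer(em, "lognorm", "score_correlation")
        return(stats::setNames(em$values[, j], em$cell_ids))
      }
    }
    stop("'", nm, "' is neither a score column nor a matrix gene")
  }
  xv <- resolve(x)
  yv <- resolve(y)
  if (is.null(strata)) strata <- list(all = scores$cell_id)
  rows <- list()
  for (s in names(strata)) {
    ids <- intersect(strata[[s]], intersect(names(xv), names(yv)))
    if (length(ids) < 3) {
      message("score_correlation: stratum '", s, "' has ", length(ids),
              " cells (< 3); skipped")
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(xv[ids], yv[ids], method = "spearman"))
    rows[[s]] <- data.frame(x_name = x, y_name = y, stratum = s,
                            sr = unname(ct$estimate), p = ct$p.value,
                            n = length(ids), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(x_name = character(0), y_name = character(0),
                      stratum = character(0), sr = numeric(0), p = numeric(0),
                      n = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
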