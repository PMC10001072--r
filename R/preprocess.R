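#' Filter cells and genes by detection
#'
#' Standard first-pass QC: drop cells detecting fewer than `min_genes` genes
#' and genes detected in fewer than `min_cells` cells. Thresholds are
#' dataset-specific; the defaults follow common single-cell practice.
#'
#' @param em raw-layer [expression_matrix].
#' @param min_genes minimum detected genes per retained cell (default 200).
#' @param min_cells minimum cells per retained gene (default 3).
#' @return Filtered [expression_matrix]; counts of removed cells/genes are
#'   reported via `message()`.
#' @export
filter_cells <- function(em, min_genes = 200, min_cells = 3) {
  .assert_layer(em, "raw", "filter_cells")
  detected <- em$values > 0
  keep_cells <- rowSums(detected) >= min_genes
  keep_genes <- colSums(detected[keep_cells, , drop = FALSE]) >= min_cells
  message("filter_cells: kept ", sum(keep_cells), "/", length(keep_cells),
          " cells and ", sum(keep_genes), "/", length(keep_genes), " genes")
  expression_matrix(em$values[keep_cells, keep_genes, drop = FALSE],
                    layer = "raw")
}

#' Normalize per-cell totals
#'
#' Rescales each cell so its total equals `target_sum`; with
#' `target_sum = "auto"` the target is the median of the per-cell totals,
#' the convention of total-count normalization in single-cell toolkits.
#' Within-cell proportions are preserved exactly.
#'
#' @param em raw-layer [expression_matrix] with no all-zero cells.
#' @param target_sum positive number, or `"auto"` for the median total.
#' @return [expression_matrix] with layer `"normalized"`.
#' @export
normalize_total <- function(em, target_sum = "auto") {
  .assert_layer(em, "raw", "normalize_total")
  totals <- rowSums(em$values)
  zero <- totals == 0
  if (any(zero))
    stop("all-zero cells cannot be normalized: ",
         paste(em$cell_ids[zero], collapse = ", "))
  if (identical(target_sum, "auto")) {
    target_sum <- stats::median(totals)
  } else {
    stopifnot(is.numeric(target_sum), length(target_sum) == 1, target_sum > 0)
  }
  out <- em$values * (target_sum / totals)
  expression_matrix(out, cell_ids = em$cell_ids, gene_ids = em$gene_ids,
                    layer = "normalized")
}

#' log1p-transform normalized expression
#'
#' @param em normalized-layer [expression_matrix].
#' @return [expression_matrix] with elementwise `log(1 + x)`, layer
#'   `"lognorm"`.
#' @export
log1p_transform <- function(em) {
  .assert_layer(em, "normalized", "log1p_transform")
  if (any(em$values < 0)) stop("log1p_transform requires non-negative input")
  expression_matrix(log1p(em$values), cell_ids = em$cell_ids,
                    gene_ids = em$gene_ids, layer = "lognorm")
}

#' Standardize genes to zero mean and unit variance
#'
#' Uses the population (n-denominator) standard deviation, the common
#' single-cell scaling convention. Zero-variance genes are set to all-zero
#' rather than dropped, and values may be clipped symmetrically.
#'
#' @param em lognorm-layer [expression_matrix].
#' @param clip positive clip bound applied as `[-clip, clip]`, or `NULL` for
#'   no clipping. Default 10.
#' @return [expression_matrix] with layer `"scaled"`.
#' @export
scale_genes <- function(em, clip = 10) {
  .assert_layer(em, "lognorm", "scale_genes")
  n <- nrow(em$values)
  mu <- colMeans(em$values)
  sd_pop <- sqrt(colMeans(sweep(em$values, 2, mu)^2))
  out <- sweep(em$values, 2, mu)
  nz <- sd_pop > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, sd_pop[nz], "/")
  out[, !nz] <- 0
  if (!is.null(clip)) {
    stopifnot(is.numeric(clip), clip > 0)
    out <- pmin(pmax(out, -clip), clip)
  }
  expression_matrix(out, cell_ids = em$cell_ids, gene_ids = em$gene_ids,
                    layer = "scaled")
}

#' Select highly variable genes by binned normalized dispersion
#'
#' The classic dispersion flavor: per-gene mean and dispersion
#' (variance/mean) are computed on `expm1()` of the lognorm layer, genes are
#' binned into `n_bins` equal-frequency bins by mean, dispersions are
#' z-scored within bin, and genes pass when
#' `min_mean < mean < max_mean` and normalized dispersion `> min_disp`.
#'
#' @param em lognorm-layer [expression_matrix].
#' @param min_mean,max_mean open bounds on the per-gene mean (defaults
#'   0.0125 and 5).
#' @param min_disp threshold on the within-bin z-scored dispersion
#'   (default 0.8).
#' @param n_bins number of equal-frequency mean bins (default 20). With
#'   fewer genes than bins a single bin is used, with a message.
#' @return Character vector of selected gene IDs.
#' @export
select_hvg <- function(em, min_mean = 0.0125, max_mean = 5, min_disp = 0.8,
                       n_bins = 20) {
  .assert_layer(em, "lognorm", "select_hvg")
  x <- expm1(em$values)
  mu <- colMeans(x)
  v <- apply(x, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, NA_real_)
  if (ncol(x) < n_bins) {
    message("select_hvg: only ", ncol(x), " genes; using a single mean bin")
    n_bins <- 1
  }
  if (n_bins == 1) {
    bins <- rep(1L, length(mu))
  } else {
    qs <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
    bins <- if (length(qs) < 2) rep(1L, length(mu))
            else cut(mu, breaks = qs, include.lowest = TRUE, labels = FALSE)
  }
  disp_norm <- rep(NA_real_, length(disp))
  for (b in unique(bins)) {
    idx <- which(bins == b & !is.na(disp))
    if (!length(idx)) next
    m <- mean(disp[idx])
    s <- stats::sd(disp[idx])
    disp_norm[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - m) / s
  }
  keep <- !is.na(disp_norm) & mu > min_mean & mu < max_mean &
    disp_norm > min_disp
  em$gene_ids[keep]
}
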