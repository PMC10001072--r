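#' Run the EMT-spectrum pipeline end to end
#'
#' Orchestrates the full analysis on a dataset — by default a synthetic one
#' with planted ground truth — and writes a report directory:
#' preprocessing (total-count normalization, log1p), ssGSEA E/M scoring
#' (with an optional overlap-exclusion robustness rerun), nnPCA E/M scoring
#' with the two-criterion component ranking, archetype-specialist
#' subtyping via the stratified resampling enrichment test under Holm
#' control, M1/M2 mesenchymal divergence classification, and
#' subtype-score/E-score correlations stratified by ASCL1 positivity and
#' treatment.
#'
#' All randomness flows from the single `seed`: stage seeds are derived
#' from it by stable offsets, so a rerun with the same seed reproduces the
#' report bit for bit (timestamps aside).
#'
#' @param out_dir report directory (created if needed).
#' @param data optional dataset list as returned by [simulate_dataset()]
#'   (elements `expression`, `metadata`, `archetype_weights`,
#'   `ground_truth`); when `NULL` one is simulated from `config`.
#' @param config [synthetic_config()] used when `data` is `NULL`.
#' @param seed root seed for the resampling stages (default the config
#'   seed).
#' @param ssgsea_alpha ssGSEA rank-weight exponent (default 0.25).
#' @param B resamples per enrichment test (default 1000).
#' @param q_cut Holm-adjusted significance threshold (default 0.1).
#' @param fdr_cut BH threshold for the M1/M2 gate (default 0.05).
#' @param specialist_threshold archetype-weight cut for specialists
#'   (default 0.95).
#' @param robustness rerun ssGSEA after excluding the EMT/SCLC-signature
#'   overlap and report the before/after Spearman per axis (default TRUE).
#' @return Invisibly, a list with the in-memory results: `scores`,
#'   `enrichment`, `subtypes`, `specialists`, `mgenes`, `correlations`,
#'   `nnpca` (fitted E/M models and component ranking) and, when
#'   `robustness`, `robustness` (per-axis Spearman). The same tables are
#'   written to `out_dir` as `scores.tsv`, `enrichment.tsv`,
#'   `subtypes.tsv`, `mgenes.tsv`, `correlations.tsv` and `run.log`.
#' @export
run_pipeline <- function(out_dir, data = NULL, config = synthetic_config(),
                         seed = NULL, ssgsea_alpha = 0.25, B = 1000,
                         q_cut = 0.1, fdr_cut = 0.05,
                         specialist_threshold = 0.95, robustness = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(data)) data <- simulate_dataset(config)
  if (is.null(seed)) seed <- data$ground_truth$config$seed
  seed <- as.integer(seed)
  log_lines <- c(sprintf("emtspectrum %s", as.character(utils::packageVersion("emtspectrum"))),
                 sprintf("seed: %d", seed),
                 sprintf("config_hash: %s", .config_hash(data$ground_truth$config)),
                 sprintf("cells: %d  genes: %d", nrow(data$expression$values),
                         ncol(data$expression$values)))

  # preprocessing (stage order fixed: normalize -> log1p)
  em_norm <- normalize_total(data$expression)
  em_log <- log1p_transform(em_norm)
  gs <- data$ground_truth$gene_sets
  log_lines <- c(log_lines, "preprocessing: total-count normalization (median target), log1p")

  # ssGSEA E/M scores
  scores <- ssgsea_table(em_log, list(E_ssgsea = gs$E, M_ssgsea = gs$M),
                         alpha = ssgsea_alpha)

  robustness_tab <- NULL
  if (robustness) {
    e_excl <- exclude_overlap(gs$E, gs$SCLC_SIGNATURE)
    m_excl <- exclude_overlap(gs$M, gs$SCLC_SIGNATURE)
    after <- ssgsea_table(em_log, list(E_ssgsea_excl = e_excl,
                                       M_ssgsea_excl = m_excl),
                          alpha = ssgsea_alpha)
    scores$E_ssgsea_excl <- after$E_ssgsea_excl
    scores$M_ssgsea_excl <- after$M_ssgsea_excl
    robustness_tab <- data.frame(
      axis = c("E", "M"),
      spearman = c(stats::cor(scores$E_ssgsea, scores$E_ssgsea_excl,
                              method = "spearman"),
                   stats::cor(scores$M_ssgsea, scores$M_ssgsea_excl,
                              method = "spearman")))
    log_lines <- c(log_lines, sprintf(
      "robustness rerun: overlap excluded; Spearman E = %.4f, M = %.4f",
      robustness_tab$spearman[1], robustness_tab$spearman[2]))
  }

  # subtyping: specialists, bulk signature scores, resampling test
  specialists <- label_specialists(data$archetype_weights,
                                   specialist_threshold)
  sig_scores <- data.frame(cell_id = em_log$cell_ids,
                           stringsAsFactors = FALSE)
  for (s in names(gs$subtype_signatures)) {
    idx <- toupper(em_log$gene_ids) %in% gs$subtype_signatures[[s]]$genes
    sig_scores[[s]] <- rowMeans(em_log$values[, idx, drop = FALSE])
  }
  strata <- stats::setNames(data$metadata$time_point, data$metadata$cell_id)
  enrichment <- enrichment_table(sig_scores, specialists, strata = strata,
                                 B = B, seed = seed + 1000L, q_cut = q_cut)
  subtype_of_archetype <- assign_subtypes(enrichment, q_cut = q_cut)
  cell_subtype <- ifelse(is.na(specialists), NA_character_,
                         subtype_of_archetype[specialists])
  names(cell_subtype) <- names(specialists)
  log_lines <- c(log_lines,
                 sprintf("specialists: %d/%d cells at threshold %.2f",
                         sum(!is.na(specialists)), length(specialists),
                         specialist_threshold),
                 sprintf("archetype labels: %s",
                         paste(names(subtype_of_archetype),
                               subtype_of_archetype, sep = "=",
                               collapse = ", ")))

  # nnPCA E/M scores ranked by the two-criterion rule on specialist labels
  nn_e <- nnpca_fit(em_log, gs$E, n_components = 5, seed = seed + 2000L)
  nn_m <- nnpca_fit(em_log, gs$M, n_components = 5, seed = seed + 3000L)
  rank_e <- select_em_pcs(nn_e, cell_subtype[em_log$cell_ids])
  rank_m <- select_em_pcs(nn_m, cell_subtype[em_log$cell_ids])
  scores$E_nnpc1 <- nn_e$scores[, rank_e[1]]
  scores$M_nnpc1 <- nn_m$scores[, rank_m[1]]
  scores$M_nnpc2 <- if (length(rank_m) > 1) nn_m$scores[, rank_m[2]] else NA_real_
  log_lines <- c(log_lines, sprintf(
    "nnPCA: E component ranking %s (var %s); M component ranking %s (var %s)",
    paste(rank_e, collapse = ","),
    paste(signif(nn_e$variance_explained, 3), collapse = ","),
    paste(rank_m, collapse = ","),
    paste(signif(nn_m$variance_explained, 3), collapse = ",")))

  # M1/M2 divergence: N-class vs Y-class on specialist-labeled cells
  labels_for_contrast <- cell_subtype[!is.na(cell_subtype)]
  n_label <- .pick_class(labels_for_contrast, c("N", "A/N"))
  y_label <- .pick_class(labels_for_contrast, c("Y", "P/Y"))
  mgenes <- classify_m_genes(em_log, labels_for_contrast, gs$M,
                             n_class = n_label, y_class = y_label,
                             fdr_cut = fdr_cut)
  log_lines <- c(log_lines, sprintf(
    "M divergence: %s vs %s; %d M1, %d M2, %d unclassified",
    n_label, y_label, sum(mgenes$m_class == "M1"),
    sum(mgenes$m_class == "M2"), sum(mgenes$m_class == "unclassified")))

  # subtype-score vs E-score correlations, stratified
  aw <- data$archetype_weights
  for (a in aw$archetype_names)
    scores[[paste0(a, "_weight")]] <-
      aw$weights[match(scores$cell_id, aw$cell_ids), a]
  strata_list <- list(all = scores$cell_id)
  if ("ASCL1" %in% toupper(em_log$gene_ids))
    strata_list$ascl1_pos <- marker_positive(em_log, "ASCL1")
  for (tr in unique(data$metadata$treatment))
    strata_list[[tr]] <-
      data$metadata$cell_id[data$metadata$treatment == tr]
  corr_pairs <- list(c("A2_weight", "E_nnpc1"), c("A_weight", "E_nnpc1"),
                     c("A2_weight", "M_nnpc1"))
  corr_pairs <- Filter(function(p) all(p %in% names(scores)), corr_pairs)
  correlations <- do.call(rbind, lapply(corr_pairs, function(p)
    score_correlation(scores, p[1], p[2], em = em_log,
                      strata = strata_list)))

  # report
  subtypes_tab <- data.frame(cell_id = names(specialists),
                             archetype = unname(specialists),
                             subtype = unname(cell_subtype),
                             stringsAsFactors = FALSE)
  .write_report_tsv(scores, file.path(out_dir, "scores.tsv"))
  .write_report_tsv(enrichment, file.path(out_dir, "enrichment.tsv"))
  .write_report_tsv(subtypes_tab, file.path(out_dir, "subtypes.tsv"))
  .write_report_tsv(mgenes, file.path(out_dir, "mgenes.tsv"))
  .write_report_tsv(correlations, file.path(out_dir, "correlations.tsv"))
  if (!is.null(robustness_tab))
    .write_report_tsv(robustness_tab, file.path(out_dir, "robustness.tsv"))
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(scores = scores, enrichment = enrichment,
                 subtypes = subtypes_tab, specialists = specialists,
                 cell_subtype = cell_subtype, mgenes = mgenes,
                 correlations = correlations,
                 nnpca = list(E = nn_e, M = nn_m, rank_E = rank_e,
                              rank_M = rank_m),
                 robustness = robustness_tab, out_dir = out_dir))
}

.pick_class <- function(labels, candidates) {
  hit <- candidates[candidates %in% labels]
  if (!length(hit))
    stop("none of the classes ", paste(candidates, collapse = "/"),
         " present among subtype labels")
  hit[1]
}

.write_report_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(cfg[order(names(cfg))]), collapse = ""), f)
  unname(tools::md5sum(f))
}

#' Serialize an nnPCA model to JSON
#'
#' Writes loadings, scores metadata, variance explained and convergence
#' information; [read_nnpca_model()] restores the model.
#'
#' @param model an `nnpca_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_nnpca_model <- function(model, path) {
  stopifnot(inherits(model, "nnpca_model"))
  obj <- list(gene_ids = model$gene_ids,
              loadings = lapply(seq_len(ncol(model$loadings)),
                                function(j) unname(model$loadings[, j])),
              variance_explained = model$variance_explained,
              n_iter = model$n_iter, converged = model$converged,
              total_variance = model$total_variance)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an nnPCA model serialized by [write_nnpca_model()]
#'
#' @param path JSON path.
#' @return List with the stored fields (`loadings` as a genes x components
#'   matrix). Scores are not serialized; they are recomputable as `X w`.
#' @export
read_nnpca_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$loadings <- do.call(cbind, lapply(obj$loadings, as.numeric))
  rownames(obj$loadings) <- obj$gene_ids
  obj
}
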