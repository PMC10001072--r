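#' Configuration for the synthetic SCLC single-cell generator
#'
#' The defaults emulate the structure of the study system the pipeline is
#' built for: five SCLC subtype populations (A, A2, N, P, Y), a 232-gene
#' epithelial program, a 193-gene mesenchymal program split into divergent
#' M1 (96, ZEB1-like, high in A/N) and M2 (97, VIM-like, high in P/Y)
#' halves, a 105-gene subtype signature sharing 20 genes with the EMT sets
#' (10 epithelial in the A2 signature, 5 M1 in the N signature, 5 M2 in the
#' Y signature), negative-binomial UMI counts with lognormal library sizes,
#' per-cell archetype weights on the simplex, and time-point / treatment
#' covariates.
#'
#' @param n_cells_per_subtype named integer vector of cells per subtype.
#' @param n_genes_background number of unstructured background genes.
#' @param e_set_size,m1_set_size,m2_set_size program sizes (232, 96, 97).
#' @param sclc_sig_size total SCLC subtype-signature size (105).
#' @param overlap_genes genes shared between the subtype signature and the
#'   EMT sets (default 20).
#' @param effect_size planted log-scale mean shift (default 1.0).
#' @param nb_dispersion negative-binomial dispersion phi, with
#'   `var = mu + phi * mu^2` (default 0.4).
#' @param library_size_lognormal `c(mu, sigma)` of log library size
#'   (default `c(log(5000), 0.3)`).
#' @param specialist_fraction fraction of cells with a concentrated
#'   (> 0.95) archetype weight (default 0.7).
#' @param n_time_points number of time-point strata (default 3).
#' @param treatment_fraction fraction of treated cells (default 0.5).
#' @param treatment_effect added M2 latent shift in treated cells
#'   (default 0.5), emulating a treatment-induced mesenchymal drift.
#' @param latent_sd SD of the per-cell latent E/M1/M2 factors (default 0.3).
#' @param e_coupling loading of the latent epithelial factor on E genes and
#'   on the A2 archetype-weight tilt (default 0.7).
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_cells_per_subtype = c(A = 500, A2 = 500,
                                                     N = 500, P = 500,
                                                     Y = 500),
                             n_genes_background = 1000,
                             e_set_size = 232, m1_set_size = 96,
                             m2_set_size = 97, sclc_sig_size = 105,
                             overlap_genes = 20, effect_size = 1.0,
                             nb_dispersion = 0.4,
                             library_size_lognormal = c(mu = log(5000),
                                                        sigma = 0.3),
                             specialist_fraction = 0.7, n_time_points = 3,
                             treatment_fraction = 0.5, treatment_effect = 0.5,
                             latent_sd = 0.3, e_coupling = 0.7, seed = 7) {
  cfg <- list(n_cells_per_subtype = n_cells_per_subtype,
              n_genes_background = n_genes_background,
              e_set_size = e_set_size, m1_set_size = m1_set_size,
              m2_set_size = m2_set_size, sclc_sig_size = sclc_sig_size,
              overlap_genes = overlap_genes, effect_size = effect_size,
              nb_dispersion = nb_dispersion,
              library_size_lognormal = library_size_lognormal,
              specialist_fraction = specialist_fraction,
              n_time_points = n_time_points,
              treatment_fraction = treatment_fraction,
              treatment_effect = treatment_effect, latent_sd = latent_sd,
              e_coupling = e_coupling, seed = seed)
  if (is.null(names(cfg$n_cells_per_subtype)) ||
      any(cfg$n_cells_per_subtype < 1))
    stop("n_cells_per_subtype must be a named vector of positive counts")
  for (f in c("n_genes_background", "e_set_size", "m1_set_size",
              "m2_set_size", "sclc_sig_size", "n_time_points"))
    if (cfg[[f]] < 1) stop(f, " must be positive")
  for (f in c("specialist_fraction", "treatment_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (cfg$overlap_genes < 0 ||
      cfg$overlap_genes > min(cfg$sclc_sig_size,
                              cfg$e_set_size + cfg$m1_set_size +
                                cfg$m2_set_size))
    stop("overlap_genes out of range")
  structure(cfg, class = "synthetic_config")
}

# planted gene identities; a handful of canonical marker names are used so
# the synthetic data exercises the marker-based code paths
.synthetic_genes <- function(cfg) {
  e_genes <- c("CDH1", sprintf("EPI%04d", seq_len(cfg$e_set_size - 1)))
  m1_genes <- c("ZEB1", sprintf("MESA%04d", seq_len(cfg$m1_set_size - 1)))
  m2_genes <- c("VIM", sprintf("MESB%04d", seq_len(cfg$m2_set_size - 1)))
  # overlap split ~ 2:1:1 between E, M1 and M2, mirroring the default 10/5/5
  o_e <- min(ceiling(cfg$overlap_genes / 2), cfg$e_set_size)
  o_m1 <- min(floor((cfg$overlap_genes - o_e) / 2), cfg$m1_set_size)
  o_m2 <- min(cfg$overlap_genes - o_e - o_m1, cfg$m2_set_size)
  n_unique <- cfg$sclc_sig_size - o_e - o_m1 - o_m2
  sig_unique <- sprintf("SIG%04d", seq_len(n_unique))
  # subtype-specific signature blocks; overlap genes live in the signature
  # of the subtype where their program is active
  split_sizes <- rep(n_unique %/% 5, 5) +
    (seq_len(5) <= n_unique %% 5)
  names(split_sizes) <- c("A", "A2", "N", "P", "Y")
  blocks <- split(sig_unique, rep(names(split_sizes), split_sizes))
  sig_sets <- list(
    A = blocks$A,
    A2 = c(blocks$A2, e_genes[seq_len(o_e)]),
    N = c(blocks$N, m1_genes[seq_len(o_m1)]),
    P = blocks$P,
    Y = c(blocks$Y, m2_genes[seq_len(o_m2)])
  )
  bg_genes <- c("ASCL1", sprintf("BG%05d", seq_len(cfg$n_genes_background - 1)))
  list(e = e_genes, m1 = m1_genes, m2 = m2_genes, sig_unique = sig_unique,
       sig_sets = sig_sets, bg = bg_genes,
       all = c(e_genes, m1_genes, m2_genes, sig_unique, bg_genes))
}

#' Simulate a single-cell dataset with planted EMT and subtype structure
#'
#' Counts are negative binomial with subtype- and program-dependent means:
#' epithelial genes are shifted up in A2 (and mildly in A) and down in P/Y;
#' M1 genes up in A and N; M2 genes up in P and Y; each subtype's signature
#' genes up in that subtype; ASCL1 up in the neuroendocrine subtypes
#' (A, A2, N). A per-cell latent epithelial factor scales E-gene means
#' within the NE subtypes and tilts the A2 archetype weight, creating the
#' within-subtype A2-E coupling; treated cells get an extra M2 latent
#' shift. Library sizes are lognormal; cell totals follow them. Archetype
#' weights are concentrated (> 0.95) for the specialist fraction and
#' near-uniform Dirichlet for generalists.
#'
#' @param config a [synthetic_config()].
#' @return List with `expression` (raw [expression_matrix]), `metadata`
#'   (`data.frame`: cell_id, subtype_label, time_point, treatment,
#'   tumor_id), `archetype_weights` ([archetype_weights]) and
#'   `ground_truth` (list: `cell_subtype`, `gene_program`, `latent`,
#'   `gene_sets`, `config`).
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  genes <- .synthetic_genes(cfg)
  subtypes <- names(cfg$n_cells_per_subtype)
  n_cells <- sum(cfg$n_cells_per_subtype)
  n_genes <- length(genes$all)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(cfg$seed))

  cell_subtype <- rep(subtypes, cfg$n_cells_per_subtype)
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  names(cell_subtype) <- cell_ids

  # gene program membership
  gene_program <- stats::setNames(rep("background", n_genes), genes$all)
  gene_program[genes$e] <- "E"
  gene_program[genes$m1] <- "M1"
  gene_program[genes$m2] <- "M2"

  # baselines: signature/program genes moderately expressed, background
  # genes spread over a wide dynamic range
  is_program <- genes$all %in% c(genes$e, genes$m1, genes$m2,
                                 genes$sig_unique, "ASCL1")
  log_base <- ifelse(is_program,
                     stats::rnorm(n_genes, log(2), 0.4),
                     stats::rnorm(n_genes, log(0.3), 1.0))
  names(log_base) <- genes$all

  e <- cfg$effect_size
  shift <- matrix(0, length(subtypes), n_genes,
                  dimnames = list(subtypes, genes$all))
  ne_like <- intersect(c("A", "A2", "N"), subtypes)
  for (s in subtypes) {
    if (s == "A2") shift[s, genes$e] <- shift[s, genes$e] + e
    if (s == "A") shift[s, genes$e] <- shift[s, genes$e] + 0.4 * e
    if (s %in% c("P", "Y")) shift[s, genes$e] <- shift[s, genes$e] - 0.4 * e
    if (s %in% c("A", "N")) shift[s, genes$m1] <- shift[s, genes$m1] + e
    if (s %in% c("P", "Y")) shift[s, genes$m2] <- shift[s, genes$m2] + e
    if (s %in% names(genes$sig_sets))
      shift[s, genes$sig_sets[[s]]] <- shift[s, genes$sig_sets[[s]]] + e
    if (s %in% ne_like) shift[s, "ASCL1"] <- shift[s, "ASCL1"] + 1.5
  }

  # covariates and per-cell latent factors
  time_point <- sample(sprintf("T%d", seq_len(cfg$n_time_points)), n_cells,
                       replace = TRUE)
  treatment <- ifelse(stats::runif(n_cells) < cfg$treatment_fraction,
                      "treated", "untreated")
  f_e <- stats::rnorm(n_cells, 0, cfg$latent_sd)
  f_m1 <- stats::rnorm(n_cells, 0, cfg$latent_sd)
  f_m2 <- stats::rnorm(n_cells, 0, cfg$latent_sd) +
    ifelse(treatment == "treated", cfg$treatment_effect, 0)

  # log-scale mean per cell and gene
  log_mu <- matrix(log_base, n_cells, n_genes, byrow = TRUE)
  log_mu <- log_mu + shift[cell_subtype, , drop = FALSE]
  is_ne <- cell_subtype %in% ne_like
  e_idx <- which(genes$all %in% genes$e)
  m1_idx <- which(genes$all %in% genes$m1)
  m2_idx <- which(genes$all %in% genes$m2)
  log_mu[, e_idx] <- log_mu[, e_idx] + cfg$e_coupling * f_e * is_ne
  log_mu[, m1_idx] <- log_mu[, m1_idx] + 0.5 * f_m1
  log_mu[, m2_idx] <- log_mu[, m2_idx] + 0.5 * f_m2

  # library sizes and NB sampling
  lib <- exp(stats::rnorm(n_cells, cfg$library_size_lognormal[[1]],
                          cfg$library_size_lognormal[[2]]))
  rel <- exp(log_mu)
  mu_counts <- rel * (lib / rowSums(rel))
  counts <- matrix(
    stats::rnbinom(n_cells * n_genes, mu = as.vector(mu_counts),
                   size = 1 / cfg$nb_dispersion),
    n_cells, n_genes, dimnames = list(cell_ids, genes$all))

  # archetype weights: own-subtype coordinate concentrated for specialists;
  # generalists Dirichlet with an A2 tilt that follows the latent E factor
  k <- length(subtypes)
  is_specialist <- stats::runif(n_cells) < cfg$specialist_fraction
  w <- matrix(0, n_cells, k, dimnames = list(cell_ids, subtypes))
  own <- match(cell_subtype, subtypes)
  for (i in seq_len(n_cells)) {
    if (is_specialist[i]) {
      top <- stats::runif(1, 0.955, 0.995)
      if (k > 1) {
        restw <- stats::rgamma(k - 1, 1, 1)
        w[i, -own[i]] <- (1 - top) * restw / sum(restw)
        w[i, own[i]] <- top
      } else {
        w[i, own[i]] <- 1
      }
    } else {
      alpha <- rep(1.5, k)
      alpha[own[i]] <- 4
      if ("A2" %in% subtypes)
        alpha[match("A2", subtypes)] <-
          alpha[match("A2", subtypes)] * exp(cfg$e_coupling * f_e[i])
      g <- stats::rgamma(k, alpha, 1)
      w[i, ] <- g / sum(g)
    }
  }

  gene_sets <- list(
    E = gene_set("E", genes$e),
    M = gene_set("M", c(genes$m1, genes$m2)),
    M1 = gene_set("M1", genes$m1),
    M2 = gene_set("M2", genes$m2),
    SCLC_SIGNATURE = gene_set("SCLC_SIGNATURE",
                              unlist(genes$sig_sets, use.names = FALSE)),
    subtype_signatures = lapply(stats::setNames(nm = names(genes$sig_sets)),
                                function(s) gene_set(paste0("SIG_", s),
                                                     genes$sig_sets[[s]]))
  )

  list(
    expression = expression_matrix(counts, layer = "raw"),
    metadata = data.frame(cell_id = cell_ids, subtype_label = cell_subtype,
                          time_point = time_point, treatment = treatment,
                          tumor_id = "SIM1", stringsAsFactors = FALSE,
                          row.names = NULL),
    archetype_weights = archetype_weights(w),
    ground_truth = list(cell_subtype = cell_subtype,
                        gene_program = gene_program,
                        is_specialist = stats::setNames(is_specialist,
                                                        cell_ids),
                        latent = data.frame(cell_id = cell_ids, f_e = f_e,
                                            f_m1 = f_m1, f_m2 = f_m2,
                                            row.names = NULL),
                        gene_sets = gene_sets,
                        config = cfg)
  )
}

#' Write the planted gene sets of a simulation to a GMT file
#'
#' Emits the epithelial set, the combined mesenchymal set (M1 union M2),
#' the M1/M2 halves, the full SCLC subtype signature (including its
#' configured overlap with the EMT sets) and the per-subtype signature
#' blocks.
#'
#' @param gt the `ground_truth` element of a [simulate_dataset()] result.
#' @param path output GMT path.
#' @return `path`, invisibly.
#' @export
emit_gene_sets <- function(gt, path) {
  gs <- gt$gene_sets
  sets <- c(list(gs$E, gs$M, gs$M1, gs$M2, gs$SCLC_SIGNATURE),
            unname(gs$subtype_signatures))
  write_gmt(sets, path)
}
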