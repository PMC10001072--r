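#' Per-cell archetype weights on the simplex
#'
#' Each cell carries a weight per archetype; weights are non-negative and
#' sum to 1 (within `1e-6`), as produced by archetypal analysis of the
#' expression space. Archetype-vertex discovery itself is upstream of this
#' package; weights are inputs here.
#'
#' @param weights numeric matrix, cells x archetypes.
#' @param cell_ids cell identifiers (default rownames).
#' @param archetype_names archetype names (default colnames).
#' @return An object of class `archetype_weights`.
#' @export
archetype_weights <- function(weights, cell_ids = rownames(weights),
                              archetype_names = colnames(weights)) {
  weights <- as.matrix(weights)
  if (is.null(cell_ids)) stop("cell_ids are required")
  if (is.null(archetype_names))
    archetype_names <- paste0("archetype", seq_len(ncol(weights)))
  .check_unique(cell_ids, "cell")
  if (any(weights < 0)) stop("archetype weights must be non-negative")
  bad <- abs(rowSums(weights) - 1) > 1e-6
  if (any(bad))
    stop("archetype weights must sum to 1 per cell; offending cells: ",
         paste(utils::head(cell_ids[bad], 5), collapse = ", "))
  dimnames(weights) <- list(cell_ids, archetype_names)
  structure(list(weights = weights, cell_ids = as.character(cell_ids),
                 archetype_names = as.character(archetype_names)),
            class = "archetype_weights")
}

#' Label archetype specialists
#'
#' A cell is a specialist of an archetype when its weight for that archetype
#' strictly exceeds `threshold`; all other cells are generalists
#' (`NA` label). With `threshold > 0.5` at most one archetype can qualify,
#' which keeps the assignment unique; lower thresholds are rejected.
#'
#' @param aw an [archetype_weights] object.
#' @param threshold strict lower bound on the winning weight (default 0.95).
#' @return Named character vector, cell_id -> archetype name, `NA` for
#'   generalists.
#' @export
label_specialists <- function(aw, threshold = 0.95) {
  stopifnot(inherits(aw, "archetype_weights"))
  if (threshold <= 0.5)
    stop("threshold must exceed 0.5 for the specialist label to be unique")
  top <- max.col(aw$weights, ties.method = "first")
  top_w <- aw$weights[cbind(seq_len(nrow(aw$weights)), top)]
  out <- ifelse(top_w > threshold, aw$archetype_names[top], NA_character_)
  names(out) <- aw$cell_ids
  out
}

#' Stratified resampling test for archetype-signature enrichment
#'
#' Tests whether the specialists of one archetype have a higher mean
#' signature score than random cells. With `n_a` specialists of mean score
#' `m`, `B` resamples of size `n_a` are drawn with replacement from the
#' non-specialist cells — allocated evenly across strata (e.g. time points)
#' so sparsely sampled strata are represented, with the remainder going to
#' the largest strata — and the p-value is the fraction of resampled means
#' at or above `m`.
#'
#' Counting ties as "at or above" (the default) keeps degenerate constant
#' data at p = 1; `strict_greater = TRUE` counts only strictly larger null
#' means. `smoothing = TRUE` reports `(count + 1) / (B + 1)` instead of
#' `count / B`.
#'
#' @param scores named numeric vector of per-cell signature scores.
#' @param specialists character vector of specialist cell IDs (non-empty,
#'   subset of `names(scores)`).
#' @param strata optional named factor/character of stratum per cell; every
#'   stratum containing cells must also contain non-specialists.
#' @param B number of resamples (default 1000; fewer than 100 warns).
#' @param seed integer seed for the resampling stream.
#' @param strict_greater count only null means strictly above `m`.
#' @param smoothing add-one smoothing of the p-value.
#' @param signature,archetype optional names recorded in the result.
#' @return An object of class `enrichment_result`: list with `archetype`,
#'   `signature`, `m`, `n_a`, `null_means` (length `B`), `p`.
#' @export
enrichment_test <- function(scores, specialists, strata = NULL, B = 1000,
                            seed = 1, strict_greater = FALSE,
                            smoothing = FALSE, signature = NA_character_,
                            archetype = NA_character_) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  specialists <- as.character(specialists)
  if (!length(specialists)) stop("specialists must be non-empty")
  if (!all(specialists %in% names(scores)))
    stop("specialists not found in scores: ",
         paste(setdiff(specialists, names(scores)), collapse = ", "))
  if (B < 100) warning("B = ", B, " resamples is low; p-values will be coarse")
  n_a <- length(specialists)
  m <- mean(scores[specialists])
  rest <- setdiff(names(scores), specialists)
  if (!length(rest)) stop("no non-specialist cells to resample from")

  if (is.null(strata)) {
    pools <- list(all = scores[rest])
    alloc <- c(all = n_a)
  } else {
    if (is.null(names(strata))) stop("strata must be named by cell_id")
    strata <- as.character(strata)[match(names(scores), names(strata))]
    names(strata) <- names(scores)
    used <- sort(unique(strata[!is.na(strata)]))
    pools <- lapply(used, function(s) scores[rest[strata[rest] %in% s]])
    names(pools) <- used
    empty <- used[vapply(pools, length, integer(1)) == 0]
    if (length(empty))
      stop("stratum with no non-specialist cells: ",
           paste(empty, collapse = ", "))
    # even allocation; remainder to the largest strata, then name order
    base <- n_a %/% length(used)
    alloc <- stats::setNames(rep(base, length(used)), used)
    rem <- n_a %% length(used)
    if (rem > 0) {
      ord <- order(-vapply(pools, length, integer(1)), names(pools))
      alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1
    }
  }

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  # one stratified draw per replicate, vectorized per stratum
  sums <- numeric(B)
  for (s in names(pools)) {
    k <- alloc[[s]]
    if (k == 0) next
    draws <- matrix(sample(pools[[s]], B * k, replace = TRUE), nrow = k)
    sums <- sums + colSums(draws)
  }
  null_means <- sums / n_a
  count <- if (strict_greater) sum(null_means > m) else sum(null_means >= m)
  p <- if (smoothing) (count + 1) / (B + 1) else count / B
  structure(list(archetype = archetype, signature = signature, m = m,
                 n_a = n_a, null_means = null_means, p = p),
            class = "enrichment_result")
}

#' Holm (step-down Bonferroni) family-wise error adjustment
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in input order, monotone in sorted order and
#'   capped at 1.
#' @export
holm_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "holm")
}

#' Assign SCLC subtype labels to archetypes from enrichment results
#'
#' Each archetype is labeled with every signature whose Holm-adjusted
#' q-value falls below `q_cut`; multiple significant signatures produce a
#' merged class (e.g. `"A/N"`, `"P/Y"`, named in the canonical subtype
#' order A, A2, N, P, Y), and an archetype with no significant signature is
#' `"unassigned"`.
#'
#' @param results `data.frame` with columns `archetype`, `signature`, `q`
#'   (as produced by [enrichment_table()]), covering every pair.
#' @param q_cut significance cut on the adjusted q-value (default 0.1).
#' @return Named character vector, archetype -> subtype label.
#' @export
assign_subtypes <- function(results, q_cut = 0.1) {
  stopifnot(is.data.frame(results),
            all(c("archetype", "signature", "q") %in% names(results)))
  canonical <- c("A", "A2", "N", "P", "Y")
  out <- vapply(unique(results$archetype), function(a) {
    sig <- results$signature[results$archetype == a & results$q < q_cut]
    if (!length(sig)) return("unassigned")
    in_canon <- sig[order(match(sig, canonical), sig)]
    paste(in_canon, collapse = "/")
  }, character(1))
  names(out) <- unique(results$archetype)
  out
}

#' Run the enrichment test over every archetype-signature pair
#'
#' Applies [enrichment_test()] for each archetype's specialists against each
#' signature score column, then Holm-adjusts the p-values across the whole
#' family of tests.
#'
#' @param score_table `data.frame` with `cell_id` plus one numeric column per
#'   signature.
#' @param specialist_labels named vector from [label_specialists()].
#' @param strata optional named stratum vector (see [enrichment_test()]).
#' @inheritParams enrichment_test
#' @param q_cut significance threshold applied to the Holm-adjusted values.
#' @return `data.frame` with columns `archetype`, `signature`, `m`, `n_a`,
#'   `p`, `q`, `significant`.
#' @export
enrichment_table <- function(score_table, specialist_labels, strata = NULL,
                             B = 1000, seed = 1, strict_greater = FALSE,
                             smoothing = FALSE, q_cut = 0.1) {
  stopifnot(is.data.frame(score_table), "cell_id" %in% names(score_table))
  sigs <- setdiff(names(score_table), "cell_id")
  archetypes <- sort(unique(stats::na.omit(specialist_labels)))
  rows <- list()
  i <- 0
  for (a in archetypes) {
    spec <- names(specialist_labels)[!is.na(specialist_labels) &
                                       specialist_labels == a]
    for (s in sigs) {
      i <- i + 1
      sc <- stats::setNames(score_table[[s]], score_table$cell_id)
      res <- enrichment_test(sc, spec, strata = strata, B = B,
                             seed = as.integer(seed) + i,
                             strict_greater = strict_greater,
                             smoothing = smoothing, signature = s,
                             archetype = a)
      rows[[i]] <- data.frame(archetype = a, signature = s, m = res$m,
                              n_a = res$n_a, p = res$p,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- holm_adjust(out$p)
  out$significant <- out$q < q_cut
  out
}
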