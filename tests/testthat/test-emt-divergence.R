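test_that("Mann-Whitney matches exact enumeration and symmetry", {
  # fully separated 3 vs 3: one arrangement of 20 is as extreme
  res <- mw_test(c(1, 2, 3), c(4, 5, 6), alternative = "greater")
  expect_equal(res$p, 0.05)
  expect_equal(res$u, 0)

  # identical samples: two-sided p = 1 with midranks
  same <- mw_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)

  # swapping groups flips U to n1*n2 - U
  set.seed(40)
  x <- rnorm(6); y <- rnorm(9)
  expect_equal(mw_test(x, y)$u, length(x) * length(y) - mw_test(y, x)$u)
  expect_equal(mw_test(x, y)$p, mw_test(y, x)$p)
  expect_error(mw_test(numeric(0), 1), "non-empty")
})

test_that("BH adjustment reproduces the step-up closed form", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_adjust(0.07), 0.07)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
})

test_that("planted M1/M2 programs are recovered without sign errors", {
  set.seed(41)
  n <- 200 # cells per class
  genes <- c(paste0("m1_", 1:40), paste0("m2_", 1:40), paste0("null_", 1:20))
  shift <- c(rep(1, 40), rep(-1, 40), rep(0, 20))
  vals <- sapply(seq_along(genes), function(j)
    c(rnorm(n, 2 + shift[j]), rnorm(n, 2)))
  vals <- pmax(vals, 0)
  em <- lognorm_em(vals, cell_ids = paste0("c", 1:(2 * n)), gene_ids = genes)
  labels <- setNames(rep(c("N", "Y"), each = n), em$cell_ids)
  tab <- classify_m_genes(em, labels, gene_set("M", genes),
                          n_class = "N", y_class = "Y", fdr_cut = 0.05)
  m1_called <- tab$gene[tab$m_class == "M1"]
  m2_called <- tab$gene[tab$m_class == "M2"]
  expect_gte(mean(paste0("m1_", 1:40) %in% m1_called), 0.9)
  expect_gte(mean(paste0("m2_", 1:40) %in% m2_called), 0.9)
  # zero sign errors: no planted gene called with the wrong sign
  expect_length(intersect(m1_called, paste0("m2_", 1:40)), 0)
  expect_length(intersect(m2_called, paste0("m1_", 1:40)), 0)
  # M1/M2 are disjoint subsets of the M set by construction
  expect_length(intersect(m1_called, m2_called), 0)
  expect_true(all(c(m1_called, m2_called) %in% genes))
  # invariants of the gated classes
  expect_true(all(tab$mean_diff[tab$m_class == "M1"] > 0))
  expect_true(all(tab$mean_diff[tab$m_class == "M2"] < 0))
  expect_true(all(tab$q[tab$m_class != "unclassified"] < 0.05))
})

test_that("identical distributions stay unclassified and absent classes error", {
  set.seed(42)
  em <- lognorm_em(matrix(rexp(600), 60, 10))
  labels <- setNames(rep(c("N", "Y"), 30), em$cell_ids)
  tab <- classify_m_genes(em, labels, gene_set("M", em$gene_ids))
  expect_true(all(tab$m_class == "unclassified"))
  expect_error(classify_m_genes(em, labels, gene_set("M", em$gene_ids),
                                n_class = "A/N"), "absent")
})

test_that("null data keep the false M-classification fraction near the FDR", {
  set.seed(43)
  frac <- replicate(100, {
    em <- lognorm_em(matrix(rgamma(80 * 30, shape = 4, rate = 2), 80, 30))
    labels <- setNames(rep(c("N", "Y"), each = 40), em$cell_ids)
    tab <- classify_m_genes(em, labels, gene_set("M", em$gene_ids))
    mean(tab$m_class != "unclassified")
  })
  expect_lte(mean(frac), 0.05 + 0.03)
})

test_that("cross-dataset divergence correlation behaves at the extremes", {
  tab <- data.frame(gene = paste0("g", 1:10), mean_diff = rnorm(10))
  expect_equal(cross_dataset_correlation(tab, tab)$r, 1)
  neg <- tab; neg$mean_diff <- -neg$mean_diff
  expect_equal(cross_dataset_correlation(tab, neg)$r, -1)
  expect_error(cross_dataset_correlation(tab[1:2, ], tab), "at least 3")

  # shared planted structure with independent noise stays strongly positive
  set.seed(44)
  truth <- c(rep(1, 40), rep(-1, 40))
  a <- data.frame(gene = paste0("g", 1:80), mean_diff = truth + rnorm(80, 0, 0.5))
  b <- data.frame(gene = paste0("g", 1:80), mean_diff = truth + rnorm(80, 0, 0.5))
  expect_gte(cross_dataset_correlation(a, b)$r, 0.5)
})

test_that("Spearman correlations are monotone-invariant and stratifiable", {
  set.seed(45)
  sc <- data.frame(cell_id = paste0("c", 1:50), a = rnorm(50))
  sc$b <- exp(2 * sc$a)       # monotone increasing transform
  sc$c <- -sc$a
  expect_equal(score_correlation(sc, "a", "b")$sr, 1)
  expect_equal(score_correlation(sc, "a", "c")$sr, -1)

  # gene-expression resolution and marker-defined strata
  em <- lognorm_em(cbind(ASCL1 = c(rep(0, 10), rexp(40)),
                         GENE2 = rnorm(50)^2),
                   cell_ids = sc$cell_id)
  pos <- marker_positive(em, "Ascl1")
  expect_length(pos, 40)
  out <- score_correlation(sc, "a", "ASCL1", em = em,
                           strata = list(all = sc$cell_id, ascl1 = pos))
  expect_identical(out$stratum, c("all", "ascl1"))
  expect_identical(out$n, c(50L, 40L))

  # undersized strata are skipped with a message
  expect_message(
    tiny <- score_correlation(sc, "a", "b",
                              strata = list(small = sc$cell_id[1:2])),
    "skipped")
  expect_identical(nrow(tiny), 0L)
  expect_error(score_correlation(sc, "a", "missing"), "neither")
})

test_that("a shared latent factor yields the A2-over-A epithelial coupling", {
  set.seed(46)
  n <- 400
  latent <- rnorm(n)
  sc <- data.frame(
    cell_id = paste0("c", seq_len(n)),
    A2 = 0.7 * latent + sqrt(1 - 0.49) * rnorm(n),
    A = rnorm(n),
    E = 0.7 * latent + sqrt(1 - 0.49) * rnorm(n))
  a2_e <- score_correlation(sc, "A2", "E")$sr
  a_e <- score_correlation(sc, "A", "E")$sr
  expect_gt(a2_e, 0)
  expect_gt(a2_e, a_e)
})
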