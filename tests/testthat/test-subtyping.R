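make_weights <- function(w) {
  archetype_weights(w, cell_ids = paste0("c", seq_len(nrow(w))),
                    archetype_names = paste0("arch", seq_len(ncol(w))))
}

test_that("specialist labeling uses a strict threshold and unique winners", {
  aw <- make_weights(rbind(c(0.97, 0.02, 0.01),
                           c(0.5, 0.5, 0.0),
                           c(0.95, 0.04, 0.01),
                           c(0.02, 0.96, 0.02)))
  lab <- label_specialists(aw, threshold = 0.95)
  expect_identical(unname(lab), c("arch1", NA, NA, "arch2"))
  # 0.95 exactly is NOT a specialist: the bound is strict
  expect_true(is.na(lab[["c3"]]))
  expect_error(label_specialists(aw, threshold = 0.5), "exceed 0.5")
})

test_that("archetype weight invariants are enforced", {
  expect_error(make_weights(rbind(c(0.6, 0.3))), "sum to 1")
  expect_error(make_weights(rbind(c(1.2, -0.2))), "non-negative")
})

test_that("enrichment test handles separated and degenerate score patterns", {
  scores <- setNames(c(10, 9, 8, seq(0.1, 0.9, length.out = 27)),
                     paste0("c", 1:30))
  spec <- c("c1", "c2", "c3")
  res <- enrichment_test(scores, spec, B = 500, seed = 5)
  expect_equal(res$p, 0) # no resampled mean can reach the specialist mean
  expect_equal(res$n_a, 3)
  expect_equal(res$m, 9)
  expect_length(res$null_means, 500)

  # constant scores: every null mean ties m, >= counting gives p = 1,
  # the strict reading gives p = 0
  flat <- setNames(rep(2, 20), paste0("c", 1:20))
  expect_equal(enrichment_test(flat, c("c1", "c2"), B = 200, seed = 1)$p, 1)
  expect_equal(enrichment_test(flat, c("c1", "c2"), B = 200, seed = 1,
                               strict_greater = TRUE)$p, 0)
  # add-one smoothing
  expect_equal(enrichment_test(flat, c("c1", "c2"), B = 200, seed = 1,
                               smoothing = TRUE)$p, 1)
  expect_equal(enrichment_test(flat, c("c1", "c2"), B = 200, seed = 1,
                               strict_greater = TRUE, smoothing = TRUE)$p,
               1 / 201)
})

test_that("identical seeds reproduce the null distribution exactly", {
  set.seed(99)
  scores <- setNames(rnorm(100), paste0("c", 1:100))
  strata <- setNames(rep(c("T1", "T2", "T3"), length.out = 100),
                     names(scores))
  a <- enrichment_test(scores, paste0("c", 1:7), strata = strata, B = 300,
                       seed = 42)
  b <- enrichment_test(scores, paste0("c", 1:7), strata = strata, B = 300,
                       seed = 42)
  expect_identical(a$null_means, b$null_means)
  expect_identical(a$p, b$p)
  c <- enrichment_test(scores, paste0("c", 1:7), strata = strata, B = 300,
                       seed = 43)
  expect_false(identical(a$null_means, c$null_means))
})

test_that("stratified resampling demands non-specialists in every stratum", {
  scores <- setNames(rnorm(10), paste0("c", 1:10))
  strata <- setNames(c(rep("T1", 8), "T2", "T2"), names(scores))
  expect_error(
    enrichment_test(scores, c("c9", "c10"), strata = strata, B = 100,
                    seed = 1),
    "T2")
  expect_warning(
    enrichment_test(scores, "c1", B = 50, seed = 1), "low")
})

test_that("Holm adjustment reproduces the step-down closed form", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(1, 1, 1)), c(1, 1, 1))
  p <- c(0.3, 0.001, 0.2)
  expect_true(all(holm_adjust(p) >= p))
})

test_that("subtype assignment merges multi-label archetypes canonically", {
  res <- data.frame(
    archetype = rep(c("arch1", "arch2", "arch3"), each = 3),
    signature = rep(c("A", "N", "A2"), 3),
    q = c(0.01, 0.02, 0.5,   # arch1: A and N
          0.5, 0.9, 0.04,    # arch2: A2 only
          0.2, 0.5, 0.9))    # arch3: nothing
  lab <- assign_subtypes(res, q_cut = 0.1)
  expect_identical(lab[["arch1"]], "A/N")
  expect_identical(lab[["arch2"]], "A2")
  expect_identical(lab[["arch3"]], "unassigned")
})

test_that("planted specialist enrichment is recovered across the test family", {
  # specialists shifted by one pooled SD must reach q < 0.1 with B = 1000
  set.seed(7)
  n <- 240
  ids <- paste0("c", seq_len(n))
  specialists <- setNames(rep(NA_character_, n), ids)
  specialists[1:30] <- "arch1"
  specialists[31:60] <- "arch2"
  tab <- data.frame(cell_id = ids,
                    sigA = rnorm(n) + (specialists %in% "arch1") * 1,
                    sigB = rnorm(n) + (specialists %in% "arch2") * 1)
  tab$sigA[is.na(specialists)] <- rnorm(sum(is.na(specialists)))
  res <- enrichment_table(tab, specialists, B = 1000, seed = 3)
  expect_true(all(res$q[res$archetype == "arch1" & res$signature == "sigA"] < 0.1))
  expect_true(all(res$q[res$archetype == "arch2" & res$signature == "sigB"] < 0.1))
  expect_false(any(res$significant[res$archetype == "arch1" &
                                     res$signature == "sigB"]))
})
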