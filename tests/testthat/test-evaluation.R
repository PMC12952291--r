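test_that("split arithmetic follows the half-split rule", {
  pool <- sprintf("G%04d", 1:5997)
  annotated <- pool[1:12]
  plan <- make_split(annotated, pool, "jia", seed = 42)
  expect_length(plan$reference, 6)
  expect_length(plan$comparison_a, 6)
  expect_length(plan$comparison_b, 5985)
  # searching for 6 relevant among 5991 candidates
  expect_equal(length(plan$comparison_a) + length(plan$comparison_b), 5991)
  expect_length(intersect(plan$reference, plan$comparison_a), 0)
  expect_length(intersect(plan$comparison_b, annotated), 0)

  odd <- make_split(pool[1:5], pool, "odd", seed = 1)
  expect_length(odd$reference, 3)
  expect_length(odd$comparison_a, 2)

  expect_identical(make_split(annotated, pool, "jia", 42),
                   make_split(annotated, pool, "jia", 42))
  expect_error(make_split(pool[1], pool, "one", 1), "at least 2")
})

test_that("imbalance subsampling draws exactly ratio * |A| series", {
  pool <- sprintf("B%03d", 1:200)
  expect_length(subsample_imbalance(pool, 6, 1, seed = 1), 6)
  expect_length(subsample_imbalance(pool, 6, 10, seed = 1), 60)
  expect_identical(subsample_imbalance(pool, 6, "all", seed = 1), pool)
  expect_identical(subsample_imbalance(pool, 6, 10, 7),
                   subsample_imbalance(pool, 6, 10, 7))
  expect_error(subsample_imbalance(pool, 6, 50, seed = 1), "only")
})

test_that("average precision matches hand-worked and closed-form cases", {
  expect_equal(precision_recall_auc(c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(precision_recall_auc(c(TRUE, FALSE, TRUE)), (1 + 2 / 3) / 2)
  for (m in c(3, 7, 12)) {
    one_last <- c(rep(FALSE, m - 1), TRUE)
    expect_equal(precision_recall_auc(one_last), 1 / m)
  }
  expect_error(precision_recall_auc(c(FALSE, FALSE)), "no relevant")
  expect_error(precision_recall_auc(c(TRUE, TRUE)), "no irrelevant")
  expect_error(precision_recall_auc(c(TRUE, NA, FALSE)), "known")
})

test_that("average precision equals the brute-force oracle on random patterns", {
  withr::with_seed(99, {
    for (i in 1:50) {
      n <- sample(2:20, 1)
      l <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (!any(l)) l[sample(n, 1)] <- TRUE
      if (all(l)) l[sample(n, 1)] <- FALSE
      expect_equal(precision_recall_auc(l), ap_bruteforce(l))
    }
  })
})

test_that("recall at n counts the top-n relevant fraction and is monotone", {
  l <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(recall_at_n(l, 2), 0.5)
  expect_equal(recall_at_n(l, 0), 0)
  expect_equal(recall_at_n(l, 4), 1)
  expect_equal(recall_at_n(l, 100), 1) # beyond list length: full recall
  withr::with_seed(8, {
    l <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    curve <- recall_at_n(l, 1:40)
    expect_true(all(diff(curve) >= 0))
  })
})

test_that("median rank aggregation uses average-rank ties across conditions", {
  res <- tibble::tibble(
    condition = rep(c("c1", "c2"), each = 2),
    backend_id = rep(c("m1", "m2"), 2),
    auprc = c(0.9, 0.5, 0.5, 0.9)
  )
  tab <- median_rank_table(res)
  expect_equal(tab$median_rank, c(1.5, 1.5))

  dom <- res; dom$auprc <- c(0.9, 0.5, 0.9, 0.5)
  tab2 <- median_rank_table(dom)
  expect_equal(tab2$median_rank[tab2$backend_id == "m1"], 1)
  expect_equal(tab2$median_rank[tab2$backend_id == "m2"], 2)

  tied <- res; tied$auprc <- c(0.7, 0.7, 0.9, 0.5)
  tab3 <- median_rank_table(tied)
  expect_equal(sort(tab3$median_rank), c(1.25, 1.75))

  expect_error(median_rank_table(res[-1, ]), "c1/m1")
})

test_that("the benchmark runs the full factorial deterministically", {
  cfg <- synthetic_config(n_conditions = 2, series_per_condition = 6,
                          n_distractors = 30, condition_token_rate = 1,
                          cross_condition_overlap = 0, seed = 21)
  s <- generate_corpus(cfg)
  b <- run_benchmark(s, backends = c("word_overlap", "bm25"),
                     ratios = list(1, "all"), chunking = c(FALSE, TRUE),
                     seed = 5)
  expect_equal(nrow(b), 2 * 2 * 2 * 2)
  b2 <- run_benchmark(s, backends = c("word_overlap", "bm25"),
                      ratios = list(1, "all"), chunking = c(FALSE, TRUE),
                      seed = 5)
  expect_identical(tidy(b), tidy(b2))
  # disjoint vocabularies: word overlap separates perfectly at ratio 1
  expect_true(all(b$auprc[b$backend_id == "word_overlap"] > 0.9))
  expect_error(
    run_benchmark(s, backends = "word_overlap", conditions = "no_such"),
    "no_such"
  )
})

test_that("added irrelevant candidates cannot raise AUPRC (imbalance degradation)", {
  withr::with_seed(31, {
    rel_scores <- runif(5, 0.4, 0.6)
    irr_base <- runif(20)
    aucs <- vapply(c(20, 100, 400), function(n_irr) {
      irr <- c(irr_base, runif(n_irr - 20))
      l <- c(rep(TRUE, 5), rep(FALSE, n_irr))[order(c(rel_scores, irr),
                                                    decreasing = TRUE)]
      precision_recall_auc(l)
    }, numeric(1))
    expect_true(all(diff(aucs) <= 0))
  })
})
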