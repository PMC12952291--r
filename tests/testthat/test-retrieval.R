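test_that("cosine similarity matches hand evaluation and degenerate rules", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2))
  expect_equal(cosine_similarity(c(0, 0), c(1, 1)), 0)
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "dimension")
})

test_that("mean embedding is the element-wise mean with contract checks", {
  expect_equal(mean_embedding(list(c(2, 0), c(0, 2))), c(1, 1))
  expect_equal(mean_embedding(list(c(3, 4))), c(3, 4))
  expect_equal(mean_embedding(list(c(1, -2), c(-1, 2))), c(0, 0))
  expect_error(mean_embedding(list()), "empty")
  expect_error(mean_embedding(list(c(1, 2), c(1, 2, 3))), "mixed")
})

ranking_fixture <- function(seed = 11) {
  cfg <- synthetic_config(n_conditions = 2, series_per_condition = 6,
                          n_distractors = 20, condition_token_rate = 1,
                          cross_condition_overlap = 0, seed = seed)
  generate_corpus(cfg)
}

test_that("a candidate identical to the reference document tops a vector ranking", {
  s <- ranking_fixture()
  dup <- s[1, ]
  dup$accession <- "GSE99990"
  corpus <- dplyr::bind_rows(s, dup)
  r <- rank_by_reference(corpus, reference = "GSE00001", backend_id = "hashed_tfidf")
  expect_equal(r$accession[1], "GSE99990")
  expect_equal(r$score[1], 1, tolerance = 1e-12)
})

test_that("relevant candidates outrank distractors when vocabularies are disjoint", {
  s <- ranking_fixture()
  ref <- s$accession[1:3]
  r <- rank_by_reference(s, ref, "word_overlap", condition = "condition_01")
  scores_rel <- r$score[r$relevant]
  scores_irr <- r$score[!r$relevant]
  expect_gt(min(scores_rel), max(scores_irr))
})

test_that("ties break by ascending accession and order is input-invariant", {
  s <- ranking_fixture()
  ref <- s$accession[1:3]
  r1 <- rank_by_reference(s, ref, "word_overlap", condition = "condition_01")
  perm <- withr::with_seed(5, s[sample(nrow(s)), ])
  r2 <- rank_by_reference(perm, ref, "word_overlap", condition = "condition_01")
  expect_equal(r1$accession, r2$accession)
  # distractors all score 0 under word overlap: their block must be sorted
  zero_block <- r1$accession[r1$score == 0]
  expect_equal(zero_block, sort(zero_block))
})

test_that("ranking with external vectors is invariant to per-vector rescaling", {
  s <- ranking_fixture()
  accs <- s$accession
  vecs <- withr::with_seed(3, matrix(rnorm(length(accs) * 8), ncol = 8,
                                     dimnames = list(accs, NULL)))
  scaled <- vecs * withr::with_seed(4, runif(length(accs), 0.1, 9))
  ref <- accs[1:3]
  r1 <- rank_by_reference(s, ref, "external:toy", vectors = vecs)
  # rescaling candidates must not change the order; the reference mean is
  # direction-only up to candidate-side cosine, so rescale candidates only
  scaled[ref, ] <- vecs[ref, ]
  r2 <- rank_by_reference(s, ref, "external:toy", vectors = scaled)
  expect_equal(r1$accession, r2$accession)
  expect_equal(r1$score, r2$score, tolerance = 1e-12)
})

test_that("empty-text candidates are kept with score zero and flagged", {
  s <- ranking_fixture()
  # a candidate whose text is all stop words cleans to empty under the
  # word_overlap default policy
  s$title[5] <- "the of and"
  s$summary[5] <- ""
  s$overall_design[5] <- ""
  r <- rank_by_reference(s, s$accession[1:2], "word_overlap")
  row <- r[r$accession == s$accession[5], ]
  expect_true(row$flagged)
  expect_equal(row$score, 0)
})

test_that("reference validation errors name the offenders", {
  s <- ranking_fixture()
  expect_error(rank_by_reference(s, character(0), "word_overlap"), "empty")
  expect_error(rank_by_reference(s, c("GSE00001", "GSEnope"), "word_overlap"),
               "GSEnope")
  expect_error(rank_by_reference(s, s$accession, "word_overlap"), "candidate")
  expect_error(rank_by_reference(s, s$accession[1], "no_such_backend"),
               "unknown backend")
})

test_that("adding a pooled token to a candidate never lowers its overlap numerator", {
  s <- ranking_fixture()
  ref <- s$accession[1:3]
  pool <- unique(unlist(clean_corpus(s[s$accession %in% ref, ],
                                     default_policy("word_overlap"))$tokens))
  cand <- s[s$accession == s$accession[10], ]
  base_tokens <- clean_corpus(cand, default_policy("word_overlap"))$tokens[[1]]
  base_inter <- length(intersect(unique(base_tokens), pool))
  aug_inter <- length(intersect(unique(c(base_tokens, pool[1])), pool))
  expect_gte(aug_inter, base_inter)
})
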