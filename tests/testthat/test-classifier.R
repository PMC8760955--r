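# independent oracles -------------------------------------------------------

# exhaustive Youden's J over a dense cutpoint sweep (score grid plus all
# observed scores), strict rule score > tau
oracle_max_yjs <- function(scores, labels) {
  taus <- sort(unique(c(0, 1, scores, seq(0, 1, by = 0.001))))
  best <- -Inf
  for (tau in taus) {
    sens <- mean(scores[labels == 1] > tau)
    spec <- mean(scores[labels == 0] <= tau)
    best <- max(best, sens + spec - 1)
  }
  best
}

# O(n^2) pairwise AUC, ties counting one half
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# ---------------------------------------------------------------------------

test_that("split_dataset honours fractions, stratification and determinism", {
  labels <- rep(c("a", "b"), each = 5)
  parts <- split_dataset(labels, seed = 4)
  expect_equal(lengths(parts)[c("train", "validation", "test")],
               c(train = 8L, validation = 1L, test = 1L))
  expect_equal(sort(unname(unlist(parts))), 1:10)  # disjoint and exhaustive

  parts2 <- split_dataset(labels, seed = 4)
  expect_identical(parts, parts2)

  # stratification within one record of the global proportions
  labels3 <- rep(c("x", "y"), times = c(70, 30))
  p3 <- split_dataset(labels3, seed = 9)
  for (part in p3) {
    n_x <- sum(labels3[part] == "x")
    expect_lte(abs(n_x - 0.7 * length(part)), 1)
  }
  expect_error(split_dataset(labels, fractions = c(0.5, 0.2, 0.2)),
               "summing to 1")
})

test_that("training separates the synthetic classes and respects contracts", {
  b <- small_heavy_bench()
  m <- b$models$V1
  train_idx <- b$parts$train
  pos <- b$reps[train_idx][b$is_human[train_idx] &
                           b$v_gene[train_idx] == "V1"]
  neg <- b$reps[train_idx][!b$is_human[train_idx]]
  sp <- score_sequences(m, pos)
  sn <- score_sequences(m, neg)
  expect_true(all(sp >= 0 & sp <= 1) && all(sn >= 0 & sn <= 1))
  expect_gt(min(sp), max(sn))  # separable world: training scores separate

  # held-out germlines order correctly
  g <- make_default_germlines()
  expect_gt(score_sequences(m, germline_as_sequence(g$human_heavy_V1)),
            score_sequences(m, germline_as_sequence(g$mouse_heavy_V1)))

  # scoring is deterministic for a fixed model
  expect_identical(score_sequences(m, b$reps[1:20]),
                   score_sequences(m, b$reps[1:20]))

  expect_error(train_model(pos, list()), "non-empty")
  expect_error(train_model(pos[1:3], small_light_bench()$kappa[1:3]),
               "share a chain")
  # n_estimators = 1 is legal and scores stay in [0, 1]
  m1 <- train_model(pos[1:20], neg[1:20], n_estimators = 1, seed = 1)
  s1 <- score_sequences(m1, b$reps[1:10])
  expect_true(all(s1 >= 0 & s1 <= 1))
})

test_that("YJS calibration equals the exhaustive-cutpoint oracle", {
  # separable toy case: smallest candidate cutpoint in the optimal interval
  res <- yjs_threshold(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(res$yjs, 1)
  expect_equal(res$sensitivity + res$specificity - 1, res$yjs)
  expect_equal(res$threshold, 0.5)  # midpoints: 0.15, 0.5, 0.85

  set.seed(42)
  for (rep in 1:20) {
    n <- 50
    scores <- round(runif(n), 2)  # duplicates force tie handling
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    res <- yjs_threshold(scores, labels)
    expect_equal(res$yjs, oracle_max_yjs(scores, labels), tolerance = 1e-12)
    # reported stats are consistent with the returned threshold
    expect_equal(res$sensitivity,
                 mean(scores[labels == 1] > res$threshold))
    expect_equal(res$specificity,
                 mean(scores[labels == 0] <= res$threshold))
  }
  expect_error(yjs_threshold(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("rank-statistic AUC equals the pairwise oracle and behaves at the ends", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  set.seed(7)
  for (rep in 1:15) {
    n <- sample(10:100, 1)
    scores <- round(runif(n), 1)  # heavy ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
  # permutation null: shuffled labels give AUC ~ 0.5
  set.seed(8)
  scores <- runif(2000)
  labels <- sample(rep(0:1, 1000))
  expect_lt(abs(roc_auc(scores, labels) - 0.5), 0.05)
  expect_error(roc_auc(c(0.5, 0.6), c(1, 1)), "both classes")
})

test_that("classify_sequence applies the strict any-model rule", {
  b <- small_heavy_bench()
  models <- b$models
  g <- make_default_germlines()
  human <- germline_as_sequence(g$human_heavy_V3)
  mouse <- germline_as_sequence(g$mouse_heavy_V1)
  rh <- classify_sequence(models, human)
  rm_ <- classify_sequence(models, mouse)
  expect_true(rh$is_human)
  expect_false(rm_$is_human)
  expect_equal(rh$best_v_gene, "V3")
  # boundary: a score exactly at tau is not human (strict inequality)
  fake <- rh
  fake$scores[] <- rh$thresholds
  expect_false(any(fake$scores > fake$thresholds))
  expect_error(classify_sequence(models, small_light_bench()$kappa[[1]]),
               "chain mismatch")
})

test_that("paired VH/VL classification is a conjunction", {
  mk_report <- function(chain, human) {
    structure(list(id = "r", chain = chain, scores = c(V1 = 0.9),
                   thresholds = c(V1 = if (human) 0.5 else 0.95),
                   best_v_gene = "V1", best_score = 0.9, is_human = human),
              class = "score_report")
  }
  expect_true(classify_pair(mk_report("heavy", TRUE),
                            mk_report("kappa", TRUE)))
  # a light chain falling short of tau sinks the pair
  expect_false(classify_pair(mk_report("heavy", TRUE),
                             mk_report("kappa", FALSE)))
  expect_false(classify_pair(mk_report("heavy", FALSE),
                             mk_report("lambda", FALSE)))
  expect_error(classify_pair(mk_report("heavy", TRUE),
                             mk_report("heavy", TRUE)),
               "one heavy and one light")
})

test_that("kappa/lambda chain-type model routes held-out light chains", {
  lb <- small_light_bench()
  for (s in lb$kappa_holdout) {
    expect_equal(classify_chain_type(lb$chain_type, s), "kappa")
  }
  for (s in lb$lambda_holdout) {
    expect_equal(classify_chain_type(lb$chain_type, s), "lambda")
  }
  expect_error(classify_chain_type(lb$chain_type, toy_heavy()),
               "light chains only")
})

test_that("feature importances are normalized and concentrate on signature positions", {
  b <- small_heavy_bench()
  m <- b$models$V1
  expect_equal(sum(m$forest$importance), 1, tolerance = 1e-9)
  top <- feature_importance(m, top_k = 12)
  expect_equal(nrow(top), 12L)
  expect_true(all(diff(top$importance) <= 0))
  sig <- signature_positions_for("heavy")
  expect_gte(sum(top$position %in% sig), 8L)
  # frequencies are real corpus frequencies in [0, 1]
  expect_true(all(top$freq_positives >= 0 & top$freq_positives <= 1))
  expect_true(all(top$freq_negatives >= 0 & top$freq_negatives <= 1))
  # discriminative features live mostly in the framework
  top10 <- feature_importance(m, top_k = 10)
  expect_gt(mean(grepl("^FR", top10$region)), 0.5)
  expect_error(feature_importance(m, top_k = 0), "top_k")
})
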