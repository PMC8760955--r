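# set-intersection oracle for the overlap metrics
oracle_overlap <- function(tool, exp, groups = NULL) {
  hits <- 0L
  grp <- function(aa) {
    for (g in names(groups)) if (aa %in% groups[[g]]) return(g)
    NA_character_
  }
  for (i in seq_len(nrow(tool))) {
    j <- which(exp$position == tool$position[i])
    if (length(j) == 0L) next
    same <- exp$to[j] == tool$to[i]
    similar <- !is.null(groups) &&
      identical(grp(exp$to[j]), grp(tool$to[i]))
    if (same || similar) hits <- hits + 1L
  }
  floor(100 * hits / nrow(tool) + 0.5)
}

random_mutation_set <- function(n, positions) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pos <- sample(positions, n)
  from <- sample(aa, n, replace = TRUE)
  to <- vapply(from, function(f) sample(setdiff(aa, f), 1), "")
  mutation_set(pos, from, to)
}

test_that("diff_sequences extracts framework final-state diffs", {
  g <- make_default_germlines()
  pre <- germline_as_sequence(g$mouse_heavy_V1, id = "pre")
  expect_equal(nrow(diff_sequences(pre, pre)), 0L)

  one <- substitute_residue(pre, "45", if (residue_at(pre, "45") == "A")
    "S" else "A")
  d <- diff_sequences(pre, one)
  expect_equal(d$position, "45")
  expect_equal(d$from, residue_at(pre, "45"))

  # CDR-only differences yield an empty set
  cdr_pos <- pre$positions[!is_framework(pre$positions)][1]
  cdr_mut <- substitute_residue(pre, cdr_pos,
                                if (residue_at(pre, cdr_pos) == "A") "S"
                                else "A")
  expect_equal(nrow(diff_sequences(pre, cdr_mut)), 0L)

  kap <- germline_as_sequence(make_default_germlines()$human_kappa_KV1)
  expect_error(diff_sequences(pre, kap), "chain mismatch")
})

test_that("mutation_set enforces framework-only, no duplicates, from != to", {
  expect_error(mutation_set("30", "A", "S"), "framework")
  expect_error(mutation_set("45", "A", "A"), "from == to")
  expect_error(mutation_set(c("45", "45"), c("A", "S"), c("S", "T")),
               "per position")
  expect_equal(nrow(mutation_set(character(), character(), character())), 0L)
})

test_that("overlap metrics match printed single-case values", {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  fr_pos <- as.character(c(1:9, 11:26, 39:55, 66:80))
  # 16 tool mutations; 14 match experiment identically or within a group
  tool_pos <- fr_pos[1:16]
  tool <- mutation_set(tool_pos, rep("A", 16),
                       c(rep("S", 10), rep("L", 4), rep("K", 2)))
  exp <- mutation_set(fr_pos[1:39], rep("G", 39),
                      c(rep("S", 10),      # identical matches
                        rep("V", 4),       # L vs V: same hydrophobic group
                        rep("D", 2),       # K vs D: no group match
                        rep("S", 23)))     # extra experimental mutations
  expect_equal(adjusted_overlap_ratio(tool, exp), 88)  # 14/16
  expect_equal(overlap_ratio(tool, exp), 63)           # 10/16 -> 62.5 -> 63
  expect_equal(mutation_ratio(tool, exp), 41)          # 16/39
  # a 20-vs-23 chain
  t2 <- mutation_set(fr_pos[1:20], rep("A", 20), rep("S", 20))
  e2 <- mutation_set(fr_pos[1:23], rep("A", 23), rep("S", 23))
  expect_equal(mutation_ratio(t2, e2), 87)

  expect_equal(overlap_ratio(tool, tool), 100)
  expect_equal(adjusted_overlap_ratio(tool, tool), 100)
  disjoint <- mutation_set(fr_pos[30:35], rep("A", 6), rep("S", 6))
  expect_equal(overlap_ratio(tool, disjoint), 0)
  expect_equal(adjusted_overlap_ratio(tool, disjoint), 0)
  empty <- mutation_set(character(), character(), character())
  expect_error(overlap_ratio(empty, exp), "undefined")
  expect_error(mutation_ratio(tool, empty), "undefined")
})

test_that("OR/AOR agree with the set-intersection oracle; AOR >= OR always", {
  groups <- default_similarity_groups()
  fr_pos <- as.character(c(1:9, 11:26, 39:55, 66:104, 118:128))
  set.seed(33)
  for (rep_ in 1:25) {
    tool <- random_mutation_set(sample(3:20, 1), fr_pos)
    exp <- random_mutation_set(sample(3:30, 1), fr_pos)
    or_ <- overlap_ratio(tool, exp)
    aor <- adjusted_overlap_ratio(tool, exp, groups)
    expect_equal(or_, oracle_overlap(tool, exp))
    expect_equal(aor, oracle_overlap(tool, exp, groups))
    expect_gte(aor, or_)
    expect_equal(mutation_ratio(tool, exp),
                 floor(100 * nrow(tool) / nrow(exp) + 0.5))
  }
})

test_that("similarity groups must partition the alphabet", {
  bad <- default_similarity_groups()
  bad$polar <- setdiff(bad$polar, "C")
  t1 <- mutation_set("45", "A", "S")
  expect_error(adjusted_overlap_ratio(t1, t1, bad), "partition")
})

test_that("aggregate_reports reproduces means and medians with half-up rounding", {
  df <- data.frame(or = c(50, 75), aor = c(57, 88), mutation_ratio = c(56, 41))
  ag <- aggregate_reports(df)
  expect_equal(ag["mean", "or"], 63)  # 62.5 rounds half-up
  expect_equal(ag["median", "aor"], 73)  # 72.5 rounds half-up
  one <- aggregate_reports(data.frame(or = 68, aor = 77, mutation_ratio = 59))
  expect_equal(unlist(one["mean", ]), unlist(one["median", ]))
  expect_error(aggregate_reports(data.frame()), "no reports")
})

test_that("random baseline: bounds, empty experiment, count guard, determinism", {
  fr_pos <- as.character(1:5)
  mutable <- setNames(rep("A", 5), fr_pos)
  rb <- random_baseline(
    mutation_set(fr_pos, rep("G", 5), rep("S", 5)), mutable, n_tool = 1,
    reps = 50, seed = 2)
  expect_true(rb$or >= 0 && rb$or <= 100)
  expect_gte(rb$aor, rb$or)
  rb2 <- random_baseline(
    mutation_set(fr_pos, rep("G", 5), rep("S", 5)), mutable, n_tool = 1,
    reps = 50, seed = 2)
  expect_identical(rb, rb2)
  empty <- mutation_set(character(), character(), character())
  rb0 <- random_baseline(empty, mutable, n_tool = 2, reps = 20, seed = 3)
  expect_equal(rb0$or, 0)
  expect_equal(rb0$aor, 0)
  expect_error(random_baseline(empty, mutable, n_tool = 6, reps = 5),
               "exceeds")
})

test_that("ada_correlation: collinear, permutation null, Pearson identity", {
  collinear <- data.frame(score = c(0.1, 0.5, 0.9),
                          ada_percent = c(90, 50, 10))
  expect_equal(ada_correlation(collinear), 1)

  set.seed(12)
  records <- data.frame(score = runif(200),
                        ada_percent = runif(200, 0, 100))
  r2 <- ada_correlation(records)
  expect_lt(r2, 0.05)  # permutation null ~ 0
  expect_equal(r2, cor(records$score, records$ada_percent)^2,
               tolerance = 1e-12)

  expect_error(ada_correlation(collinear[1:2, ]), "at least 3")
  expect_error(ada_correlation(
    data.frame(score = rep(0.5, 5), ada_percent = 1:5)), "degenerate")
})

test_that("positional category accounting", {
  fr_pos <- as.character(c(1:9, 11:26))
  sets <- list(mutation_set(fr_pos[1:4], rep("A", 4), rep("S", 4)),
               mutation_set(fr_pos[5:6], rep("A", 2), rep("S", 2)))
  far <- as.character(66:70)
  st <- positional_category_stats(sets, far)
  expect_equal(st$counts, c(0L, 0L))
  all_cat <- positional_category_stats(sets, fr_pos)
  expect_equal(all_cat$counts, c(4L, 2L))
  expect_equal(all_cat$mean_count, 3)
  # category-restricted OR with matching experimental sets
  st2 <- positional_category_stats(sets, fr_pos, exp_sets = sets)
  expect_equal(st2$category_or, 100)
  expect_error(positional_category_stats(sets, character()), "empty")
  expect_error(positional_category_stats(sets, "30"), "framework")
})
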