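# Mutual information, mRMR ranking, SFS wrapper and comparator rankers.

test_that("quantile discretization yields near-equal bins", {
  expect_identical(discretize(1:9, 3), rep(0:2, each = 3))
  expect_identical(discretize(rep(5, 7)), integer(7))
  set.seed(2)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    b <- sample(2:5, 1)
    bins <- discretize(rnorm(n), b)
    counts <- table(bins)
    expect_lte(max(counts) - min(counts), 1)
    expect_identical(sort(unique(bins)), 0:(b - 1))
  }
})

test_that("mutual information matches closed forms and the oracle", {
  # independent uniform columns with exactly uniform joint: MI = 0
  a <- rep(0:2, times = 3)
  b <- rep(0:2, each = 3)
  expect_equal(mutual_info(a, b), 0, tolerance = 1e-12)
  # identical balanced binary columns: MI = H = ln 2
  x <- rep(0:1, 50)
  expect_equal(mutual_info(x, x), log(2), tolerance = 1e-12)
  set.seed(14)
  for (i in 1:20) {
    n <- sample(20:120, 1)
    a <- sample(0:3, n, replace = TRUE)
    b <- sample(0:2, n, replace = TRUE)
    expect_equal(mutual_info(a, b), mi_brute(a, b), tolerance = 1e-12)
    expect_gte(mutual_info(a, b), -1e-12)
  }
  expect_error(mutual_info(1:3, 1:4), "equal length")
})

test_that("mRMR ranks relevance first and penalizes redundancy", {
  tab <- generate_matrix_table(n = 250, p = 12, planted = 1, effect = 2,
                               seed = 5)
  ranking <- mrmr_rank(tab)
  expect_identical(ranking[1], "f001")
  # first pick is always the marginal-MI argmax
  disc <- apply(tab$rows, 2, discretize)
  rel <- apply(disc, 2, mutual_info, b = tab$labels)
  expect_identical(ranking[1], names(which.max(rel)))
  # an exact duplicate of the top feature ranks below an independent,
  # weaker informative feature
  rows <- cbind(tab$rows[, 1:6], dup = tab$rows[, 1])
  rows[, 2] <- rows[, 2] + 0.8 * tab$labels   # weaker signal, independent
  sch <- feature_schema(c(sprintf("f%03d", 1:6), "dup"), rep("conventional", 7))
  tab2 <- feature_table(rows, tab$labels, tab$groups, sch)
  r2 <- mrmr_rank(tab2)
  expect_lt(match("f002", r2), match("dup", r2))
  expect_error(mrmr_rank(feature_table(matrix(numeric(0), 0, 0), integer(0),
                                       character(0),
                                       feature_schema(character(0),
                                                      character(0)))),
               "empty")
})

test_that("greedy mRMR trace equals brute-force greedy recomputation", {
  tab <- generate_matrix_table(n = 120, p = 6, planted = 2, seed = 7)
  ranking <- mrmr_rank(tab)
  # independent greedy MID recomputation
  disc <- apply(tab$rows, 2, discretize)
  rel <- apply(disc, 2, mutual_info, b = tab$labels)
  chosen <- integer(0)
  remaining <- 1:6
  for (step in 1:6) {
    best <- NA
    best_score <- -Inf
    for (j in remaining) {
      red <- if (length(chosen)) {
        mean(sapply(chosen, function(s) mutual_info(disc[, j], disc[, s])))
      } else 0
      sc <- rel[j] - red
      if (sc > best_score + 1e-15) {
        best_score <- sc
        best <- j
      }
    }
    chosen <- c(chosen, best)
    remaining <- setdiff(remaining, best)
  }
  expect_identical(ranking, colnames(tab$rows)[chosen])
})

test_that("SFS grows only while the objective improves", {
  # one perfectly predictive feature placed first: subset of size 1
  set.seed(30)
  n <- 120
  labels <- rep(0:1, each = n / 2)
  rows <- cbind(perfect = labels + rnorm(n, 0, 1e-3),
                matrix(rnorm(n * 4), n, 4))
  colnames(rows) <- c("perfect", paste0("noise", 1:4))
  tab <- feature_table(rows, labels, rep(c("g1", "g2"), n / 2),
                       feature_schema(colnames(rows), rep("conventional", 5)))
  res <- sfs(tab, colnames(rows), cv_folds = 5, seed = 2)
  expect_identical(res$selected_subset, "perfect")
  # running-best trace is non-decreasing
  expect_true(all(diff(res$objective_trace) >= 0))
  # pure noise: the subset only grows on strict objective improvements, and
  # the walk stops within `patience` steps of the last improvement
  tab_noise <- generate_matrix_table(n = 100, p = 8, planted = 0, seed = 3)
  res_n <- sfs(tab_noise, colnames(tab_noise$rows), cv_folds = 5,
               patience = 3, seed = 2)
  tr <- res_n$objective_trace
  n_improvements <- 1L + sum(diff(tr) > 0)
  expect_identical(length(res_n$selected_subset), n_improvements)
  last_improvement <- max(which(tr == max(tr))[1], 1L)
  expect_lte(length(tr), last_improvement + 3L)
})

test_that("two-step mRMR-SFS recovers planted features and is deterministic", {
  hits <- numeric(6)
  for (s in 1:6) {
    tab <- generate_matrix_table(n = 300, p = 30, planted = 5, effect = 1,
                                 seed = 100 + s)
    res <- mrmr_sfs(tab, cv_folds = 5, seed = s)
    hits[s] <- length(intersect(res$selected_subset, attr(tab, "planted"))) / 5
  }
  expect_gte(median(hits), 0.8)
  tab <- generate_matrix_table(n = 200, p = 15, planted = 3, seed = 9)
  r1 <- mrmr_sfs(tab, cv_folds = 5, seed = 4)
  r2 <- mrmr_sfs(tab, cv_folds = 5, seed = 4)
  expect_identical(r1, r2)
})

test_that("comparator rankers return full deterministic permutations", {
  tab <- generate_matrix_table(n = 150, p = 12, planted = 3, effect = 1.5,
                               seed = 6)
  for (m in c("rf_importance", "svm_rfe")) {
    r <- comparator_rank(tab, m, seed = 1)
    expect_setequal(r, colnames(tab$rows))
    expect_identical(r, comparator_rank(tab, m, seed = 1))
  }
  # planted features land in the top quartile of the RF ranking
  r <- comparator_rank(tab, "rf_importance", seed = 1)
  expect_true(all(match(attr(tab, "planted"), r) <= 6))
  expect_error(comparator_rank(tab, "pca"), "arg")
})
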