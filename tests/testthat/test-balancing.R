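# SMOTE synthesis, Tomek links, SMOTE-Tomek and comparator samplers.

test_that("single-sample synthesis interpolates (or reflects) correctly", {
  x <- c(0, 0)
  xn <- c(1, 1)
  expect_equal(smote_synthesize(x, xn, 0.5), c(0.5, 0.5))
  expect_equal(smote_synthesize(x, xn, 0.5, sign = "reflect"), c(-0.5, -0.5))
  # identical points are a fixed point for any u
  expect_equal(smote_synthesize(xn, xn, 0.73), xn)
  # continuity at u -> 0
  expect_equal(smote_synthesize(x, xn, 1e-12), x, tolerance = 1e-10)
  expect_error(smote_synthesize(c(1, 2), c(1, 2, 3), 0.5), "width")
  expect_error(smote_synthesize(x, xn, 1), "u must")
})

test_that("SMOTE balances 102:179 training counts to exactly 1:1", {
  tb <- generate_matrix_table(n = 281, p = 8, planted = 2, seed = 3)
  labels <- c(rep(1L, 102), rep(0L, 179))
  out <- smote(tb$rows, labels, seed = 74)
  expect_identical(sum(out$labels == 1L), 179L)
  expect_identical(sum(out$labels == 0L), 179L)
  # majority untouched, originals first and unmodified
  expect_identical(out$rows[1:281, ], tb$rows)
  expect_identical(out$provenance[1:281], rep("original", 281))
  expect_identical(unique(out$labels[out$provenance == "synthetic"]), 1L)
  # already balanced input: nothing synthesized
  bal <- smote(tb$rows[1:40, ], rep(c(0L, 1L), 20), seed = 1)
  expect_identical(sum(bal$provenance == "synthetic"), 0L)
  expect_error(smote(tb$rows, c(1L, rep(0L, 280))), "fewer than 2")
})

test_that("synthetic rows are convex combinations of minority pairs", {
  cl <- two_cluster_table(n_pos = 15, n_neg = 40)
  out <- smote(cl$rows, cl$labels, seed = 9)
  minority <- cl$rows[cl$labels == 1L, , drop = FALSE]
  synth <- out$rows[out$provenance == "synthetic", , drop = FALSE]
  for (i in seq_len(nrow(synth))) {
    s <- synth[i, ]
    found <- FALSE
    for (a in seq_len(nrow(minority))) {
      for (b in seq_len(nrow(minority))) {
        if (a == b) next
        d <- minority[b, ] - minority[a, ]
        t_hat <- sum((s - minority[a, ]) * d) / sum(d * d)
        resid <- s - (minority[a, ] + t_hat * d)
        if (max(abs(resid)) < 1e-8 && t_hat > -1e-12 && t_hat < 1 + 1e-12) {
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    expect_true(found)
  }
})

test_that("Tomek links match the all-pairs brute-force oracle", {
  # interleaved opposite-class pair forms exactly one link
  rows <- rbind(c(0, 0), c(0.1, 0), c(5, 5), c(9, 9))
  labels <- c(0L, 1L, 0L, 0L)
  links <- tomek_links(rows, labels)
  expect_identical(nrow(links), 1L)
  expect_identical(as.vector(links[1, ]), c(1L, 2L))
  # well-separated clusters: no links
  cl <- two_cluster_table(sep = 30)
  expect_identical(nrow(tomek_links(cl$rows, cl$labels)), 0L)
  # random instances vs oracle
  set.seed(19)
  for (i in 1:8) {
    n <- 30
    rows <- matrix(rnorm(n * 2), n, 2)
    labels <- rbinom(n, 1, 0.4)
    expect_identical(unname(tomek_links(rows, labels)),
                     unname(tomek_brute(rows, labels)))
  }
})

test_that("SMOTE-Tomek removes exactly the majority link members", {
  cl <- two_cluster_table(n_pos = 25, n_neg = 60, sep = 1.2, seed = 12)
  out <- smote_tomek(cl$rows, cl$labels, seed = 74)
  after_smote <- attr(out, "counts_after_smote")
  after_clean <- attr(out, "counts_after_cleaning")
  expect_identical(unname(after_smote), c(60L, 60L))
  expect_lte(after_clean[["neg"]], 60L)
  expect_identical(after_clean[["pos"]], 60L)
  # reconstruct: cleaning must have dropped the majority member of each link
  sm <- smote(cl$rows, cl$labels, seed = 74)
  links <- tomek_links(sm$rows, sm$labels)
  maj_members <- unique(as.vector(links)[sm$labels[as.vector(links)] == 0L])
  expect_identical(nrow(out$rows), nrow(sm$rows) - length(maj_members))
  kept <- sm$rows[setdiff(seq_len(nrow(sm$rows)), maj_members), ]
  expect_identical(out$rows, kept)
  # no links -> output equals the SMOTE output
  far <- two_cluster_table(sep = 30, seed = 5)
  out2 <- smote_tomek(far$rows, far$labels, seed = 74)
  sm2 <- smote(far$rows, far$labels, seed = 74)
  expect_identical(out2$rows, sm2$rows)
})

test_that("comparator samplers meet their contracts", {
  cl <- two_cluster_table(n_pos = 18, n_neg = 45, seed = 8)
  ro <- random_oversample(cl$rows, cl$labels, seed = 2)
  expect_identical(sum(ro$labels == 1L), sum(ro$labels == 0L))
  synth <- ro$rows[ro$provenance == "synthetic", , drop = FALSE]
  minority <- cl$rows[cl$labels == 1L, , drop = FALSE]
  for (i in seq_len(nrow(synth))) {
    expect_true(any(apply(minority, 1, function(r) all(r == synth[i, ]))))
  }
  ad <- adasyn(cl$rows, cl$labels, k = 5, seed = 3)
  n_pos <- sum(ad$labels == 1L)
  n_neg <- sum(ad$labels == 0L)
  # rounding of per-point allocations can move the total slightly
  expect_lte(abs(n_pos - n_neg), 5L)
  # a minority point surrounded only by minority receives no synthesis:
  # an isolated tight minority clump far from the majority, plus boundary
  # minority points at the majority cluster. With k = 3 each clump member's
  # neighborhood (density estimate and interpolation partners) stays inside
  # the clump, so all synthesis happens near the boundary.
  rows <- rbind(matrix(rnorm(12, sd = 0.05), 6, 2) + 100,
                matrix(rnorm(40), 20, 2),
                matrix(rnorm(8, sd = 0.5), 4, 2))
  labels <- c(rep(1L, 6), rep(0L, 20), rep(1L, 4))
  ad2 <- adasyn(rows, labels, k = 3, seed = 4)
  synth2 <- ad2$rows[ad2$provenance == "synthetic", , drop = FALSE]
  expect_gt(nrow(synth2), 0L)
  expect_true(all(synth2[, 1] < 50))  # nothing synthesized in the clump
})

test_that("samplers are bitwise deterministic per seed", {
  cl <- two_cluster_table(seed = 21)
  for (f in list(function(s) smote(cl$rows, cl$labels, seed = s),
                 function(s) smote_tomek(cl$rows, cl$labels, seed = s),
                 function(s) adasyn(cl$rows, cl$labels, seed = s),
                 function(s) random_oversample(cl$rows, cl$labels, seed = s))) {
    expect_identical(f(74), f(74))
    a <- f(74)
    b <- f(75)
    same <- identical(a$rows, b$rows)
    expect_true(!same || nrow(a$rows) == nrow(cl$rows))
  }
})
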