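# Class rebalancing for the hot/non-hot imbalance: SMOTE interpolation,
# Tomek-link boundary cleaning, their combination, and two comparator
# samplers (random oversampling, ADASYN). All samplers operate on the
# training data only and are deterministic for a fixed seed.

balanced_dataset <- function(rows, labels, provenance, seed) {
  stopifnot(nrow(rows) == length(labels),
            length(provenance) == length(labels),
            all(provenance %in% c("original", "synthetic")))
  structure(list(rows = rows, labels = as.integer(labels),
                 provenance = provenance, seed = as.integer(seed)),
            class = "balanced_dataset")
}

#' @export
print.balanced_dataset <- function(x, ...) {
  cat(sprintf("<balanced_dataset> %d rows (%d synthetic) | %d pos / %d neg\n",
              nrow(x$rows), sum(x$provenance == "synthetic"),
              sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

# z-score columns; zero-variance columns are left centered only.
zscale <- function(rows) {
  mu <- colMeans(rows)
  sdv <- apply(rows, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  sweep(sweep(rows, 2, mu), 2, sdv, "/")
}

minority_label <- function(labels) {
  if (sum(labels == 1L) <= sum(labels == 0L)) 1L else 0L
}

# k nearest neighbors of each query row among reference rows (Euclidean),
# excluding self-matches by index when ref and query coincide. Ties broken
# by lowest index.
knn_indices <- function(query, ref, k, self = FALSE) {
  d <- as.matrix(stats::dist(rbind(query, ref)))
  nq <- nrow(query)
  d <- d[seq_len(nq), nq + seq_len(nrow(ref)), drop = FALSE]
  res <- vapply(seq_len(nq), function(i) {
    ord <- order(d[i, ], seq_len(ncol(d)))
    if (self) ord <- ord[-1L]
    ord[seq_len(k)]
  }, integer(k))
  if (k == 1L) matrix(res, ncol = 1L) else t(res)
}

#' Interpolate one synthetic minority sample
#'
#' The conventional SMOTE step `x + (xn - x) * u` places the new sample on
#' the segment between a minority sample `x` and one of its minority
#' neighbors `xn`. `sign = "reflect"` instead extrapolates away from the
#' neighbor (`x + (x - xn) * u`).
#'
#' @param x,xn numeric vectors of equal length.
#' @param u interpolation factor in (0, 1).
#' @param sign `"interpolate"` (default) or `"reflect"`.
#' @return numeric vector.
#' @export
smote_synthesize <- function(x, xn, u, sign = c("interpolate", "reflect")) {
  sign <- match.arg(sign)
  if (length(x) != length(xn)) {
    stop("x and xn must have the same width", call. = FALSE)
  }
  if (u <= 0 || u >= 1) stop("u must lie in (0, 1)", call. = FALSE)
  if (sign == "interpolate") x + (xn - x) * u else x + (x - xn) * u
}

#' SMOTE oversampling
#'
#' Synthesizes minority-class rows until the minority:majority ratio reaches
#' `target_ratio`. Each synthetic row interpolates a randomly chosen minority
#' row and one of its `k_neighbors` nearest minority neighbors (Euclidean
#' distance on z-scored features; interpolation happens in the original
#' feature space).
#'
#' @param rows numeric feature matrix.
#' @param labels 0/1 vector; the minority class is oversampled.
#' @param k_neighbors neighborhood size (capped at minority count - 1).
#' @param target_ratio desired minority/majority count ratio (default 1.0).
#' @param seed integer seed.
#' @param sign interpolation direction, see [smote_synthesize()].
#' @return a `balanced_dataset`; original rows come first, unmodified.
#' @export
smote <- function(rows, labels, k_neighbors = 5L, target_ratio = 1.0,
                  seed = 74L, sign = c("interpolate", "reflect")) {
  sign <- match.arg(sign)
  rows <- as.matrix(rows)
  labels <- as.integer(labels)
  min_lab <- minority_label(labels)
  idx_min <- which(labels == min_lab)
  n_min <- length(idx_min)
  n_maj <- length(labels) - n_min
  if (n_maj == 0L || n_min == 0L) {
    stop("both classes must be nonempty", call. = FALSE)
  }
  if (n_min <= 1L) {
    stop("cannot interpolate: minority class has fewer than 2 samples",
         call. = FALSE)
  }
  n_new <- round(n_maj * target_ratio) - n_min
  if (n_new <= 0L) {
    return(balanced_dataset(rows, labels, rep("original", length(labels)),
                            seed))
  }
  k <- min(k_neighbors, n_min - 1L)
  zmin <- zscale(rows)[idx_min, , drop = FALSE]
  nn <- knn_indices(zmin, zmin, k, self = TRUE)
  synth <- with_seed(seed, {
    base <- sample(n_min, n_new, replace = TRUE)
    pick <- sample.int(k, n_new, replace = TRUE)
    u <- stats::runif(n_new)
    u[u == 0] <- 0.5  # runif(1) can in principle return 0; keep u in (0,1)
    t(vapply(seq_len(n_new), function(j) {
      i <- base[j]
      smote_synthesize(rows[idx_min[i], ], rows[idx_min[nn[i, pick[j]]], ],
                       u[j], sign = sign)
    }, numeric(ncol(rows))))
  })
  balanced_dataset(rbind(rows, synth),
                   c(labels, rep(min_lab, n_new)),
                   c(rep("original", length(labels)),
                     rep("synthetic", n_new)),
                   seed)
}

#' Find Tomek links
#'
#' A Tomek link is a pair of opposite-class rows that are mutual single
#' nearest neighbors (Euclidean distance on the rows as given; nearest
#' neighbor ties are broken by lowest index).
#'
#' @param rows numeric feature matrix with at least 2 rows.
#' @param labels 0/1 vector.
#' @return two-column integer matrix of linked index pairs, `i < j` per row.
#' @export
tomek_links <- function(rows, labels) {
  rows <- as.matrix(rows)
  n <- nrow(rows)
  if (n < 2L) stop("need at least 2 rows", call. = FALSE)
  d <- as.matrix(stats::dist(rows))
  diag(d) <- Inf
  nn <- vapply(seq_len(n), function(i) which.min(d[i, ]), integer(1))
  pairs <- which(nn[nn] == seq_len(n) & labels != labels[nn] &
                   seq_len(n) < nn)
  cbind(i = pairs, j = nn[pairs], deparse.level = 0)
}

#' SMOTE followed by Tomek-link cleaning
#'
#' Oversamples the minority class to a 1:1 ratio with [smote()], then finds
#' Tomek links in the expanded data and removes the link member belonging to
#' the (originally) majority class, sharpening the class boundary.
#'
#' @inheritParams smote
#' @return a `balanced_dataset`. Attributes `counts_after_smote` and
#'   `counts_after_cleaning` report the positive/negative counts at both
#'   stages.
#' @export
smote_tomek <- function(rows, labels, k_neighbors = 5L, seed = 74L,
                        sign = c("interpolate", "reflect")) {
  sign <- match.arg(sign)
  maj_lab <- 1L - minority_label(as.integer(labels))
  sm <- smote(rows, labels, k_neighbors = k_neighbors, target_ratio = 1.0,
              seed = seed, sign = sign)
  links <- tomek_links(sm$rows, sm$labels)
  drop <- unique(as.vector(links)[sm$labels[as.vector(links)] == maj_lab])
  keep <- setdiff(seq_along(sm$labels), drop)
  out <- balanced_dataset(sm$rows[keep, , drop = FALSE], sm$labels[keep],
                          sm$provenance[keep], seed)
  attr(out, "counts_after_smote") <- c(pos = sum(sm$labels == 1L),
                                       neg = sum(sm$labels == 0L))
  attr(out, "counts_after_cleaning") <- c(pos = sum(out$labels == 1L),
                                          neg = sum(out$labels == 0L))
  out
}

#' Random oversampling comparator
#'
#' Duplicates uniformly sampled minority rows until the classes are 1:1.
#'
#' @inheritParams smote
#' @return a `balanced_dataset`; synthetic rows are exact duplicates.
#' @export
random_oversample <- function(rows, labels, seed = 74L) {
  rows <- as.matrix(rows)
  labels <- as.integer(labels)
  min_lab <- minority_label(labels)
  idx_min <- which(labels == min_lab)
  n_new <- sum(labels != min_lab) - length(idx_min)
  if (length(idx_min) == 0L || n_new < 0L) {
    stop("both classes must be nonempty", call. = FALSE)
  }
  if (n_new == 0L) {
    return(balanced_dataset(rows, labels, rep("original", length(labels)),
                            seed))
  }
  dup <- with_seed(seed, sample(idx_min, n_new, replace = TRUE))
  balanced_dataset(rbind(rows, rows[dup, , drop = FALSE]),
                   c(labels, rep(min_lab, n_new)),
                   c(rep("original", length(labels)),
                     rep("synthetic", n_new)),
                   seed)
}

#' ADASYN comparator
#'
#' Adaptive synthetic sampling: the amount of synthesis at each minority row
#' is proportional to the fraction of majority samples among its `k` nearest
#' neighbors (over both classes), so synthesis concentrates near the class
#' boundary. Minority rows surrounded only by minority neighbors receive no
#' synthesis.
#'
#' @inheritParams smote
#' @param k neighborhood size for both the density estimate and the
#'   interpolation partners.
#' @return a `balanced_dataset`.
#' @export
adasyn <- function(rows, labels, k = 5L, seed = 74L) {
  rows <- as.matrix(rows)
  labels <- as.integer(labels)
  min_lab <- minority_label(labels)
  idx_min <- which(labels == min_lab)
  n_min <- length(idx_min)
  n_maj <- length(labels) - n_min
  if (n_min <= 1L || n_maj == 0L) {
    stop("cannot interpolate: need >= 2 minority and >= 1 majority samples",
         call. = FALSE)
  }
  g_total <- n_maj - n_min
  if (g_total <= 0L) {
    return(balanced_dataset(rows, labels, rep("original", length(labels)),
                            seed))
  }
  z <- zscale(rows)
  k_all <- min(k, nrow(rows) - 1L)
  nn_all <- knn_indices(z[idx_min, , drop = FALSE], z, k_all, self = TRUE)
  r <- rowSums(matrix(labels[nn_all] != min_lab, nrow = n_min)) / k_all
  if (sum(r) == 0) {
    return(balanced_dataset(rows, labels, rep("original", length(labels)),
                            seed))
  }
  g <- round(r / sum(r) * g_total)
  k_min <- min(k, n_min - 1L)
  nn_min <- knn_indices(z[idx_min, , drop = FALSE], z[idx_min, , drop = FALSE],
                        k_min, self = TRUE)
  synth <- with_seed(seed, {
    out <- vector("list", n_min)
    for (i in seq_len(n_min)) {
      if (g[i] == 0L) next
      pick <- sample.int(k_min, g[i], replace = TRUE)
      u <- stats::runif(g[i])
      u[u == 0] <- 0.5
      out[[i]] <- t(vapply(seq_len(g[i]), function(j) {
        smote_synthesize(rows[idx_min[i], ],
                         rows[idx_min[nn_min[i, pick[j]]], ], u[j])
      }, numeric(ncol(rows))))
    }
    do.call(rbind, out)
  })
  n_new <- if (is.null(synth)) 0L else nrow(synth)
  balanced_dataset(rbind(rows, synth),
                   c(labels, rep(min_lab, n_new)),
                   c(rep("original", length(labels)),
                     rep("synthetic", n_new)),
                   seed)
}

#' Apply a named balancing strategy
#'
#' Dispatch used by the cross-validation loop and the pipeline.
#'
#' @param rows,labels training fold.
#' @param method one of `"smote-tomek"`, `"smote"`, `"adasyn"`, `"random"`,
#'   `"none"`.
#' @param seed integer seed.
#' @param k_neighbors neighborhood size passed through to the sampler.
#' @return a `balanced_dataset` (for `"none"`, the input marked original).
#' @export
apply_balancing <- function(rows, labels,
                            method = c("smote-tomek", "smote", "adasyn",
                                       "random", "none"),
                            seed = 74L, k_neighbors = 5L) {
  method <- match.arg(method)
  switch(method,
         "smote-tomek" = smote_tomek(rows, labels, k_neighbors, seed),
         "smote" = smote(rows, labels, k_neighbors, seed = seed),
         "adasyn" = adasyn(rows, labels, k = k_neighbors, seed = seed),
         "random" = random_oversample(rows, labels, seed),
         "none" = balanced_dataset(as.matrix(rows), labels,
                                   rep("original", length(labels)), seed))
}
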