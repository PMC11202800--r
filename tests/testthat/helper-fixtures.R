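# Shared fixtures and independent brute-force oracles used across tests.

# A deterministic residue record with structured (non-degenerate) signals.
make_record <- function(seed = 1, constant = FALSE, monotone_dasa = FALSE) {
  set.seed(seed)
  sig <- function(len) {
    if (constant) return(rep(1.5, len))
    sin(2 * pi * seq_len(len) / len * 2 + seed) + rnorm(len, 0, 0.3)
  }
  residue_record(
    complex_id = sprintf("CPX%02d", seed), chain = "A", position = seed,
    wild_aa = "R", ddg = 1.8,
    asa_complex = sig(8), asa_unbound = sig(8),
    asa_delta = if (monotone_dasa) seq(0.1, 0.8, length.out = 8) else sig(8),
    dssp = sig(6), dpx_cx = sig(12), hbond_count = 2)
}

# O(n^2) pair-counting AUC (ties count 1/2).
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Contingency-table mutual information written independently of the package.
mi_brute <- function(a, b) {
  ua <- unique(a)
  ub <- unique(b)
  n <- length(a)
  total <- 0
  for (va in ua) for (vb in ub) {
    pab <- sum(a == va & b == vb) / n
    if (pab > 0) {
      total <- total + pab * log(pab / ((sum(a == va) / n) * (sum(b == vb) / n)))
    }
  }
  total
}

# All-pairs Tomek-link oracle: mutual single nearest neighbors of opposite
# class, Euclidean, ties by lowest index.
tomek_brute <- function(rows, labels) {
  n <- nrow(rows)
  nn <- integer(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (j == i) next
      dij <- sqrt(sum((rows[i, ] - rows[j, ])^2))
      if (dij < best) {
        best <- dij
        nn[i] <- j
      }
    }
  }
  out <- NULL
  for (i in seq_len(n)) {
    j <- nn[i]
    if (nn[j] == i && labels[i] != labels[j] && i < j) {
      out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# Run one of the shipped python reference scripts on a JSON request.
run_py_oracle <- function(script, request) {
  path <- system.file("oracle", script, package = "pdhotspot")
  stopifnot(nzchar(path))
  out <- system2("python", shQuote(path),
                 input = jsonlite::toJSON(request, auto_unbox = TRUE,
                                          digits = NA),
                 stdout = TRUE)
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
}

# Small feature table with known geometry for balancing tests.
two_cluster_table <- function(n_pos = 20, n_neg = 35, sep = 3, seed = 4) {
  set.seed(seed)
  rows <- rbind(matrix(rnorm(n_pos * 3), n_pos, 3) + sep,
                matrix(rnorm(n_neg * 3), n_neg, 3))
  labels <- c(rep(1L, n_pos), rep(0L, n_neg))
  list(rows = rows, labels = labels)
}
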