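# Haar (db1) discrete wavelet transform and level-3 wavelet packet
# transform of the per-residue descriptor signals, plus the energy/entropy
# summaries that form the wavelet feature block.

#' Wavelet configuration
#'
#' @param wavelet wavelet family; only the Haar wavelet (`"db1"`) is
#'   implemented.
#' @param level decomposition depth (default 3, giving 8 packet leaves).
#' @param entropy_param threshold parameter of the `sure` and `threshold`
#'   entropies (default 0.2).
#' @return a list of class `wavelet_config`.
#' @export
wavelet_config <- function(wavelet = "db1", level = 3L, entropy_param = 0.2) {
  wavelet <- match.arg(wavelet, c("db1", "haar"))
  stopifnot(level >= 1L, entropy_param > 0)
  structure(list(wavelet = "db1", level = as.integer(level),
                 entropy_param = entropy_param),
            class = "wavelet_config")
}

#' One Haar analysis step
#'
#' Splits a sequence into approximation `a[k] = (x[2k-1] + x[2k]) / sqrt(2)`
#' and detail `d[k] = (x[2k-1] - x[2k]) / sqrt(2)` coefficients. Odd-length
#' inputs are zero-padded by one sample. The step is orthonormal:
#' `sum(a^2) + sum(d^2) == sum(x^2)`.
#'
#' @param seq numeric vector, nonempty.
#' @return list with numeric vectors `approximation` and `detail`.
#' @export
haar_step <- function(seq) {
  if (length(seq) == 0L) stop("empty input", call. = FALSE)
  check_finite(seq, "seq")
  if (length(seq) %% 2L == 1L) seq <- c(seq, 0)
  odd <- seq[c(TRUE, FALSE)]
  even <- seq[c(FALSE, TRUE)]
  list(approximation = (odd + even) / sqrt(2),
       detail = (odd - even) / sqrt(2))
}

# DWT cascade: repeatedly split the approximation band. Returns per-level
# approximation and detail coefficient vectors.
haar_dwt <- function(seq, level = 3L) {
  a <- seq
  approx <- vector("list", level)
  detail <- vector("list", level)
  for (l in seq_len(level)) {
    st <- haar_step(a)
    approx[[l]] <- st$approximation
    detail[[l]] <- st$detail
    a <- st$approximation
  }
  list(approximation = approx, detail = detail)
}

#' Wavelet packet leaves
#'
#' Full binary wavelet-packet expansion with the Haar filter: both the
#' approximation and the detail branch are recursed at every level. Leaves
#' are returned in natural (filter-bank) order. The input is zero-padded to
#' the next multiple of `2^level`, so level 3 always yields 8 leaves.
#'
#' @param seq numeric vector, nonempty.
#' @param level decomposition depth (>= 1).
#' @return list of class `wp_tree` with element `leaves`, a list of
#'   `2^level` coefficient vectors.
#' @export
wpt_leaves <- function(seq, level = 3L) {
  if (level < 1L) stop("level must be >= 1", call. = FALSE)
  if (length(seq) == 0L) stop("empty input", call. = FALSE)
  block <- 2L^level
  pad <- (block - length(seq) %% block) %% block
  nodes <- list(c(as.numeric(seq), numeric(pad)))
  for (l in seq_len(level)) {
    nxt <- vector("list", 2L * length(nodes))
    for (j in seq_along(nodes)) {
      st <- haar_step(nodes[[j]])
      nxt[[2L * j - 1L]] <- st$approximation
      nxt[[2L * j]] <- st$detail
    }
    nodes <- nxt
  }
  structure(list(leaves = nodes, level = as.integer(level)),
            class = "wp_tree")
}

#' Wavelet entropy summaries
#'
#' Classical coefficient entropies computed on unnormalized coefficients
#' `s`: `shannon = -sum(s^2 * log(s^2))` and
#' `log_energy = sum(log(s^2))`, both over nonzero coefficients;
#' `threshold = #(|s| > param)`;
#' `sure = N - #(|s| <= param) + sum(pmin(s^2, param^2))`;
#' `norm = sum(|s|^1.5)`.
#'
#' @param coeffs numeric coefficient vector, nonempty.
#' @param kind one of `"shannon"`, `"sure"`, `"threshold"`, `"norm"`,
#'   `"log_energy"`.
#' @param param threshold parameter for `sure` / `threshold`.
#' @return numeric scalar.
#' @export
wavelet_entropy <- function(coeffs,
                            kind = c("shannon", "sure", "threshold", "norm",
                                     "log_energy"),
                            param = 0.2) {
  kind <- match.arg(kind)
  if (length(coeffs) == 0L) stop("empty coefficient vector", call. = FALSE)
  check_finite(coeffs, "coeffs")
  s2 <- coeffs^2
  nz <- s2 > 0
  switch(kind,
         shannon = -sum(s2[nz] * log(s2[nz])),
         sure = length(coeffs) - sum(abs(coeffs) <= param) +
           sum(pmin(s2, param^2)),
         threshold = sum(abs(coeffs) > param),
         norm = sum(abs(coeffs)^1.5),
         log_energy = sum(log(s2[nz])))
}

ENTROPY_KINDS <- c("shannon", "sure", "threshold", "norm", "log_energy")

# The 33 wavelet summaries of one signal group, in schema order.
wavelet_group_block <- function(signal, config = wavelet_config()) {
  level <- config$level
  dwt <- haar_dwt(c(as.numeric(signal),
                    numeric((2L^level - length(signal) %% 2L^level) %%
                              2L^level)),
                  level = level)
  ea <- vapply(dwt$approximation, function(v) sum(v^2), numeric(1))
  ed <- sum(dwt$detail[[level]]^2)
  dwt_coeffs <- c(unlist(dwt$detail), dwt$approximation[[level]])
  tree <- wpt_leaves(signal, level = level)
  leaf_e <- vapply(tree$leaves, function(v) sum(v^2), numeric(1))
  total_e <- sum(leaf_e)
  rel_e <- if (total_e > 0) leaf_e / total_e else rep(0, length(leaf_e))
  ent_dwt <- vapply(ENTROPY_KINDS, function(k)
    wavelet_entropy(dwt_coeffs, k, config$entropy_param), numeric(1))
  ent_wpt <- vapply(ENTROPY_KINDS, function(k)
    wavelet_entropy(unlist(tree$leaves), k, config$entropy_param), numeric(1))
  c(ea, stats::sd(ea), mean(ea), ed, ent_dwt, total_e, leaf_e, ent_wpt, rel_e)
}

#' Extract the wavelet feature block of one residue record
#'
#' For each of the four signal groups (ASA, uASA, dASA, SS), 33 summaries in
#' fixed order: approximation-band energies of DWT levels 1-3, their standard
#' deviation and mean, the level-3 detail energy, five entropies of the
#' concatenated DWT coefficients, the total packet-leaf energy, the 8
#' absolute leaf energies, five entropies of the concatenated packet leaves,
#' and the 8 relative leaf energies (defined as 0 when the total energy is
#' 0). Concatenated over groups: 132 values.
#'
#' @param record a [residue_record()].
#' @param config a [wavelet_config()].
#' @return named numeric vector of length `4 * (2^level + 25)` (132 at the
#'   default level 3).
#' @export
extract_wavelet_block <- function(record, config = wavelet_config()) {
  stopifnot(inherits(record, "residue_record"))
  signals <- signal_groups(record)
  out <- unlist(lapply(signals, wavelet_group_block, config = config),
                use.names = FALSE)
  if (config$level == 3L) names(out) <- wavelet_feature_names()
  out
}
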