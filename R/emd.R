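# Empirical mode decomposition (EMD) of the short per-residue descriptor
# signals, and the statistics of the resulting intrinsic mode functions
# (IMFs) that form the EMD feature block.
#
# Sifting follows the classical scheme: locate interior extrema, interpolate
# cubic-spline upper/lower envelopes through them (after mirror extension of
# the extrema nearest each end), subtract the envelope mean, and repeat until
# the candidate satisfies the IMF count condition and a Cauchy-type
# convergence criterion. The IMF is then removed from the signal and the
# process restarts on the residual.

#' EMD configuration
#'
#' @param max_imfs maximum number of IMFs to extract (default 3: the first
#'   three mode functions carry the features).
#' @param sd_threshold Cauchy convergence threshold for sifting: iteration
#'   stops once `sum((h_prev - h)^2) / sum(h_prev^2)` falls below it.
#' @param max_sift_iterations soft cap on sifting iterations per IMF; a hard
#'   cap of three times this value applies while the candidate still fails
#'   the IMF count condition.
#' @param boundary envelope boundary policy; only `"mirror"` (reflect the
#'   extrema nearest each end about the signal endpoints) is implemented.
#' @param min_extrema stop decomposing once the residual has fewer interior
#'   extrema than this.
#' @param lag autocorrelation lag used by [imf_stats()].
#' @return a list of class `emd_config`.
#' @export
emd_config <- function(max_imfs = 3L, sd_threshold = 0.2,
                       max_sift_iterations = 10L, boundary = "mirror",
                       min_extrema = 2L, lag = 1L) {
  stopifnot(max_imfs >= 1L, sd_threshold > 0, max_sift_iterations >= 1L,
            min_extrema >= 1L, lag >= 0L)
  boundary <- match.arg(boundary, "mirror")
  structure(list(max_imfs = as.integer(max_imfs),
                 sd_threshold = sd_threshold,
                 max_sift_iterations = as.integer(max_sift_iterations),
                 boundary = boundary, min_extrema = as.integer(min_extrema),
                 lag = as.integer(lag)),
            class = "emd_config")
}

#' Locate strict interior extrema
#'
#' Equal-valued plateaus contribute a single extremum at their midpoint
#' index (rounded down). Signal endpoints are never extrema. Indices are
#' 1-based.
#'
#' @param signal numeric vector, length >= 3 for any extrema to exist.
#' @return list with sorted integer vectors `maxima` and `minima`.
#' @export
find_extrema <- function(signal) {
  n <- length(signal)
  maxima <- integer(0)
  minima <- integer(0)
  if (n < 3L) return(list(maxima = maxima, minima = minima))
  r <- rle(signal)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  if (k >= 3L) {
    for (j in 2:(k - 1L)) {
      mid <- (starts[j] + ends[j]) %/% 2L
      if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L]) {
        maxima <- c(maxima, mid)
      } else if (r$values[j] < r$values[j - 1L] &&
                 r$values[j] < r$values[j + 1L]) {
        minima <- c(minima, mid)
      }
    }
  }
  list(maxima = maxima, minima = minima)
}

# Zero crossings: sign changes after dropping exact zeros.
count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1] != s[-length(s)])
}

# IMF count condition: #extrema and #zero-crossings differ by at most one.
imf_count_condition <- function(x) {
  ex <- find_extrema(x)
  n_ext <- length(ex$maxima) + length(ex$minima)
  abs(n_ext - count_zero_crossings(x)) <= 1L
}

not_enough_extrema <- function(msg = "not enough extrema to build envelopes") {
  stop(errorCondition(msg, class = c("pdhotspot_not_enough_extrema", "error")))
}

# Spline envelope through (idx, value) knots after mirroring the <=2 extrema
# nearest each end about the signal endpoints.
spline_envelope <- function(idx, val, n) {
  if (length(idx) < 1L) not_enough_extrema()
  kl <- seq_len(min(2L, length(idx)))
  kr <- seq(length(idx), by = -1L, length.out = min(2L, length(idx)))
  x <- c(2L - idx[rev(kl)], idx, 2L * n - idx[kr])
  y <- c(val[rev(kl)], val, val[kr])
  keep <- !duplicated(x)
  stats::spline(x[keep], y[keep], xout = seq_len(n), method = "fmm")$y
}

#' Mean of the upper and lower cubic-spline envelopes
#'
#' @param signal numeric vector.
#' @param maxima,minima extrema indices; located with [find_extrema()] when
#'   omitted.
#' @return numeric vector, same length as `signal`. Signals with no interior
#'   maximum or no interior minimum raise a `pdhotspot_not_enough_extrema`
#'   condition (the caller stops sifting).
#' @export
envelope_mean <- function(signal, maxima = NULL, minima = NULL) {
  if (is.null(maxima) || is.null(minima)) {
    ex <- find_extrema(signal)
    maxima <- maxima %||% ex$maxima
    minima <- minima %||% ex$minima
  }
  if (length(maxima) < 1L || length(minima) < 1L) not_enough_extrema()
  n <- length(signal)
  upper <- spline_envelope(maxima, signal[maxima], n)
  lower <- spline_envelope(minima, signal[minima], n)
  (upper + lower) / 2
}

#' Test the intrinsic-mode-function conditions
#'
#' A sequence is an IMF when (i) its interior extremum count and
#' zero-crossing count differ by at most one and (ii) the mean of its upper
#' and lower envelopes is close to zero everywhere — here, at most
#' `tol` times the signal half-range.
#'
#' @param seq numeric vector.
#' @param tol envelope-mean tolerance relative to the signal half-range.
#' @return logical scalar.
#' @export
is_imf <- function(seq, tol = 0.25) {
  if (length(seq) < 3L) return(FALSE)
  if (!imf_count_condition(seq)) return(FALSE)
  amp <- (max(seq) - min(seq)) / 2
  if (amp == 0) return(FALSE)
  m <- tryCatch(envelope_mean(seq),
                pdhotspot_not_enough_extrema = function(e) NULL)
  if (is.null(m)) return(FALSE)
  max(abs(m)) <= tol * amp
}

#' Empirical mode decomposition by sifting
#'
#' Decomposes a signal into at most `config$max_imfs` intrinsic mode
#' functions plus a residual. Decomposition stops early when the residual is
#' monotone or has fewer than `config$min_extrema` interior extrema. The
#' returned components reconstruct the input exactly:
#' `Reduce("+", imfs) + residual == signal` up to floating-point error.
#'
#' @param signal numeric vector.
#' @param config an [emd_config()].
#' @return list of class `imf_set` with elements `imfs` (list of numeric
#'   vectors, possibly empty) and `residual`.
#' @export
sift <- function(signal, config = emd_config()) {
  check_finite(signal, "signal")
  imfs <- list()
  residual <- as.numeric(signal)
  n <- length(signal)
  if (n >= 4L) {
    for (k in seq_len(config$max_imfs)) {
      ex <- find_extrema(residual)
      if (length(ex$maxima) + length(ex$minima) < config$min_extrema) break
      h <- residual
      ok <- FALSE
      hard_cap <- 3L * config$max_sift_iterations
      for (it in seq_len(hard_cap)) {
        m <- tryCatch(envelope_mean(h),
                      pdhotspot_not_enough_extrema = function(e) NULL)
        if (is.null(m)) break
        h_new <- h - m
        denom <- sum(h^2)
        sd_crit <- if (denom > 0) sum((h - h_new)^2) / denom else 0
        h <- h_new
        converged <- sd_crit < config$sd_threshold ||
          it >= config$max_sift_iterations
        if (converged && imf_count_condition(h)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) break
      imfs[[k]] <- h
      residual <- residual - h
    }
  }
  structure(list(imfs = imfs, residual = residual), class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMF(s), signal length %d\n",
              length(x$imfs), length(x$residual)))
  invisible(x)
}

#' Statistics of one IMF component
#'
#' Mean, variance (N-1 denominator), energy (sum of squares) and the lag-`m`
#' autocorrelation value `sum(x[i] * x[i+m])` over the overlapping range
#' (real signals, no wraparound).
#'
#' @param seq numeric vector, length >= 2.
#' @param m autocorrelation lag, `0 <= m < length(seq)`.
#' @return list of class `imf_stats` with fields `mean`, `variance`,
#'   `energy`, `autocorr`.
#' @export
imf_stats <- function(seq, m = 1L) {
  check_finite(seq, "seq")
  n <- length(seq)
  if (n < 2L) stop("variance undefined for length < 2", call. = FALSE)
  if (m < 0L || m >= n) {
    stop(sprintf("invalid lag m = %d for length %d", m, n), call. = FALSE)
  }
  structure(list(
    mean = sum(seq) / n,
    variance = sum((seq - mean(seq))^2) / (n - 1),
    energy = sum(seq^2),
    autocorr = sum(seq[seq_len(n - m)] * seq[seq_len(n - m) + m])),
    class = "imf_stats")
}

#' Extract the EMD feature block of one residue record
#'
#' Each of the four signal groups (ASA, uASA, dASA, SS) is decomposed with
#' [sift()] and each kept IMF contributes its [imf_stats()]. The default
#' layout keeps all four statistics of IMFs 1-3 for the three
#' solvent-accessibility groups (36 values) and, for the shorter
#' secondary-structure signal, all four statistics of IMF 1 plus the mean,
#' variance and energy of IMF 2 (7 values): 43 in total. Slots whose IMF was
#' not extracted (signal exhausted early) are filled with 0, keeping rows
#' fixed-width.
#'
#' @param record a [residue_record()].
#' @param config an [emd_config()].
#' @param slots slot layout data frame (columns `group`, `imf`, `stat`,
#'   `name`); defaults to the 43-slot layout matching [emd_feature_names()].
#' @return named numeric vector, one value per slot.
#' @export
extract_emd_block <- function(record, config = emd_config(),
                              slots = emd_slot_table()) {
  stopifnot(inherits(record, "residue_record"))
  signals <- signal_groups(record)
  decomp <- lapply(signals, sift, config = config)
  out <- numeric(nrow(slots))
  for (i in seq_len(nrow(slots))) {
    s <- slots[i, ]
    imfs <- decomp[[s$group]]$imfs
    if (s$imf <= length(imfs)) {
      st <- imf_stats(imfs[[s$imf]], m = min(config$lag,
                                             length(imfs[[s$imf]]) - 1L))
      out[i] <- switch(s$stat, meanValue = st$mean, variance = st$variance,
                       energy = st$energy, autocorr = st$autocorr)
    }
  }
  names(out) <- slots$name
  out
}
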