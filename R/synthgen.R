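# Synthetic residue-table generator. Emulates the statistical shape of a
# curated alanine-mutagenesis dataset at a protein-DNA interface: rows
# grouped by complex, a hot:non-hot imbalance near 131:208, ddG values
# straddling the 1.0 kcal/mol hot-spot threshold, smooth short descriptor
# signals (so EMD and wavelet extraction have structure to work on) and a
# small set of genuinely informative conventional features.

#' Synthetic dataset specification
#'
#' @param n_complexes number of protein-DNA complexes (default 117).
#' @param residues_min,residues_max residues (mutation sites) per complex,
#'   drawn uniformly from this range (default 2-5).
#' @param hot_fraction marginal probability that a site is a hot spot
#'   (default 131/339).
#' @param informative_slots indices into the 43 conventional features that
#'   carry class signal (default: one slot in each of the ASA, uASA, dASA,
#'   SS and DPX/CX blocks).
#' @param effect_size class shift at informative slots, in units of
#'   `noise_sd`.
#' @param noise_sd descriptor noise standard deviation.
#' @param seed integer seed; generation is exactly reproducible.
#' @return a list of class `synth_spec`.
#' @export
synth_spec <- function(n_complexes = 117L, residues_min = 2L,
                       residues_max = 5L, hot_fraction = 131 / 339,
                       informative_slots = c(2L, 10L, 18L, 27L, 35L),
                       effect_size = 1.0, noise_sd = 1.0, seed = 1L) {
  stopifnot(n_complexes >= 2L, residues_min >= 1L,
            residues_max >= residues_min,
            hot_fraction > 0, hot_fraction < 1, effect_size >= 0,
            noise_sd > 0,
            all(informative_slots >= 1L), all(informative_slots <= 42L))
  structure(list(n_complexes = as.integer(n_complexes),
                 residues_min = as.integer(residues_min),
                 residues_max = as.integer(residues_max),
                 hot_fraction = hot_fraction,
                 informative_slots = as.integer(informative_slots),
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# Truncated-normal draw by rejection; the truncation bounds keep labels and
# ddG consistent with the 1.0 kcal/mol rule by construction.
rtrunc_norm <- function(mean, sd, lower = -Inf, upper = Inf) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower && x < upper) return(x)
  }
}

# Smooth low-order sinusoid base curve for one signal block.
base_curve <- function(len) {
  amp <- stats::runif(1, 0.5, 2)
  cycles <- sample(1:2, 1)
  phase <- stats::runif(1, 0, 2 * pi)
  offset <- stats::runif(1, -1, 1)
  amp * sin(2 * pi * cycles * seq_len(len) / len + phase) + offset
}

#' Generate synthetic residue records
#'
#' Per record: a hot-spot label drawn with probability `hot_fraction`; a ddG
#' from a two-component model (hot: normal mean 2.0 sd 0.8 truncated to
#' `>= 1.0` kcal/mol, non-hot: mean 0.2 sd 0.4 truncated to `< 1.0`);
#' descriptor blocks built as smooth sinusoidal base curves plus Gaussian
#' noise; and an `effect_size * noise_sd` class shift added at the
#' informative conventional slots.
#'
#' @param spec a [synth_spec()].
#' @return list of [residue_record()]s.
#' @export
generate_records <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  conv_names <- conventional_feature_names()
  with_seed(spec$seed, {
    records <- list()
    for (cpx in seq_len(spec$n_complexes)) {
      cid <- sprintf("CPX%03d", cpx)
      n_res <- sample(spec$residues_min:spec$residues_max, 1)
      for (res in seq_len(n_res)) {
        label <- stats::rbinom(1, 1, spec$hot_fraction)
        ddg <- if (label == 1L) rtrunc_norm(2.0, 0.8, lower = 1.0)
               else rtrunc_norm(0.2, 0.4, upper = 1.0)
        conv <- c(base_curve(8) + stats::rnorm(8, 0, spec$noise_sd),
                  base_curve(8) + stats::rnorm(8, 0, spec$noise_sd),
                  base_curve(8) + stats::rnorm(8, 0, spec$noise_sd),
                  base_curve(6) + stats::rnorm(6, 0, spec$noise_sd),
                  base_curve(12) + stats::rnorm(12, 0, spec$noise_sd))
        conv[spec$informative_slots] <- conv[spec$informative_slots] +
          spec$effect_size * spec$noise_sd * label
        records[[length(records) + 1L]] <- residue_record(
          complex_id = cid, chain = "A", position = res,
          wild_aa = sample(c("A", "R", "N", "D", "E", "K", "S", "T", "W",
                             "Y"), 1),
          ddg = ddg, label = label,
          asa_complex = conv[1:8], asa_unbound = conv[9:16],
          asa_delta = conv[17:24], dssp = conv[25:30],
          dpx_cx = conv[31:42],
          hbond_count = stats::rpois(1, 2))
      }
    }
    records
  })
}

#' Names of the planted informative features
#'
#' @param spec a [synth_spec()].
#' @return character vector of conventional feature names, for
#'   selection-recovery experiments.
#' @export
ground_truth <- function(spec = synth_spec()) {
  conventional_feature_names()[spec$informative_slots]
}

#' Generate a plain synthetic feature matrix table
#'
#' Generic benchmark table for selection and leakage experiments: `p`
#' standard-normal features, of which `planted` carry a mean shift of
#' `effect` (in SD units) in the positive class. Rows are split over
#' `n_groups` pseudo-complexes.
#'
#' @param n rows.
#' @param p features.
#' @param planted number of informative features (the first `planted`
#'   columns).
#' @param effect class shift in SD units.
#' @param hot_fraction positive-class probability.
#' @param n_groups number of row groups.
#' @param seed integer seed.
#' @return a [feature_table()] with features named `f001, f002, ...`;
#'   attribute `"planted"` holds the informative names.
#' @export
generate_matrix_table <- function(n = 300L, p = 50L, planted = 5L,
                                  effect = 1.0, hot_fraction = 0.4,
                                  n_groups = max(2L, n %/% 3L), seed = 1L) {
  stopifnot(planted <= p, n >= 4L)
  with_seed(seed, {
    labels <- stats::rbinom(n, 1, hot_fraction)
    # guarantee both classes
    if (sum(labels) == 0L) labels[1L] <- 1L
    if (sum(labels) == n) labels[1L] <- 0L
    rows <- matrix(stats::rnorm(n * p), n, p)
    if (planted > 0L) {
      rows[, seq_len(planted)] <- rows[, seq_len(planted)] + effect * labels
    }
    nm <- sprintf("f%03d", seq_len(p))
    schema <- feature_schema(nm, rep("conventional", p))
    groups <- sprintf("G%04d", rep_len(seq_len(n_groups), n))
    out <- feature_table(rows, labels, groups, schema)
    attr(out, "planted") <- nm[seq_len(planted)]
    out
  })
}
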