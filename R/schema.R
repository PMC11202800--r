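# Feature schema: the ordered, named column layout of the assembled feature
# vector. Three provenance blocks: "conventional" (structural descriptors as
# measured), "wavelet" (Haar DWT/WPT energies and entropies) and "emd"
# (statistics of intrinsic mode functions).

# Atom-class / state grid for the solvent-accessibility block: absolute and
# relative area over four atom classes, in the bound complex ("ASA"), the
# unbound monomer ("uASA") and their difference ("dASA"). 8 values per state.
ASA_ATOM_CLASSES <- c("all", "nonpolar", "polar", "side")
ASA_KINDS <- c("abs", "rel")

SIGNAL_GROUPS <- c("ASA", "uASA", "dASA", "SS")

asa_state_names <- function(prefix) {
  as.vector(t(outer(ASA_ATOM_CLASSES, ASA_KINDS,
                    function(a, k) paste(prefix, a, k, sep = "_"))))
}

dssp_names <- function() {
  paste0("SS_", c("tco", "kappa", "alpha", "phi", "psi", "water"))
}

dpx_cx_names <- function() {
  grid <- c("mean_bound", "sd_bound", "mean_unbound", "sd_unbound",
            "d_mean", "d_sd")
  c(paste0("DPX_", grid), paste0("CX_", grid))
}

#' Conventional feature names (43 columns)
#'
#' Bound/unbound/delta solvent accessibility (8 each), six secondary-structure
#' descriptors, twelve depth/protrusion descriptors and the hydrogen-bond
#' count, in the fixed assembly order.
#'
#' @return character vector of length 43.
#' @export
conventional_feature_names <- function() {
  c(asa_state_names("ASA"), asa_state_names("uASA"), asa_state_names("dASA"),
    dssp_names(), dpx_cx_names(), "Hbond_count")
}

# 33 wavelet-derived names for one signal group, fixed extraction order.
wavelet_group_names <- function(group) {
  ent <- c("shannon", "sure", "threshold", "norm", "logenergy")
  c(paste0("wt_", group, "_Ea_L", 1:3),
    paste0("wt_", group, c("_Ea_sd", "_Ea_mean", "_Ed")),
    paste0("wt_", group, "_ent_", ent),
    paste0("wpt_", group, "_energy_total"),
    paste0("wpt_", group, "_node_", 1:8),
    paste0("wpt_", group, "_ent_", ent),
    paste0("wpt_", group, "_rel_node_", 1:8))
}

#' Wavelet feature names (132 columns)
#'
#' 33 energy/entropy descriptors per signal group (ASA, uASA, dASA, SS).
#'
#' @return character vector of length 132.
#' @export
wavelet_feature_names <- function() {
  unlist(lapply(SIGNAL_GROUPS, wavelet_group_names), use.names = FALSE)
}

# Per-group layout of the EMD block: which (imf, statistic) slots are kept.
# The three accessibility groups keep all four statistics of IMFs 1-3
# (12 each); the shorter secondary-structure signal keeps IMF1 fully and
# IMF2 without the autocorrelation, totalling 43.
emd_slot_table <- function() {
  stats4 <- c("meanValue", "variance", "energy", "autocorr")
  rows <- list()
  for (g in c("ASA", "uASA", "dASA")) {
    for (k in 1:3) {
      rows[[length(rows) + 1L]] <-
        data.frame(group = g, imf = k, stat = stats4)
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(group = "SS", imf = 1L, stat = stats4)
  rows[[length(rows) + 1L]] <-
    data.frame(group = "SS", imf = 2L, stat = stats4[1:3])
  out <- do.call(rbind, rows)
  out$name <- sprintf("imf_%d_%s_%s", out$imf, out$group, out$stat)
  out
}

#' EMD feature names (43 columns)
#'
#' Statistics (mean, variance, energy, lag-1 autocorrelation) of the first
#' intrinsic mode functions of each signal group; see [extract_emd_block()]
#' for the slot layout.
#'
#' @return character vector of length 43.
#' @export
emd_feature_names <- function() {
  emd_slot_table()$name
}

#' Construct a feature schema
#'
#' A feature schema is an ordered list of column names, each tagged with the
#' block it comes from (`conventional`, `wavelet` or `emd`).
#'
#' @param names character vector of unique column names.
#' @param blocks character vector, same length, each one of
#'   `"conventional"`, `"wavelet"`, `"emd"`.
#' @return an object of class `feature_schema`.
#' @export
feature_schema <- function(names, blocks) {
  stopifnot(is.character(names), is.character(blocks),
            length(names) == length(blocks))
  if (anyDuplicated(names)) {
    stop("feature names must be unique", call. = FALSE)
  }
  bad <- setdiff(unique(blocks), c("conventional", "wavelet", "emd"))
  if (length(bad)) {
    stop("unknown block label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = names, block = blocks), class = "feature_schema")
}

#' @export
length.feature_schema <- function(x) length(x$name)

#' @export
print.feature_schema <- function(x, ...) {
  tab <- table(factor(x$block, levels = c("conventional", "wavelet", "emd")))
  cat(sprintf("<feature_schema> %d columns (%s)\n", length(x),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' The default 218-column feature schema
#'
#' 43 conventional + 132 wavelet + 43 EMD columns, in assembly order.
#'
#' @param blocks which blocks to include, in fixed order.
#' @return a [feature_schema()].
#' @export
default_schema <- function(blocks = c("conventional", "wavelet", "emd")) {
  blocks <- match.arg(blocks, several.ok = TRUE)
  nm <- character(0)
  bl <- character(0)
  if ("conventional" %in% blocks) {
    nm <- c(nm, conventional_feature_names())
    bl <- c(bl, rep("conventional", 43L))
  }
  if ("wavelet" %in% blocks) {
    nm <- c(nm, wavelet_feature_names())
    bl <- c(bl, rep("wavelet", 132L))
  }
  if ("emd" %in% blocks) {
    nm <- c(nm, emd_feature_names())
    bl <- c(bl, rep("emd", 43L))
  }
  feature_schema(nm, bl)
}

#' Read / write a schema registry file
#'
#' Schemas are stored as plain JSON (`{"name": [...], "block": [...]}`). The
#' package ships the default 218-column registry at
#' `system.file("extdata", "schema_default.json", package = "pdhotspot")`.
#'
#' @param path file path.
#' @return [feature_schema()] for `read_schema`; `path`, invisibly, for
#'   `write_schema`.
#' @export
read_schema <- function(path) {
  x <- jsonlite::fromJSON(path)
  feature_schema(x$name, x$block)
}

#' @param schema a [feature_schema()].
#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "feature_schema"))
  jsonlite::write_json(list(name = schema$name, block = schema$block), path,
                       pretty = TRUE)
  invisible(path)
}

# Expected width of each block within a schema.
schema_block_counts <- function(schema) {
  vapply(c("conventional", "wavelet", "emd"),
         function(b) sum(schema$block == b), integer(1))
}
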