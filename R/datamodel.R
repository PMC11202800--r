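# Residue records, feature tables, labeling and complex-level splitting.
#
# A residue record describes one mutation site at a protein-DNA interface:
# identifiers, four short descriptor "signal" blocks (bound/unbound/delta
# solvent accessibility and secondary structure), twelve depth/protrusion
# values, the hydrogen-bond count, and a binding free-energy change (ddG,
# kcal/mol) and/or a binary hot-spot label.

BLOCK_LENGTHS <- c(asa_complex = 8L, asa_unbound = 8L, asa_delta = 8L,
                   dssp = 6L, dpx_cx = 12L)

#' Create a residue record
#'
#' @param complex_id complex identifier (e.g. a PDB code).
#' @param chain chain identifier.
#' @param position residue position (integer).
#' @param wild_aa one-letter wild-type amino acid.
#' @param ddg change in binding free energy upon mutation, kcal/mol
#'   (optional if `label` is given).
#' @param label binary hot-spot label, 1 = hot spot (optional if `ddg` is
#'   given; derived from `ddg` with [label_from_ddg()] when missing).
#' @param asa_complex,asa_unbound,asa_delta numeric length-8 blocks:
#'   absolute and relative solvent-accessible area over four atom classes in
#'   the bound state, the unbound state, and their difference.
#' @param dssp numeric length-6 secondary-structure descriptor block.
#' @param dpx_cx numeric length-12 depth-index / protrusion-index block.
#' @param hbond_count non-negative integer hydrogen-bond count.
#' @return an object of class `residue_record`.
#' @export
residue_record <- function(complex_id, chain, position, wild_aa,
                           ddg = NULL, label = NULL,
                           asa_complex, asa_unbound, asa_delta,
                           dssp, dpx_cx, hbond_count) {
  if (is.null(ddg) && is.null(label)) {
    stop("at least one of `ddg` and `label` must be given", call. = FALSE)
  }
  if (!is.null(ddg)) check_finite(ddg, "ddg")
  if (!is.null(label) && !label %in% c(0, 1)) {
    stop("`label` must be 0 or 1", call. = FALSE)
  }
  blocks <- list(asa_complex = asa_complex, asa_unbound = asa_unbound,
                 asa_delta = asa_delta, dssp = dssp, dpx_cx = dpx_cx)
  for (b in names(blocks)) {
    v <- blocks[[b]]
    if (length(v) != BLOCK_LENGTHS[[b]]) {
      stop(sprintf("block `%s` must have length %d (got %d)",
                   b, BLOCK_LENGTHS[[b]], length(v)), call. = FALSE)
    }
    check_finite(v, sprintf("block `%s`", b))
  }
  if (length(hbond_count) != 1L || !is.finite(hbond_count) || hbond_count < 0) {
    stop("`hbond_count` must be a single non-negative number", call. = FALSE)
  }
  if (is.null(label)) label <- label_from_ddg(ddg)
  structure(list(complex_id = as.character(complex_id),
                 chain = as.character(chain),
                 position = as.integer(position),
                 wild_aa = as.character(wild_aa),
                 ddg = if (is.null(ddg)) NULL else as.numeric(ddg),
                 label = as.integer(label),
                 asa_complex = as.numeric(asa_complex),
                 asa_unbound = as.numeric(asa_unbound),
                 asa_delta = as.numeric(asa_delta),
                 dssp = as.numeric(dssp),
                 dpx_cx = as.numeric(dpx_cx),
                 hbond_count = as.numeric(hbond_count)),
            class = "residue_record")
}

#' Label a mutation site from its ddG
#'
#' A site is a hot spot when the binding free-energy change upon mutation is
#' at least `threshold` kcal/mol; the boundary value itself is a hot spot.
#'
#' @param ddg ddG in kcal/mol (vectorized).
#' @param threshold hot-spot threshold, kcal/mol (default 1.0).
#' @return integer 0/1 vector.
#' @export
label_from_ddg <- function(ddg, threshold = 1.0) {
  if (!is.numeric(ddg) || length(ddg) == 0L || any(!is.finite(ddg))) {
    stop("`ddg` must be finite numeric", call. = FALSE)
  }
  as.integer(ddg >= threshold)
}

# The four per-residue signal groups fed to the EMD and wavelet extractors.
signal_groups <- function(record) {
  list(ASA = record$asa_complex, uASA = record$asa_unbound,
       dASA = record$asa_delta, SS = record$dssp)
}

# 43-vector of conventional descriptors in schema order.
conventional_block <- function(record) {
  v <- c(record$asa_complex, record$asa_unbound, record$asa_delta,
         record$dssp, record$dpx_cx, record$hbond_count)
  names(v) <- conventional_feature_names()
  v
}

#' Assemble one feature row
#'
#' Concatenates the conventional descriptor block of a record with
#' externally computed wavelet and EMD blocks, in schema order
#' (conventional, then wavelet, then EMD).
#'
#' @param record a [residue_record()].
#' @param wavelet_block numeric vector (length = schema's wavelet count).
#' @param emd_block numeric vector (length = schema's EMD count).
#' @param schema a [feature_schema()]; defaults to the 218-column layout.
#' @return named numeric vector of length `length(schema)`.
#' @export
assemble_features <- function(record, wavelet_block = numeric(0),
                              emd_block = numeric(0),
                              schema = default_schema()) {
  stopifnot(inherits(record, "residue_record"),
            inherits(schema, "feature_schema"))
  counts <- schema_block_counts(schema)
  conv <- if (counts[["conventional"]] > 0L) conventional_block(record)
          else numeric(0)
  if (length(conv) != counts[["conventional"]]) {
    stop(sprintf("conventional block has %d values, schema expects %d",
                 length(conv), counts[["conventional"]]), call. = FALSE)
  }
  if (length(wavelet_block) != counts[["wavelet"]]) {
    stop(sprintf("wavelet block has %d values, schema expects %d",
                 length(wavelet_block), counts[["wavelet"]]), call. = FALSE)
  }
  if (length(emd_block) != counts[["emd"]]) {
    stop(sprintf("emd block has %d values, schema expects %d",
                 length(emd_block), counts[["emd"]]), call. = FALSE)
  }
  row <- c(conv, wavelet_block, emd_block)
  names(row) <- schema$name
  row
}

#' Create a feature table
#'
#' A feature table couples a samples-by-features matrix with a schema, binary
#' labels and the complex identifier of every row (used for leakage-safe,
#' complex-level splitting).
#'
#' @param rows numeric matrix, one row per mutation site.
#' @param labels integer 0/1 vector.
#' @param groups character vector of complex identifiers, one per row.
#' @param schema a [feature_schema()] whose length equals `ncol(rows)`.
#' @param ddg optional numeric ddG vector.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(rows, labels, groups, schema, ddg = NULL) {
  rows <- as.matrix(rows)
  storage.mode(rows) <- "double"
  stopifnot(inherits(schema, "feature_schema"))
  if (ncol(rows) != length(schema)) {
    stop(sprintf("row width %d does not match schema length %d",
                 ncol(rows), length(schema)), call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be 0/1", call. = FALSE)
  }
  if (length(labels) != nrow(rows) || length(groups) != nrow(rows)) {
    stop("labels and groups must have one entry per row", call. = FALSE)
  }
  colnames(rows) <- schema$name
  structure(list(rows = rows, labels = as.integer(labels),
                 groups = as.character(groups), schema = schema,
                 ddg = if (is.null(ddg)) NULL else as.numeric(ddg)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d rows x %d features | %d complexes | %d hot / %d non-hot\n",
    nrow(x$rows), ncol(x$rows), length(unique(x$groups)),
    sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$rows)

# Subset a feature table by row indices, preserving metadata.
subset_table <- function(x, idx) {
  feature_table(x$rows[idx, , drop = FALSE], x$labels[idx], x$groups[idx],
                x$schema, ddg = if (!is.null(x$ddg)) x$ddg[idx])
}

# Subset columns by feature names (selection results plug in here).
select_columns <- function(x, names) {
  keep <- match(names, x$schema$name)
  if (anyNA(keep)) {
    stop("unknown feature name(s): ",
         paste(names[is.na(keep)], collapse = ", "), call. = FALSE)
  }
  feature_table(x$rows[, keep, drop = FALSE], x$labels, x$groups,
                feature_schema(x$schema$name[keep], x$schema$block[keep]),
                ddg = x$ddg)
}

ID_COLUMNS <- c("complex_id", "chain", "position", "wild_aa")

#' Read a per-residue feature table from CSV/TSV
#'
#' Expects a header row with the identifier columns (`complex_id`, `chain`,
#' `position`, `wild_aa`), at least one of `ddg` / `label`, and the 43
#' conventional descriptor columns named as in
#' [conventional_feature_names()]. Returns a conventional-block
#' [feature_table()]; the parsed [residue_record()]s are attached as
#' attribute `"records"` for downstream signal-feature extraction.
#'
#' @param path input file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return a [feature_table()] with the 43-column conventional schema.
#' @export
read_feature_table <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = list(character = ID_COLUMNS))
  conv <- conventional_feature_names()
  missing_cols <- setdiff(c(ID_COLUMNS, conv), names(dt))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!("ddg" %in% names(dt)) && !("label" %in% names(dt))) {
    stop("schema error: need at least one of `ddg` / `label`", call. = FALSE)
  }
  for (col in intersect(c("ddg", "label", conv), names(dt))) {
    v <- dt[[col]]
    if (is.character(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "")
      if (length(bad)) {
        stop(sprintf("parse error: row %d, column `%s`: cannot parse %s",
                     bad[1], col, dQuote(v[bad[1]])), call. = FALSE)
      }
      data.table::set(dt, j = col, value = num)
    }
  }
  records <- lapply(seq_len(nrow(dt)), function(i) {
    residue_record(
      complex_id = dt$complex_id[i], chain = dt$chain[i],
      position = dt$position[i], wild_aa = dt$wild_aa[i],
      ddg = if ("ddg" %in% names(dt)) dt$ddg[i],
      label = if ("label" %in% names(dt)) dt$label[i],
      asa_complex = as.numeric(dt[i, conv[1:8], with = FALSE]),
      asa_unbound = as.numeric(dt[i, conv[9:16], with = FALSE]),
      asa_delta = as.numeric(dt[i, conv[17:24], with = FALSE]),
      dssp = as.numeric(dt[i, conv[25:30], with = FALSE]),
      dpx_cx = as.numeric(dt[i, conv[31:42], with = FALSE]),
      hbond_count = dt[[conv[43]]][i])
  })
  out <- records_to_table(records, schema = default_schema("conventional"))
  attr(out, "records") <- records
  out
}

#' Write a feature table to CSV/TSV
#'
#' Writes identifier columns (when the table carries records), `label`,
#' `ddg` when present, and all feature columns. Doubles are written with 17
#' significant digits so that write-then-read round-trips exactly.
#'
#' @param x a [feature_table()] or a list of [residue_record()]s.
#' @param path output file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  if (is.list(x) && !inherits(x, "feature_table")) {
    x <- records_to_table(x, schema = default_schema("conventional"),
                          keep_records = TRUE)
  }
  stopifnot(inherits(x, "feature_table"))
  records <- attr(x, "records")
  cols <- list()
  if (!is.null(records)) {
    cols$complex_id <- vapply(records, `[[`, "", "complex_id")
    cols$chain <- vapply(records, `[[`, "", "chain")
    cols$position <- vapply(records, `[[`, 0L, "position")
    cols$wild_aa <- vapply(records, `[[`, "", "wild_aa")
  } else {
    cols$complex_id <- x$groups
  }
  if (!is.null(x$ddg)) cols$ddg <- fmt_double(x$ddg)
  cols$label <- x$labels
  dt <- data.table::as.data.table(cols)
  for (j in seq_len(ncol(x$rows))) {
    data.table::set(dt, j = colnames(x$rows)[j],
                    value = fmt_double(x$rows[, j]))
  }
  data.table::fwrite(dt, path, sep = sep, quote = FALSE)
  invisible(path)
}

# %.17g round-trips IEEE doubles exactly; integers print without exponent.
fmt_double <- function(v) {
  out <- sprintf("%.17g", v)
  whole <- is.finite(v) & v == round(v) & abs(v) < 1e15
  out[whole] <- sprintf("%.0f", v[whole])
  out
}

#' Build a conventional feature table from records
#'
#' @param records list of [residue_record()]s.
#' @param schema schema of the output (conventional block only).
#' @param keep_records attach the record list as attribute `"records"`.
#' @return a [feature_table()].
#' @export
records_to_table <- function(records, schema = default_schema("conventional"),
                             keep_records = FALSE) {
  rows <- t(vapply(records, conventional_block,
                   numeric(length(conventional_feature_names()))))
  labels <- vapply(records, `[[`, 0L, "label")
  groups <- vapply(records, `[[`, "", "complex_id")
  ddg <- lapply(records, `[[`, "ddg")
  ddg <- if (any(vapply(ddg, is.null, TRUE))) NULL else unlist(ddg)
  out <- feature_table(rows, labels, groups, schema, ddg = ddg)
  if (keep_records) attr(out, "records") <- records
  out
}

#' Split rows into train/test sets at the complex level
#'
#' Complexes (not rows) are sampled into the test set, so that no complex
#' contributes rows to both sides — the grouping that prevents information
#' leakage between homologous mutation sites.
#'
#' @param x a [feature_table()] or a list of [residue_record()]s.
#' @param n_test_complexes number of complexes to place in the test set.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return list with integer vectors `train_indices` and `test_indices`.
#' @export
split_by_complex <- function(x, n_test_complexes, seed) {
  groups <- if (inherits(x, "feature_table")) x$groups
            else vapply(x, `[[`, "", "complex_id")
  ids <- unique(groups)
  if (n_test_complexes >= length(ids)) {
    stop(sprintf("n_test_complexes (%d) must be < number of complexes (%d)",
                 n_test_complexes, length(ids)), call. = FALSE)
  }
  if (n_test_complexes < 1L) {
    stop("n_test_complexes must be >= 1", call. = FALSE)
  }
  test_ids <- with_seed(seed, sample(ids, n_test_complexes))
  test <- which(groups %in% test_ids)
  list(train_indices = setdiff(seq_along(groups), test),
       test_indices = test)
}
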