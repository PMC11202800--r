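# Assembly of the full feature table from residue records.

#' Build the full feature table from residue records
#'
#' Runs the wavelet and EMD extractors on every record and assembles rows in
#' schema order (conventional, wavelet, EMD).
#'
#' @param records list of [residue_record()]s.
#' @param emd_cfg an [emd_config()].
#' @param wavelet_cfg a [wavelet_config()].
#' @param schema output layout; defaults to the 218-column schema.
#' @return a [feature_table()].
#' @export
build_feature_table <- function(records, emd_cfg = emd_config(),
                                wavelet_cfg = wavelet_config(),
                                schema = default_schema()) {
  counts <- schema_block_counts(schema)
  rows <- t(vapply(records, function(rec) {
    wb <- if (counts[["wavelet"]] > 0L) extract_wavelet_block(rec, wavelet_cfg)
          else numeric(0)
    eb <- if (counts[["emd"]] > 0L) extract_emd_block(rec, emd_cfg)
          else numeric(0)
    assemble_features(rec, wb, eb, schema)
  }, numeric(length(schema))))
  labels <- vapply(records, `[[`, 0L, "label")
  groups <- vapply(records, `[[`, "", "complex_id")
  ddg <- lapply(records, `[[`, "ddg")
  ddg <- if (any(vapply(ddg, is.null, TRUE))) NULL else unlist(ddg)
  feature_table(rows, labels, groups, schema, ddg = ddg)
}
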