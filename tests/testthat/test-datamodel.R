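# Domain types, labeling, table I/O, complex-level splitting, assembly.

test_that("ddG labeling uses an inclusive 1.0 kcal/mol threshold", {
  expect_identical(label_from_ddg(1.0), 1L)
  expect_identical(label_from_ddg(0.999), 0L)
  expect_identical(label_from_ddg(-2.5), 0L)
  expect_identical(label_from_ddg(c(0.2, 3.1, 1.0)), c(0L, 1L, 1L))
  expect_identical(label_from_ddg(2.0, threshold = 2.5), 0L)
  expect_error(label_from_ddg(NaN), "finite")
})

test_that("residue records validate block lengths and required fields", {
  rec <- make_record(1)
  expect_s3_class(rec, "residue_record")
  expect_error(residue_record("1ABC", "A", 1, "R", ddg = 1,
                              asa_complex = 1:7, asa_unbound = 1:8,
                              asa_delta = 1:8, dssp = 1:6, dpx_cx = 1:12,
                              hbond_count = 0),
               "asa_complex")
  expect_error(residue_record("1ABC", "A", 1, "R",
                              asa_complex = 1:8, asa_unbound = 1:8,
                              asa_delta = 1:8, dssp = 1:6, dpx_cx = 1:12,
                              hbond_count = 0),
               "at least one")
  # label derived from ddg when absent
  expect_identical(make_record(2)$label, 1L)
})

test_that("schema has 218 uniquely named columns in three blocks", {
  sch <- default_schema()
  expect_length(sch, 218L)
  expect_false(anyDuplicated(sch$name) > 0)
  expect_identical(as.vector(table(factor(sch$block,
                     c("conventional", "wavelet", "emd")))),
                   c(43L, 132L, 43L))
  # shipped registry file matches the programmatic default
  shipped <- read_schema(system.file("extdata", "schema_default.json",
                                     package = "pdhotspot"))
  expect_identical(shipped$name, sch$name)
  expect_identical(shipped$block, sch$block)
})

test_that("feature assembly concatenates blocks to schema width", {
  rec <- make_record(3)
  wb <- extract_wavelet_block(rec)
  eb <- extract_emd_block(rec)
  row <- assemble_features(rec, wb, eb)
  expect_length(row, 218L)
  expect_identical(names(row), default_schema()$name)
  expect_identical(unname(row[1:8]), rec$asa_complex)
  expect_identical(unname(row[43]), rec$hbond_count)
  # conventional-only schema
  conv <- assemble_features(rec, schema = default_schema("conventional"))
  expect_length(conv, 43L)
  # length mismatches are schema errors
  expect_error(assemble_features(rec, wb[-1], eb), "wavelet")
  expect_error(assemble_features(rec, wb, eb[-1]), "emd")
})

test_that("assembly width equals schema length for random sub-schemas", {
  rec <- make_record(5)
  full <- default_schema()
  for (blocks in list("conventional", c("conventional", "emd"),
                      c("conventional", "wavelet"),
                      c("conventional", "wavelet", "emd"))) {
    sch <- default_schema(blocks)
    wb <- if ("wavelet" %in% blocks) extract_wavelet_block(rec) else numeric(0)
    eb <- if ("emd" %in% blocks) extract_emd_block(rec) else numeric(0)
    expect_length(assemble_features(rec, wb, eb, sch), length(sch))
  }
})

test_that("feature table CSV round-trips at full precision", {
  records <- generate_records(synth_spec(n_complexes = 6, seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(records, path)
  tab <- read_feature_table(path)
  orig <- records_to_table(records)
  expect_identical(tab$rows, orig$rows)
  expect_identical(tab$labels, orig$labels)
  expect_identical(tab$groups, orig$groups)
  expect_equal(tab$ddg, orig$ddg, tolerance = 0)
  # write what we read, read again: byte-stable values
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path2)
  expect_identical(read_feature_table(path2)$rows, tab$rows)
  # tsv dialect round-trips too
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab, path3, dialect = "tsv")
  expect_identical(read_feature_table(path3, dialect = "tsv")$rows, tab$rows)
})

test_that("reader rejects missing blocks and malformed numerics", {
  records <- generate_records(synth_spec(n_complexes = 3, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(records, path)
  dt <- data.table::fread(path)
  dt2 <- dt[, !grepl("^SS_", names(dt)), with = FALSE]
  path2 <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(dt2, path2)
  expect_error(read_feature_table(path2), "schema error.*SS_", ignore.case = TRUE)
  dt3 <- data.table::copy(dt)
  dt3$ASA_all_abs <- as.character(dt3$ASA_all_abs)
  dt3$ASA_all_abs[2] <- "not-a-number"
  path3 <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(dt3, path3)
  expect_error(read_feature_table(path3), "row 2.*ASA_all_abs")
})

test_that("complex-level splits never leak a complex across sides", {
  records <- generate_records(synth_spec(n_complexes = 117, seed = 31))
  sp <- split_by_complex(records, n_test_complexes = 25, seed = 7)
  groups <- vapply(records, `[[`, "", "complex_id")
  expect_length(intersect(groups[sp$train_indices], groups[sp$test_indices]),
                0L)
  expect_identical(sort(c(sp$train_indices, sp$test_indices)),
                   seq_along(records))
  expect_length(unique(groups[sp$test_indices]), 25L)
  # determinism
  sp2 <- split_by_complex(records, n_test_complexes = 25, seed = 7)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_by_complex(records, 25, seed = 8)))
  # grouping invariant across seeds
  for (seed in 1:10) {
    s <- split_by_complex(records, n_test_complexes = 10, seed = seed)
    expect_length(intersect(groups[s$train_indices], groups[s$test_indices]),
                  0L)
  }
  expect_error(split_by_complex(records, 117, seed = 1), "must be <")
})
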