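test_that("GCT round-trip preserves identifiers and values exactly", {
  path <- write_lines_tmp(c(
    "#1.2", "2\t2",
    "Name\tDescription\ts1\ts2",
    "gA\tdesc\t1\t2",
    "gB\tdesc\t3\t4"))
  m <- read_gct(path)
  expect_identical(dim(m), c(2L, 2L))
  expect_identical(unname(m), matrix(c(1, 3, 2, 4), nrow = 2))
  expect_identical(rownames(m), c("gA", "gB"))
  expect_identical(colnames(m), c("s1", "s2"))

  out <- withr::local_tempfile(fileext = ".gct")
  write_gct(m, out)
  expect_identical(read_gct(out), m)
})

test_that("malformed GCT files are rejected with format errors", {
  no_tag <- write_lines_tmp(c("2\t2", "Name\tDescription\ts1\ts2", "gA\td\t1\t2"))
  expect_error(read_gct(no_tag), class = "gendulf_format_error")

  wrong_rows <- write_lines_tmp(c(
    "#1.2", "3\t2", "Name\tDescription\ts1\ts2",
    "gA\td\t1\t2", "gB\td\t3\t4"))
  expect_error(read_gct(wrong_rows), class = "gendulf_format_error")

  dup <- write_lines_tmp(c(
    "#1.2", "2\t2", "Name\tDescription\ts1\ts2",
    "gA\td\t1\t2", "gA\td\t3\t4"))
  expect_error(read_gct(dup), class = "gendulf_duplicate_id_error")

  neg <- write_lines_tmp(c(
    "#1.2", "1\t2", "Name\tDescription\ts1\ts2", "gA\td\t-1\t2"))
  expect_error(read_gct(neg), class = "gendulf_value_error")
})

test_that("TSV matrices parse, drop fully blank rows, and reject lone blanks", {
  path <- write_lines_tmp(c("gene_id\ts1\ts2\ts3", "gA\t1\t2\t3"))
  m <- read_tsv_matrix(path)
  expect_identical(dim(m), c(1L, 3L))

  blank_row <- write_lines_tmp(c("gene_id\ts1\ts2", "gA\t1\t2", "gB\t\t"))
  expect_warning(m2 <- read_tsv_matrix(blank_row), "gB")
  expect_identical(rownames(m2), "gA")

  lone <- write_lines_tmp(c("gene_id\ts1\ts2", "gA\t1\tx"))
  expect_error(read_tsv_matrix(lone), class = "gendulf_value_error")

  ragged <- write_lines_tmp(c("gene_id\ts1\ts2", "gA\t1\t2", "gB\t3"))
  expect_error(read_tsv_matrix(ragged), class = "gendulf_format_error")
})

test_that("GCT and TSV readers agree on equivalent content", {
  gct <- write_lines_tmp(c(
    "#1.2", "2\t3", "Name\tDescription\ta\tb\tc",
    "g1\tx\t0.5\t1.5\t2.5", "g2\tx\t4\t5\t6"))
  tsv <- write_lines_tmp(c(
    "gene_id\ta\tb\tc", "g1\t0.5\t1.5\t2.5", "g2\t4\t5\t6"))
  expect_identical(read_gct(gct), read_tsv_matrix(tsv))
})

test_that("case-control studies apply the label partition with its edge rules", {
  mat <- write_lines_tmp(c("gene_id\ts1\ts2\ts3\ts4",
                           "gA\t1\t2\t3\t4"))
  labs <- write_lines_tmp(c("s1\tcase", "s2\tcase", "s3\tcontrol", "s4\tcontrol"))
  study <- read_case_control(mat, labs)
  expect_s3_class(study, "case_control_study")
  expect_length(study$case_ids, 2L)
  expect_length(study$control_ids, 2L)

  conflicting <- write_lines_tmp(c("s1\tcase", "s1\tcontrol",
                                   "s2\tcase", "s3\tcontrol", "s4\tcontrol"))
  expect_error(read_case_control(mat, conflicting), class = "gendulf_label_error")

  all_control <- write_lines_tmp(c("s1\tcontrol", "s2\tcontrol",
                                   "s3\tcontrol", "s4\tcontrol"))
  expect_error(read_case_control(mat, all_control),
               class = "gendulf_composition_error")

  partial <- write_lines_tmp(c("s1\tcase", "s3\tcontrol"))
  expect_warning(study2 <- read_case_control(mat, partial), "unlabelled")
  expect_identical(colnames(study2$matrix), c("s1", "s3"))
})

test_that("gene lists read as plain text or BED4 with 0-based half-open intervals", {
  plain <- write_lines_tmp(c("GENE1", "GENE2", "GENE3"))
  gl <- read_gene_list(plain)
  expect_identical(gl$gene_id, c("GENE1", "GENE2", "GENE3"))
  expect_true(all(is.na(gl$start)))

  bed <- write_lines_tmp(c("chr19\t100\t200\tCEACAM5"))
  gb <- read_gene_list(bed)
  expect_identical(gb$gene_id, "CEACAM5")
  expect_identical(gb$start, 100L)
  expect_identical(gb$end, 200L)

  dup <- write_lines_tmp(c("GENE1", "GENE1"))
  expect_error(read_gene_list(dup), class = "gendulf_duplicate_id_error")

  bad_iv <- write_lines_tmp(c("chr1\t200\t100\tX"))
  expect_error(read_gene_list(bad_iv), class = "gendulf_format_error")
})

test_that("record tables round-trip through TSV with full p-value precision", {
  recs <- data.frame(gene_id = c("gA", "gB"), N = c(100L, 100L),
                     k = c(9L, 2L), p_raw = c(5.263158e-3, 0.9312),
                     is_pm = c(TRUE, FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_records(recs, path)
  lines <- readLines(path)
  expect_length(lines, 3L)  # header + 2 records
  back <- read_records(path)
  expect_identical(back$gene_id, recs$gene_id)
  expect_identical(back$N, recs$N)
  expect_identical(back$k, recs$k)
  expect_equal(back$p_raw, recs$p_raw, tolerance = 1e-6)
  expect_identical(back$is_pm, recs$is_pm)

  empty <- recs[0, ]
  write_records(empty, path)
  expect_length(readLines(path), 1L)
})
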