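test_that("GFF3 coordinates convert to 0-based half-open and round-trip", {
  ann <- make_ann(
    tx("T1", "L1", "chr1", "+", "CDS-p", list(c(100, 200), c(300, 450))),
    tx("T2", "L2", "chr1", "-", "ncRNA", list(c(150, 260))))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, path)
  lines <- readLines(path)
  # 1-based closed on disk: internal [100, 200) prints as 101..200
  expect_match(lines[grepl("exon\t101\t200", lines)][1], "Parent=T1")
  back <- read_gff3(path)
  expect_equal(as.data.frame(back), as.data.frame(ann))
  expect_equal(nrow(transcript_spans(back)), 2L)
  expect_equal(sum(back$transcript_id == "T1"), 2L)
})

test_that("write_gff3 emits one transcript line plus one line per exon", {
  ann <- make_ann(tx("T1", "L1", "chr1", "+", "CDS-p",
                     list(c(0, 100), c(200, 300))))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, path)
  body <- readLines(path)[-1]
  expect_length(body, 3L)
  empty <- make_ann(tibble::tibble(
    transcript_id = character(), locus_id = character(), chrom = character(),
    strand = character(), biotype = character(), exon_start = integer(),
    exon_end = integer()))
  path2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(empty, path2)
  expect_equal(readLines(path2), "##gff-version 3")
})

test_that("malformed and inconsistent GFF3 input is rejected with context", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\ttranscript\t1\t100\t.\t+\t.\tID=T1;locus_id=L1;biotype=CDS-p",
               "chr1\tsrc\texon\t1\t100"), path)
  expect_error(read_gff3(path), "line 3")

  ann <- tibble::tibble(
    transcript_id = "T1", locus_id = "L1", chrom = "chr1",
    strand = c("+", "-"), biotype = "CDS-p",
    exon_start = c(0L, 200L), exon_end = c(100L, 300L))
  expect_error(validate_annotation(ann), "strand conflict")
  ann2 <- tx("T1", "L1", "chr1", "+", "protein_coding", list(c(0, 100)))
  expect_error(validate_annotation(ann2), "unknown biotype")
  ann3 <- tx("T1", "L1", "chr1", "+", "CDS-p", list(c(0, 100), c(50, 200)))
  expect_error(validate_annotation(ann3), "non-overlapping")
})

test_that("exonic length never exceeds span length, equal iff gap-free", {
  spliced <- transcript_spans(make_ann(
    tx("T1", "L1", "chr1", "+", "CDS-p", list(c(0, 100), c(200, 300)))))
  expect_lt(spliced$exonic_length, spliced$end - spliced$start)
  contiguous <- transcript_spans(make_ann(
    tx("T2", "L2", "chr1", "+", "CDS-p", list(c(0, 300)))))
  expect_equal(contiguous$exonic_length, contiguous$end - contiguous$start)
})

test_that("BED6 small-RNA reads parse with copies, lengths and 5' nucleotide", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t124\tr1_TACGTACGTACGTACGTACGTACG\t5\t+",
               "chr1\t500\t521\tr2_GGGTTTAAACCCGGGTTTAAA\t2\t-",
               "chr2\t10\t30\tr3\t1\t+"), path)
  reads <- read_smallrna_bed(path, condition = "cold")
  expect_equal(reads$length, c(24L, 21L, 20L))
  expect_equal(reads$copies, c(5L, 2L, 1L))
  # sequence is given in read orientation: first character as-is, even on -
  expect_equal(reads$first_nt, c("T", "G", "N"))
  expect_true(all(reads$condition == "cold"))

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_equal(nrow(read_smallrna_bed(empty)), 0L)
})

test_that("invalid BED records are rejected", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t124\tr1\t0\t+", path)
  expect_error(read_smallrna_bed(path), "copy count")
  writeLines("chr1\t124\t100\tr1\t3\t+", path)
  expect_error(read_smallrna_bed(path), "start >= end")
})

test_that("expression tables validate keys, signs and required columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  grid <- tidyr::expand_grid(transcript_id = c("T1", "T2"),
                             condition = c("control", "salt", "cold", "drought"))
  grid$fpkm <- c(3.2, 0, 1.1, 2.2, 0.5, 4.4, 0.1, 9)
  grid$fragment_count <- 10L
  grid$library_size <- 1e6
  readr::write_tsv(grid, path)
  expr <- read_expression_table(path)
  expect_equal(nrow(expr), 8L)
  expect_true(any(expr$fpkm == 0))   # zero FPKM encodes "not expressed"

  readr::write_tsv(grid[, setdiff(names(grid), "library_size")], path)
  expect_error(read_expression_table(path), "library_size")
  readr::write_tsv(dplyr::bind_rows(grid, grid[1, ]), path)
  expect_error(read_expression_table(path), "duplicate")
  bad <- grid
  bad$fpkm[1] <- -1
  readr::write_tsv(bad, path)
  expect_error(read_expression_table(path), "fpkm")
})
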