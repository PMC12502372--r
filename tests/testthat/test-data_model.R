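test_that("FASTA reader handles UniProt headers, bare ids and normalization", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|P00001|TEST1_HUMAN Some protein GN=TST1",
               "RGGRGG",
               ">seq1",
               "acdef*"), f)
  rec <- read_fasta(f)
  expect_equal(rec$accession, c("P00001", "seq1"))
  expect_equal(rec$length, c(6L, 5L))
  expect_equal(rec$sequence[2L], "ACDEF")
  expect_equal(rec$gene_name[1L], "TST1")
})

test_that("FASTA reader rejects duplicate accessions and empty sequences", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|P00001|A x", "RG", ">sp|P00001|B y", "GG"), f)
  expect_error(read_fasta(f), "P00001")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">empty1", "*"), f2)
  expect_error(read_fasta(f2), "empty sequence")
})

write_ann <- function(rows) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("accession\tkind\tpayload", rows), f)
  f
}

test_that("annotation reader converts 1-based inclusive to half-open and merges disorder", {
  rec <- data.frame(accession = "P00001", gene_name = NA, description = "",
                    sequence = strrep("A", 20), length = 20L)
  p <- read_annotations(write_ann("P00001\tdisorder\t1-10"), rec)
  expect_equal(p$disorder[["P00001"]], iv(0L, 10L), ignore_attr = TRUE)

  p2 <- read_annotations(write_ann(c("P00001\tdisorder\t1-5",
                                     "P00001\tdisorder\t4-8")), rec)
  expect_equal(p2$disorder[["P00001"]], iv(0L, 8L), ignore_attr = TRUE)

  expect_error(read_annotations(write_ann("P00001\tsaps\t1.3"), rec),
               "saps")
  expect_error(read_annotations(write_ann("P00001\tdisorder\t5-30"), rec),
               "out of bounds")
})

test_that("annotation rows for unknown accessions are skipped with a message", {
  rec <- data.frame(accession = "P00001", gene_name = NA, description = "",
                    sequence = "AAAA", length = 4L)
  expect_message(
    p <- read_annotations(write_ann(c("P00001\tgo\tGO:1",
                                      "PXXXXX\tgo\tGO:2")), rec),
    "unknown accession")
  expect_equal(p$go[["P00001"]], "GO:1")
})

test_that("written tables use 1-based inclusive coordinates and sorted rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  rows <- data.frame(accession = c("B1", "A1"), start = c(0L, 5L),
                     end = c(10L, 9L), score = c(0.123456789, 1))
  write_table(rows, f)
  lines <- readLines(f)
  expect_equal(lines[2L], "A1\t6\t9\t1")         # sorted by accession
  expect_equal(lines[3L], "B1\t1\t10\t0.123457") # 6 significant digits

  empty <- rows[0L, ]
  write_table(empty, f)
  expect_equal(length(readLines(f)), 1L)  # header only
})

test_that("interval coordinates round-trip through write and re-read", {
  set.seed(11)
  n <- 1000L
  starts <- sample.int(500L, n, replace = TRUE) - 1L
  ends <- starts + sample.int(80L, n, replace = TRUE)
  rows <- data.frame(accession = sprintf("P%04d", seq_len(n)),
                     start = starts, end = ends,
                     midr_start = starts, midr_end = ends)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_table(rows, f)
  back <- read_result_table(f)
  expect_equal(back$start, rows$start)
  expect_equal(back$end, rows$end)
  expect_equal(back$midr_start, rows$midr_start)
})

test_that("disorder intervals are sorted, disjoint and in bounds after read", {
  set.seed(7)
  for (rep in 1:20) {
    len <- sample(50:300, 1L)
    rec <- data.frame(accession = "P1", gene_name = NA, description = "",
                      sequence = strrep("A", len), length = len)
    k <- sample(1:6, 1L)
    s1 <- sample.int(len - 1L, k, replace = TRUE)
    e1 <- pmin(len, s1 + sample.int(40L, k, replace = TRUE))
    rows <- sprintf("P1\tdisorder\t%d-%d", s1, e1)
    p <- read_annotations(write_ann(rows), rec)
    ivs <- p$disorder[["P1"]]
    expect_true(all(ivs$start < ivs$end))
    expect_true(all(ivs$end <= len))
    if (nrow(ivs) > 1L) {
      expect_true(all(ivs$start[-1L] > ivs$end[-nrow(ivs)]))
    }
  }
})
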