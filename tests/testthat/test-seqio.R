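test_that("FASTA parsing handles minimal, multi-line and empty input", {
  r <- parse_fasta(">s1 desc\nACGT\n")
  expect_equal(r$id, "s1")
  expect_equal(r$name, "s1 desc")
  expect_equal(r$seq, "ACGT")
  expect_true(is.na(r$qual))
  expect_equal(r$source_index, 0L)

  r2 <- parse_fasta(">a\nAC\nGT\n>b\nNNN\n")
  expect_equal(r2$seq, c("ACGT", "NNN"))
  expect_equal(r2$source_index, 0:1)

  expect_equal(nrow(parse_fasta("")), 0L)
  # blank lines between records are ignored; CRLF accepted
  r3 <- parse_fasta(">a\r\nAC\r\n\r\n>b\r\nGT\r\n")
  expect_equal(r3$seq, c("AC", "GT"))
})

test_that("malformed FASTA is rejected with the byte offset", {
  expect_error(parse_fasta("ACGT\n>a\nAC\n"), "offset 0",
               class = "fastkit_data_error")
  expect_error(parse_fasta("\n\nACGT\n"), "offset 2",
               class = "fastkit_data_error")
})

test_that("FASTQ parsing is strictly 4-line with validated structure", {
  r <- parse_fastq("@r1\nACGT\n+\nIIII\n")
  expect_equal(r$seq, "ACGT")
  expect_equal(r$qual, "IIII")
  # named separator line accepted
  r2 <- parse_fastq("@r1\nAC\n+r1\nII\n")
  expect_equal(r2$qual, "II")
  expect_equal(nrow(parse_fastq("")), 0L)
  # length mismatch carries the record ordinal
  expect_error(parse_fastq("@r1\nACGT\n+\nIII\n"), "ordinal 0",
               class = "fastkit_data_error")
  expect_error(parse_fastq("@r1\nACGT\nX\nIIII\n"), "separator",
               class = "fastkit_data_error")
  expect_error(parse_fastq("@r1\nACGT\n+\n"), "multiple of 4",
               class = "fastkit_data_error")
})

test_that("record boundaries are found by full-record validation", {
  # first candidate '@' line fails its 4-line parse (putative '+' is AAAA)
  expect_equal(find_record_boundary("@@@@\n@r2\nAAAA\n+\nIIII\n", "fastq", 0L), 5L)
  expect_equal(find_record_boundary("GT\n>b\nNNN\n", "fasta", 0L), 3L)
  # no header: one-past-end sentinel
  expect_equal(find_record_boundary("ACGT\nTTTT\n", "fasta", 0L), 10L)
  # search_from skips earlier headers
  expect_equal(find_record_boundary(">a\nAC\n>b\nGT\n", "fasta", 1L), 6L)
  # a quality line starting '@' is not mistaken for a header
  buf <- "@r1\nACGT\n+\n@III\n@r2\nTTTT\n+\nJJJJ\n"
  expect_equal(find_record_boundary(buf, "fastq", 1L), 16L)
})

test_that("splitting at arbitrary offsets and resynchronizing loses nothing", {
  for (fmt in c("fasta", "fastq")) {
    recs <- rand_records(40, seed = 101, fastq = fmt == "fastq")
    text <- write_records(recs, fmt)
    whole <- if (fmt == "fasta") parse_fasta(text) else parse_fastq(text)
    nb <- nchar(text, type = "bytes")
    set.seed(7)
    offs <- sample.int(nb, 200, replace = TRUE)
    parse_fn <- if (fmt == "fasta") parse_fasta else parse_fastq
    for (o in offs) {
      r <- find_record_boundary(text, fmt, o)
      left <- parse_fn(substr(text, 1L, r))
      right <- parse_fn(substr(text, r + 1L, nb))
      got <- rbind(left, right)
      expect_equal(got$name, whole$name)
      expect_equal(got$seq, whole$seq)
      expect_equal(got$qual, whole$qual)
    }
  }
})

test_that("writing wraps FASTA and round-trips both formats exactly", {
  one <- seq_records("id", "ACGTA")
  expect_equal(write_records(one, "fasta", wrap = 2L), ">id\nAC\nGT\nA\n")
  expect_equal(write_records(one, "fasta", wrap = 0L), ">id\nACGTA\n")
  # exact-multiple wrap leaves no blank line
  expect_equal(write_records(seq_records("x", "ACGT"), "fasta", wrap = 2L),
               ">x\nAC\nGT\n")
  expect_error(write_records(one, "fastq"), class = "fastkit_usage_error")

  for (fmt in c("fasta", "fastq")) {
    recs <- rand_records(500, seed = 55, fastq = fmt == "fastq")
    wraps <- if (fmt == "fasta") c(0L, 7L, 60L) else 0L
    for (w in wraps) {
      back <- if (fmt == "fasta") {
        parse_fasta(write_records(recs, fmt, wrap = w))
      } else {
        parse_fastq(write_records(recs, fmt))
      }
      expect_equal(back, recs)
    }
  }
})

test_that("FAI entries match hand-computed byte offsets", {
  fa <- write_bytes(">s1\nACGTA\nCGT\n", tempfile(fileext = ".fa"))
  e <- build_fai(fa)
  expect_equal(unname(unlist(e[1, ])),
               c("s1", "8", "4", "5", "6"))
  expect_true(file.exists(paste0(fa, ".fai")))

  fq <- write_tmp(parse_fastq("@r1\nACGT\n+\nIIII\n"), "fastq")
  eq <- build_fai(fq)
  expect_equal(as.numeric(eq[1, -1]), c(4, 4, 4, 5, 11))
  expect_equal(ncol(eq), 6L)

  # ragged interior lines violate the samtools layout
  bad <- write_bytes(">s\nACGTA\nACGTAA\nAC\n", tempfile(fileext = ".fa"))
  expect_error(build_fai(bad), "different lengths", class = "fastkit_data_error")

  # duplicate names would make index lookups ambiguous
  dup <- write_tmp(parse_fasta(">a\nAC\n>a\nGT\n"), "fasta")
  expect_error(build_fai(dup), "duplicate", class = "fastkit_data_error")
})

test_that("FAI files are byte-identical to the reference fixtures", {
  for (f in c("ref.fa", "ref.fq")) {
    src <- test_path("fixtures", f)
    tmp <- tempfile(fileext = paste0(".", tools::file_ext(f)))
    file.copy(src, tmp)
    build_fai(tmp)
    expect_identical(file_bytes(paste0(tmp, ".fai")),
                     file_bytes(test_path("fixtures", paste0(f, ".fai"))))
  }
})

test_that("FAI agrees with samtools on generated files of both formats", {
  dir <- withr::local_tempdir()
  fa <- generate_fixture(fixture_spec(n_records = 25, seed = 31), dir, "sam_fa")$paths[1]
  fq <- generate_fixture(fixture_spec(n_records = 20, seed = 32, format = "fastq"),
                         dir, "sam_fq")$paths[1]
  ours_fa <- write_fai(build_fai(fa, write = FALSE))
  ours_fq <- write_fai(build_fai(fq, write = FALSE))
  system2("samtools", c("faidx", fa))
  system2("samtools", c("fqidx", fq))
  expect_identical(ours_fa, rawToChar(file_bytes(paste0(fa, ".fai"))))
  expect_identical(ours_fq, rawToChar(file_bytes(paste0(fq, ".fai"))))
})

test_that("CRLF input parses and indexes with the original line width", {
  tmp <- write_bytes(">w\r\nACG\r\nAC\r\n", tempfile(fileext = ".fa"))
  r <- parse_fasta(read_file_text(tmp))
  expect_equal(r$seq, "ACGAC")
  e <- build_fai(tmp, write = FALSE)
  expect_equal(as.numeric(e[1, -1]), c(5, 4, 3, 5))
})

test_that("regions fetch through offset arithmetic, clamped and 1-based", {
  fa <- write_tmp(parse_fasta(">s\nACGTACGT\n"), "fasta")
  fai <- build_fai(fa)
  expect_equal(fetch_region(fa, fai, "s:2-4")$seq, "CGT")
  expect_equal(fetch_region(fa, fai, "s:1-8")$seq, "ACGTACGT")
  expect_equal(fetch_region(fa, fai, "s:7-99")$seq, "GT")
  expect_equal(fetch_region(fa, fai, "s:2-4")$id, "s:2-4")
  expect_equal(fetch_region(fa, fai, "s:-3--1")$seq, "CGT")
  expect_equal(fetch_region(fa, fai, "s:9-10")$seq, "")
  expect_error(fetch_region(fa, fai, "nope:1-2"), class = "fastkit_usage_error")

  # multi-line wrapped records round-trip through the index
  recs <- rand_records(60, seed = 77, min_len = 1L, max_len = 200L)
  path <- write_tmp(recs, "fasta")
  fai2 <- build_fai(path, write = FALSE)
  for (i in seq_len(nrow(recs))) {
    got <- fetch_region(path, fai2, sprintf("%s:1-%d", recs$id[i],
                                            nchar(recs$seq[i])))
    expect_identical(got$seq, recs$seq[i])
  }
})

test_that("gzip input parses but refuses FAI building", {
  recs <- rand_records(20, seed = 5)
  gz <- tempfile(fileext = ".fa.gz")
  write_records(recs, "fasta", path = gz)
  ds <- partition_file(gz, partitions = 3L)
  expect_equal(pd_collect(ds)$seq, recs$seq)
  expect_error(build_fai(gz), "gzip", class = "fastkit_usage_error")
})

test_that("empty sequences are legal records and indexable", {
  txt <- ">e\n>f\nAC\n"
  r <- parse_fasta(txt)
  expect_equal(r$seq, c("", "AC"))
  tmp <- write_bytes(txt, tempfile(fileext = ".fa"))
  e <- build_fai(tmp, write = FALSE)
  expect_equal(e$length, c(0L, 2L))
  expect_equal(e$name, c("e", "f"))
})
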