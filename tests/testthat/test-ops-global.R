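test_that("hypergeometric split allocates exactly and degenerately", {
  expect_equal(hypergeometric_split(c(4L, 6L), 10L, seed = 1L), c(4L, 6L))
  expect_equal(hypergeometric_split(c(3L, 5L, 2L), 0L, seed = 1L), c(0L, 0L, 0L))
  expect_error(hypergeometric_split(c(2L, 2L), 5L, seed = 1L),
               class = "fastkit_usage_error")
  for (s in 1:50) {
    sizes <- sample(0:20, sample(2:5, 1), replace = TRUE)
    n <- sample(0:sum(sizes), 1)
    ks <- hypergeometric_split(sizes, n, seed = s)
    expect_equal(sum(ks), n)
    expect_true(all(ks >= 0L & ks <= sizes))
  }
})

test_that("sampling is order-preserving, exact in count and unbiased in proportion", {
  recs <- rand_records(40, seed = 23)
  ds <- as_pdataset(recs, partitions = 3L)
  expect_equal(fk_sample(ds, n = 40L, seed = 1L), recs)
  expect_equal(fk_sample(ds, p = 1.0, seed = 1L), recs)
  expect_equal(nrow(fk_sample(ds, p = 0.0, seed = 1L)), 0L)
  sm <- fk_sample(ds, n = 13L, seed = 2L)
  expect_equal(nrow(sm), 13L)
  expect_false(is.unsorted(sm$source_index))
  expect_error(fk_sample(ds, n = 3L, p = 0.5), class = "fastkit_usage_error")

  # proportion mode is partitioning-invariant and within the binomial bound
  big <- rand_records(10000, seed = 24, min_len = 5L, max_len = 6L)
  kept1 <- fk_sample(as_pdataset(big, partitions = 1L), p = 0.3, seed = 7L)
  kept8 <- fk_sample(as_pdataset(big, partitions = 8L), p = 0.3, seed = 7L)
  expect_equal(kept1, kept8)
  expect_lt(abs(nrow(kept1) / 10000 - 0.3), 0.015)
})

test_that("rmdup keeps first occurrences and survives forced hash collisions", {
  recs <- seq_records(c("a", "b", "a", "c", "b"), c("A", "C", "G", "T", "AA"))
  got <- fk_rmdup(recs, by = "id")
  expect_equal(got$source_index, c(0L, 1L, 3L))
  uniq <- rand_records(20, seed = 25)
  expect_equal(fk_rmdup(uniq, by = "id"), uniq)
  # distinct keys under a constant hash must all survive
  forced <- fk_rmdup(uniq, by = "id", hash_fn = function(k, m) rep(0L, length(k)))
  expect_equal(forced, uniq)
  # idempotence for every key choice
  dup <- rand_records(50, seed = 26, dup_ids = TRUE)
  for (by in c("id", "name", "seq")) {
    once <- fk_rmdup(dup, by = by)
    expect_equal(fk_rmdup(once, by = by), once)
  }
  # first-occurrence linear-scan oracle
  for (case in 1:30) {
    r <- rand_records(sample(2:40, 1), seed = 600 + case, dup_ids = TRUE)
    expect_equal(fk_rmdup(r, by = "id"), r[!duplicated(id)])
    expect_equal(fk_rmdup(r, by = "seq"), r[!duplicated(seq)])
  }
  d <- fk_rmdup(seq_records(c("a", "A", "b"), c("x", "y", "z")), by = "id",
                ignore_case = TRUE)
  expect_equal(d$id, c("a", "b"))
})

test_that("common intersects files by key and emits from the first file", {
  f1 <- parse_fasta(">x\nAC\n>z\nTT\n")
  f2 <- parse_fasta(">w\nGG\n>x\nAC\n")
  f3 <- parse_fasta(">x\nAC\n>q\nCC\n")
  expect_equal(fk_common(list(f1, f2, f3), by = "id")$id, "x")
  disjoint <- fk_common(list(parse_fasta(">a\nA\n"), parse_fasta(">b\nC\n")))
  expect_equal(nrow(disjoint), 0L)
  # by sequence, different ids
  s1 <- parse_fasta(">p\nACGT\n")
  s2 <- parse_fasta(">q\nACGT\n")
  expect_equal(fk_common(list(s1, s2), by = "seq")$id, "p")
  expect_error(fk_common(list(f1)), class = "fastkit_usage_error")
  # identity on duplicated inputs
  r <- rand_records(30, seed = 27)
  expect_equal(fk_common(list(r, r, r), by = "id")[, !"source_tag"],
               r[, !"source_tag"])
  # brute-force multiset-intersection oracle on ids
  for (case in 1:30) {
    a <- rand_records(sample(2:20, 1), seed = 700 + case, dup_ids = TRUE)
    a <- a[!duplicated(id)]
    b <- rand_records(sample(2:20, 1), seed = 800 + case, dup_ids = TRUE)
    b <- b[!duplicated(id)]
    want <- a[id %in% intersect(a$id, b$id)]
    expect_equal(fk_common(list(a, b), by = "id")[, !"source_tag"],
                 want[, !"source_tag"])
  }
})

test_that("pair matches mates by stripped id across two files", {
  f1 <- parse_fastq("@r1/1\nAC\n+\nII\n@r2/1\nGG\n+\nII\n")
  f2 <- parse_fastq("@r2/2\nTT\n+\nII\n@r3/2\nCC\n+\nII\n")
  pr <- fk_pair(f1, f2)
  expect_equal(pr$paired_1$id, "r2/1")
  expect_equal(pr$paired_2$id, "r2/2")
  expect_equal(pr$unpaired_1$id, "r1/1")
  expect_equal(pr$unpaired_2$id, "r3/2")
  # identical id sets pair fully in file-1 order
  all1 <- parse_fastq("@b/1\nAC\n+\nII\n@a/1\nGG\n+\nII\n")
  all2 <- parse_fastq("@a/2\nTT\n+\nII\n@b/2\nCC\n+\nII\n")
  pr2 <- fk_pair(all1, all2)
  expect_equal(pr2$paired_1$id, c("b/1", "a/1"))
  expect_equal(pr2$paired_2$id, c("b/2", "a/2"))
  expect_equal(nrow(pr2$unpaired_1), 0L)
  # empty mate file
  pr3 <- fk_pair(f1, parse_fastq(""))
  expect_equal(nrow(pr3$paired_1), 0L)
  expect_equal(pr3$unpaired_1$id, f1$id)
  dupd <- parse_fastq("@r1/1\nAC\n+\nII\n@r1/1\nGG\n+\nII\n")
  expect_error(fk_pair(dupd, f2), "r1", class = "fastkit_data_error")
  # paired fixture ground truth
  fx <- generate_fixture(fixture_spec(n_records = 60, seed = 33, format = "fastq",
                                      paired = TRUE, unpaired_rate = 0.3),
                         withr::local_tempdir(), "pairfx")
  ds1 <- partition_file(fx$paths[1], partitions = 2L)
  ds2 <- partition_file(fx$paths[2], partitions = 3L)
  got <- fk_pair(ds1, ds2)
  both <- fx$truth[in_file1 & in_file2]
  expect_equal(sub("/1$", "", got$paired_1$id), both$id)
  expect_equal(nrow(got$unpaired_1), sum(fx$truth$in_file1 & !fx$truth$in_file2))
})

test_that("concat joins same-id sequences in file order", {
  f1 <- parse_fasta(">x\nAC\n>only\nGG\n")
  f2 <- parse_fasta(">x\nGT\n")
  got <- fk_concat(list(f1, f2))
  expect_equal(got$id, "x")
  expect_equal(got$seq, "ACGT")
  dup <- parse_fasta(">x\nA\n>x\nC\n")
  expect_error(fk_concat(list(dup, f2)), class = "fastkit_data_error")
  # qualities concatenate when all inputs are FASTQ
  q1 <- parse_fastq("@x\nAC\n+\nIJ\n")
  q2 <- parse_fastq("@x\nGT\n+\nKL\n")
  cq <- fk_concat(list(q1, q2))
  expect_equal(cq$qual, "IJKL")
  # per-id sequential join oracle over 3 files
  for (case in 1:20) {
    fs <- lapply(1:3, function(i) {
      r <- rand_records(sample(2:12, 1), seed = 900 + 10 * case + i)
      r$id <- sprintf("r%d", sample(1:12, nrow(r)))
      r$name <- r$id
      r
    })
    shared <- Reduce(intersect, lapply(fs, `[[`, "id"))
    want <- vapply(shared, function(i) {
      paste(vapply(fs, function(f) f$seq[f$id == i], character(1)), collapse = "")
    }, character(1))
    first_order <- fs[[1]]$id[fs[[1]]$id %in% shared]
    got <- fk_concat(fs)
    expect_equal(got$id, first_order)
    expect_equal(got$seq, unname(want[first_order]))
  }
})

test_that("rename suffixes duplicate ids in occurrence order", {
  got <- fk_rename(parse_fasta(">a\nA\n>a\nC\n>a\nG\n"))
  expect_equal(got$id, c("a", "a_2", "a_3"))
  uniq <- rand_records(15, seed = 28)
  expect_equal(fk_rename(uniq), uniq)
  for (case in 1:10) {
    r <- rand_records(40, seed = 950 + case, dup_ids = TRUE)
    out <- fk_rename(r)
    expect_false(anyDuplicated(out$id) > 0L)
    expect_equal(out$seq, r$seq)
  }
  # names keep their descriptions
  d <- fk_rename(parse_fasta(">a hello\nA\n>a world\nC\n"))
  expect_equal(d$name, c("a hello", "a_2 world"))
})

test_that("sort orders records by any field, stably, via the sample sort", {
  recs <- seq_records(c("b", "a", "c"), c("AAA", "A", "AA"))
  expect_equal(fk_sort(recs, by = "id")$id, c("a", "b", "c"))
  expect_equal(fk_sort(recs, by = "length", descending = TRUE)$seq,
               c("AAA", "AA", "A"))
  big <- rand_records(1000, seed = 29, dup_ids = TRUE)
  for (by in c("id", "name", "seq", "length")) {
    keyv <- if (by == "length") nchar(big$seq) else big[[by]]
    want <- big[order(keyv, source_index, method = "radix")]
    for (np in c(1L, 4L)) {
      expect_equal(fk_sort(as_pdataset(big, partitions = np), by = by), want)
    }
  }
  # sort-then-rmdup equals sorted first occurrences
  srt <- fk_sort(big, by = "id")
  lhs <- fk_rmdup(srt[, .SD, .SDcols = names(big)][, source_index := .I - 1L],
                  by = "id")
  firsts <- big[!duplicated(id)]
  expect_equal(lhs$id, sort(firsts$id, method = "radix"))
})

test_that("shuffle is a seeded deterministic permutation", {
  recs <- rand_records(50, seed = 30)
  s1 <- fk_shuffle(recs, seed = 4L)
  s2 <- fk_shuffle(recs, seed = 4L)
  expect_equal(s1, s2)
  expect_equal(sort(s1$source_index), recs$source_index)
  expect_false(identical(fk_shuffle(recs, seed = 5L)$id, s1$id))
})
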