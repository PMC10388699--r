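## fixtures: deterministic synthetic FASTA/FASTQ generation. Every byte is a
## pure function of the spec's seed (through the package PRF), so the same
## spec always produces byte-identical files. The generator records ground
## truth (duplicate classes, pair table, per-record lengths) alongside the
## files so test oracles never re-derive truth from the code under test.

#' Describe a synthetic FASTA/FASTQ fixture
#'
#' @param n_records number of records.
#' @param length_law sequence-length distribution: `list(type = "fixed",
#'   length =)`, `list(type = "uniform", min =, max =)`, or `list(type =
#'   "mixture")` (80% short reads 30-80 bp, 20% long fragments 500-2000 bp,
#'   a skewed spread emulating mixed assemblies).
#' @param alphabet `"ACGT"`, `"ACGTN"` (2% N) or `"protein"`.
#' @param dup_rate fraction of records (after the first) that are copies of
#'   an earlier record.
#' @param dup_key what a copy shares: `"record"` (id and sequence),
#'   `"seq"` (sequence only, fresh id) or `"id"` (id only, fresh sequence).
#' @param gap_rate per-base probability of a `-` gap symbol.
#' @param qual_range inclusive Phred score range for FASTQ qualities.
#' @param format `"fasta"` or `"fastq"`.
#' @param paired emit two FASTQ files with `/1`-`/2` id suffixes.
#' @param unpaired_rate fraction of ids present in only one of the two
#'   paired files.
#' @param seed integer seed determining every byte.
#' @return a fixture spec list.
#' @export
fixture_spec <- function(n_records = 100L,
                         length_law = list(type = "uniform", min = 50L, max = 150L),
                         alphabet = "ACGT", dup_rate = 0, dup_key = "record",
                         gap_rate = 0, qual_range = c(2L, 40L),
                         format = "fasta", paired = FALSE, unpaired_rate = 0,
                         seed = 1L) {
  spec <- list(n_records = as.integer(n_records), length_law = length_law,
               alphabet = alphabet, dup_rate = dup_rate, dup_key = dup_key,
               gap_rate = gap_rate, qual_range = qual_range, format = format,
               paired = paired, unpaired_rate = unpaired_rate,
               seed = as.integer(seed))
  if (spec$n_records < 0L) usage_error("n_records must be >= 0")
  for (p in c("dup_rate", "gap_rate", "unpaired_rate")) {
    if (spec[[p]] < 0 || spec[[p]] > 1) {
      usage_error(sprintf("%s must be a probability in [0, 1]", p))
    }
  }
  if (spec$dup_rate > 0 && spec$n_records < 2L) {
    usage_error("dup_rate > 0 needs at least 2 records")
  }
  if (spec$paired && spec$format != "fastq") {
    usage_error("paired fixtures are FASTQ only")
  }
  spec
}

.fix_len <- function(law, u1, u2) {
  switch(law$type,
    fixed = law$length,
    uniform = law$min + floor(u1 * (law$max - law$min + 1L)),
    mixture = if (u1 < 0.8) 30L + floor(u2 * 51) else 500L + floor(u2 * 1501),
    usage_error(sprintf("unknown length law '%s'", law$type)))
}

.fix_alphabet <- function(alphabet) {
  switch(alphabet,
    ACGT = c("A", "C", "G", "T"),
    ACGTN = c(rep(c("A", "C", "G", "T"), 49L), rep("N", 4L)),
    protein = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
    usage_error(sprintf("unknown alphabet '%s'", alphabet)))
}

.fix_seq <- function(len, letters_, seed, stream, gap_rate) {
  if (len == 0L) return("")
  u <- prf_unif(seed, stream, seq_len(len))
  chars <- letters_[floor(u * length(letters_)) + 1L]
  if (gap_rate > 0) {
    g <- prf_unif(seed, stream + 1L, seq_len(len))
    chars[g < gap_rate] <- "-"
  }
  paste(chars, collapse = "")
}

.fix_qual <- function(len, qr, seed, stream) {
  if (len == 0L) return("")
  u <- prf_unif(seed, stream, seq_len(len))
  q <- qr[1] + floor(u * (qr[2] - qr[1] + 1L))
  rawToChar(as.raw(q + 33L))
}

#' Generate a synthetic fixture
#'
#' Writes the FASTA/FASTQ file(s) described by the spec plus a tab-separated
#' ground-truth sidecar (`<prefix>.truth.tsv`) listing, per record: id,
#' length, whether it is a duplicate and of which earlier record, and (for
#' paired output) its mate status.
#'
#' @param spec a spec from [fixture_spec()].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return a list: `paths` (the data files), `truth` (the ground-truth
#'   `data.table`, also written to the sidecar), `records` (file-1 records).
#' @export
generate_fixture <- function(spec, dir = tempdir(), prefix = "fixture") {
  n <- spec$n_records
  seed <- spec$seed
  letters_ <- .fix_alphabet(spec$alphabet)
  fastq <- spec$format == "fastq"
  ids <- sprintf("%s%04d", if (fastq) "read" else "seq", seq_len(n))
  u_len1 <- prf_unif(seed, 21L, seq_len(n))
  u_len2 <- prf_unif(seed, 22L, seq_len(n))
  u_dup <- prf_unif(seed, 23L, seq_len(n))
  u_src <- prf_unif(seed, 24L, seq_len(n))
  lens <- integer(n)
  seqs <- character(n)
  quals <- if (fastq) character(n) else rep(NA_character_, n)
  dup_of <- rep(NA_integer_, n)
  if (n > 0L) {
    for (i in seq_len(n)) {
      is_dup <- i > 1L && u_dup[i] < spec$dup_rate
      if (is_dup) {
        j <- floor(u_src[i] * (i - 1L)) + 1L
        dup_of[i] <- j
        if (spec$dup_key %in% c("record", "seq")) {
          lens[i] <- lens[j]
          seqs[i] <- seqs[j]
        } else {
          lens[i] <- .fix_len(spec$length_law, u_len1[i], u_len2[i])
          seqs[i] <- .fix_seq(lens[i], letters_, seed, 1000L + 3L * i, spec$gap_rate)
        }
        if (spec$dup_key == "record") ids[i] <- ids[j]
        if (spec$dup_key == "id") ids[i] <- ids[j]
      } else {
        lens[i] <- .fix_len(spec$length_law, u_len1[i], u_len2[i])
        seqs[i] <- .fix_seq(lens[i], letters_, seed, 1000L + 3L * i, spec$gap_rate)
      }
      if (fastq) quals[i] <- .fix_qual(lens[i], spec$qual_range, seed, 2000000L + i)
    }
  }
  names_ <- paste0(ids, " synthetic record ", seq_len(n))
  if (n == 0L) names_ <- character(0)
  truth <- data.table(ordinal = seq_len(n) - 1L, id = ids, length = lens,
                      dup_of = dup_of)
  ext <- if (fastq) "fastq" else "fasta"
  if (spec$paired) {
    u_un <- prf_unif(seed, 25L, seq_len(n))
    u_side <- prf_unif(seed, 26L, seq_len(n))
    in1 <- u_un >= spec$unpaired_rate | u_side < 0.5
    in2 <- u_un >= spec$unpaired_rate | u_side >= 0.5
    mk <- function(mask, mate) {
      sel <- which(mask)
      seq_records(paste0(ids[sel], "/", mate, " synthetic mate ", mate),
                  seqs[sel], quals[sel])
    }
    r1 <- mk(in1, 1L)
    r2 <- mk(in2, 2L)
    p1 <- file.path(dir, paste0(prefix, "_1.", ext))
    p2 <- file.path(dir, paste0(prefix, "_2.", ext))
    write_records(r1, "fastq", path = p1)
    write_records(r2, "fastq", path = p2)
    truth[, `:=`(in_file1 = in1, in_file2 = in2)]
    paths <- c(p1, p2)
    records <- r1
  } else {
    records <- seq_records(names_, seqs, quals)
    paths <- file.path(dir, paste0(prefix, ".", ext))
    write_records(records, ext, path = paths)
  }
  tpath <- file.path(dir, paste0(prefix, ".truth.tsv"))
  fwrite(truth, tpath, sep = "\t")
  list(paths = paths, truth = truth, records = records, truth_path = tpath)
}
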