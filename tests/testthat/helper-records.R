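# Test helpers. Oracle-side record generation uses base R's RNG (set.seed /
# sample) so it is independent of the package's PRF-based generator.

rand_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

rand_records <- function(n, seed, fastq = FALSE, min_len = 5L, max_len = 60L,
                         dup_ids = FALSE) {
  set.seed(seed)
  lens <- sample(min_len:max_len, n, replace = TRUE)
  ids <- if (dup_ids) {
    sprintf("r%d", sample.int(max(2L, n %/% 2L), n, replace = TRUE))
  } else {
    sprintf("r%04d", seq_len(n))
  }
  seqs <- vapply(lens, rand_seq, character(1))
  quals <- if (fastq) {
    vapply(lens, function(l) {
      rawToChar(as.raw(sample(2:40, l, replace = TRUE) + 33L))
    }, character(1))
  } else {
    NA_character_
  }
  seq_records(paste0(ids, " desc ", seq_len(n)), seqs, quals)
}

## Serialize to a temp file; returns the path.
write_tmp <- function(records, format, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile(tmpdir = dir, fileext = paste0(".", format))
  write_records(records, format, path = path)
  path
}

file_bytes <- function(path) readBin(path, "raw", n = file.size(path))

write_bytes <- function(text, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (nchar(text, type = "bytes") > 0L) {
    writeChar(text, con, eos = NULL, useBytes = TRUE)
  }
  path
}

## Byte serialization used to compare command outputs across run configs.
rec_bytes <- function(recs) {
  fmt <- if (nrow(recs) > 0L && !anyNA(recs$qual)) "fastq" else "fasta"
  write_records(recs, fmt)
}
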