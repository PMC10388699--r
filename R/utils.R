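## Shared helpers: error conditions, byte-text IO, PRF wrappers, IUPAC tables.

usage_error <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("fastkit_usage_error", "fastkit_error")))
}

data_error <- function(msg) {
  stop(errorCondition(msg, class = c("fastkit_data_error", "fastkit_error")))
}

#' Deterministic uniform variates from the counter-based PRF
#'
#' Every source of randomness in the package is a pure function of
#' `(seed, stream, counter)`, evaluated through a splitmix64-based
#' pseudo-random function. The global R RNG state is never read or written,
#' so results are reproducible and independent of partitioning and worker
#' scheduling.
#'
#' @param seed integer seed.
#' @param stream integer stream id separating independent uses of one seed.
#' @param counter integer vector of counters (e.g. record indices).
#' @return numeric vector of variates in `[0, 1)`, one per counter.
#' @export
prf_unif <- function(seed, stream, counter) {
  .prf_u01(as.numeric(seed), as.numeric(stream), as.numeric(counter))
}

## k distinct positions out of n, drawn uniformly via a partial Fisher-Yates
## driven by PRF uniforms; returned sorted ascending.
prf_choose <- function(n, k, seed, stream) {
  if (k <= 0L) return(integer(0))
  if (k >= n) return(seq_len(n))
  idx <- seq_len(n)
  u <- prf_unif(seed, stream, seq_len(k))
  for (j in seq_len(k)) {
    pick <- j + floor(u[j] * (n - j + 1))
    tmp <- idx[j]; idx[j] <- idx[pick]; idx[pick] <- tmp
  }
  sort(idx[seq_len(k)])
}

## Derive a bounded integer sub-seed (< 2^31) for labelling streams.
derive_seed <- function(seed, stream) {
  as.integer(floor(prf_unif(seed, stream, 0) * 2147483647))
}

#' Read a whole file as a byte string
#'
#' Reads a plain or gzip file into a single latin1-encoded string, so one
#' character is one byte and `substr()`/`nchar()` arithmetic operates on
#' byte offsets. This is the buffer representation all parsing and boundary
#' functions work on.
#'
#' @param path input file (gzip detected from the magic bytes).
#' @return a latin1 character scalar.
#' @export
read_file_text <- function(path) {
  if (!file.exists(path)) usage_error(sprintf("input file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  seek(con, 0L)
  if (length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)) {
    close(con); on.exit()
    con <- gzfile(path, "rb")
    on.exit(close(con))
    chunks <- list()
    repeat {
      part <- readBin(con, "raw", n = 1048576L)
      if (length(part) == 0L) break
      chunks[[length(chunks) + 1L]] <- part
    }
    raw <- do.call(c, c(chunks, list(raw(0))))
  } else {
    raw <- readBin(con, "raw", n = file.size(path))
  }
  txt <- rawToChar(raw)
  Encoding(txt) <- "latin1"
  txt
}

is_gzip_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

## IUPAC nucleotide complement, case preserving; gaps and unknowns unchanged.
.comp_from <- "ACGTURYSWKMBDHVNacgturyswkmbdhvn"
.comp_to   <- "TGCAAYRSWMKVHDBNtgcaayrswmkvhdbn"

complement_seq <- function(x) chartr(.comp_from, .comp_to, x)

reverse_seq <- function(x) .rev_strings(x)

revcomp_seq <- function(x) .rev_strings(chartr(.comp_from, .comp_to, x))

## IUPAC degenerate code -> base set (uppercase).
.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

## Degenerate motif -> regex character classes ("AY" -> "A[CT]").
iupac_to_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), names(.iupac_sets))
  if (length(bad) > 0) {
    usage_error(sprintf("non-IUPAC character(s) %s in degenerate pattern '%s'",
                        paste(sQuote(bad), collapse = ", "), pattern))
  }
  paste(vapply(chars, function(ch) {
    set <- .iupac_sets[[ch]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
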