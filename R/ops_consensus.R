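## ops_consensus: commands needing a merge or global position information --
## stats via a partial-summary reduction, head/range/head-genome over global
## indices, grep --delete-matched, and the parallel FAI builder.

## ---- stats ----------------------------------------------------------------

## Mergeable per-partition summary. The length multiset is carried exactly
## (desk scale) so the merged N50 is exact; the merge is commutative and
## associative on every field.
.chunk_stats <- function(ch, quality_offset = 33L) {
  if (nrow(ch) == 0L) {
    return(list(num_seqs = 0, sum_len = 0, min_len = NA_integer_,
                max_len = NA_integer_, lengths = integer(0),
                q20 = 0, q30 = 0, total_q = 0, has_qual = FALSE))
  }
  len <- nchar(ch$seq, type = "bytes")
  quals <- ch$qual[!is.na(ch$qual)]
  if (length(quals) > 0L && sum(nchar(quals, type = "bytes")) > 0L) {
    phred <- as.integer(charToRaw(paste(quals, collapse = ""))) - quality_offset
    q20 <- sum(phred >= 20L)
    q30 <- sum(phred >= 30L)
    tq <- length(phred)
  } else {
    q20 <- 0; q30 <- 0; tq <- 0
  }
  list(num_seqs = nrow(ch), sum_len = sum(len), min_len = min(len),
       max_len = max(len), lengths = len, q20 = q20, q30 = q30,
       total_q = tq, has_qual = length(quals) > 0L)
}

.merge_stats <- function(a, b) {
  list(num_seqs = a$num_seqs + b$num_seqs,
       sum_len = a$sum_len + b$sum_len,
       min_len = suppressWarnings(min(a$min_len, b$min_len, na.rm = TRUE)),
       max_len = suppressWarnings(max(a$max_len, b$max_len, na.rm = TRUE)),
       lengths = c(a$lengths, b$lengths),
       q20 = a$q20 + b$q20, q30 = a$q30 + b$q30,
       total_q = a$total_q + b$total_q,
       has_qual = a$has_qual || b$has_qual)
}

#' N50 of a set of lengths
#'
#' The length at which the cumulative sum of lengths, sorted in descending
#' order, first reaches at least half of the total (ties resolved toward
#' the larger length).
#'
#' @param lengths integer vector of sequence lengths.
#' @return the N50, or 0 for an empty set.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) return(0L)
  ls <- sort(lengths, decreasing = TRUE)
  ls[which(cumsum(as.numeric(ls)) >= sum(as.numeric(ls)) / 2)[1]]
}

#' Sequence statistics (the `stats` command)
#'
#' Per-partition summaries are merged with an associative reduction, so the
#' result is identical for every partition count. Q20%/Q30% are
#' `100 * bases with Phred >= 20 (>= 30) / total bases` under the configured
#' quality offset; both are 0 (with `has_qual = FALSE`) for FASTA input.
#'
#' @param x records or a `pdataset`.
#' @param quality_offset Phred encoding offset (33 default).
#' @param workers forked workers.
#' @return a list: num_seqs, sum_len, min_len, avg_len (1 decimal), max_len,
#'   n50, q20_pct, q30_pct (2 decimals), has_qual.
#' @export
fk_stats <- function(x, quality_offset = 33L, workers = 1L) {
  ds <- as_records_ds(x)
  summaries <- pool_lapply(pd_chunks(ds), .chunk_stats, workers)
  summaries <- lapply(summaries, function(s) s)
  total <- tree_reduce(pdataset(list(summaries)), .merge_stats)
  if (total$num_seqs == 0L) {
    return(list(num_seqs = 0L, sum_len = 0, min_len = 0L, avg_len = 0,
                max_len = 0L, n50 = 0L, q20_pct = 0, q30_pct = 0,
                has_qual = FALSE))
  }
  list(num_seqs = total$num_seqs,
       sum_len = total$sum_len,
       min_len = total$min_len,
       avg_len = round(total$sum_len / total$num_seqs, 1),
       max_len = total$max_len,
       n50 = n50(total$lengths),
       q20_pct = if (total$total_q > 0) round(100 * total$q20 / total$total_q, 2) else 0,
       q30_pct = if (total$total_q > 0) round(100 * total$q30 / total$total_q, 2) else 0,
       has_qual = total$has_qual)
}

#' One-row tab-separated stats report
#' @param st a stats list from [fk_stats()].
#' @param file label for the file column.
#' @param format `"fasta"`/`"fastq"` label.
#' @return a one-row `data.table` with the printed columns.
#' @export
stats_report <- function(st, file = "-", format = "fasta") {
  data.table(file = file, format = toupper(format),
             type = "DNA",
             num_seqs = st$num_seqs, sum_len = st$sum_len,
             min_len = st$min_len, avg_len = st$avg_len,
             max_len = st$max_len, N50 = st$n50,
             `Q20(%)` = st$q20_pct, `Q30(%)` = st$q30_pct)
}

## ---- head / range ---------------------------------------------------------

#' Select records by ordinal (the `head` and `range` commands)
#'
#' Ordinals are 1-based inclusive record positions; negatives count from the
#' end (`-1` is the last record). Implemented over the global index, so the
#' result is independent of partitioning. Out-of-bounds ranges clamp; an
#' empty result is returned when start exceeds end after resolution.
#'
#' @param x records or a `pdataset`.
#' @param start,end 1-based inclusive ordinals, possibly negative, never 0.
#' @return records.
#' @export
fk_range <- function(x, start, end) {
  if (start == 0L || end == 0L) usage_error("record ordinal 0 is invalid")
  ds <- with_global_index(as_records_ds(x))
  n <- pd_count(ds)
  s <- if (start < 0L) n + start + 1L else start
  e <- if (end < 0L) n + end + 1L else end
  s <- max(s, 1L)
  e <- min(e, n)
  out <- pd_collect(pd_map(ds, function(ch) {
    if (nrow(ch) == 0L) return(ch)
    ch[global_index + 1L >= s & global_index + 1L <= e]
  }))
  if ("global_index" %in% names(out)) out[, global_index := NULL]
  out[]
}

#' @rdname fk_range
#' @param n number of leading records (`head n` is `range 1:n`).
#' @export
fk_head <- function(x, n) {
  if (n < 0L) usage_error("head count must be >= 0")
  if (n == 0L) return(.empty_records())
  fk_range(x, 1L, as.integer(n))
}

#' Records of the first genome by shared description prefix
#' (the `head-genome` command)
#'
#' Let W be the whitespace-split words of the first record's description
#' (header text after the id token). The first record is emitted, then every
#' subsequent record whose description shares at least `min_words` leading
#' words with W; emission stops at the first record that does not.
#'
#' @param x records or a `pdataset`.
#' @param min_words minimum number of leading words that must agree (>= 1).
#' @return records.
#' @export
fk_head_genome <- function(x, min_words = 1L) {
  if (min_words < 1L) usage_error("min_words must be >= 1")
  recs <- if (inherits(x, "pdataset")) pd_collect(x) else x
  if (nrow(recs) == 0L) return(recs)
  desc <- sub("^\\S+\\s*", "", recs$name)
  words <- strsplit(desc, "\\s+")
  W <- words[[1]]
  if (length(W) == 0L || !nzchar(desc[1])) {
    usage_error("first record has no description; the shared-prefix rule cannot apply")
  }
  k <- min(min_words, length(W))
  ok <- vapply(words, function(w) {
    length(w) >= k && identical(w[seq_len(k)], W[seq_len(k)])
  }, logical(1))
  stop_at <- which(!ok)[1]
  if (is.na(stop_at)) recs else recs[seq_len(stop_at - 1L)]
}

## ---- grep --delete-matched ------------------------------------------------

#' Grep keeping one record per pattern (the `grep --delete-matched` mode)
#'
#' Like [fk_grep()], but each pattern contributes at most one emitted
#' record: its match with the smallest `source_index`. A record matched by
#' several patterns counts against all of them. Survivors are re-sorted by
#' `source_index`.
#'
#' @inheritParams fk_grep
#' @return records.
#' @export
fk_grep_delete_matched <- function(x, patterns, by = c("id", "name", "seq"),
                                   use_regex = FALSE, ignore_case = FALSE,
                                   workers = 1L) {
  by <- match.arg(by)
  if (length(patterns) == 0L) usage_error("at least one pattern is required")
  if (use_regex) .check_regex(patterns)
  ds <- as_records_ds(x)
  hit_chunks <- pool_lapply(pd_chunks(ds), function(ch) {
    if (nrow(ch) == 0L) {
      return(data.table(pat = integer(0), source_index = integer(0)))
    }
    mm <- .grep_match_matrix(ch, patterns, by, use_regex, ignore_case)
    w <- which(mm, arr.ind = TRUE)
    data.table(pat = as.integer(w[, 2]), source_index = ch$source_index[w[, 1]])
  }, workers)
  hits <- rbindlist(hit_chunks)
  if (nrow(hits) == 0L) return(.empty_records())
  firsts <- hits[, .(source_index = min(source_index)), by = pat]
  keep <- sort(unique(firsts$source_index))
  all <- pd_collect(ds)
  all[source_index %in% keep][order(source_index)]
}

## ---- parallel FAI ---------------------------------------------------------

#' Build a FAI index in parallel over byte-range partitions
#'
#' The file's byte range is split and resynchronized to record boundaries;
#' each partition computes entries with offsets local to its chunk, and a
#' prefix sum over chunk byte sizes converts them to global offsets. The
#' result is byte-identical to the sequential [build_fai()] for every
#' partition count.
#'
#' @inheritParams build_fai
#' @param partitions number of byte-range partitions.
#' @param workers forked workers.
#' @return a `data.table` of FAI entries (and the sibling `.fai` file).
#' @export
build_fai_parallel <- function(path, format = NULL, partitions = 1L,
                               workers = 1L, write = TRUE) {
  if (is_gzip_file(path)) {
    usage_error("cannot build a FAI index over gzip input: byte offsets are not addressable")
  }
  text <- read_file_text(path)
  format <- format %||% detect_format(text)
  nb <- nchar(text, type = "bytes")
  if (is.na(format) || nb == 0L) {
    entries <- data.table(name = character(0), length = integer(0),
                          seq_offset = numeric(0), linebases = integer(0),
                          linewidth = integer(0))
    if (write) write_fai(entries, paste0(path, ".fai"))
    return(entries)
  }
  p <- max(1L, as.integer(partitions))
  raw_bounds <- unique(round(seq(0, nb, length.out = p + 1L)))
  sync <- vapply(raw_bounds[-length(raw_bounds)], function(b) {
    find_record_boundary(text, format, b)
  }, numeric(1))
  sync[1] <- 0  # the first chunk starts at byte 0 so malformed leads surface
  sync <- c(sync, nb)
  parts <- pool_lapply(seq_len(length(sync) - 1L), function(i) {
    if (sync[i + 1] <= sync[i]) return(NULL)
    piece <- substr(text, sync[i] + 1L, sync[i + 1])
    ent <- .fai_from_lines(.split_lines(piece), format)
    if (nrow(ent) > 0L) {
      ent[, seq_offset := seq_offset + sync[i]]
      if ("qual_offset" %in% names(ent)) ent[, qual_offset := qual_offset + sync[i]]
    }
    ent
  }, workers)
  entries <- rbindlist(Filter(Negate(is.null), parts))
  if (anyDuplicated(entries$name)) {
    data_error(sprintf("cannot index: duplicate record name '%s'",
                       entries$name[duplicated(entries$name)][1]))
  }
  if (write) write_fai(entries, paste0(path, ".fai"))
  entries
}
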