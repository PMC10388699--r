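## seqio: FASTA/FASTQ parsing and writing over byte buffers, record-boundary
## resynchronization (what makes byte-range splitting safe), and samtools-
## dialect FAI indexing for both formats.
##
## All buffers are latin1-encoded character scalars so that one character is
## one byte and substr()/nchar() arithmetic operates on byte offsets.

#' @import data.table
NULL

## ---- line table -----------------------------------------------------------

## Split a buffer into lines, keeping byte offsets. Returns:
##   content  lines with the trailing CR (if any) removed
##   starts   0-based byte offset of each line start
##   widths   byte width of each line including its terminator (the final
##            line may lack one)
##   blen     base length of each line (bytes minus CR/LF)
.split_lines <- function(text) {
  nb <- nchar(text, type = "bytes")
  if (nb == 0L) {
    return(list(content = character(0), starts = integer(0),
                widths = integer(0), blen = integer(0)))
  }
  raw_lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(raw_lines) == 0L) raw_lines <- ""
  n <- length(raw_lines)
  rl_n <- nchar(raw_lines, type = "bytes")
  ends_nl <- substr(text, nb, nb) == "\n"
  widths <- rl_n + 1L
  if (!ends_nl) widths[n] <- rl_n[n]
  starts <- c(0L, cumsum(widths)[-n])
  has_cr <- endsWith(raw_lines, "\r")
  content <- raw_lines
  content[has_cr] <- substr(raw_lines[has_cr], 1L, rl_n[has_cr] - 1L)
  list(content = content, starts = as.integer(starts),
       widths = as.integer(widths), blen = as.integer(rl_n - has_cr))
}

## ---- record container -----------------------------------------------------

#' Construct a sequence-record table
#'
#' Records are plain `data.table`s with columns `id` (header token up to the
#' first whitespace), `name` (full header without the leading `>`/`@`
#' marker), `seq`, `qual` (`NA` for FASTA records), `source_index` (0-based
#' ordinal of the record in its source file) and `source_tag` (which input
#' file the record came from, for multi-file commands).
#'
#' @param name full header lines (without marker).
#' @param seq sequence strings.
#' @param qual quality strings or `NA`.
#' @param start_index 0-based ordinal of the first record.
#' @param source_tag integer file tag.
#' @return a `data.table` of records.
#' @export
seq_records <- function(name, seq, qual = NA_character_,
                        start_index = 0L, source_tag = 0L) {
  n <- length(name)
  qual <- rep_len(qual, n)
  bad <- !is.na(qual) & nchar(qual, type = "bytes") != nchar(seq, type = "bytes")
  if (any(bad)) {
    data_error(sprintf(
      "quality length differs from sequence length for record ordinal %d",
      start_index + which(bad)[1] - 1L))
  }
  data.table(
    id = sub("[ \t].*$", "", name),
    name = name,
    seq = seq,
    qual = qual,
    source_index = start_index + seq_len(n) - 1L,
    source_tag = rep_len(as.integer(source_tag), n)
  )
}

.empty_records <- function() {
  data.table(id = character(0), name = character(0), seq = character(0),
             qual = character(0), source_index = integer(0),
             source_tag = integer(0))
}

## ---- parsing --------------------------------------------------------------

#' Parse FASTA from a byte buffer
#'
#' Multi-line sequences are concatenated with line terminators removed, blank
#' lines between records are ignored, and CR is stripped before LF handling
#' (CRLF input accepted). Records are returned in file order with
#' `source_index` 0..n-1.
#'
#' @param text a latin1 character scalar holding the file bytes.
#' @param start_index 0-based ordinal assigned to the first record.
#' @param source_tag integer tag for the source file.
#' @return a `data.table` of records (see [seq_records()]).
#' @export
parse_fasta <- function(text, start_index = 0L, source_tag = 0L) {
  sl <- .split_lines(text)
  content <- sl$content
  nonblank <- which(nzchar(content))
  if (length(nonblank) == 0L) return(.empty_records())
  first <- nonblank[1]
  if (!startsWith(content[first], ">")) {
    data_error(sprintf(
      "malformed FASTA: first non-blank byte at offset %d is not '>'",
      sl$starts[first]))
  }
  hdr <- which(startsWith(content, ">"))
  grp <- findInterval(seq_along(content), hdr)
  sidx <- setdiff(nonblank, hdr)
  seqs <- vapply(split(content[sidx], factor(grp[sidx], levels = seq_along(hdr))),
                 paste, character(1), collapse = "")
  names(seqs) <- NULL
  seq_records(substring(content[hdr], 2L), seqs,
              start_index = start_index, source_tag = source_tag)
}

#' Parse 4-line FASTQ from a byte buffer
#'
#' Records are strictly 4-line (`@`-header, sequence, `+`-separator,
#' quality); multi-line FASTQ is rejected. The `+` line content is ignored
#' and may repeat the header.
#'
#' @inheritParams parse_fasta
#' @return a `data.table` of records.
#' @export
parse_fastq <- function(text, start_index = 0L, source_tag = 0L) {
  sl <- .split_lines(text)
  content <- sl$content
  while (length(content) > 0L && !nzchar(content[length(content)])) {
    content <- content[-length(content)]
  }
  if (length(content) == 0L) return(.empty_records())
  if (!startsWith(content[1], "@")) {
    data_error(sprintf(
      "malformed FASTQ: first non-blank byte at offset %d is not '@'",
      sl$starts[1]))
  }
  if (length(content) %% 4L != 0L) {
    data_error(sprintf(
      "malformed FASTQ: %d lines is not a multiple of 4 (multi-line FASTQ is unsupported)",
      length(content)))
  }
  n <- length(content) %/% 4L
  l1 <- content[seq(1L, by = 4L, length.out = n)]
  l2 <- content[seq(2L, by = 4L, length.out = n)]
  l3 <- content[seq(3L, by = 4L, length.out = n)]
  l4 <- content[seq(4L, by = 4L, length.out = n)]
  bad_hdr <- which(!startsWith(l1, "@"))
  if (length(bad_hdr) > 0L) {
    data_error(sprintf("malformed FASTQ record ordinal %d: header does not start with '@'",
                       start_index + bad_hdr[1] - 1L))
  }
  bad_sep <- which(!startsWith(l3, "+"))
  if (length(bad_sep) > 0L) {
    data_error(sprintf("malformed FASTQ record ordinal %d: separator line does not start with '+'",
                       start_index + bad_sep[1] - 1L))
  }
  seq_records(substring(l1, 2L), l2, qual = l4,
              start_index = start_index, source_tag = source_tag)
}

#' Find the next safe record boundary in a byte buffer
#'
#' Used to resynchronize after splitting a file at an arbitrary byte offset.
#' For FASTA the boundary is the first line start at or after `search_from`
#' whose line begins with `>`. For FASTQ a candidate `@` line is only
#' accepted if a full 4-line parse from it succeeds (the line two below
#' starts with `+` and sequence/quality lengths match) -- this disambiguates
#' `@` occurring as a quality character.
#'
#' @param buffer latin1 character scalar (a window of the file reaching to
#'   its end, or to at least several records past the split point).
#' @param format `"fasta"` or `"fastq"`.
#' @param search_from 0-based byte offset to search from.
#' @return the 0-based byte offset of the first record header at or after
#'   `search_from`; if none exists, the buffer length in bytes (one past the
#'   end) as the no-boundary sentinel.
#' @export
find_record_boundary <- function(buffer, format = c("fasta", "fastq"),
                                 search_from = 0L) {
  format <- match.arg(format)
  nb <- nchar(buffer, type = "bytes")
  if (nb == 0L) return(0L)
  sl <- .split_lines(buffer)
  cand <- which(sl$starts >= search_from)
  if (format == "fasta") {
    hit <- cand[startsWith(sl$content[cand], ">")]
    if (length(hit) > 0L) return(sl$starts[hit[1]])
  } else {
    n <- length(sl$content)
    for (i in cand) {
      if (!startsWith(sl$content[i], "@")) next
      if (i + 3L > n) next
      if (!startsWith(sl$content[i + 2L], "+")) next
      if (nchar(sl$content[i + 1L], type = "bytes") !=
          nchar(sl$content[i + 3L], type = "bytes")) next
      return(sl$starts[i])
    }
  }
  nb
}

## ---- writing --------------------------------------------------------------

#' Serialize records to FASTA or FASTQ bytes
#'
#' FASTA sequences are wrapped at `wrap` bases per line (0 disables
#' wrapping); FASTQ output is always 4-line. `parse_*(write_records(x))`
#' reproduces ids, names, sequences and qualities exactly.
#'
#' @param records a record `data.table`.
#' @param format `"fasta"` or `"fastq"`.
#' @param wrap bases per FASTA line; 0 for single-line output.
#' @param path optional output file (gzip if it ends in `.gz`); when `NULL`
#'   the byte stream is returned as a string.
#' @return the byte stream as a latin1 string (invisibly when `path` given).
#' @export
write_records <- function(records, format = c("fasta", "fastq"), wrap = 60L,
                          path = NULL) {
  format <- match.arg(format)
  if (nrow(records) == 0L) {
    out <- ""
  } else if (format == "fasta") {
    s <- records$seq
    if (wrap > 0L) {
      s <- gsub(sprintf("(.{%d})", as.integer(wrap)), "\\1\n", s)
      s <- sub("\n$", "", s)
    }
    body <- ifelse(nzchar(s), paste0(s, "\n"), "")
    out <- paste0(">", records$name, "\n", body, collapse = "")
  } else {
    if (anyNA(records$qual)) {
      usage_error("FASTQ output requested for records without quality strings")
    }
    out <- paste0("@", records$name, "\n", records$seq, "\n+\n", records$qual,
                  "\n", collapse = "")
  }
  Encoding(out) <- "latin1"
  if (is.null(path)) return(out)
  con <- if (endsWith(path, ".gz")) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (nchar(out, type = "bytes") > 0L) writeChar(out, con, eos = NULL, useBytes = TRUE)
  invisible(out)
}

## ---- format detection -----------------------------------------------------

#' Detect FASTA vs FASTQ from the first non-blank byte
#' @param text latin1 buffer.
#' @return `"fasta"`, `"fastq"`, or `NA` for an empty buffer.
#' @export
detect_format <- function(text) {
  m <- regmatches(text, regexpr("[^\r\n]", text))
  if (length(m) == 0L || !nzchar(m)) return(NA_character_)
  switch(m, ">" = "fasta", "@" = "fastq",
         data_error(sprintf("cannot detect format: first non-blank byte is '%s'", m)))
}

## ---- FAI index ------------------------------------------------------------

.fai_cols_fasta <- c("name", "length", "seq_offset", "linebases", "linewidth")
.fai_cols_fastq <- c(.fai_cols_fasta, "qual_offset")

## Core FAI computation over a line table; offsets are relative to the start
## of the buffer. Shared by the sequential and the parallel builder.
.fai_from_lines <- function(sl, format, ordinal_base = 0L) {
  content <- sl$content
  if (format == "fasta") {
    hdr <- which(startsWith(content, ">"))
    if (length(hdr) == 0L) {
      return(data.table(name = character(0), length = integer(0),
                        seq_offset = numeric(0), linebases = integer(0),
                        linewidth = integer(0)))
    }
    ends <- c(hdr[-1] - 1L, length(content))
    rows <- vector("list", length(hdr))
    for (r in seq_along(hdr)) {
      h <- hdr[r]
      li <- if (ends[r] >= h + 1L) seq(h + 1L, ends[r]) else integer(0)
      while (length(li) > 0L && !nzchar(content[li[length(li)]])) {
        li <- li[-length(li)]
      }
      if (any(!nzchar(content[li]))) {
        data_error(sprintf("cannot index record '%s': blank line inside sequence",
                           substring(content[h], 2L)))
      }
      name <- sub("[ \t].*$", "", substring(content[h], 2L))
      if (length(li) == 0L) {
        rows[[r]] <- list(name = name, length = 0L,
                          seq_offset = as.numeric(sl$starts[h] + sl$widths[h]),
                          linebases = 0L, linewidth = 1L)
        next
      }
      bl <- sl$blen[li]
      wd <- sl$widths[li]
      k <- length(li)
      if (k > 1L && (any(bl[-k] != bl[1]) || any(wd[-k] != wd[1]) || bl[k] > bl[1])) {
        data_error(sprintf("cannot index record '%s': sequence lines have different lengths",
                           name))
      }
      rows[[r]] <- list(name = name, length = sum(bl),
                        seq_offset = as.numeric(sl$starts[li[1]]),
                        linebases = bl[1],
                        linewidth = if (wd[1] > bl[1]) wd[1] else bl[1] + 1L)
    }
    out <- rbindlist(rows)
  } else {
    while (length(content) > 0L && !nzchar(content[length(content)])) {
      content <- content[-length(content)]
    }
    if (length(content) == 0L) {
      return(data.table(name = character(0), length = integer(0),
                        seq_offset = numeric(0), linebases = integer(0),
                        linewidth = integer(0), qual_offset = numeric(0)))
    }
    if (length(content) %% 4L != 0L) {
      data_error("cannot index FASTQ: line count is not a multiple of 4")
    }
    n <- length(content) %/% 4L
    i1 <- seq(1L, by = 4L, length.out = n)
    bl <- sl$blen[i1 + 1L]
    if (any(bl != sl$blen[i1 + 3L])) {
      bad <- which(bl != sl$blen[i1 + 3L])[1]
      data_error(sprintf("cannot index FASTQ record ordinal %d: sequence/quality length mismatch",
                         ordinal_base + bad - 1L))
    }
    out <- data.table(
      name = sub("[ \t].*$", "", substring(content[i1], 2L)),
      length = bl,
      seq_offset = as.numeric(sl$starts[i1 + 1L]),
      linebases = bl,
      linewidth = sl$widths[i1 + 1L],
      qual_offset = as.numeric(sl$starts[i1 + 3L])
    )
  }
  out
}

#' Build a samtools-dialect FAI index
#'
#' FASTA entries have the 5 samtools columns (name, length, seq_offset,
#' linebases, linewidth); FASTQ entries add a 6th column, qual_offset, in the
#' samtools fqidx dialect. All sequence lines of a record except the last
#' must have equal length (the samtools layout requirement for offset
#' arithmetic). A sibling `<path>.fai` file is written unless `write = FALSE`.
#'
#' @param path input FASTA/FASTQ file (plain text; gzip input is refused
#'   because byte offsets into compressed streams are not addressable).
#' @param format `"fasta"` or `"fastq"`; auto-detected when `NULL`.
#' @param write whether to write the sibling `.fai` file.
#' @return a `data.table` of FAI entries, one per record in file order.
#' @export
build_fai <- function(path, format = NULL, write = TRUE) {
  if (is_gzip_file(path)) {
    usage_error("cannot build a FAI index over gzip input: byte offsets are not addressable")
  }
  text <- read_file_text(path)
  format <- format %||% detect_format(text)
  if (is.na(format)) {
    entries <- data.table(name = character(0), length = integer(0),
                          seq_offset = numeric(0), linebases = integer(0),
                          linewidth = integer(0))
  } else {
    entries <- .fai_from_lines(.split_lines(text), format)
  }
  if (anyDuplicated(entries$name)) {
    data_error(sprintf("cannot index: duplicate record name '%s'",
                       entries$name[duplicated(entries$name)][1]))
  }
  if (write) write_fai(entries, paste0(path, ".fai"))
  entries
}

#' Serialize FAI entries to the tab-separated on-disk form
#' @param entries FAI `data.table`.
#' @param path output path; `NULL` returns the bytes.
#' @return the index text (invisibly when `path` given).
#' @export
write_fai <- function(entries, path = NULL) {
  cols <- if ("qual_offset" %in% names(entries)) .fai_cols_fastq else .fai_cols_fasta
  if (nrow(entries) == 0L) {
    txt <- ""
  } else {
    fields <- lapply(cols, function(cl) format(entries[[cl]], scientific = FALSE, trim = TRUE))
    txt <- paste0(do.call(paste, c(fields, sep = "\t")), "\n", collapse = "")
  }
  if (is.null(path)) return(txt)
  con <- file(path, "wb")
  on.exit(close(con))
  if (nchar(txt, type = "bytes") > 0L) writeChar(txt, con, eos = NULL, useBytes = TRUE)
  invisible(txt)
}

#' Read a FAI index file
#' @param path a `.fai` file (5 or 6 columns).
#' @return a `data.table` of FAI entries.
#' @export
read_fai <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  cols <- if (ncol(dt) == 6L) .fai_cols_fastq else .fai_cols_fasta
  setnames(dt, cols)
  dt
}

## ---- region fetch ---------------------------------------------------------

#' Parse a region string of the form "name:start-end"
#'
#' Coordinates are 1-based inclusive; negative values count from the end of
#' the sequence (-k is the k-th base from the end).
#'
#' @param s region string; a bare name selects the whole record.
#' @return a list with `name`, `start`, `end` (`NA` when the whole record).
#' @export
parse_region <- function(s) {
  m <- regmatches(s, regexec("^(.*):(-?[0-9]+)-(-?[0-9]+)$", s))[[1]]
  if (length(m) == 4L) {
    list(name = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
  } else {
    list(name = s, start = NA_integer_, end = NA_integer_)
  }
}

## Resolve 1-based possibly-negative coordinates against a length L.
.resolve_coord <- function(x, L) {
  if (is.na(x)) return(NA_integer_)
  if (x == 0L) usage_error("coordinate 0 is invalid in 1-based space")
  if (x < 0L) L + x + 1L else x
}

#' Fetch a subsequence through the FAI index
#'
#' Reads only the bytes covered by the region using the
#' seq_offset/linebases/linewidth arithmetic (no full-file scan). An end
#' beyond the record length is clamped; a start beyond it yields an empty
#' sequence. The emitted record id is `"name:start-end"`.
#'
#' @param path the indexed FASTA/FASTQ file.
#' @param fai FAI entries from [build_fai()] or [read_fai()].
#' @param region a region string or list as from [parse_region()].
#' @return a one-row record `data.table` (with quality for FASTQ entries).
#' @export
fetch_region <- function(path, fai, region) {
  if (is.character(region)) region <- parse_region(region)
  row <- fai[fai$name == region$name, ]
  if (nrow(row) == 0L) {
    usage_error(sprintf("sequence '%s' not found in index", region$name))
  }
  L <- row$length[1]
  start <- .resolve_coord(region$start %||% NA_integer_, L)
  end <- .resolve_coord(region$end %||% NA_integer_, L)
  if (is.na(start)) start <- 1L
  if (is.na(end)) end <- L
  start <- max(start, 1L)
  end <- min(end, L)
  hdr <- if (is.na(region$start %||% NA_integer_)) row$name[1] else {
    sprintf("%s:%d-%d", row$name[1], start, end)
  }
  empty <- L == 0L || start > end || start > L
  pull <- function(base_off) {
    if (empty) return("")
    pos <- function(k) {
      base_off + ((k - 1) %/% row$linebases[1]) * row$linewidth[1] +
        (k - 1) %% row$linebases[1]
    }
    con <- file(path, "rb")
    on.exit(close(con))
    seek(con, pos(start))
    nbytes <- pos(end) - pos(start) + 1
    bytes <- readBin(con, "raw", n = nbytes)
    gsub("[\r\n]", "", rawToChar(bytes))
  }
  seqv <- pull(row$seq_offset[1])
  qualv <- if ("qual_offset" %in% names(row)) pull(row$qual_offset[1]) else NA_character_
  seq_records(hdr, seqv, qual = qualv)
}
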