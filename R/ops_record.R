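## ops_record: embarrassingly parallel commands -- pure per-record transforms
## implemented as order-preserving maps over partitions. Every function here
## commutes with partitioning: output under any partition count equals the
## single-partition output byte-for-byte.

## Coerce command input (records table or pdataset) to a pdataset.
as_records_ds <- function(x, partitions = 1L) {
  if (inherits(x, "pdataset")) x else as_pdataset(x, partitions = partitions)
}

## Map over record chunks and collect.
.map_collect <- function(x, f, workers = 1L) {
  ds <- as_records_ds(x)
  out <- pd_collect(pd_map(ds, f, workers = workers))
  out
}

#' Transform sequences (the `seq` command)
#'
#' Length filters drop records outside `[min_len, max_len]`; `complement`
#' maps IUPAC codes case-preservingly; `rc` is reverse then complement with
#' the quality string reversed alongside; `gap_remove` deletes `-` and `.`;
#' `only_id`/`only_name`/`only_seq` emit one line per record instead of
#' records.
#'
#' @param x records or a `pdataset`.
#' @param reverse,complement,rc,upper,lower,gap_remove transform flags.
#' @param only_id,only_name,only_seq output-mode flags (mutually exclusive);
#'   when set, a character vector is returned instead of records.
#' @param min_len,max_len length filter bounds (`NULL` = unbounded).
#' @param workers forked workers.
#' @return records, or a character vector in an `only_*` mode.
#' @export
fk_seq <- function(x, reverse = FALSE, complement = FALSE, rc = FALSE,
                   upper = FALSE, lower = FALSE, gap_remove = FALSE,
                   only_id = FALSE, only_name = FALSE, only_seq = FALSE,
                   min_len = NULL, max_len = NULL, workers = 1L) {
  if (sum(only_id, only_name, only_seq) > 1L) {
    usage_error("only one of only_id / only_name / only_seq may be set")
  }
  if (upper && lower) usage_error("upper and lower are contradictory")
  out <- .map_collect(x, function(ch) {
    if (nrow(ch) == 0L) return(ch)
    ch <- copy(ch)
    len <- nchar(ch$seq, type = "bytes")
    keep <- rep(TRUE, nrow(ch))
    if (!is.null(min_len)) keep <- keep & len >= min_len
    if (!is.null(max_len)) keep <- keep & len <= max_len
    ch <- ch[keep]
    if (nrow(ch) == 0L) return(ch)
    if (gap_remove) ch[, seq := gsub("[-.]", "", seq)]
    if (rc) {
      ch[, seq := revcomp_seq(seq)]
      ch[!is.na(qual), qual := .rev_strings(qual)]
    } else {
      if (reverse) {
        ch[, seq := .rev_strings(seq)]
        ch[!is.na(qual), qual := .rev_strings(qual)]
      }
      if (complement) ch[, seq := complement_seq(seq)]
    }
    if (upper) ch[, seq := toupper(seq)]
    if (lower) ch[, seq := tolower(seq)]
    ch
  }, workers = workers)
  if (only_id) return(out$id)
  if (only_name) return(out$name)
  if (only_seq) return(out$seq)
  out
}

#' Extract a subsequence from every record (the `subseq` command)
#'
#' Coordinates are 1-based inclusive; negative values count from the end of
#' each record (`-k` is the k-th base from the end). After resolution the
#' window is clamped to the record; a record whose resolved start exceeds
#' its resolved end is dropped. Qualities are sliced identically.
#'
#' @param x records or a `pdataset`.
#' @param start,end 1-based inclusive coordinates, possibly negative,
#'   never 0.
#' @param workers forked workers.
#' @return records.
#' @export
fk_subseq <- function(x, start, end, workers = 1L) {
  if (start == 0L || end == 0L) {
    usage_error("coordinate 0 is invalid in 1-based space")
  }
  .map_collect(x, function(ch) {
    if (nrow(ch) == 0L) return(ch)
    ch <- copy(ch)
    L <- nchar(ch$seq, type = "bytes")
    s <- pmax(if (start < 0L) L + start + 1L else rep_len(start, nrow(ch)), 1L)
    e <- pmin(if (end < 0L) L + end + 1L else rep_len(end, nrow(ch)), L)
    keep <- s <= e
    ch <- ch[keep]
    s <- s[keep]
    e <- e[keep]
    if (nrow(ch) == 0L) return(ch)
    set(ch, j = "seq", value = substr(ch$seq, s, e))
    hasq <- which(!is.na(ch$qual))
    if (length(hasq) > 0L) {
      set(ch, i = hasq, j = "qual", value = substr(ch$qual[hasq], s[hasq], e[hasq]))
    }
    ch
  }, workers = workers)
}

## ---- translation ----------------------------------------------------------

## Resolve one possibly-ambiguous codon against a genetic-code table: all
## IUPAC expansions must agree on the amino acid, otherwise 'X'.
.resolve_codon <- function(codon, code) {
  chars <- strsplit(codon, "", fixed = TRUE)[[1]]
  sets <- .iupac_sets[chars]
  if (any(vapply(sets, is.null, logical(1)))) return("X")
  combos <- expand.grid(sets, stringsAsFactors = FALSE)
  aas <- unique(code[apply(combos, 1L, paste, collapse = "")])
  if (length(aas) == 1L && !is.na(aas)) aas else "X"
}

.translate_one <- function(s, frame, code, cache) {
  s <- chartr("u", "t", chartr("U", "T", s))
  if (frame < 0L) s <- revcomp_seq(s)
  skip <- abs(frame) - 1L
  s <- toupper(substring(s, skip + 1L))
  n <- nchar(s, type = "bytes")
  ncod <- n %/% 3L
  if (ncod == 0L) return("")
  starts <- seq(1L, by = 3L, length.out = ncod)
  codons <- substring(s, starts, starts + 2L)
  aa <- unname(code[codons])
  miss <- which(is.na(aa))
  for (i in miss) {
    key <- codons[i]
    hit <- cache[[key]]
    if (is.null(hit)) {
      hit <- .resolve_codon(key, code)
      cache[[key]] <- hit
    }
    aa[i] <- hit
  }
  paste(aa, collapse = "")
}

#' Translate nucleotide records to protein (the `translate` command)
#'
#' Negative frames translate the reverse complement; the leading
#' `|frame| - 1` bases are skipped and a trailing incomplete codon is
#' dropped. A codon with IUPAC ambiguity translates to an amino acid only
#' when every expansion agrees, otherwise to `X`; stops are `*`; `U` is
#' treated as `T`. Genetic codes follow the standard NCBI numbering
#' (table 1 default).
#'
#' @param x records or a `pdataset`.
#' @param frame one of 1, 2, 3, -1, -2, -3.
#' @param table NCBI genetic-code table id.
#' @param workers forked workers.
#' @return records holding protein sequences (qualities dropped).
#' @export
fk_translate <- function(x, frame = 1L, table = 1L, workers = 1L) {
  if (!frame %in% c(1L, 2L, 3L, -1L, -2L, -3L)) {
    usage_error("frame must be one of 1, 2, 3, -1, -2, -3")
  }
  code <- tryCatch(Biostrings::getGeneticCode(as.character(table)),
                   error = function(e) usage_error(
                     sprintf("unknown genetic-code table id '%s'", table)))
  cache <- new.env(parent = emptyenv())
  .map_collect(x, function(ch) {
    if (nrow(ch) == 0L) return(ch)
    ch <- copy(ch)
    ch[, seq := vapply(seq, .translate_one, character(1),
                       frame = frame, code = code, cache = cache)]
    ch[, qual := NA_character_]
    ch
  }, workers = workers)
}

## ---- grep / locate --------------------------------------------------------

.check_regex <- function(patterns) {
  for (p in patterns) {
    ok <- tryCatch({grepl(p, "x", perl = TRUE); TRUE},
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) usage_error(sprintf("invalid regular expression: '%s'", p))
  }
}

## Per-chunk match mask shared by fk_grep and fk_grep_delete_matched.
## Returns an n x n_patterns logical matrix.
.grep_match_matrix <- function(ch, patterns, by, use_regex, ignore_case) {
  field <- ch[[by]]
  mm <- vapply(patterns, function(p) {
    if (use_regex) {
      grepl(p, field, perl = TRUE, ignore.case = ignore_case)
    } else if (by == "seq") {
      if (ignore_case) grepl(tolower(p), tolower(field), fixed = TRUE)
      else grepl(p, field, fixed = TRUE)
    } else {
      if (ignore_case) tolower(field) == tolower(p) else field == p
    }
  }, logical(nrow(ch)))
  if (!is.matrix(mm)) mm <- matrix(mm, nrow = nrow(ch))
  mm
}

#' Filter records by id, name or sequence (the `grep` command)
#'
#' Without `use_regex`, id/name are matched by full-string equality and
#' sequences by substring containment (identifier matching vs motif search);
#' with it, by unanchored regular-expression search on the chosen field. A
#' record is emitted when any pattern matches (none, under `invert`); input
#' order is preserved.
#'
#' @param x records or a `pdataset`.
#' @param patterns character vector of patterns (non-empty).
#' @param by field to match: `"id"`, `"name"` or `"seq"`.
#' @param use_regex treat patterns as regular expressions.
#' @param invert emit non-matching records instead.
#' @param ignore_case case-insensitive matching.
#' @param workers forked workers.
#' @return records.
#' @export
fk_grep <- function(x, patterns, by = c("id", "name", "seq"),
                    use_regex = FALSE, invert = FALSE, ignore_case = FALSE,
                    workers = 1L) {
  by <- match.arg(by)
  if (length(patterns) == 0L) usage_error("at least one pattern is required")
  if (use_regex) .check_regex(patterns)
  .map_collect(x, function(ch) {
    if (nrow(ch) == 0L) return(ch)
    mm <- .grep_match_matrix(ch, patterns, by, use_regex, ignore_case)
    hit <- rowSums(mm) > 0L
    ch[if (invert) !hit else hit]
  }, workers = workers)
}

#' Locate motif occurrences on both strands (the `locate` command)
#'
#' All (overlapping) occurrences of each pattern are reported on the plus
#' strand, and occurrences of its reverse complement as strand `-`;
#' coordinates are always 1-based inclusive on the plus strand, and
#' `matched` holds the plus-strand bases of the hit. With `degenerate`,
#' patterns are IUPAC motifs (`Y` = C/T etc.). Hits are ordered by
#' (record, start, strand, pattern).
#'
#' @param x records or a `pdataset`.
#' @param patterns character vector of motifs; names, when present, become
#'   `pattern_name` (else the motif itself).
#' @param ignore_case case-insensitive matching.
#' @param degenerate interpret patterns as IUPAC-degenerate motifs.
#' @param workers forked workers.
#' @return a `data.table` of hits: record_id, pattern_name, pattern, strand,
#'   start, end, matched.
#' @export
fk_locate <- function(x, patterns, ignore_case = FALSE, degenerate = FALSE,
                      workers = 1L) {
  if (length(patterns) == 0L) usage_error("at least one pattern is required")
  pnames <- names(patterns) %||% patterns
  pnames[!nzchar(pnames)] <- patterns[!nzchar(pnames)]
  esc <- function(p) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", p)
  rx_of <- function(p) if (degenerate) iupac_to_regex(p) else esc(p)
  rx_plus <- vapply(patterns, rx_of, character(1))
  rx_minus <- vapply(revcomp_seq(toupper(patterns)), rx_of, character(1))
  plen <- nchar(patterns, type = "bytes")
  hits_ds <- pd_map(as_records_ds(x), function(ch) {
    if (nrow(ch) == 0L) return(.empty_locate())
    rows <- vector("list", 0L)
    for (r in seq_len(nrow(ch))) {
      sq <- ch$seq[r]
      for (pi in seq_along(patterns)) {
        for (str in c("+", "-")) {
          rx <- if (str == "+") rx_plus[pi] else rx_minus[pi]
          m <- gregexpr(paste0("(?=", rx, ")"), sq, perl = TRUE,
                        ignore.case = ignore_case || degenerate)[[1]]
          starts <- as.integer(m[m > 0L])
          if (length(starts) == 0L) next
          rows[[length(rows) + 1L]] <- data.table(
            record_pos = ch$source_index[r],
            record_id = ch$id[r],
            pattern_name = pnames[pi], pattern = patterns[pi],
            strand = str, start = starts, end = starts + plen[pi] - 1L,
            matched = substring(sq, starts, starts + plen[pi] - 1L),
            pat_idx = pi)
        }
      }
    }
    if (length(rows) == 0L) .empty_locate() else rbindlist(rows)
  }, workers = workers)
  hits <- pd_collect(hits_ds)
  if (!is.data.frame(hits) || nrow(hits) == 0L) return(.empty_locate()[, !c("record_pos", "pat_idx")])
  setorder(hits, record_pos, start, strand, pat_idx)
  hits[, c("record_pos", "pat_idx") := NULL]
  hits[]
}

.empty_locate <- function() {
  data.table(record_pos = integer(0), record_id = character(0),
             pattern_name = character(0), pattern = character(0),
             strand = character(0), start = integer(0), end = integer(0),
             matched = character(0), pat_idx = integer(0))
}

#' Emit each record several times (the `duplicate` command)
#' @param x records or a `pdataset`.
#' @param times copies per record (>= 1), emitted consecutively.
#' @param workers forked workers.
#' @return records.
#' @export
fk_duplicate <- function(x, times = 2L, workers = 1L) {
  if (times < 1L) usage_error("times must be >= 1")
  .map_collect(x, function(ch) {
    if (nrow(ch) == 0L) return(ch)
    ch[rep(seq_len(nrow(ch)), each = times)]
  }, workers = workers)
}

#' Regex replacement on names or sequences (the `replace` command)
#'
#' All non-overlapping matches in the chosen field are replaced; the
#' replacement may use capture references (`\\1`) and the placeholder
#' `{nr}`, which expands to the record's 1-based global ordinal (via the
#' global index, so output is independent of partitioning).
#'
#' @param x records or a `pdataset`.
#' @param pattern a regular expression.
#' @param replacement replacement text.
#' @param field `"name"` or `"seq"`.
#' @param ignore_case case-insensitive matching.
#' @param workers forked workers.
#' @return records (ids recomputed when names change).
#' @export
fk_replace <- function(x, pattern, replacement, field = c("name", "seq"),
                       ignore_case = FALSE, workers = 1L) {
  field <- match.arg(field)
  .check_regex(pattern)
  ds <- with_global_index(as_records_ds(x))
  out <- pd_collect(pd_map(ds, function(ch) {
    if (nrow(ch) == 0L) return(ch)
    ch <- copy(ch)
    if (field == "seq" && any(!is.na(ch$qual))) {
      usage_error("replacing sequence content of FASTQ records would desynchronize qualities")
    }
    vals <- ch[[field]]
    if (grepl("{nr}", replacement, fixed = TRUE)) {
      repl <- vapply(ch$global_index + 1L, function(nr) {
        gsub("{nr}", nr, replacement, fixed = TRUE)
      }, character(1))
      new <- vapply(seq_along(vals), function(i) {
        gsub(pattern, repl[i], vals[i], perl = TRUE, ignore.case = ignore_case)
      }, character(1))
    } else {
      new <- gsub(pattern, replacement, vals, perl = TRUE,
                  ignore.case = ignore_case)
    }
    set(ch, j = field, value = new)
    if (field == "name") ch[, id := sub("[ \t].*$", "", name)]
    ch
  }, workers = workers))
  out[, global_index := NULL]
  out[]
}

#' Convert FASTQ records to FASTA (the `fq2fa` command)
#' @param x records or a `pdataset`.
#' @param workers forked workers.
#' @return records with qualities dropped.
#' @export
fk_fq2fa <- function(x, workers = 1L) {
  .map_collect(x, function(ch) {
    ch <- copy(ch)
    if (nrow(ch) > 0L) ch[, qual := NA_character_]
    ch
  }, workers = workers)
}

#' Retrieve FASTQ records named by a FASTA file (the `fa2fq` command)
#'
#' Emits exactly those FASTQ records whose id appears among the FASTA
#' records' ids, in FASTQ-file order, with their original qualities.
#'
#' @param fastq FASTQ records or a `pdataset` (must carry qualities).
#' @param fasta FASTA records whose ids select the output.
#' @param workers forked workers.
#' @return FASTQ records.
#' @export
fk_fa2fq <- function(fastq, fasta, workers = 1L) {
  fa <- if (inherits(fasta, "pdataset")) pd_collect(fasta) else fasta
  wanted <- unique(fa$id)
  .map_collect(fastq, function(ch) {
    if (nrow(ch) == 0L) return(ch)
    if (anyNA(ch$qual)) usage_error("fa2fq input must be FASTQ (qualities required)")
    ch[id %in% wanted]
  }, workers = workers)
}
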