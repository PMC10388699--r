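## engine: a small deterministic partitioned-dataset engine. A pdataset is an
## ordered list of chunks; concatenating chunks in order is the canonical
## element sequence, and every primitive is defined so its result does not
## depend on the partition count or the number of workers.
##
## Chunks are either record data.tables (elements = rows) or plain
## vectors/lists (elements = entries); the chunk_* helpers abstract over the
## two.

## ---- chunk helpers --------------------------------------------------------

chunk_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

chunk_take <- function(x, idx) {
  if (is.data.frame(x)) x[idx, , drop = FALSE] else x[idx]
}

chunk_bind <- function(chunks) {
  chunks <- chunks[vapply(chunks, function(c) chunk_len(c) > 0L, logical(1))]
  if (length(chunks) == 0L) return(NULL)
  if (is.data.frame(chunks[[1]])) rbindlist(chunks) else do.call(c, chunks)
}

## ---- construction / storage tiers ----------------------------------------

.encode_chunk <- function(x, tier, spill_dir, codec) {
  switch(tier,
    memory = x,
    compressed = memCompress(serialize(x, NULL), type = codec),
    disk = {
      f <- tempfile("chunk_", tmpdir = spill_dir, fileext = ".bin")
      con <- file(f, "wb")
      writeBin(serialize(x, NULL), con)
      close(con)
      f
    })
}

.decode_chunk <- function(x, tier, codec) {
  switch(tier,
    memory = x,
    compressed = unserialize(memDecompress(x, type = codec)),
    disk = unserialize(readBin(x, "raw", n = file.size(x))))
}

#' Create a partitioned dataset
#'
#' @param chunks list of chunks (record `data.table`s or plain vectors).
#' @param tier storage tier: `"memory"` (default), `"compressed"`
#'   (each chunk held as a compressed serialized buffer), or `"disk"` (each
#'   chunk spilled to a file). The observable element sequence is identical
#'   under every tier.
#' @param spill_dir writable directory for the disk tier.
#' @param codec compression codec for the compressed tier (`"gzip"` default;
#'   speed is favoured over ratio).
#' @return a `pdataset`.
#' @export
pdataset <- function(chunks, tier = "memory", spill_dir = NULL, codec = "gzip") {
  tier <- match.arg(tier, c("memory", "compressed", "disk"))
  if (tier == "disk") {
    spill_dir <- spill_dir %||% tempdir()
    if (!dir.exists(spill_dir) || file.access(spill_dir, 2L) != 0L) {
      usage_error(sprintf("spill directory '%s' is not writable", spill_dir))
    }
  }
  sizes <- vapply(chunks, chunk_len, integer(1))
  enc <- lapply(chunks, .encode_chunk, tier = tier, spill_dir = spill_dir,
                codec = codec)
  structure(list(chunks = enc, sizes = sizes, tier = tier,
                 spill_dir = spill_dir, codec = codec),
            class = "pdataset")
}

#' @export
print.pdataset <- function(x, ...) {
  cat(sprintf("<pdataset: %d element(s) in %d partition(s), %s tier>\n",
              pd_count(x), pd_npart(x), x$tier))
  invisible(x)
}

#' Number of elements in a pdataset
#' @param ds a `pdataset`.
#' @export
pd_count <- function(ds) sum(ds$sizes)

#' Number of partitions in a pdataset
#' @param ds a `pdataset`.
#' @export
pd_npart <- function(ds) length(ds$chunks)

pd_chunk <- function(ds, i) .decode_chunk(ds$chunks[[i]], ds$tier, ds$codec)

pd_chunks <- function(ds) lapply(seq_along(ds$chunks), function(i) pd_chunk(ds, i))

## Rebuild a pdataset in the same tier from plain chunks.
pd_rewrap <- function(ds, chunks) {
  pdataset(chunks, tier = ds$tier, spill_dir = ds$spill_dir, codec = ds$codec)
}

#' Materialize a pdataset into a single collection
#' @param ds a `pdataset`.
#' @return the concatenation of all partitions in canonical order.
#' @export
pd_collect <- function(ds) {
  out <- chunk_bind(pd_chunks(ds))
  if (is.null(out)) {
    empty <- .empty_records()
    return(empty)
  }
  out
}

#' Split a collection into a partitioned dataset
#'
#' @param x a record `data.table` or a plain vector/list.
#' @param partitions number of contiguous chunks.
#' @inheritParams pdataset
#' @return a `pdataset` whose canonical order equals the input order.
#' @export
as_pdataset <- function(x, partitions = 1L, tier = "memory", spill_dir = NULL,
                        codec = "gzip") {
  if (inherits(x, "pdataset")) return(x)
  n <- chunk_len(x)
  p <- max(1L, as.integer(partitions))
  bounds <- round(seq(0, n, length.out = p + 1L))
  chunks <- lapply(seq_len(p), function(i) {
    if (bounds[i + 1] > bounds[i]) chunk_take(x, (bounds[i] + 1L):bounds[i + 1]) else chunk_take(x, integer(0))
  })
  pdataset(chunks, tier = tier, spill_dir = spill_dir, codec = codec)
}

#' Change the storage tier of a pdataset
#'
#' @param ds a `pdataset`.
#' @inheritParams pdataset
#' @return a `pdataset` with identical observable elements in the new tier.
#' @export
set_storage <- function(ds, tier, spill_dir = NULL, codec = NULL) {
  pdataset(pd_chunks(ds), tier = tier,
           spill_dir = spill_dir %||% ds$spill_dir,
           codec = codec %||% ds$codec)
}

## ---- worker pool ----------------------------------------------------------

## Order-preserving map over an arbitrary list, optionally forking workers.
## mclapply returns results in input order, so worker count never changes
## results; on platforms without fork it falls back to lapply.
pool_lapply <- function(xs, f, workers = 1L) {
  workers <- max(1L, as.integer(workers))
  if (workers > 1L && .Platform$OS.type == "unix" && length(xs) > 1L) {
    parallel::mclapply(xs, f, mc.cores = workers, mc.preschedule = TRUE)
  } else {
    lapply(xs, f)
  }
}

#' Order-preserving map over partitions
#'
#' @param ds a `pdataset`.
#' @param f function applied to each chunk (must return a chunk).
#' @param workers number of forked workers (results are identical for any
#'   worker count).
#' @return a `pdataset` in the same storage tier.
#' @export
pd_map <- function(ds, f, workers = 1L) {
  pd_rewrap(ds, pool_lapply(pd_chunks(ds), f, workers))
}

## ---- primitives -----------------------------------------------------------

#' Read a file as a partitioned dataset of records
#'
#' The file's byte range is divided into `partitions` contiguous chunks;
#' each chunk start is resynchronized to a true record boundary with
#' [find_record_boundary()], so a record belongs to the chunk in which its
#' header byte lies. `source_index` is assigned in global file order, and the
#' canonical order equals a sequential whole-file parse for every choice of
#' `partitions` and `workers`. gzip input is accepted but decompressed as one
#' sequential stream before splitting (gzip is not byte-splittable).
#'
#' @param path FASTA/FASTQ file, plain or gzip.
#' @param format `"fasta"` or `"fastq"`; auto-detected when `NULL`.
#' @param partitions number of partitions.
#' @param workers forked workers used to parse chunks.
#' @param source_tag integer tag stored on each record.
#' @inheritParams pdataset
#' @return a `pdataset` of records.
#' @export
partition_file <- function(path, format = NULL, partitions = 1L, workers = 1L,
                           source_tag = 0L, tier = "memory", spill_dir = NULL,
                           codec = "gzip") {
  text <- read_file_text(path)
  partition_text(text, format = format, partitions = partitions,
                 workers = workers, source_tag = source_tag, tier = tier,
                 spill_dir = spill_dir, codec = codec)
}

#' @rdname partition_file
#' @param text file contents as a latin1 byte string.
#' @export
partition_text <- function(text, format = NULL, partitions = 1L, workers = 1L,
                           source_tag = 0L, tier = "memory", spill_dir = NULL,
                           codec = "gzip") {
  format <- format %||% detect_format(text)
  p <- max(1L, as.integer(partitions))
  nb <- nchar(text, type = "bytes")
  if (is.na(format) || nb == 0L) {
    return(pdataset(rep(list(.empty_records()), p), tier = tier,
                    spill_dir = spill_dir, codec = codec))
  }
  raw_bounds <- unique(round(seq(0, nb, length.out = p + 1L)))
  sync <- vapply(raw_bounds[-length(raw_bounds)], function(b) {
    find_record_boundary(text, format, b)
  }, numeric(1))
  sync[1] <- 0  # the first chunk starts at byte 0 so malformed leads surface
  sync <- c(sync, nb)
  parse_fn <- if (format == "fasta") parse_fasta else parse_fastq
  pieces <- pool_lapply(seq_len(length(sync) - 1L), function(i) {
    if (sync[i + 1] > sync[i]) {
      parse_fn(substr(text, sync[i] + 1L, sync[i + 1]), source_tag = source_tag)
    } else {
      .empty_records()
    }
  }, workers)
  counts <- vapply(pieces, nrow, integer(1))
  offsets <- cumsum(c(0L, counts))[seq_along(pieces)]
  pieces <- lapply(seq_along(pieces), function(i) {
    ch <- pieces[[i]]
    if (nrow(ch) > 0L) ch$source_index <- ch$source_index + offsets[i]
    ch
  })
  while (length(pieces) < p) pieces <- c(pieces, list(.empty_records()))
  pdataset(pieces, tier = tier, spill_dir = spill_dir, codec = codec)
}

#' Attach dense global indices to a dataset
#'
#' Indices are 0..n-1 in canonical order, independent of partitioning.
#' Record chunks gain a `global_index` column; plain chunks become lists of
#' `list(index =, value =)` pairs.
#'
#' @param ds a `pdataset`.
#' @return a `pdataset` of indexed elements.
#' @export
with_global_index <- function(ds) {
  offsets <- cumsum(c(0L, ds$sizes))[seq_along(ds$sizes)]
  chunks <- pd_chunks(ds)
  out <- lapply(seq_along(chunks), function(i) {
    ch <- chunks[[i]]
    n <- chunk_len(ch)
    if (is.data.frame(ch)) {
      ch <- copy(ch)
      ch[, `:=`(global_index = offsets[i] + seq_len(.N) - 1L)]
      ch
    } else {
      lapply(seq_len(n), function(j) list(index = offsets[i] + j - 1L,
                                          value = ch[[j]]))
    }
  })
  pd_rewrap(ds, out)
}

#' Group elements by a key, hash-routed across partitions
#'
#' Each distinct key ends up in exactly one group holding its full preimage;
#' the 64-bit byte hash only routes keys to partitions, and grouping inside a
#' partition always compares full key values, so hash collisions can never
#' merge distinct keys. Member order within a group is ascending
#' `source_index` (record chunks) or canonical position.
#'
#' @param ds a `pdataset`.
#' @param key_fn vectorized function mapping a chunk to a character vector
#'   of keys, one per element.
#' @param target_partitions number of output partitions.
#' @param hash_fn optional replacement routing hash (`function(keys, m)`
#'   returning integers in `0..m-1`); used by tests to force collisions.
#' @return a `pdataset` whose chunks are lists of groups
#'   `list(key =, members =)`.
#' @export
group_by_key <- function(ds, key_fn, target_partitions = pd_npart(ds),
                         hash_fn = NULL) {
  m <- max(1L, as.integer(target_partitions))
  all <- pd_collect(ds)
  n <- chunk_len(all)
  if (n == 0L) return(pd_rewrap(ds, rep(list(list()), m)))
  keys <- key_fn(all)
  route <- if (is.null(hash_fn)) .hash_mod(keys, m) else hash_fn(keys, m)
  chunks <- lapply(seq_len(m) - 1L, function(b) {
    sel <- which(route == b)
    if (length(sel) == 0L) return(list())
    ks <- keys[sel]
    groups <- split(sel, factor(ks, levels = unique(ks)))
    lapply(names(groups), function(k) {
      list(key = k, members = chunk_take(all, groups[[k]]))
    })
  })
  pd_rewrap(ds, chunks)
}

#' Reduce a dataset with an associative combiner
#'
#' Per-partition partial results are combined pairwise in a binary tree, so
#' the result equals a left fold over the canonical order for any
#' associative `combine_fn`, regardless of partitioning.
#'
#' @param ds a `pdataset` with plain (vector/list) chunks.
#' @param combine_fn associative binary function.
#' @param workers forked workers for the per-partition folds.
#' @return the reduced element.
#' @export
tree_reduce <- function(ds, combine_fn, workers = 1L) {
  chunks <- Filter(function(c) chunk_len(c) > 0L, pd_chunks(ds))
  if (length(chunks) == 0L) usage_error("cannot reduce an empty dataset")
  partials <- pool_lapply(chunks, function(ch) {
    xs <- if (is.list(ch)) ch else as.list(ch)
    Reduce(combine_fn, xs)
  }, workers)
  while (length(partials) > 1L) {
    nxt <- lapply(seq_len(ceiling(length(partials) / 2)), function(i) {
      a <- 2L * i - 1L
      if (2L * i <= length(partials)) combine_fn(partials[[a]], partials[[2L * i]])
      else partials[[a]]
    })
    partials <- nxt
  }
  partials[[1]]
}

## Rank-encode character or numeric keys into integers under C-locale
## (bytewise) order, so routing and sorting never depend on the collation
## locale.
.key_codes <- function(keys, splitter_keys = NULL) {
  if (is.numeric(keys)) {
    return(list(codes = keys, scodes = splitter_keys))
  }
  u <- sort(unique(c(keys, splitter_keys)), method = "radix")
  list(codes = match(keys, u), scodes = if (!is.null(splitter_keys)) match(splitter_keys, u))
}

## Stable order of a chunk by key then tiebreak; radix is C-locale.
.stable_order <- function(codes, tiebreak, descending = FALSE) {
  if (descending) order(-xtfrm(codes), tiebreak, method = "radix")
  else order(codes, tiebreak, method = "radix")
}

## Tie-break vector: records use source_index, plain chunks use position.
.tiebreak_of <- function(chunk, offset = 0L) {
  if (is.data.frame(chunk) && "source_index" %in% names(chunk)) chunk$source_index
  else offset + seq_len(chunk_len(chunk))
}

#' Distributed sample merge-sort
#'
#' Each partition contributes up to `32 * P` sampled keys (seeded through
#' the PRF); the pooled sample is sorted and `P - 1` splitters taken at even
#' quantiles; elements are routed into splitter ranges, each bucket is
#' sorted locally by `(key, source_index)` (stable), and buckets are
#' concatenated in splitter order. The output is globally sorted and
#' identical for every partition count and worker count.
#'
#' @param ds a `pdataset`.
#' @param key_fn vectorized chunk -> keys function (character or numeric).
#' @param ascending sort direction (ties stay in source order either way).
#' @param seed integer seed for splitter sampling.
#' @param workers forked workers for bucket sorts.
#' @return a sorted `pdataset` with one chunk per bucket.
#' @export
sample_sort <- function(ds, key_fn, ascending = TRUE, seed = 0L, workers = 1L) {
  P <- pd_npart(ds)
  chunks <- pd_chunks(ds)
  offsets <- cumsum(c(0L, ds$sizes))[seq_along(ds$sizes)]
  keyed <- lapply(seq_along(chunks), function(i) {
    ch <- chunks[[i]]
    list(chunk = ch,
         keys = if (chunk_len(ch) > 0L) key_fn(ch) else character(0),
         tie = .tiebreak_of(ch, offsets[i]))
  })
  if (P > 1L) {
    samples <- unlist(lapply(seq_along(keyed), function(i) {
      ks <- keyed[[i]]$keys
      s <- min(length(ks), 32L * P)
      if (s == 0L) return(ks[0])
      ks[prf_choose(length(ks), s, seed, stream = 7000L + i)]
    }), use.names = FALSE)
    splitters <- if (length(samples) >= P) {
      ss <- sort(samples, method = "radix", decreasing = FALSE)
      ss[round(seq_len(P - 1L) * length(ss) / P)]
    } else samples[0]
  } else {
    splitters <- NULL
  }
  all_keys <- unlist(lapply(keyed, `[[`, "keys"), use.names = FALSE)
  all_tie <- unlist(lapply(keyed, `[[`, "tie"), use.names = FALSE)
  all <- chunk_bind(lapply(keyed, `[[`, "chunk"))
  if (is.null(all)) return(ds)
  enc <- .key_codes(all_keys, if (length(splitters)) splitters else NULL)
  bucket <- if (length(splitters)) {
    sc <- sort(enc$scodes)
    if (!ascending) findInterval(-xtfrm(enc$codes), sort(-xtfrm(sc)))
    else findInterval(enc$codes, sc)
  } else {
    rep(0L, chunk_len(all))
  }
  nb <- if (length(splitters)) length(splitters) + 1L else 1L
  out <- pool_lapply(seq_len(nb) - 1L, function(b) {
    sel <- which(bucket == b)
    if (length(sel) == 0L) return(chunk_take(all, integer(0)))
    o <- .stable_order(enc$codes[sel], all_tie[sel], descending = !ascending)
    chunk_take(all, sel[o])
  }, workers)
  pd_rewrap(ds, out)
}

#' Seeded deterministic random permutation
#'
#' Each element receives the key `PRF(seed, source_index)` and the dataset
#' is sorted by that key, yielding a permutation that is identical for every
#' partition and worker count.
#'
#' @param ds a `pdataset`.
#' @param seed integer seed.
#' @return a permuted `pdataset`.
#' @export
keyed_random_order <- function(ds, seed = 0L) {
  P <- pd_npart(ds)
  all <- pd_collect(ds)
  n <- chunk_len(all)
  if (n == 0L) return(ds)
  idx <- if (is.data.frame(all) && "source_index" %in% names(all)) {
    all$source_index
  } else {
    seq_len(n) - 1L
  }
  key <- prf_unif(seed, 11L, idx)
  perm <- order(key, idx, method = "radix")
  reordered <- chunk_take(all, perm)
  out <- as_pdataset(reordered, partitions = P, tier = ds$tier,
                     spill_dir = ds$spill_dir, codec = ds$codec)
  out
}
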