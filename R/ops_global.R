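## ops_global: commands whose sequential algorithm cannot be mapped over
## records, re-expressed with the engine primitives: distributed sampling via
## sequential hypergeometric splitting, collision-checked dedup, multi-file
## set operations, pairing, concatenation, rename, sample merge-sort and
## seeded shuffle.
##
## Output-order policy: every set-type command restores input order via
## source_index, so parallel output is byte-comparable to sequential output.

## ---- sampling -------------------------------------------------------------

#' Allocate a without-replacement sample across partitions
#'
#' Sequentially over partitions i = 1..P-1, the number of sampled records
#' k_i is drawn from the hypergeometric distribution with population N_rem,
#' marked class n_i (the partition size) and S_rem draws; N_rem and S_rem
#' are then decremented and the last partition receives the remainder. The
#' draw uses the exact integer inverse CDF ([stats::qhyper]) driven by PRF
#' uniforms. Combined with a uniform within-partition choice this selects
#' every n-subset of the whole dataset with equal probability.
#'
#' @param partition_sizes integer vector of partition sizes.
#' @param sample_size total records to sample (<= sum of sizes).
#' @param seed integer seed.
#' @return integer vector of per-partition counts summing to `sample_size`.
#' @export
hypergeometric_split <- function(partition_sizes, sample_size, seed = 0L) {
  N <- sum(partition_sizes)
  if (sample_size > N) {
    usage_error(sprintf("sample size %d exceeds the %d available records",
                        sample_size, N))
  }
  if (sample_size < 0L) usage_error("sample size must be >= 0")
  P <- length(partition_sizes)
  ks <- integer(P)
  N_rem <- N
  S_rem <- sample_size
  if (P > 1L) {
    u <- prf_unif(seed, 2L, seq_len(P - 1L))
    for (i in seq_len(P - 1L)) {
      ni <- partition_sizes[i]
      ks[i] <- stats::qhyper(u[i], m = ni, n = N_rem - ni, k = S_rem)
      N_rem <- N_rem - ni
      S_rem <- S_rem - ks[i]
    }
  }
  ks[P] <- S_rem
  ks
}

#' Sample records by count or proportion (the `sample` command)
#'
#' Count mode allocates per-partition counts with
#' [hypergeometric_split()], then draws that many distinct positions
#' uniformly within each partition (seeded by the partition index); the
#' selection is exactly uniform over all n-subsets. Proportion mode keeps a
#' record iff `PRF(seed, source_index) < p` and is therefore independent of
#' partitioning. Output preserves input order in both modes.
#'
#' @param x records or a `pdataset`.
#' @param n records to draw (count mode).
#' @param p keep probability in `[0, 1]` (proportion mode).
#' @param seed integer seed.
#' @return records.
#' @export
fk_sample <- function(x, n = NULL, p = NULL, seed = 0L) {
  if (is.null(n) == is.null(p)) {
    usage_error("exactly one of n (count) or p (proportion) must be given")
  }
  ds <- as_records_ds(x)
  if (!is.null(p)) {
    if (p < 0 || p > 1) usage_error("proportion must be in [0, 1]")
    out <- pd_collect(pd_map(ds, function(ch) {
      if (nrow(ch) == 0L) return(ch)
      ch[prf_unif(seed, 3L, source_index) < p]
    }))
    return(out)
  }
  sizes <- ds$sizes
  ks <- hypergeometric_split(sizes, as.integer(n), seed)
  chunks <- pd_chunks(ds)
  picked <- lapply(seq_along(chunks), function(i) {
    if (ks[i] == 0L) return(chunks[[i]][0L])
    pos <- prf_choose(sizes[i], ks[i], seed, stream = 100L + i)
    chunks[[i]][pos]
  })
  out <- chunk_bind(picked)
  if (is.null(out)) .empty_records() else out
}

## ---- dedup / set operations -----------------------------------------------

.key_fn_for <- function(by, ignore_case = FALSE) {
  force(by); force(ignore_case)
  function(ch) {
    k <- ch[[by]]
    if (ignore_case) tolower(k) else k
  }
}

#' Remove duplicated records (the `rmdup` command)
#'
#' Records are grouped by a hash of the chosen key; the hash only routes --
#' within each group records are compared by the actual key value, so a
#' hash collision can never remove a non-duplicate. The record with the
#' smallest `source_index` in each duplicate class survives, and survivors
#' are re-sorted by `source_index` (input order preserved).
#'
#' @param x records or a `pdataset`.
#' @param by dedup key: `"id"`, `"name"` or `"seq"`.
#' @param ignore_case compare keys case-insensitively.
#' @param detail also return the duplicate classes.
#' @param hash_fn optional routing-hash override (see [group_by_key()]).
#' @return records, or (with `detail`) a list of `records` and a
#'   `duplicates` table (key, count).
#' @export
fk_rmdup <- function(x, by = c("id", "name", "seq"), ignore_case = FALSE,
                     detail = FALSE, hash_fn = NULL) {
  by <- match.arg(by)
  ds <- as_records_ds(x)
  groups_ds <- group_by_key(ds, .key_fn_for(by, ignore_case),
                            target_partitions = pd_npart(ds),
                            hash_fn = hash_fn)
  groups <- unlist(pd_chunks(groups_ds), recursive = FALSE)
  keep <- vapply(groups, function(g) min(g$members$source_index), integer(1))
  all <- pd_collect(ds)
  out <- all[source_index %in% keep][order(source_index)]
  if (!detail) return(out)
  dups <- rbindlist(lapply(groups, function(g) {
    if (nrow(g$members) > 1L) data.table(key = g$key, count = nrow(g$members))
  }))
  list(records = out, duplicates = if (nrow(dups)) dups[order(key)] else dups)
}

#' Records common to all input files (the `common` command)
#'
#' All files' records are unioned and grouped by the chosen key (hash-routed,
#' compared by actual value as in [fk_rmdup()]); a key qualifies iff its
#' group contains at least one member from every file. The qualifying
#' records of the first file are emitted in that file's order.
#'
#' @param datasets list of >= 2 record tables or `pdataset`s, one per file.
#' @param by key field: `"id"`, `"name"` or `"seq"`.
#' @param ignore_case compare keys case-insensitively.
#' @return records of the first file.
#' @export
fk_common <- function(datasets, by = c("id", "name", "seq"),
                      ignore_case = FALSE) {
  by <- match.arg(by)
  if (length(datasets) < 2L) usage_error("common requires at least 2 input files")
  tabs <- lapply(seq_along(datasets), function(i) {
    dt <- if (inherits(datasets[[i]], "pdataset")) pd_collect(datasets[[i]]) else copy(datasets[[i]])
    dt[, source_tag := i - 1L]
    dt
  })
  all <- rbindlist(tabs)
  ds <- as_pdataset(all, partitions = max(1L, length(tabs)))
  groups <- unlist(pd_chunks(group_by_key(ds, .key_fn_for(by, ignore_case))),
                   recursive = FALSE)
  ntags <- length(tabs)
  good <- vapply(groups, function(g) {
    length(unique(g$members$source_tag)) == ntags
  }, logical(1))
  good_keys <- vapply(groups[good], `[[`, character(1), "key")
  first <- tabs[[1]]
  k <- .key_fn_for(by, ignore_case)(first)
  first[k %in% good_keys][order(source_index)]
}

## ---- pairing / concatenation ----------------------------------------------

.pair_key <- function(id) sub("/[12]$", "", id)

.dup_key_check <- function(keys, label) {
  d <- keys[duplicated(keys)]
  if (length(d) > 0L) {
    data_error(sprintf("ambiguous pairing: id '%s' occurs more than once in %s",
                       d[1], label))
  }
}

#' Match up paired-end reads from two FASTQ files (the `pair` command)
#'
#' The pairing key is the record id with a trailing `/1` or `/2` stripped.
#' Keys from both files are unified and grouped; a key with exactly one
#' member from each file forms a pair. Paired outputs are ordered by the
#' file-1 member's `source_index` and positionally aligned.
#'
#' @param fq1,fq2 FASTQ records or `pdataset`s.
#' @return a list: `paired_1`, `paired_2`, `unpaired_1`, `unpaired_2`.
#' @export
fk_pair <- function(fq1, fq2) {
  a <- if (inherits(fq1, "pdataset")) pd_collect(fq1) else fq1
  b <- if (inherits(fq2, "pdataset")) pd_collect(fq2) else fq2
  ka <- .pair_key(a$id)
  kb <- .pair_key(b$id)
  .dup_key_check(ka, "file 1")
  .dup_key_check(kb, "file 2")
  common <- intersect(ka, kb)
  a_ord <- a[ka %in% common][order(source_index)]
  key_order <- .pair_key(a_ord$id)
  b_idx <- match(key_order, kb)
  list(paired_1 = a_ord,
       paired_2 = b[b_idx],
       unpaired_1 = a[!ka %in% common][order(source_index)],
       unpaired_2 = b[!kb %in% common][order(source_index)])
}

#' Concatenate same-id sequences across files (the `concat` command)
#'
#' For each id present in every file, one record is emitted whose sequence
#' (and quality, when all inputs are FASTQ) is the concatenation in file
#' order; ids missing from any file are dropped. Output is ordered by the
#' first file's `source_index`.
#'
#' @param datasets list of >= 2 record tables or `pdataset`s.
#' @return records.
#' @export
fk_concat <- function(datasets) {
  if (length(datasets) < 2L) usage_error("concat requires at least 2 input files")
  tabs <- lapply(datasets, function(d) {
    if (inherits(d, "pdataset")) pd_collect(d) else d
  })
  for (i in seq_along(tabs)) {
    d <- tabs[[i]]$id[duplicated(tabs[[i]]$id)]
    if (length(d) > 0L) {
      data_error(sprintf("ambiguous concatenation: id '%s' occurs more than once in file %d",
                         d[1], i))
    }
  }
  shared <- Reduce(intersect, lapply(tabs, `[[`, "id"))
  first <- tabs[[1]][id %in% shared][order(source_index)]
  if (nrow(first) == 0L) return(.empty_records())
  all_qual <- all(vapply(tabs, function(t) !anyNA(t$qual[t$id %in% shared]),
                         logical(1)))
  seqs <- first$seq
  quals <- if (all_qual) first$qual else NA_character_
  for (i in seq_along(tabs)[-1]) {
    idx <- match(first$id, tabs[[i]]$id)
    seqs <- paste0(seqs, tabs[[i]]$seq[idx])
    if (all_qual) quals <- paste0(quals, tabs[[i]]$qual[idx])
  }
  out <- copy(first)
  out[, seq := seqs]
  out[, qual := if (all_qual) quals else NA_character_]
  out
}

## ---- rename / sort / shuffle ----------------------------------------------

#' Rename duplicated ids (the `rename` command)
#'
#' Records are grouped by id; within each group, ordered by
#' `source_index`, the first keeps its id and the k-th (k >= 2) gets
#' `id_k`. All other fields are unchanged and output stays in input order.
#'
#' @param x records or a `pdataset`.
#' @return records.
#' @export
fk_rename <- function(x) {
  recs <- if (inherits(x, "pdataset")) pd_collect(x) else copy(x)
  if (nrow(recs) == 0L) return(recs)
  recs <- recs[order(source_index)]
  recs[, .occ := seq_len(.N), by = id]
  nid <- ifelse(recs$.occ > 1L, paste0(recs$id, "_", recs$.occ), recs$id)
  desc <- substring(recs$name, nchar(recs$id) + 1L)
  recs[, `:=`(name = paste0(nid, desc), id = nid, .occ = NULL)]
  recs[]
}

#' Sort records (the `sort` command)
#'
#' A distributed sample merge-sort by the chosen field: bytewise order for
#' id/name/seq, numeric for length. The sort is stable (ties keep source
#' order); `descending` reverses the key order, not the tie order.
#'
#' @param x records or a `pdataset`.
#' @param by sort key: `"id"`, `"name"`, `"seq"` or `"length"`.
#' @param descending sort direction.
#' @param seed seed for splitter sampling (does not affect the result).
#' @param workers forked workers.
#' @return records.
#' @export
fk_sort <- function(x, by = c("id", "name", "seq", "length"),
                    descending = FALSE, seed = 0L, workers = 1L) {
  by <- match.arg(by)
  key_fn <- if (by == "length") {
    function(ch) nchar(ch$seq, type = "bytes")
  } else {
    function(ch) ch[[by]]
  }
  ds <- as_records_ds(x)
  pd_collect(sample_sort(ds, key_fn, ascending = !descending, seed = seed,
                         workers = workers))
}

#' Seeded shuffle (the `shuffle` command)
#'
#' A deterministic permutation keyed by `PRF(seed, source_index)`; the same
#' seed yields the same order for every partition and worker count.
#'
#' @param x records or a `pdataset`.
#' @param seed integer seed.
#' @return records.
#' @export
fk_shuffle <- function(x, seed = 0L) {
  pd_collect(keyed_random_order(as_records_ds(x), seed = seed))
}
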