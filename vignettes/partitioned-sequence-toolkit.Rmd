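---
title: "Deterministic partitioned processing of FASTA/FASTQ files"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic partitioned processing of FASTA/FASTQ files}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastkit)
```

## The problem

Sequence toolkits operate record-by-record on FASTA/FASTQ files, but most
of their commands are written as sequential scans. Parallelizing them by
splitting the file into byte ranges raises three correctness questions that
this package is organized around:

1. **Where may a chunk start?** A byte offset usually lands mid-record, and
   in FASTQ a line starting with `@` may be a quality string rather than a
   header.
2. **Which operations commute with partitioning?** Per-record maps do;
   statistics need an associative merge; sampling, sorting and
   deduplication need new algorithms to give the *same answer* as a
   sequential run.
3. **How do we know the parallel answer is right?** Our contract is strong:
   byte-identical output for every partition count, worker count and
   storage tier. That makes sequential output the oracle for every
   parallel configuration, and it is the property the test suite leans on
   hardest.

## Record model and boundary resynchronization

A record is `(id, name, seq, qual, source_index, source_tag)`: `id` is the
first whitespace token of the header, `name` the full header, and
`source_index` the 0-based ordinal of the record in its file. Commands that
restore "input order" sort by `source_index`, which is also the stable
tie-break everywhere a sort appears.

`find_record_boundary()` returns the first byte at or after a split point
that starts a true record. For FASTA this is the next line beginning `>`.
For FASTQ a candidate `@` line is accepted only if a full 4-line record
parses from it: the line two below must start `+` and the sequence and
quality lines must have equal length. This rejects quality lines that start
with `@`. The check is heuristic in principle — one can construct files
where a quality line followed by coincidentally well-shaped lines validates
— but such inputs do not arise from real instruments, and the property
suite (1,000 random split points per fixture) verifies that no record is
lost, duplicated or split on the data we generate.

Two deliberate restrictions keep resynchronization well-posed:

- **FASTQ is strictly 4-line.** Multi-line FASTQ is rejected with a clear
  error; resynchronization on wrapped FASTQ is ill-posed and real-world
  FASTQ is 4-line.
- **gzip input is read as one sequential stream** and split in memory;
  gzip is not byte-addressable, so FAI building on gzip input is refused.

CRLF input is accepted (CR stripped before LF handling); output always
uses LF. The first chunk always starts at byte 0 so that malformed leading
bytes surface as parse errors rather than being silently skipped by
resynchronization.

## The engine

A `pdataset` is an ordered list of chunks; concatenating chunks in order is
the canonical element sequence, and nothing observable may depend on how
elements are cut into chunks. The primitives:

- `pd_map()` — order-preserving per-chunk map, optionally over forked
  workers (`parallel::mclapply` keeps result order, so worker count never
  changes output).
- `with_global_index()` — dense 0..n−1 indices in canonical order,
  computed from chunk sizes by prefix sum.
- `group_by_key()` — a stable FNV-1a 64-bit byte hash routes keys to
  partitions; groups are then formed by *full key equality* within each
  partition. The hash is fixed across runs and platforms, and is only a
  router: collisions cost performance, never correctness. Tests force a
  constant hash to verify this structurally.
- `tree_reduce()` — per-partition folds combined pairwise; equal to a
  sequential left fold for associative combiners.
- `sample_sort()` — each partition contributes up to `32 × P` seeded sample
  keys; `P − 1` splitters are taken at even quantiles of the pooled sorted
  sample; elements are routed into splitter ranges and each bucket is
  sorted by `(key, source_index)`. The splitter sample size is a documented
  constant: at 32 samples per output bucket the expected bucket imbalance
  is modest, and correctness never depends on splitter quality. String keys
  are rank-encoded through a C-locale radix sort so ordering never depends
  on the collation locale.
- `keyed_random_order()` — elements are keyed by `PRF(seed, source_index)`
  and sorted; a seeded permutation identical under any partitioning.

**Randomness.** Every random decision is a pure function of
`(seed, stream, counter)` through a splitmix64-based PRF (`prf_unif()`).
The global R RNG state is never touched, results cannot depend on worker
scheduling, and the same seed reproduces the same bytes everywhere. Streams
separate independent uses of one seed (sampling draws, per-partition
position draws, shuffle keys, fixture fields).

**Storage tiers.** Chunks live in memory, as zlib-compressed serialized
buffers, or as spill files. Transforms decode on access and re-encode into
the same tier; the observable sequence is tier-invariant by construction
and verified byte-for-byte. The codec is configurable (`gzip` default,
favouring speed); the disk tier requires a writable spill directory and
fails fast otherwise. Evaluation is eager: the sequential-equivalence
contract makes laziness an invisible optimization we chose not to take.

## Command semantics worth stating

- **stats**: per-partition summaries carry the exact length multiset, so
  the merged N50 is exact. N50 is the length at which the descending
  cumulative length sum first reaches ≥ half the total, ties toward the
  larger length (the ≥ convention differs across tools, so it is pinned
  here). Q20%/Q30% use Phred+33 by default with a configurable offset and
  no auto-detection — silent misdetection is worse than an explicit flag.
  Average length is reported to 1 decimal, quality percentages to 2.
- **sample**: count mode allocates per-partition counts by sequential
  hypergeometric draws k_i ~ Hypergeom(N_rem, n_i, S_rem) using the exact
  integer inverse CDF (`stats::qhyper`) driven by PRF uniforms, then draws
  positions uniformly within partitions via a partial Fisher–Yates. The
  two stages compose to an exactly uniform draw of every n-subset
  (verified by a chi-square over 100,000 draws on a 5-record toy). The
  selected *set* depends on the partition count (the distribution does
  not); proportion mode keys on `source_index` and is
  partitioning-invariant.
- **rmdup / common**: hash groups, actual-value comparison, first
  occurrence (minimum `source_index`) survives, survivors restored to
  input order. Order restoration is our policy — it makes parallel output
  byte-comparable to sequential output, which is the test surface.
- **pair**: the pairing key strips a trailing `/1` or `/2` only; modern
  headers keeping the mate flag in the description already share the id
  token. A key occurring twice within one file is an error naming the id.
- **concat** requires an id in *every* file (intersection semantics) and
  concatenates in file order; qualities concatenate only when all inputs
  are FASTQ.
- **rename** suffixes the k-th occurrence (k ≥ 2) of an id with `_k`.
- **grep** matches ids/names by full-string equality and sequences by
  substring containment (identifier lookup vs motif search); regex mode is
  an unanchored search on the chosen field. `--delete-matched` keeps, per
  pattern, the match with the smallest `source_index`; a record matched by
  several patterns counts against all of them.
- **locate** reports all overlapping occurrences; minus-strand hits are
  found by scanning for the reverse complement and reported with
  plus-strand coordinates. For a palindromic motif both strand records are
  reported at the same interval — the convention is stated because it is
  genuinely ambiguous. IUPAC-degenerate motifs expand to character
  classes.
- **translate** uses the NCBI genetic-code tables (via
  `Biostrings::getGeneticCode`); a codon with IUPAC ambiguity translates
  to an amino acid only if every expansion agrees, else `X`; stops are
  `*`; `U` is treated as `T`; negative frames translate the reverse
  complement after skipping `|frame| − 1` bases.
- **subseq / range / faidx regions** are 1-based inclusive; `-k` counts
  from the end; coordinate 0 is an error; out-of-range ends clamp.
- **faidx** emits the samtools dialect byte-exactly (verified against
  samtools in the tests), including the 6-column FASTQ form. Duplicate
  record names are an error — a last-wins dialect exists in the wild, but
  an index with ambiguous lookups is a trap. Empty sequences are legal and
  indexed with `linebases 0, linewidth 1` (samtools itself silently drops
  them; we prefer to keep the record addressable).
- **head-genome**: the shared-prefix rule is ours (the one-line synopsis
  underdetermines it): compare the first `min_words` whitespace-split
  words of each record's *description* (header minus id), case-sensitive,
  and stop at the first mismatch.

## The synthetic data generator

`generate_fixture()` emulates the axes that matter to these commands:
record count, length spread (fixed, uniform, or a short/long mixture
echoing mixed assemblies), alphabet, exact-duplicate rate (sharing id,
sequence, or both), gap rate, Phred range, and paired files with a
controllable unpaired fraction. Every byte is a pure function of the spec
seed, and the generator records ground truth (lengths, duplicate classes,
the pair table) in a sidecar so test oracles never re-derive truth from
the code under test.

It does **not** model platform error profiles, quality-by-cycle decay,
adapter content or realistic base composition. Passing tests therefore
demonstrate the *algebraic* properties — partitioning/worker/tier
invariance, oracle agreement, exact sampling laws — on well-formed data;
they say nothing about tolerance to pathological real-world files beyond
the malformed-input errors the parser raises deliberately.

## Problem sizes and numerical choices

The property suites run at desk scale, chosen to exercise every code path
(multiple records per partition, empty partitions, duplicate keys) while
keeping the suite quick: 1,000-record fixtures for the
parallel-equals-sequential grid (workers 1/2/4 × partitions 1/2/3/8),
1,000 random split points for boundary safety, 100,000 seeded draws for
the sampling law (tolerance ±0.5 percentage points per subset, chi-square
p > 0.01), and ≥ 100 random instances per brute-force oracle. Counts and
offsets are held as doubles where byte offsets may exceed integer range;
all string ordering is bytewise (C locale) to be platform-independent.

## Known limitations

- Single-machine only: workers are forked processes on one host; there is
  no multi-node execution, RPC or fault tolerance (errors fail fast).
- No approximate (mismatch-tolerant) grep/locate; scope is
  exact/regex/degenerate matching.
- No GTF/BED-driven subsequence extraction or flanking windows.
- No BGZF virtual offsets; gzip input is sequential-read only.
- Count-mode sampling is deterministic for a fixed `(seed, partitions)`
  pair but selects a different (equally distributed) subset if the
  partition count changes.
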