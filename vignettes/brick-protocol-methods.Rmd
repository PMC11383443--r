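---
title: "Methods: the brick protocol, its invariants, and the design choices behind bricktools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the brick protocol, its invariants, and the design choices behind bricktools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bricktools)
```

`bricktools` implements a package-manager protocol for versioned data
assets. This vignette explains the model the package implements, the
parameters that matter, the decisions taken where the protocol left room,
and what the offline fixtures do and do not demonstrate.

## The model

A **brick** couples three things: user ETL code plus a pipeline file
(`dvc.yaml`) describing how the data is built; a lock file (`dvc.lock`)
mapping every pipeline dependency and output to an MD5 content hash; and a
`brick/` payload directory of built artifacts. A **library** is a local
directory holding installed brick versions under `<org>/<name>/<commit>`
next to a shared content-addressed `cache/`. A **registry** serves
repository trees by version and payload objects by digest.

The protocol stands on one primitive: *content addressing*. An object's
identity is the MD5 of its bytes, which gives deduplication (identical
content maps to one cache path), cheap integrity checking (re-hash and
compare), and incremental everything — installs fetch only unknown digests,
and pipeline stages rerun only when a recorded digest moves.

MD5 is retained deliberately despite its cryptographic weakness: digests
here *identify* content, they do not authenticate it, and the hash must
match what existing lock files record. The cache layout reserves room for
an algorithm change (the configuration carries the cache root; the sharded
path scheme is independent of the hash length).

## Content cache

Objects live at `cache/<first 2 hex>/<remaining 30 hex>`; the two-character
shard keeps directory fanout bounded (256 subdirectories), the convention
most object stores use. Stored objects are chmod-ed read-only, and storing
existing content is a byte-level no-op — both matter for the idempotence
invariant (installing twice must leave identical bytes on disk).

Lock files hash *directories* as well as files (a download stage's output
is typically a directory), but a directory has no canonical byte stream.
We define one: the **tree manifest**, a minimal JSON array of
`[relative-path, digest]` pairs, UTF-8, no whitespace, paths in byte order
with POSIX separators; the tree digest is the MD5 of that serialization.
The empty directory therefore digests the two-byte string `[]`. This makes
directory digests independent of creation and traversal order and
bit-reproducible across platforms. It is a defined stand-in, not a claim
about how any other tool hashes directories; the format is documented so
any implementation can reproduce it. Symbolic links inside hashed trees are
resolved to their target content, so a linked and a copied payload digest
identically.

Materialization prefers symlinks and falls back to copying where the
filesystem refuses links; the contract is stated in terms of content
equality (reading the destination yields bytes hashing to the digest), so
callers never depend on the mechanism.

## The brick anatomy and its parsers

The pipeline dialect is a strict subset of the DVC stage schema: per stage
`cmd` (required), `deps`, `outs`, and a `frozen` flag. Anything else
(`wdir`, `params`, `metrics`, `foreach`, ...) is rejected with an
"unsupported key" error rather than silently ignored — a pipeline using
unsupported features should fail loudly, not build differently.

`write_lock()` always emits a canonical form: stages sorted by name, paths
sorted within stage, every scalar single-quoted. Canonicalization is what
makes the lock a usable ledger: `write(parse(text))` is byte-identical for
equivalent inputs, so version-control diffs show real changes only, and
byte equality of lock files is equivalent to semantic equality.

Asset identifiers are derived from payload paths by replacing every
character outside `[A-Za-z0-9_]` with `_` (a leading digit gains a `_`
prefix). The rule is the simplest one consistent with the
`file.parquet → file_parquet` convention; collisions (`x.parquet` vs
`x_parquet`) are detected at enumeration and reported as errors rather than
resolved by renaming, since silent renaming would break downstream code.

The dependencies file (`.bb/dependencies.txt`) is one entry per line,
`<org>/<name> <commit>` or `<git-url> <commit>`, `#` comments and blank
lines ignored. Two whitespace-separated fields keep the file trivially
diffable and mergeable. A brick may depend on an org/name at most once;
`bb_add()` therefore *replaces* an existing entry when given a newer
commit instead of appending a duplicate.

## Resolution and the registry backend

Bare names resolve under a configurable default organization; omitting a
commit resolves the head of the `main` branch. Commit prefixes of at least
five hex characters are accepted on input and always expanded to the full
identifier before being stored or used in paths — library layouts and
dependency files never contain abbreviations, so uniqueness can never decay
as the registry grows. Ambiguous prefixes are an error listing candidates.

The registry is an interface (`resolve head`, `fetch tree`,
`fetch object`) with a local-directory reference implementation:
`<registry>/<org>/<name>/refs` (branch map), `.../commits` (ordered log),
`.../<commit>/` (tree), `objects/` (sharded store). Any transport-backed
backend (git plus an object store) honours the same three generics and
passes the same contract tests. Tokens are stored and passed through but
ignored by the local backend; authentication is a backend concern.

## Install semantics

Install is four phases in a fixed order — clone, enumerate, fetch, link —
and the report's conservation law (`fetched + skipped_cached = assets
enumerated`) is asserted property-style in the tests. Fetched objects are
*always* verified against their digest before entering the cache; a
mismatch aborts with an integrity error naming the asset. On failure after
a partial fetch the cache keeps what arrived but the repository directory
is removed: the cache is content-addressed so partial state there is
harmless and makes the retry cheaper, while a half-linked repository
directory would be indistinguishable from a healthy one.

`bb_pull()` installs direct dependencies only, by default. The protocol is
silent on transitivity; non-recursive is the conservative reading (a brick
declares what *it* needs), and a `transitive = TRUE` mode with a visited
set is provided for users who want closure. When entries fail, the
remaining ones are still attempted and one summary error is raised at the
end — a single bad dependency should not block the rest of an environment.

`bb_assets()` without a commit uses the newest *installed* version,
preferring the backend's commit order and falling back to install
modification time when the registry is unreachable — offline use should
degrade, not fail.

## Incremental execution

The stage DAG has an edge from producer to consumer when an output equals,
contains, or is contained by a dependency (paths normalized, leading `./`
stripped). Prefix matching is what lets a stage depend on a directory
another stage produces. Visit order is topological with lexicographic
tie-breaks, so plans are deterministic; cycles are an error naming the
stages involved.

A stage is stale when (in reason order): it has no dependencies (the
primary-source-check pattern — such stages run on every build, opt-out via
`frozen: true`); it has no lock entry; its command string changed
(byte-wise — whitespace counts, because guessing at shell semantics is how
build systems acquire bugs); a dependency is missing or its digest moved;
an output is missing or was edited. Statuses are recomputed at visit time
rather than snapshotted up front, so an upstream stage that reruns but
regenerates byte-identical output correctly leaves its dependents fresh
within the same pass.

A successful stage rewrites its lock entry with fresh digests; a failed
stage leaves its entry untouched and all transitive dependents are skipped
for that run. With deterministic commands and no zero-dependency stages,
`repro ∘ repro` executes nothing on the second pass — the fixed-point
property the test suite asserts.

## The harmonization schema

The three-table reduction — substances, properties, activities — trades
schema richness for uniformity: any source that can name a substance, a
measured property and a value fits. Binary outcomes are encoded positive →
1, negative → 0 in the shared numeric `value` column with a `value_type`
tag; numeric endpoints (binding affinities, LD50 doses) pass through
unchanged. Structure strings (SMILES, InChI) are carried verbatim — no
canonicalization is attempted, because silently rewriting identifiers is a
data-integrity hazard and structure normalization is a modeling-stage
concern.

Substances deduplicate by structure key: records sharing an InChI collapse
to one substance (first-seen metadata wins); records without an InChI stay
per-source. Ids are minted as digests of the structure key or of
`(source, local id)` — never random — so a release rebuilt from identical
inputs is bit-identical, which the tests check with `identical()` on whole
result objects. Metadata is serialized as canonical JSON (keys sorted
recursively, compact) for the same reason.

"Major properties" are those with *strictly more than* the threshold
(default 1,000) activities — the natural reading of "over 1,000" — ordered
by count descending, pid ascending on ties. `validate_harmony()` reports
dangling foreign keys, non-canonical metadata and out-of-range binary
values; `harmonize()` output always validates clean, which is asserted as
an invariant rather than assumed.

## What the fixtures emulate — and what they do not

The fixture registry stands in for a hosted git + object-store pair: refs,
ordered commits, version trees, sharded objects. Payloads are small but
real where format matters (Parquet written by `arrow`; SQLite written via
the Python standard-library driver, with a header-tagged byte fallback;
HDT and other formats as opaque seeded bytes, which is also how the
installer treats them). The three-stage pipeline fixture reproduces the
canonical status → download → process shape over a mutable local "primary
source" directory, with the status stage snapshotting the source — a
digest-equivalent stand-in for fetching a status page over the network.
The chemical fixtures generate two schema-divergent sources (word outcomes
vs numeric doses) with a controlled number of shared InChIs, and return
expected counts computed by construction bookkeeping, independent of the
harmonizer.

Passing tests therefore demonstrate protocol correctness — hashing,
deduplication, staleness propagation, conservation laws, id stability —
at desk scale. They do not demonstrate behaviour against real transports
(HTTP retries, auth, partial downloads), multi-gigabyte payloads,
concurrent writers to one cache, or the messiness of real source schemas;
those are transport- and adapter-level concerns behind interfaces designed
for substitution.

## Problem sizes and numerical choices

The test suite runs the default fixture brick (3 assets), randomized
installer registries (1–6 files × 5 seeds), 200 random DAGs for
topological-order checking, 40 randomized pipelines against the
brute-force staleness oracle in the unit suite and 200 in the end-to-end
suite (2–4 stages, copy/concatenate commands with fully known semantics,
random source mutations and output deletions), 120 draws over 40 distinct
contents for cache deduplication, and 25 generated lock files for
round-trip byte identity. These sizes were chosen so each property is
exercised across many shapes while the whole suite stays fast enough to
run on every change; all randomness is seeded.

Degenerate inputs are defined, not accidental: the empty directory has a
digest (of `[]`), an empty pipeline is valid and runs nothing, an empty
dependencies file pulls nothing, an empty source harmonizes to three empty
tables, and a brick with no payload yields an empty namespace with a
warning rather than an error.

## Known limitations

- Hashing happens per visit during a run; very large dependency trees pay
  that cost each pass (no mtime-based short-circuit is attempted, by
  design — correctness first).
- The runner executes stages sequentially; the DAG would admit parallel
  execution, which is future work.
- Unicode paths are carried as UTF-8 but not normalized to a canonical
  form; two byte-distinct encodings of the same visual name are distinct
  paths.
- The local registry backend does not model network failure modes;
  contract tests cover semantics, not transport faults.
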