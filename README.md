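# bricktools

A package manager for versioned life-science data assets, in R.

Life-science analyses routinely begin with weeks of ad-hoc data wrangling:
every lab re-downloads the same public databases, re-writes the same
extract-transform-load (ETL) code, and pins versions by hand, if at all.
`bricktools` treats datasets the way CRAN or pip treat code. A dataset is
packaged as a **brick**: a repository holding the ETL pipeline that builds
it, a lock file of content hashes for everything the pipeline produced, and
a payload directory of the built artifacts (Parquet tables, SQLite
databases, HDT triple stores, or any other serializable file). Bricks are
versioned by commit, installed into a local library, and may declare data
dependencies on other bricks — so a derived asset such as a harmonized
chemical-activity database has unambiguous, reproducible upstream versions.

## The machinery

- **Content-addressed cache.** Every payload file is identified by the MD5
  of its bytes and stored once at `cache/<2 hex>/<30 hex>`. Two bricks (or
  two versions of one brick) that share a file share one stored object;
  installed payloads are links into the cache. Directory payloads get a
  single digest via a canonical manifest (a minimal JSON array of
  `[path, digest]` pairs, sorted by path), so whole partitioned tables are
  addressable too.
- **Versioned library.** Installed bricks live at
  `<library>/<org>/<name>/<commit>`, so multiple versions coexist and a
  script can pin the exact data it was written against.
- **Four-phase installer.** `install` clones the repository tree,
  enumerates the payload from the lock file, fetches only the objects not
  already cached (verifying each against its digest), and links them into
  place. Re-installs fetch nothing; append-only bricks fetch exactly their
  new files.
- **Incremental pipeline runner.** `run` replays a brick's pipeline the way
  lockfile-driven build systems do: a stage re-executes only when its
  command, dependencies or outputs changed since the lock was written —
  except zero-dependency stages (the "check the primary source" step),
  which run on every build.
- **Chemical-activity harmonizer.** Heterogeneous source tables reduce to
  three linked tables — `substances` (sid + JSON metadata), `properties`
  (pid + metadata) and `activities` (sid, pid, value, SMILES/InChI) —
  with activity values either binary (1 positive / 0 negative) or numeric
  (e.g. an LD50 in mg/kg). A *major property* is one with strictly more
  than 1,000 activities.
- **Offline fixtures.** Seeded generators build local registries, pipeline
  workspaces and chemical source tables, so everything above runs and is
  tested without a network.

## Worked example

```r
library(bricktools)

td  <- tempfile(); dir.create(td)
reg <- file.path(td, "registry")
fixture_registry(reg, seed = 1)          # offline stand-in for a hosted registry

Sys.setenv(BRICKTOOLS_CONFIG = file.path(td, "config.yaml"))
config <- bb_configure(file.path(td, "lib"), registry = reg)

bb_install(config, "hgnc")
#> <install> biobricks-ai/hgnc@7379989d1b74be00765623ac397a6f4e
#>   clone     1
#>   enumerate 3
#>   fetch     3
#>   link      3
#>   fetched 3, already cached 0

bb_install(config, "hgnc")               # warm: everything is cached already
#> ...
#>   fetched 0, already cached 3

bb_assets(config, "hgnc")
#> <assets> biobricks-ai/hgnc @ 7379989d1b74be00765623ac397a6f4e
#>   hgnc_complete_set_parquet -> .../brick/hgnc_complete_set.parquet
#>   hgnc_graph_hdt            -> .../brick/hgnc_graph.hdt
#>   hgnc_index_sqlite         -> .../brick/hgnc_index.sqlite
```

The install report shows the four phases with their item counts: one
repository tree cloned, three payload assets enumerated from the lock file,
three objects fetched into the cache (zero on the second run), three links
materialized. `bb_assets()` maps each payload file to a stable identifier
(path with separators and dots replaced by underscores) so downstream code
can say `arrow::read_parquet(assets[["hgnc_complete_set_parquet"]])`.

Running a pipeline incrementally:

```r
ws <- file.path(td, "smrt")
fx <- fixture_smrt_like(ws, seed = 1)
bb_repro(workspace = ws)$executed        # cold build
#> [1] "status"   "download" "process"
bb_repro(workspace = ws)$executed        # source unchanged
#> [1] "status"
fx$mutate_source(99)
bb_repro(workspace = ws)$executed        # change cascades
#> [1] "status"   "download" "process"
```

Harmonizing two schema-divergent chemical sources:

```r
fx <- fixture_chem_sources(seed = 1)
h  <- harmonize(fx$adapters, fx$sources)
h
#> <harmony set> 4 substance(s), 3 propertie(s), 7 activitie(s)
count_by_source(h)
#>        source activities
#> 1   acute_tox          3
#> 2 assay_calls          4
```

Five raw substances collapse to four because one InChI is shared across the
two sources; the seven activities are conserved exactly and every activity
links to an existing substance and property (`validate_harmony(h)` has zero
findings).

A thin shell front end is installed as `exec/bricktools`
(`configure`, `install`, `assets`, `init`, `add`, `pull`, `run`,
`harmonize`, `fixtures`), with exit code 0 on success, 1 on user error and
2 on integrity/backend failure.

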