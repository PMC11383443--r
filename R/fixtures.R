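#' @title Seeded offline fixtures
#' @description
#' Generators for everything the protocol needs to run without a network:
#' a local registry populated with versioned bricks and a content store, a
#' three-stage extract/download/process pipeline over a mutable mock
#' primary source, and schema-divergent chemical-activity tables for the
#' harmonizer.  Identical seed and parameters yield byte-identical trees,
#' so every test and example is reproducible.
#' @name fixtures
NULL

# evaluate code under a temporary RNG state
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  force(code)
}

seeded_bytes <- function(seed, n = 256L) {
  with_seed(seed, as.raw(sample.int(256L, n, replace = TRUE) - 1L))
}

seeded_parquet_bytes <- function(seed, rows = 20L) {
  df <- with_seed(seed, data.frame(
    id = seq_len(rows),
    symbol = replicate(rows, paste0(sample(LETTERS, 4), collapse = "")),
    value = round(stats::runif(rows), 6)
  ))
  tmp <- tempfile(fileext = ".parquet")
  on.exit(unlink(tmp))
  arrow::write_parquet(df, tmp)
  readBin(tmp, "raw", file.size(tmp))
}

# a small real SQLite database, written with the python stdlib driver when
# python is on the PATH, else a byte payload carrying the SQLite magic
# header (the package manager treats .sqlite payloads as opaque bytes)
seeded_sqlite_bytes <- function(seed, rows = 10L) {
  values <- with_seed(seed, round(stats::runif(rows) * 1000))
  tmp <- tempfile(fileext = ".sqlite")
  on.exit(unlink(tmp))
  python <- Sys.which("python")
  if (nzchar(python)) {
    script <- sprintf(paste0(
      "import sqlite3,sys\n",
      "con=sqlite3.connect(sys.argv[1])\n",
      "con.execute('create table fixture (id integer primary key, value real)')\n",
      "con.executemany('insert into fixture values (?,?)', %s)\n",
      "con.commit(); con.close()\n"),
      paste0("[", paste(sprintf("(%d,%s)", seq_along(values), values),
                        collapse = ","), "]"))
    code <- suppressWarnings(system2(python, c("-", shQuote(tmp)),
                                     input = script,
                                     stdout = FALSE, stderr = FALSE))
    if (code == 0L && file.exists(tmp)) {
      return(readBin(tmp, "raw", file.size(tmp)))
    }
  }
  c(charToRaw("SQLite format 3"), as.raw(0), seeded_bytes(seed, 512L))
}

payload_bytes <- function(type, seed) {
  switch(type,
         parquet = seeded_parquet_bytes(seed),
         sqlite = seeded_sqlite_bytes(seed),
         seeded_bytes(seed, 512L))
}

# content of a fixture payload file is keyed by (seed, relpath, type) only,
# not by brick -- so bricks that declare the same file genuinely share
# bytes, and unchanged files persist across versions (append-only growth)
fixture_file_bytes <- function(seed, relpath, type) {
  payload_bytes(sub("#.*$", "", type),
                derive_seed(seed, paste("content", relpath, type)))
}

store_registry_object <- function(dir, bytes) {
  digest <- hash_bytes(bytes)
  dest <- file.path(dir, "objects", substr(digest, 1, 2), substr(digest, 3, 32))
  if (!file.exists(dest)) {
    dir_create(dirname(dest))
    writeBin(bytes, dest)
  }
  digest
}

# write one brick version into a fixture registry.
# payload: data.frame(relpath, digest) -- objects must already be stored.
registry_put_version <- function(dir, org, name, payload, seq) {
  payload <- payload[order(payload$relpath, method = "radix"), , drop = FALSE]
  manifest <- data.frame(path = payload$relpath, digest = payload$digest,
                         stringsAsFactors = FALSE)
  commit <- hash_bytes(charToRaw(paste0(manifest_json(manifest), "#", seq)))
  tree <- file.path(dir, org, name, commit)
  dir_create(tree)
  outs_yaml <- paste(sprintf("    - %s", payload$relpath), collapse = "\n")
  write_text(paste0(
    "stages:\n",
    "  build:\n",
    "    cmd: 'sh scripts/build.sh'\n",
    "    outs:\n", outs_yaml, "\n"), file.path(tree, "dvc.yaml"))
  lock <- structure(list(stages = list(
    build = list(cmd = "sh scripts/build.sh",
                 deps = empty_path_digests(),
                 outs = data.frame(path = payload$relpath,
                                   md5 = payload$digest,
                                   stringsAsFactors = FALSE))
  )), class = "bb_lock")
  write_text(write_lock(lock), file.path(tree, "dvc.lock"))
  dir_create(file.path(tree, ".bb"))
  write_text("", file.path(tree, ".bb", "dependencies.txt"))
  commits_file <- file.path(dir, org, name, "commits")
  cat(commit, "\n", sep = "", file = commits_file, append = TRUE)
  yaml::write_yaml(list(main = commit), file.path(dir, org, name, "refs"))
  commit
}

default_fixture_bricks <- function() {
  list(list(
    org = "biobricks-ai", name = "hgnc",
    versions = list(c(
      "brick/hgnc_complete_set.parquet" = "parquet",
      "brick/hgnc_index.sqlite" = "sqlite",
      "brick/hgnc_graph.hdt" = "hdt"))
  ))
}

#' Build a local fixture registry
#'
#' Populates an empty directory with the reference registry layout: per
#' brick a `refs` branch map, a `commits` log and one repository tree per
#' version, plus a shared sharded object store holding every distinct
#' payload exactly once.  `main` points at each brick's newest version.
#'
#' @param dir target directory; must be empty (or absent).
#' @param seed integer seed; same seed and spec give byte-identical trees.
#' @param bricks fixture spec: list of `list(org, name, versions)` where
#'   each version is a named character vector mapping payload path to a
#'   content type (`"parquet"`, `"sqlite"`, `"hdt"`, anything else is
#'   opaque bytes; append `#<salt>` to force distinct content).
#' @return The registry directory, invisibly, with a `"commits"` attribute
#'   naming each brick's versions oldest-first.
#' @export
fixture_registry <- function(dir, seed = 1L,
                             bricks = default_fixture_bricks()) {
  if (dir.exists(dir) && length(list.files(dir, all.files = TRUE,
                                           no.. = TRUE)) > 0) {
    bb_stop(sprintf("refusing to build a registry in non-empty '%s'", dir),
            "bb_argument_error")
  }
  dir_create(dir)
  commits <- list()
  for (brick in bricks) {
    for (v in seq_along(brick$versions)) {
      files <- brick$versions[[v]]
      payload <- data.frame(relpath = names(files), digest = NA_character_,
                            stringsAsFactors = FALSE)
      for (i in seq_len(nrow(payload))) {
        bytes <- fixture_file_bytes(seed, payload$relpath[i], files[[i]])
        payload$digest[i] <- store_registry_object(dir, bytes)
      }
      key <- paste(brick$org, brick$name, sep = "/")
      commits[[key]] <- c(commits[[key]],
                          registry_put_version(dir, brick$org, brick$name,
                                               payload, seq = v))
    }
  }
  invisible(structure(dir, commits = commits))
}

#' Append a new version to a fixture brick
#'
#' Emulates an append-only source: the new version keeps every existing
#' payload file and adds `n_new_files` fresh ones, and `main` advances.
#' Installing the new version over the old therefore fetches exactly the
#' new objects.
#'
#' @param dir fixture registry directory.
#' @param org,name brick coordinates.
#' @param n_new_files number of payload files to add (0 gives a new commit
#'   with no new objects).
#' @param seed integer seed for the new file contents.
#' @return The new commit id.
#' @export
fixture_grow_brick <- function(dir, org, name, n_new_files, seed = 1L) {
  backend <- local_registry(dir)
  log <- registry_commits(backend, org, name)
  if (length(log) == 0L) {
    bb_stop(sprintf("brick '%s/%s' not found in registry", org, name),
            "bb_not_found_error")
  }
  head <- log[length(log)]
  lock <- parse_lock(read_text(file.path(dir, org, name, head, "dvc.lock")))
  outs <- lock$stages$build$outs
  payload <- data.frame(relpath = outs$path, digest = outs$md5,
                        stringsAsFactors = FALSE)
  existing_parts <- sum(grepl("^brick/part_", payload$relpath))
  for (k in seq_len(n_new_files)) {
    relpath <- sprintf("brick/part_%03d.parquet", existing_parts + k)
    bytes <- seeded_parquet_bytes(
      derive_seed(seed, paste("grow", org, name, relpath)))
    payload <- rbind(payload, data.frame(
      relpath = relpath, digest = store_registry_object(dir, bytes),
      stringsAsFactors = FALSE))
  }
  registry_put_version(dir, org, name, payload, seq = length(log) + 1L)
}

#' Three-stage pipeline fixture over a mutable mock primary source
#'
#' Creates, in an empty workspace, a mock primary source file
#' (`source/data.csv`), and a `dvc.yaml` with the classic
#' status / download / process shape: *status* has no dependencies (so it
#' runs on every build) and snapshots the source into `status.txt`;
#' *download* depends on `status.txt` and copies it into the `download/`
#' directory; *process* depends on `download/` and emits
#' `brick/smrt_dataset.parquet`.  All three commands are tiny portable
#' shell one-liners.  An unchanged source leaves `status.txt`
#' byte-identical, so a second build runs only the status stage; mutating
#' the source cascades through all three.
#'
#' @param workdir target workspace; must be empty (or absent).
#' @param seed integer seed for the source contents.
#' @return A list with `workdir` and `mutate_source(new_seed)`, a helper
#'   that rewrites the primary source with fresh seeded content.
#' @export
fixture_smrt_like <- function(workdir, seed = 1L) {
  if (dir.exists(workdir) && length(list.files(workdir, all.files = TRUE,
                                               no.. = TRUE)) > 0) {
    bb_stop(sprintf("refusing to build a fixture in non-empty '%s'", workdir),
            "bb_argument_error")
  }
  dir_create(file.path(workdir, "source"))
  write_source <- function(s) {
    df <- with_seed(derive_seed(s, "smrt-source"), data.frame(
      molecule = sprintf("M%04d", sample.int(9999L, 25L)),
      retention_time = round(stats::runif(25L, 1, 30), 3)
    ))
    utils::write.csv(df, file.path(workdir, "source", "data.csv"),
                     row.names = FALSE)
  }
  write_source(seed)
  write_text(paste0(
    "stages:\n",
    "  status:\n",
    "    cmd: 'cp source/data.csv status.txt'\n",
    "    outs:\n",
    "    - status.txt\n",
    "  download:\n",
    "    cmd: 'mkdir -p download && cp status.txt download/raw.csv'\n",
    "    deps:\n",
    "    - status.txt\n",
    "    outs:\n",
    "    - ./download\n",
    "  process:\n",
    "    cmd: 'mkdir -p brick && cp download/raw.csv brick/smrt_dataset.parquet'\n",
    "    deps:\n",
    "    - ./download\n",
    "    outs:\n",
    "    - brick/smrt_dataset.parquet\n"),
    file.path(workdir, "dvc.yaml"))
  list(workdir = workdir,
       mutate_source = function(new_seed) write_source(new_seed))
}

## ---- chemical source fixtures -------------------------------------------

#' Toy adapters for the two fixture source schemas
#'
#' `chem_outcome_adapter()` reads an assay-call table (columns `compound`,
#' `inchi`, `assay`, `call` with values `"positive"`/`"negative"`) and
#' encodes calls as binary activities (positive = 1, negative = 0).
#' `chem_ld50_adapter()` reads an acute-toxicity table (columns `chem_id`,
#' `inchi_code`, `endpoint`, `dose_mg_kg`, `smiles`) and emits numeric
#' activities.
#'
#' @param name source name.
#' @return A [source_adapter()].
#' @export
chem_outcome_adapter <- function(name = "assay_calls") {
  source_adapter(name, function(raw) {
    subs <- raw[!duplicated(raw$compound),
                c("compound", "inchi"), drop = FALSE]
    props <- unique(raw$assay)
    list(
      substances = data.frame(
        local_id = subs$compound, inchi = subs$inchi,
        metadata = I(lapply(subs$compound, function(s) list(name = s))),
        stringsAsFactors = FALSE),
      properties = data.frame(
        local_id = props,
        metadata = I(lapply(props, function(p)
          list(assay = p, readout = "binary call"))),
        stringsAsFactors = FALSE),
      activities = data.frame(
        substance = raw$compound, property = raw$assay,
        value = ifelse(raw$call == "positive", 1, 0),
        value_type = "binary", inchi = raw$inchi,
        smiles = NA_character_, stringsAsFactors = FALSE)
    )
  })
}

#' @rdname chem_outcome_adapter
#' @export
chem_ld50_adapter <- function(name = "acute_tox") {
  source_adapter(name, function(raw) {
    subs <- raw[!duplicated(raw$chem_id),
                c("chem_id", "inchi_code", "smiles"), drop = FALSE]
    props <- unique(raw$endpoint)
    list(
      substances = data.frame(
        local_id = subs$chem_id, inchi = subs$inchi_code,
        metadata = I(lapply(seq_len(nrow(subs)), function(i)
          list(chem_id = subs$chem_id[i], smiles = subs$smiles[i]))),
        stringsAsFactors = FALSE),
      properties = data.frame(
        local_id = props,
        metadata = I(lapply(props, function(p)
          list(endpoint = p, unit = "mg/kg"))),
        stringsAsFactors = FALSE),
      activities = data.frame(
        substance = raw$chem_id, property = raw$endpoint,
        value = raw$dose_mg_kg, value_type = "numeric",
        inchi = raw$inchi_code, smiles = raw$smiles,
        stringsAsFactors = FALSE)
    )
  })
}

fake_inchi <- function(i) {
  sprintf("InChI=1S/C%dH%d/fixture%03d", 3 + i %% 7, 6 + i %% 9, i)
}

#' Schema-divergent chemical source tables with known harmonized counts
#'
#' Generates two raw tables -- an assay-call source with word outcomes and
#' an acute-toxicity source with numeric LD50-style doses -- whose column
#' names share nothing, plus the adapters that harmonize them.
#' `shared_inchi` substances of the second source reuse InChIs from the
#' first, so the expected substance count after structure-based
#' deduplication is known by construction; the expected property and
#' activity counts are plain sums.
#'
#' @param seed integer seed.
#' @param sizes list of two integer triples `(substances, properties,
#'   activities)`, one per source.
#' @param shared_inchi how many substances of source two reuse an InChI
#'   from source one.
#' @return A list with `sources` (named raw tables), `adapters`, and
#'   `expected` counts (`substances`, `properties`, `activities`,
#'   `by_source`).
#' @export
fixture_chem_sources <- function(seed = 1L,
                                 sizes = list(c(3L, 2L, 4L), c(2L, 1L, 3L)),
                                 shared_inchi = 1L) {
  stopifnot(length(sizes) == 2L, all(unlist(sizes) > 0L),
            shared_inchi <= min(sizes[[1]][1], sizes[[2]][1]))
  n1 <- sizes[[1]]; n2 <- sizes[[2]]
  # every substance and property must appear in at least one activity row,
  # since the adapters enumerate them from the raw table
  stopifnot(n1[3] >= max(n1[1], n1[2]), n2[3] >= max(n2[1], n2[2]))
  cover_idx <- function(n_items, n_rows) {
    c(seq_len(n_items), sample.int(n_items, n_rows - n_items,
                                   replace = TRUE))[seq_len(n_rows)]
  }
  compounds <- sprintf("CMP-%02d", seq_len(n1[1]))
  inchi1 <- vapply(seq_len(n1[1]), fake_inchi, "")
  assays <- paste0("assay_", utils::head(letters, n1[2]))
  src1 <- with_seed(derive_seed(seed, "chem-src-1"), {
    idx_s <- cover_idx(n1[1], n1[3])
    idx_p <- cover_idx(n1[2], n1[3])
    data.frame(
      compound = compounds[idx_s],
      inchi = inchi1[idx_s],
      assay = assays[idx_p],
      call = sample(c("positive", "negative"), n1[3], replace = TRUE),
      stringsAsFactors = FALSE)
  })
  chems <- sprintf("TOX:%03d", seq_len(n2[1]))
  inchi2 <- c(utils::head(inchi1, shared_inchi),
              vapply(100L + seq_len(n2[1] - shared_inchi), fake_inchi, ""))
  endpoints <- sprintf("LD50_oral_rat_%d", seq_len(n2[2]))
  src2 <- with_seed(derive_seed(seed, "chem-src-2"), {
    idx_s <- cover_idx(n2[1], n2[3])
    idx_p <- cover_idx(n2[2], n2[3])
    data.frame(
      chem_id = chems[idx_s],
      inchi_code = inchi2[idx_s],
      endpoint = endpoints[idx_p],
      dose_mg_kg = round(stats::rlnorm(n2[3], meanlog = 5), 2),
      smiles = sprintf("C%dCO", idx_s),
      stringsAsFactors = FALSE)
  })
  adapters <- list(chem_outcome_adapter("assay_calls"),
                   chem_ld50_adapter("acute_tox"))
  list(
    sources = list(assay_calls = src1, acute_tox = src2),
    adapters = adapters,
    expected = list(
      substances = n1[1] + n2[1] - shared_inchi,
      properties = n1[2] + n2[2],
      activities = n1[3] + n2[3],
      by_source = c(assay_calls = n1[3], acute_tox = n2[3])
    )
  )
}
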