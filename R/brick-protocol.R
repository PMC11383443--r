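#' @title The brick repository anatomy
#' @description
#' A brick is a repository with user code, a `dvc.yaml` pipeline file, a
#' `dvc.lock` hash ledger, an optional `.bb/` directory holding
#' `dependencies.txt`, and a `brick/` payload directory of built data files
#' (Parquet, SQLite, HDT, or any other serializable format, carried as
#' opaque bytes).  This file implements the parsers, writers and validators
#' for that anatomy.
#' @name brick-protocol
NULL

pipeline_allowed_keys <- c("cmd", "deps", "outs", "frozen")

as_path_vector <- function(x, stage, field) {
  if (is.null(x)) return(character(0))
  if (!is.list(x) && !is.character(x)) {
    bb_stop(sprintf("stage '%s': %s must be a list of paths", stage, field),
            "bb_schema_error")
  }
  out <- vapply(as.list(x), function(p) {
    if (!is.character(p) || length(p) != 1L || !nzchar(p)) {
      bb_stop(sprintf("stage '%s': %s entries must be non-empty strings",
                      stage, field), "bb_schema_error")
    }
    p
  }, "")
  unname(out)
}

#' Parse a pipeline file
#'
#' The accepted dialect is a strict subset of the DVC `dvc.yaml` schema: a
#' top-level `stages` mapping where each stage has a required `cmd` string
#' and optional `deps` / `outs` path lists (plus an optional `frozen` flag
#' that disables the always-run rule for zero-dependency stages).  Any other
#' per-stage key (`wdir`, `params`, `metrics`, `plots`, `foreach`, ...) is
#' rejected as unsupported.
#'
#' @param text pipeline file contents.
#' @return A `bb_pipeline` object: list of stage definitions in declaration
#'   order, each with `name`, `cmd`, `deps`, `outs`, `frozen`.
#' @export
parse_pipeline <- function(text) {
  doc <- tryCatch(yaml::yaml.load(text),
                  error = function(e) bb_stop(
                    paste0("pipeline file is not well-formed YAML: ",
                           conditionMessage(e)), "bb_parse_error"))
  if (!is.list(doc) || !("stages" %in% names(doc))) {
    bb_stop("pipeline file must have a top-level 'stages' mapping",
            "bb_schema_error")
  }
  stages <- doc$stages
  if (is.null(stages)) stages <- list()
  nm <- names(stages)
  if (length(stages) > 0 && (is.null(nm) || any(!nzchar(nm)))) {
    bb_stop("every stage must be named", "bb_schema_error")
  }
  if (anyDuplicated(nm)) {
    bb_stop(sprintf("duplicate stage name '%s'", nm[duplicated(nm)][1]),
            "bb_schema_error")
  }
  defs <- vector("list", length(stages))
  for (i in seq_along(stages)) {
    s <- stages[[i]]
    name <- nm[i]
    extra <- setdiff(names(s), pipeline_allowed_keys)
    if (length(extra) > 0) {
      bb_stop(sprintf("stage '%s': unsupported key '%s'", name, extra[1]),
              "bb_schema_error")
    }
    if (!is.character(s$cmd) || length(s$cmd) != 1L || !nzchar(s$cmd)) {
      bb_stop(sprintf("stage '%s': missing cmd", name), "bb_schema_error")
    }
    deps <- as_path_vector(s$deps, name, "deps")
    outs <- as_path_vector(s$outs, name, "outs")
    if (length(outs) == 0L) {
      bb_stop(sprintf("stage '%s': outs must be non-empty", name),
              "bb_schema_error")
    }
    both <- intersect(normalize_relpath(deps), normalize_relpath(outs))
    if (length(both) > 0) {
      bb_stop(sprintf("stage '%s': path '%s' is both a dep and an out",
                      name, both[1]), "bb_schema_error")
    }
    defs[[i]] <- list(name = name, cmd = s$cmd, deps = deps, outs = outs,
                      frozen = isTRUE(s$frozen))
  }
  all_outs <- normalize_relpath(unlist(lapply(defs, `[[`, "outs")))
  if (anyDuplicated(all_outs)) {
    dup <- all_outs[duplicated(all_outs)][1]
    owners <- nm[vapply(defs, function(d)
      dup %in% normalize_relpath(d$outs), NA)]
    bb_stop(sprintf("output '%s' is declared by more than one stage (%s)",
                    dup, paste(owners, collapse = ", ")), "bb_schema_error")
  }
  structure(list(stages = defs), class = "bb_pipeline")
}

#' @export
print.bb_pipeline <- function(x, ...) {
  cat(sprintf("<bb_pipeline> %d stage(s)\n", length(x$stages)))
  for (s in x$stages) {
    cat(sprintf("  %s: %d dep(s) -> %d out(s)\n",
                s$name, length(s$deps), length(s$outs)))
  }
  invisible(x)
}

empty_path_digests <- function() {
  data.frame(path = character(0), md5 = character(0), stringsAsFactors = FALSE)
}

as_path_digests <- function(x, stage, field) {
  if (is.null(x) || length(x) == 0L) return(empty_path_digests())
  rows <- lapply(x, function(e) {
    if (!is.list(e) || is.null(e$path) || is.null(e$md5)) {
      bb_stop(sprintf("lock stage '%s': %s entries need 'path' and 'md5'",
                      stage, field), "bb_schema_error")
    }
    if (!is_hex_digest(as.character(e$md5))) {
      bb_stop(sprintf(
        "lock stage '%s': malformed digest '%s' for path '%s'",
        stage, e$md5, e$path), "bb_schema_error")
    }
    data.frame(path = as.character(e$path), md5 = as.character(e$md5),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$path, method = "radix"), , drop = FALSE]
}

#' Parse and write lock files
#'
#' The lock file is the hash ledger of a brick: per stage it records the
#' command plus the MD5 of every dependency and output at the time the
#' stage last ran.  `write_lock()` always emits the canonical form: stages
#' sorted by name, paths sorted within each stage, every scalar
#' single-quoted, so that `write_lock(parse_lock(text))` is byte-identical
#' for any equivalent input and the file diffs cleanly under version
#' control.
#'
#' @param text lock file contents.
#' @return `parse_lock()`: a `bb_lock` object (named list of per-stage
#'   records with `cmd`, `deps`, `outs` path/digest tables).
#'   `write_lock()`: a single string in canonical form.
#' @export
parse_lock <- function(text) {
  doc <- tryCatch(yaml::yaml.load(text),
                  error = function(e) bb_stop(
                    paste0("lock file is not well-formed YAML: ",
                           conditionMessage(e)), "bb_parse_error"))
  stages <- doc$stages %||% list()
  nm <- names(stages)
  if (length(stages) > 0 && anyDuplicated(nm)) {
    bb_stop("duplicate stage in lock file", "bb_schema_error")
  }
  recs <- lapply(seq_along(stages), function(i) {
    s <- stages[[i]]
    if (!is.character(s$cmd) || length(s$cmd) != 1L) {
      bb_stop(sprintf("lock stage '%s': missing cmd", nm[i]),
              "bb_schema_error")
    }
    list(cmd = s$cmd,
         deps = as_path_digests(s$deps, nm[i], "deps"),
         outs = as_path_digests(s$outs, nm[i], "outs"))
  })
  names(recs) <- nm
  recs <- recs[sort_c(nm)]
  structure(list(stages = recs), class = "bb_lock")
}

empty_lock <- function() structure(list(stages = list()), class = "bb_lock")

yaml_squote <- function(x) paste0("'", gsub("'", "''", x), "'")

#' @rdname parse_lock
#' @param lock a `bb_lock` object.
#' @export
write_lock <- function(lock) {
  stopifnot(inherits(lock, "bb_lock"))
  lines <- c("schema: '2.0'")
  if (length(lock$stages) == 0L) {
    lines <- c(lines, "stages: {}")
    return(paste0(paste(lines, collapse = "\n"), "\n"))
  }
  lines <- c(lines, "stages:")
  for (name in sort_c(names(lock$stages))) {
    if (!is_identifier(name)) {
      bb_stop(sprintf("stage name '%s' is not an identifier", name),
              "bb_schema_error")
    }
    s <- lock$stages[[name]]
    lines <- c(lines, sprintf("  %s:", name),
               sprintf("    cmd: %s", yaml_squote(s$cmd)))
    for (field in c("deps", "outs")) {
      tab <- s[[field]]
      if (is.null(tab) || nrow(tab) == 0L) next
      tab <- tab[order(tab$path, method = "radix"), , drop = FALSE]
      lines <- c(lines, sprintf("    %s:", field))
      for (i in seq_len(nrow(tab))) {
        lines <- c(lines,
                   sprintf("    - path: %s", yaml_squote(tab$path[i])),
                   sprintf("      md5: %s", yaml_squote(tab$md5[i])))
      }
    }
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

read_lock_file <- function(path) {
  if (!file.exists(path)) return(empty_lock())
  parse_lock(read_text(path))
}

#' Asset identifier for a payload path
#'
#' Payload files under `brick/` are addressed by identifiers derived from
#' their relative path: every character that is not a letter, digit or
#' underscore (separators and the extension dot included) becomes an
#' underscore, and a leading underscore is added when the path starts with
#' a digit.  `hgnc_complete_set.parquet` becomes
#' `hgnc_complete_set_parquet`.
#'
#' @param relpath path of a payload file relative to the `brick/` directory.
#' @return An identifier string.
#' @export
asset_identifier <- function(relpath) {
  id <- gsub("[^A-Za-z0-9_]", "_", relpath)
  ifelse(grepl("^[A-Za-z_]", id), id, paste0("_", id))
}

format_tag_for <- function(relpath) {
  ext <- tolower(tools::file_ext(relpath))
  if (ext %in% c("parquet", "sqlite", "hdt")) ext else "opaque"
}

#' Enumerate the payload assets of a brick
#'
#' When the brick has a lock file its `brick/`-prefixed outputs are
#' authoritative (they carry recorded digests); otherwise the payload
#' directory is listed and digests are computed on the spot.  Identifier
#' collisions (two paths normalising to the same identifier) are an error.
#'
#' @param brick_dir root of a brick repository.
#' @param lock optional `bb_lock`; read from `dvc.lock` when present and
#'   not supplied.
#' @return A data frame with `relpath` (relative to the repo root),
#'   `identifier`, `digest`, `format_tag`.
#' @export
enumerate_assets <- function(brick_dir, lock = NULL) {
  if (is.null(lock)) lock <- read_lock_file(file.path(brick_dir, "dvc.lock"))
  paths <- character(0); digests <- character(0)
  if (length(lock$stages) > 0) {
    for (s in lock$stages) {
      outs <- s$outs
      keep <- grepl("^(\\./)?brick/", outs$path)
      paths <- c(paths, normalize_relpath(outs$path[keep]))
      digests <- c(digests, outs$md5[keep])
    }
  }
  if (length(paths) == 0L) {
    payload <- file.path(brick_dir, "brick")
    if (dir.exists(payload)) {
      rel <- list.files(payload, recursive = TRUE)
      rel <- rel[!dir.exists(file.path(payload, rel))]
      paths <- file.path("brick", sort_c(rel))
      digests <- vapply(paths, function(p) hash_file(file.path(brick_dir, p)), "")
    }
  }
  ord <- order(paths, method = "radix")
  paths <- paths[ord]; digests <- unname(digests)[ord]
  rel_to_payload <- sub("^brick/", "", paths)
  ids <- asset_identifier(rel_to_payload)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    clash <- paths[ids == dup]
    bb_stop(sprintf("asset identifier collision: '%s' from paths %s",
                    dup, paste(sQuote(clash), collapse = " and ")),
            "bb_collision_error")
  }
  data.frame(relpath = paths, identifier = ids, digest = digests,
             format_tag = vapply(rel_to_payload, format_tag_for, ""),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Parse and format the dependencies file
#'
#' `.bb/dependencies.txt` records one direct data dependency per line as
#' `<org>/<name> <commit>` (or `<git-url> <commit>`); blank lines and lines
#' starting with `#` are ignored.  Order is preserved, the round trip is
#' stable, and a brick may depend on a given org/name at most once.
#'
#' @param text dependencies file contents.
#' @return `parse_dependencies()`: a `bb_dependency_list` (data frame of
#'   `organization`, `name`, `commit`, `url`). `format_dependencies()`: the
#'   file text.
#' @export
parse_dependencies <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  rows <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    fields <- strsplit(line, "[[:space:]]+")[[1]]
    if (length(fields) != 2L) {
      bb_stop(sprintf("dependencies line %d: expected '<ref> <commit>', got %d field(s)",
                      i, length(fields)), "bb_parse_error")
    }
    ref <- parse_brick_spec(fields[1])
    commit <- fields[2]
    if (!grepl("^[0-9a-f]{5,40}$", commit)) {
      bb_stop(sprintf("dependencies line %d: malformed commit '%s'", i, commit),
              "bb_parse_error")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      organization = ref$organization, name = ref$name, commit = commit,
      url = ref$url %||% NA_character_, stringsAsFactors = FALSE)
  }
  entries <- if (length(rows) == 0L) {
    data.frame(organization = character(0), name = character(0),
               commit = character(0), url = character(0),
               stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  key <- paste(entries$organization, entries$name, sep = "/")
  if (anyDuplicated(key)) {
    bb_stop(sprintf("duplicate dependency on '%s'", key[duplicated(key)][1]),
            "bb_duplicate_dependency_error")
  }
  structure(list(entries = entries), class = "bb_dependency_list")
}

#' @rdname parse_dependencies
#' @param deps a `bb_dependency_list`.
#' @export
format_dependencies <- function(deps) {
  stopifnot(inherits(deps, "bb_dependency_list"))
  e <- deps$entries
  if (nrow(e) == 0L) return("")
  spec <- ifelse(is.na(e$url), paste(e$organization, e$name, sep = "/"), e$url)
  paste0(paste(spec, e$commit, collapse = "\n"), "\n")
}

# "name", "org/name", or a git URL -> list(organization, name, url)
parse_brick_spec <- function(spec, default_org = "biobricks-ai") {
  if (grepl("^[a-z]+://", spec) || grepl("^git@", spec)) {
    stripped <- sub("^[a-z]+://", "", spec)
    stripped <- sub("^git@[^:]+:", "", stripped)
    stripped <- sub("\\.git$", "", stripped)
    parts <- strsplit(stripped, "/", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) < 2L) {
      bb_stop(sprintf("cannot parse brick URL '%s'", spec), "bb_parse_error")
    }
    n <- length(parts)
    return(list(organization = parts[n - 1L], name = parts[n], url = spec))
  }
  parts <- strsplit(spec, "/", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 1L) {
    list(organization = default_org, name = parts[1], url = NULL)
  } else if (length(parts) == 2L) {
    list(organization = parts[1], name = parts[2], url = NULL)
  } else {
    bb_stop(sprintf("cannot parse brick spec '%s'", spec), "bb_parse_error")
  }
}

#' Validate the shape of a brick repository
#'
#' Reports the presence of the pipeline file, lock file, payload directory
#' and `.bb/` directory, and checks that every lock stage exists in the
#' pipeline.  The `.bb/` directory is optional, so its absence is recorded
#' but does not fail validation.
#'
#' @param repo_dir root of a brick repository.
#' @return A `bb_validation` report: data frame of `check`, `ok`,
#'   `required`, `detail`, with an `ok` attribute summarising the required
#'   checks.
#' @export
validate_brick <- function(repo_dir) {
  if (!dir.exists(repo_dir)) {
    bb_stop(sprintf("no such directory: '%s'", repo_dir), "bb_not_found_error")
  }
  checks <- list()
  add <- function(check, ok, required, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, ok = ok, required = required, detail = detail,
      stringsAsFactors = FALSE)
  }
  has_pipeline <- file.exists(file.path(repo_dir, "dvc.yaml"))
  has_lock <- file.exists(file.path(repo_dir, "dvc.lock"))
  has_payload <- dir.exists(file.path(repo_dir, "brick"))
  has_bb <- dir.exists(file.path(repo_dir, ".bb"))
  add("pipeline file (dvc.yaml)", has_pipeline, TRUE,
      if (has_pipeline) "" else "pipeline file missing")
  add("lock file (dvc.lock)", has_lock, TRUE,
      if (has_lock) "" else "lock file missing")
  add("payload directory (brick/)", has_payload, TRUE,
      if (has_payload) "" else "payload directory missing")
  add("dependency directory (.bb/)", has_bb, FALSE,
      if (has_bb) "" else ".bb directory absent (optional)")
  if (has_pipeline && has_lock) {
    consistent <- TRUE; detail <- ""
    res <- tryCatch({
      spec <- parse_pipeline(read_text(file.path(repo_dir, "dvc.yaml")))
      lock <- parse_lock(read_text(file.path(repo_dir, "dvc.lock")))
      missing <- setdiff(names(lock$stages),
                         vapply(spec$stages, `[[`, "", "name"))
      if (length(missing) > 0) {
        consistent <- FALSE
        detail <- sprintf("lock stage(s) absent from pipeline: %s",
                          paste(missing, collapse = ", "))
      }
      NULL
    }, bb_error = function(e) conditionMessage(e))
    if (!is.null(res)) { consistent <- FALSE; detail <- res }
    add("lock/pipeline consistency", consistent, TRUE, detail)
  }
  report <- do.call(rbind, checks)
  structure(report, ok = all(report$ok[report$required]),
            class = c("bb_validation", class(report)))
}

#' @export
print.bb_validation <- function(x, ...) {
  cat(sprintf("<bb_validation> %s\n",
              if (isTRUE(attr(x, "ok"))) "valid brick" else "findings present"))
  for (i in seq_len(nrow(x))) {
    mark <- if (x$ok[i]) "ok " else if (x$required[i]) "FAIL" else "note"
    cat(sprintf("  [%s] %s%s\n", mark, x$check[i],
                if (nzchar(x$detail[i])) paste0(" - ", x$detail[i]) else ""))
  }
  invisible(x)
}

# quick structural check used by list_installed / install warm-skip
looks_like_brick <- function(dir) {
  file.exists(file.path(dir, "dvc.lock")) &&
    file.exists(file.path(dir, "dvc.yaml"))
}
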