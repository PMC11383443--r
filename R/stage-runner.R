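#' @title Incremental lockfile-driven pipeline execution
#' @description
#' Reproduces the build semantics bricks rely on: stages are visited in
#' dependency order and a stage runs only when it is stale -- no lock
#' entry yet, its command changed, a dependency or output hash moved, or it
#' declares no dependencies at all (such stages, typically the
#' check-the-primary-source step, run on every build).  After each
#' successful run the stage's lock entry is rewritten with fresh digests,
#' so an immediately repeated build of a fully dependency-tracked pipeline
#' executes nothing.
#' @name stage-runner
NULL

# do two normalized workspace paths denote the same file or nest?
paths_overlap <- function(a, b) {
  a == b | startsWith(b, paste0(a, "/")) | startsWith(a, paste0(b, "/"))
}

#' Topological stage order of a pipeline
#'
#' There is an edge from stage A to stage B when some output of A equals,
#' contains, or is contained by some dependency of B (prefix matching links
#' a directory output like `./download` to file dependencies beneath it).
#' The order is deterministic: among ready stages the lexicographically
#' smallest name goes first.
#'
#' @param spec a `bb_pipeline`.
#' @return Character vector of stage names in execution order.
#' @export
build_dag <- function(spec) {
  stopifnot(inherits(spec, "bb_pipeline"))
  names_ <- vapply(spec$stages, `[[`, "", "name")
  outs <- lapply(spec$stages, function(s) normalize_relpath(s$outs))
  deps <- lapply(spec$stages, function(s) normalize_relpath(s$deps))
  n <- length(names_)
  edges <- matrix(FALSE, n, n, dimnames = list(names_, names_))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      for (o in outs[[a]]) {
        if (any(paths_overlap(o, deps[[b]]))) {
          edges[a, b] <- TRUE
          break
        }
      }
    }
  }
  indeg <- colSums(edges)
  order_out <- character(0)
  remaining <- names_
  while (length(remaining) > 0) {
    ready <- remaining[indeg[remaining] == 0]
    if (length(ready) == 0) {
      bb_stop(sprintf("dependency cycle among stages: %s",
                      paste(sort_c(remaining), collapse = ", ")),
              "bb_cycle_error")
    }
    nxt <- sort_c(ready)[1]
    order_out <- c(order_out, nxt)
    remaining <- setdiff(remaining, nxt)
    indeg <- indeg - edges[nxt, ]
  }
  structure(order_out, edges = edges)
}

# digest of a workspace path: file hash, tree digest for directories,
# NA when absent
path_digest <- function(workspace, relpath) {
  p <- file.path(workspace, relpath)
  if (dir.exists(p)) {
    hash_tree(p)$digest
  } else if (file.exists(p)) {
    hash_file(p)
  } else {
    NA_character_
  }
}

#' Freshness of one stage against the lock
#'
#' A stage is stale when it declares no dependencies (always rebuilt unless
#' marked `frozen`), has no lock entry, its command changed, any
#' dependency's current digest differs from the recorded one (or the
#' dependency is missing), or any output is missing or changed.  The reason
#' reported is the first that applies, in that order.
#'
#' @param stage a stage definition from [parse_pipeline()].
#' @param lock a `bb_lock`.
#' @param workspace workspace root.
#' @return A list with `name`, `state` (`"fresh"`/`"stale"`), `reason`.
#' @export
stage_status <- function(stage, lock, workspace) {
  status <- function(state, reason = NA_character_) {
    list(name = stage$name, state = state, reason = reason)
  }
  if (length(stage$deps) == 0L && !isTRUE(stage$frozen)) {
    return(status("stale", "zero-dep-always"))
  }
  entry <- lock$stages[[stage$name]]
  if (is.null(entry)) return(status("stale", "no-lock-entry"))
  if (!identical(entry$cmd, stage$cmd)) return(status("stale", "cmd-changed"))
  recorded <- stats::setNames(entry$deps$md5, normalize_relpath(entry$deps$path))
  for (dep in normalize_relpath(stage$deps)) {
    current <- path_digest(workspace, dep)
    if (is.na(current) || !identical(unname(recorded[dep]), current)) {
      return(status("stale", "dep-changed"))
    }
  }
  recorded_outs <- stats::setNames(entry$outs$md5,
                                   normalize_relpath(entry$outs$path))
  for (out in normalize_relpath(stage$outs)) {
    current <- path_digest(workspace, out)
    if (is.na(current)) return(status("stale", "out-missing"))
    if (!identical(unname(recorded_outs[out]), current)) {
      return(status("stale", "out-changed"))
    }
  }
  status("fresh")
}

run_stage_command <- function(cmd, workspace) {
  old <- setwd(workspace)
  on.exit(setwd(old))
  suppressWarnings(system2(
    "sh", c("-c", shQuote(cmd)),
    env = paste0("BB_WORKSPACE=", shQuote(workspace)),
    stdout = FALSE, stderr = FALSE))
}

lock_entry_for <- function(stage, workspace) {
  digest_table <- function(paths) {
    paths <- normalize_relpath(paths)
    if (length(paths) == 0L) return(empty_path_digests())
    md5 <- vapply(paths, function(p) {
      d <- path_digest(workspace, p)
      if (is.na(d)) {
        bb_stop(sprintf("stage '%s' did not produce declared path '%s'",
                        stage$name, p), "bb_io_error")
      }
      d
    }, "")
    out <- data.frame(path = paths, md5 = unname(md5),
                      stringsAsFactors = FALSE)
    out[order(out$path, method = "radix"), , drop = FALSE]
  }
  list(cmd = stage$cmd,
       deps = digest_table(stage$deps),
       outs = digest_table(stage$outs))
}

#' Reproduce a pipeline incrementally
#'
#' Visits stages in DAG order; each stage's status is recomputed at visit
#' time (so a rerun upstream stage that regenerates byte-identical output
#' does not trigger downstream work) and the stage runs only if stale.  A
#' successful run rewrites that stage's lock entry with fresh digests of
#' its command, dependencies and outputs; a failing command leaves the lock
#' entry untouched and all transitive dependents are skipped for the rest
#' of the run.  The updated lock is written back to `dvc.lock` in canonical
#' form.
#'
#' @param spec a `bb_pipeline` (read from `workspace/dvc.yaml` by default).
#' @param workspace workspace root where commands run (the shell inherits
#'   the environment plus `BB_WORKSPACE`).
#' @param lock starting `bb_lock` (read from `workspace/dvc.lock` by
#'   default; absent file means an empty lock).
#' @param dry_run only report planned statuses, execute nothing and leave
#'   the lock alone.
#' @return A `bb_run_report`: `executed`, `skipped`, `failed`, `blocked`
#'   stage names, per-stage `status` (exit codes), `reasons`, and the
#'   updated `lock`.
#' @export
bb_repro <- function(spec = NULL, workspace = ".", lock = NULL,
                     dry_run = FALSE) {
  workspace <- normalizePath(workspace)
  if (is.null(spec)) {
    pf <- file.path(workspace, "dvc.yaml")
    if (!file.exists(pf)) {
      bb_stop(sprintf("no pipeline file at '%s'", pf), "bb_not_found_error")
    }
    spec <- parse_pipeline(read_text(pf))
  }
  if (is.null(lock)) lock <- read_lock_file(file.path(workspace, "dvc.lock"))
  order_ <- build_dag(spec)
  edges <- attr(order_, "edges")
  stages <- stats::setNames(spec$stages,
                            vapply(spec$stages, `[[`, "", "name"))
  executed <- character(0); skipped <- character(0)
  failed <- character(0); blocked <- character(0)
  exit_status <- stats::setNames(integer(0), character(0))
  reasons <- stats::setNames(character(0), character(0))
  for (name in order_) {
    upstream_failed <- any(vapply(c(failed, blocked), function(f)
      isTRUE(edges[f, name]), NA))
    if (isTRUE(upstream_failed)) {
      blocked <- c(blocked, name)
      reasons[name] <- "upstream-failed"
      next
    }
    st <- stage_status(stages[[name]], lock, workspace)
    reasons[name] <- st$reason %||% NA_character_
    if (st$state == "fresh") {
      skipped <- c(skipped, name)
      next
    }
    if (dry_run) {
      executed <- c(executed, name)
      next
    }
    code <- run_stage_command(stages[[name]]$cmd, workspace)
    exit_status[name] <- code
    if (code != 0L) {
      failed <- c(failed, name)
      next
    }
    executed <- c(executed, name)
    lock$stages[[name]] <- lock_entry_for(stages[[name]], workspace)
  }
  if (!dry_run) {
    lock$stages <- lock$stages[sort_c(names(lock$stages))]
    write_text(write_lock(lock), file.path(workspace, "dvc.lock"))
  }
  structure(list(
    executed = executed, skipped = skipped, failed = failed,
    blocked = blocked, status = exit_status, reasons = reasons,
    lock = lock, dry_run = dry_run
  ), class = "bb_run_report")
}

#' @export
print.bb_run_report <- function(x, ...) {
  cat(sprintf("<run%s> executed: %s\n",
              if (x$dry_run) " (dry)" else "",
              if (length(x$executed)) paste(x$executed, collapse = ", ")
              else "<none>"))
  if (length(x$skipped)) {
    cat("  fresh  :", paste(x$skipped, collapse = ", "), "\n")
  }
  if (length(x$failed)) {
    cat("  failed :", paste(x$failed, collapse = ", "), "\n")
  }
  if (length(x$blocked)) {
    cat("  blocked:", paste(x$blocked, collapse = ", "), "\n")
  }
  invisible(x)
}
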