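#' @title Installing bricks and accessing their assets
#' @description
#' The package-manager surface: `bb_install()` runs the four-phase install
#' (clone the repository tree, enumerate the payload assets, fetch the
#' objects not already cached, link them into the payload directory);
#' `bb_assets()` exposes the installed payload as an identifier-to-path
#' namespace; `bb_init()` / `bb_add()` / `bb_pull()` manage a brick's own
#' data dependencies.
#' @name installer
NULL

#' Install a brick version into the library
#'
#' Four phases, in order: *clone* the repository tree to
#' `<library>/<org>/<name>/<commit>`, *enumerate* the payload assets from
#' the lock file, *fetch* every asset object whose digest is not yet in the
#' cache (verifying each fetched object against its digest), and *link* all
#' assets from the cache into the brick's payload directory.  Objects
#' already cached are never re-fetched, so re-installing is cheap and
#' append-only bricks transfer only their new files.  If anything fails
#' after a partial fetch, the cache keeps what was fetched but the
#' repository directory is removed, so a retry resumes cleanly.
#'
#' @param config a `bb_config`.
#' @param spec brick name, `org/name`, or URL.
#' @param commit optional commit id or prefix.
#' @param backend registry backend (from the config by default).
#' @return A `bb_install_report`: the resolved `ref`, a `phases` table of
#'   (phase, count), and `fetched` / `skipped_cached` object counts.
#' @export
bb_install <- function(config, spec, commit = NULL,
                       backend = config_backend(config)) {
  ref <- bb_resolve(config, spec, commit, backend = backend)
  dest <- bb_local_path(config, ref)
  cache <- config_cache(config)
  fresh_clone <- !looks_like_brick(dest)
  tryCatch({
      if (fresh_clone) registry_fetch_tree(backend, ref, dest)
      assets <- enumerate_assets(dest)
      fetched <- 0L; skipped <- 0L
      for (i in seq_len(nrow(assets))) {
        digest <- assets$digest[i]
        if (cache_has(cache, digest)) {
          skipped <- skipped + 1L
          next
        }
        tmp <- tempfile("bbfetch")
        on.exit(unlink(tmp), add = TRUE)
        registry_fetch_object(backend, digest, tmp)
        actual <- hash_file(tmp)
        if (!identical(actual, digest)) {
          bb_stop(sprintf(
            "integrity failure fetching asset '%s' of %s: expected %s, got %s",
            assets$relpath[i], format(ref), digest, actual),
            "bb_integrity_error")
        }
        cache_store(cache, tmp)
        fetched <- fetched + 1L
      }
      for (i in seq_len(nrow(assets))) {
        link_dest <- file.path(dest, assets$relpath[i])
        dir_create(dirname(link_dest))
        cache_link(cache, assets$digest[i], link_dest)
      }
      structure(list(
        ref = ref,
        phases = data.frame(
          phase = c("clone", "enumerate", "fetch", "link"),
          count = c(1L, nrow(assets), fetched, nrow(assets)),
          stringsAsFactors = FALSE),
        fetched = fetched,
        skipped_cached = skipped
      ), class = "bb_install_report")
  }, error = function(e) {
    # keep fetched objects in the cache, drop the half-installed repo
    if (fresh_clone) unlink(dest, recursive = TRUE, force = TRUE)
    stop(e)
  })
}

#' @export
print.bb_install_report <- function(x, ...) {
  cat(sprintf("<install> %s\n", format(x$ref)))
  for (i in seq_len(nrow(x$phases))) {
    cat(sprintf("  %-9s %d\n", x$phases$phase[i], x$phases$count[i]))
  }
  cat(sprintf("  fetched %d, already cached %d\n", x$fetched, x$skipped_cached))
  invisible(x)
}

installed_versions <- function(config, org, name) {
  d <- file.path(config$library, org, name)
  if (!dir.exists(d)) return(character(0))
  commits <- list.dirs(d, recursive = FALSE, full.names = FALSE)
  commits[vapply(commits, function(cm)
    looks_like_brick(file.path(d, cm)), NA)]
}

# newest installed version: registry commit order when reachable,
# else directory modification time
newest_installed <- function(config, org, name, backend = NULL) {
  versions <- installed_versions(config, org, name)
  if (length(versions) == 0L) return(NULL)
  ordered <- tryCatch({
    log <- registry_commits(backend %||% config_backend(config), org, name)
    hits <- log[log %in% versions]
    if (length(hits) > 0) hits[length(hits)] else NULL
  }, error = function(e) NULL)
  if (!is.null(ordered)) return(ordered)
  mtimes <- file.mtime(file.path(config$library, org, name, versions))
  versions[which.max(mtimes)]
}

#' Asset namespace of an installed brick
#'
#' Maps each payload identifier (see [asset_identifier()]) to the resolved
#' path of the installed file.  Without a commit, the newest installed
#' version is used (registry commit order when the backend is reachable,
#' install time otherwise).
#'
#' @param config a `bb_config`.
#' @param spec brick name or `org/name`.
#' @param commit optional installed commit.
#' @param verify re-hash every payload file against its recorded digest and
#'   raise an integrity error on mismatch.
#' @return A named character vector (class `bb_asset_namespace`) of
#'   identifier -> absolute path.
#' @export
bb_assets <- function(config, spec, commit = NULL, verify = FALSE) {
  parsed <- parse_brick_spec(spec, default_org = config$default_org)
  org <- parsed$organization; name <- parsed$name
  if (is.null(commit)) {
    commit <- newest_installed(config, org, name)
  } else if (!commit %in% installed_versions(config, org, name)) {
    hits <- installed_versions(config, org, name)
    hits <- hits[startsWith(hits, commit)]
    commit <- if (length(hits) == 1L) hits else NULL
  }
  if (is.null(commit)) {
    bb_stop(sprintf(
      "brick '%s/%s' is not installed; run bb_install() (CLI: install %s)",
      org, name, spec), "bb_not_installed_error")
  }
  repo <- file.path(config$library, org, name, commit)
  assets <- enumerate_assets(repo)
  if (nrow(assets) == 0L) {
    warning(sprintf("brick '%s/%s' has no payload files", org, name),
            call. = FALSE)
  }
  paths <- file.path(repo, assets$relpath)
  if (verify) {
    for (i in seq_len(nrow(assets))) {
      actual <- hash_file(paths[i])
      if (!identical(actual, assets$digest[i])) {
        bb_stop(sprintf(
          "payload '%s' of %s/%s fails verification: expected %s, got %s",
          assets$relpath[i], org, name, assets$digest[i], actual),
          "bb_integrity_error")
      }
    }
  }
  structure(stats::setNames(paths, assets$identifier),
            brick = paste(org, name, sep = "/"), commit = commit,
            class = "bb_asset_namespace")
}

#' @export
print.bb_asset_namespace <- function(x, ...) {
  cat(sprintf("<assets> %s @ %s\n", attr(x, "brick"), attr(x, "commit")))
  for (id in names(x)) cat(sprintf("  %s -> %s\n", id, x[[id]]))
  invisible(x)
}

#' Initialise dependency tracking in a brick workspace
#'
#' Creates `.bb/` and an empty `.bb/dependencies.txt`; never clobbers an
#' existing file.
#'
#' @param workdir brick workspace.
#' @return Invisibly, the character vector of paths created (empty on
#'   re-runs).
#' @export
bb_init <- function(workdir) {
  if (!dir.exists(workdir)) {
    bb_stop(sprintf("no such directory: '%s'", workdir), "bb_not_found_error")
  }
  created <- character(0)
  bbdir <- file.path(workdir, ".bb")
  if (!dir.exists(bbdir)) {
    dir_create(bbdir)
    created <- c(created, bbdir)
  }
  depfile <- file.path(bbdir, "dependencies.txt")
  if (!file.exists(depfile)) {
    write_text("", depfile)
    created <- c(created, depfile)
  }
  invisible(created)
}

#' Record a data dependency of a brick
#'
#' Resolves `spec` (to the head of `main` when no commit is given, always
#' storing the full commit id) and appends it to `.bb/dependencies.txt`,
#' replacing any existing entry for the same org/name.  The workspace is
#' auto-initialised if needed.
#'
#' @param config a `bb_config`.
#' @param workdir brick workspace.
#' @param spec brick name, `org/name`, or URL.
#' @param commit optional commit id or prefix.
#' @param backend registry backend (from the config by default).
#' @return The updated `bb_dependency_list`, invisibly.
#' @export
bb_add <- function(config, workdir, spec, commit = NULL,
                   backend = config_backend(config)) {
  ref <- bb_resolve(config, spec, commit, backend = backend)
  bb_init(workdir)
  depfile <- file.path(workdir, ".bb", "dependencies.txt")
  deps <- parse_dependencies(read_text(depfile))
  e <- deps$entries
  key <- paste(e$organization, e$name, sep = "/")
  new_key <- paste(ref$organization, ref$name, sep = "/")
  if (new_key %in% key) {
    e$commit[key == new_key] <- ref$commit
  } else {
    e <- rbind(e, data.frame(organization = ref$organization,
                             name = ref$name, commit = ref$commit,
                             url = NA_character_, stringsAsFactors = FALSE))
  }
  deps <- structure(list(entries = e), class = "bb_dependency_list")
  write_text(format_dependencies(deps), depfile)
  invisible(deps)
}

#' Install every recorded dependency of a workspace
#'
#' Reads `.bb/dependencies.txt` and installs each listed brick version;
#' already-installed versions produce a zero-fetch report.  Direct
#' dependencies only by default; `transitive = TRUE` follows the installed
#' bricks' own dependency files (with cycle protection).  When some entries
#' fail, the remaining ones are still attempted and a single error
#' summarising the failures is raised at the end (the partial reports ride
#' on the condition).
#'
#' @param config a `bb_config`.
#' @param workdir brick workspace.
#' @param transitive also install dependencies of dependencies.
#' @param backend registry backend (from the config by default).
#' @return A list of `bb_install_report`, one per dependency installed or
#'   skipped.
#' @export
bb_pull <- function(config, workdir, transitive = FALSE,
                    backend = config_backend(config)) {
  depfile <- file.path(workdir, ".bb", "dependencies.txt")
  if (!file.exists(depfile)) {
    bb_stop(sprintf("no dependencies file at '%s'; run bb_init() first",
                    depfile), "bb_not_found_error")
  }
  queue <- parse_dependencies(read_text(depfile))$entries
  reports <- list()
  failures <- character(0)
  visited <- character(0)
  while (nrow(queue) > 0L) {
    entry <- queue[1L, ]
    queue <- queue[-1L, , drop = FALSE]
    key <- paste(entry$organization, entry$name, entry$commit, sep = "/")
    if (key %in% visited) next
    visited <- c(visited, key)
    res <- tryCatch(
      bb_install(config, paste(entry$organization, entry$name, sep = "/"),
                 entry$commit, backend = backend),
      bb_error = function(e) e)
    if (inherits(res, "bb_error")) {
      failures <- c(failures, sprintf("%s: %s", key, conditionMessage(res)))
      next
    }
    reports[[length(reports) + 1L]] <- res
    if (transitive) {
      sub <- file.path(bb_local_path(config, res$ref), ".bb",
                       "dependencies.txt")
      if (file.exists(sub)) {
        queue <- rbind(queue, parse_dependencies(read_text(sub))$entries)
      }
    }
  }
  if (length(failures) > 0) {
    bb_stop(sprintf("pull finished with %d failure(s):\n  %s",
                    length(failures), paste(failures, collapse = "\n  ")),
            "bb_backend_error", reports = reports, failures = failures)
  }
  reports
}
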