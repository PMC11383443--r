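#' @title Library configuration and registry backends
#' @description
#' A library is a user-owned directory holding installed brick versions
#' under `<org>/<name>/<commit>` plus a shared content-addressed `cache/`
#' subdirectory.  Brick references are resolved against a pluggable
#' registry backend; the reference backend shipped here is a plain local
#' directory (refs map + version trees + sharded object store) so the whole
#' protocol runs offline.
#' @name library-registry
NULL

#' Path of the persisted configuration file
#'
#' Defaults to the platform user-config convention
#' (`tools::R_user_dir("bricktools", "config")`); the `BRICKTOOLS_CONFIG`
#' environment variable overrides it, which is how tests and scripts keep
#' isolated configurations.
#'
#' @return A file path.
#' @export
bb_config_path <- function() {
  env <- Sys.getenv("BRICKTOOLS_CONFIG", "")
  if (nzchar(env)) return(env)
  file.path(tools::R_user_dir("bricktools", "config"), "config.yaml")
}

#' Configure a brick library
#'
#' Creates the library directory and its `cache/` subdirectory, persists
#' the configuration, and returns it.  Re-running with the same arguments
#' is a no-op.
#'
#' @param path library directory (created if needed; must be writable).
#' @param token optional access token handed to the registry backend (the
#'   local reference backend ignores it).
#' @param registry registry locator; for the reference backend, the path of
#'   a local registry directory.
#' @param default_org organization assumed for bare brick names.
#' @param config_file where to persist the configuration.
#' @return A `bb_config` object.
#' @export
bb_configure <- function(path, token = NULL, registry = NULL,
                         default_org = "biobricks-ai",
                         config_file = bb_config_path()) {
  ok <- tryCatch({ dir_create(path); TRUE },
                 bb_error = function(e) FALSE)
  if (!ok || file.access(path, 2L) != 0L) {
    bb_stop(sprintf("library path '%s' is not writable", path),
            "bb_config_error")
  }
  dir_create(file.path(path, "cache"))
  config <- structure(list(
    library = normalizePath(path),
    token = token,
    registry = registry,
    default_org = default_org
  ), class = "bb_config")
  dir_create(dirname(config_file))
  yaml::write_yaml(list(
    BBLIB = config$library,
    TOKEN = config$token,
    REGISTRY = config$registry,
    DEFAULT_ORG = config$default_org
  ), config_file)
  config
}

#' Load a persisted configuration
#'
#' Environment variables `BRICKTOOLS_BBLIB`, `BRICKTOOLS_TOKEN` and
#' `BRICKTOOLS_REGISTRY` override the persisted values.
#'
#' @param config_file configuration file path.
#' @return A `bb_config` object.
#' @export
bb_load_config <- function(config_file = bb_config_path()) {
  if (!file.exists(config_file)) {
    bb_stop(sprintf(
      "no configuration at '%s'; run bb_configure() (CLI: configure) first",
      config_file), "bb_config_error")
  }
  raw <- yaml::read_yaml(config_file)
  env_or <- function(var, fallback) {
    v <- Sys.getenv(var, "")
    if (nzchar(v)) v else fallback
  }
  structure(list(
    library = env_or("BRICKTOOLS_BBLIB", raw$BBLIB),
    token = env_or("BRICKTOOLS_TOKEN", raw$TOKEN),
    registry = env_or("BRICKTOOLS_REGISTRY", raw$REGISTRY),
    default_org = raw$DEFAULT_ORG %||% "biobricks-ai"
  ), class = "bb_config")
}

#' @export
print.bb_config <- function(x, ...) {
  cat("<bb_config>\n")
  cat("  library :", x$library, "\n")
  cat("  registry:", x$registry %||% "<unset>", "\n")
  cat("  default organization:", x$default_org, "\n")
  invisible(x)
}

config_cache <- function(config) bb_cache(file.path(config$library, "cache"))

#' A versioned brick reference
#'
#' @param organization owning organization.
#' @param name brick name.
#' @param commit full version identifier (hex).
#' @return A `bb_brick_ref` object.
#' @export
brick_ref <- function(organization, name, commit) {
  for (f in c(organization, name, commit)) {
    if (!is.character(f) || length(f) != 1L || !nzchar(f)) {
      bb_stop("brick reference fields must all be non-empty strings",
              "bb_argument_error")
    }
  }
  structure(list(organization = organization, name = name, commit = commit),
            class = "bb_brick_ref")
}

#' @export
print.bb_brick_ref <- function(x, ...) {
  cat(sprintf("<brick> %s/%s @ %s\n", x$organization, x$name, x$commit))
  invisible(x)
}

#' @export
format.bb_brick_ref <- function(x, ...) {
  sprintf("%s/%s@%s", x$organization, x$name, x$commit)
}

## ---- registry backend contract ------------------------------------------

#' Registry backend generics
#'
#' A registry backend serves three things: the head commit of a branch, the
#' repository tree of a given version (code, pipeline and lock files -- not
#' the payload bytes), and payload objects by content digest.  Any backend
#' honouring these generics (a git+object-store pair, say) plugs into the
#' installer unchanged; [local_registry()] is the offline reference
#' implementation.
#'
#' @param backend a registry backend object.
#' @param org,name brick coordinates.
#' @param branch branch name (the default branch is `"main"`).
#' @param ref a [brick_ref()].
#' @param dest destination path.
#' @param digest content digest of a payload object.
#' @name registry-backend
NULL

#' @rdname registry-backend
#' @export
registry_resolve_head <- function(backend, org, name, branch = "main") {
  UseMethod("registry_resolve_head")
}

#' @rdname registry-backend
#' @export
registry_commits <- function(backend, org, name) UseMethod("registry_commits")

#' @rdname registry-backend
#' @export
registry_fetch_tree <- function(backend, ref, dest) {
  UseMethod("registry_fetch_tree")
}

#' @rdname registry-backend
#' @export
registry_fetch_object <- function(backend, digest, dest) {
  UseMethod("registry_fetch_object")
}

#' Local directory registry backend
#'
#' Reference registry layout: `<dir>/<org>/<name>/refs` (YAML branch to
#' commit map), `<dir>/<org>/<name>/commits` (one commit per line, oldest
#' first), `<dir>/<org>/<name>/<commit>/` (the repository tree) and
#' `<dir>/objects/<2 hex>/<30 hex>` (sharded payload object store).
#'
#' @param dir registry root directory.
#' @return A `bb_local_registry` backend.
#' @export
local_registry <- function(dir) {
  if (!dir.exists(dir)) {
    bb_stop(sprintf("registry directory '%s' does not exist", dir),
            "bb_backend_error")
  }
  structure(list(dir = normalizePath(dir)),
            class = c("bb_local_registry", "bb_registry_backend"))
}

registry_brick_dir <- function(backend, org, name, must_exist = TRUE) {
  d <- file.path(backend$dir, org, name)
  if (must_exist && !dir.exists(d)) {
    bb_stop(sprintf("brick '%s/%s' not found in registry", org, name),
            "bb_not_found_error")
  }
  d
}

#' @export
registry_resolve_head.bb_local_registry <- function(backend, org, name,
                                                    branch = "main") {
  refs_file <- file.path(registry_brick_dir(backend, org, name), "refs")
  refs <- if (file.exists(refs_file)) yaml::read_yaml(refs_file) else list()
  head <- refs[[branch]]
  if (is.null(head)) {
    bb_stop(sprintf("brick '%s/%s' has no branch '%s'", org, name, branch),
            "bb_not_found_error")
  }
  head
}

#' @export
registry_commits.bb_local_registry <- function(backend, org, name) {
  f <- file.path(registry_brick_dir(backend, org, name), "commits")
  if (!file.exists(f)) return(character(0))
  lines <- readLines(f, warn = FALSE)
  lines[nzchar(lines)]
}

#' @export
registry_fetch_tree.bb_local_registry <- function(backend, ref, dest) {
  src <- file.path(registry_brick_dir(backend, ref$organization, ref$name),
                   ref$commit)
  if (!dir.exists(src)) {
    bb_stop(sprintf("commit '%s' of '%s/%s' not found in registry",
                    ref$commit, ref$organization, ref$name),
            "bb_not_found_error")
  }
  dir_create(dest)
  entries <- list.files(src, recursive = TRUE, all.files = TRUE, no.. = TRUE)
  for (e in entries) {
    target <- file.path(dest, e)
    dir_create(dirname(target))
    file.copy(file.path(src, e), target, overwrite = TRUE)
  }
  invisible(dest)
}

registry_object_path <- function(backend, digest) {
  file.path(backend$dir, "objects", substr(digest, 1, 2), substr(digest, 3, 32))
}

#' @export
registry_fetch_object.bb_local_registry <- function(backend, digest, dest) {
  src <- registry_object_path(backend, digest)
  if (!file.exists(src)) {
    bb_stop(sprintf("payload object %s not found in registry", digest),
            "bb_missing_object_error")
  }
  if (!file.copy(src, dest, overwrite = TRUE)) {
    bb_stop(sprintf("failed to fetch object %s", digest), "bb_backend_error")
  }
  invisible(dest)
}

config_backend <- function(config) {
  if (is.null(config$registry) || !nzchar(config$registry)) {
    bb_stop("no registry configured", "bb_config_error")
  }
  local_registry(config$registry)
}

## ---- resolution and layout ----------------------------------------------

#' Resolve a brick spec to a full reference
#'
#' A bare name resolves under the configured default organization; an
#' `org/name` pair or full git URL is taken as-is.  Without a commit the
#' head of the default branch (`main`) is used; a commit prefix of at least
#' five hex characters resolves to the unique matching commit (ambiguity is
#' an error listing the candidates).
#'
#' @param config a `bb_config`.
#' @param spec bare name, `org/name`, or URL.
#' @param commit optional commit id or prefix (>= 5 hex chars).
#' @param backend registry backend (from the config by default).
#' @return A [brick_ref()].
#' @export
bb_resolve <- function(config, spec, commit = NULL,
                       backend = config_backend(config)) {
  parsed <- parse_brick_spec(spec, default_org = config$default_org)
  org <- parsed$organization; name <- parsed$name
  if (is.null(commit)) {
    return(brick_ref(org, name, registry_resolve_head(backend, org, name)))
  }
  if (!grepl("^[0-9a-f]{5,40}$", commit)) {
    bb_stop(sprintf(
      "commit '%s' must be 5-40 lowercase hex characters", commit),
      "bb_argument_error")
  }
  known <- registry_commits(backend, org, name)
  if (commit %in% known) return(brick_ref(org, name, commit))
  hits <- known[startsWith(known, commit)]
  if (length(hits) == 0L) {
    bb_stop(sprintf("no commit of '%s/%s' matches '%s'", org, name, commit),
            "bb_not_found_error")
  }
  if (length(hits) > 1L) {
    bb_stop(sprintf("commit prefix '%s' is ambiguous for '%s/%s': %s",
                    commit, org, name, paste(hits, collapse = ", ")),
            "bb_ambiguity_error")
  }
  brick_ref(org, name, hits)
}

#' Library path of a brick version
#'
#' Pure function: `<library>/<org>/<name>/<commit>`, independent of whether
#' the version is installed.
#'
#' @param config a `bb_config`.
#' @param ref a [brick_ref()].
#' @return A directory path.
#' @export
bb_local_path <- function(config, ref) {
  stopifnot(inherits(ref, "bb_brick_ref"))
  file.path(config$library, ref$organization, ref$name, ref$commit)
}

#' List installed brick versions
#'
#' One entry per `<org>/<name>/<commit>` directory in the library that
#' holds a valid brick; stray directories are excluded with a warning.
#'
#' @param config a `bb_config`.
#' @return A list of [brick_ref()] objects.
#' @export
bb_list_installed <- function(config) {
  lib <- config$library
  refs <- list()
  orgs <- setdiff(list.dirs(lib, recursive = FALSE, full.names = FALSE),
                  "cache")
  for (org in orgs) {
    for (name in list.dirs(file.path(lib, org), recursive = FALSE,
                           full.names = FALSE)) {
      for (commit in list.dirs(file.path(lib, org, name), recursive = FALSE,
                               full.names = FALSE)) {
        d <- file.path(lib, org, name, commit)
        if (looks_like_brick(d)) {
          refs[[length(refs) + 1L]] <- brick_ref(org, name, commit)
        } else {
          warning(sprintf("ignoring non-brick directory '%s'", d),
                  call. = FALSE)
        }
      }
    }
  }
  refs
}
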