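#' Content-addressed object cache
#'
#' Every distinct payload file in a library is stored exactly once, keyed by
#' the MD5 of its bytes, under a two-level sharded layout
#' `<cache>/<first 2 hex chars>/<remaining 30 chars>`.  Directory payloads
#' are represented by a tree manifest -- a canonical minimal-JSON array of
#' `[path, digest]` pairs sorted by path -- stored with a `.dir` suffix, so a
#' whole directory gets a single reproducible digest.  Stored objects are
#' made read-only; deduplication is automatic because identical content maps
#' to an identical cache path.
#'
#' @param root cache root directory (created if absent).
#' @return An object of class `bb_cache`.
#' @examples
#' cache <- bb_cache(file.path(tempdir(), "demo-cache"))
#' f <- tempfile(); writeLines("abc", f)
#' entry <- cache_store(cache, f)
#' cache_verify(cache, entry$digest)
#' @export
bb_cache <- function(root) {
  if (is.null(root) || !nzchar(root)) {
    bb_stop("cache root is not configured", "bb_config_error")
  }
  dir_create(root)
  structure(list(root = normalizePath(root)), class = "bb_cache")
}

#' @export
print.bb_cache <- function(x, ...) {
  objs <- list.files(x$root, recursive = TRUE)
  cat(sprintf("<bb_cache> %s (%d objects)\n", x$root, length(objs)))
  invisible(x)
}

#' MD5 digest of a file
#'
#' Streams the file through MD5 and returns the 32-character lowercase hex
#' digest that keys the cache and the lock files.
#'
#' @param path path to an existing regular file.
#' @return A 32-character lowercase hex string.
#' @export
hash_file <- function(path) {
  if (!file.exists(path)) {
    bb_stop(sprintf("no such file: '%s'", path), "bb_not_found_error")
  }
  if (dir.exists(path)) {
    bb_stop(sprintf("'%s' is a directory, not a file (use hash_tree)", path),
            "bb_wrong_kind_error")
  }
  d <- unname(tools::md5sum(path))
  if (is.na(d)) bb_stop(sprintf("cannot read '%s'", path), "bb_io_error")
  d
}

# MD5 of an in-memory raw vector (via a scratch file; tools::md5sum is the
# single hashing backend so file and byte digests can never disagree)
hash_bytes <- function(bytes) {
  stopifnot(is.raw(bytes))
  tmp <- tempfile("bbhash")
  on.exit(unlink(tmp))
  writeBin(bytes, tmp)
  unname(tools::md5sum(tmp))
}

# canonical minimal-JSON serialization of a tree manifest
manifest_json <- function(manifest) {
  if (nrow(manifest) == 0L) return("[]")
  pairs <- lapply(seq_len(nrow(manifest)),
                  function(i) c(manifest$path[i], manifest$digest[i]))
  as.character(jsonlite::toJSON(pairs))
}

#' Digest of a directory tree
#'
#' Lists every regular file under `dir` (recursively, symlinks resolved to
#' their target content), digests each, and derives a single tree digest as
#' the MD5 of the canonical manifest: a minimal JSON array of
#' `[relative-path, digest]` pairs, UTF-8, no whitespace, sorted by path in
#' byte order.  The digest is therefore independent of file creation and
#' traversal order.
#'
#' @param dir path to an existing directory.
#' @return A list with `manifest` (data frame of `path`, `digest`) and
#'   `digest` (the tree digest).
#' @export
hash_tree <- function(dir) {
  if (!dir.exists(dir)) {
    bb_stop(sprintf("no such directory: '%s'", dir), "bb_not_found_error")
  }
  files <- list.files(dir, recursive = TRUE, all.files = TRUE, no.. = TRUE)
  files <- files[!dir.exists(file.path(dir, files))]
  files <- sort_c(enc2utf8(files))
  digests <- vapply(files, function(f) hash_file(file.path(dir, f)), "")
  manifest <- data.frame(path = files, digest = unname(digests),
                         stringsAsFactors = FALSE, row.names = NULL)
  list(manifest = manifest,
       digest = hash_bytes(charToRaw(manifest_json(manifest))))
}

# sharded path of an object inside the cache
cache_object_path <- function(cache, digest, kind = c("file", "tree-manifest")) {
  kind <- match.arg(kind)
  suffix <- if (kind == "tree-manifest") ".dir" else ""
  file.path(cache$root, substr(digest, 1, 2),
            paste0(substr(digest, 3, 32), suffix))
}

# locate a stored object of either kind; NULL when absent
cache_find <- function(cache, digest) {
  for (kind in c("file", "tree-manifest")) {
    p <- cache_object_path(cache, digest, kind)
    if (file.exists(p)) return(list(path = p, kind = kind))
  }
  NULL
}

cache_has <- function(cache, digest) !is.null(cache_find(cache, digest))

# write bytes into the cache at their content address; no-op when present
cache_put_bytes <- function(cache, bytes, kind = "file", digest = NULL) {
  digest <- digest %||% hash_bytes(bytes)
  dest <- cache_object_path(cache, digest, kind)
  if (!file.exists(dest)) {
    dir_create(dirname(dest))
    tmp <- tempfile(tmpdir = dirname(dest))
    writeBin(bytes, tmp)
    file.rename(tmp, dest)
    Sys.chmod(dest, "0444")
  }
  list(digest = digest, size = file.size(dest), kind = kind, path = dest)
}

#' Store a file or directory in the cache
#'
#' Files are stored at their content address; directories are stored as a
#' tree manifest (every contained file is stored individually first).
#' Storing identical content twice is a no-op returning the same entry, and
#' stored objects are write-protected.
#'
#' @param cache a [bb_cache()].
#' @param path file or directory to store.
#' @return A cache entry: list with `digest`, `size`, `kind`, `path`.
#' @export
cache_store <- function(cache, path) {
  if (dir.exists(path)) {
    tree <- hash_tree(path)
    for (i in seq_len(nrow(tree$manifest))) {
      cache_store(cache, file.path(path, tree$manifest$path[i]))
    }
    entry <- cache_put_bytes(cache, charToRaw(manifest_json(tree$manifest)),
                             kind = "tree-manifest", digest = tree$digest)
    return(entry)
  }
  digest <- hash_file(path)
  dest <- cache_object_path(cache, digest, "file")
  if (!file.exists(dest)) {
    dir_create(dirname(dest))
    tmp <- tempfile(tmpdir = dirname(dest))
    file.copy(path, tmp)
    file.rename(tmp, dest)
    Sys.chmod(dest, "0444")
  }
  list(digest = digest, size = file.size(dest), kind = "file", path = dest)
}

#' Materialize a cached object at a destination path
#'
#' Creates `dest` as a symbolic link to the cache object, falling back to a
#' copy on filesystems without link support (the returned record says which).
#' Tree-manifest objects are materialized as a directory of links, one per
#' manifest entry.
#'
#' @param cache a [bb_cache()].
#' @param digest digest of a stored object.
#' @param dest destination path; its parent must exist.
#' @return A link record: list with `dest`, `digest`, `mode` ("symlink" or
#'   "copy").
#' @export
cache_link <- function(cache, digest, dest) {
  assert_digest(digest)
  found <- cache_find(cache, digest)
  if (is.null(found)) {
    bb_stop(sprintf("object %s is not in the cache", digest),
            "bb_missing_object_error")
  }
  if (!dir.exists(dirname(dest))) {
    bb_stop(sprintf("parent directory of '%s' does not exist", dest),
            "bb_io_error")
  }
  if (found$kind == "tree-manifest") {
    manifest <- parse_manifest_json(read_text(found$path))
    dir_create(dest)
    modes <- character(0)
    for (i in seq_len(nrow(manifest))) {
      sub <- file.path(dest, manifest$path[i])
      dir_create(dirname(sub))
      rec <- cache_link(cache, manifest$digest[i], sub)
      modes <- c(modes, rec$mode)
    }
    mode <- if (any(modes == "copy")) "copy" else "symlink"
    return(list(dest = dest, digest = digest, mode = mode))
  }
  if (file.exists(dest)) unlink(dest)
  ok <- suppressWarnings(file.symlink(found$path, dest))
  mode <- "symlink"
  if (!isTRUE(ok)) {
    file.copy(found$path, dest)
    mode <- "copy"
  }
  list(dest = dest, digest = digest, mode = mode)
}

parse_manifest_json <- function(text) {
  entries <- jsonlite::fromJSON(text, simplifyMatrix = FALSE,
                                simplifyDataFrame = FALSE)
  if (length(entries) == 0L) {
    return(data.frame(path = character(0), digest = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    path = vapply(entries, `[[`, "", 1L),
    digest = vapply(entries, `[[`, "", 2L),
    stringsAsFactors = FALSE
  )
}

#' Verify a cached object against its digest
#'
#' @param cache a [bb_cache()].
#' @param digest digest to check.
#' @return `TRUE` iff the object exists and its bytes re-hash to `digest`;
#'   otherwise `FALSE` with a `"diagnostic"` attribute saying why.
#' @export
cache_verify <- function(cache, digest) {
  found <- cache_find(cache, digest)
  if (is.null(found)) {
    return(structure(FALSE, diagnostic = sprintf("object %s not stored", digest)))
  }
  actual <- hash_file(found$path)
  if (!identical(actual, digest)) {
    return(structure(FALSE, diagnostic = sprintf(
      "object %s is corrupt: stored bytes hash to %s", digest, actual)))
  }
  if (found$kind == "tree-manifest") {
    manifest <- parse_manifest_json(read_text(found$path))
    for (i in seq_len(nrow(manifest))) {
      if (!isTRUE(cache_verify(cache, manifest$digest[i]))) {
        return(structure(FALSE, diagnostic = sprintf(
          "tree %s: entry '%s' fails verification",
          digest, manifest$path[i])))
      }
    }
  }
  TRUE
}
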