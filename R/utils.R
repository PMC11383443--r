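# small shared helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

# Normalise a workspace-relative path for comparison: POSIX separators,
# no leading "./", no trailing "/".
normalize_relpath <- function(path) {
  path <- gsub("\\\\", "/", path)
  path <- sub("^\\./", "", path)
  sub("/+$", "", path)
}

# byte-order sort, independent of the session locale
sort_c <- function(x) sort(x, method = "radix")

is_hex_digest <- function(x) {
  is.character(x) & !is.na(x) & grepl("^[0-9a-f]{32}$", x)
}

assert_digest <- function(x, what = "digest") {
  if (length(x) != 1L || !is_hex_digest(x)) {
    bb_stop(
      sprintf("%s must be a 32-character lowercase hex MD5 string, got %s",
              what, deparse(substitute(x))),
      "bb_schema_error"
    )
  }
  invisible(x)
}

read_text <- function(path) {
  readChar(path, file.size(path), useBytes = TRUE)
}

write_text <- function(text, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(text), con)
  invisible(path)
}

# deterministic integer sub-seed derived from a master seed and a label,
# kept below 2^31
derive_seed <- function(seed, label) {
  h <- utils::head(charToRaw(hash_bytes(charToRaw(paste0(seed, ":", label)))), 7)
  as.integer(sum(as.integer(h) * 256^(0:6)) %% 2147483647)
}

dir_create <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) {
    bb_stop(sprintf("cannot create directory '%s'", path), "bb_io_error")
  }
  invisible(path)
}

is_identifier <- function(x) grepl("^[A-Za-z_][A-Za-z0-9_]*$", x)
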