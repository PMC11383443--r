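#' @title Harmonizing heterogeneous chemical-activity sources
#' @description
#' Many chemical-safety databases publish the same kind of fact -- "this
#' substance shows this activity for this property" -- under wildly
#' different tabular schemas.  The harmonizer reduces them all to one
#' three-table schema: `substances` (sid + canonical JSON metadata),
#' `properties` (pid + metadata), and `activities` linking sid to pid with
#' a value that is either binary (1 positive / 0 negative) or numeric (a
#' binding affinity, an LD50), carrying SMILES/InChI structure strings
#' verbatim when the source provides them.  Substance and property ids are
#' minted deterministically as digests, so re-running a release is
#' bit-stable.
#' @name harmonizer
NULL

# canonical JSON: keys sorted recursively, compact, scalars unboxed
canonical_json <- function(x) {
  sort_keys <- function(v) {
    if (is.list(v) && !is.null(names(v))) {
      v <- v[sort_c(names(v))]
      lapply(v, sort_keys)
    } else if (is.list(v)) {
      lapply(v, sort_keys)
    } else v
  }
  as.character(jsonlite::toJSON(sort_keys(x), auto_unbox = TRUE,
                                digits = NA, null = "null"))
}

is_canonical_json <- function(text) {
  parsed <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) NULL)
  if (is.null(parsed)) return(FALSE)
  identical(canonical_json(parsed), text)
}

#' Define a source adapter
#'
#' An adapter turns one raw source table (or list of tables) into the
#' harmonized shape.  `transform(raw)` must return a list with three data
#' frames, keyed by source-local identifiers:
#' \describe{
#'   \item{substances}{`local_id`, optional `inchi`, `metadata` (a list
#'     column or JSON strings).}
#'   \item{properties}{`local_id`, `metadata`.}
#'   \item{activities}{`substance`, `property` (local ids), `value`,
#'     `value_type` ("binary" or "numeric"), optional `smiles`, `inchi`.}
#' }
#' Adapters must be deterministic in their input.
#'
#' @param name source name (used in ids and the `source` column).
#' @param transform function of one argument as described above.
#' @return A `bb_source_adapter`.
#' @export
source_adapter <- function(name, transform) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.function(transform))
  structure(list(name = name, transform = transform),
            class = "bb_source_adapter")
}

mint_id <- function(...) hash_bytes(charToRaw(paste(..., sep = "\x1f")))

metadata_json <- function(metadata, i) {
  m <- if (is.list(metadata)) metadata[[i]] else metadata[i]
  if (is.character(m) && length(m) == 1L) {
    # a JSON-encoded string is canonicalized; anything else is a scalar
    parsed <- tryCatch(jsonlite::fromJSON(m, simplifyVector = FALSE),
                       error = function(e) NULL)
    if (!is.null(parsed)) return(canonical_json(parsed))
  }
  canonical_json(m)
}

#' Reduce source tables to the three-table harmonized set
#'
#' Runs every adapter on its raw input and unions the results.  Substances
#' are deduplicated by structure: records sharing an InChI collapse to one
#' substance (first-seen metadata wins); substances without an InChI are
#' kept per source.  sids and pids are digests of the structure key or of
#' (source, local id), so identical inputs always yield identical output
#' bytes.  An activity referencing a local id its adapter never emitted is
#' an integrity error naming the source and row.
#'
#' @param adapters list of [source_adapter()]s.
#' @param sources named list of raw inputs, one per adapter name.
#' @return A `bb_harmony_set`: list of data frames `substances`
#'   (sid, metadata), `properties` (pid, metadata) and `activities`
#'   (aid, sid, pid, source, value, value_type, smiles, inchi).
#' @export
harmonize <- function(adapters, sources) {
  if (inherits(adapters, "bb_source_adapter")) adapters <- list(adapters)
  sub_rows <- list(); prop_rows <- list(); act_rows <- list()
  seen_sid <- character(0); seen_pid <- character(0)
  for (adapter in adapters) {
    stopifnot(inherits(adapter, "bb_source_adapter"))
    src <- adapter$name
    if (!src %in% names(sources)) {
      bb_stop(sprintf("no raw input supplied for source '%s'", src),
              "bb_argument_error")
    }
    raw <- sources[[src]]
    out <- adapter$transform(raw)
    subs <- out$substances; props <- out$properties; acts <- out$activities
    # mint sids: structure key when an InChI is present, else per-source
    inchi <- if ("inchi" %in% names(subs)) subs$inchi else
      rep(NA_character_, nrow(subs))
    sid_map <- character(0)
    for (i in seq_len(nrow(subs))) {
      sid <- if (!is.na(inchi[i]) && nzchar(inchi[i])) {
        mint_id("inchi", inchi[i])
      } else {
        mint_id("substance", src, subs$local_id[i])
      }
      sid_map[subs$local_id[i]] <- sid
      if (!sid %in% seen_sid) {
        seen_sid <- c(seen_sid, sid)
        sub_rows[[length(sub_rows) + 1L]] <- data.frame(
          sid = sid, metadata = metadata_json(subs$metadata, i),
          stringsAsFactors = FALSE)
      }
    }
    pid_map <- character(0)
    for (i in seq_len(nrow(props))) {
      pid <- mint_id("property", src, props$local_id[i])
      pid_map[props$local_id[i]] <- pid
      if (!pid %in% seen_pid) {
        seen_pid <- c(seen_pid, pid)
        prop_rows[[length(prop_rows) + 1L]] <- data.frame(
          pid = pid, metadata = metadata_json(props$metadata, i),
          stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(nrow(acts))) {
      sid <- sid_map[acts$substance[i]]
      pid <- pid_map[acts$property[i]]
      if (is.na(sid)) {
        bb_stop(sprintf(
          "source '%s', activity row %d: unknown substance '%s'",
          src, i, acts$substance[i]), "bb_integrity_error")
      }
      if (is.na(pid)) {
        bb_stop(sprintf(
          "source '%s', activity row %d: unknown property '%s'",
          src, i, acts$property[i]), "bb_integrity_error")
      }
      value <- as.numeric(acts$value[i])
      value_type <- acts$value_type[i]
      if (value_type == "binary" && !value %in% c(0, 1)) {
        bb_stop(sprintf(
          "source '%s', activity row %d: binary value must be 0 or 1, got %s",
          src, i, value), "bb_integrity_error")
      }
      act_rows[[length(act_rows) + 1L]] <- data.frame(
        aid = mint_id("activity", src, acts$substance[i], acts$property[i], i),
        sid = unname(sid), pid = unname(pid), source = src,
        value = value, value_type = value_type,
        smiles = if ("smiles" %in% names(acts)) acts$smiles[i] else NA_character_,
        inchi = if ("inchi" %in% names(acts)) acts$inchi[i] else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  bind <- function(rows, template) {
    if (length(rows) == 0L) return(template)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  h <- structure(list(
    substances = bind(sub_rows, data.frame(
      sid = character(0), metadata = character(0), stringsAsFactors = FALSE)),
    properties = bind(prop_rows, data.frame(
      pid = character(0), metadata = character(0), stringsAsFactors = FALSE)),
    activities = bind(act_rows, data.frame(
      aid = character(0), sid = character(0), pid = character(0),
      source = character(0), value = numeric(0), value_type = character(0),
      smiles = character(0), inchi = character(0), stringsAsFactors = FALSE))
  ), class = "bb_harmony_set")
  h
}

#' @export
print.bb_harmony_set <- function(x, ...) {
  cat(sprintf(
    "<harmony set> %d substance(s), %d propertie(s), %d activitie(s)\n",
    nrow(x$substances), nrow(x$properties), nrow(x$activities)))
  invisible(x)
}

#' Activity counts per source
#'
#' @param h a `bb_harmony_set`.
#' @return Data frame of `source`, `activities`, one row per distinct
#'   source; the counts sum to the total number of activities.
#' @export
count_by_source <- function(h) {
  stopifnot(inherits(h, "bb_harmony_set"))
  if (nrow(h$activities) == 0L) {
    return(data.frame(source = character(0), activities = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(h$activities$source)
  data.frame(source = sort_c(names(tab)),
             activities = as.integer(tab[sort_c(names(tab))]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Major properties
#'
#' Properties with strictly more than `threshold` linked activities
#' ("over" 1,000 by default), ordered by activity count descending with
#' ties broken by pid ascending.
#'
#' @param h a `bb_harmony_set`.
#' @param threshold minimum activity count (exclusive); non-negative.
#' @return Character vector of pids.
#' @export
major_properties <- function(h, threshold = 1000) {
  stopifnot(inherits(h, "bb_harmony_set"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    bb_stop("threshold must be a single non-negative count",
            "bb_argument_error")
  }
  if (nrow(h$activities) == 0L) return(character(0))
  tab <- table(h$activities$pid)
  counts <- as.integer(tab)
  pids <- names(tab)
  keep <- counts > threshold
  ord <- order(-counts[keep], pids[keep], method = "radix")
  pids[keep][ord]
}

#' Validate a harmonized set
#'
#' Reports dangling foreign keys, non-canonical metadata JSON, and binary
#' activity values outside {0, 1}.  A valid set yields an empty report.
#'
#' @param h a `bb_harmony_set`.
#' @return Data frame of findings (`table`, `row`, `finding`); zero rows
#'   when the set is valid.
#' @export
validate_harmony <- function(h) {
  stopifnot(inherits(h, "bb_harmony_set"))
  findings <- list()
  add <- function(tab, row, finding) {
    findings[[length(findings) + 1L]] <<- data.frame(
      table = tab, row = row, finding = finding, stringsAsFactors = FALSE)
  }
  a <- h$activities
  bad_sid <- which(!a$sid %in% h$substances$sid)
  for (i in bad_sid) add("activities", i, sprintf("unknown sid '%s'", a$sid[i]))
  bad_pid <- which(!a$pid %in% h$properties$pid)
  for (i in bad_pid) add("activities", i, sprintf("unknown pid '%s'", a$pid[i]))
  bad_bin <- which(a$value_type == "binary" & !a$value %in% c(0, 1))
  for (i in bad_bin) {
    add("activities", i, sprintf("binary value out of range: %s", a$value[i]))
  }
  for (i in which(!vapply(h$substances$metadata, is_canonical_json, NA))) {
    add("substances", i, "metadata is not canonical JSON")
  }
  for (i in which(!vapply(h$properties$metadata, is_canonical_json, NA))) {
    add("properties", i, "metadata is not canonical JSON")
  }
  if (length(findings) == 0L) {
    return(data.frame(table = character(0), row = integer(0),
                      finding = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, findings)
  rownames(out) <- NULL
  out
}

#' Write a harmonized set as a brick payload
#'
#' Emits `substances.parquet`, `properties.parquet` and
#' `activities.parquet` under `<brick_dir>/brick/`.
#'
#' @param h a `bb_harmony_set`.
#' @param brick_dir brick repository root.
#' @return Invisibly, the three file paths written.
#' @export
write_harmony <- function(h, brick_dir) {
  stopifnot(inherits(h, "bb_harmony_set"))
  payload <- dir_create(file.path(brick_dir, "brick"))
  paths <- character(0)
  for (tab in c("substances", "properties", "activities")) {
    p <- file.path(payload, paste0(tab, ".parquet"))
    arrow::write_parquet(h[[tab]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a harmonized set back from a brick payload
#'
#' @param brick_dir brick repository root containing the three Parquet
#'   tables under `brick/`.
#' @return A `bb_harmony_set`.
#' @export
read_harmony <- function(brick_dir) {
  payload <- file.path(brick_dir, "brick")
  tabs <- lapply(c("substances", "properties", "activities"), function(tab) {
    p <- file.path(payload, paste0(tab, ".parquet"))
    if (!file.exists(p)) {
      bb_stop(sprintf("missing harmonized table '%s'", p),
              "bb_not_found_error")
    }
    as.data.frame(arrow::read_parquet(p))
  })
  structure(stats::setNames(tabs, c("substances", "properties", "activities")),
            class = "bb_harmony_set")
}
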