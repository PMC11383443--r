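# Independent MD5 oracle: python's hashlib, never the package's own hasher.
python_md5 <- function(path) {
  out <- system2("python", c("-c", shQuote(
    "import hashlib,sys;print(hashlib.md5(open(sys.argv[1],'rb').read()).hexdigest())"),
    shQuote(path)), stdout = TRUE)
  trimws(out[1])
}

python_md5_string <- function(text) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(charToRaw(text), tmp)
  python_md5(tmp)
}

write_file <- function(path, content) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "wb")
  writeBin(charToRaw(content), con)
  close(con)
  path
}

# an isolated configured library + default fixture registry
local_bb_setup <- function(seed = 1L, bricks = NULL, env = parent.frame()) {
  td <- withr::local_tempdir(.local_envir = env)
  withr::local_envvar(
    c(BRICKTOOLS_CONFIG = file.path(td, "config.yaml"),
      BRICKTOOLS_BBLIB = NA, BRICKTOOLS_REGISTRY = NA),
    .local_envir = env)
  reg <- file.path(td, "registry")
  if (is.null(bricks)) {
    fixture_registry(reg, seed = seed)
  } else {
    fixture_registry(reg, seed = seed, bricks = bricks)
  }
  config <- bb_configure(file.path(td, "lib"), registry = reg)
  list(td = td, registry = reg, config = config)
}

# digest snapshot of a directory tree, via the python oracle
tree_snapshot <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, all.files = TRUE,
                           no.. = TRUE), method = "radix")
  files <- files[!dir.exists(file.path(dir, files))]
  vapply(files, function(f) python_md5(file.path(dir, f)), "")
}

## ---- random pipeline generator + brute-force staleness oracle -----------

# A pipeline whose commands have fully known semantics (each stage
# concatenates its declared deps into its single output), so staleness can
# be decided by an oracle that tracks file contents virtually and never
# calls the runner's code.
random_pipeline <- function(seed, allow_zero_dep = TRUE) {
  set.seed(seed)
  n_sources <- sample(1:3, 1)
  sources <- sprintf("src%d.txt", seq_len(n_sources))
  n_stages <- sample(2:4, 1)
  # avoid single letters YAML 1.1 reads as booleans (y, n, t, f)
  stage_names <- sort(sample(setdiff(letters, c("y", "n", "t", "f")),
                             n_stages))
  stages <- list()
  available <- sources
  for (i in seq_len(n_stages)) {
    out <- sprintf("out_%s.txt", stage_names[i])
    zero_dep <- allow_zero_dep && stats::runif(1) < 0.25
    deps <- if (zero_dep) character(0) else {
      unique(sample(available, sample(seq_len(min(2, length(available))), 1)))
    }
    cmd <- if (length(deps) == 0) {
      sprintf("printf constant-%s > %s", stage_names[i], out)
    } else {
      sprintf("cat %s > %s", paste(deps, collapse = " "), out)
    }
    stages[[i]] <- list(name = stage_names[i], cmd = cmd,
                        deps = deps, outs = out)
    available <- c(available, out)
  }
  list(sources = sources, stages = stages)
}

pipeline_yaml <- function(pl) {
  lines <- "stages:"
  for (s in pl$stages) {
    lines <- c(lines, sprintf("  %s:", s$name),
               sprintf("    cmd: '%s'", s$cmd))
    if (length(s$deps) > 0) {
      lines <- c(lines, "    deps:", sprintf("    - %s", s$deps))
    }
    lines <- c(lines, "    outs:", sprintf("    - %s", s$outs))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

materialize_pipeline <- function(pl, workspace, source_contents) {
  dir.create(workspace, recursive = TRUE, showWarnings = FALSE)
  for (s in pl$sources) write_file(file.path(workspace, s),
                                   source_contents[[s]])
  write_file(file.path(workspace, "dvc.yaml"), pipeline_yaml(pl))
}

# Brute-force oracle: given current virtual file contents and the contents
# recorded at the last successful run, decide which stages a rebuild must
# execute.  Works purely on content strings (content equality <=> digest
# equality) and applies each stale stage's known effect before moving on.
oracle_executed <- function(pl, current, recorded, order_) {
  stages <- setNames(pl$stages, vapply(pl$stages, `[[`, "", "name"))
  executed <- character(0)
  for (name in order_) {
    s <- stages[[name]]
    stale <- if (length(s$deps) == 0) {
      TRUE  # zero-dependency stages rebuild every time
    } else if (is.null(recorded$locked[[name]])) {
      TRUE
    } else {
      dep_changed <- any(vapply(s$deps, function(d)
        !identical(current[[d]], recorded$locked[[name]]$deps[[d]]), NA))
      out_bad <- is.null(current[[s$outs]]) ||
        !identical(current[[s$outs]], recorded$locked[[name]]$outs)
      dep_changed || out_bad
    }
    if (stale) {
      executed <- c(executed, name)
      current[[s$outs]] <- if (length(s$deps) == 0) {
        sprintf("constant-%s", name)
      } else {
        paste0(unlist(current[s$deps]), collapse = "")
      }
      recorded$locked[[name]] <- list(
        deps = setNames(lapply(s$deps, function(d) current[[d]]), s$deps),
        outs = current[[s$outs]])
    }
  }
  list(executed = executed, current = current, recorded = recorded)
}
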