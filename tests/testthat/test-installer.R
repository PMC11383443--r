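test_that("a cold install runs the four phases and fetches every asset", {
  setup <- local_bb_setup()
  report <- bb_install(setup$config, "hgnc")
  expect_identical(report$phases$phase, c("clone", "enumerate", "fetch", "link"))
  expect_identical(report$phases$count, c(1L, 3L, 3L, 3L))
  expect_identical(report$fetched, 3L)
  expect_identical(report$skipped_cached, 0L)
  # every linked payload re-hashes to its recorded digest
  repo <- bb_local_path(setup$config, report$ref)
  assets <- enumerate_assets(repo)
  for (i in seq_len(nrow(assets))) {
    expect_identical(python_md5(file.path(repo, assets$relpath[i])),
                     assets$digest[i])
  }
})

test_that("re-installing skips every cached object", {
  setup <- local_bb_setup()
  bb_install(setup$config, "hgnc")
  report <- bb_install(setup$config, "hgnc")
  expect_identical(report$fetched, 0L)
  expect_identical(report$skipped_cached, 3L)
})

test_that("append-only growth fetches exactly the new objects", {
  setup <- local_bb_setup()
  bb_install(setup$config, "hgnc")
  fixture_grow_brick(setup$registry, "biobricks-ai", "hgnc", 1, seed = 5)
  report <- bb_install(setup$config, "hgnc")
  expect_identical(report$fetched, 1L)
  expect_identical(report$skipped_cached, 3L)
  fixture_grow_brick(setup$registry, "biobricks-ai", "hgnc", 0, seed = 6)
  report0 <- bb_install(setup$config, "hgnc")
  expect_identical(report0$fetched, 0L)
  expect_identical(report0$skipped_cached, 4L)
})

test_that("fetched plus skipped always equals the asset count", {
  # conservation across randomized registries
  for (seed in 1:5) {
    set.seed(seed)
    n_files <- sample(1:6, 1)
    files <- stats::setNames(
      rep("text", n_files),
      sprintf("brick/data_%d.bin", sample.int(20, n_files)))
    setup <- local_bb_setup(seed = seed, bricks = list(list(
      org = "o", name = "rand", versions = list(files))))
    report <- bb_install(setup$config, "o/rand")
    expect_identical(report$fetched + report$skipped_cached, n_files)
    second <- bb_install(setup$config, "o/rand")
    expect_identical(second$fetched, 0L)
    expect_identical(second$fetched + second$skipped_cached, n_files)
  }
})

test_that("bricks sharing a payload share one cache object", {
  bricks <- list(
    list(org = "o", name = "b1",
         versions = list(c("brick/shared.parquet" = "parquet",
                           "brick/own1.hdt" = "hdt"))),
    list(org = "o", name = "b2",
         versions = list(c("brick/shared.parquet" = "parquet",
                           "brick/own2.hdt" = "hdt#salt"))))
  setup <- local_bb_setup(bricks = bricks)
  bb_install(setup$config, "o/b1")
  bb_install(setup$config, "o/b2")
  a1 <- enumerate_assets(bb_local_path(setup$config,
                                       bb_resolve(setup$config, "o/b1")))
  a2 <- enumerate_assets(bb_local_path(setup$config,
                                       bb_resolve(setup$config, "o/b2")))
  expect_identical(a1$digest[a1$relpath == "brick/shared.parquet"],
                   a2$digest[a2$relpath == "brick/shared.parquet"])
  # brute-force oracle: distinct digests across both bricks
  expected <- length(unique(c(a1$digest, a2$digest)))
  stored <- list.files(file.path(setup$config$library, "cache"),
                       recursive = TRUE)
  expect_length(stored, expected)
  expect_length(stored, 3L)
})

test_that("a corrupted registry object aborts with an integrity error", {
  setup <- local_bb_setup()
  backend <- local_registry(setup$registry)
  head <- registry_resolve_head(backend, "biobricks-ai", "hgnc")
  tree <- file.path(setup$registry, "biobricks-ai", "hgnc", head)
  lock <- parse_lock(paste(readLines(file.path(tree, "dvc.lock")),
                           collapse = "\n"))
  digest <- lock$stages$build$outs$md5[1]
  obj <- file.path(setup$registry, "objects", substr(digest, 1, 2),
                   substr(digest, 3, 32))
  writeBin(charToRaw("corrupted bytes"), obj)
  err <- expect_error(bb_install(setup$config, "hgnc"),
                      class = "bb_integrity_error")
  expect_match(conditionMessage(err), "integrity")
  # failed install leaves no half-installed repository behind
  expect_length(bb_list_installed(setup$config), 0L)
})

test_that("assets_view maps identifiers to verifiable payload paths", {
  setup <- local_bb_setup()
  bb_install(setup$config, "hgnc")
  ns <- bb_assets(setup$config, "hgnc")
  expect_true("hgnc_complete_set_parquet" %in% names(ns))
  expect_true(all(file.exists(ns)))
  expect_silent(ns2 <- bb_assets(setup$config, "hgnc", verify = TRUE))
  # tamper with a payload: verification must catch it
  target <- ns[["hgnc_complete_set_parquet"]]
  unlink(target)  # replace the link with divergent content
  writeBin(charToRaw("not the payload"), target)
  expect_error(bb_assets(setup$config, "hgnc", verify = TRUE),
               class = "bb_integrity_error")
})

test_that("assets_view without a commit picks the newest installed version", {
  setup <- local_bb_setup()
  bb_install(setup$config, "hgnc")
  v1 <- bb_resolve(setup$config, "hgnc")$commit
  fixture_grow_brick(setup$registry, "biobricks-ai", "hgnc", 1, seed = 9)
  bb_install(setup$config, "hgnc")
  v2 <- bb_resolve(setup$config, "hgnc")$commit
  ns <- bb_assets(setup$config, "hgnc")
  expect_identical(attr(ns, "commit"), v2)
  ns1 <- bb_assets(setup$config, "hgnc", commit = v1)
  expect_identical(attr(ns1, "commit"), v1)
  expect_error(bb_assets(setup$config, "never-installed"),
               class = "bb_not_installed_error")
})

test_that("init creates dependency tracking once and never clobbers", {
  wd <- withr::local_tempdir()
  created <- bb_init(wd)
  expect_length(created, 2L)
  expect_true(file.exists(file.path(wd, ".bb", "dependencies.txt")))
  expect_length(bb_init(wd), 0L)
  writeLines("org/name abcde1", file.path(wd, ".bb", "dependencies.txt"))
  bb_init(wd)
  expect_identical(readLines(file.path(wd, ".bb", "dependencies.txt")),
                   "org/name abcde1")
})

test_that("add records full commits and replaces same-brick entries", {
  setup <- local_bb_setup()
  wd <- file.path(setup$td, "work"); dir.create(wd)
  head1 <- bb_resolve(setup$config, "hgnc")$commit
  deps <- bb_add(setup$config, wd, "hgnc")
  expect_identical(deps$entries$commit, head1)
  expect_identical(deps$entries$organization, "biobricks-ai")
  # an explicit prefix is stored as the full identifier
  deps <- bb_add(setup$config, wd, "hgnc", substr(head1, 1, 6))
  expect_identical(deps$entries$commit, head1)
  expect_equal(nrow(deps$entries), 1L)
  # a newer commit replaces, never duplicates
  fixture_grow_brick(setup$registry, "biobricks-ai", "hgnc", 1, seed = 3)
  head2 <- bb_resolve(setup$config, "hgnc")$commit
  deps <- bb_add(setup$config, wd, "hgnc")
  expect_equal(nrow(deps$entries), 1L)
  expect_identical(deps$entries$commit, head2)
})

test_that("pull installs missing dependencies and skips installed ones", {
  bricks <- list(
    list(org = "o", name = "b1",
         versions = list(c("brick/a.parquet" = "parquet"))),
    list(org = "o", name = "b2",
         versions = list(c("brick/b.hdt" = "hdt"))))
  setup <- local_bb_setup(bricks = bricks)
  wd <- file.path(setup$td, "work"); dir.create(wd)
  bb_add(setup$config, wd, "o/b1")
  bb_add(setup$config, wd, "o/b2")
  bb_install(setup$config, "o/b1")
  reports <- bb_pull(setup$config, wd)
  expect_length(reports, 2L)
  fetched <- vapply(reports, `[[`, 0L, "fetched")
  names(fetched) <- vapply(reports, function(r) r$ref$name, "")
  expect_identical(unname(fetched[c("b1", "b2")]), c(0L, 1L))

  # empty dependency file pulls nothing
  wd2 <- file.path(setup$td, "work2"); dir.create(wd2)
  bb_init(wd2)
  expect_length(bb_pull(setup$config, wd2), 0L)
})

test_that("pull attempts every entry before summarising failures", {
  setup <- local_bb_setup(bricks = list(
    list(org = "o", name = "real",
         versions = list(c("brick/a.parquet" = "parquet")))))
  wd <- file.path(setup$td, "work"); dir.create(wd)
  bb_init(wd)
  head <- bb_resolve(setup$config, "o/real")$commit
  writeLines(c("o/ghost abcdef1234", paste("o/real", head)),
             file.path(wd, ".bb", "dependencies.txt"))
  err <- expect_error(bb_pull(setup$config, wd), class = "bb_backend_error")
  expect_match(conditionMessage(err), "ghost")
  # the resolvable entry was still installed
  expect_length(bb_list_installed(setup$config), 1L)
  expect_length(err$reports, 1L)
})
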