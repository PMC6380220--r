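test_that("plan_shards deals chunks round-robin, every file exactly once", {
  files <- sprintf("f%03d.sdf", 1:36)
  plan <- plan_shards(files, workers = 2L)
  expect_length(plan, 2L)
  expect_equal(lengths(plan), c(1L, 1L))
  expect_equal(plan[[1L]][[1L]], files[1:18])
  expect_equal(plan[[2L]][[1L]], files[19:36])

  plan1 <- plan_shards("only.sdf", workers = 8L)
  expect_equal(sum(lengths(plan1)), 1L)
  expect_equal(plan1[[1L]][[1L]], "only.sdf")

  files <- sprintf("g%03d.sdf", 1:100)
  plan <- plan_shards(files, workers = 7L, chunk_size = 18L)
  got <- unlist(plan)
  expect_setequal(got, files)
  expect_length(got, 100L)
})

test_that("dedupe_obsolete keeps the last occurrence per cid", {
  mk <- function(cid) {
    m <- builtins$water
    m$cid <- cid
    m
  }
  res <- dedupe_obsolete(list(mk("A"), mk("A"), mk("A")))
  expect_length(res$kept, 1L)
  expect_equal(nrow(res$superseded), 2L)
  expect_equal(res$superseded$position, c(1L, 2L))

  res <- dedupe_obsolete(list(mk("A"), mk("B"), mk("C")))
  expect_length(res$kept, 3L)
  expect_equal(nrow(res$superseded), 0L)

  # interleaved duplicates: survivor determined by overall read order
  res <- dedupe_obsolete(list(mk("A"), mk("B"), mk("A"), mk("B")))
  expect_equal(vapply(res$kept, function(m) m$cid, ""), c("A", "B"))
  expect_equal(res$superseded$position, c(1L, 2L))
})

test_that("run_batch over an empty directory yields empty outputs", {
  ind <- withr::local_tempdir()
  outd <- withr::local_tempdir()
  s <- run_batch(ind, outd)
  expect_equal(s$entries_total, 0L)
  expect_equal(s$entries_flagged, 0L)
  expect_true(file.exists(file.path(outd, "summary.json")))
  expect_length(readLines(file.path(outd, "flagged_stereochemistry.txt")), 0L)
})

test_that("run_batch audits a corpus, writes conserved flag lists, resumes", {
  ind <- withr::local_tempdir()
  outd <- withr::local_tempdir()
  truth <- make_corpus(12, seed = 77, discrepancy_rate = 0.25, ind,
                       records_per_file = 5L)
  expect_equal(sum(truth$kind != "permute_atoms"), 3L)
  s <- run_batch(ind, outd, batch_config(seed = 77))
  expect_equal(s$entries_audited, 12L)
  expect_equal(s$entries_flagged, 3L)

  # conservation: summary counts equal flagged-list row counts
  for (ct in names(s$flagged_by_category)) {
    expect_length(readLines(file.path(outd,
                                      sprintf("flagged_%s.txt", ct))),
                  s$flagged_by_category[[ct]])
  }

  # outputs table carries the 11 fields
  outputs <- read.csv(file.path(outd, "outputs.csv"),
                      colClasses = "character")
  expect_equal(ncol(outputs), 11L)
  expect_equal(nrow(outputs), 12L)
  expect_true(all(startsWith(outputs$inchi, "InChI=1S")))

  # metadata table: cid unique, four columns
  meta <- read.csv(file.path(outd, "meta_data.csv"),
                   colClasses = "character")
  expect_equal(ncol(meta), 4L)
  expect_false(anyDuplicated(meta$cid) > 0)

  # resume: a second run skips everything and rewrites identical bytes
  before <- vapply(sort(list.files(outd, full.names = TRUE)),
                   function(f) paste(readLines(f, warn = FALSE),
                                     collapse = "\n"), "")
  s2 <- run_batch(ind, outd, batch_config(seed = 77))
  after <- vapply(sort(list.files(outd, full.names = TRUE)),
                  function(f) paste(readLines(f, warn = FALSE),
                                    collapse = "\n"), "")
  expect_identical(before, after)
  expect_equal(s2$entries_processed_this_run, 0L)
})

test_that("run_batch output is independent of worker count", {
  ind <- withr::local_tempdir()
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  make_corpus(8, seed = 5, discrepancy_rate = 0.25, ind,
              records_per_file = 3L)
  run_batch(ind, out1, batch_config(workers = 1L, seed = 5))
  run_batch(ind, out2, batch_config(workers = 4L, chunk_size = 2L, seed = 5))
  for (f in c("outputs.csv", "reports.csv", "meta_data.csv",
              "flagged_charge.txt", "flagged_stereochemistry.txt")) {
    expect_identical(readLines(file.path(out1, f), warn = FALSE),
                     readLines(file.path(out2, f), warn = FALSE), info = f)
  }
})

test_that("unreadable records are logged and the run continues", {
  ind <- withr::local_tempdir()
  outd <- withr::local_tempdir()
  good <- builtins$water
  good$cid <- "W1"
  good$properties <- list(PUBCHEM_COMPOUND_CID = "W1")
  bad <- water_sdf_lines
  bad[4] <- "  X  2  0  0  0  0  0  0  0  0999 V2000"
  writeLines(c(strsplit(write_sdf(good), "\n")[[1L]], bad),
             file.path(ind, "mixed.sdf"))
  s <- run_batch(ind, outd)
  expect_equal(s$entries_audited, 1L)
  expect_equal(s$read_errors, 1L)
  errs <- read.csv(file.path(outd, "errors.csv"))
  expect_equal(nrow(errs), 1L)
})

test_that("2D-only entries are listed and skipped", {
  ind <- withr::local_tempdir()
  outd <- withr::local_tempdir()
  flat <- builtins$glycine
  flat$atoms$z <- 0
  flat <- molecule(flat$atoms, flat$bonds, cid = "FLAT1", is_3d = FALSE)
  flat$properties <- list(PUBCHEM_COMPOUND_CID = "FLAT1")
  writeLines(write_sdf(flat), file.path(ind, "flat.sdf"))
  s <- run_batch(ind, outd)
  expect_equal(s$entries_skipped_2d, 1L)
  expect_equal(s$entries_audited, 0L)
  expect_equal(readLines(file.path(outd, "skipped_2d_only.txt")), "FLAT1")
})

test_that("the CLI dispatches check-one and fixtures", {
  ind <- withr::local_tempdir()
  f <- file.path(ind, "one.sdf")
  writeLines(write_sdf(builtins$water), f)
  expect_output(audit_cli(c("check-one", f,
                            "--deposited-inchi", "InChI=1S/H2O/h1H2")),
                "discrepancy_report")
  outd <- withr::local_tempdir()
  audit_cli(c("fixtures", "--n", "4", "--seed", "3", "--out", outd,
              "--rate", "0.25"))
  expect_true(file.exists(file.path(outd, "truth.csv")))
  expect_equal(nrow(read.csv(file.path(outd, "truth.csv"))), 4L)
})
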