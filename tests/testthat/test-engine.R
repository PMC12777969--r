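# Engine tests run on tiny hand-built SAM batches for speed; the full
# simulated-fixture equivalences live in test-acceptance.R.

tiny_batches <- function(dir, n = 4L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (b in seq_len(n)) {
    lines <- vapply(1:3, function(i) {
      sam_line(sprintf("b%d_r%d", b, i), 0, "chr1",
               10000 * b + i * 10 + 1, 60, "2000M50D2000M")
    }, character(1))
    paths[b] <- write_sam(lines, file.path(dir, sprintf("b%d.sam", b)))
  }
  paths
}

test_that("stabilized files are detected once and in order", {
  dir <- withr::local_tempdir()
  f1 <- write_sam(sam_line("r", 0, "chr1", 1, 60, "100M"),
                  file.path(dir, "a.sam"))
  f2 <- write_sam(sam_line("r", 0, "chr1", 1, 60, "100M"),
                  file.path(dir, "b.sam"))
  Sys.setFileTime(f1, Sys.time() - 10)
  ready <- detect_stable_files(dir, stability_window = 0.05)
  expect_equal(basename(ready$path), c("a.sam", "b.sam"))  # mtime order
  ready <- detect_stable_files(dir, known = "a.sam", stability_window = 0.05)
  expect_equal(basename(ready$path), "b.sam")
  # temp files are never ready
  file.copy(f1, file.path(dir, "c.sam.tmp123"))
  ready <- detect_stable_files(dir, stability_window = 0.05)
  expect_false(any(grepl("tmp", basename(ready$path))))
})

test_that("a file growing between polls is not ready", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "grow.sam")
  writeLines("@HD\tVN:1.6", path)
  expect_equal(nrow(detect_stable_files(dir, stability_window = 0.05)), 1)
  # schedule an append to land inside the stability window
  system(sprintf("(sleep 0.1; echo x >> %s) &", shQuote(path)))
  expect_equal(nrow(detect_stable_files(dir, stability_window = 0.5)), 0)
})

test_that("processing a batch updates store, depth and ledger atomically", {
  dir <- withr::local_tempdir()
  paths <- tiny_batches(dir, 1L)
  state <- engine_state(two_contigs())
  state <- process_batch(paths[1], state)
  expect_equal(nrow(state$ledger), 1)
  expect_equal(state$ledger$n_records, 3L)
  expect_equal(nrow(state$store), state$ledger$n_signatures)
  expect_gt(state$depth$total_bases, 0)
  expect_error(process_batch(paths[1], state),
               class = "svstream_ledger_error")
})

test_that("checkpoints round-trip the complete engine state", {
  dir <- withr::local_tempdir()
  paths <- tiny_batches(dir, 2L)
  state <- engine_state(two_contigs())
  for (p in paths) state <- process_batch(p, state)
  state$rate_history <- c(0.5, 0.75)
  state$cycle_index <- 2L
  cp <- file.path(dir, "checkpoint.json")
  save_checkpoint(state, cp)
  restored <- load_checkpoint(cp)
  for (field in names(state)) {
    expect_equal(restored[[field]], state[[field]], info = field)
  }
})

test_that("corrupt or unknown-version checkpoints fail distinguishably", {
  cp <- tempfile()
  writeLines('{"version": "svstream-checkpo', cp)  # truncated JSON
  expect_error(load_checkpoint(cp), class = "svstream_corrupt_checkpoint")
  writeLines('{"version": "svstream-checkpoint-99"}', cp)
  expect_error(load_checkpoint(cp), class = "svstream_checkpoint_version")
  expect_error(load_checkpoint(tempfile()),
               class = "svstream_checkpoint_error")
})

test_that("a kill between temp write and rename leaves the old checkpoint", {
  dir <- withr::local_tempdir()
  state <- engine_state(two_contigs())
  cp <- file.path(dir, "checkpoint.json")
  save_checkpoint(state, cp)
  # a stray temp file from an interrupted second save
  writeLines("{garbage", paste0(cp, ".tmp9999"))
  restored <- load_checkpoint(cp)
  expect_equal(restored$cycle_index, 0L)
  rec <- recover_engine(dir, dir, two_contigs())
  expect_length(list.files(dir, pattern = "tmp"), 0)  # stray temp cleaned
})

test_that("recovery re-queues unprocessed batches and drops partial output", {
  watch <- withr::local_tempdir()
  out <- withr::local_tempdir()
  paths <- tiny_batches(watch, 4L)
  state <- engine_state(two_contigs())
  for (p in paths[1:2]) state <- process_batch(p, state)
  save_checkpoint(state, file.path(out, "checkpoint.json"))
  writeLines("partial", file.path(out, "cycle_0000.vcf"))  # never checkpointed
  rec <- recover_engine(watch, out, stability_window = 0.05)
  expect_equal(basename(rec$queue$path), c("b3.sam", "b4.sam"))
  expect_false(file.exists(file.path(out, "cycle_0000.vcf")))
  expect_equal(nrow(rec$state$ledger), 2)
})

test_that("recovery without a checkpoint queues everything fresh", {
  watch <- withr::local_tempdir()
  out <- withr::local_tempdir()
  tiny_batches(watch, 4L)
  rec <- recover_engine(watch, out, two_contigs(), stability_window = 0.05)
  expect_equal(nrow(rec$state$ledger), 0)
  expect_equal(nrow(rec$queue), 4)
})

test_that("a mutated ledgered batch is a hard checksum error", {
  watch <- withr::local_tempdir()
  out <- withr::local_tempdir()
  paths <- tiny_batches(watch, 2L)
  state <- engine_state(two_contigs())
  state <- process_batch(paths[1], state)
  save_checkpoint(state, file.path(out, "checkpoint.json"))
  write("mutation", paths[1], append = TRUE)
  expect_error(recover_engine(watch, out, stability_window = 0.05),
               regexp = "b1.sam", class = "svstream_checksum_error")
})

test_that("unreadable batches are retried then quarantined, state unchanged", {
  watch <- withr::local_tempdir()
  out <- withr::local_tempdir()
  tiny_batches(watch, 2L)
  writeLines("not a sam file at all", file.path(watch, "b0.sam"))
  expect_warning(
    res <- run_engine(watch, out, two_contigs(), max_retries = 3L,
                      stability_window = 0.02, poll_interval = 0.02),
    regexp = "quarantined"
  )
  expect_equal(res$quarantined, "b0.sam")
  expect_equal(nrow(res$state$ledger), 2)  # good batches still processed
})

test_that("ledger signature counts reconcile with the store", {
  watch <- withr::local_tempdir()
  out <- withr::local_tempdir()
  tiny_batches(watch, 3L)
  res <- run_engine(watch, out, two_contigs(), stability_window = 0.02,
                    poll_interval = 0.02)
  expect_equal(sum(res$state$ledger$n_signatures), nrow(res$state$store))
})

test_that("rerunning a cycle with no new batches reproduces the VCF bytes", {
  watch <- withr::local_tempdir()
  out <- withr::local_tempdir()
  paths <- tiny_batches(watch, 2L)
  state <- engine_state(two_contigs())
  for (p in paths) state <- process_batch(p, state)
  c1 <- run_cycle(state, out)
  c2 <- run_cycle(state, out)  # same pre-cycle state again
  expect_identical(readLines(c1$vcf), readLines(c2$vcf))
})

test_that("batch arrival order does not change the final callset", {
  watch1 <- withr::local_tempdir(); out1 <- withr::local_tempdir()
  watch2 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  tiny_batches(watch1, 3L)
  tiny_batches(watch2, 3L)
  r1 <- call_offline(list.files(watch1, full.names = TRUE), two_contigs())
  r2 <- call_offline(rev(list.files(watch2, full.names = TRUE)),
                     two_contigs())
  expect_identical(r1$calls, r2$calls)
})
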