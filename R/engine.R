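# The streaming engine. State is a plain list (ledger of processed batches
# with content checksums, cumulative signature store, depth track, cycle
# counter, detection-rate history) checkpointed as versioned JSON after every
# batch and every cycle. Recovery loads the last complete checkpoint,
# verifies ledger checksums against the files on disk, clears partial output
# for the current cycle and re-queues unprocessed batches — the resumed run's
# final callset is identical to an uninterrupted run's.

CHECKPOINT_VERSION <- "svstream-checkpoint-1"

#' Create a fresh engine state
#'
#' @param contigs [contig_table()].
#' @param eparams [extraction_params()].
#' @param cparams [cluster_params()].
#' @param bin_size Depth-track bin width in bp.
#' @return A list of class `svstream_state`.
#' @export
engine_state <- function(contigs, eparams = extraction_params(),
                         cparams = cluster_params(), bin_size = 1000L) {
  structure(
    list(
      version = CHECKPOINT_VERSION,
      contigs = contigs,
      eparams = eparams,
      cparams = cparams,
      ledger = data.frame(path = character(0), checksum = character(0),
                          n_records = integer(0), n_signatures = integer(0),
                          stringsAsFactors = FALSE),
      store = empty_signature_frame(),
      depth = depth_track(contigs, bin_size),
      cycle_index = 0L,
      rate_history = numeric(0)
    ),
    class = "svstream_state"
  )
}

# Content checksum: file length plus md5 of the first and last 64 KiB.
# Detects truncation and in-place mutation without re-reading whole batches.
file_checksum <- function(path) {
  size <- file.size(path)
  chunk <- 65536L
  con <- file(path, open = "rb")
  on.exit(close(con))
  head_bytes <- readBin(con, "raw", n = min(size, chunk))
  tail_bytes <- raw(0)
  if (size > chunk) {
    seek(con, where = max(size - chunk, 0))
    tail_bytes <- readBin(con, "raw", n = chunk)
  }
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeBin(c(head_bytes, tail_bytes), tmp)
  paste0(size, "-", unname(tools::md5sum(tmp)))
}

#' Detect stabilized batch files in a watch directory
#'
#' A file is ready when its size and modification time are unchanged across
#' two polls separated by `stability_window` seconds and its basename is not
#' in `known`. Temporary files (`*.tmp*`) are ignored; files vanishing
#' between polls are dropped silently. Ready files are ordered by
#' (modification time, name).
#'
#' @param watch_dir Directory to scan.
#' @param known Character vector of already-processed or queued basenames.
#' @param stability_window Seconds between the two polls.
#' @param pattern Filename regexp for batch files.
#' @return data.frame with `path`, `size_bytes`, `mtime`.
#' @export
detect_stable_files <- function(watch_dir, known = character(0),
                                stability_window = 0.1,
                                pattern = "\\.(sam|bam)$") {
  poll <- function() {
    f <- list.files(watch_dir, pattern = pattern, full.names = TRUE)
    f <- f[!grepl("\\.tmp", basename(f))]
    info <- file.info(f)
    data.frame(path = f, size = info$size, mtime = as.numeric(info$mtime),
               stringsAsFactors = FALSE)
  }
  p1 <- poll()
  Sys.sleep(stability_window)
  p2 <- poll()
  m <- merge(p1, p2, by = "path")
  ready <- m[!is.na(m$size.x) & !is.na(m$size.y) &
               m$size.x == m$size.y & m$mtime.x == m$mtime.y &
               !(basename(m$path) %in% known), , drop = FALSE]
  ready <- ready[order(ready$mtime.y, basename(ready$path)), , drop = FALSE]
  data.frame(path = ready$path, size_bytes = ready$size.y,
             mtime = ready$mtime.y, stringsAsFactors = FALSE)
}

#' Process one alignment batch into the engine state
#'
#' Reads the batch, appends its signatures to the store, adds its aligned
#' bases to the depth track and records (basename, content checksum, counts)
#' in the processed ledger. The returned state is a value: the update becomes
#' durable only when the caller checkpoints it, so a crash in between leaves
#' the batch unprocessed rather than half-applied.
#'
#' @param path Batch file (SAM/BAM).
#' @param state [engine_state()].
#' @return The updated state. Re-processing a ledgered batch is an error of
#'   class `svstream_ledger_error`; unreadable input raises
#'   `svstream_batch_error` (recoverable: the engine re-queues it).
#' @export
process_batch <- function(path, state) {
  base <- basename(path)
  if (base %in% state$ledger$path) {
    stop_svstream(paste0("batch already processed: ", base),
                  "svstream_ledger_error")
  }
  checksum <- file_checksum(path)
  records <- read_alignment_batch(path, state$contigs,
                                  state$eparams$min_mapq)
  sigs <- extract_signatures(records, state$contigs, state$eparams)
  state$store <- rbind(state$store, sigs)
  state$depth <- depth_add(state$depth, records)
  state$ledger <- rbind(state$ledger, data.frame(
    path = base, checksum = checksum, n_records = nrow(records),
    n_signatures = nrow(sigs), stringsAsFactors = FALSE
  ))
  state
}

#' Run one clustering/genotyping cycle
#'
#' Calls [call_variants()] on the accumulated state, writes the interim VCF
#' `cycle_<index>.vcf`, computes the detection-rate feedback report when a
#' truth set is configured, increments the cycle counter and checkpoints.
#'
#' @param state [engine_state()].
#' @param out_dir Output directory (interim VCFs + checkpoint).
#' @param truth Optional AF-filtered truth data.frame; `NULL` marks the
#'   report absent (no stop signal possible).
#' @param criteria [match_criteria()] for the detection-rate statistic.
#' @param stop_threshold Detection-rate threshold for the stop
#'   recommendation; `NULL` disables it.
#' @param patience Consecutive qualifying cycles required by [should_stop()].
#' @param vcf_opts List of [write_vcf()] options (`sample`, `filedate`,
#'   `source`).
#' @return List with the updated `state`, the interim `vcf` path and the
#'   feedback `report`.
#' @export
run_cycle <- function(state, out_dir, truth = NULL,
                      criteria = match_criteria(), stop_threshold = NULL,
                      patience = 2L, vcf_opts = list()) {
  calls <- call_variants(state$store, state$depth, state$contigs,
                         state$cparams)
  vcf <- file.path(out_dir, sprintf("cycle_%04d.vcf", state$cycle_index))
  do.call(write_vcf, c(list(calls = calls, contigs = state$contigs,
                            path = vcf), vcf_opts))
  report <- list(
    cycle_index = state$cycle_index,
    mean_depth = mean_depth(state$depth),
    truth_available = !is.null(truth) && nrow(truth) > 0,
    n_truth = NA_integer_, n_matched = NA_integer_,
    detection_rate = NA_real_, stop_recommended = FALSE
  )
  if (report$truth_available) {
    dr <- detection_rate(calls, truth, criteria)
    state$rate_history <- c(state$rate_history, dr$rate)
    report$n_truth <- nrow(truth)
    report$n_matched <- dr$n_matched
    report$detection_rate <- dr$rate
    if (!is.null(stop_threshold)) {
      report$stop_recommended <- should_stop(state$rate_history,
                                             stop_threshold, patience)
    }
  }
  state$cycle_index <- state$cycle_index + 1L
  save_checkpoint(state, file.path(out_dir, "checkpoint.json"))
  list(state = state, vcf = vcf, report = report)
}

state_to_list <- function(state) {
  list(
    version = state$version,
    contigs = list(name = state$contigs$name, length = state$contigs$length),
    eparams = unclass(state$eparams),
    cparams = list(
      max_bias = as.list(state$cparams$max_bias),
      support_ratio = state$cparams$support_ratio,
      min_support_floor = state$cparams$min_support_floor,
      min_support_cap = state$cparams$min_support_cap,
      genotype_eps = state$cparams$genotype_eps
    ),
    ledger = as.list(state$ledger),
    store = as.list(state$store),
    depth = list(
      bin_size = state$depth$bin_size,
      bins = state$depth$bins,
      genome_length = state$depth$genome_length,
      total_bases = state$depth$total_bases
    ),
    cycle_index = state$cycle_index,
    rate_history = state$rate_history
  )
}

list_to_state <- function(x) {
  contigs <- contig_table(x$contigs$name, x$contigs$length)
  eparams <- do.call(extraction_params, x$eparams)
  cparams <- cluster_params(
    max_bias = unlist(x$cparams$max_bias),
    support_ratio = x$cparams$support_ratio,
    min_support_floor = x$cparams$min_support_floor,
    min_support_cap = x$cparams$min_support_cap,
    genotype_eps = x$cparams$genotype_eps
  )
  ledger <- data.frame(
    path = as.character(unlist(x$ledger$path) %||% character(0)),
    checksum = as.character(unlist(x$ledger$checksum) %||% character(0)),
    n_records = as.integer(unlist(x$ledger$n_records) %||% integer(0)),
    n_signatures = as.integer(unlist(x$ledger$n_signatures) %||% integer(0)),
    stringsAsFactors = FALSE
  )
  store <- empty_signature_frame()
  if (length(x$store$svtype)) {
    store <- data.frame(
      svtype = as.character(x$store$svtype),
      contig = as.character(x$store$contig),
      start = as.integer(x$store$start),
      length = as.integer(x$store$length),
      mate_contig = as.character(x$store$mate_contig),
      mate_pos = as.integer(x$store$mate_pos),
      read_id = as.character(x$store$read_id),
      origin = as.character(x$store$origin),
      stringsAsFactors = FALSE
    )
  }
  depth <- structure(
    list(
      bin_size = as.integer(x$depth$bin_size),
      bins = lapply(x$depth$bins, as.numeric),
      genome_length = as.numeric(x$depth$genome_length),
      total_bases = as.numeric(x$depth$total_bases)
    ),
    class = "svstream_depth"
  )
  structure(
    list(version = x$version, contigs = contigs, eparams = eparams,
         cparams = cparams, ledger = ledger, store = store, depth = depth,
         cycle_index = as.integer(x$cycle_index),
         rate_history = as.numeric(unlist(x$rate_history) %||% numeric(0))),
    class = "svstream_state"
  )
}

#' Save / load an engine checkpoint
#'
#' The complete engine state is written as versioned JSON to a temporary file
#' and renamed into place, so a crash mid-write leaves the previous complete
#' checkpoint intact. Loading a truncated or unparsable file raises
#' `svstream_corrupt_checkpoint`; an unknown version string raises
#' `svstream_checkpoint_version` (both subclasses of
#' `svstream_checkpoint_error`).
#'
#' @param state [engine_state()].
#' @param path Checkpoint file path.
#' @return `save_checkpoint`: `path` invisibly; `load_checkpoint`: the
#'   reconstructed state.
#' @export
save_checkpoint <- function(state, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  jsonlite::write_json(state_to_list(state), tmp, digits = NA,
                       auto_unbox = TRUE, na = "null", null = "null")
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    stop_svstream(paste0("no checkpoint at ", path),
                  c("svstream_corrupt_checkpoint", "svstream_checkpoint_error"))
  }
  x <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) {
      stop_svstream(
        paste0("corrupt checkpoint '", path, "': ", conditionMessage(e)),
        c("svstream_corrupt_checkpoint", "svstream_checkpoint_error")
      )
    }
  )
  if (!identical(x$version, CHECKPOINT_VERSION)) {
    stop_svstream(
      paste0("unknown checkpoint version: ", x$version %||% "<missing>"),
      c("svstream_checkpoint_version", "svstream_checkpoint_error")
    )
  }
  tryCatch(list_to_state(x), error = function(e) {
    stop_svstream(
      paste0("corrupt checkpoint '", path, "': ", conditionMessage(e)),
      c("svstream_corrupt_checkpoint", "svstream_checkpoint_error")
    )
  })
}

#' Recover engine state from an output directory
#'
#' Loads the last complete checkpoint (a corrupt one falls back to a fresh
#' state with everything re-queued), verifies each ledger entry's content
#' checksum against the file in `watch_dir` (a mismatch is a hard error: the
#' input was mutated mid-run), deletes stray checkpoint temp files and any
#' interim VCF at or beyond the checkpointed cycle index (those may be
#' partial), and queues every stabilized batch absent from the ledger.
#'
#' @param watch_dir Directory of batch files.
#' @param out_dir Engine output directory holding `checkpoint.json`.
#' @param contigs,eparams,cparams Used to build a fresh state when no usable
#'   checkpoint exists; `contigs` is required in that case.
#' @param stability_window Passed to [detect_stable_files()].
#' @return List with `state` and `queue` (data.frame of batches to process).
#' @export
recover_engine <- function(watch_dir, out_dir, contigs = NULL,
                           eparams = extraction_params(),
                           cparams = cluster_params(),
                           stability_window = 0.1) {
  cp <- file.path(out_dir, "checkpoint.json")
  state <- NULL
  if (file.exists(cp)) {
    state <- tryCatch(
      load_checkpoint(cp),
      svstream_checkpoint_error = function(e) {
        warning("unusable checkpoint; rebuilding from scratch: ",
                conditionMessage(e))
        NULL
      }
    )
  }
  if (is.null(state)) {
    if (is.null(contigs)) {
      stop_svstream("no usable checkpoint and no contig table supplied",
                    "svstream_recover_error")
    }
    state <- engine_state(contigs, eparams, cparams)
  }
  # input integrity: every ledgered batch must still be on disk, unchanged
  for (i in seq_len(nrow(state$ledger))) {
    f <- file.path(watch_dir, state$ledger$path[i])
    if (!file.exists(f) || file_checksum(f) != state$ledger$checksum[i]) {
      stop_svstream(
        paste0("ledgered batch missing or mutated on disk: ",
               state$ledger$path[i]),
        "svstream_checksum_error"
      )
    }
  }
  # stray temp checkpoints from an interrupted save
  unlink(list.files(out_dir, pattern = "^checkpoint\\.json\\.tmp",
                    full.names = TRUE))
  # interim VCFs at/after the checkpointed cycle may be partial: regenerate
  vcfs <- list.files(out_dir, pattern = "^cycle_[0-9]+\\.vcf", full.names = TRUE)
  idx <- as.integer(sub("^cycle_([0-9]+)\\.vcf.*$", "\\1", basename(vcfs)))
  unlink(vcfs[idx >= state$cycle_index])
  queue <- detect_stable_files(watch_dir, known = state$ledger$path,
                               stability_window = stability_window)
  list(state = state, queue = queue)
}

#' Run the streaming engine over a watch directory
#'
#' The real-time loop: poll for stabilized batch files, process each new
#' batch (checkpointing after every one), run a clustering cycle once the
#' queue drains (or after every batch with `cycle_every_batch`), emit interim
#' VCFs and feedback reports, and exit when the directory stays idle for
#' `max_idle_polls` polls or a stop recommendation fires. Unreadable batches
#' are retried up to `max_retries` times, then quarantined with a warning.
#' Calling with the same `out_dir` after an interruption resumes from the
#' checkpoint via [recover_engine()]; the final callset is identical to an
#' uninterrupted run's.
#'
#' @param watch_dir Directory into which batch SAM/BAM files arrive.
#' @param out_dir Output directory (interim VCFs, `final.vcf`,
#'   `checkpoint.json`).
#' @param contigs [contig_table()]; may be `NULL` when resuming.
#' @param eparams,cparams Extraction and clustering parameters.
#' @param truth Optional truth data.frame (already AF-filtered), or a VCF
#'   path to read and filter with `af_min`.
#' @param af_min AF filter applied when `truth` is a path.
#' @param criteria [match_criteria()].
#' @param stop_threshold,patience Early-stop rule; `NULL` threshold disables.
#' @param stability_window,poll_interval,max_idle_polls Polling behaviour.
#' @param cycle_every_batch Run a cycle after every batch instead of after
#'   every queue drain (finer-grained rate history).
#' @param stop_after_batches Return right after this many batch checkpoints
#'   without running a final cycle — simulates a crash at that point for
#'   recovery testing.
#' @param max_retries Re-queue attempts for unreadable batches.
#' @param vcf_opts Options forwarded to [write_vcf()].
#' @return Invisibly, a list: `state`, `reports` (one per cycle),
#'   `final_vcf`, `interim_vcfs`, `quarantined`, `status`
#'   (`"done"`/`"stopped"`/`"interrupted"`).
#' @export
run_engine <- function(watch_dir, out_dir, contigs = NULL,
                       eparams = extraction_params(),
                       cparams = cluster_params(),
                       truth = NULL, af_min = 0.1,
                       criteria = match_criteria(),
                       stop_threshold = NULL, patience = 2L,
                       stability_window = 0.05, poll_interval = 0.05,
                       max_idle_polls = 2L, cycle_every_batch = FALSE,
                       stop_after_batches = NULL, max_retries = 3L,
                       vcf_opts = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lock <- file.path(out_dir, ".svstream.lock")
  if (file.exists(lock)) {
    warning("stale lock in ", out_dir, " (previous run crashed?); taking over")
  }
  writeLines(as.character(Sys.getpid()), lock)
  on.exit(unlink(lock), add = TRUE)

  if (is.character(truth) && length(truth) == 1L) {
    truth <- filter_truth(read_truth_vcf(truth), af_min)
  }
  rec <- recover_engine(watch_dir, out_dir, contigs, eparams, cparams,
                        stability_window)
  state <- rec$state
  known <- state$ledger$path
  retries <- integer(0)
  quarantined <- character(0)
  reports <- list()
  interim <- character(0)
  status <- "done"
  batches_done <- 0L
  pending_cycle <- FALSE
  idle <- 0L
  queue <- rec$queue

  do_cycle <- function(state) {
    cyc <- run_cycle(state, out_dir, truth = truth, criteria = criteria,
                     stop_threshold = stop_threshold, patience = patience,
                     vcf_opts = vcf_opts)
    reports[[length(reports) + 1L]] <<- cyc$report
    interim[length(interim) + 1L] <<- cyc$vcf
    cyc
  }

  repeat {
    if (!nrow(queue)) {
      if (pending_cycle) {
        cyc <- do_cycle(state)
        state <- cyc$state
        pending_cycle <- FALSE
        if (cyc$report$stop_recommended) { status <- "stopped"; break }
      }
      idle <- idle + 1L
      if (idle >= max_idle_polls) break
      Sys.sleep(poll_interval)
      queue <- detect_stable_files(watch_dir, known, stability_window)
      next
    }
    idle <- 0L
    stopped <- FALSE
    for (path in queue$path) {
      base <- basename(path)
      res <- tryCatch(process_batch(path, state),
                      svstream_batch_error = function(e) e)
      if (inherits(res, "svstream_batch_error")) {
        retries[base] <- (if (base %in% names(retries)) retries[[base]] else 0L) + 1L
        if (retries[[base]] > max_retries) {
          warning("quarantined unreadable batch after ", max_retries,
                  " retries: ", base)
          quarantined <- c(quarantined, base)
          known <- c(known, base)
        }
        next
      }
      state <- res
      save_checkpoint(state, file.path(out_dir, "checkpoint.json"))
      known <- c(known, base)
      batches_done <- batches_done + 1L
      pending_cycle <- TRUE
      if (!is.null(stop_after_batches) && batches_done >= stop_after_batches) {
        return(invisible(list(state = state, reports = reports,
                              final_vcf = NULL, interim_vcfs = interim,
                              quarantined = quarantined,
                              status = "interrupted")))
      }
      if (cycle_every_batch) {
        cyc <- do_cycle(state)
        state <- cyc$state
        pending_cycle <- FALSE
        if (cyc$report$stop_recommended) { stopped <- TRUE; break }
      }
    }
    if (stopped) { status <- "stopped"; break }
    queue <- detect_stable_files(watch_dir, known, stability_window)
  }

  if (pending_cycle) {
    cyc <- do_cycle(state)
    state <- cyc$state
  }
  final_vcf <- NULL
  if (length(interim)) {
    final_vcf <- file.path(out_dir, "final.vcf")
    file.copy(interim[length(interim)], final_vcf, overwrite = TRUE)
  }
  invisible(list(state = state, reports = reports, final_vcf = final_vcf,
                 interim_vcfs = interim, quarantined = quarantined,
                 status = status))
}

#' Offline single-pass SV calling
#'
#' Processes the given batches in order through the identical
#' extraction/accumulation path as the streaming engine and clusters once at
#' the end — the reference the streaming callset must equal.
#'
#' @param batch_paths Batch files in order.
#' @param contigs [contig_table()].
#' @param out_vcf Optional VCF output path.
#' @param eparams,cparams Parameters as in [run_engine()].
#' @param vcf_opts Options forwarded to [write_vcf()].
#' @return List with `calls` (data.frame), `state`, and `vcf` (path or NULL).
#' @export
call_offline <- function(batch_paths, contigs, out_vcf = NULL,
                         eparams = extraction_params(),
                         cparams = cluster_params(), vcf_opts = list()) {
  state <- engine_state(contigs, eparams, cparams)
  for (p in batch_paths) state <- process_batch(p, state)
  calls <- call_variants(state$store, state$depth, contigs, cparams)
  if (!is.null(out_vcf)) {
    do.call(write_vcf, c(list(calls = calls, contigs = contigs,
                              path = out_vcf), vcf_opts))
  }
  list(calls = calls, state = state, vcf = out_vcf)
}
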