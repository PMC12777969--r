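test_that("the reference generator is seed-deterministic", {
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  r1 <- make_reference(2, 20000, seed = 1, fasta = f1)
  r2 <- make_reference(2, 20000, seed = 1, fasta = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(r1$contigs$length, c(20000, 20000))
  r3 <- make_reference(2, 20000, seed = 2)
  expect_false(identical(r1$seqs, r3$seqs))
})

test_that("implanted SVs respect counts, spacing and contig bounds", {
  ref <- make_reference(2, 200000, seed = 1)
  spec <- sv_spec(n_del = 10, n_ins = 0, n_inv = 0, n_dup = 0, n_bnd = 0)
  svs <- sample_sv_set(ref$contigs, spec, seed = 5)
  expect_equal(nrow(svs), 10)
  expect_true(all(svs$svtype == "DEL"))
  for (ctg in unique(svs$contig)) {
    s <- svs[svs$contig == ctg, ]
    s <- s[order(s$pos), ]
    if (nrow(s) > 1) {
      gaps <- s$pos[-1] - (s$pos[-nrow(s)] + s$length[-nrow(s)])
      expect_true(all(gaps >= spec$spacing))
    }
    len <- ref$contigs$length[ref$contigs$name == ctg]
    expect_true(all(s$pos >= spec$margin & s$pos + s$length <= len - spec$margin))
  }
  expect_identical(svs, sample_sv_set(ref$contigs, spec, seed = 5))
})

test_that("breakends require two contigs", {
  ref <- make_reference(1, 100000, seed = 1)
  expect_error(sample_sv_set(ref$contigs, sv_spec(n_bnd = 1), seed = 1),
               class = "svstream_sim_error")
})

test_that("a noise-free homozygous deletion appears in every spanning read", {
  ref <- make_reference(1, 100000, seed = 3)
  svs <- data.frame(svtype = "DEL", contig = "ctg1", pos = 50000L,
                    length = 100L, zygosity = "hom", af = 0.5,
                    mate_contig = NA_character_, mate_pos = NA_integer_,
                    stringsAsFactors = FALSE)
  recs <- simulate_alignments(ref$contigs, svs,
                              sim_params(coverage = 10, jitter_sd = 0,
                                         dropout = 0, bg_indel_per_kb = 0),
                              seed = 4)
  spans <- GenomicAlignments::cigarWidthAlongReferenceSpace(recs$cigar)
  spanning <- recs$ref_start + 100L <= svs$pos &
    recs$ref_start + spans - 100L >= svs$pos + svs$length
  expect_gt(sum(spanning), 3)
  expect_true(all(grepl("100D", recs$cigar[spanning])))
  expect_false(any(grepl("D", recs$cigar[!spanning])))
})

test_that("read count approximates coverage over the genome", {
  ref <- make_reference(1, 200000, seed = 1)
  p <- sim_params(coverage = 15)
  recs <- simulate_alignments(ref$contigs, sample_sv_set(ref$contigs,
                                                         sv_spec(n_del = 2, n_ins = 0, n_inv = 0,
                                                                 n_dup = 0, n_bnd = 0),
                                                         seed = 2), p, seed = 9)
  n_reads <- length(unique(recs$read_id))
  expect_equal(n_reads, round(p$coverage * 200000 / p$read_len_mean))
})

test_that("batches are equal-size read splits that keep reads whole", {
  fx <- default_fixture()
  expect_length(fx$batch_paths, 10)
  per_batch <- lapply(fx$batch_paths, function(p) {
    recs <- read_alignment_batch(p, fx$contigs, min_mapq = 0L)
    unique(recs$read_id)
  })
  sizes <- lengths(per_batch)
  expect_true(max(sizes) - min(sizes[-length(sizes)]) <= 1)
  # no read id appears in two batches (primary + supplementary stay together)
  expect_false(any(duplicated(unlist(per_batch))))
})

test_that("the simulated run is deterministic under its seed", {
  d1 <- file.path(tempdir(), "svstream-det1")
  d2 <- file.path(tempdir(), "svstream-det2")
  spec <- sv_spec(n_del = 3, n_ins = 2, n_inv = 1, n_dup = 1, n_bnd = 1)
  p <- sim_params(coverage = 5)
  f1 <- simulate_run(d1, seed = 7, contig_length = 60000L, spec = spec,
                     p = p, n_batches = 3, write_fasta = FALSE)
  f2 <- simulate_run(d2, seed = 7, contig_length = 60000L, spec = spec,
                     p = p, n_batches = 3, write_fasta = FALSE)
  expect_identical(readLines(f1$truth_vcf), readLines(f2$truth_vcf))
  for (i in seq_along(f1$batch_paths)) {
    expect_identical(readLines(f1$batch_paths[i]),
                     readLines(f2$batch_paths[i]))
  }
})

test_that("noise-free evidence accounting: every spanning variant read signs", {
  fx <- noise_free_fixture()
  recs <- do.call(rbind, lapply(fx$batch_paths, read_alignment_batch,
                                contigs = fx$contigs))
  sigs <- extract_signatures(recs, fx$contigs)
  spans <- GenomicAlignments::cigarWidthAlongReferenceSpace(recs$cigar)
  for (i in which(fx$svs$svtype == "DEL")) {
    sv <- fx$svs[i, ]
    n_span <- sum(!recs$is_supplementary & recs$contig == sv$contig &
                    recs$ref_start + 100L <= sv$pos &
                    recs$ref_start + spans - 100L >= sv$pos + sv$length)
    hits <- sigs[sigs$svtype == "DEL" & sigs$contig == sv$contig &
                   abs(sigs$start - sv$pos) <= 50, ]
    expect_equal(nrow(hits), n_span)
    expect_true(all(hits$length == sv$length))  # jitter 0: exact lengths
  }
})
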