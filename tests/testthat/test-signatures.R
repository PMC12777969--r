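p_def <- extraction_params()

test_that("CIGAR deletions are anchored by reference-consumption arithmetic", {
  s <- cigar_signatures(make_rec(ref_start = 1000L, cigar = "100M50D100M"))
  expect_equal(s$svtype, "DEL")
  expect_equal(s$start, 1100L)
  expect_equal(s$length, 50L)

  expect_equal(
    nrow(cigar_signatures(make_rec(ref_start = 1000L, cigar = "100M20D100M"))),
    0
  )
})

test_that("same-type candidates merge across small spacers before the size filter", {
  # two 40 bp deletions split by a 10 bp match: merged to one 80 bp deletion
  s <- cigar_signatures(make_rec(ref_start = 1000L,
                                 cigar = "100M40D10M40D100M"))
  expect_equal(nrow(s), 1)
  expect_equal(s$start, 1100L)
  expect_equal(s$length, 80L)

  # two sub-threshold insertions merge into a reportable one at the
  # length-weighted mean anchor (half-up)
  s <- cigar_signatures(make_rec(ref_start = 0L, cigar = "100M20I100M25I100M"))
  expect_equal(s$svtype, "INS")
  expect_equal(s$length, 45L)
  expect_equal(s$start, floor((100 * 20 + 200 * 25) / 45 + 0.5))

  # beyond merge_dist they stay separate and both fail the size filter
  s <- cigar_signatures(make_rec(cigar = "100M20D700M20D100M"))
  expect_equal(nrow(s), 0)
})

test_that("segments are reconstructed from the primary and its SA tag", {
  # primary only
  segs <- read_segments(make_rec(cigar = "5000M"))
  expect_equal(nrow(segs), 1)

  # primary (+, query 0-5000) with a supplementary (+, query 5000-10000)
  rec <- make_rec(ref_start = 10000L, cigar = "5000M5000S",
                  sa = "chr1,16001,+,5000H5000M,60,0;")
  segs <- read_segments(rec)
  expect_equal(segs$query_start, c(0L, 5000L))
  expect_equal(segs$ref_start, c(10000L, 16000L))
  expect_equal(segs$ref_end, c(15000L, 21000L))

  # low-mapq SA segment dropped
  rec$sa <- "chr1,16001,+,5000H5000M,5,0;"
  expect_equal(nrow(read_segments(rec)), 1)

  # short-span SA segment dropped
  rec$sa <- "chr1,16001,+,5000H100M,60,0;"
  expect_equal(nrow(read_segments(rec)), 1)
})

test_that("reverse-strand query intervals are expressed on the forward read", {
  # 1000H2000M3000H on the minus strand: forward-read interval is [3000,5000)
  seg <- svstream:::segment_from_cigar("chr1", 100L, "-", "1000H2000M3000H",
                                       60L)
  expect_equal(seg$query_start, 3000L)
  expect_equal(seg$query_end, 5000L)
})

test_that("split-read geometry yields DEL/INS/INV/DUP/BND signatures", {
  # reference gap 1000 with no query gap: deletion at the first segment end
  s <- split_read_signatures(rbind(
    make_seg(0, 5000, "chr1", 10000, 15000),
    make_seg(5000, 10000, "chr1", 16000, 21000)
  ), "r1")
  expect_equal(s$svtype, "DEL")
  expect_equal(s$start, 15000L)
  expect_equal(s$length, 1000L)

  # query gap 800 with no reference gap: insertion
  s <- split_read_signatures(rbind(
    make_seg(0, 5000, "chr1", 10000, 15000),
    make_seg(5800, 10000, "chr1", 15000, 19200)
  ), "r1")
  expect_equal(s$svtype, "INS")
  expect_equal(s$length, 800L)

  # strand flip: inversion spanning the united interval
  s <- split_read_signatures(rbind(
    make_seg(0, 5000, "chr1", 10000, 15000, "+"),
    make_seg(5000, 10000, "chr1", 15000, 20000, "-")
  ), "r1")
  expect_equal(s$svtype, "INV")
  expect_equal(s$start, 10000L)
  expect_equal(s$length, 10000L)

  # rewind past the first segment end: tandem duplication
  s <- split_read_signatures(rbind(
    make_seg(0, 5000, "chr1", 10000, 15000),
    make_seg(5000, 9000, "chr1", 14500, 18500)
  ), "r1")
  expect_equal(s$svtype, "DUP")
  expect_equal(s$start, 14500L)
  expect_equal(s$length, 500L)

  # contig change: breakend with mate coordinates
  s <- split_read_signatures(rbind(
    make_seg(0, 5000, "chr1", 10000, 15000),
    make_seg(5000, 9000, "chr2", 500, 4500)
  ), "r1")
  expect_equal(s$svtype, "BND")
  expect_equal(s$start, 15000L)
  expect_equal(s$mate_contig, "chr2")
  expect_equal(s$mate_pos, 500L)
})

test_that("batch extraction is deterministic and keeps duplicate evidence", {
  recs <- rbind(
    make_rec("rA", ref_start = 1000L, cigar = "100M50D100M"),
    make_rec("rA", ref_start = 1000L, cigar = "100M50D100M"),  # duplicate
    make_rec("rB", contig = "chr2", ref_start = 500L, cigar = "50M40I50M")
  )
  sigs <- extract_signatures(recs, two_contigs())
  expect_equal(nrow(sigs), 3)  # duplicates retained; dedup is clustering's job
  expect_equal(sigs$contig, c("chr1", "chr1", "chr2"))  # contig-table order

  pure <- make_rec(cigar = "1000M")
  expect_equal(nrow(extract_signatures(pure, two_contigs())), 0)
})

test_that("extraction is additive over any read-preserving batch partition", {
  fx <- default_fixture()
  recs <- read_alignment_batch(fx$batch_paths[1], fx$contigs)
  all_sigs <- extract_signatures(recs, fx$contigs)
  set.seed(7)
  for (rep in 1:3) {
    reads <- unique(recs$read_id)
    grp <- sample(1:3, length(reads), replace = TRUE)
    names(grp) <- reads
    parts <- lapply(1:3, function(g) {
      extract_signatures(recs[grp[recs$read_id] == g, , drop = FALSE],
                         fx$contigs)
    })
    merged <- sort_sig <- do.call(rbind, parts)
    merged <- merged[order(merged$contig, merged$start, merged$svtype,
                           merged$read_id, merged$length), ]
    ref <- all_sigs[order(all_sigs$contig, all_sigs$start, all_sigs$svtype,
                          all_sigs$read_id, all_sigs$length), ]
    rownames(merged) <- rownames(ref) <- NULL
    expect_equal(merged, ref)
  }
})

test_that("emitted DEL lengths conserve isolated large D operations", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(1:4, 1)
    dlens <- sample(30:200, n, replace = TRUE)
    spacers <- sample(501:2000, n + 1, replace = TRUE)
    cigar <- paste0(
      paste0(spacers[1], "M"),
      paste(paste0(dlens, "D", spacers[-1], "M"), collapse = "")
    )
    s <- cigar_signatures(make_rec(cigar = cigar))
    expect_equal(sort(s$length), sort(dlens))
  }
})

test_that("no signature falls outside its contig", {
  fx <- default_fixture()
  store <- fx$offline$state$store
  len <- fx$contigs$length[match(store$contig, fx$contigs$name)]
  expect_true(all(store$start >= 0 & store$start < len))
})
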