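# Synthetic fixture generator: a toy reference, an implanted SV truth set,
# constructed alignment records carrying the corresponding CIGAR/split-read
# evidence, and equal-size read batches dripped into a directory like a
# sequencer would. Alignments are built directly (no aligner): each
# variant-allele read gets exactly the alignment geometry the extraction
# rules consume, plus configurable noise (breakpoint jitter, per-read
# evidence dropout, sub-threshold background indels).

#' Implanted SV set specification
#'
#' @param n_del,n_ins,n_inv,n_dup,n_bnd Per-type counts (defaults sum to 40).
#' @param size_range Named list of c(min, max) length ranges in bp. The INV
#'   default is larger than the other types because split-read inversion
#'   evidence spans the inverted interval plus one alignable flanking segment
#'   (>= `min_segment_len`): an inversion much shorter than its flanks could
#'   never pass a size-ratio match against its own truth record.
#' @param spacing Minimum gap in bp between implanted SV intervals.
#' @param het_fraction Fraction of SVs implanted heterozygous.
#' @param af_range Range of the uniform population allele-frequency
#'   annotation written to the truth VCF (so the AF filter has work to do).
#' @param margin Minimum distance in bp from contig ends.
#' @return List of class `svstream_sv_spec`.
#' @export
sv_spec <- function(n_del = 12L, n_ins = 12L, n_inv = 5L, n_dup = 6L,
                    n_bnd = 5L,
                    size_range = list(DEL = c(50L, 500L), INS = c(50L, 500L),
                                      INV = c(1000L, 2500L),
                                      DUP = c(50L, 500L)),
                    spacing = 2000L, het_fraction = 0.5,
                    af_range = c(0.02, 0.6), margin = 10000L) {
  structure(
    list(n = c(DEL = as.integer(n_del), INS = as.integer(n_ins),
               INV = as.integer(n_inv), DUP = as.integer(n_dup),
               BND = as.integer(n_bnd)),
         size_range = size_range, spacing = as.integer(spacing),
         het_fraction = het_fraction, af_range = af_range,
         margin = as.integer(margin)),
    class = "svstream_sv_spec"
  )
}

#' Read-simulation parameters
#'
#' @param coverage Target fold coverage.
#' @param read_len_mean,read_len_sd,read_len_min Read-length model in bp
#'   (normal, floored).
#' @param jitter_sd Breakpoint/length jitter standard deviation in bp.
#' @param dropout Per-read probability that a variant-allele read is emitted
#'   as a reference read (evidence dropout).
#' @param bg_indel_per_kb Expected background small-indel count per kb of
#'   read; sizes 1..`bg_indel_max` bp, all below the extraction `min_size`,
#'   so the size filter must remove them.
#' @param bg_indel_max Maximum background indel size in bp.
#' @return List of class `svstream_sim_params`.
#' @export
sim_params <- function(coverage = 20, read_len_mean = 8000,
                       read_len_sd = 2000, read_len_min = 500,
                       jitter_sd = 10, dropout = 0.1,
                       bg_indel_per_kb = 0.2, bg_indel_max = 10L) {
  stopifnot(coverage > 0, dropout >= 0, dropout < 1)
  structure(
    list(coverage = coverage, read_len_mean = read_len_mean,
         read_len_sd = read_len_sd, read_len_min = read_len_min,
         jitter_sd = jitter_sd, dropout = dropout,
         bg_indel_per_kb = bg_indel_per_kb,
         bg_indel_max = as.integer(bg_indel_max)),
    class = "svstream_sim_params"
  )
}

#' Generate a random toy reference
#'
#' Uniform-random A/C/G/T contigs, byte-identical under a fixed seed.
#'
#' @param n_contigs Number of contigs.
#' @param length_each Length of each contig in bp (>= 10 kb).
#' @param seed RNG seed.
#' @param fasta Optional output FASTA path.
#' @return List with `contigs` ([contig_table()]) and `seqs` (character).
#' @export
make_reference <- function(n_contigs = 2L, length_each = 500000L, seed = 1L,
                           fasta = NULL) {
  stopifnot(length_each >= 10000L)
  seqs <- with_seed(seed, {
    vapply(seq_len(n_contigs), function(i) {
      paste(sample(c("A", "C", "G", "T"), length_each, replace = TRUE),
            collapse = "")
    }, character(1))
  })
  names(seqs) <- paste0("ctg", seq_len(n_contigs))
  contigs <- contig_table(names(seqs), rep(length_each, n_contigs))
  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta)
  }
  list(contigs = contigs, seqs = seqs)
}

#' Sample a non-overlapping implanted SV set
#'
#' Positions are uniform within contigs (proportionally to length) subject to
#' the minimum spacing and end margins; each SV is tagged hom/het by the
#' heterozygous fraction and annotated with a population allele frequency
#' drawn from `spec$af_range`. Breakend mates land on a different contig.
#'
#' @param contigs [contig_table()].
#' @param spec [sv_spec()].
#' @param seed RNG seed.
#' @return data.frame with `svtype`, `contig`, `pos` (0-based), `length`,
#'   `zygosity`, `af`, `mate_contig`, `mate_pos`.
#' @export
sample_sv_set <- function(contigs, spec = sv_spec(), seed = 1L) {
  if (spec$n[["BND"]] > 0L && nrow(contigs) < 2L) {
    stop_svstream("breakends need at least two contigs",
                  "svstream_sim_error")
  }
  with_seed(seed, {
    placed <- list()  # per contig: matrix of (lo, hi) occupied intervals
    place <- function(ctg, span) {
      len <- contigs$length[contigs$name == ctg]
      lo_ok <- spec$margin
      hi_ok <- len - spec$margin - span
      if (hi_ok <= lo_ok) return(NA_integer_)
      occ <- placed[[ctg]]
      for (try in 1:200) {
        pos <- floor(stats::runif(1, lo_ok, hi_ok))
        if (is.null(occ) ||
            all(pos > occ[, 2] + spec$spacing | pos + span < occ[, 1] - spec$spacing)) {
          placed[[ctg]] <<- rbind(occ, c(pos, pos + span))
          return(as.integer(pos))
        }
      }
      NA_integer_
    }
    rows <- list()
    for (type in names(spec$n)) {
      for (k in seq_len(spec$n[[type]])) {
        size <- if (type == "BND") 0L else {
          r <- spec$size_range[[type]]
          as.integer(floor(stats::runif(1, r[1], r[2] + 1)))
        }
        ctg <- sample(contigs$name, 1L, prob = contigs$length)
        pos <- place(ctg, max(size, 1L))
        if (is.na(pos)) {
          stop_svstream("could not place all SVs at the requested spacing",
                        "svstream_sim_error")
        }
        mate_contig <- NA_character_
        mate_pos <- NA_integer_
        if (type == "BND") {
          mate_contig <- sample(setdiff(contigs$name, ctg), 1L)
          mlen <- contigs$length[contigs$name == mate_contig]
          mate_pos <- as.integer(floor(stats::runif(1, spec$margin,
                                                    mlen - spec$margin)))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          svtype = type, contig = ctg, pos = pos, length = size,
          zygosity = if (stats::runif(1) < spec$het_fraction) "het" else "hom",
          af = stats::runif(1, spec$af_range[1], spec$af_range[2]),
          mate_contig = mate_contig, mate_pos = mate_pos,
          stringsAsFactors = FALSE
        )
      }
    }
    svs <- do.call(rbind, rows)
    svs <- svs[order(contig_factor(svs$contig, contigs), svs$pos), ,
               drop = FALSE]
    rownames(svs) <- NULL
    svs
  })
}

# --- alignment construction -------------------------------------------------

# Minimum alignable flank for split segments; paired with an upper bound so
# cluster positions stay within the per-type partition bias.
SPLIT_FLANK_MIN <- 300L
SPLIT_FLANK_MAX <- 400L

cigar_string <- function(lens, ops) paste0(lens, ops, collapse = "")

sa_entry <- function(contig, pos0, strand, cigar, mapq = 60L) {
  sprintf("%s,%d,%s,%s,%d,0;", contig, pos0 + 1L, strand, cigar, mapq)
}

# Build the single-record CIGAR of a read spanning [start, start+rl) with
# deletion/insertion events (refpos, len) already jittered and vetted.
build_cigar_read <- function(read_id, contig, start, rl, events) {
  lens <- integer(0); ops <- character(0)
  refcur <- start
  if (nrow(events)) {
    events <- events[order(events$refpos), , drop = FALSE]
    for (i in seq_len(nrow(events))) {
      gap <- events$refpos[i] - refcur
      if (gap < 1L) next
      dlen <- if (events$op[i] == "D") events$len[i] else 0L
      if (events$refpos[i] + dlen > start + rl - 1L) next
      lens <- c(lens, gap, events$len[i])
      ops <- c(ops, "M", events$op[i])
      refcur <- events$refpos[i] + dlen
    }
  }
  lens <- c(lens, start + rl - refcur)
  ops <- c(ops, "M")
  data.frame(
    read_id = read_id, contig = contig, ref_start = as.integer(start),
    strand = "+", mapq = 60L, cigar = cigar_string(lens, ops),
    is_supplementary = FALSE, sa = NA_character_, stringsAsFactors = FALSE
  )
}

# Build the 2-3 record split-read geometry for one INV/DUP/BND.
build_split_read <- function(read_id, sv, a, b) {
  rec <- function(contig, pos0, strand, cigar, supp, sa) {
    data.frame(read_id = read_id, contig = contig,
               ref_start = as.integer(pos0), strand = strand, mapq = 60L,
               cigar = cigar, is_supplementary = supp, sa = sa,
               stringsAsFactors = FALSE)
  }
  s <- sv$pos; L <- sv$length
  if (sv$svtype == "INV") {
    cig_a <- paste0(a, "M", L + b, "S")
    cig_b <- paste0(b, "H", L, "M", a, "H")
    cig_c <- paste0(a + L, "H", b, "M")
    sa_a <- paste0(sa_entry(sv$contig, s, "-", cig_b),
                   sa_entry(sv$contig, s + L, "+", cig_c))
    sa_back <- sa_entry(sv$contig, s - a, "+", cig_a)
    rbind(
      rec(sv$contig, s - a, "+", cig_a, FALSE, sa_a),
      rec(sv$contig, s, "-", cig_b, TRUE, sa_back),
      rec(sv$contig, s + L, "+", cig_c, TRUE, sa_back)
    )
  } else if (sv$svtype == "DUP") {
    cig_a <- paste0(a, "M", b, "S")
    cig_b <- paste0(a, "H", b, "M")
    rbind(
      rec(sv$contig, s + L - a, "+", cig_a, FALSE,
          sa_entry(sv$contig, s, "+", cig_b)),
      rec(sv$contig, s, "+", cig_b, TRUE,
          sa_entry(sv$contig, s + L - a, "+", cig_a))
    )
  } else {  # BND
    cig_a <- paste0(a, "M", b, "S")
    cig_b <- paste0(a, "H", b, "M")
    rbind(
      rec(sv$contig, s - a, "+", cig_a, FALSE,
          sa_entry(sv$mate_contig, sv$mate_pos, "+", cig_b)),
      rec(sv$mate_contig, sv$mate_pos, "+", cig_b, TRUE,
          sa_entry(sv$contig, s - a, "+", cig_a))
    )
  }
}

#' Construct alignment records over an implanted SV set
#'
#' Reads are placed uniformly to reach the target coverage. A read spanning a
#' deletion or insertion of the variant allele carries the corresponding
#' D/I operation (length jittered) in its CIGAR; a read across an inversion,
#' duplication or breakend junction becomes a primary record plus
#' supplementary records with consistent SA tags and forward-read query
#' intervals. Heterozygous SVs are carried with probability 1/2; `dropout`
#' turns a variant-allele read into a reference read; background indels below
#' the extraction size threshold are sprinkled into CIGARs.
#'
#' @param contigs [contig_table()].
#' @param svs data.frame from [sample_sv_set()].
#' @param p [sim_params()].
#' @param seed RNG seed.
#' @return data.frame of alignment records in read order (a read's primary
#'   and supplementary records are adjacent), same columns as
#'   [read_alignment_batch()].
#' @export
simulate_alignments <- function(contigs, svs, p = sim_params(), seed = 1L) {
  with_seed(seed, {
    out <- vector("list", 0L)
    for (ci in seq_len(nrow(contigs))) {
      ctg <- contigs$name[ci]
      clen <- contigs$length[ci]
      on_ctg <- svs[svs$contig == ctg, , drop = FALSE]
      n_reads <- round(p$coverage * clen / p$read_len_mean)
      for (j in seq_len(n_reads)) {
        rl <- min(clen, max(p$read_len_min,
                            round(stats::rnorm(1, p$read_len_mean,
                                               p$read_len_sd))))
        start <- floor(stats::runif(1, 0, clen - rl + 1))
        read_id <- sprintf("%s_r%05d", ctg, j)
        ov <- on_ctg[on_ctg$pos < start + rl &
                       on_ctg$pos + pmax(on_ctg$length, 1L) > start, ,
                     drop = FALSE]
        carried <- ov[ov$zygosity == "hom" | stats::runif(nrow(ov)) < 0.5, ,
                      drop = FALSE]
        if (nrow(carried) && p$dropout > 0) {
          carried <- carried[stats::runif(nrow(carried)) >= p$dropout, ,
                             drop = FALSE]
        }
        split_rec <- NULL
        if (nrow(carried)) {
          for (k in seq_len(nrow(carried))) {
            sv <- carried[k, ]
            geom <- split_geometry(sv, start, rl)
            if (!is.null(geom)) {
              split_rec <- build_split_read(read_id, sv, geom$a, geom$b)
              break
            }
          }
        }
        if (!is.null(split_rec)) {
          out[[length(out) + 1L]] <- split_rec
          next
        }
        events <- cigar_events(carried, start, rl, p)
        out[[length(out) + 1L]] <-
          build_cigar_read(read_id, ctg, start, rl, events)
      }
    }
    recs <- do.call(rbind, out)
    rownames(recs) <- NULL
    recs
  })
}

# Feasible split geometry for one read over an INV/DUP/BND, or NULL.
split_geometry <- function(sv, start, rl) {
  if (!sv$svtype %in% c("INV", "DUP", "BND")) return(NULL)
  fa <- as.integer(floor(stats::runif(1, SPLIT_FLANK_MIN, SPLIT_FLANK_MAX)))
  fb <- as.integer(floor(stats::runif(1, SPLIT_FLANK_MIN, SPLIT_FLANK_MAX)))
  ok <- switch(sv$svtype,
    INV = start <= sv$pos - fa && sv$pos + sv$length + fb <= start + rl,
    DUP = sv$pos + sv$length - fa >= start &&
      sv$pos + sv$length + fb <= start + rl,
    BND = start <= sv$pos - fa && sv$pos - start + fb <= rl
  )
  if (ok) list(a = fa, b = fb) else NULL
}

# Deletion/insertion CIGAR events (real SVs jittered + background indels).
cigar_events <- function(carried, start, rl, p) {
  ev <- data.frame(refpos = integer(0), op = character(0), len = integer(0),
                   stringsAsFactors = FALSE)
  inner_lo <- start + 100L
  inner_hi <- start + rl - 100L
  if (nrow(carried)) {
    for (k in seq_len(nrow(carried))) {
      sv <- carried[k, ]
      if (!sv$svtype %in% c("DEL", "INS")) next
      jl <- max(1L, as.integer(sv$length +
                                 round(stats::rnorm(1, 0, p$jitter_sd))))
      fits <- if (sv$svtype == "DEL") {
        sv$pos >= inner_lo && sv$pos + jl <= inner_hi
      } else {
        sv$pos >= inner_lo && sv$pos <= inner_hi
      }
      if (fits) {
        ev <- rbind(ev, data.frame(refpos = sv$pos,
                                   op = if (sv$svtype == "DEL") "D" else "I",
                                   len = jl, stringsAsFactors = FALSE))
      }
    }
  }
  n_bg <- stats::rpois(1, p$bg_indel_per_kb * rl / 1000)
  if (n_bg > 0) {
    bg <- data.frame(
      refpos = as.integer(floor(stats::runif(n_bg, start + 50L,
                                             start + rl - 50L))),
      op = sample(c("D", "I"), n_bg, replace = TRUE),
      len = sample.int(p$bg_indel_max, n_bg, replace = TRUE),
      stringsAsFactors = FALSE
    )
    # keep events well separated so the constructed CIGAR stays simple
    for (i in seq_len(nrow(bg))) {
      if (!nrow(ev) || all(abs(bg$refpos[i] - ev$refpos) > 30L)) {
        ev <- rbind(ev, bg[i, ])
      }
    }
  }
  ev
}

#' Write alignment records as batch SAM files
#'
#' Records are split in read order into equal-size read batches (a read's
#' primary and supplementary records always land in the same batch), each
#' written to a temporary name and renamed so the stability poll only ever
#' sees complete files, optionally one per time interval.
#'
#' @param records data.frame from [simulate_alignments()].
#' @param contigs [contig_table()] for the SAM headers.
#' @param out_dir Output directory.
#' @param batch_size Reads per batch (overridden by `n_batches`).
#' @param n_batches Split into this many equal batches instead.
#' @param interval,jitter Seconds between file appearances (0 = all at once).
#' @return Character vector of batch file paths.
#' @export
write_batches <- function(records, contigs, out_dir, batch_size = NULL,
                          n_batches = NULL, interval = 0, jitter = 0) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reads <- unique(records$read_id)
  if (!is.null(n_batches)) batch_size <- ceiling(length(reads) / n_batches)
  stopifnot(!is.null(batch_size), batch_size >= 1)
  batch_of <- stats::setNames(ceiling(seq_along(reads) / batch_size), reads)
  header <- c("@HD\tVN:1.6",
              sprintf("@SQ\tSN:%s\tLN:%d", contigs$name,
                      as.integer(contigs$length)))
  paths <- character(0)
  for (bi in sort(unique(batch_of))) {
    sel <- records[batch_of[records$read_id] == bi, , drop = FALSE]
    flag <- ifelse(sel$is_supplementary, 2048L, 0L) +
      ifelse(sel$strand == "-", 16L, 0L)
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*%s",
                     sel$read_id, flag, sel$contig, sel$ref_start + 1L,
                     sel$mapq, sel$cigar,
                     ifelse(is.na(sel$sa), "", paste0("\tSA:Z:", sel$sa)))
    path <- file.path(out_dir, sprintf("batch_%04d.sam", bi))
    tmp <- paste0(path, ".tmp")
    con <- file(tmp, open = "wb")
    writeLines(c(header, lines), con, sep = "\n", useBytes = TRUE)
    close(con)
    file.rename(tmp, path)
    paths <- c(paths, path)
    if (interval > 0 && bi < max(batch_of)) {
      Sys.sleep(interval + stats::runif(1, 0, jitter))
    }
  }
  paths
}

#' Generate a complete streaming fixture
#'
#' Reference FASTA, truth VCF with AF annotations, and batch SAM files under
#' `dir/batches/`, all deterministic under `seed`.
#'
#' @param dir Output directory.
#' @param seed Master seed; reference, SV set and reads use derived seeds.
#' @param n_contigs,contig_length Reference shape.
#' @param spec [sv_spec()].
#' @param p [sim_params()].
#' @param n_batches Number of equal read batches.
#' @param interval,jitter Batch drip timing in seconds.
#' @param write_fasta Write `reference.fa` (not needed downstream; the
#'   framework consumes alignments).
#' @return List with `contigs`, `svs`, `truth_vcf`, `batch_dir`,
#'   `batch_paths`, `fasta`.
#' @export
simulate_run <- function(dir, seed = 42L, n_contigs = 2L,
                         contig_length = 500000L, spec = sv_spec(),
                         p = sim_params(), n_batches = 10L, interval = 0,
                         jitter = 0, write_fasta = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- if (write_fasta) file.path(dir, "reference.fa") else NULL
  ref <- make_reference(n_contigs, contig_length, seed = seed, fasta = fasta)
  svs <- sample_sv_set(ref$contigs, spec, seed = seed + 1L)
  truth_vcf <- file.path(dir, "truth.vcf")
  write_truth_vcf(svs, ref$contigs, truth_vcf)
  records <- simulate_alignments(ref$contigs, svs, p, seed = seed + 2L)
  batch_dir <- file.path(dir, "batches")
  batch_paths <- write_batches(records, ref$contigs, batch_dir,
                               n_batches = n_batches, interval = interval,
                               jitter = jitter)
  list(contigs = ref$contigs, svs = svs, truth_vcf = truth_vcf,
       batch_dir = batch_dir, batch_paths = batch_paths, fasta = fasta)
}
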