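# Read-level SV signature extraction.
#
# Two evidence classes feed the cumulative store:
#   intra-alignment — I/D operations inside one record's CIGAR;
#   inter-alignment — geometry of a primary record and its SA-tag
#                     supplementary segments (split reads).
# Every signature carries the read id so clustering can count distinct
# supporting reads, and an origin label (intra/inter).

CIGAR_REF_OPS <- c("M", "D", "N", "=", "X")
CIGAR_QUERY_OPS <- c("M", "I", "S", "=", "X")

signature_row <- function(svtype, contig, start, length, read_id, origin,
                          mate_contig = NA_character_, mate_pos = NA_integer_) {
  data.frame(
    svtype = svtype, contig = contig, start = as.integer(start),
    length = as.integer(length), mate_contig = mate_contig,
    mate_pos = as.integer(mate_pos), read_id = read_id, origin = origin,
    stringsAsFactors = FALSE
  )
}

# Merge same-type CIGAR candidates of one read: chained grouping while
# successive anchors are within merge_dist, then one merged candidate per
# group. Merging happens before the size filter so several sub-threshold ops
# can add up to a reportable SV.
merge_cigar_candidates <- function(anchor, len, type, merge_dist) {
  if (!length(anchor)) return(list(start = integer(0), length = integer(0)))
  grp <- cumsum(c(TRUE, diff(anchor) > merge_dist))
  if (type == "DEL") {
    start <- as.integer(tapply(anchor, grp, function(a) a[1]))
  } else {
    # insertion anchor: length-weighted mean of member anchors, half-up
    start <- as.integer(round_half_up(
      tapply(seq_along(anchor), grp,
             function(i) stats::weighted.mean(anchor[i], len[i]))
    ))
  }
  list(start = start, length = as.integer(tapply(len, grp, sum)))
}

.cigar_sigs <- function(contig, ref_start, ops, lens, read_id, params) {
  ref_consume <- ifelse(ops %in% CIGAR_REF_OPS, lens, 0L)
  pos_before <- ref_start + c(0L, cumsum(ref_consume))[seq_along(ops)]
  out <- list()
  for (type in c("DEL", "INS")) {
    sel <- ops == (if (type == "DEL") "D" else "I")
    if (!any(sel)) next
    m <- merge_cigar_candidates(pos_before[sel], lens[sel], type,
                                params$merge_dist)
    keep <- m$length >= params$min_size
    if (any(keep)) {
      out[[type]] <- signature_row(type, contig, m$start[keep],
                                   m$length[keep], read_id, "intra")
    }
  }
  if (!length(out)) empty_signature_frame() else do.call(rbind, out)
}

#' Intra-alignment signatures from one record's CIGAR
#'
#' Each `D` operation is a deletion candidate at its reference interval and
#' each `I` operation an insertion candidate anchored where it interrupts the
#' reference walk. Same-type candidates whose anchors lie within
#' `params$merge_dist` are merged (deletions: first start, summed length;
#' insertions: length-weighted mean anchor rounded half-up, summed length);
#' merged candidates shorter than `params$min_size` are discarded.
#'
#' @param rec A single alignment record (one-row data.frame or list with
#'   `contig`, `ref_start`, `cigar`, `read_id`).
#' @param params [extraction_params()].
#' @return Signature data.frame (possibly empty).
#' @export
cigar_signatures <- function(rec, params = extraction_params()) {
  ops <- GenomicAlignments::explodeCigarOps(rec$cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(rec$cigar)[[1]]
  .cigar_sigs(rec$contig, as.integer(rec$ref_start), ops, lens,
              rec$read_id, params)
}

# Segment geometry from (ref_start, strand, cigar): query interval expressed
# on the forward-strand read (clips flipped for reverse alignments), reference
# interval half-open.
segment_from_cigar <- function(contig, ref_start, strand, cigar, mapq) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  clip <- ops %in% c("S", "H")
  n <- length(ops)
  lclip <- if (clip[1]) {
    i <- 1L; while (i < n && clip[i + 1L]) i <- i + 1L
    sum(lens[seq_len(i)])
  } else 0L
  rclip <- if (clip[n]) {
    i <- n; while (i > 1L && clip[i - 1L]) i <- i - 1L
    sum(lens[i:n])
  } else 0L
  qalen <- sum(lens[ops %in% c("M", "I", "=", "X")])
  rspan <- sum(lens[ops %in% CIGAR_REF_OPS])
  qs <- if (strand == "+") lclip else rclip
  data.frame(
    query_start = as.integer(qs), query_end = as.integer(qs + qalen),
    contig = contig, ref_start = as.integer(ref_start),
    ref_end = as.integer(ref_start + rspan), strand = strand,
    mapq = as.integer(mapq), stringsAsFactors = FALSE
  )
}

#' Split-read segments of a primary record
#'
#' One segment for the primary alignment plus one per SA-tag supplementary
#' passing the mapping-quality and reference-span gates, sorted by position on
#' the forward-strand read.
#'
#' @param rec A primary alignment record (row of [read_alignment_batch()]).
#' @param params [extraction_params()]; supplies `min_mapq` and
#'   `min_segment_len` for SA segments.
#' @return Segment data.frame sorted by `query_start`.
#' @export
read_segments <- function(rec, params = extraction_params()) {
  prim <- segment_from_cigar(rec$contig, rec$ref_start, rec$strand, rec$cigar,
                             rec$mapq)
  sa <- parse_sa_tag(if (is.null(rec$sa)) NA_character_ else rec$sa)
  segs <- prim
  if (nrow(sa)) {
    supp <- do.call(rbind, lapply(seq_len(nrow(sa)), function(i) {
      segment_from_cigar(sa$contig[i], sa$ref_start[i], sa$strand[i],
                         sa$cigar[i], sa$mapq[i])
    }))
    supp <- supp[supp$mapq >= params$min_mapq &
                   (supp$ref_end - supp$ref_start) >= params$min_segment_len, ,
                 drop = FALSE]
    segs <- rbind(prim, supp)
  }
  segs <- segs[order(segs$query_start, segs$query_end), , drop = FALSE]
  rownames(segs) <- NULL
  segs
}

#' Inter-alignment signatures from one read's segments
#'
#' Scans consecutive segment pairs in read (query) order. Same contig and
#' strand with the second segment downstream: the difference between the
#' reference gap and the query gap implies a deletion or insertion; same
#' contig and strand with the second segment rewinding past the first implies
#' a tandem duplication; a strand flip on one contig implies an inversion
#' spanning the united reference interval; a contig change yields a breakend.
#'
#' @param segments Output of [read_segments()] for one read.
#' @param read_id Read identifier propagated into the signatures.
#' @param params [extraction_params()].
#' @return Signature data.frame (possibly empty).
#' @export
split_read_signatures <- function(segments, read_id,
                                  params = extraction_params()) {
  n <- nrow(segments)
  if (n < 2L) return(empty_signature_frame())
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    a <- segments[i, ]
    b <- segments[i + 1L, ]
    if (a$contig != b$contig) {
      out[[i]] <- signature_row("BND", a$contig, a$ref_end, 0L, read_id,
                                "inter", mate_contig = b$contig,
                                mate_pos = b$ref_start)
    } else if (a$strand != b$strand) {
      lo <- min(a$ref_start, b$ref_start)
      hi <- max(a$ref_end, b$ref_end)
      out[[i]] <- signature_row("INV", a$contig, lo, hi - lo, read_id, "inter")
    } else if (b$ref_start >= a$ref_end) {
      ref_gap <- b$ref_start - a$ref_end
      query_gap <- b$query_start - a$query_end
      if (ref_gap - query_gap >= params$min_size) {
        out[[i]] <- signature_row("DEL", a$contig, a$ref_end,
                                  ref_gap - query_gap, read_id, "inter")
      } else if (query_gap - ref_gap >= params$min_size) {
        out[[i]] <- signature_row("INS", a$contig, a$ref_end,
                                  query_gap - ref_gap, read_id, "inter")
      }
    } else if (b$ref_start < a$ref_end - params$min_size) {
      out[[i]] <- signature_row("DUP", a$contig, b$ref_start,
                                a$ref_end - b$ref_start, read_id, "inter")
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) empty_signature_frame() else do.call(rbind, out)
}

#' Extract all signatures of one batch
#'
#' Union of intra-alignment signatures over all mapped records and
#' inter-alignment signatures over each primary record's segment set, in a
#' deterministic order (contig order, start, type, read id). Duplicate
#' evidence from duplicated records is retained; clustering deduplicates by
#' read id when counting support.
#'
#' @param records Batch data.frame from [read_alignment_batch()].
#' @param contigs [contig_table()] fixing the contig order.
#' @param params [extraction_params()].
#' @return Signature data.frame.
#' @export
extract_signatures <- function(records, contigs,
                               params = extraction_params()) {
  if (!nrow(records)) return(empty_signature_frame())
  ops_all <- GenomicAlignments::explodeCigarOps(records$cigar)
  lens_all <- GenomicAlignments::explodeCigarOpLengths(records$cigar)
  parts <- vector("list", 2L * nrow(records))
  for (i in seq_len(nrow(records))) {
    if (any(ops_all[[i]] %in% c("D", "I"))) {
      parts[[i]] <- .cigar_sigs(records$contig[i], records$ref_start[i],
                                ops_all[[i]], lens_all[[i]],
                                records$read_id[i], params)
    }
    if (!records$is_supplementary[i] && !is.na(records$sa[i])) {
      segs <- read_segments(records[i, ], params)
      parts[[nrow(records) + i]] <-
        split_read_signatures(segs, records$read_id[i], params)
    }
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  sigs <- if (length(parts)) do.call(rbind, parts) else empty_signature_frame()
  sort_signatures(sigs, contigs)
}

sort_signatures <- function(sigs, contigs) {
  if (!nrow(sigs)) return(sigs)
  o <- order(contig_factor(sigs$contig, contigs), sigs$start, sigs$svtype,
             sigs$read_id)
  sigs <- sigs[o, , drop = FALSE]
  rownames(sigs) <- NULL
  sigs
}
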