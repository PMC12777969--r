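# Alignment-batch input. SAM batches are converted to temporary BAMs with
# Rsamtools::asBam (no sorting, so file order is preserved) and read with
# scanBam; BAM batches are read directly.

FLAG_UNMAPPED <- 4L
FLAG_REVERSE <- 16L
FLAG_SECONDARY <- 256L
FLAG_SUPPLEMENTARY <- 2048L

as_bam_path <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(path)
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, dest, indexDestination = FALSE, overwrite = TRUE)
}

#' Read one alignment batch
#'
#' Reads a SAM or BAM batch file, keeping mapped primary and supplementary
#' records with mapping quality at least `min_mapq`, in file order. Secondary
#' and unmapped records are dropped. This is the single mapping-quality gate:
#' a read whose primary record fails it contributes no signatures at all.
#'
#' @param path SAM or BAM file whose header names every contig.
#' @param contigs A [contig_table()]; records on contigs absent from it are a
#'   hard error.
#' @param min_mapq Minimum mapping quality (default 20).
#' @return A data.frame with one row per retained record: `read_id`, `contig`,
#'   `ref_start` (0-based), `strand`, `mapq`, `cigar`, `is_supplementary`,
#'   `sa` (raw SA tag, `NA` if absent). Unreadable or truncated files raise a
#'   recoverable condition of class `svstream_batch_error`, which the stream
#'   engine answers by re-queueing the batch.
#' @export
read_alignment_batch <- function(path, contigs, min_mapq = 20L) {
  res <- tryCatch({
    bam <- as_bam_path(path)
    param <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar"),
      tag = "SA"
    )
    Rsamtools::scanBam(bam, param = param)[[1]]
  }, error = function(e) {
    stop_svstream(
      paste0("failed to read batch '", path, "': ", conditionMessage(e)),
      "svstream_batch_error"
    )
  })
  flag <- res$flag
  keep <- !bitwAnd(flag, FLAG_UNMAPPED) &
    !bitwAnd(flag, FLAG_SECONDARY) &
    !is.na(res$pos) &
    res$mapq >= min_mapq
  keep[is.na(keep)] <- FALSE
  rec <- data.frame(
    read_id = res$qname[keep],
    contig = as.character(res$rname[keep]),
    ref_start = res$pos[keep] - 1L,
    strand = ifelse(bitwAnd(flag[keep], FLAG_REVERSE) > 0L, "-", "+"),
    mapq = as.integer(res$mapq[keep]),
    cigar = res$cigar[keep],
    is_supplementary = bitwAnd(flag[keep], FLAG_SUPPLEMENTARY) > 0L,
    sa = if (length(res$tag$SA)) as.character(res$tag$SA)[keep] else
      rep(NA_character_, sum(keep)),
    stringsAsFactors = FALSE
  )
  contig_factor(rec$contig, contigs)  # hard error on unknown contig
  rownames(rec) <- NULL
  rec
}

# Parse one SA tag ("contig,pos,strand,CIGAR,mapQ,NM;...") into a data.frame
# with 0-based ref_start. Returns a zero-row frame for NA/empty tags.
parse_sa_tag <- function(sa) {
  if (is.na(sa) || !nzchar(sa)) {
    return(data.frame(contig = character(0), ref_start = integer(0),
                      strand = character(0), cigar = character(0),
                      mapq = integer(0), stringsAsFactors = FALSE))
  }
  entries <- strsplit(sa, ";", fixed = TRUE)[[1]]
  entries <- entries[nzchar(entries)]
  parts <- strsplit(entries, ",", fixed = TRUE)
  data.frame(
    contig = vapply(parts, `[[`, character(1), 1L),
    ref_start = as.integer(vapply(parts, `[[`, character(1), 2L)) - 1L,
    strand = vapply(parts, `[[`, character(1), 3L),
    cigar = vapply(parts, `[[`, character(1), 4L),
    mapq = as.integer(vapply(parts, `[[`, character(1), 5L)),
    stringsAsFactors = FALSE
  )
}
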