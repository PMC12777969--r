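# VCF output and truth-set input. Output is written as plain text with fixed
# header date/source strings so that repeated runs over the same state are
# byte-identical — whole-file comparison is the contract behind the
# streaming/offline and crash-recovery equivalences.

vcf_header <- function(contigs, sample, filedate, source) {
  c(
    "##fileformat=VCFv4.2",
    paste0("##fileDate=", filedate),
    paste0("##source=", source),
    sprintf("##contig=<ID=%s,length=%d>", contigs$name,
            as.integer(contigs$length)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of structural variant, negative for deletions\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of structural variant\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Number of distinct supporting reads\">",
    "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Mate contig of a breakend\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DR,Number=1,Type=Integer,Description=\"Number of reference-supporting reads\">",
    "##FORMAT=<ID=DV,Number=1,Type=Integer,Description=\"Number of variant-supporting reads\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
}

#' Write a callset as VCF 4.2
#'
#' One record per call with INFO keys `SVTYPE`, `SVLEN` (negative for
#' deletions), `END`, `SUPPORT` (plus `CHR2` for breakends) and sample field
#' `GT:DR:DV`. Positions are converted from the internal 0-based convention
#' to 1-based here, at the single output boundary. Header date and source are
#' fixed (configurable) strings so repeated writes of the same callset are
#' byte-identical.
#'
#' @param calls Callset from [call_variants()], sorted by (contig order,
#'   position); unsorted input is an error.
#' @param contigs [contig_table()].
#' @param path Output path; written atomically (temp file + rename).
#' @param sample Sample name in the header line.
#' @param filedate Fixed `##fileDate` string.
#' @param source Fixed `##source` string.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, contigs, path, sample = "SAMPLE",
                      filedate = "20240101", source = "svstream") {
  if (nrow(calls)) {
    cf <- contig_factor(calls$contig, contigs)
    if (is.unsorted(order(cf, calls$pos))) {
      # order() of a sorted keyset is 1..n; anything else means unsorted input
      stop_svstream("calls must be sorted by (contig order, position)",
                    "svstream_vcf_error")
    }
  }
  lines <- vcf_header(contigs, sample, filedate, source)
  if (nrow(calls)) {
    idx <- stats::ave(seq_len(nrow(calls)), calls$svtype, FUN = seq_along)
    id <- sprintf("svstream.%s.%d", calls$svtype, idx)
    alt <- ifelse(
      calls$svtype == "BND" & !is.na(calls$mate_contig),
      sprintf("N[%s:%d[", calls$mate_contig, calls$mate_pos + 1L),
      sprintf("<%s>", calls$svtype)
    )
    svlen <- ifelse(calls$svtype == "DEL", -calls$length, calls$length)
    # half-open internal end == 1-based inclusive END; point types use POS
    end1 <- ifelse(calls$svtype %in% c("INS", "BND"),
                   calls$end + 1L, calls$end)
    info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d;SUPPORT=%d",
                    calls$svtype, svlen, end1, calls$dv)
    bnd <- calls$svtype == "BND" & !is.na(calls$mate_contig)
    info[bnd] <- paste0(info[bnd], sprintf(";CHR2=%s", calls$mate_contig[bnd]))
    lines <- c(lines, sprintf(
      "%s\t%d\t%s\tN\t%s\t%d\tPASS\t%s\tGT:DR:DV\t%s:%d:%d",
      calls$contig, calls$pos + 1L, id, alt, calls$qual, info,
      calls$gt, calls$dr, calls$dv
    ))
  }
  tmp <- paste0(path, ".tmp", Sys.getpid())
  con <- file(tmp, open = "wb")
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

info_field <- function(info, key) {
  pat <- paste0("(?:^|.*;)", key, "=([^;]*).*")
  hit <- grepl(paste0("(^|;)", key, "="), info)
  out <- rep(NA_character_, length(info))
  out[hit] <- sub(pat, "\\1", info[hit], perl = TRUE)
  out
}

#' Read an SV truth set (or any svstream output) from a VCF
#'
#' Each record needs a resolvable `SVTYPE` (from INFO or a symbolic ALT) and,
#' for length-bearing types, a length from `SVLEN` or `END - POS`; breakends
#' get length 0. The allele frequency is taken from INFO `AF` when present,
#' otherwise computed from sample `GT` fields, otherwise recorded as missing
#' (`NA`). Unresolvable records are skipped with a warning and counted in the
#' `n_skipped` attribute.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return A data.frame of class `svstream_truth` with columns `contig`,
#'   `pos` (0-based), `svtype`, `length`, `af`; attribute `n_skipped`.
#' @export
read_truth_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  empty <- data.frame(contig = character(0), pos = integer(0),
                      svtype = character(0), length = integer(0),
                      af = numeric(0), stringsAsFactors = FALSE)
  if (is.null(fix) || nrow(fix) == 0) {
    attr(empty, "n_skipped") <- 0L
    class(empty) <- c("svstream_truth", "data.frame")
    return(empty)
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  info <- fix$INFO
  svtype <- info_field(info, "SVTYPE")
  # fall back to symbolic ALT <DEL> etc.
  sym <- grepl("^<(DEL|INS|INV|DUP|BND)>$", fix$ALT %||% "")
  svtype[is.na(svtype) & sym] <- gsub("[<>]", "", fix$ALT[is.na(svtype) & sym])
  pos1 <- as.integer(fix$POS)
  svlen <- suppressWarnings(as.integer(info_field(info, "SVLEN")))
  end1 <- suppressWarnings(as.integer(info_field(info, "END")))
  len <- ifelse(!is.na(svlen), abs(svlen),
                ifelse(!is.na(end1), end1 - pos1, NA_integer_))
  len[!is.na(svtype) & svtype == "BND"] <- 0L
  af <- suppressWarnings(as.numeric(info_field(info, "AF")))
  if (any(is.na(af)) && ncol(v@gt %||% matrix(nrow = 0, ncol = 0)) > 1) {
    gt <- vcfR::extract.gt(v, element = "GT")
    gt_af <- apply(gt, 1, function(g) {
      g <- g[!is.na(g)]
      if (!length(g)) return(NA_real_)
      al <- unlist(strsplit(g, "[/|]"))
      al <- al[al != "."]
      if (!length(al)) return(NA_real_)
      mean(al != "0")
    })
    af[is.na(af)] <- gt_af[is.na(af)]
  }
  ok <- !is.na(svtype) & svtype %in% c("DEL", "INS", "INV", "DUP", "BND") &
    !is.na(len)
  n_skipped <- sum(!ok)
  if (n_skipped) {
    warning(sprintf("skipped %d VCF record(s) with unresolvable SVTYPE/length",
                    n_skipped))
  }
  out <- data.frame(
    contig = fix$CHROM[ok], pos = pos1[ok] - 1L, svtype = svtype[ok],
    length = as.integer(len[ok]), af = af[ok], stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_skipped") <- as.integer(n_skipped)
  class(out) <- c("svstream_truth", "data.frame")
  out
}

# Truth-set writer used by the fixture generator: same header machinery, with
# AF in INFO and a GT-only sample column.
write_truth_vcf <- function(svs, contigs, path, sample = "TRUTH",
                            filedate = "20240101", source = "svstream") {
  o <- order(contig_factor(svs$contig, contigs), svs$pos)
  svs <- svs[o, , drop = FALSE]
  lines <- vcf_header(contigs, sample, filedate, source)
  if (nrow(svs)) {
    idx <- stats::ave(seq_len(nrow(svs)), svs$svtype, FUN = seq_along)
    svlen <- ifelse(svs$svtype == "DEL", -svs$length, svs$length)
    end1 <- ifelse(svs$svtype %in% c("INS", "BND"), svs$pos + 1L,
                   svs$pos + svs$length)
    info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d;AF=%s", svs$svtype, svlen,
                    end1, formatC(svs$af, format = "g", digits = 6))
    bnd <- svs$svtype == "BND" & !is.na(svs$mate_contig)
    info[bnd] <- paste0(info[bnd], sprintf(";CHR2=%s", svs$mate_contig[bnd]))
    alt <- ifelse(bnd, sprintf("N[%s:%d[", svs$mate_contig, svs$mate_pos + 1L),
                  sprintf("<%s>", svs$svtype))
    gt <- ifelse(svs$zygosity == "hom", "1/1", "0/1")
    lines <- c(lines, sprintf(
      "%s\t%d\tsvstream.truth.%s.%d\tN\t%s\t.\tPASS\t%s\tGT\t%s",
      svs$contig, svs$pos + 1L, svs$svtype, idx, alt, info, gt
    ))
  }
  tmp <- paste0(path, ".tmp", Sys.getpid())
  con <- file(tmp, open = "wb")
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}
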