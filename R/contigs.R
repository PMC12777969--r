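#' Reference contig table
#'
#' An ordered table of reference sequence names and lengths. The row order is
#' fixed for a whole run and defines the sort order of every callset and
#' signature store.
#'
#' @param names Character vector of unique contig names.
#' @param lengths Integer vector of contig lengths (> 0).
#' @return A data.frame of class `svstream_contigs` with columns `name`,
#'   `length`.
#' @export
contig_table <- function(names, lengths) {
  names <- as.character(names)
  lengths <- as.numeric(lengths)
  if (anyDuplicated(names)) {
    stop_svstream("contig names must be unique", "svstream_contig_error")
  }
  if (length(names) != length(lengths) || any(lengths <= 0)) {
    stop_svstream("contig lengths must be positive and match names",
                  "svstream_contig_error")
  }
  ct <- data.frame(name = names, length = lengths, stringsAsFactors = FALSE)
  class(ct) <- c("svstream_contigs", "data.frame")
  ct
}

#' Read a contig table from a FASTA index (.fai) file
#'
#' @param path Path to a samtools-style `.fai` (or any tab file whose first
#'   two columns are name and length).
#' @return A `svstream_contigs` table.
#' @export
read_fai <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  contig_table(tab[[1]], tab[[2]])
}

#' Read the contig table from a SAM/BAM header
#'
#' @param path SAM or BAM file with `@SQ` lines naming every contig.
#' @return A `svstream_contigs` table in header order.
#' @export
sam_contigs <- function(path) {
  bam <- as_bam_path(path)
  targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  contig_table(names(targets), unname(targets))
}

# Factor a contig vector by run contig order; unknown contigs are a hard error
# everywhere (they indicate a reference mismatch, not recoverable input noise).
contig_factor <- function(x, contigs) {
  bad <- setdiff(unique(x), contigs$name)
  if (length(bad)) {
    stop_svstream(
      paste0("contig(s) not in contig table: ", paste(bad, collapse = ", ")),
      "svstream_contig_error"
    )
  }
  factor(x, levels = contigs$name)
}
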