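#' Signature-extraction parameters
#'
#' Tuning constants for converting alignments into read-level SV signatures.
#'
#' @param min_size Minimum SV length in bp; merged CIGAR candidates and
#'   split-read gaps below this are discarded.
#' @param merge_dist Maximum reference distance in bp between same-type CIGAR
#'   candidates of one read that are merged into a single signature.
#' @param min_mapq Minimum mapping quality; applied to whole records at batch
#'   reading time and to supplementary (SA) segments.
#' @param min_segment_len Minimum reference span in bp for a supplementary
#'   segment to enter split-read analysis.
#' @return A list of class `svstream_extraction_params`.
#' @export
extraction_params <- function(min_size = 30L, merge_dist = 500L,
                              min_mapq = 20L, min_segment_len = 300L) {
  p <- list(
    min_size = as.integer(min_size),
    merge_dist = as.integer(merge_dist),
    min_mapq = as.integer(min_mapq),
    min_segment_len = as.integer(min_segment_len)
  )
  stopifnot(all(vapply(p, function(x) x > 0L, logical(1))))
  class(p) <- "svstream_extraction_params"
  p
}

#' Clustering and genotyping parameters
#'
#' @param max_bias Named integer vector of the maximum start-to-start gap in bp
#'   that keeps two neighbouring signatures of one SV type in the same cluster.
#' @param support_ratio Fraction of the run-level mean depth used as the
#'   supporting-read threshold before clamping.
#' @param min_support_floor,min_support_cap Clamp bounds for the depth-adaptive
#'   supporting-read threshold.
#' @param genotype_eps Alt-read probability under the homozygous-reference
#'   model (and its complement under homozygous-alt) in the binomial
#'   genotype likelihoods.
#' @return A list of class `svstream_cluster_params`.
#' @export
cluster_params <- function(max_bias = c(DEL = 200L, INS = 100L, INV = 500L,
                                        DUP = 500L, BND = 50L),
                           support_ratio = 0.1,
                           min_support_floor = 2L,
                           min_support_cap = 10L,
                           genotype_eps = 0.1) {
  stopifnot(
    all(c("DEL", "INS", "INV", "DUP", "BND") %in% names(max_bias)),
    all(max_bias > 0), support_ratio > 0,
    genotype_eps > 0, genotype_eps < 0.5,
    min_support_floor >= 1, min_support_cap >= min_support_floor
  )
  p <- list(
    max_bias = vapply(max_bias, as.integer, integer(1)),
    support_ratio = support_ratio,
    min_support_floor = as.integer(min_support_floor),
    min_support_cap = as.integer(min_support_cap),
    genotype_eps = genotype_eps
  )
  class(p) <- "svstream_cluster_params"
  p
}

#' Call-to-truth matching criteria
#'
#' The rule used by the detection-rate statistic and by offline benchmarking:
#' a call matches a truth record when types agree (if `type_strict`),
#' breakpoints are within `max_dist` bp, and for length-bearing types the
#' smaller/larger length ratio is at least `min_size_ratio`. Breakends are
#' matched on contig and position only.
#'
#' @param max_dist Maximum breakpoint distance in bp.
#' @param min_size_ratio Minimum min/max length ratio.
#' @param type_strict Require equal SV types.
#' @return A list of class `svstream_match_criteria`.
#' @export
match_criteria <- function(max_dist = 1000L, min_size_ratio = 0.7,
                           type_strict = TRUE) {
  stopifnot(max_dist >= 0, min_size_ratio > 0, min_size_ratio <= 1)
  p <- list(
    max_dist = as.integer(max_dist),
    min_size_ratio = min_size_ratio,
    type_strict = isTRUE(type_strict)
  )
  class(p) <- "svstream_match_criteria"
  p
}
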