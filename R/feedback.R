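# Real-time detection-rate feedback: coverage of a frequency-filtered truth
# set by the current callset, and the early-stop recommendation derived from
# its recent history.

#' Filter a truth set by allele frequency
#'
#' Keeps records whose allele frequency is present and strictly greater than
#' `af_min`; records with missing AF fail the filter.
#'
#' @param truth Truth data.frame from [read_truth_vcf()].
#' @param af_min Allele-frequency threshold (default 0.1, strict).
#' @return Filtered truth data.frame.
#' @export
filter_truth <- function(truth, af_min = 0.1) {
  keep <- !is.na(truth$af) & truth$af > af_min
  out <- truth[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Vectorised core: does each truth record match at least one call?
truth_matched <- function(calls, truth, criteria = match_criteria()) {
  if (!nrow(truth)) return(logical(0))
  if (!nrow(calls)) return(rep(FALSE, nrow(truth)))
  vapply(seq_len(nrow(truth)), function(i) {
    t_contig <- truth$contig[i]
    t_type <- truth$svtype[i]
    t_pos <- truth$pos[i]
    t_len <- truth$length[i]
    sel <- calls$contig == t_contig &
      abs(calls$pos - t_pos) <= criteria$max_dist
    if (criteria$type_strict) sel <- sel & calls$svtype == t_type
    if (!any(sel)) return(FALSE)
    if (t_type == "BND") return(TRUE)  # position and contig test only
    ratio <- pmin(calls$length[sel], t_len) / pmax(calls$length[sel], t_len)
    any(ratio >= criteria$min_size_ratio)
  }, logical(1))
}

#' Does a call match a truth record?
#'
#' @param call One-row callset data.frame (or list with `contig`, `pos`,
#'   `svtype`, `length`).
#' @param truth One-row truth data.frame (or list with the same fields).
#' @param criteria [match_criteria()].
#' @return Logical scalar.
#' @export
sv_match <- function(call, truth, criteria = match_criteria()) {
  truth_matched(as.data.frame(call, stringsAsFactors = FALSE),
                as.data.frame(truth, stringsAsFactors = FALSE), criteria)[1]
}

#' Detection rate of a truth set by a callset
#'
#' Truth-side coverage: the fraction of truth records matched by at least one
#' call. Each truth record counts once however many calls hit it, and one
#' call may cover several truth records, so adding calls can never lower the
#' rate.
#'
#' @param calls Callset data.frame.
#' @param truth Nonempty truth data.frame (empty truth is an error: the
#'   statistic is undefined).
#' @param criteria [match_criteria()].
#' @return List with `n_matched` and `rate`.
#' @export
detection_rate <- function(calls, truth, criteria = match_criteria()) {
  if (!nrow(truth)) {
    stop_svstream("detection rate is undefined for an empty truth set",
                  "svstream_feedback_error")
  }
  m <- sum(truth_matched(calls, truth, criteria))
  list(n_matched = as.integer(m), rate = m / nrow(truth))
}

#' Early-stop recommendation from a detection-rate history
#'
#' Recommends stopping when the last `patience` rates are all at least
#' `threshold`; a history shorter than `patience` never recommends stopping.
#'
#' @param rate_history Numeric vector of per-cycle detection rates.
#' @param threshold Detection-rate threshold.
#' @param patience Number of consecutive qualifying cycles required (>= 1).
#' @return Logical scalar.
#' @export
should_stop <- function(rate_history, threshold, patience = 2L) {
  stopifnot(patience >= 1)
  if (length(rate_history) < patience) return(FALSE)
  all(utils::tail(rate_history, patience) >= threshold)
}

#' Benchmark a callset against a same-sample truth set
#'
#' Offline precision/recall/F1 under the same matching rule as the feedback
#' statistic: recall is truth-side coverage, precision the fraction of calls
#' matching at least one truth record.
#'
#' @param calls Callset data.frame.
#' @param truth Truth data.frame.
#' @param criteria [match_criteria()].
#' @return List with `precision`, `recall`, `f1`, `n_calls`, `n_truth`.
#' @export
sv_benchmark <- function(calls, truth, criteria = match_criteria()) {
  recall <- if (nrow(truth)) {
    mean(truth_matched(calls, truth, criteria))
  } else NA_real_
  precision <- if (nrow(calls)) {
    # symmetric rule: a call is a true positive if some truth matches it
    mean(vapply(seq_len(nrow(calls)), function(i) {
      any(truth_matched(calls[i, , drop = FALSE], truth, criteria))
    }, logical(1)))
  } else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1,
       n_calls = nrow(calls), n_truth = nrow(truth))
}
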