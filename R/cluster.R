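# Clustering, depth-adaptive support filtering, and genotyping of the
# cumulative signature store. call_variants() is a pure function of
# (store, depth, params): re-running it on the same state reproduces the
# interim VCF byte for byte, which is what makes the streaming callset equal
# the offline one.

#' Partition sorted signatures into clusters
#'
#' Greedy linear scan over signatures of one contig and SV type sorted by
#' start: a new cluster opens whenever the start-to-start gap to the previous
#' signature exceeds `max_bias`. Gaps chain, so a cluster may span more than
#' `max_bias` end to end.
#'
#' @param sigs Signature data.frame (one contig, one type, sorted by start).
#' @param max_bias Maximum start gap in bp.
#' @return Integer vector of cluster ids (1-based, non-decreasing).
#' @export
partition_signatures <- function(sigs, max_bias) {
  n <- nrow(sigs)
  if (!n) return(integer(0))
  cumsum(c(TRUE, diff(sigs$start) > max_bias))
}

#' Summarise one cluster into a candidate call
#'
#' Position and length are lower medians of the member signatures (the lower
#' of the two central order statistics for even counts, so coordinates stay
#' integral and permutation-invariant); support is the number of distinct
#' read ids. For breakends the mate is the majority mate contig with the
#' lower-median mate position among its members.
#'
#' @param cluster Signature data.frame of one cluster.
#' @return A list with `pos`, `length`, `dv`, `read_ids`, `mate_contig`,
#'   `mate_pos`.
#' @export
resolve_cluster <- function(cluster) {
  stopifnot(nrow(cluster) > 0)
  mate_contig <- NA_character_
  mate_pos <- NA_integer_
  if (cluster$svtype[1] == "BND" && !all(is.na(cluster$mate_contig))) {
    tab <- sort(table(cluster$mate_contig), decreasing = TRUE)
    mate_contig <- names(tab)[1]
    sel <- cluster$mate_contig == mate_contig
    mate_pos <- as.integer(lower_median(cluster$mate_pos[sel]))
  }
  list(
    pos = as.integer(lower_median(cluster$start)),
    length = as.integer(lower_median(cluster$length)),
    dv = length(unique(cluster$read_id)),
    read_ids = sort(unique(cluster$read_id)),
    mate_contig = mate_contig,
    mate_pos = mate_pos
  )
}

#' Depth-adaptive supporting-read threshold
#'
#' `clamp(round_half_up(support_ratio * mean_depth), floor, cap)`: a
#' piecewise-constant function of the run-level mean depth. As depth
#' accumulates during a run the threshold steps upward, which can transiently
#' drop marginal calls right after a step.
#'
#' @param depth Run-level mean depth (nonnegative).
#' @param params [cluster_params()].
#' @return Integer threshold.
#' @export
min_support <- function(depth, params = cluster_params()) {
  stopifnot(depth >= 0)
  as.integer(clamp(round_half_up(params$support_ratio * depth),
                   params$min_support_floor, params$min_support_cap))
}

#' Genotype a call from supporting and reference read counts
#'
#' Binomial likelihoods over `n = dv + dr` reads with alt-read probability
#' `eps` (0/0), `0.5` (0/1) and `1 - eps` (1/1), a uniform prior, and the
#' maximum-posterior genotype (ties resolved toward the lower-alt genotype).
#' Quality is `round(-10 log10(1 - max posterior))`, capped at 100.
#'
#' @param dv Supporting (variant) read count.
#' @param dr Reference read count.
#' @param eps Sequencing/assignment error fraction (default 0.1).
#' @return List with `gt` ("0/0", "0/1", "1/1", or "./." when `dv + dr = 0`)
#'   and integer `qual`.
#' @export
genotype_call <- function(dv, dr, eps = 0.1) {
  n <- dv + dr
  if (n == 0L) return(list(gt = "./.", qual = 0L))
  p <- c(eps, 0.5, 1 - eps)
  lik <- stats::dbinom(dv, n, p)
  post <- lik / sum(lik)
  g <- which.max(post)  # which.max takes the first maximum: lower-alt wins
  q <- -10 * log10(max(0, 1 - post[g]))
  list(gt = c("0/0", "0/1", "1/1")[g],
       qual = as.integer(min(100, round(q))))
}

#' Cluster and genotype the signature store
#'
#' For every (contig, SV type): sort, [partition_signatures()], summarise with
#' [resolve_cluster()], keep candidates whose distinct-read support reaches
#' the depth-adaptive [min_support()], estimate reference reads from the local
#' depth (`dr = max(0, round_half_up(local_depth) - dv)`), and genotype.
#'
#' @param store Signature data.frame accumulated over all processed batches.
#' @param depth A [depth_track()] accumulated over the same batches.
#' @param contigs [contig_table()].
#' @param params [cluster_params()].
#' @return Callset data.frame sorted by (contig order, position, type) with
#'   columns `contig`, `pos`, `svtype`, `length`, `end`, `dv`, `dr`, `gt`,
#'   `qual`, `af`, `mate_contig`, `mate_pos`.
#' @export
call_variants <- function(store, depth, contigs, params = cluster_params()) {
  if (!nrow(store)) return(empty_call_frame())
  ms <- min_support(mean_depth(depth), params)
  store <- sort_signatures(store, contigs)
  key <- paste(store$contig, store$svtype, sep = "\r")
  calls <- list()
  for (k in unique(key)) {
    sigs <- store[key == k, , drop = FALSE]
    svtype <- sigs$svtype[1]
    cl <- partition_signatures(sigs, params$max_bias[[svtype]])
    for (id in unique(cl)) {
      cand <- resolve_cluster(sigs[cl == id, , drop = FALSE])
      if (cand$dv < ms) next
      dr <- max(0L, as.integer(
        round_half_up(local_depth(depth, sigs$contig[1], cand$pos))
      ) - cand$dv)
      g <- genotype_call(cand$dv, dr, params$genotype_eps)
      end <- switch(svtype,
        INS = cand$pos,
        BND = cand$pos,
        cand$pos + cand$length
      )
      calls[[length(calls) + 1L]] <- data.frame(
        contig = sigs$contig[1], pos = cand$pos, svtype = svtype,
        length = cand$length, end = as.integer(end),
        dv = as.integer(cand$dv), dr = dr, gt = g$gt, qual = g$qual,
        af = cand$dv / (cand$dv + dr),
        mate_contig = cand$mate_contig, mate_pos = cand$mate_pos,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(calls)) return(empty_call_frame())
  out <- do.call(rbind, calls)
  o <- order(contig_factor(out$contig, contigs), out$pos, out$svtype)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}
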