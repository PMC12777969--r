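# Independent oracles used by property and acceptance tests. These are
# deliberately separate implementations: they share no code with the package
# internals they check.

# Brute-force genotype posterior from explicit binomial products.
oracle_genotype <- function(dv, dr, eps = 0.1) {
  n <- dv + dr
  if (n == 0) return("./.")
  lik <- vapply(c(eps, 0.5, 1 - eps), function(p) {
    choose(n, dv) * p^dv * (1 - p)^(n - dv)
  }, numeric(1))
  post <- lik / sum(lik)
  c("0/0", "0/1", "1/1")[which(post == max(post))[1]]
}

# Character-by-character CIGAR walk emitting merged DEL/INS candidates.
# Independent parser (no explodeCigar*) and an independent nested-while
# formulation of the chained merge rule.
oracle_cigar_signatures <- function(ref_start, cigar, min_size = 30,
                                    merge_dist = 500) {
  chars <- strsplit(cigar, "")[[1]]
  num <- ""
  refpos <- ref_start
  dels <- list(); inss <- list()
  for (ch in chars) {
    if (ch %in% as.character(0:9)) {
      num <- paste0(num, ch)
      next
    }
    len <- as.integer(num); num <- ""
    if (ch %in% c("M", "=", "X", "N")) {
      refpos <- refpos + len
    } else if (ch == "D") {
      dels[[length(dels) + 1]] <- c(refpos, len)
      refpos <- refpos + len
    } else if (ch == "I") {
      inss[[length(inss) + 1]] <- c(refpos, len)
    }
  }
  merge_one <- function(items, type) {
    if (!length(items)) return(NULL)
    anchors <- vapply(items, `[`, numeric(1), 1)
    lens <- vapply(items, `[`, numeric(1), 2)
    out <- NULL
    i <- 1
    while (i <= length(anchors)) {
      j <- i
      while (j + 1 <= length(anchors) &&
             anchors[j + 1] - anchors[j] <= merge_dist) {
        j <- j + 1
      }
      total <- sum(lens[i:j])
      start <- if (type == "DEL") anchors[i] else {
        floor(sum(anchors[i:j] * lens[i:j]) / total + 0.5)
      }
      if (total >= min_size) {
        out <- rbind(out, data.frame(svtype = type, start = start,
                                     length = total))
      }
      i <- j + 1
    }
    out
  }
  out <- rbind(merge_one(dels, "DEL"), merge_one(inss, "INS"))
  if (is.null(out)) {
    out <- data.frame(svtype = character(0), start = numeric(0),
                      length = numeric(0))
  }
  out[order(out$svtype, out$start), , drop = FALSE]
}

# Random but valid CIGAR: M blocks interleaved with I/D events, optional
# soft clips.
random_cigar <- function() {
  n_ev <- sample(0:6, 1)
  parts <- character(0)
  if (runif(1) < 0.3) parts <- c(parts, paste0(sample(1:500, 1), "S"))
  parts <- c(parts, paste0(sample(1:600, 1), "M"))
  for (i in seq_len(n_ev)) {
    parts <- c(parts, paste0(sample(1:80, 1), sample(c("I", "D"), 1)),
               paste0(sample(1:600, 1), "M"))
  }
  if (runif(1) < 0.3) parts <- c(parts, paste0(sample(1:500, 1), "S"))
  paste(parts, collapse = "")
}
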