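# Internal helpers shared across modules.

# round() uses banker's rounding; callset arithmetic needs the deterministic
# half-up convention so merged insertion anchors and depth-derived counts are
# stable across platforms.
round_half_up <- function(x) floor(x + 0.5)

# Lower median: for even n return the n/2-th order statistic. Used for cluster
# position/length summaries so ties never produce half-integer coordinates.
lower_median <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run code with a private RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_svstream <- function(msg, class) {
  stop(structure(
    class = c(class, "svstream_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_signature_frame <- function() {
  data.frame(
    svtype = character(0), contig = character(0),
    start = integer(0), length = integer(0),
    mate_contig = character(0), mate_pos = integer(0),
    read_id = character(0), origin = character(0),
    stringsAsFactors = FALSE
  )
}

empty_call_frame <- function() {
  data.frame(
    contig = character(0), pos = integer(0), svtype = character(0),
    length = integer(0), end = integer(0), dv = integer(0), dr = integer(0),
    gt = character(0), qual = integer(0), af = numeric(0),
    mate_contig = character(0), mate_pos = integer(0),
    stringsAsFactors = FALSE
  )
}
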