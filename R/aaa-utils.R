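# shared low-level helpers

NUCS <- c("A", "C", "T", "G")

#' Mix arbitrary values into a reproducible 32-bit seed
#'
#' Deterministic hash of integers/strings used to derive independent
#' sub-stream seeds per (seed, node, phase, segment), so that per-segment
#' evolution is reproducible regardless of iteration order.
#'
#' @param ... integers or character scalars/vectors to mix.
#' @return a single integer in `[0, 2^31)`.
#' @keywords internal
mix_seed <- function(...) {
  h <- 104729
  for (p in list(...)) {
    if (is.character(p)) {
      p <- vapply(p, function(s) {
        cs <- utf8ToInt(s)
        sum(cs * seq_along(cs)) %% 1000003
      }, numeric(1))
    }
    for (v in as.numeric(p)) {
      h <- (h * 7919 + (abs(v) %% 1000003) + 1) %% 2147483563
    }
  }
  as.integer(h)
}

# sample() without its surprising scalar-x behaviour
sample_one <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

# draw n category labels from a named probability vector
sample_cat <- function(prob, n = 1L) {
  names(prob)[sample.int(length(prob), n, replace = TRUE, prob = prob)]
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0

# positions of transitions among A<->G, C<->T
is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}
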