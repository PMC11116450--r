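#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a child seed from a global seed and a counter
#'
#' Expands one global seed into a stream of per-column / per-stage child
#' seeds so that results are reproducible independently of the order in
#' which columns or stages are generated. The scheme is a fixed affine
#' congruential step kept below 2^31 so the result is always a valid R
#' integer seed.
#'
#' @param seed integer global seed.
#' @param index nonnegative integer counter (column or stage index).
#' @return an integer seed.
#' @export
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  # 2147483629 is the largest prime below 2^31; multiplier is an arbitrary
  # fixed odd constant. All arithmetic in double, exact below 2^53.
  as.integer((abs(seed) * 48271 + index * 16807 + 1) %% 2147483629)
}

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("oastratify_config_error", "error")))
}

stop_degenerate <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("oastratify_degenerate_error", "error")))
}
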