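#' @importFrom rlang abort warn inform %||% .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats rbinom rpois runif setNames
#' @importFrom utils head tail
NULL

# internal: stop with a classed condition so callers/tests can be specific
.stop <- function(msg, class) {
  rlang::abort(msg, class = c(class, "sexmarkr_error"))
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == trunc(x)
}

.is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

# derive a phase seed from a master seed; keeps results < 2^31 - 1
.sub_seed <- function(seed, phase) {
  (as.numeric(seed) * 97L + phase * 1009L) %% 2147483629
}
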