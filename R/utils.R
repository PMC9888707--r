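# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm glm binomial coef vcov pnorm pt pchisq qchisq
#'   rnorm rbinom rpois runif median sd quantile complete.cases
#'   fisher.test p.adjust pbinom dbinom ks.test rlnorm setNames var
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0 | x > 1))
    stop_input(sprintf("'%s' must be a probability in [0, 1]", name))
  invisible(x)
}

# Deterministic named substream seed derived from one root seed, kept
# below 2^31 so it is a valid R integer.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- (sum(codes * seq_along(codes)) * 31 + 17) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  set.seed(substream_seed(seed, name))
  expr
}

# Largest-remainder rounding of n * p to integer counts summing to n.
balanced_counts <- function(n, p) {
  if (n == 0L) return(rep(0L, length(p)))
  p <- p / sum(p)
  raw <- n * p
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    o <- order(raw - k, decreasing = TRUE)
    k[o[seq_len(rem)]] <- k[o[seq_len(rem)]] + 1
  }
  as.integer(k)
}
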