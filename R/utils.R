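#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate binomial chisq.test coef dnorm glm.fit
#'   model.frame model.matrix model.response median optim pchisq plogis
#'   pnorm qlogis rbinom rnorm runif setNames terms uniroot var
#' @importFrom utils read.csv write.csv modifyList
NULL

# log(sum(exp(x))) by row of a matrix, overflow-safe
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Derive a reproducible child seed for a pipeline stage
#'
#' One master seed drives the whole pipeline; each stage (women, geography,
#' ...) gets its own deterministic child seed so stages can be rerun in
#' isolation and still match an end-to-end run.
#'
#' @param seed master integer seed.
#' @param stage character stage label.
#' @return an integer seed in \code{[0, 2^31 - 2]}.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 16807) %% (2^31 - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, msg, call. = FALSE) {
  stop(sprintf("[%s] %s", stage, msg), call. = call.)
}
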