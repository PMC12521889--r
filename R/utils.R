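#' @useDynLib valdec, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rpois var sd predict lm coef quantile
#'   binom.test pchisq
#' @importFrom utils write.csv read.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' Deterministically maps a (master seed, label) pair to a 31-bit integer so
#' that every stochastic component of an experiment draws from its own
#' stream, all reproducible from one master seed.
#'
#' @param seed master seed (integer).
#' @param ... labels (strings/numbers) identifying the consumer.
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, ...) {
  salt <- paste(unlist(list(...)), collapse = "/")
  h <- as.double(seed %% 2147483647)
  for (k in utf8ToInt(salt)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# numerically stable row softmax
softmax_rows <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# Shannon entropy (nats) of one distribution or of each row
entropy_nats <- function(p) {
  f <- function(v) {
    v <- v[v > 0]
    -sum(v * log(v))
  }
  if (is.null(dim(p))) f(p) else apply(p, 1, f)
}

onehot <- function(idx, n) {
  m <- matrix(0, length(idx), n)
  ok <- !is.na(idx) & idx >= 1
  m[cbind(which(ok), idx[ok])] <- 1
  m
}

# promote [cells x bins] to [cells x bins x 1]
as_trial_array <- function(x) {
  if (length(dim(x)) == 2L) array(x, dim = c(dim(x), 1L)) else x
}
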