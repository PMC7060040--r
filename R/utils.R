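#' @import data.table
#' @importFrom stats rnorm runif rgeom rpois optim ecdf quantile chisq.test
#'   dist sd var
#' @importFrom utils head tail read.csv write.csv packageVersion
#' @importFrom graphics hist
NULL

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded helpers never perturb the session stream.
#' `NULL` leaves the RNG untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Deterministic substream seeds
#'
#' One master seed spawns independent child seeds per generator, restart or
#' pipeline stage. Values stay below 2^31 - 1.
#'
#' @param seed master integer seed (or `NULL`, passed through).
#' @param stream integer substream index.
#' @return derived integer seed.
#' @export
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 104729) %%
               2147483647)
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# row-normalize a non-negative matrix; zero rows left as uniform
row_normalize <- function(M) {
  rs <- rowSums(M)
  bad <- rs <= 0 | !is.finite(rs)
  if (any(bad)) {
    M[bad, ] <- 1
    rs[bad] <- ncol(M)
  }
  M / rs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invariant <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
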