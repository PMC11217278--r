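#' @useDynLib subparc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats anova aggregate lm median pchisq pf pnorm pt qnorm quantile rbinom
#'   rmultinom rnorm runif sd var BIC complete.cases setNames model.matrix relevel
#'   as.formula cor
#' @importFrom utils head read.csv write.csv tail
NULL

# Typed condition helpers: config errors (exit 2), data errors (3),
# statistical precondition failures (4).
abort_config <- function(msg) stop(errorCondition(msg, class = c("subparc_config_error", "subparc_error")))
abort_data   <- function(msg) stop(errorCondition(msg, class = c("subparc_data_error", "subparc_error")))
abort_stat   <- function(msg) stop(errorCondition(msg, class = c("subparc_stat_error", "subparc_error")))

#' Derive a scoped child seed from a master seed
#'
#' Every source of randomness in the package draws from a child stream derived
#' from `(master_seed, tag)` so that, e.g., changing the classifier search
#' budget never perturbs the synthetic cohort, and cohorts are extensible
#' without perturbing existing subjects.
#'
#' @param master integer master seed.
#' @param ... tags (coerced to character) identifying the scope, e.g.
#'   `derive_seed(7, "subject", 12)`.
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  tag <- paste(c(format(master, scientific = FALSE), vapply(list(...), as.character, "")),
               collapse = "/")
  bytes <- utf8ToInt(tag)
  # FNV-1a over the tag bytes, folded into 31 bits (kept in double precision:
  # all intermediates < 2^53 so arithmetic is exact).
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

# xor of two non-negative doubles representing 32-bit ints
bitwXor_dbl <- function(a, b) {
  r <- 0; p <- 1
  for (i in 1:32) {
    r <- r + p * as.numeric((a %% 2) != (b %% 2))
    a <- a %/% 2; b <- b %/% 2; p <- p * 2
    if (a == 0 && b == 0) break
  }
  r
}

# Evaluate expr with a temporarily-set RNG state, restoring on exit.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# md5 of an arbitrary R object (via serialization to a temp file); used for
# content-hash cache keys and provenance.
hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
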