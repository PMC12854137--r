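#' @useDynLib vssunet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif median lm coef sd
#' @importFrom utils modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a temporary RNG state; restores .Random.seed afterwards so
# package functions never clobber the caller's stream.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Truncated normal at +/- 2 sd, the usual transformer/VSS initializer.
trunc_normal <- function(n, sd = 0.02) {
  x <- rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

init_mat <- function(nin, nout, sd = 0.02) matrix(trunc_normal(nin * nout, sd), nin, nout)

sigmoid_ <- function(x) 1 / (1 + exp(-x))
silu_ <- function(x) x * sigmoid_(x)
silu_grad_ <- function(x) { s <- sigmoid_(x); s * (1 + x * (1 - s)) }
softplus_ <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
relu_ <- function(x) pmax(x, 0)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# FNV-1a hash of a serialized R object, as a hex string (no digest pkg needed).
# 32-bit arithmetic done on doubles, split 16/16 to stay exact.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2)[-(1:14)]) # drop header
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

is_fm <- function(x) is.array(x) && length(dim(x)) == 3L

check_fm <- function(x, what = "feature map") {
  if (!is_fm(x)) stopf("%s must be an H x W x C array", what)
  d <- dim(x)
  if (any(d < 1L)) stopf("%s has an empty dimension (%s)", what, paste(d, collapse = "x"))
  if (!all(is.finite(x))) stopf("%s contains non-finite values", what)
  invisible(x)
}

fm_mat <- function(x) { d <- dim(x); dim(x) <- c(d[1] * d[2], d[3]); x }
mat_fm <- function(m, H, W) { dim(m) <- c(H, W, ncol(m)); m }
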