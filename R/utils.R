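#' @keywords internal
#' @useDynLib xwas, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Run `code` under a fixed seed without disturbing the caller's RNG state.
# `seed` is forced before the state is saved: a lazily evaluated seed
# expression may itself draw from the caller's RNG.
local_seed <- function(seed, code) {
  seed <- as.integer(seed)
  if (!is.null(old <- get0(".Random.seed", envir = globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stream seed derivation; stays inside 32-bit range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %%
               2147483587) + 1L
}

# Column-standardize to mean 0, sd 1 (population sd is not used anywhere;
# sample sd keeps cor() identities exact).
standardize <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  if (any(s == 0)) stop("cannot standardize a zero-variance column")
  sweep(sweep(X, 2, ctr, "-"), 2, s, "/")
}

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, in log space.
logdiffexp <- function(a, b) {
  if (b > a + 1e-12) stop("logdiffexp requires a >= b")
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
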