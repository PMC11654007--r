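# Internal helpers shared across modules.

# Derive a reproducible child seed from a global seed and a stage label, so
# that independent pipeline stages draw from independent, stable streams.
# Result stays inside the 32-bit integer range R requires of set.seed().
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  chars <- utf8ToInt(stage)
  h <- 0
  for (ch in chars) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(seed) * 7919 + h) %% 2147483647)
}

# Vector of 0/1 from logical / numeric / two-level factor labels.
as_binary01 <- function(x, arg = "labels") {
  if (is.logical(x)) return(as.integer(x))
  if (is.factor(x)) {
    if (nlevels(droplevels(x)) > 2L)
      stop(sprintf("'%s' must have at most two levels", arg), call. = FALSE)
    return(as.integer(x == levels(droplevels(x))[length(levels(droplevels(x)))]))
  }
  x <- as.numeric(x)
  if (!all(x %in% c(0, 1)))
    stop(sprintf("'%s' must be binary (0/1, logical, or a two-level factor)", arg),
         call. = FALSE)
  as.integer(x)
}

# Clopper-Pearson exact confidence interval for a binomial proportion.
clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  c(lower = lo, upper = hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
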