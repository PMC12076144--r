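# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# all package randomness flows through this: evaluate expr under an explicit
# integer seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# derive a stream-specific child seed; kept below 2^31 - 1
child_seed <- function(seed, stream) {
  (as.integer(seed) * 1009L + as.integer(stream)) %% 2147483647L
}

stop_msg <- function(...) stop(sprintf(...), call. = FALSE)

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop_msg("%s must be >= %d", name, min)
  as.integer(x)
}

clip01 <- function(x) pmin(1, pmax(0, x))

site_key <- function(chrom, pos) paste0(chrom, ":", pos)

# half-open interval overlap: [s1, e1) vs [s2, e2)
overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
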