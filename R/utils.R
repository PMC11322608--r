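# Internal helpers shared across modules.

# Population (n-denominator) variance / sd; the model-selection and z-score
# arithmetic is defined on population moments.
pop_var <- function(x) mean((x - mean(x))^2)
pop_sd <- function(x) sqrt(pop_var(x))

# z-score with population sd; returns all-zero when sd == 0 (degenerate
# flat vector) so callers can detect "no structure" instead of NaN.
pop_zscore <- function(x) {
  s <- pop_sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Deterministic polynomial string hash over the Mersenne prime 2^31 - 1,
# used to fan a single global seed out to per-segment sampler seeds.
# Pure double arithmetic (values stay < 2^43), so no integer overflow.
string_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 4099 + b) %% 2147483647
  h
}

# Seed for one (focus, context, k) sampler run, derived from the global seed.
segment_seed <- function(seed, focus, context, k) {
  as.integer((string_hash(paste(focus, context, k, sep = "|")) + seed) %% 2147483647)
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_binary <- function(x) all(x %in% c(0, 1))
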