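# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a deterministic child seed from a parent seed and a stream label.
# Kept strictly below 2^31 so it is always a valid R integer.
child_seed <- function(seed, stream, k = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + k * 7919) %% 2147483563) + 1L
}

# Names of feature columns in a subject table. Features are the columns whose
# names match `prefix` (the generator emits roi_001 ... roi_NNN).
feature_names <- function(data, prefix = "^roi_") {
  nm <- grep(prefix, names(data), value = TRUE)
  if (length(nm) == 0) {
    abort("no feature columns found (expected names matching '^roi_')")
  }
  nm
}

feature_matrix <- function(data, prefix = "^roi_") {
  as.matrix(data[, feature_names(data, prefix), drop = FALSE])
}

# Canonical form of a hard clustering: relabel clusters by order of first
# appearance so two labelings that differ only by a permutation compare equal.
canonical_labels <- function(labels) {
  match(labels, unique(labels))
}

# Stratified fold assignment: within every stratum, fold ids are dealt out in
# shuffled round-robin order so fold sizes differ by at most one per stratum.
stratified_folds <- function(strata, folds, seed) {
  with_seed(seed, {
    out <- integer(length(strata))
    for (s in unique(strata)) {
      i <- which(strata == s)
      out[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
    out
  })
}

# All permutations of 1..n (n small; used for exact label matching).
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- as.integer(append(p, n, after = pos - 1L))
    }
  }
  out
}
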