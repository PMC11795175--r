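# Independent brute-force oracles used to cross-check the package's
# statistics. They share no code with the implementation: tail probabilities
# are enumerated term by term from binomial coefficients, and the running
# scan walks every cutoff with explicit set intersections.

# Hypergeometric upper tail by direct enumeration of P(X = i), i = x..min(K,n).
oracle_hyper_tail <- function(N, K, n, x) {
  if (x <= max(0, K + n - N)) return(1)
  i <- x:min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Running scan over every tie-group boundary of a ranked symbol list.
oracle_scan <- function(symbols, scores_abs, ref_set, N) {
  m <- length(symbols)
  if (m == 0 || length(ref_set) == 0)
    return(list(p_raw = 1, p_corrected = 1, k_best = 0L, n_cutoffs = 0L))
  ps <- c(); ks <- c()
  for (k in seq_len(m)) {
    if (k < m && scores_abs[k] == scores_abs[k + 1]) next  # inside a tie group
    x <- length(intersect(symbols[seq_len(k)], ref_set))
    ps <- c(ps, oracle_hyper_tail(N, length(ref_set), k, x))
    ks <- c(ks, k)
  }
  i <- which(ps == min(ps))[1]
  list(p_raw = ps[i], p_corrected = min(1, ps[i] * length(ps)),
       k_best = as.integer(ks[i]), n_cutoffs = length(ps))
}

# Full four-direction + unsigned comparison, mirroring the contract of
# signature_overlap() from first principles.
oracle_compare <- function(query, reference, N) {
  qe <- query$entries; re <- reference$entries
  qup <- qe[qe$score > 0, ]; qdn <- qe[qe$score < 0, ]
  rup <- re$symbol[re$score > 0]; rdn <- re$symbol[re$score < 0]
  scans <- list(
    up_up = oracle_scan(qup$symbol, abs(qup$score), rup, N),
    down_down = oracle_scan(qdn$symbol, abs(qdn$score), rdn, N),
    up_down = oracle_scan(qup$symbol, abs(qup$score), rdn, N),
    down_up = oracle_scan(qdn$symbol, abs(qdn$score), rup, N))
  counts <- c(up_up = length(intersect(qup$symbol, rup)),
              down_down = length(intersect(qdn$symbol, rdn)),
              up_down = length(intersect(qup$symbol, rdn)),
              down_up = length(intersect(qdn$symbol, rup)))
  overall <- oracle_scan(qe$symbol, abs(qe$score), re$symbol, N)
  conc <- -log10(scans$up_up$p_corrected) - log10(scans$down_down$p_corrected)
  disc <- -log10(scans$up_down$p_corrected) - log10(scans$down_up$p_corrected)
  list(scans = scans, counts = counts,
       total_shared = length(intersect(qe$symbol, re$symbol)),
       overall_p = overall$p_corrected,
       concordant_score = conc, discordant_score = disc,
       dominant = if (conc >= disc) "positive" else "negative")
}

# Random signature inside a symbol pool; discrete score magnitudes force tie
# groups so the tie-boundary logic is exercised.
random_signature <- function(pool, n, name = "rand", tie_levels = 6) {
  syms <- sample(pool, n)
  mags <- sample(seq_len(tie_levels), n, replace = TRUE) / 2
  signs <- sample(c(-1, 1), n, replace = TRUE)
  gene_signature(syms, mags * signs, name = name)
}

# Negate all scores of a signature.
negate_signature <- function(sig) {
  gene_signature(sig$entries$symbol, -sig$entries$score,
                 sig$entries$p_value, name = sig$name, species = sig$species)
}

small_config <- function(seed, ...) {
  synthetic_config(universe_size = 600, maturity_size = 120, ph_up_size = 10,
                   ph_down_size = 40, hyper_size = 150,
                   n_background_degs = 30, seed = seed, ...)
}
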