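# independent oracles, written before the implementation paths they check

# schoolbook polynomial long division: parity symbols of a systematic RS
# codeword, computed coefficient-by-coefficient (no LFSR shortcut)
oracle_rs_parity <- function(data, spec) {
  f <- spec$field
  np <- spec$n - spec$k
  dividend <- c(integer(np), rev(as.integer(data)))  # ascending x^(np)*m(x)
  g <- spec$generator
  for (d in length(dividend):(np + 1L)) {
    c0 <- dividend[d]
    if (c0 != 0L) {
      seg <- (d - np):d
      dividend[seg] <- bitwXor(dividend[seg], gf_mul(f, c0, g))
    }
  }
  rev(dividend[seq_len(np)])
}

# brute-force sliding dynamic-programming semi-global alignment: query
# aligned end-to-end, target locally (free end gaps in the target only);
# returns the best achievable score
oracle_semiglobal_score <- function(query, target, match = 1, mismatch = -1,
                                    gap = -2) {
  q <- strsplit(query, "")[[1L]]
  t <- strsplit(target, "")[[1L]]
  nq <- length(q); nt <- length(t)
  D <- matrix(-Inf, nq + 1L, nt + 1L)
  D[1L, ] <- 0                       # free leading gap in the target
  for (i in seq_len(nq)) D[i + 1L, 1L] <- i * gap
  for (i in seq_len(nq)) {
    for (j in seq_len(nt)) {
      s <- if (q[i] == t[j]) match else mismatch
      D[i + 1L, j + 1L] <- max(D[i, j] + s,       # (mis)match
                               D[i, j + 1L] + gap, # gap in target
                               D[i + 1L, j] + gap) # gap in query
    }
  }
  max(D[nq + 1L, ])                  # free trailing gap in the target
}

# deterministic single-electrode read set for a strand table
sim_pool_reads <- function(strands, params, seed = 1L, cycle = 0L,
                           model = NULL) {
  simulate_reads(list(electrode("E1", strands)), "E1", params,
                 cycle = cycle, model = model, seed = seed)
}

random_bytes <- function(n, seed) with_seed(seed, sample(0:255, n, replace = TRUE))

# first d reads of one index bin: exact-depth subsets for consensus studies
reads_at_depth <- function(reads, index, d) {
  utils::head(reads$sequence[reads$index == index], d)
}
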