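# Independent brute-force oracles kept deliberately separate from the
# package implementations they check.

# greedy clumping by direct definition: smallest p first, absorb in-window
# high-LD neighbours, repeat
clump_oracle <- function(assoc, ld, r2 = 0.1, window = 5e5) {
  assigned <- rep(NA_character_, nrow(assoc))
  repeat {
    cand <- which(is.na(assigned))
    if (!length(cand)) break
    i <- cand[order(assoc$p[cand], assoc$pos[cand])][1]
    assigned[i] <- assoc$variant_id[i]
    for (j in which(is.na(assigned))) {
      if (assoc$chrom[j] == assoc$chrom[i] &&
          abs(assoc$pos[j] - assoc$pos[i]) <= window &&
          ld[assoc$variant_id[i], assoc$variant_id[j]] > r2) {
        assigned[j] <- assoc$variant_id[i]
      }
    }
  }
  assigned
}
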