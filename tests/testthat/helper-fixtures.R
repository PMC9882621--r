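# Shared fixtures, built in code.

# small toy genome + catalog + decoy, cached per test run
toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_genome(L = 3000L, seed = 42L)
    cache
  }
})

random_genome <- function(L, seed) {
  set.seed(seed)
  circular_genome("chrM", paste(sample(c("A", "C", "G", "T"), L,
                                       replace = TRUE), collapse = ""))
}

# random non-overlapping edit set (substitutions, insertions, deletions)
random_edits <- function(g, n_edits, seed) {
  set.seed(seed)
  # keep edits away from position 1 and the end so deletions fit
  pos <- sort(sample(10:(g$length - 10L), n_edits * 3))
  pos <- pos[c(TRUE, diff(pos) > 6)][seq_len(n_edits)]
  pos <- pos[!is.na(pos)]
  kind <- sample(c("sub", "ins", "del"), length(pos), replace = TRUE)
  ref <- alt <- character(length(pos))
  for (i in seq_along(pos)) {
    b <- substr(g$sequence, pos[i], pos[i])
    if (kind[i] == "sub") {
      ref[i] <- b
      alt[i] <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    } else if (kind[i] == "ins") {
      ref[i] <- b
      alt[i] <- paste0(b, paste(sample(c("A", "C", "G", "T"),
                                       sample(1:3, 1), replace = TRUE),
                                collapse = ""))
    } else {
      del_len <- sample(1:3, 1)
      ref[i] <- substr(g$sequence, pos[i], pos[i] + del_len)
      alt[i] <- b
    }
  }
  consensus_edits(pos, ref, alt)
}

# a read carrying the CSBII-like tract AA C^a [spacer] C^b GC with flanks
tract_read <- function(a, spacer, b, flank_l = "GGT", flank_r = "AAG") {
  paste0(flank_l, "AA", strrep("C", a), spacer, strrep("C", b), "GC", flank_r)
}
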