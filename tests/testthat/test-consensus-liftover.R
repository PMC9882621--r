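test_that("consensus edit selection applies thresholds and tie-breaks", {
  g <- random_genome(200, seed = 1)
  b <- function(p) substr(g$sequence, p, p)
  othr <- function(p) setdiff(c("A", "C", "G", "T"), b(p))[1]
  calls <- variant_calls("chrM", c(10, 20, 30), sapply(c(10, 20, 30), b),
                         sapply(c(10, 20, 30), othr),
                         af = c(0.97, 0.50, 0.96), dp = 100,
                         ad = c(97, 50, 96))
  ed <- select_consensus_edits(calls, g)
  expect_equal(ed$pos, c(10L, 30L))       # 0.50 below threshold

  # overlapping candidates: higher fraction wins
  ov <- variant_calls("chrM", c(50, 50), c(b(50), b(50)),
                      c("A", "G")[match(TRUE, c(b(50) != "A", TRUE)) + 0:1][1:2],
                      af = c(0.96, 0.99), dp = 100, ad = c(96, 99))
  ov$alt <- vapply(seq_len(2), function(i) setdiff(c("A","C","G","T"), ov$ref[i])[i], "")
  ed2 <- select_consensus_edits(ov, g)
  expect_equal(nrow(ed2), 1L)
  expect_equal(ed2$source_fraction, 0.99)

  # reference mismatch errors
  bad <- variant_calls("chrM", 10, setdiff(c("A","C","G","T"), b(10))[1],
                       b(10), 0.99, 100, 99)
  expect_error(select_consensus_edits(bad, g), "mismatch")

  # nuclear homozygous calls included regardless of fraction column use
  nuc <- variant_calls("chrM", 70, b(70), othr(70), 1, 40, 40)
  nuc$source <- "nuclear_homozygous"
  expect_equal(nrow(select_consensus_edits(nuc, g)), 1L)
})

test_that("consensus construction and position lift follow offset arithmetic", {
  g <- random_genome(100, seed = 3)
  # no edits: identity
  id <- build_consensus(g, consensus_edits(integer(), character(), character()))
  expect_equal(id$genome$sequence, g$sequence)
  expect_equal(lift_position(id$map, 7, "cons_to_ref")$pos, 7)

  # substitution: same length, base changed
  b10 <- substr(g$sequence, 10, 10)
  sub <- build_consensus(g, consensus_edits(10, b10,
                                            setdiff(c("A","C","G","T"), b10)[1]))
  expect_equal(sub$genome$length, 100L)
  expect_false(substr(sub$genome$sequence, 10, 10) == b10)

  # +2 insertion after p = 10: length 102, ref 11 at consensus 13
  b <- substr(g$sequence, 10, 10)
  ins <- build_consensus(g, consensus_edits(10, b, paste0(b, "TT")))
  expect_equal(ins$genome$length, 102L)
  expect_equal(lift_position(ins$map, 11, "ref_to_cons")$pos, 13)
  expect_equal(lift_position(ins$map, 13, "cons_to_ref")$pos, 11)
  # inside inserted bases: left-anchored with flag
  li <- lift_position(ins$map, 11:12, "cons_to_ref")
  expect_equal(li$flag, rep("inside_insertion", 2))
  expect_equal(li$pos, c(10, 10))

  # deletion: reference positions inside map left-anchored
  del_ref <- substr(g$sequence, 40, 42)
  del <- build_consensus(g, consensus_edits(40, del_ref, substr(del_ref, 1, 1)))
  ld <- lift_position(del$map, 41:42, "ref_to_cons")
  expect_equal(ld$flag, rep("inside_deletion", 2))

  # round trip outside footprints; monotone
  outside <- setdiff(1:100, 10:12)
  rt <- lift_position(ins$map, lift_position(ins$map, outside,
                                             "ref_to_cons")$pos, "cons_to_ref")
  expect_equal(rt$pos, outside)
  cons_pos <- lift_position(ins$map, outside, "ref_to_cons")$pos
  expect_true(all(diff(cons_pos) > 0))

  # overlapping edits are rejected
  expect_error(consensus_edits(c(10, 11), c(substr(g$sequence, 10, 11),
                                            substr(g$sequence, 11, 11)),
                               c("A", "A")), "overlap")
  expect_error(lift_position(ins$map, 0, "cons_to_ref"), "range")
})

test_that("variant-call liftover composes edits and computes remainders", {
  g <- circular_genome("chrM", paste0("TTTT", "A", strrep("ACGT", 50)))
  ed <- consensus_edits(5, "A", "G")
  cons <- build_consensus(g, ed)

  # edit with no consensus-space call at the site -> fraction 1.0
  out <- lift_sample_calls(cons$map, variant_calls())
  expect_equal(nrow(out), 1L)
  expect_equal(out$pos, 5L)
  expect_equal(c(out$ref, out$alt), c("A", "G"))
  expect_equal(out$af, 1.0)

  # competing call: A->T (0.3) and A->G (0.7)
  out2 <- lift_sample_calls(cons$map,
                            variant_calls("chrM", 5, "G", "T", 0.3, 100, 30))
  expect_equal(out2$alt, c("G", "T"))
  expect_equal(out2$af[out2$alt == "T"], 0.3)
  expect_equal(out2$af[out2$alt == "G"], 0.7)

  # pass-through at un-edited site: position shifted only
  ins <- build_consensus(g, consensus_edits(10, substr(g$sequence, 10, 10),
                                            paste0(substr(g$sequence, 10, 10), "CA")))
  q <- 50L  # consensus position after the +2 insertion
  pass <- lift_variant_call(ins$map,
                            variant_calls("chrM", q,
                                          substr(ins$genome$sequence, q, q),
                                          "T", 0.2, 100, 20))
  expect_equal(pass$pos, q - 2L)
  expect_equal(pass$af, 0.2)

  # back-mutation to the reference allele is not emitted as a variant
  back <- lift_sample_calls(cons$map,
                            variant_calls("chrM", 5, "G", "A", 0.3, 100, 30))
  expect_equal(nrow(back), 1L)
  expect_equal(back$af, 0.7)
})

test_that("liftover reproduces random edit sets with fraction 1.0", {
  g <- random_genome(2000, seed = 9)
  for (s in 1:25) {
    ed <- random_edits(g, n_edits = 6, seed = 1000 + s)
    cons <- build_consensus(g, ed)
    out <- lift_sample_calls(cons$map, variant_calls())
    # compare against the normalized representation of each edit
    want <- t(vapply(seq_len(nrow(ed)), function(i) {
      nm <- normalize_call(ed$pos[i], ed$ref[i], ed$alt[i], g$sequence)
      c(nm$pos, nm$ref, nm$alt)
    }, c("", "", "")))
    ord <- order(as.integer(want[, 1]), want[, 3])
    expect_equal(out$pos, as.integer(want[ord, 1]))
    expect_equal(out$ref, want[ord, 2])
    expect_equal(out$alt, want[ord, 3])
    expect_true(all(out$af == 1.0))
  }
})

test_that("coverage liftover obeys the exact bookkeeping identity", {
  g <- random_genome(500, seed = 4)
  # identity map copies
  id <- build_consensus(g, consensus_edits(integer(), character(), character()))
  cov <- rpois(500, 80)
  expect_equal(lift_coverage(id$map, cov), cov)

  # deletion: deleted reference positions inherit the left flank depth
  del_ref <- substr(g$sequence, 100, 102)
  del <- build_consensus(g, consensus_edits(100, del_ref, substr(del_ref, 1, 1)))
  covc <- rpois(del$map$cons_length, 60)
  covc[100] <- 80
  out <- lift_coverage(del$map, covc)
  expect_equal(out[101], 80)
  expect_equal(out[102], 80)
  expect_length(out, 500L)

  # insertion: inserted depths dropped, length restored
  b <- substr(g$sequence, 200, 200)
  ins <- build_consensus(g, consensus_edits(200, b, paste0(b, "GG")))
  covi <- rpois(502, 70)
  outi <- lift_coverage(ins$map, covi)
  expect_length(outi, 500L)
  # bookkeeping: total out = total in - inserted + duplicated-flank
  expect_equal(sum(outi), sum(covi) - sum(covi[201:202]))

  expect_error(lift_coverage(ins$map, covi[-1]), "length")
})

test_that("coordinate maps round-trip through the chain text format", {
  g <- random_genome(800, seed = 6)
  ed <- random_edits(g, 5, seed = 77)
  map <- build_consensus(g, ed)$map
  path <- withr::local_tempfile(fileext = ".chain.txt")
  write_chain(map, path)
  map2 <- read_chain(path, g)
  expect_equal(map2$edits$pos, map$edits$pos)
  expect_equal(map2$edits$alt, map$edits$alt)
  expect_equal(map2$cons_length, map$cons_length)
})

test_that("variant normalization trims and left-aligns in homopolymer context", {
  #            123456789
  ref_seq <- "GATCCCCAG"
  # insertion inside the C run shifts to the run's left anchor
  nm <- normalize_call(6, "C", "CC", ref_seq)
  expect_equal(nm$pos, 3L)
  expect_equal(c(nm$ref, nm$alt), c("T", "TC"))
  # parsimony trim of shared suffix/prefix
  nm2 <- normalize_call(4, "CCA", "CTA", ref_seq)
  expect_equal(nm2$pos, 5L)
  expect_equal(c(nm2$ref, nm2$alt), c("C", "T"))
})
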