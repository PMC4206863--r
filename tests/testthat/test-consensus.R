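test_that("consensus takes the per-column majority with alphabetical ties", {
  # identical members: consensus equals the sequence
  aln <- toy_alignment(c(a = "CAACAACAAC", b = "CAACAACAAC", c = "CAACAACAAC"))
  prof <- build_consensus(aln)
  expect_identical(paste(prof$residue, collapse = ""), "CAACAACAAC")
  # majority column {A, A, C}... and a tie column {G, T, G, T}
  aln2 <- toy_alignment(c(a = "CAGCAACAAC", b = "CATCAACAAC",
                          c = "CAGCAACAAC", d = "CATCAACAAC"))
  expect_identical(build_consensus(aln2)$residue[3], "G")  # G < T
  # member order does not matter
  aln3 <- toy_alignment(c(d = "CATCAACAAC", b = "CATCAACAAC",
                          a = "CAGCAACAAC", c = "CAGCAACAAC"))
  expect_identical(build_consensus(aln3)$residue, build_consensus(aln2)$residue)
})

test_that("ragged alignments are rejected", {
  expect_error(toy_alignment(c(a = "CAACAACAAC", b = "CAACAACAACAA")),
               "inconsistent column counts")
})

test_that("packaged complement alignment has the canonical anchor geometry", {
  aln <- complement_scr_alignment()
  expect_identical(nrow(aln$mat), 124L)
  expect_identical(aln$anchor_positions, c(1L, 26L, 39L, 49L))
  prof <- build_consensus(aln)
  expect_identical(prof$residue[c(1, 26, 39, 49)], rep("C", 4))
  expect_identical(prof$region[c(1, 26, 39, 49)], rep("cys_anchor", 4))
  expect_identical(prof$region[11:15], rep("hypervariable_loop", 5))
  expect_true(all(table(prof$region)[c("cys_anchor", "hypervariable_loop")] ==
                    c(4L, 5L)))
})

test_that("position mapping is monotone and the identity without insertions", {
  fx <- gen_alignment_fixture(n_members = 6, substitution_rate = 0.1,
                              insertion_rate = 0, seed = 7)
  aln <- fx$alignment
  for (m in aln$members$id) {
    L <- aln$members$end[aln$members$id == m]
    mapped <- vapply(seq_len(L), function(p)
      map_position_to_consensus(aln, m, p), integer(1))
    expect_identical(mapped, seq_len(L))  # identity on consensus columns
  }
})

test_that("insertions map to the preceding consensus position", {
  fx <- gen_alignment_fixture(n_members = 8, substitution_rate = 0.05,
                              insertion_rate = 0.08, seed = 11)
  aln <- fx$alignment
  got <- vapply(seq_len(nrow(fx$mapping)), function(i) {
    map_position_to_consensus(aln, fx$mapping$member[i],
                              fx$mapping$residue_index[i])
  }, integer(1))
  expect_identical(got, fx$mapping$consensus_pos)
  # monotone within each member
  for (m in unique(fx$mapping$member)) {
    gm <- got[fx$mapping$member == m]
    expect_true(all(diff(gm) >= 0), label = m)
  }
  expect_error(map_position_to_consensus(aln, aln$members$id[1], 9999),
               "outside span")
  expect_error(map_position_to_consensus(aln, "nope", 1), "unknown")
})

test_that("leading residues before the first consensus column are unmappable", {
  aln <- complement_scr_alignment()
  # the packaged members carry two leading residues before Cys-1
  start <- aln$members$start[aln$members$id == "CFH_SCR-20"]
  expect_true(is.na(map_position_to_consensus(aln, "CFH_SCR-20", start)))
  expect_identical(map_position_to_consensus(aln, "CFH_SCR-20", start + 2L), 1L)
})

test_that("region tally partitions mutations with anchor precedence", {
  rt <- region_tally(c(26, 26, 26))
  expect_identical(rt$cys_pct, 100L)
  expect_identical(rt$loop_count + rt$cys_count + rt$other_count, rt$total)
  # anchors take precedence over the loop when they coincide
  expect_identical(consensus_region(12L, anchors = c(12L)), "cys_anchor")
  # empty input: zero counts, absent percentages
  empty <- region_tally(integer(0))
  expect_identical(empty$total, 0L)
  expect_true(is.na(empty$loop_pct))
})

test_that("uniform random positions hit the loop at its length fraction", {
  set.seed(42)
  L <- 51; n <- 5000L
  pos <- sample.int(L, n, replace = TRUE)
  rt <- region_tally(pos)
  # exact binomial 99.9% envelope around 5/51
  lo <- qbinom(5e-4, n, 5 / L); hi <- qbinom(1 - 5e-4, n, 5 / L)
  expect_gte(rt$loop_count, lo)
  expect_lte(rt$loop_count, hi)
  expect_identical(rt$loop_count + rt$cys_count + rt$other_count, n)
})

test_that("accessibility profiles average per position and bin in deciles", {
  one <- list(c(5, 15, 95, NA))
  expect_identical(average_accessibility_profile(one)$bin,
                   c(0L, 1L, 9L, NA_integer_))
  two <- average_accessibility_profile(list(c(10, NA, 0), c(30, 40, 0)))
  expect_equal(two$mean_accessibility, c(20, 40, 0))
  expect_identical(two$bin, c(2L, 4L, 0L))  # mean 20% -> bin 2
  expect_error(average_accessibility_profile(list(1:3, 1:4)), "length")
})

test_that("mapped curated mutations partition into regions exactly", {
  reg <- complement_registry()
  aln <- complement_scr_alignment()
  mapped <- map_mutations_to_consensus(reg, aln)
  in_scr <- mapped[!mapped$region %in% c("outside_scr", "unmappable"), ]
  # every mapped mutation has exactly one region label
  expect_true(all(in_scr$region %in%
                    c("hypervariable_loop", "cys_anchor", "other")))
  rt <- region_tally(in_scr$consensus_pos, anchors = aln$anchor_positions)
  expect_identical(rt$loop_count + rt$cys_count + rt$other_count, rt$total)
  # the CFH linker missense is excluded from consensus mapping
  cfh_outside <- mapped[mapped$protein == "CFH" &
                          mapped$region == "outside_scr", ]
  expect_true(445 %in% cfh_outside$protein_pos)
})
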