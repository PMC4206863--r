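defs <- complement_proteins()

test_that("collapsing to residues conserves mutation counts", {
  df <- data.frame(
    protein = "CFH",
    dna_change = NA, protein_change = c("Arg53Cys", "Arg53His", "Tyr402His"),
    consequence = "missense", disease_tags = "aHUS", phenotype_type = NA,
    source_ref = c("a", "b", "c"), stringsAsFactors = FALSE)
  ann <- collapse_to_residues(as_registry(df), proteins = defs)
  expect_identical(nrow(ann), 2L)
  expect_identical(ann$n_mutations[ann$position == 53], 2L)
  expect_identical(sum(ann$n_mutations), 3L)
  expect_identical(ann$domain[ann$position == 402], "SCR-7")
})

test_that("collapsing synthetic registries matches generator ground truth", {
  for (seed in c(3, 14)) {
    sim <- gen_mutation_table(defs$MCP, n = 150, seed = seed,
                              duplicate_prob = 0.3,
                              mixture = c(missense = 1))
    ann <- collapse_to_residues(sim$registry)
    pos <- sim$truth$positions
    expect_identical(sum(ann$n_mutations), length(pos))
    counts <- table(pos)  # brute-force dictionary count
    expect_identical(nrow(ann), length(counts))
    expect_identical(ann$n_mutations[order(ann$position)],
                     as.integer(counts[order(as.integer(names(counts)))]))
  }
})

test_that("burial summaries split evaluable and unresolved residues", {
  ann <- data.frame(protein = "X", position = c(1, 2, 3, 4, 5),
                    n_mutations = c(1L, 2L, 1L, 1L, 1L))
  prof <- data.frame(resno = c(1, 2, 3, 4), bin = c(0L, 5L, 2L, NA))
  class(prof) <- c("accessibility_profile", "data.frame")
  s <- burial_summary(ann, prof)
  # residue 5 absent and residue 4 side-chain-unresolved: both excluded
  expect_identical(s$unresolved, 2L)
  expect_identical(s$buried, 2L)      # bins 0 and 2
  expect_identical(s$exposed, 1L)
  expect_identical(s$evaluable, 3L)
  expect_identical(s$buried_pct, 67L)
  # counting mutations instead of residues
  s2 <- burial_summary(ann, prof, count_mutations = TRUE)
  expect_identical(s2$buried + s2$exposed + s2$unresolved, 6L)
  # stricter threshold reclassifies bin-2 residues as exposed
  s3 <- burial_summary(ann, prof, threshold_bin = 1)
  expect_identical(s3$buried, 1L)
})

test_that("burial of mapped mutations works end-to-end on the template", {
  template <- scr_template()
  prof <- accessibility_profile(template, n_points = 480)
  reg <- as_registry(data.frame(
    protein = "SYN", dna_change = NA,
    protein_change = paste0(aa1to3(substr(scrmap:::SYNTH_CONSENSUS, 1, 1)),
                            1, "Arg"),
    consequence = "missense", disease_tags = "syn", phenotype_type = NA,
    source_ref = "t", stringsAsFactors = FALSE), validate = FALSE)
  ann <- collapse_to_residues(reg)
  s <- burial_summary(ann, prof)
  expect_identical(s$evaluable + s$unresolved, 1L)
})

test_that("hotspot ranking orders domains by frequency per 100 residues", {
  reg <- complement_registry()
  cfh <- reg[reg$protein == "CFH", ]
  hs <- domain_hotspots(cfh, defs$CFH)
  expect_identical(hs$domain[1], "SCR-20")
  expect_true(all(diff(hs$frequency) <= 0))
  expect_equal(hs$frequency, 100 * hs$count / hs$length)
  # a single loaded domain ranks first
  sim <- gen_mutation_table(defs$MCP, n = 40, seed = 2,
                            rates = c(`SCR-2` = 1),
                            mixture = c(missense = 1))
  hs2 <- domain_hotspots(sim$registry, defs$MCP)
  expect_identical(hs2$domain[1], "SCR-2")
  expect_identical(hs2$count[1], 40L)
  expect_true(all(hs2$count[-1] == 0L))
})

test_that("whole-protein frequency is the length-weighted mean over regions", {
  reg <- complement_registry()
  cfh <- reg[reg$protein == "CFH", ]
  hs <- domain_hotspots(cfh, defs$CFH)
  # counts in domains + counts outside domains = positioned non-intronic
  f <- nonintronic_frequency(cfh, defs$CFH)
  outside <- f$count - sum(hs$count)
  expect_gte(outside, 0L)
  # length-weighted mean of per-domain frequencies recovers the domain-region
  # rate
  dom_len <- sum(hs$length)
  expect_equal(sum(hs$frequency * hs$length) / dom_len,
               100 * sum(hs$count) / dom_len)
})

test_that("uniform mutations leave every domain inside the sampling envelope", {
  sim <- gen_mutation_table(defs$CFH, n = 400, seed = 21,
                            mixture = c(missense = 1))
  hs <- domain_hotspots(sim$registry, defs$CFH)
  for (i in seq_len(nrow(hs))) {
    p <- hs$length[i] / sum(hs$length)
    lo <- qbinom(5e-4, 400, p); hi <- qbinom(1 - 5e-4, 400, p)
    expect_gte(hs$count[i], lo)
    expect_lte(hs$count[i], hi)
  }
})

test_that("enrichment p-values flag a planted hotspot", {
  rates <- setNames(vapply(defs$MCP$domains, domain_length, numeric(1)),
                    names(defs$MCP$domains))
  rates["SCR-3"] <- rates["SCR-3"] * 5
  sim <- gen_mutation_table(defs$MCP, n = 120, seed = 6, rates = rates,
                            mixture = c(missense = 1))
  hs <- domain_hotspots(sim$registry, defs$MCP, enrichment_p = TRUE)
  expect_identical(hs$domain[1], "SCR-3")
  expect_lt(hs$p_enrich[hs$domain == "SCR-3"], 0.001)
})

test_that("phenotype prediction follows the burial heuristic", {
  expect_identical(predict_phenotype_class("Cys", "exposed"), "Type I-like")
  expect_identical(predict_phenotype_class("Arg", "buried"), "Type I-like")
  expect_identical(predict_phenotype_class("Arg", "exposed"), "Type II-like")
  expect_identical(predict_phenotype_class("Arg", NA), "unknown")
  expect_identical(predict_phenotype_class("Arg", "unresolved"), "unknown")
})

test_that("summary reports are self-consistent and detect corruption", {
  reg <- complement_registry()
  rep <- summary_report(reg, defs$C3)
  expect_identical(rep$total, 48L)
  expect_silent(check_report(rep))
  rep$consequence_tally$count[1] <- rep$consequence_tally$count[1] + 1L
  expect_error(check_report(rep), "sum")
})
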