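defs <- complement_proteins()

test_that("protein-change parser handles both dialects and all kinds", {
  cases <- list(
    list("Arg102Gly", "Arg", 102L, "Gly", "missense"),
    list("K65Q", "Lys", 65L, "Gln", "missense"),
    list("Tyr402His", "Tyr", 402L, "His", "missense"),
    list("p.Tyr402His", "Tyr", 402L, "His", "missense"),
    list("Arg1210Ter", "Arg", 1210L, "Ter", "nonsense"),
    list("W528X", "Trp", 528L, "Ter", "nonsense"),
    list("R78*", "Arg", 78L, "Ter", "nonsense"),
    list("Ala304=", "Ala", 304L, "Ala", "silent"),
    list("Ser62Ser", "Ser", 62L, "Ser", "silent"),
    list("Leu24del", "Leu", 24L, NA_character_, "deletion"),
    list("Ser722fs", "Ser", 722L, NA_character_, "frameshift"),
    list("Gly54dup", "Gly", 54L, NA_character_, "insertion"))
  for (cs in cases) {
    p <- parse_protein_change(cs[[1]])
    expect_identical(p$ref_aa, cs[[2]], label = cs[[1]])
    expect_identical(p$position, cs[[3]], label = cs[[1]])
    expect_identical(p$alt_aa, cs[[4]], label = cs[[1]])
    expect_identical(p$kind, cs[[5]], label = cs[[1]])
  }
})

test_that("parser rejects malformed tokens, naming the offender", {
  expect_error(parse_protein_change("Xyz12Abc"), "Xyz12Abc")
  expect_error(parse_protein_change("Arg0Gly"), "non-positive")
  expect_error(parse_protein_change("B12C"), "B12C")
  expect_error(parse_protein_change(""), "non-empty")
  expect_error(parse_protein_change("Arg102"), "Arg102")
  expect_error(parse_protein_change("Ter12Arg"), "stop")
})

test_that("domain assignment covers domains, split parts, linkers and signal", {
  expect_identical(assign_domain(1320, defs$C3)$label, "CUB")  # split part
  expect_identical(assign_domain(155, defs$C3)$label, "MG2")
  expect_identical(assign_domain(770, defs$C3)$label, "MG6")   # split part
  expect_identical(assign_domain(1000, defs$C3)$label, "TED")
  expect_identical(assign_domain(1210, defs$CFH)$label, "SCR-20")
  expect_identical(assign_domain(445, defs$CFH)$label, "linker")
  expect_identical(assign_domain(10, defs$CFH)$label, "signal_peptide")
  expect_error(assign_domain(0, defs$CFH), "outside")
  expect_error(assign_domain(1232, defs$CFH), "outside")
})

test_that("domain definitions enforce span and vocabulary invariants", {
  expect_error(domain_definition("X", "FOO", 1, 10), "domain class")
  expect_error(domain_definition("X", "SCR", 10, 5), "invalid span")
  expect_error(protein_definition("P", "G", "U", 100, list(
    domain_definition("A", "SCR", 1, 50),
    domain_definition("B", "SCR", 40, 90))), "overlap")
  expect_error(protein_definition("P", "G", "U", 100, list(
    domain_definition("A", "SCR", 1, 120))), "outside")
})

test_that("tallies partition records and compose with filters", {
  reg <- complement_registry()
  cfh <- reg[reg$protein == "CFH", ]
  ct <- tally(cfh, "consequence")
  expect_identical(sum(ct$count), attr(ct, "total"))
  expect_identical(attr(ct, "total"), nrow(cfh))
  # per-domain tallies (+ signal/linker) partition the positioned records
  pos <- cfh[!is.na(cfh$position), ]
  dt <- tally(pos, "domain", proteins = defs)
  expect_identical(sum(dt$count), nrow(pos))
  # empty registry: zero table
  empty <- cfh[0, ]
  expect_identical(attr(tally(empty, "consequence"), "total"), 0L)
  expect_error(tally(cfh, "flavour"), "grouping key")
})

test_that("registry round-trips through TSV field-for-field", {
  reg <- complement_registry()
  tmp <- tempfile(fileext = ".tsv")
  write_registry(reg, tmp)
  back <- read_registry(tmp, proteins = defs)
  for (col in c("protein", "dna_change", "protein_change", "consequence",
                "disease_tags", "phenotype_type", "source_ref", "position",
                "ref_aa", "alt_aa")) {
    expect_identical(back[[col]], reg[[col]], label = col)
  }
})

test_that("validation catches inconsistent records", {
  df <- data.frame(protein = "CFH", dna_change = NA, protein_change = "Arg53Cys",
                   consequence = "banana", disease_tags = "aHUS",
                   phenotype_type = NA, source_ref = "x",
                   stringsAsFactors = FALSE)
  expect_error(as_registry(df), "consequence")
  df$consequence <- "missense"
  expect_silent(as_registry(df))
  df$protein_change <- "Arg2000Cys"
  expect_error(as_registry(df, proteins = defs), "outside")
})

test_that("non-intronic frequency matches the definition and is linear", {
  reg <- complement_registry()
  cfh <- reg[reg$protein == "CFH", ]
  f <- nonintronic_frequency(cfh, defs$CFH)
  expect_equal(f$frequency, 100 * f$count / defs$CFH$length)
  # empty registry: frequency 0
  expect_identical(nonintronic_frequency(cfh[0, ], defs$CFH)$rounded, 0L)
  # doubling every record doubles the unrounded frequency
  f2 <- nonintronic_frequency(rbind(cfh, cfh), defs$CFH)
  expect_equal(f2$frequency, 2 * f$frequency)
})

test_that("half-away-from-zero rounding follows the documented convention", {
  expect_identical(round_half_away(c(12.5, 13.08, 2.89, 44.35, -2.5, 0.49)),
                   c(13, 13, 3, 44, -3, 0))
})

test_that("synthetic tally marginals equal the generator's ground truth", {
  for (seed in c(11, 52, 93)) {
    sim <- gen_mutation_table(defs$MCP, n = 120, seed = seed,
                              duplicate_prob = 0.1)
    ct <- tally(sim$registry, "consequence")
    for (cls in names(sim$truth$per_consequence)) {
      got <- ct$count[match(cls, ct$key)]
      expect_identical(ifelse(is.na(got), 0L, got),
                       as.integer(sim$truth$per_consequence[[cls]]),
                       label = paste(seed, cls))
    }
    dt <- tally(sim$registry[!is.na(sim$registry$position), ], "domain",
                proteins = list(MCP = defs$MCP))
    for (dom in names(sim$truth$per_domain)) {
      got <- dt$count[match(dom, dt$key)]
      expect_identical(ifelse(is.na(got), 0L, got),
                       as.integer(sim$truth$per_domain[[dom]]),
                       label = paste(seed, dom))
    }
  }
})
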