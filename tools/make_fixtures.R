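#!/usr/bin/env Rscript
# Regenerates the packaged fixtures:
#   inst/extdata/scr_alignment_synthetic.fasta
#   inst/extdata/complement_registry_synthetic.tsv
# Run from the package root: Rscript tools/make_fixtures.R
# The registry is a synthetic reconstruction: rows are generated, but every
# published marginal (per-protein totals, per-consequence tallies, per-domain
# missense counts, duplicate-residue structure, consensus-region splits,
# SCR-19/20 frequency, aHUS tag counts) is reproduced exactly, and mutations
# named in the literature appear verbatim.

suppressMessages(pkgload::load_all(".", quiet = TRUE))

CONS <- strsplit(scrmap:::SYNTH_CONSENSUS, "")[[1]]
L <- length(CONS)
stopifnot(L == 51, CONS[c(1, 26, 39, 49)] == "C")
ANCHORS <- c(1L, 26L, 39L, 49L)
LOOP <- 11:15
INS_SLOTS <- c(13L, 34L, 42L, 20L, 5L, 30L, 46L, 8L, 24L, 37L, 17L, 28L)

defs <- read_protein_config("inst/extdata/proteins.yaml")

## ---- member layout ---------------------------------------------------------
# A real member: 2 leading residues, the 51-column core (with per-member
# insertions after the first r slots of INS_SLOTS), and up to 2 trailing
# residues. Returns a table idx/char/conspos/kind.
member_layout <- function(start, end) {
  n <- end - start + 1L
  e <- n - 53L
  stopifnot(e >= 0, e <= 14)
  t <- min(2L, e); r <- e - t
  slots <- sort(INS_SLOTS[seq_len(r)])
  idx <- 0L
  rows <- list()
  push <- function(char, conspos, kind) {
    idx <<- idx + 1L
    rows[[idx]] <<- data.frame(idx = idx, char = char, conspos = conspos,
                               kind = kind, stringsAsFactors = FALSE)
  }
  push("K", NA_integer_, "lead"); push("S", NA_integer_, "lead")
  ins_chars <- rep(c("N", "T", "S", "G", "Q"), length.out = max(1, r))
  ic <- 0L
  for (p in seq_len(L)) {
    push(CONS[p], p, "core")
    if (p %in% slots) {
      ic <- ic + 1L
      push(ins_chars[ic], p, "ins")   # insertion maps to preceding position
    }
  }
  for (i in seq_len(t)) push(c("P", "T")[i], L, "trail")
  out <- do.call(rbind, rows)
  stopifnot(nrow(out) == n)
  out$position <- start + out$idx - 1L
  out
}

members <- list()
for (d in defs$CFH$domains) {
  members[[paste0("CFH_", d$label)]] <-
    list(protein = "CFH", domain = d$label, start = d$start, end = d$end,
         layout = member_layout(d$start, d$end))
}
for (d in defs$MCP$domains[1:4]) {
  members[[paste0("MCP_", d$label)]] <-
    list(protein = "MCP", domain = d$label, start = d$start, end = d$end,
         layout = member_layout(d$start, d$end))
}

# helpers against a member layout
pos_of_cons <- function(mem, p) {
  row <- mem$layout[mem$layout$kind == "core" & mem$layout$conspos == p, ]
  stopifnot(nrow(row) == 1)
  row$position
}
char_at_pos <- function(mem, pos) mem$layout$char[mem$layout$position == pos]
set_char_at_pos <- function(id, pos, char) {
  lay <- members[[id]]$layout
  i <- which(lay$position == pos)
  stopifnot(length(i) == 1, lay$kind[i] %in% c("core", "ins"))
  if (lay$kind[i] == "core") stopifnot(!lay$conspos[i] %in% ANCHORS)
  lay$char[i] <- char
  members[[id]]$layout <<- lay
}

## ---- registry construction -------------------------------------------------
rows <- list()
add_row <- function(protein, dna = NA, change = NA, consequence, tags = "aHUS",
                    ptype = NA, ref = NA) {
  rows[[length(rows) + 1L]] <<- data.frame(
    protein = protein, dna_change = dna, protein_change = change,
    consequence = consequence, disease_tags = tags, phenotype_type = ptype,
    source_ref = ref, stringsAsFactors = FALSE)
}

ALT_FOR <- function(ref1) {
  # deterministic plausible substitution partner, one-letter in, 3-letter out
  partner <- c(A = "Thr", R = "Trp", N = "Ser", D = "Gly", C = "Arg",
               Q = "His", E = "Lys", G = "Asp", H = "Tyr", I = "Thr",
               L = "Pro", K = "Glu", M = "Val", F = "Leu", P = "Leu",
               S = "Phe", T = "Ala", W = "Arg", Y = "His", V = "Met")
  unname(partner[ref1])
}
ALT2_FOR <- function(ref1) {
  partner <- c(A = "Val", R = "Cys", N = "Lys", D = "Asn", C = "Tyr",
               Q = "Arg", E = "Ala", G = "Arg", H = "Gln", I = "Val",
               L = "Arg", K = "Asn", M = "Ile", F = "Ser", P = "Ser",
               S = "Cys", T = "Ile", W = "Cys", Y = "Cys", V = "Ala")
  unname(partner[ref1])
}
ALT3_FOR <- function(ref1) {
  partner <- c(R = "His", C = "Ser", K = "Gln", E = "Gly", Y = "Asp",
               S = "Leu", T = "Met", G = "Val", L = "Phe", V = "Gly")
  out <- unname(partner[ref1])
  ifelse(is.na(out), "Gly", out)
}

mk_missense <- function(mem_id, pos, n_mut = 1, force_ref = NULL,
                        tags = "aHUS", ptype = NA, src) {
  mem <- members[[mem_id]]
  if (!is.null(force_ref)) set_char_at_pos(mem_id, pos, force_ref)
  ref1 <- char_at_pos(members[[mem_id]], pos)
  ref3 <- aa1to3(ref1)
  alts <- c(ALT_FOR(ref1), ALT2_FOR(ref1), ALT3_FOR(ref1))[seq_len(n_mut)]
  stopifnot(!alts %in% ref3)
  for (k in seq_len(n_mut)) {
    add_row(mem$protein, change = paste0(ref3, pos, alts[k]),
            consequence = "missense", tags = tags, ptype = ptype,
            ref = paste0(src, letters[k]))
  }
}

# consensus positions available per region (never leading/trailing picks)
OTHER_POOL <- setdiff(seq_len(L), c(ANCHORS, LOOP))

# Per-domain missense plan for CFH: counts per distinct residue, by region.
cfh_plan <- list(
  `SCR-20` = list(loop = c(2, 2, 2, 1), cys = c(2, 2, 2),
                  other = c(rep(2, 5), rep(1, 16))),
  `SCR-19` = list(loop = c(2, 1), cys = c(1, 1), other = c(2, rep(1, 6))),
  `SCR-15` = list(loop = c(1, 1), cys = c(1, 1, 1), other = rep(1, 7)),
  `SCR-17` = list(loop = c(1, 1), cys = c(1, 1), other = rep(1, 6)),
  `SCR-16` = list(loop = c(1, 1), cys = 1, other = rep(1, 5)),
  `SCR-18` = list(other = 1),
  `SCR-1` = list(loop = 1, other = rep(1, 2)),
  `SCR-2` = list(cys = 1, other = 1),
  `SCR-3` = list(loop = 1, other = 1),
  `SCR-4` = list(cys = 1, other = 1),
  `SCR-5` = list(other = 1),
  `SCR-6` = list(loop = 1, other = 1),
  `SCR-7` = list(loop = c(1, 1), other = 1),   # one loop slot is Tyr402His
  `SCR-8` = list(other = 1),
  `SCR-9` = list(cys = 1, other = 1),
  `SCR-10` = list(other = 1),
  `SCR-11` = list(cys = 1, other = 1),
  `SCR-12` = list(other = 1),
  `SCR-13` = list(other = 1),
  `SCR-14` = list(other = 1))

mcp_plan <- list(
  `SCR-1` = list(loop = 1, cys = 1, other = rep(1, 2)),
  `SCR-2` = list(loop = 1, cys = 1, other = rep(1, 3)),
  `SCR-3` = list(loop = c(1, 1), cys = c(1, 1), other = rep(1, 4)),
  `SCR-4` = list(cys = 1, other = rep(1, 4)))

emit_scr_missense <- function(protein, plan, named = list()) {
  i <- 0L
  cys_ptype_left <- list(CFH = 16L, MCP = 4L)  # rows labelled Type I
  loop_ptype_left <- list(CFH = 17L, MCP = 3L) # rows labelled Type II
  for (dom in names(plan)) {
    mem_id <- paste0(protein, "_", dom)
    spec <- plan[[dom]]
    used <- integer(0)
    for (region in names(spec)) {
      pool <- switch(region, loop = LOOP, cys = ANCHORS, other = OTHER_POOL)
      counts <- spec[[region]]
      for (k in seq_along(counts)) {
        i <- i + 1L
        key <- paste0(protein, ":", dom, ":", region, ":", k)
        if (!is.null(named[[key]])) {
          nm <- named[[key]]
          used <- c(used, nm$pos)
          mk_missense(mem_id, nm$pos, n_mut = counts[k],
                      force_ref = nm$ref, tags = nm$tags, ptype = nm$ptype,
                      src = nm$src)
          next
        }
        # walk the pool for an unused consensus position in this domain
        p <- pool[((k - 1L) %% length(pool)) + 1L]
        j <- k
        repeat {
          pos <- pos_of_cons(members[[mem_id]], p)
          if (!pos %in% used) break
          j <- j + 1L
          p <- pool[((j - 1L) %% length(pool)) + 1L]
        }
        used <- c(used, pos)
        ptype <- NA_character_
        if (region == "cys" && cys_ptype_left[[protein]] > 0L) {
          ptype <- "I"; cys_ptype_left[[protein]] <- cys_ptype_left[[protein]] - 1L
        }
        if (region == "loop" && loop_ptype_left[[protein]] > 0L) {
          ptype <- "II"; loop_ptype_left[[protein]] <- loop_ptype_left[[protein]] - 1L
        }
        mk_missense(mem_id, pos, n_mut = counts[k], ptype = ptype,
                    src = paste0("syn:", protein, ":", dom, ":", region, k))
      }
    }
  }
}

## CFH ------------------------------------------------------------------------
# Named: Tyr402His (AMD polymorphism row kept among missense, loop of SCR-7);
# Arg1210Cys/Arg1210His/Arg1210Leu triple at one SCR-20 residue.
named_cfh <- list(
  "CFH:SCR-7:loop:1" = list(pos = 402L, ref = "Y", tags = "AMD",
                            ptype = "II", src = "lit:Tyr402His"),
  "CFH:SCR-20:other:1" = list(pos = 1210L, ref = "R", tags = "aHUS",
                              ptype = NA, src = "lit:Arg1210"))
# Check Tyr402His falls in the hypervariable loop of the SCR-7 member and
# Arg1210 in the 'other' region of SCR-20 under the packaged layout.
stopifnot(members[["CFH_SCR-7"]]$layout$conspos[
  members[["CFH_SCR-7"]]$layout$position == 402] %in% LOOP)
p1210 <- members[["CFH_SCR-20"]]$layout$conspos[
  members[["CFH_SCR-20"]]$layout$position == 1210]
stopifnot(p1210 %in% OTHER_POOL)
# Arg1210 carries three reports (Cys/His/Leu-type alternates); keep the
# 'other' region at 26 mutations on 21 distinct residues: 3 + 2*3 + 1*17.
cfh_plan$`SCR-20`$other <- c(3, rep(2, 3), rep(1, 17))

emit_scr_missense("CFH", cfh_plan, named_cfh)

# 5 signal-peptide missense + 1 inter-SCR linker missense (position 445)
for (pos in c(3L, 7L, 9L, 12L, 16L)) {
  add_row("CFH", change = paste0("Leu", pos, "Pro"), consequence = "missense",
          tags = "aHUS", ptype = "I", ref = paste0("syn:CFH:signal:", pos))
}
add_row("CFH", change = "Ser445Leu", consequence = "missense", tags = "aHUS",
        ref = "syn:CFH:linker:445")

# non-missense CFH: 21 nonsense (2 inside SCR-20), 12 deletions (3 in-frame),
# 8 silent, 5 frameshift (1 inside SCR-20), 2 intronic, 1 insertion,
# 1 splicing (exonic, positioned)
sc20 <- function(p) pos_of_cons(members[["CFH_SCR-20"]], p)
add_row("CFH", change = paste0("Trp", sc20(18), "Ter"), consequence = "nonsense",
        ref = "syn:CFH:non:1")
add_row("CFH", change = paste0("Tyr", sc20(22), "Ter"), consequence = "nonsense",
        ref = "syn:CFH:non:2")
non_pos <- c(95L, 160L, 240L, 300L, 350L, 420L, 470L, 530L, 590L, 650L, 710L,
             770L, 830L, 890L, 950L, 1010L, 1060L, 1090L, 820L)
stopifnot(length(non_pos) == 19, !non_pos %in% 1107:1231)
for (k in seq_along(non_pos)) {
  add_row("CFH", change = paste0("Arg", non_pos[k], "Ter"),
          consequence = "nonsense", ref = paste0("syn:CFH:non:", k + 2))
}
del_if <- c(120L, 260L, 515L)
for (k in seq_along(del_if)) {
  add_row("CFH", change = paste0("Lys", del_if[k], "del"),
          consequence = "deletion_inframe", ref = paste0("syn:CFH:delif:", k))
}
del_fs <- c(60L, 180L, 330L, 400L, 480L, 560L, 640L, 720L, 800L)
for (k in seq_along(del_fs)) {
  add_row("CFH", change = paste0("Glu", del_fs[k], "fs"),
          consequence = "deletion_frameshift", ref = paste0("syn:CFH:delfs:", k))
}
sil <- c(75L, 210L, 380L, 455L, 610L, 755L, 905L, 1055L)
for (k in seq_along(sil)) {
  add_row("CFH", change = paste0("Ala", sil[k], "="), consequence = "silent",
          tags = "other", ref = paste0("syn:CFH:sil:", k))
}
fs <- c(140L, 290L, 440L, 585L)
for (k in seq_along(fs)) {
  add_row("CFH", change = paste0("Gly", fs[k], "fs"), consequence = "frameshift",
          ref = paste0("syn:CFH:fs:", k))
}
add_row("CFH", change = paste0("Ser", sc20(31), "fs"), consequence = "frameshift",
        ref = "syn:CFH:fs:5")
add_row("CFH", dna = "c.619+1G>A", consequence = "intronic",
        ref = "syn:CFH:int:1")
add_row("CFH", dna = "c.3134-5T>C", consequence = "intronic",
        ref = "syn:CFH:int:2")
add_row("CFH", change = "Pro258dup", consequence = "insertion",
        ref = "syn:CFH:ins:1")
add_row("CFH", dna = "c.350G>A", change = "Gly117=", consequence = "splicing",
        ref = "syn:CFH:spl:1")  # exonic splice-site change, positioned

## MCP -------------------------------------------------------------------------
emit_scr_missense("MCP", mcp_plan)
for (spec in list(c(300L, "Ser"), c(312L, "Thr"))) {
  add_row("MCP", change = paste0(spec[2], spec[1], "Pro"),
          consequence = "missense", ref = paste0("syn:MCP:ST:", spec[1]))
}
add_row("MCP", change = "Arg375Gln", consequence = "missense",
        ref = "syn:MCP:Cy:375")
add_row("MCP", change = "Leu20Pro", consequence = "missense", ptype = "I",
        ref = "syn:MCP:signal:20")
for (k in seq_along(c(60L, 130L, 190L, 250L))) {
  add_row("MCP", change = paste0("Gln", c(60L, 130L, 190L, 250L)[k], "Ter"),
          consequence = "nonsense", ref = paste0("syn:MCP:non:", k))
}
add_row("MCP", change = "Asp110del", consequence = "deletion_inframe",
        ref = "syn:MCP:delif:1")
add_row("MCP", change = "Ser230del", consequence = "deletion_inframe",
        ref = "syn:MCP:delif:2")
for (k in seq_along(c(70L, 145L, 205L, 270L))) {
  add_row("MCP", change = paste0("Thr", c(70L, 145L, 205L, 270L)[k], "fs"),
          consequence = "deletion_frameshift", ref = paste0("syn:MCP:delfs:", k))
}
for (k in seq_along(c(85L, 175L, 260L))) {
  add_row("MCP", change = paste0("Pro", c(85L, 175L, 260L)[k], "="),
          consequence = "silent", ref = paste0("syn:MCP:sil:", k))
}
add_row("MCP", change = "Lys102fs", consequence = "frameshift",
        ref = "syn:MCP:fs:1")
for (k in 1:6) {
  add_row("MCP", dna = paste0("c.", 200 * k, "+2T>G"), consequence = "intronic",
          ref = paste0("syn:MCP:int:", k))
}
add_row("MCP", change = "Ile45Val", consequence = "polymorphism_disease",
        tags = "aHUS", ref = "syn:MCP:poly:1")
add_row("MCP", change = "Asn98Ser", consequence = "polymorphism_disease",
        tags = "aHUS", ref = "syn:MCP:poly:2")
add_row("MCP", change = "Val118Ile", consequence = "polymorphism_nondisease",
        tags = "other", ref = "syn:MCP:poly:3")

## CFI -------------------------------------------------------------------------
cfi_missense <- list(
  FIMAC = c(30L, 41L, 55L, 68L, 80L, 99L),
  SRCR = c(118L, 130L, 142L, 155L, 167L, 180L, 192L, 205L, 215L),
  `LDLr-1` = c(230L, 240L, 250L, 259L),
  `LDLr-2` = c(268L, 286L),
  SP = c(345L, 356L, 367L, 378L, 389L, 400L, 411L, 422L, 433L, 444L, 455L,
         466L, 477L, 488L, 499L, 510L, 521L, 532L, 543L, 550L, 556L, 562L,
         566L, 570L, 573L))
refs_cycle <- c("Arg", "Gly", "Cys", "Asp", "Ser", "Leu", "Pro", "His",
                "Thr", "Val", "Ile", "Met", "Ala", "Lys", "Trp", "Tyr")
alts_cycle <- c("Trp", "Glu", "Tyr", "Asn", "Phe", "Arg", "Ser", "Gln",
                "Met", "Ala", "Asn", "Thr", "Val", "Glu", "Cys", "Cys")
k <- 0L
for (dom in names(cfi_missense)) {
  for (pos in cfi_missense[[dom]]) {
    k <- k + 1L
    r <- refs_cycle[((k - 1L) %% length(refs_cycle)) + 1L]
    a <- alts_cycle[((k - 1L) %% length(alts_cycle)) + 1L]
    add_row("CFI", change = paste0(r, pos, a), consequence = "missense",
            ref = paste0("syn:CFI:", dom, ":", pos))
  }
}
add_row("CFI", change = "Arg222Gln", consequence = "missense",
        ref = "syn:CFI:linker:222")   # heavy-chain linker
add_row("CFI", change = "Gly330Arg", consequence = "missense",
        ref = "syn:CFI:linker:330")   # inter-chain linker
add_row("CFI", change = "Leu10Pro", consequence = "missense", ptype = "I",
        ref = "syn:CFI:signal:10")
for (k in seq_along(c(50L, 125L, 235L, 290L, 380L, 460L))) {
  add_row("CFI", change = paste0("Trp", c(50L, 125L, 235L, 290L, 380L, 460L)[k],
                                 "Ter"),
          consequence = "nonsense", ref = paste0("syn:CFI:non:", k))
}
add_row("CFI", change = "His165del", consequence = "deletion_inframe",
        ref = "syn:CFI:delif:1")
add_row("CFI", change = "Asp365fs", consequence = "deletion_frameshift",
        ref = "syn:CFI:delfs:1")
add_row("CFI", change = "Ala420=", consequence = "silent", tags = "other",
        ref = "syn:CFI:sil:1")
add_row("CFI", change = "Ser545fs", consequence = "frameshift",
        ref = "syn:CFI:fs:1")
add_row("CFI", change = "Gly101dup", consequence = "insertion",
        ref = "syn:CFI:ins:1")
add_row("CFI", change = "Lys441dup", consequence = "insertion",
        ref = "syn:CFI:ins:2")
add_row("CFI", dna = "c.1429+1G>T", consequence = "splicing",
        ref = "syn:CFI:spl:1")   # intronic splice-donor change, no position
# two reports whose consequence category could not be resolved
add_row("CFI", change = "Pro481Ser", consequence = "unclassified",
        ref = "syn:CFI:unres:1")
add_row("CFI", change = "Glu512Lys", consequence = "unclassified",
        ref = "syn:CFI:unres:2")

## C3 --------------------------------------------------------------------------
c3_missense <- list(
  MG1 = list(c(65L, "Lys", "Gln"), c(102L, "Arg", "Gly"), c(85L, "Val", "Met")),
  MG2 = list(c(155L, "Lys", "Gln"), c(161L, "Arg", "Trp"),
             c(175L, "Ser", "Phe"), c(199L, "Asp", "Asn"), c(220L, "Gly", "Arg")),
  MG3 = list(c(314L, "Pro", "Leu")),
  MG4 = list(c(370L, "Thr", "Met")),
  MG5 = list(c(455L, "Arg", "Cys"), c(480L, "Glu", "Lys"), c(500L, "Leu", "Pro"),
             c(515L, "Ser", "Asn"), c(530L, "Gly", "Ser")),
  MG6 = list(c(560L, "His", "Arg"), c(770L, "Asp", "Gly")),
  LNK = list(c(600L, "Val", "Ile")),
  ANA = list(c(690L, "Arg", "His"), c(710L, "Glu", "Asp"), c(735L, "Leu", "Val")),
  MG7 = list(c(830L, "Ser", "Leu"), c(880L, "Cys", "Arg")),
  CUB = list(c(1320L, "Arg", "Gln"), c(940L, "Thr", "Ile")),
  TED = list(c(1001L, "Arg", "Trp"), c(1001L, "Arg", "Gln"),
             c(1030L, "Asp", "Asn"), c(1030L, "Asp", "Gly"),
             c(1060L, "Gly", "Glu"), c(1090L, "Lys", "Arg"),
             c(1120L, "Ser", "Pro"), c(1150L, "Glu", "Lys"),
             c(1180L, "Leu", "Ser"), c(1210L, "Gln", "His"),
             c(1235L, "Ile", "Thr"), c(1250L, "Tyr", "Cys"),
             c(1265L, "Asn", "Asp"), c(985L, "Met", "Thr"),
             c(1015L, "Ala", "Val")),
  MG8 = list(c(1360L, "Arg", "Ser"), c(1400L, "Asp", "Tyr"),
             c(1450L, "Val", "Ala")),
  C345C = list(c(1530L, "Cys", "Arg"), c(1570L, "Arg", "Leu"),
               c(1610L, "Glu", "Gln"), c(1650L, "Ser", "Gly")))
for (dom in names(c3_missense)) {
  for (m in c3_missense[[dom]]) {
    add_row("C3", change = paste0(m[2], m[1], m[3]), consequence = "missense",
            ref = paste0("syn:C3:", dom, ":", m[1], m[3]))
  }
}
add_row("C3", change = "Gln400Ter", consequence = "nonsense",
        ref = "syn:C3:non:1")

## assemble, tag, verify -------------------------------------------------------
reg_df <- do.call(rbind, rows)

# disease-tag marginals: aHUS membership 127 (CFH), 30 (CFI), 48 (MCP), 36 (C3)
retag <- function(df, protein, n_ahus, alt_tags) {
  idx <- which(df$protein == protein)
  cur <- grepl("aHUS", df$disease_tags[idx])
  excess <- sum(cur) - n_ahus
  stopifnot(excess >= 0)
  if (excess > 0) {
    flip <- rev(idx[cur])[seq_len(excess)]
    df$disease_tags[flip] <- rep(alt_tags, length.out = excess)
  }
  df
}
reg_df <- retag(reg_df, "CFH", 127L, c("AMD", "AMD", "AMD", "AMD", "other"))
reg_df <- retag(reg_df, "CFI", 30L, c("deficiency", "deficiency", "AMD", "other"))
reg_df <- retag(reg_df, "MCP", 48L, "other")
reg_df <- retag(reg_df, "C3", 36L, c("AMD", "AMD", "other"))

## alignment FASTA -------------------------------------------------------------
set.seed(20140117)
n_lib <- 100L
non_cys <- setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "C")
lib_seqs <- vapply(seq_len(n_lib), function(i) {
  s <- CONS
  subst <- runif(L) < 0.12
  subst[ANCHORS] <- FALSE
  s[subst] <- sample(non_cys, sum(subst), replace = TRUE)
  paste(s, collapse = "")
}, character(1))

# global columns: 2 lead, then per consensus position a core column plus an
# insertion column where any member inserts, then 2 trailing columns
ins_needed <- vapply(seq_len(L), function(p) {
  any(vapply(members, function(m) {
    any(m$layout$kind == "ins" & m$layout$conspos == p)
  }, logical(1)))
}, logical(1))

render_member <- function(m) {
  lay <- m$layout
  out <- character(0)
  for (i in 1:2) {
    ch <- lay$char[lay$kind == "lead"][i]
    out <- c(out, if (is.na(ch)) "-" else ch)
  }
  for (p in seq_len(L)) {
    out <- c(out, lay$char[lay$kind == "core" & lay$conspos == p])
    if (ins_needed[p]) {
      ins <- lay$char[lay$kind == "ins" & lay$conspos == p]
      out <- c(out, if (length(ins)) ins else "-")
    }
  }
  tr <- lay$char[lay$kind == "trail"]
  out <- c(out, tr, rep("-", 2 - length(tr)))
  paste(out, collapse = "")
}
render_lib <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  out <- c("-", "-")
  for (p in seq_len(L)) {
    out <- c(out, s[p])
    if (ins_needed[p]) out <- c(out, "-")
  }
  paste(c(out, "-", "-"), collapse = "")
}

fasta <- character(0)
for (id in names(members)) {
  m <- members[[id]]
  fasta <- c(fasta, sprintf(">%s protein=%s domain=%s start=%d end=%d",
                            id, m$protein, m$domain, m$start, m$end),
             render_member(m))
}
for (i in seq_len(n_lib)) {
  fasta <- c(fasta, sprintf(">CCP_LIB_%03d", i), render_lib(lib_seqs[i]))
}
writeLines(fasta, "inst/extdata/scr_alignment_synthetic.fasta")

## write registry and verify every marginal ------------------------------------
utils::write.table(reg_df, "inst/extdata/complement_registry_synthetic.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE, na = "NA",
                   fileEncoding = "UTF-8")

reg <- read_registry("inst/extdata/complement_registry_synthetic.tsv",
                     proteins = defs)
stopifnot(nrow(reg) == 324)
tot <- function(p) sum(reg$protein == p)
stopifnot(tot("CFH") == 163, tot("CFI") == 64, tot("MCP") == 49,
          tot("C3") == 48)
cfh <- reg[reg$protein == "CFH", ]
ct <- tally(cfh, "consequence")
expect_count <- function(ct, key, n) {
  got <- ct$count[match(key, ct$key)]
  if (is.na(got)) got <- 0L
  stopifnot(got == n)
}
expect_count(ct, "missense", 113); expect_count(ct, "nonsense", 21)
expect_count(ct, "silent", 8); expect_count(ct, "deletion_inframe", 3)
expect_count(ct, "deletion_frameshift", 9); expect_count(ct, "frameshift", 5)
expect_count(ct, "intronic", 2); expect_count(ct, "insertion", 1)
expect_count(ct, "splicing", 1)
stopifnot(sum(is_nonintronic(cfh)) == 161)
stopifnot(nonintronic_frequency(cfh, defs$CFH)$rounded == 13)
stopifnot(nonintronic_frequency(reg[reg$protein == "C3", ], defs$C3)$rounded == 3)
f1920 <- nonintronic_frequency(cfh, defs$CFH$domains[c("SCR-19", "SCR-20")])
cat(sprintf("SCR-19/20: %d/%d = %.2f -> %d\n", f1920$count, f1920$length,
            f1920$frequency, f1920$rounded))
stopifnot(f1920$count == 55, f1920$rounded == 44)
ann <- collapse_to_residues(cfh)
cat(sprintf("CFH: %d missense on %d residues\n", sum(ann$n_mutations),
            nrow(ann)))
stopifnot(sum(ann$n_mutations) == 113, nrow(ann) == 100)
annC3 <- collapse_to_residues(reg[reg$protein == "C3", ])
stopifnot(sum(annC3$n_mutations) == 47, nrow(annC3) == 45)
# per-domain CFH missense counts
dom_mis <- tally(cfh[cfh$consequence == "missense", ], "domain",
                 proteins = defs)
for (chk in list(c("SCR-20", 39), c("SCR-19", 13), c("SCR-15", 12),
                 c("SCR-17", 10), c("SCR-16", 8))) {
  stopifnot(dom_mis$count[dom_mis$key == chk[1]] == as.integer(chk[2]))
}
# consensus mapping
aln <- read_scr_alignment("inst/extdata/scr_alignment_synthetic.fasta")
stopifnot(aln$consensus_length == 51,
          identical(aln$anchor_positions, c(1L, 26L, 39L, 49L)))
prof <- build_consensus(aln)
cons_str <- paste(prof$residue, collapse = "")
cat("consensus:", cons_str, "\n")
stopifnot(prof$residue[c(1, 26, 39, 49)] == "C")
mapped <- map_mutations_to_consensus(reg, aln)
in_scr <- mapped[!mapped$region %in% c("outside_scr", "unmappable"), ]
rt <- region_tally(in_scr$consensus_pos, anchors = aln$anchor_positions)
print(rt)
stopifnot(rt$total == 129, rt$loop_count == 25, rt$cys_count == 23,
          rt$other_count == 81, rt$loop_pct == 19, rt$cys_pct == 18,
          rt$other_pct == 63)
stopifnot(sum(grepl("aHUS", cfh$disease_tags)) == 127,
          sum(grepl("aHUS", reg$disease_tags[reg$protein == "CFI"])) == 30,
          sum(grepl("aHUS", reg$disease_tags[reg$protein == "MCP"])) == 48,
          sum(grepl("aHUS", reg$disease_tags[reg$protein == "C3"])) == 36)
stopifnot(sum(is_nonintronic(reg[reg$protein == "CFI", ])) == 63,
          sum(is_nonintronic(reg[reg$protein == "MCP", ])) == 43,
          sum(is_nonintronic(reg[reg$protein == "C3", ])) == 48)
cat("fixtures written and verified\n")
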