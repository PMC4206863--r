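# Seeded synthetic inputs with exact ground truth: mutation tables, decoy
# SCR-like coordinate sets under known rigid transforms, and alignment
# fixtures with known consensus and insertion structure. All randomness uses
# R's seeded Mersenne-Twister stream; identical seeds give identical outputs.

# 51-position SCR-like consensus used by the synthetic generators: Cys anchors
# at 1, 26, 39, 49, conserved Trp at 45, hypervariable loop at 11-15.
SYNTH_CONSENSUS <- paste0("CPKPPEIENGKIESG", "YSYGSVVTYSCNEGY",
                          "SLIGESTLCTEATGWSPAC", "PT")

#' Idealised SCR-like template structure
#'
#' A hand-built ~60-residue coordinate set (backbone N/CA/C/O plus
#' C-beta) on a serpentine four-strand path, carrying the five superposition
#' anchor residues of an SCR domain (Cys 1, 26, 39, 49 and Trp 45). It is a
#' geometric test article, not a modelled fold: it exists so that
#' superposition, SASA and burial code can be exercised without any
#' coordinate download.
#'
#' @param n_residues number of residues (default 60; at least 49).
#' @return a `structure_model` with attribute `anchors` (the five anchor
#'   residue numbers).
#' @export
scr_template <- function(n_residues = 60) {
  stopifnot(n_residues >= 49)
  seq3 <- aa1to3(strsplit(SYNTH_CONSENSUS, "")[[1]])
  extra <- n_residues - length(seq3)
  if (extra > 0) seq3 <- c(seq3, rep(c("Pro", "Glu", "Lys", "Ser", "Gly",
                                       "Thr", "Val", "Asn", "Ala"),
                                     length.out = extra))
  seq3 <- seq3[seq_len(n_residues)]
  per_strand <- 10
  ca <- t(vapply(seq_len(n_residues), function(i) {
    strand <- (i - 1) %/% per_strand
    k <- (i - 1) %% per_strand
    along <- if (strand %% 2 == 0) k else per_strand - 1 - k
    c(3.4 * along + 1.1 * (strand %% 2), 1.0 * (k %% 2), 4.8 * strand)
  }, numeric(3)))
  rows <- lapply(seq_len(n_residues), function(i) {
    aa <- toupper(seq3[i])
    atoms <- data.frame(
      chain = "A", resno = i, resid = aa,
      elety = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      x = ca[i, 1] + c(-1.2, 0, 1.2, 1.9),
      y = ca[i, 2] + c(0.5, 0, 0.5, 1.5),
      z = ca[i, 3] + c(-0.3, 0, -0.3, 0.2),
      stringsAsFactors = FALSE)
    if (aa != "GLY") {
      atoms <- rbind(atoms, data.frame(
        chain = "A", resno = i, resid = aa, elety = "CB",
        element = if (aa == "CYS") "C" else "C",
        x = ca[i, 1], y = ca[i, 2] - 1.4, z = ca[i, 3] + 0.8,
        stringsAsFactors = FALSE))
      if (aa == "CYS") {
        atoms <- rbind(atoms, data.frame(
          chain = "A", resno = i, resid = aa, elety = "SG", element = "S",
          x = ca[i, 1] + 0.4, y = ca[i, 2] - 2.6, z = ca[i, 3] + 1.3,
          stringsAsFactors = FALSE))
      }
    }
    atoms
  })
  model <- structure_model(do.call(rbind, rows), source = "scr_template")
  attr(model, "anchors") <- c(1L, 26L, 39L, 45L, 49L)
  model
}

#' Random proper rotation matrix
#'
#' Uniform over SO(3) via normalised quaternions; uses the current RNG
#' stream.
#'
#' @return 3 x 3 rotation matrix with det +1.
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Generate a synthetic mutation table with known marginals
#'
#' Draws `n` records for one protein: a consequence class from `mixture`,
#' and, for positioned classes, a domain from the per-domain weights and a
#' uniform residue within it; with probability `duplicate_prob` a positioned
#' record reuses an already-mutated residue. The ground truth (exact
#' per-consequence and per-domain counts, recorded as the rows are drawn) is
#' returned beside the table and is what downstream tests compare against.
#'
#' @param protein a [protein_definition()].
#' @param n number of records.
#' @param rates named non-negative per-domain weights (names must be domain
#'   labels of `protein`); all-zero weights yield an empty table.
#' @param mixture named consequence probabilities (subset of the consequence
#'   vocabulary), normalised to sum to 1.
#' @param duplicate_prob probability of reusing an affected residue.
#' @param seed integer seed.
#' @return list with `registry` (a validated `mutation_registry`) and `truth`
#'   (`per_consequence`, `per_domain`, `positions`).
#' @export
gen_mutation_table <- function(protein, n = 100,
                               rates = NULL,
                               mixture = c(missense = 0.7, nonsense = 0.1,
                                           silent = 0.1, intronic = 0.1),
                               duplicate_prob = 0, seed = 1) {
  stopifnot(inherits(protein, "protein_definition"))
  if (is.null(rates)) {
    rates <- vapply(protein$domains, domain_length, numeric(1))
  }
  bad <- setdiff(names(rates), names(protein$domains))
  if (length(bad)) stop("rate(s) for unknown domain(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (any(rates < 0)) stop("negative domain rate", call. = FALSE)
  if (any(mixture < 0) || sum(mixture) <= 0) {
    stop("consequence mixture must be non-negative with positive sum",
         call. = FALSE)
  }
  if (!all(names(mixture) %in% CONSEQUENCE_CLASSES)) {
    stop("unknown consequence class in mixture", call. = FALSE)
  }
  mixture <- mixture / sum(mixture)
  set.seed(as.integer(seed))
  if (sum(rates) == 0) n <- 0L
  cons <- if (n > 0) sample(names(mixture), n, replace = TRUE,
                            prob = mixture) else character(0)
  positioned <- !cons %in% c("intronic", "splicing")
  dom_draw <- character(n); pos <- rep(NA_integer_, n)
  ref <- rep(NA_character_, n); alt <- rep(NA_character_, n)
  token <- rep(NA_character_, n)
  used <- integer(0)
  for (i in seq_len(n)) {
    if (!positioned[i]) next
    if (length(used) && stats::runif(1) < duplicate_prob) {
      pos[i] <- used[sample.int(length(used), 1)]
    } else {
      d <- sample(names(rates), 1, prob = rates)
      res <- domain_residues(protein$domains[[d]])
      pos[i] <- res[sample.int(length(res), 1)]
    }
    dom_draw[i] <- assign_domain(pos[i], protein)$label
    used <- c(used, pos[i])
    ref[i] <- sample(AA3, 1)
    token[i] <- switch(cons[i],
      missense = {
        alt[i] <- sample(setdiff(AA3, ref[i]), 1)
        paste0(ref[i], pos[i], alt[i])
      },
      nonsense = { alt[i] <- "Ter"; paste0(ref[i], pos[i], "Ter") },
      silent = { alt[i] <- ref[i]; paste0(ref[i], pos[i], "=") },
      deletion_inframe = paste0(ref[i], pos[i], "del"),
      deletion_frameshift = paste0(ref[i], pos[i], "fs"),
      frameshift = paste0(ref[i], pos[i], "fs"),
      insertion = paste0(ref[i], pos[i], "dup"),
      paste0(ref[i], pos[i], "=")
    )
  }
  registry <- data.frame(
    protein = rep(protein$name, n),
    dna_change = ifelse(positioned, NA_character_,
                        paste0("c.", seq_len(n), "+1G>A")),
    protein_change = token,
    consequence = cons,
    disease_tags = rep("synthetic", n),
    phenotype_type = rep(NA_character_, n),
    source_ref = if (n > 0) paste0("sim:", seed, ":", seq_len(n))
                 else character(0),
    stringsAsFactors = FALSE)
  truth <- list(
    per_consequence = table(factor(cons, levels = names(mixture))),
    per_domain = table(factor(dom_draw[positioned],
                              levels = names(protein$domains))),
    positions = pos)
  reg <- if (n > 0) as_registry(registry,
                                proteins = stats::setNames(list(protein),
                                                           protein$name))
         else as_registry(registry[0, ], validate = FALSE)
  list(registry = reg, truth = truth)
}

#' Generate decoy structures under known rigid transforms
#'
#' Each decoy is the template under a recorded uniform random rotation and
#' translation, plus isotropic Gaussian coordinate noise.
#'
#' @param template a `structure_model` carrying an `anchors` attribute (five
#'   anchor residue numbers); defaults to [scr_template()].
#' @param n_decoys number of decoys.
#' @param sigma coordinate noise standard deviation (Angstrom) per axis.
#' @param max_translation translations drawn uniformly in
#'   `[-max_translation, max_translation]` per axis.
#' @param seed integer seed.
#' @return list with `decoys` (list of `structure_model`) and `truth` (list
#'   of `rotation`/`translation` per decoy).
#' @export
gen_scr_decoys <- function(template = scr_template(), n_decoys = 10,
                           sigma = 0, max_translation = 20, seed = 1) {
  anchors <- attr(template, "anchors")
  if (is.null(anchors)) stop("template carries no anchor residues",
                             call. = FALSE)
  found <- template$atoms$resno[template$atoms$elety == "CA"]
  if (!all(anchors %in% found)) {
    stop("template is missing anchor residue(s): ",
         paste(setdiff(anchors, found), collapse = ", "), call. = FALSE)
  }
  if (sigma < 0) stop("noise sigma must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  decoys <- vector("list", n_decoys)
  truth <- vector("list", n_decoys)
  for (k in seq_len(n_decoys)) {
    R <- random_rotation()
    tv <- stats::runif(3, -max_translation, max_translation)
    d <- apply_transform(template, list(rotation = R, translation = tv))
    if (sigma > 0) {
      na <- nrow(d$atoms)
      d$atoms$x <- d$atoms$x + stats::rnorm(na, sd = sigma)
      d$atoms$y <- d$atoms$y + stats::rnorm(na, sd = sigma)
      d$atoms$z <- d$atoms$z + stats::rnorm(na, sd = sigma)
    }
    d$source <- paste0("decoy_", k)
    attr(d, "anchors") <- anchors
    decoys[[k]] <- d
    truth[[k]] <- list(rotation = R, translation = tv)
  }
  list(decoys = decoys, truth = truth, anchors = anchors)
}

#' Generate an SCR-like alignment fixture with known ground truth
#'
#' Members are copies of the consensus with random substitutions at
#' non-anchor positions (never to Cys, so anchor auto-detection stays exact)
#' and single-residue insertions after interior consensus positions. The true
#' consensus and the exact residue-to-consensus mapping of every member are
#' returned beside the alignment.
#'
#' @param consensus consensus amino-acid string (one-letter); must carry Cys
#'   at the four anchor positions.
#' @param anchors anchor positions within the consensus (default
#'   `c(1, 26, 39, 49)`).
#' @param n_members number of members.
#' @param substitution_rate per-position substitution probability at
#'   non-anchor positions.
#' @param insertion_rate per-gap probability of a single-residue insertion.
#' @param seed integer seed.
#' @return list with `alignment` (an `scr_alignment`), `consensus` (the true
#'   string) and `mapping` (data frame `member`, `residue_index`,
#'   `consensus_pos` with `NA` for none -- insertions map to the preceding
#'   consensus position in `expected_map`).
#' @export
gen_alignment_fixture <- function(consensus = SYNTH_CONSENSUS,
                                  anchors = c(1L, 26L, 39L, 49L),
                                  n_members = 10, substitution_rate = 0,
                                  insertion_rate = 0, seed = 1) {
  cons <- strsplit(consensus, "")[[1]]
  L <- length(cons)
  if (!all(cons[anchors] == "C")) {
    stop("consensus must carry Cys at every anchor position", call. = FALSE)
  }
  set.seed(as.integer(seed))
  non_cys <- setdiff(AA1, "C")
  member_res <- vector("list", n_members)   # residues, one-letter
  member_map <- vector("list", n_members)   # consensus pos per residue
  ins_after <- matrix(0L, n_members, L)     # insertions after position p
  for (m in seq_len(n_members)) {
    res <- cons
    subst <- stats::runif(L) < substitution_rate
    subst[anchors] <- FALSE
    res[subst] <- sample(non_cys, sum(subst), replace = TRUE)
    seq_out <- character(0); map_out <- integer(0)
    for (p in seq_len(L)) {
      seq_out <- c(seq_out, res[p]); map_out <- c(map_out, p)
      if (p < L && stats::runif(1) < insertion_rate) {
        ins_after[m, p] <- 1L
        seq_out <- c(seq_out, sample(non_cys, 1))
        map_out <- c(map_out, p)  # insertion maps to preceding position
      }
    }
    member_res[[m]] <- seq_out
    member_map[[m]] <- map_out
  }
  gap_width <- apply(ins_after, 2, max)
  aligned <- vapply(seq_len(n_members), function(m) {
    out <- character(0); r <- member_res[[m]]; k <- 1L
    for (p in seq_len(L)) {
      out <- c(out, r[k]); k <- k + 1L
      if (gap_width[p] > 0) {
        if (ins_after[m, p] > 0) {
          out <- c(out, r[k]); k <- k + 1L
        } else {
          out <- c(out, "-")
        }
      }
    }
    paste(out, collapse = "")
  }, character(1))
  names(aligned) <- sprintf("SYN_%03d", seq_len(n_members))
  members <- data.frame(id = names(aligned), protein = names(aligned),
                        domain = "SYN",
                        start = 1L,
                        end = vapply(member_res, length, integer(1)),
                        stringsAsFactors = FALSE)
  aln <- scr_alignment(aligned, members = members)
  mapping <- do.call(rbind, lapply(seq_len(n_members), function(m) {
    data.frame(member = names(aligned)[m],
               residue_index = seq_along(member_map[[m]]),
               consensus_pos = member_map[[m]], stringsAsFactors = FALSE)
  }))
  list(alignment = aln, consensus = consensus, mapping = mapping)
}
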