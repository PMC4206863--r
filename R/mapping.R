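# Mutation-to-structure statistics: affected-residue collapsing, burial
# summaries, per-domain hotspot frequencies and Type I/II prediction.

#' Collapse missense records to affected residues
#'
#' One annotation per distinct (protein, residue); the per-residue counts sum
#' to the number of input records.
#'
#' @param registry a `mutation_registry`; only missense rows with positions
#'   are used.
#' @param proteins optional named list of [protein_definition()]; if given,
#'   each annotation carries its domain label.
#' @return data frame `protein`, `position`, `n_mutations`, and `domain` when
#'   `proteins` is supplied.
#' @examples
#' ann <- collapse_to_residues(complement_registry())
#' sum(ann$n_mutations[ann$protein == "CFH"])  # 113 missense
#' nrow(ann[ann$protein == "CFH", ])           # on 100 residues
#' @export
collapse_to_residues <- function(registry, proteins = NULL) {
  keep <- registry$consequence == "missense" & !is.na(registry$position)
  reg <- registry[keep, , drop = FALSE]
  key <- paste(reg$protein, reg$position)
  tab <- table(key)
  first <- reg[!duplicated(key), , drop = FALSE]
  out <- data.frame(protein = first$protein, position = first$position,
                    n_mutations = as.integer(tab[paste(first$protein,
                                                       first$position)]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein, out$position), ]
  rownames(out) <- NULL
  if (!is.null(proteins)) {
    out$domain <- vapply(seq_len(nrow(out)), function(i) {
      pd <- proteins[[out$protein[i]]]
      if (is.null(pd)) return(NA_character_)
      assign_domain(out$position[i], pd)$label
    }, character(1))
  }
  out
}

#' Buried/exposed summary of mutated residues
#'
#' Joins affected residues against a structure's accessibility profile.
#' Residues without structural coverage (absent or side-chain-unresolved in
#' the profile) are excluded from the percentage denominator and reported in
#' the `unresolved` count, mirroring the convention of quoting e.g. "19 out
#' of 48" when one residue is disordered.
#'
#' @param annotations output of [collapse_to_residues()] for one protein.
#' @param profile an `accessibility_profile` of the matching structure
#'   (residue numbering must agree with protein numbering).
#' @param threshold_bin burial threshold bin (default 2).
#' @param count_mutations if `TRUE` summarise mutations rather than distinct
#'   residues (a residue with two mutations counts twice).
#' @return list `buried`, `exposed`, `unresolved`, `evaluable`,
#'   `buried_pct`, `exposed_pct` (integer percentages of the evaluable set,
#'   half away from zero; `NA` when nothing is evaluable).
#' @export
burial_summary <- function(annotations, profile, threshold_bin = 2,
                           count_mutations = FALSE) {
  buried_flags <- classify_buried(profile, threshold_bin)
  idx <- match(annotations$position, profile$resno)
  state <- ifelse(is.na(idx), NA, buried_flags[idx])
  w <- if (count_mutations) annotations$n_mutations else
    rep(1L, nrow(annotations))
  unresolved <- sum(w[is.na(state)])
  buried <- sum(w[!is.na(state) & state])
  exposed <- sum(w[!is.na(state) & !state])
  evaluable <- buried + exposed
  list(buried = buried, exposed = exposed, unresolved = unresolved,
       evaluable = evaluable,
       buried_pct = if (evaluable > 0)
         as.integer(round_half_away(100 * buried / evaluable)) else
           NA_integer_,
       exposed_pct = if (evaluable > 0)
         as.integer(round_half_away(100 * exposed / evaluable)) else
           NA_integer_)
}

#' Rank domains by non-intronic mutational frequency
#'
#' Descriptive hotspot ranking: non-intronic mutations per 100 residues for
#' every domain of a protein, ranked in descending order. An optional exact
#' binomial enrichment p-value (domain count vs. the protein-wide rate) is
#' provided as an extension beyond the descriptive ranking.
#'
#' @param registry a `mutation_registry` restricted to one protein.
#' @param protein a [protein_definition()].
#' @param enrichment_p add a `p_enrich` column from one-sided
#'   [stats::binom.test()] (default `FALSE`).
#' @return data frame `domain`, `count`, `length`, `frequency`, `rounded`,
#'   ordered by decreasing frequency.
#' @export
domain_hotspots <- function(registry, protein, enrichment_p = FALSE) {
  rows <- lapply(protein$domains, function(d) {
    f <- nonintronic_frequency(registry, d)
    data.frame(domain = d$label, count = f$count, length = f$length,
               frequency = f$frequency, rounded = f$rounded,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (enrichment_p) {
    total <- sum(is_nonintronic(registry) & !is.na(registry$position))
    out$p_enrich <- vapply(seq_len(nrow(out)), function(i) {
      if (total == 0) return(NA_real_)
      stats::binom.test(out$count[i], total,
                        p = out$length[i] / protein$length,
                        alternative = "greater")$p.value
    }, numeric(1))
  }
  out[order(-out$frequency, out$domain), , drop = FALSE]
}

#' Heuristic Type I / Type II phenotype prediction
#'
#' Type I disorders (low circulating protein: misfolding, secretion defect)
#' are predicted for mutations that remove a cysteine or hit a buried side
#' chain; Type II (normal level, functional defect) for mutations at exposed
#' side chains. Without structural coverage the prediction is `unknown`. The
#' label is heuristic ("-like") and never overrides a curated phenotype.
#'
#' @param ref_aa three-letter reference residue.
#' @param burial_state `"buried"`, `"exposed"` or `NA`/`"unresolved"`.
#' @return one of `"Type I-like"`, `"Type II-like"`, `"unknown"`.
#' @export
predict_phenotype_class <- function(ref_aa, burial_state) {
  if (!is.na(ref_aa) && ref_aa == "Cys") return("Type I-like")
  if (is.na(burial_state) || burial_state == "unresolved") return("unknown")
  if (isTRUE(burial_state == "buried") || isTRUE(burial_state)) {
    return("Type I-like")
  }
  "Type II-like"
}

#' Per-protein summary report
#'
#' Assembles the registry-level statistics for one protein: consequence
#' tally, non-intronic totals under both counting conventions (all
#' non-intronic records, and those with residue positions), overall and
#' per-domain frequencies per 100 residues, affected-residue collapsing and,
#' when an accessibility profile is supplied, the buried/exposed split.
#'
#' @param registry full `mutation_registry`.
#' @param protein a [protein_definition()].
#' @param profile optional `accessibility_profile` for burial statistics.
#' @param threshold_bin burial threshold bin (default 2).
#' @return a `summary_report` list.
#' @export
summary_report <- function(registry, protein, profile = NULL,
                           threshold_bin = 2) {
  reg <- registry[registry$protein == protein$name, , drop = FALSE]
  freq <- nonintronic_frequency(reg, protein)
  ann <- collapse_to_residues(reg)
  rep <- list(
    protein = protein$name,
    total = nrow(reg),
    consequence_tally = tally(reg, "consequence"),
    nonintronic = sum(is_nonintronic(reg)),
    nonintronic_positioned = freq$count,
    frequency = freq,
    missense = sum(reg$consequence == "missense"),
    affected_residues = nrow(ann),
    hotspots = domain_hotspots(reg, protein)
  )
  if (!is.null(profile)) {
    rep$burial <- burial_summary(ann, profile, threshold_bin = threshold_bin)
  }
  class(rep) <- "summary_report"
  check_report(rep)
  rep
}

#' Self-consistency check of a summary report
#'
#' Verifies that every derived quantity in the report is reproducible from
#' its own numerator/denominator fields: consequence counts sum to the total,
#' the frequency equals 100 * count / length, and burial percentages match
#' their counts. Runs automatically on every report.
#'
#' @param report a `summary_report`.
#' @return the report, invisibly; errors on any inconsistency.
#' @export
check_report <- function(report) {
  ct <- report$consequence_tally
  if (sum(ct$count) != report$total) {
    stop("consequence tally does not sum to the record total", call. = FALSE)
  }
  f <- report$frequency
  if (abs(f$frequency - 100 * f$count / f$length) > 1e-9) {
    stop("frequency is not 100 * count / length", call. = FALSE)
  }
  if (!is.null(report$burial)) {
    b <- report$burial
    if (b$evaluable != b$buried + b$exposed) {
      stop("burial counts do not sum to the evaluable total", call. = FALSE)
    }
    if (b$evaluable > 0 &&
        b$buried_pct != round_half_away(100 * b$buried / b$evaluable)) {
      stop("buried percentage does not match its counts", call. = FALSE)
    }
  }
  invisible(report)
}

#' @export
print.summary_report <- function(x, ...) {
  cat(sprintf("<summary_report> %s: %d mutations (%d non-intronic), %d missense on %d residues; %.1f non-intronic/100 aa\n",
              x$protein, x$total, x$nonintronic, x$missense,
              x$affected_residues, x$frequency$frequency))
  if (!is.null(x$burial)) {
    cat(sprintf("  burial: %d buried / %d exposed / %d unresolved (%d%% buried)\n",
                x$burial$buried, x$burial$exposed, x$burial$unresolved,
                x$burial$buried_pct))
  }
  invisible(x)
}
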