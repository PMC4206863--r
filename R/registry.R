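# Mutation registry: TSV I/O, validation, tallies and non-intronic frequencies.

CONSEQUENCE_CLASSES <- c("missense", "nonsense", "silent", "deletion_inframe",
                         "deletion_frameshift", "frameshift", "insertion",
                         "splicing", "intronic", "polymorphism_nondisease",
                         "polymorphism_disease")
# `unclassified` marks registry rows whose per-category assignment could not be
# resolved from the source reports; they count in per-protein totals but in no
# named consequence class.
CONSEQUENCE_EXTENDED <- c(CONSEQUENCE_CLASSES, "unclassified")

REGISTRY_COLUMNS <- c("protein", "dna_change", "protein_change", "consequence",
                      "disease_tags", "phenotype_type", "source_ref")

#' Round half away from zero
#'
#' Nearest-integer rounding with ties going away from zero (so 12.5 -> 13 and
#' -12.5 -> -13), the convention used for all printed integer frequencies and
#' percentages in this package.
#'
#' @param x numeric vector.
#' @return numeric vector of rounded values.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Read a mutation registry from TSV
#'
#' The file must carry the header
#' `protein dna_change protein_change consequence disease_tags phenotype_type
#' source_ref` (tab-separated, UTF-8, `;`-separated multi-tags). Residue
#' positions and reference/alternate residues are derived by parsing
#' `protein_change` with [parse_protein_change()]; rows without a protein-level
#' token (intronic and some splicing records) carry `NA` positions.
#'
#' @param path path to a TSV file.
#' @param validate validate records after reading (default `TRUE`).
#' @param proteins optional named list of [protein_definition()] used for
#'   position-range validation.
#' @return a `mutation_registry` data frame with the seven input columns plus
#'   derived `position`, `ref_aa`, `alt_aa`.
#' @export
read_registry <- function(path, validate = TRUE, proteins = NULL) {
  if (!file.exists(path)) stop("registry file not found: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = c("NA", ""),
                          fileEncoding = "UTF-8")
  missing <- setdiff(REGISTRY_COLUMNS, names(df))
  if (length(missing)) {
    stop("registry is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  as_registry(df[REGISTRY_COLUMNS], validate = validate, proteins = proteins)
}

#' Build a mutation registry from a data frame
#'
#' @param df data frame with the seven registry columns (see
#'   [read_registry()]).
#' @inheritParams read_registry
#' @return a `mutation_registry` data frame.
#' @export
as_registry <- function(df, validate = TRUE, proteins = NULL) {
  df$position <- rep(NA_integer_, nrow(df))
  df$ref_aa <- rep(NA_character_, nrow(df))
  df$alt_aa <- rep(NA_character_, nrow(df))
  has_tok <- !is.na(df$protein_change)
  for (i in which(has_tok)) {
    p <- parse_protein_change(df$protein_change[i])
    df$position[i] <- p$position
    df$ref_aa[i] <- p$ref_aa
    df$alt_aa[i] <- p$alt_aa
  }
  class(df) <- c("mutation_registry", "data.frame")
  if (validate) validate_registry(df, proteins = proteins)
  df
}

#' Validate a mutation registry
#'
#' Checks the consequence vocabulary, the consistency of parsed protein
#' changes with the declared consequence class (missense rows must carry
#' distinct reference/alternate residues, silent rows identical ones) and,
#' when protein definitions are supplied, that every position lies inside
#' `[1, protein length]`.
#'
#' @param registry a `mutation_registry`.
#' @param proteins optional named list of [protein_definition()].
#' @return the registry, invisibly; errors describe the first offending row.
#' @export
validate_registry <- function(registry, proteins = NULL) {
  bad <- !registry$consequence %in% CONSEQUENCE_EXTENDED
  if (any(bad)) {
    stop("unknown consequence class '", registry$consequence[which(bad)[1]],
         "' at row ", which(bad)[1], call. = FALSE)
  }
  mis <- registry$consequence == "missense"
  if (any(mis & (is.na(registry$position) | is.na(registry$ref_aa) |
                 is.na(registry$alt_aa)))) {
    stop("missense record without parsed position/ref/alt at row ",
         which(mis & is.na(registry$position))[1], call. = FALSE)
  }
  if (any(mis & registry$ref_aa == registry$alt_aa, na.rm = TRUE)) {
    stop("missense record with identical ref and alt residue", call. = FALSE)
  }
  sil <- registry$consequence == "silent" & !is.na(registry$alt_aa)
  if (any(registry$ref_aa[sil] != registry$alt_aa[sil])) {
    stop("silent record with differing ref and alt residue", call. = FALSE)
  }
  if (!is.null(proteins)) {
    for (i in which(!is.na(registry$position))) {
      pd <- proteins[[registry$protein[i]]]
      if (is.null(pd)) next
      if (registry$position[i] < 1L || registry$position[i] > pd$length) {
        stop("row ", i, ": position ", registry$position[i],
             " outside [1, ", pd$length, "] for ", pd$name, call. = FALSE)
      }
    }
  }
  invisible(registry)
}

#' Write a mutation registry to TSV
#'
#' Writes the seven canonical columns; reading the file back with
#' [read_registry()] reproduces the records field-for-field.
#'
#' @param registry a `mutation_registry`.
#' @param path output path.
#' @export
write_registry <- function(registry, path) {
  utils::write.table(registry[REGISTRY_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Packaged registry of complement disease-associated mutations
#'
#' A synthetic reconstruction of the published mutation registry for CFH, CFI,
#' MCP and C3: the per-mutation rows are constructed (the source supplementary
#' table is not redistributed) but every reported marginal is reproduced --
#' per-protein totals (163/64/49/48), per-consequence tallies, per-domain
#' missense counts, duplicate-residue structure, consensus-region splits and
#' aHUS disease-tag counts. Mutations named in the literature (Arg102Gly,
#' Lys65Gln, Lys155Gln, Arg161Trp, Pro314Leu, Arg1320Gln, Tyr402His,
#' Arg1210Cys, ...) appear verbatim.
#'
#' @return a validated `mutation_registry`.
#' @export
complement_registry <- function() {
  read_registry(system.file("extdata", "complement_registry_synthetic.tsv",
                            package = "scrmap", mustWork = TRUE),
                proteins = complement_proteins())
}

#' Is a record non-intronic?
#'
#' A record is intronic when its consequence is `intronic`, or `splicing`
#' without a residue-level protein change (a splice change inside an intron).
#' Everything else -- including exonic splice-site changes -- is non-intronic.
#'
#' @param registry a `mutation_registry`.
#' @return logical vector.
#' @export
is_nonintronic <- function(registry) {
  !(registry$consequence == "intronic" |
      (registry$consequence == "splicing" & is.na(registry$position)))
}

#' Tally mutation records by a grouping key
#'
#' @param registry a `mutation_registry` (possibly pre-filtered).
#' @param by grouping key: `"consequence"`, `"protein"`, `"domain"`,
#'   `"disease_tags"` or `"phenotype_type"`. Domain grouping requires
#'   `proteins` and uses [assign_domain()]; records without a position are
#'   grouped as `"unpositioned"`. Disease-tag grouping uses the full
#'   `;`-separated tag set as the key so that counts partition the records.
#' @param proteins named list of [protein_definition()] (needed for
#'   `by = "domain"`).
#' @return a `tally_table` data frame with columns `key` and `count`, and a
#'   `total` attribute equal to the number of records tallied.
#' @examples
#' reg <- complement_registry()
#' tally(reg[reg$protein == "CFH", ], "consequence")
#' @export
tally <- function(registry, by = "consequence", proteins = NULL) {
  keys <- switch(by,
    consequence = registry$consequence,
    protein = registry$protein,
    phenotype_type = ifelse(is.na(registry$phenotype_type), "unknown",
                            registry$phenotype_type),
    disease_tags = ifelse(is.na(registry$disease_tags), "none",
                          registry$disease_tags),
    domain = {
      if (is.null(proteins)) {
        stop("domain tallies require protein definitions", call. = FALSE)
      }
      vapply(seq_len(nrow(registry)), function(i) {
        if (is.na(registry$position[i])) return("unpositioned")
        pd <- proteins[[registry$protein[i]]]
        if (is.null(pd)) {
          stop("no protein definition for '", registry$protein[i], "'",
               call. = FALSE)
        }
        assign_domain(registry$position[i], pd)$label
      }, character(1))
    },
    stop("unknown grouping key '", by, "'", call. = FALSE)
  )
  tab <- table(keys)
  out <- data.frame(key = as.character(names(tab)), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  if (nrow(out) > 0) out <- out[order(-out$count, out$key), ]
  rownames(out) <- NULL
  attr(out, "total") <- nrow(registry)
  attr(out, "by") <- by
  class(out) <- c("tally_table", "data.frame")
  out
}

#' @export
print.tally_table <- function(x, ...) {
  cat(sprintf("<tally_table> by %s, total %d\n", attr(x, "by"),
              attr(x, "total")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Non-intronic mutational frequency per 100 residues
#'
#' `100 * (non-intronic records with a position inside the region) /
#' (region residue length)`, with the integer form rounded half away from
#' zero. The region is a whole protein or a set of its domains (the union of
#' their spans; inter-domain linkers are then not counted in the length).
#'
#' @param registry a `mutation_registry` restricted to one protein.
#' @param region a [protein_definition()], a [domain_definition()], or a list
#'   of domain definitions.
#' @return list with `count`, `length`, `frequency` (real) and `rounded`.
#' @examples
#' defs <- complement_proteins()
#' reg <- complement_registry()
#' nonintronic_frequency(reg[reg$protein == "CFH", ], defs$CFH)$rounded  # 13
#' @export
nonintronic_frequency <- function(registry, region) {
  if (inherits(region, "protein_definition")) {
    residues <- seq_len(region$length)
  } else {
    if (inherits(region, "domain_definition")) region <- list(region)
    residues <- sort(unique(unlist(lapply(region, domain_residues))))
  }
  len <- length(residues)
  if (len == 0L) stop("zero-length region", call. = FALSE)
  keep <- is_nonintronic(registry) & !is.na(registry$position) &
    registry$position %in% residues
  count <- sum(keep)
  freq <- 100 * count / len
  list(count = count, length = len, frequency = freq,
       rounded = as.integer(round_half_away(freq)))
}
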