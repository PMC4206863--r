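# Protein and domain architecture definitions.

DOMAIN_CLASSES <- c("SCR", "FIMAC", "SRCR", "LDLr", "SP", "MG", "TED", "CUB",
                    "ANA", "LNK", "C345C", "ST", "TM", "Cy", "linker")

#' Define a protein domain
#'
#' @param label domain label, e.g. `"SCR-20"` or `"TED"`.
#' @param klass domain class, one of the controlled vocabulary
#'   (`SCR`, `FIMAC`, `SRCR`, `LDLr`, `SP`, `MG`, `TED`, `CUB`, `ANA`, `LNK`,
#'   `C345C`, `ST`, `TM`, `Cy`, `linker`).
#' @param start,end 1-based inclusive residue span.
#' @param split_parts optional list of `c(start, end)` pairs for
#'   sequence-discontinuous domains (e.g. the two parts of MG6 and CUB in C3).
#' @return an object of class `domain_definition`.
#' @export
domain_definition <- function(label, klass, start, end, split_parts = NULL) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!klass %in% DOMAIN_CLASSES) {
    stop("unknown domain class '", klass, "'; must be one of: ",
         paste(DOMAIN_CLASSES, collapse = ", "), call. = FALSE)
  }
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end || start < 1L) {
    stop("invalid span ", start, "-", end, " for domain '", label, "'",
         call. = FALSE)
  }
  if (!is.null(split_parts)) {
    split_parts <- lapply(split_parts, function(p) {
      p <- as.integer(p)
      stopifnot(length(p) == 2L, p[1] <= p[2])
      p
    })
    main <- seq.int(start, end)
    for (p in split_parts) {
      if (any(seq.int(p[1], p[2]) %in% main)) {
        stop("split part ", p[1], "-", p[2], " overlaps main span of '",
             label, "'", call. = FALSE)
      }
    }
  }
  structure(list(label = label, klass = klass, start = start, end = end,
                 split_parts = split_parts),
            class = "domain_definition")
}

#' Residue positions covered by a domain (main span plus split parts)
#' @param domain a `domain_definition`.
#' @return integer vector of residue indices.
#' @export
domain_residues <- function(domain) {
  out <- seq.int(domain$start, domain$end)
  for (p in domain$split_parts) out <- c(out, seq.int(p[1], p[2]))
  sort(out)
}

#' Residue length of a domain or set of domains
#' @param domains a `domain_definition` or list of them.
#' @return total residue count.
#' @export
domain_length <- function(domains) {
  if (inherits(domains, "domain_definition")) domains <- list(domains)
  sum(vapply(domains, function(d) length(domain_residues(d)), integer(1)))
}

#' Define a protein and its domain architecture
#'
#' Residue numbering is 1-based from the initiator methionine throughout
#' (HGVS convention); the signal peptide is counted, not subtracted.
#'
#' @param name protein name, e.g. `"CFH"`.
#' @param gene gene symbol.
#' @param uniprot_id UniProt accession used as the span authority.
#' @param length protein length in residues, counted from Met-1.
#' @param domains ordered list of [domain_definition()] objects with
#'   non-overlapping spans inside `[1, length]`.
#' @param signal_peptide_end last residue of the signal peptide, or `NA`.
#' @return an object of class `protein_definition`.
#' @export
protein_definition <- function(name, gene, uniprot_id, length, domains,
                               signal_peptide_end = NA_integer_) {
  length <- as.integer(length)
  stopifnot(length > 0L)
  covered <- integer(0)
  starts <- vapply(domains, `[[`, integer(1), "start")
  if (is.unsorted(starts)) stop("domains must be ordered by start position",
                                call. = FALSE)
  for (d in domains) {
    res <- domain_residues(d)
    if (min(res) < 1L || max(res) > length) {
      stop("domain '", d$label, "' extends outside [1, ", length, "]",
           call. = FALSE)
    }
    if (any(res %in% covered)) {
      stop("domain '", d$label, "' overlaps an earlier domain", call. = FALSE)
    }
    covered <- c(covered, res)
  }
  names(domains) <- vapply(domains, `[[`, character(1), "label")
  structure(list(name = name, gene = gene, uniprot_id = uniprot_id,
                 length = length, domains = domains,
                 signal_peptide_end = as.integer(signal_peptide_end)),
            class = "protein_definition")
}

#' @export
print.protein_definition <- function(x, ...) {
  cat(sprintf("<protein_definition> %s (%s, %s), %d aa, %d domains\n",
              x$name, x$gene, x$uniprot_id, x$length, length(x$domains)))
  invisible(x)
}

#' Assign a residue position to a domain
#'
#' Positions between domain spans are assigned to `"linker"`; positions inside
#' the signal peptide to `"signal_peptide"`. Split domains match any of their
#' parts.
#'
#' @param position residue index, 1-based from Met-1.
#' @param protein a [protein_definition()].
#' @return a list with `label` (domain label, `"linker"` or
#'   `"signal_peptide"`) and `klass` (domain class or `NA`).
#' @examples
#' defs <- complement_proteins()
#' assign_domain(1320, defs$C3)$label  # CUB
#' @export
assign_domain <- function(position, protein) {
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > protein$length) {
    stop("position ", position, " outside [1, ", protein$length, "] for ",
         protein$name, call. = FALSE)
  }
  for (d in protein$domains) {
    if (position %in% domain_residues(d)) {
      return(list(label = d$label, klass = d$klass))
    }
  }
  spe <- protein$signal_peptide_end
  if (!is.na(spe) && position <= spe) {
    return(list(label = "signal_peptide", klass = NA_character_))
  }
  list(label = "linker", klass = "linker")
}

.parse_span <- function(s) {
  m <- regmatches(s, regexec("^([0-9]+)-([0-9]+)$", trimws(s)))[[1]]
  if (length(m) != 3L) stop("bad span string '", s, "'", call. = FALSE)
  c(as.integer(m[2]), as.integer(m[3]))
}

#' Read protein definitions from a YAML configuration file
#'
#' One document per protein; spans written as `"start-end"` (1-based,
#' inclusive); discontinuous domains list additional spans under `parts`.
#'
#' @param path path to a YAML file.
#' @return named list of [protein_definition()] objects.
#' @export
read_protein_config <- function(path) {
  if (!file.exists(path)) stop("protein config not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  out <- lapply(cfg, function(p) {
    domains <- lapply(p$domains, function(d) {
      span <- .parse_span(d$span)
      parts <- if (!is.null(d$parts)) lapply(d$parts, .parse_span) else NULL
      domain_definition(d$label, d$class, span[1], span[2], parts)
    })
    protein_definition(p$name, p$gene, p$uniprot, p$length, domains,
                       if (is.null(p$signal_peptide_end)) NA_integer_
                       else p$signal_peptide_end)
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Packaged complement protein architectures
#'
#' Curated domain architectures for CFH, CFI, MCP and C3 (UniProt P08603,
#' P05156, P15529, P01024 as authority; HGVS Met-1 numbering).
#'
#' @return named list of [protein_definition()] objects.
#' @export
complement_proteins <- function() {
  read_protein_config(system.file("extdata", "proteins.yaml",
                                  package = "scrmap", mustWork = TRUE))
}
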