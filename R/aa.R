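# Amino-acid code tables and HGVS-style protein-change parsing.

AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
         "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
names(AA1) <- AA3

#' Convert one-letter amino-acid codes to three-letter codes
#'
#' @param x character vector of one-letter codes (e.g. `"K"`). `"*"` and `"X"`
#'   are accepted as stop codons and return `"Ter"`.
#' @return character vector of three-letter codes.
#' @export
aa1to3 <- function(x) {
  out <- AA3[match(toupper(x), AA1)]
  out[x %in% c("*", "X", "x")] <- "Ter"
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown one-letter amino-acid code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Convert three-letter amino-acid codes to one-letter codes
#'
#' @param x character vector of three-letter codes (case-insensitive first
#'   letter capitalised form, e.g. `"Arg"`). `"Ter"` returns `"*"`.
#' @return character vector of one-letter codes.
#' @export
aa3to1 <- function(x) {
  xn <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, 3)))
  out <- unname(AA1[xn])
  out[xn == "Ter"] <- "*"
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown three-letter amino-acid code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

.norm_aa3 <- function(x, token) {
  xn <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
  if (xn %in% c("Ter", "X", "*")) return("Ter")
  if (nchar(xn) == 1) {
    if (xn %in% c("*")) return("Ter")
    hit <- AA3[match(toupper(xn), AA1)]
    if (is.na(hit)) stop("unknown amino-acid code '", x, "' in token '", token,
                         "'", call. = FALSE)
    return(hit)
  }
  if (!(xn %in% AA3)) {
    stop("unknown amino-acid code '", x, "' in token '", token, "'",
         call. = FALSE)
  }
  xn
}

#' Parse an HGVS-style protein change token
#'
#' Accepts the three-letter dialect (`"Arg102Gly"`, `"Tyr402His"`,
#' `"Arg1210Ter"`, `"Leu24del"`, `"Ser722fs"`, `"Lys224ins"`, `"Gly54dup"`,
#' `"Ala304="`) and the one-letter dialect (`"K65Q"`, `"W528X"`, `"R102G"`),
#' with or without a leading `"p."` and optional surrounding parentheses.
#' Stop-codon substitutions (`Ter`, `X`, `*`) are classified as nonsense and
#' identical reference/alternate residues (or `"="`) as silent.
#'
#' @param token a single non-empty protein-change string.
#' @return a list with elements `ref_aa` (three-letter code), `position`
#'   (positive integer), `alt_aa` (three-letter code or `NA` for
#'   deletion/frameshift/insertion kinds) and `kind` (one of `"missense"`,
#'   `"nonsense"`, `"silent"`, `"deletion"`, `"frameshift"`, `"insertion"`).
#' @examples
#' parse_protein_change("Arg102Gly")
#' parse_protein_change("K65Q")
#' parse_protein_change("p.Tyr402His")
#' @export
parse_protein_change <- function(token) {
  if (!is.character(token) || length(token) != 1L || is.na(token) ||
      !nzchar(token)) {
    stop("protein change token must be a single non-empty string",
         call. = FALSE)
  }
  raw <- token
  tok <- sub("^p\\.", "", trimws(token))
  tok <- sub("^\\((.*)\\)$", "\\1", tok)

  m <- regmatches(tok, regexec(
    "^([A-Za-z]{1,3})([0-9]+)([A-Za-z*=]{1,3}|\\*)$", tok))[[1]]
  if (length(m) != 4L) {
    stop("malformed protein change token '", raw, "'", call. = FALSE)
  }
  ref <- m[2]; pos <- suppressWarnings(as.integer(m[3])); alt <- m[4]
  if (is.na(pos) || pos <= 0L) {
    stop("non-positive residue position in token '", raw, "'", call. = FALSE)
  }
  ref3 <- .norm_aa3(ref, raw)
  if (ref3 == "Ter") stop("reference residue cannot be a stop codon in '",
                          raw, "'", call. = FALSE)
  kind <- NULL
  alt_l <- tolower(alt)
  if (alt_l == "del") {
    kind <- "deletion"; alt3 <- NA_character_
  } else if (alt_l == "fs") {
    kind <- "frameshift"; alt3 <- NA_character_
  } else if (alt_l %in% c("ins", "dup")) {
    kind <- "insertion"; alt3 <- NA_character_
  } else if (alt == "=") {
    kind <- "silent"; alt3 <- ref3
  } else {
    alt3 <- .norm_aa3(alt, raw)
    kind <- if (alt3 == "Ter") "nonsense"
            else if (alt3 == ref3) "silent"
            else "missense"
  }
  list(ref_aa = ref3, position = pos, alt_aa = alt3, kind = kind)
}
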