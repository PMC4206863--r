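# Consensus SCR profile: aligned-FASTA input, majority consensus, mapping of
# protein positions into consensus numbering, and region tallies.

HYPERVARIABLE_LOOP <- 11:15
SCR_REGIONS <- c("hypervariable_loop", "cys_anchor", "other")

#' Read an SCR domain alignment from aligned FASTA
#'
#' Member headers may carry `key=value` metadata after the identifier, e.g.
#' `>CFH_SCR-20 protein=CFH domain=SCR-20 start=1167 end=1231`; `start`/`end`
#' give the member's residue span in protein coordinates (HGVS Met-1
#' numbering) and make the member usable for position mapping. The gap
#' character is `-`.
#'
#' The four cysteine anchor columns are auto-detected as the columns in which
#' every member carries Cys, unless `anchor_cols` supplies them. Consensus
#' columns are the majority-occupied columns from the first anchor column
#' onwards; columns before the first Cys and sparse insertion columns fall
#' outside the consensus numbering.
#'
#' @param path aligned FASTA file.
#' @param anchor_cols optional integer vector of four alignment columns.
#' @return an object of class `scr_alignment`.
#' @export
read_scr_alignment <- function(path, anchor_cols = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path,
                               call. = FALSE)
  seqs <- Biostrings::readAAStringSet(path)
  ids <- names(seqs)
  meta <- lapply(ids, function(h) {
    parts <- strsplit(h, "\\s+")[[1]]
    kv <- grep("=", parts, value = TRUE)
    vals <- stats::setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
    list(id = parts[1], protein = unname(vals["protein"]),
         domain = unname(vals["domain"]),
         start = suppressWarnings(as.integer(vals["start"])),
         end = suppressWarnings(as.integer(vals["end"])))
  })
  aligned <- as.character(seqs)
  names(aligned) <- vapply(meta, `[[`, character(1), "id")
  scr_alignment(aligned, members = do.call(rbind, lapply(meta, function(m) {
    data.frame(id = m$id, protein = ifelse(is.null(m$protein) || is.na(m$protein),
                                           NA_character_, m$protein),
               domain = ifelse(is.null(m$domain) || is.na(m$domain),
                               NA_character_, m$domain),
               start = m$start, end = m$end, stringsAsFactors = FALSE)
  })), anchor_cols = anchor_cols)
}

#' Construct an SCR alignment object
#'
#' @param aligned named character vector of equal-width aligned sequences
#'   (gap `-`).
#' @param members optional data frame with columns `id`, `protein`, `domain`,
#'   `start`, `end` describing each member's protein coordinates.
#' @param anchor_cols optional integer vector of four anchor columns; if
#'   `NULL` they are auto-detected as the all-Cys columns.
#' @return an object of class `scr_alignment`.
#' @export
scr_alignment <- function(aligned, members = NULL, anchor_cols = NULL) {
  widths <- nchar(aligned)
  if (length(unique(widths)) != 1L) {
    stop("alignment members have inconsistent column counts: ",
         paste(unique(widths), collapse = ", "), call. = FALSE)
  }
  ncol <- widths[[1]]
  mat <- do.call(rbind, strsplit(toupper(aligned), ""))
  rownames(mat) <- names(aligned)
  if (is.null(anchor_cols)) {
    anchor_cols <- which(apply(mat, 2, function(col) all(col == "C")))
  }
  if (length(anchor_cols) != 4L) {
    stop("expected 4 cysteine anchor columns, found ", length(anchor_cols),
         call. = FALSE)
  }
  anchor_cols <- sort(as.integer(anchor_cols))
  occupancy <- colMeans(mat != "-")
  core_cols <- which(occupancy >= 0.5)
  core_cols <- core_cols[core_cols >= anchor_cols[1]]
  if (!all(anchor_cols %in% core_cols)) {
    stop("anchor columns fall outside the majority-occupied core",
         call. = FALSE)
  }
  consensus_index <- rep(NA_integer_, ncol)
  consensus_index[core_cols] <- seq_along(core_cols)
  if (is.null(members)) {
    members <- data.frame(id = names(aligned), protein = NA_character_,
                          domain = NA_character_, start = NA_integer_,
                          end = NA_integer_, stringsAsFactors = FALSE)
  }
  structure(list(mat = mat, members = members, ncol = ncol,
                 anchor_cols = anchor_cols, core_cols = core_cols,
                 consensus_index = consensus_index,
                 consensus_length = length(core_cols),
                 anchor_positions = consensus_index[anchor_cols]),
            class = "scr_alignment")
}

#' @export
print.scr_alignment <- function(x, ...) {
  cat(sprintf(paste0("<scr_alignment> %d members x %d columns; consensus ",
                     "length %d; Cys anchors at consensus %s\n"),
              nrow(x$mat), x$ncol, x$consensus_length,
              paste(x$anchor_positions, collapse = ", ")))
  invisible(x)
}

#' Packaged SCR alignment for the complement proteins
#'
#' A 124-member SCR-domain alignment: the 20 CFH and 4 MCP domain members
#' carry protein coordinates for position mapping; the remaining 100 members
#' are synthetic library sequences that fix the consensus. The file is a
#' synthetic stand-in for the published 124-sequence human complement SCR set
#' (whose membership is not enumerated in the source), with the canonical
#' anchor geometry: Cys at consensus positions 1, 26, 39 and 49 and the
#' hypervariable loop at 11-15.
#'
#' @return an `scr_alignment`.
#' @export
complement_scr_alignment <- function() {
  read_scr_alignment(system.file("extdata", "scr_alignment_synthetic.fasta",
                                 package = "scrmap", mustWork = TRUE))
}

#' Build a consensus profile from an SCR alignment
#'
#' The consensus residue at each position is the most frequent residue in
#' that column (gaps ignored; ties broken by amino-acid alphabetical order).
#' Positions are labelled `cys_anchor` at the four anchor positions,
#' `hypervariable_loop` at positions 11-15 (anchors take precedence) and
#' `other` elsewhere.
#'
#' @param alignment an `scr_alignment`.
#' @return a `consensus_profile` data frame with columns `position`,
#'   `residue`, `region`, and attributes `anchor_positions` and `loop`.
#' @export
build_consensus <- function(alignment) {
  stopifnot(inherits(alignment, "scr_alignment"))
  residues <- vapply(alignment$core_cols, function(c) {
    col <- alignment$mat[, c]
    col <- col[col != "-"]
    tab <- table(col)
    names(tab)[order(-tab, names(tab))][1]  # ties: alphabetical
  }, character(1))
  position <- seq_len(alignment$consensus_length)
  region <- rep("other", length(position))
  region[position %in% HYPERVARIABLE_LOOP] <- "hypervariable_loop"
  region[position %in% alignment$anchor_positions] <- "cys_anchor"
  out <- data.frame(position = position, residue = residues, region = region,
                    stringsAsFactors = FALSE)
  attr(out, "anchor_positions") <- alignment$anchor_positions
  attr(out, "loop") <- HYPERVARIABLE_LOOP
  class(out) <- c("consensus_profile", "data.frame")
  out
}

#' Map a protein residue position into consensus numbering
#'
#' Residues in consensus columns map directly; residues in insertion columns
#' map to the nearest preceding consensus position; residues before the first
#' consensus column are unmappable and return `NA`.
#'
#' @param alignment an `scr_alignment` whose members carry `start`/`end`
#'   protein coordinates.
#' @param member member identifier.
#' @param protein_position residue index (protein coordinates) inside the
#'   member span.
#' @return consensus position (integer), or `NA` if unmappable.
#' @export
map_position_to_consensus <- function(alignment, member, protein_position) {
  mi <- match(member, alignment$members$id)
  if (is.na(mi)) stop("unknown alignment member '", member, "'",
                      call. = FALSE)
  start <- alignment$members$start[mi]
  if (is.na(start)) stop("member '", member, "' carries no protein coordinates",
                         call. = FALSE)
  row <- alignment$mat[mi, ]
  res_cols <- which(row != "-")
  k <- as.integer(protein_position) - start + 1L
  if (k < 1L || k > length(res_cols)) {
    stop("position ", protein_position, " outside span of member '", member,
         "'", call. = FALSE)
  }
  col <- res_cols[k]
  idx <- alignment$consensus_index[col]
  if (!is.na(idx)) return(idx)
  prior <- alignment$core_cols[alignment$core_cols < col]
  if (!length(prior)) return(NA_integer_)  # before the first consensus column
  alignment$consensus_index[max(prior)]
}

#' Region label of a consensus position
#' @param position consensus position(s).
#' @param anchors anchor positions (default `c(1, 26, 39, 49)`).
#' @param loop hypervariable loop positions (default `11:15`).
#' @return character vector in `{hypervariable_loop, cys_anchor, other}`.
#' @export
consensus_region <- function(position, anchors = c(1L, 26L, 39L, 49L),
                             loop = HYPERVARIABLE_LOOP) {
  out <- rep("other", length(position))
  out[position %in% loop] <- "hypervariable_loop"
  out[position %in% anchors] <- "cys_anchor"  # precedence over the loop
  out[is.na(position)] <- NA_character_
  out
}

#' Map a registry's SCR missense mutations into consensus numbering
#'
#' For each missense record of a protein represented in the alignment, the
#' member whose span covers the mutated position provides the mapping;
#' mutations outside every member span (linkers, signal peptide, non-SCR
#' regions) are reported with region `outside_scr` and an `NA` consensus
#' position.
#'
#' @param registry a `mutation_registry`.
#' @param alignment an `scr_alignment` with coordinate-bearing members.
#' @return data frame `protein, domain, protein_pos, consensus_pos, region`.
#' @export
map_mutations_to_consensus <- function(registry, alignment) {
  mem <- alignment$members
  mem <- mem[!is.na(mem$start) & !is.na(mem$protein), , drop = FALSE]
  keep <- registry$consequence == "missense" &
    registry$protein %in% mem$protein & !is.na(registry$position)
  reg <- registry[keep, , drop = FALSE]
  n <- nrow(reg)
  out <- data.frame(protein = reg$protein, domain = NA_character_,
                    protein_pos = reg$position,
                    consensus_pos = NA_integer_, region = "outside_scr",
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    hit <- which(mem$protein == reg$protein[i] &
                   mem$start <= reg$position[i] & mem$end >= reg$position[i])
    if (!length(hit)) next
    m <- mem[hit[1], ]
    cp <- map_position_to_consensus(alignment, m$id, reg$position[i])
    out$domain[i] <- m$domain
    out$consensus_pos[i] <- cp
    out$region[i] <- if (is.na(cp)) "unmappable"
                     else consensus_region(cp,
                                           anchors = alignment$anchor_positions)
  }
  out
}

#' Tally mapped mutations by consensus region
#'
#' Partitions consensus positions into hypervariable loop (11-15), cysteine
#' anchors and other, with integer percentages (half away from zero) computed
#' from the unrounded ratios. Empty input yields zero counts and `NA`
#' percentages.
#'
#' @param positions integer vector of consensus positions.
#' @param anchors anchor positions (default `c(1, 26, 39, 49)`).
#' @param loop loop positions (default `11:15`).
#' @return a `region_counts` list: `loop_count`, `cys_count`, `other_count`,
#'   `total`, `loop_pct`, `cys_pct`, `other_pct`.
#' @export
region_tally <- function(positions, anchors = c(1L, 26L, 39L, 49L),
                         loop = HYPERVARIABLE_LOOP) {
  positions <- positions[!is.na(positions)]
  region <- consensus_region(positions, anchors = anchors, loop = loop)
  total <- length(region)
  counts <- c(loop_count = sum(region == "hypervariable_loop"),
              cys_count = sum(region == "cys_anchor"),
              other_count = sum(region == "other"))
  pct <- if (total > 0) {
    as.integer(round_half_away(100 * counts / total))
  } else rep(NA_integer_, 3L)
  structure(list(loop_count = unname(counts[1]), cys_count = unname(counts[2]),
                 other_count = unname(counts[3]), total = total,
                 loop_pct = pct[1], cys_pct = pct[2], other_pct = pct[3]),
            class = "region_counts")
}

#' @export
print.region_counts <- function(x, ...) {
  cat(sprintf(paste0("<region_counts> total %d: loop %d (%s%%), Cys %d ",
                     "(%s%%), other %d (%s%%)\n"),
              x$total, x$loop_count, x$loop_pct, x$cys_count, x$cys_pct,
              x$other_count, x$other_pct))
  invisible(x)
}

#' Average per-position accessibility profiles over structures
#'
#' Each input profile is a numeric vector of relative side-chain
#' accessibilities (percent) indexed by consensus position, `NA` where the
#' structure does not cover the position. Positions are averaged over the
#' structures that cover them, then binned into deciles 0-9
#' (`floor(mean / 10)`, clamped).
#'
#' @param profiles list of numeric vectors of equal length.
#' @return data frame `position`, `mean_accessibility`, `bin` (`NA` where no
#'   structure covers the position).
#' @export
average_accessibility_profile <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  lens <- vapply(profiles, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("profiles must share the consensus length", call. = FALSE)
  }
  m <- do.call(rbind, profiles)
  means <- colMeans(m, na.rm = TRUE)
  means[!is.finite(means)] <- NA_real_
  bins <- ifelse(is.na(means), NA_integer_,
                 pmin(9L, pmax(0L, as.integer(floor(means / 10)))))
  data.frame(position = seq_along(means), mean_accessibility = means,
             bin = bins)
}
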