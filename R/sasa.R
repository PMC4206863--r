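# Solvent-accessible surface area (rolling-probe, Shrake-Rupley quadrature),
# relative side-chain accessibility, decile binning and burial classification.

# van der Waals radii (Angstrom); hydrogens are ignored throughout.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90)

# Theoretical maximum residue solvent accessibilities (Angstrom^2),
# Tien et al. (2013) theoretical set; used as the per-residue-type reference
# denominators for relative accessibility.
MAX_SASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
              GLU = 223, GLN = 225, GLY = 104, HIS = 224, ILE = 197,
              LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
              SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Deterministic golden-spiral sphere quadrature points
#'
#' Seed-free, exactly reproducible unit-sphere point layout used by [sasa()].
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Per-atom solvent-accessible surface area
#'
#' Rolling-probe numerical SASA: each heavy atom is inflated by the probe
#' radius and sampled with a deterministic golden-spiral quadrature; a sample
#' point is exposed when it lies outside every neighbouring inflated sphere,
#' and the atom's area is the exposed fraction of `4 * pi * (r + probe)^2`.
#'
#' @param model a `structure_model`.
#' @param probe_radius probe radius in Angstrom (default 1.4, water).
#' @param n_points quadrature points per atom (default 960).
#' @return the model's atom table with an added `sasa` column (Angstrom^2).
#' @export
sasa <- function(model, probe_radius = 1.4, n_points = 960) {
  at <- model$atoms
  radii <- VDW_RADII[at$element]
  if (anyNA(radii)) {
    bad <- unique(at$element[is.na(radii)])
    stop("no van der Waals radius configured for element(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  R <- unname(radii) + probe_radius
  xyz <- as.matrix(at[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- golden_spiral_points(n_points)
  areas <- numeric(n)
  maxR <- max(R)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (R[i] + maxR)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (R[i] + R[nb])^2]
    if (!length(nb)) {
      areas[i] <- 4 * pi * R[i]^2
      next
    }
    p <- sweep(pts * R[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj <- rowSums(sweep(p, 2, xyz[j, ])^2)
      exposed <- exposed & dj >= R[j]^2
    }
    areas[i] <- mean(exposed) * 4 * pi * R[i]^2
  }
  at$sasa <- areas
  at
}

#' Per-residue accessibility profile
#'
#' Sums side-chain atom SASA per residue (for glycine the alpha-carbon serves
#' as the side-chain proxy), normalises by the residue-type reference maximum
#' (Tien et al. theoretical values), caps the percentage at 100, bins it into
#' deciles 0-9 (`floor(pct / 10)`) and flags residues at or below the burial
#' threshold bin as buried.
#'
#' @param model a `structure_model`.
#' @param probe_radius,n_points passed to [sasa()].
#' @param threshold_bin burial threshold: buried when `bin <= threshold_bin`
#'   (default 2; the stricter convention `bin <= 1` is available by setting
#'   `threshold_bin = 1`).
#' @return an `accessibility_profile` data frame with columns `chain`,
#'   `resno`, `aa`, `sc_sasa`, `rel_pct`, `bin`, `buried`. Residue types
#'   without a reference maximum get `NA` accessibility.
#' @export
accessibility_profile <- function(model, probe_radius = 1.4, n_points = 960,
                                  threshold_bin = 2) {
  at <- sasa(model, probe_radius = probe_radius, n_points = n_points)
  key <- paste(at$chain, at$resno)
  res <- !duplicated(key)
  out <- data.frame(chain = at$chain[res], resno = at$resno[res],
                    aa = at$resid[res], sc_sasa = NA_real_,
                    rel_pct = NA_real_, bin = NA_integer_, buried = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    rows <- at[key == paste(out$chain[i], out$resno[i]), , drop = FALSE]
    sc <- if (out$aa[i] == "GLY") {
      rows[rows$elety == "CA", , drop = FALSE]
    } else {
      rows[!rows$elety %in% BACKBONE_ATOMS, , drop = FALSE]
    }
    if (!nrow(sc)) next  # side chain unresolved
    ref <- MAX_SASA[out$aa[i]]
    if (is.na(ref)) next
    out$sc_sasa[i] <- sum(sc$sasa)
    out$rel_pct[i] <- min(100, 100 * out$sc_sasa[i] / ref)
    out$bin[i] <- min(9L, max(0L, as.integer(floor(out$rel_pct[i] / 10))))
  }
  out$buried <- out$bin <= threshold_bin
  attr(out, "threshold_bin") <- threshold_bin
  attr(out, "probe_radius") <- probe_radius
  attr(out, "n_points") <- n_points
  class(out) <- c("accessibility_profile", "data.frame")
  out
}

#' Classify residues as buried from an accessibility profile
#'
#' Buried means decile bin at or below the threshold (default `bin <= 2`).
#'
#' @param profile an `accessibility_profile`.
#' @param threshold_bin burial threshold bin.
#' @return logical vector aligned with the profile rows (`NA` for residues
#'   without accessibility values).
#' @export
classify_buried <- function(profile, threshold_bin = 2) {
  profile$bin <= threshold_bin
}

#' Write an accessibility profile to TSV
#' @param profile an `accessibility_profile`.
#' @param path output path.
#' @export
write_accessibility <- function(profile, path) {
  df <- data.frame(chain = profile$chain, resnum = profile$resno,
                   aa = profile$aa,
                   sc_sasa_A2 = round(profile$sc_sasa, 2),
                   rel_pct = round(profile$rel_pct, 1), bin = profile$bin,
                   buried = profile$buried)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
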