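# Analytic oracles and small constructed fixtures used across tests.

# Exposed area of two intersecting probe-inflated spheres (closed form):
# each sphere loses a spherical cap where the other overlaps it.
two_sphere_exposed <- function(r1, r2, d, probe = 0) {
  R1 <- r1 + probe; R2 <- r2 + probe
  full <- c(4 * pi * R1^2, 4 * pi * R2^2)
  if (d >= R1 + R2) return(full)
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  c(full[1] - 2 * pi * R1 * h1, full[2] - 2 * pi * R2 * h2)
}

# Minimal structure: bare atoms at given coordinates.
atoms_model <- function(xyz, element = "C", resno = 1L, resid = "ALA",
                        elety = "CB", chain = "A") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  structure_model(data.frame(
    chain = rep(chain, n), resno = rep(resno, length.out = n),
    resid = rep(resid, length.out = n),
    elety = rep(elety, length.out = n),
    element = rep(element, length.out = n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE),
    source = "test")
}

# A serine whose side chain sits inside a closed cage of blocking atoms:
# its side-chain SASA must be exactly zero.
caged_residue <- function(cage_radius = 2.8, n_cage = 42) {
  ser <- data.frame(chain = "A", resno = 1L, resid = "SER",
                    elety = c("N", "CA", "C", "O", "CB"),
                    element = c("N", "C", "C", "O", "C"),
                    x = c(30, 31, 32, 33, 0), y = c(0, 0, 0, 0, 0),
                    z = c(0, 0, 0, 0, 0), stringsAsFactors = FALSE)
  cage_xyz <- golden_spiral_points(n_cage) * cage_radius
  cage <- data.frame(chain = "A", resno = 2L, resid = "LYS",
                     elety = "CD", element = "C",
                     x = cage_xyz[, 1], y = cage_xyz[, 2], z = cage_xyz[, 3],
                     stringsAsFactors = FALSE)
  structure_model(rbind(ser, cage), source = "cage")
}

# Tiny in-memory alignment built directly from strings.
toy_alignment <- function(seqs, members = NULL) {
  if (is.null(names(seqs))) names(seqs) <- paste0("m", seq_along(seqs))
  scr_alignment(seqs, members = members)
}
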