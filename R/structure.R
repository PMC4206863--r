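# Coordinate models: PDB input/output (via bio3d) and anchor-based rigid-body
# superposition with a closed-form least-squares (Kabsch) fit.

#' Construct a structure model from an atom table
#'
#' @param atoms data frame with columns `chain`, `resno`, `resid` (three-letter
#'   residue type), `elety` (atom name), `element`, `x`, `y`, `z`, and
#'   optionally `occupancy` and `b`.
#' @param source identifier for the coordinate set (e.g. a PDB code).
#' @return an object of class `structure_model`.
#' @export
structure_model <- function(atoms, source = "model") {
  need <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z")
  missing <- setdiff(need, names(atoms))
  if (length(missing)) stop("atom table missing column(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates", call. = FALSE)
  }
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  atoms$resno <- as.integer(atoms$resno)
  structure(list(atoms = atoms, source = source), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s: %d atoms, %d residues\n", x$source,
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno)))))
  invisible(x)
}

#' Read a coordinate model from a PDB-format file
#'
#' Parses fixed-column ATOM records (first model of multi-model files);
#' alternate locations are resolved to the highest-occupancy conformer and
#' waters/hetero groups are excluded by default. Hydrogens are dropped
#' (the solvent-accessibility code ignores them).
#'
#' @param path path to a PDB-format file.
#' @param include_hetero keep non-water HETATM records (default `FALSE`).
#' @return a `structure_model`.
#' @export
read_coordinates <- function(path, include_hetero = FALSE) {
  if (!file.exists(path)) stop("coordinate file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  short <- rec & nchar(lines) < 54
  if (any(short)) {
    stop("unparseable (truncated) coordinate record at line ", which(short)[1],
         " of ", path, call. = FALSE)
  }
  bad <- which(rec)[is.na(suppressWarnings(
    as.numeric(substr(lines[rec], 31, 38)) +
      as.numeric(substr(lines[rec], 39, 46)) +
      as.numeric(substr(lines[rec], 47, 54))))]
  if (length(bad)) {
    stop("unparseable coordinate field at line ", bad[1], " of ", path,
         call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (!include_hetero) at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[at$resid != "HOH", , drop = FALSE]
  elem <- at$elesy
  guess <- is.na(elem) | !nzchar(trimws(elem))
  elem[guess] <- substr(trimws(at$elety[guess]), 1, 1)
  at$element <- toupper(trimws(elem))
  at <- at[at$element != "H", , drop = FALSE]
  at$o[is.na(at$o)] <- 1
  # alternate locations: keep the highest-occupancy conformer per atom
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  ord <- order(key, -at$o)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(at$chain, at$resno, at$eleno), , drop = FALSE]
  structure_model(data.frame(chain = at$chain, resno = at$resno,
                             resid = at$resid, elety = trimws(at$elety),
                             element = at$element, x = at$x, y = at$y,
                             z = at$z, occupancy = at$o,
                             b = ifelse(is.na(at$b), 0, at$b),
                             stringsAsFactors = FALSE),
                  source = tools::file_path_sans_ext(basename(path)))
}

#' Write a structure model to a PDB-format file
#'
#' Optionally annotates the B-factor column with per-residue values (e.g.
#' mutation counts), the conventional channel for colouring structures by an
#' external quantity.
#'
#' @param model a `structure_model`.
#' @param path output path.
#' @param residue_values optional named numeric vector (names = residue
#'   numbers) written into the B-factor column of every atom of that residue;
#'   residues not named get 0.
#' @export
write_coordinates <- function(model, path, residue_values = NULL) {
  at <- model$atoms
  b <- at$b
  if (!is.null(residue_values)) {
    b <- unname(residue_values[as.character(at$resno)])
    b[is.na(b)] <- 0
  }
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = at$resno, resid = at$resid,
                   elety = at$elety, chain = at$chain, o = at$occupancy,
                   b = b)
  invisible(path)
}

#' Extract anchor-atom coordinates
#'
#' @param model a `structure_model`.
#' @param resno residue numbers.
#' @param elety atom name to pick per residue (default `"CA"`).
#' @param chain optional chain restriction.
#' @return numeric matrix (length(resno) x 3); errors if an anchor is absent.
#' @export
anchor_coordinates <- function(model, resno, elety = "CA", chain = NULL) {
  at <- model$atoms
  if (!is.null(chain)) at <- at[at$chain == chain, , drop = FALSE]
  idx <- vapply(resno, function(r) {
    hit <- which(at$resno == r & at$elety == elety)
    if (!length(hit)) stop("anchor atom ", elety, " of residue ", r,
                           " absent from ", model$source, call. = FALSE)
    hit[1]
  }, integer(1))
  as.matrix(at[idx, c("x", "y", "z")])
}

#' Least-squares rigid-body superposition (Kabsch fit)
#'
#' Closed-form optimal rotation/translation of `mobile` anchor atoms onto
#' `reference` anchor atoms, with a proper rotation (det +1) enforced through
#' the sign-corrected singular value decomposition; reflections are never
#' returned. The RMSD is computed over the anchor atoms after applying the
#' transform.
#'
#' @param mobile,reference `structure_model`s, or bare n x 3 coordinate
#'   matrices.
#' @param anchors for structure models, a two-column matrix or data frame of
#'   residue-number pairs `(mobile_resno, reference_resno)`; ignored for bare
#'   coordinate matrices (rows pair up directly).
#' @param elety anchor atom name (default `"CA"`).
#' @return a `superposition_result`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom over anchors), `n_anchors`.
#'   The fitted mobile coordinates are `x' = x R^T + t` for row vectors `x`.
#' @export
superpose <- function(mobile, reference, anchors = NULL, elety = "CA") {
  if (inherits(mobile, "structure_model")) {
    if (is.null(anchors)) stop("anchor residue pairs required", call. = FALSE)
    anchors <- as.matrix(anchors)
    X <- anchor_coordinates(mobile, anchors[, 1], elety = elety)
    Y <- anchor_coordinates(reference, anchors[, 2], elety = elety)
  } else {
    X <- as.matrix(mobile); Y <- as.matrix(reference)
  }
  if (nrow(X) != nrow(Y)) stop("anchor sets differ in size", call. = FALSE)
  n <- nrow(X)
  if (n < 3L) stop("at least 3 anchor pairs required, got ", n,
                   call. = FALSE)
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  sv <- svd(Xc)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1)) {
    stop("anchor atoms are collinear; superposition is ill-defined",
         call. = FALSE)
  }
  C <- crossprod(Xc, Yc)            # 3x3 covariance
  s <- svd(C)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- as.numeric(cy - R %*% cx)
  fitted <- Xc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Yc)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd,
                 n_anchors = n),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition_result> %d anchors, rmsd %.4f A\n",
              x$n_anchors, x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to coordinates or a structure model
#'
#' @param x a `structure_model` or an n x 3 coordinate matrix.
#' @param transform a `superposition_result`, or a list with `rotation` and
#'   `translation`.
#' @return object of the same type with transformed coordinates.
#' @export
apply_transform <- function(x, transform) {
  R <- transform$rotation; tv <- transform$translation
  if (inherits(x, "structure_model")) {
    xyz <- as.matrix(x$atoms[, c("x", "y", "z")])
    new <- sweep(xyz %*% t(R), 2, tv, `+`)
    x$atoms$x <- new[, 1]; x$atoms$y <- new[, 2]; x$atoms$z <- new[, 3]
    return(x)
  }
  sweep(as.matrix(x) %*% t(R), 2, tv, `+`)
}
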