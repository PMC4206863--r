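template <- scr_template()
anchors <- attr(template, "anchors")
anchor_pairs <- cbind(anchors, anchors)

test_that("structure models round-trip through PDB format", {
  tmp <- tempfile(fileext = ".pdb")
  write_coordinates(template, tmp)
  back <- read_coordinates(tmp)
  expect_identical(nrow(back$atoms), nrow(template$atoms))
  expect_identical(back$atoms$resno, template$atoms$resno)
  expect_identical(back$atoms$resid, template$atoms$resid)
  expect_identical(back$atoms$elety, template$atoms$elety)
  expect_equal(back$atoms$x, template$atoms$x, tolerance = 1e-3)
  expect_equal(back$atoms$y, template$atoms$y, tolerance = 1e-3)
  expect_equal(back$atoms$z, template$atoms$z, tolerance = 1e-3)
})

test_that("B-factor export writes per-residue values", {
  tmp <- tempfile(fileext = ".pdb")
  counts <- c(`1` = 3, `26` = 1)
  write_coordinates(template, tmp, residue_values = counts)
  back <- read_coordinates(tmp)
  expect_true(all(back$atoms$b[back$atoms$resno == 1] == 3))
  expect_true(all(back$atoms$b[back$atoms$resno == 26] == 1))
  expect_true(all(back$atoms$b[back$atoms$resno == 2] == 0))
})

test_that("truncated and corrupt records are format errors with line numbers", {
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A   1      11.104"), tmp)
  expect_error(read_coordinates(tmp), "line 1")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.104   6.134   2.100  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2      abc.def   6.134   2.100  1.00  0.00           C"),
    tmp)
  expect_error(read_coordinates(tmp), "line 2")
  expect_error(read_coordinates(tempfile()), "not found")
})

test_that("self-superposition is the identity with zero rmsd", {
  sp <- superpose(template, template, anchors = anchor_pairs)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-10)
  expect_equal(sp$translation, c(0, 0, 0), tolerance = 1e-10)
})

test_that("known rigid transforms are recovered exactly", {
  set.seed(5)
  for (k in 1:5) {
    R <- random_rotation(); tv <- runif(3, -30, 30)
    decoy <- apply_transform(template, list(rotation = R, translation = tv))
    sp <- superpose(decoy, template, anchors = anchor_pairs)
    expect_lt(sp$rmsd, 1e-6)
    # recovered transform is the inverse of the applied one
    expect_equal(sp$rotation %*% R, diag(3), tolerance = 1e-6)
    expect_equal(as.numeric(sp$rotation %*% tv + sp$translation), c(0, 0, 0),
                 tolerance = 1e-6)
    # rotation is orthonormal and proper
    expect_equal(crossprod(sp$rotation), diag(3), tolerance = 1e-8)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
  }
})

test_that("mirrored coordinates still yield a proper rotation", {
  mirrored <- template
  mirrored$atoms$x <- -mirrored$atoms$x
  sp <- superpose(mirrored, template, anchors = anchor_pairs)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
  expect_gt(sp$rmsd, 0.1)  # a reflection cannot be absorbed
})

test_that("rmsd is invariant under a common rigid transform", {
  set.seed(9)
  decoys <- gen_scr_decoys(template, n_decoys = 1, sigma = 0.4, seed = 3)
  mob <- decoys$decoys[[1]]
  sp0 <- superpose(mob, template, anchors = anchor_pairs)
  common <- list(rotation = random_rotation(), translation = c(5, -3, 12))
  sp1 <- superpose(apply_transform(mob, common),
                   apply_transform(template, common), anchors = anchor_pairs)
  expect_equal(sp1$rmsd, sp0$rmsd, tolerance = 1e-9)
})

test_that("superposition is idempotent after fitting", {
  decoys <- gen_scr_decoys(template, n_decoys = 1, sigma = 0, seed = 8)
  fitted <- apply_transform(decoys$decoys[[1]],
                            superpose(decoys$decoys[[1]], template,
                                      anchors = anchor_pairs))
  sp <- superpose(fitted, template, anchors = anchor_pairs)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-6)
  expect_lt(sp$rmsd, 1e-6)
})

test_that("degenerate anchor sets raise geometry errors", {
  expect_error(superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("noisy decoys give anchor rmsd near the degrees-of-freedom value", {
  sigma <- 0.3
  n_anchor <- length(anchors)
  rmsds <- vapply(1:100, function(s) {
    d <- gen_scr_decoys(template, n_decoys = 1, sigma = sigma, seed = s)
    superpose(d$decoys[[1]], template, anchors = anchor_pairs)$rmsd
  }, numeric(1))
  expect_true(all(rmsds > 0.05 & rmsds < 0.9))
  expect_gt(mean(rmsds), 0.2)
  expect_lt(mean(rmsds), 0.5)
  # E[rmsd^2] ~= sigma^2 (3 - 6/N): fitting removes six rigid degrees of freedom
  theory <- sigma * sqrt(3 - 6 / n_anchor)
  expect_lt(abs(mean(rmsds) - theory) / theory, 0.2)
})

test_that("superposition agrees with an independent least-squares fit", {
  set.seed(31)
  d <- gen_scr_decoys(template, n_decoys = 1, sigma = 0.5, seed = 17)
  mob <- d$decoys[[1]]
  X <- anchor_coordinates(mob, anchors)
  Y <- anchor_coordinates(template, anchors)
  sp <- superpose(X, Y)
  fitted <- apply_transform(X, sp)
  # oracle: bio3d's least-squares rotation on the same centred point sets
  ref_fit <- bio3d::rot.lsq(xx = as.numeric(t(X)), yy = as.numeric(t(Y)))
  ref_rmsd <- sqrt(mean(rowSums(
    (matrix(ref_fit, ncol = 3, byrow = TRUE) - Y)^2)))
  expect_equal(sp$rmsd, ref_rmsd, tolerance = 1e-6)
  expect_equal(fitted, matrix(ref_fit, ncol = 3, byrow = TRUE),
               tolerance = 1e-6, ignore_attr = TRUE)
})
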