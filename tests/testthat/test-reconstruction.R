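test_that("stacked system has the block and substitution structure", {
  sp <- brain_tissue_spectra()
  set.seed(12)
  K <- 10; N <- 4
  jacs <- lapply(1:3, function(i) matrix(rnorm(K * N), K, N))
  st <- assemble_stacked(jacs, sp)
  expect_equal(dim(st$S), c(3 * K, 2 * N))
  expect_equal(dim(st$S_reduced), c(3 * K, N))
  # block i equals J_i %*% A_i computed via the sparse coefficient matrix
  for (i in 1:3) {
    A <- as.matrix(coefficient_matrix(sp, i, N))
    expect_equal(st$blocks[[i]], jacs[[i]] %*% A)
  }
  # reduced column n = tissue-2 column minus tissue-1 column (contrast)
  for (n in 1:N) {
    expect_equal(st$S_reduced[, n], st$S[, 2 * n] - st$S[, 2 * n - 1])
  }
  # single-frequency degenerate case
  sp1 <- tissue_spectra(sp$values[, 1, drop = FALSE])
  st1 <- assemble_stacked(jacs[1], sp1)
  expect_equal(nrow(st1$S), K)
  expect_error(assemble_stacked(jacs[1:2], sp), "match")
})

test_that("identical blocks do not raise the stacked rank", {
  set.seed(21)
  J <- matrix(rnorm(12 * 6), 12, 6)
  flat <- tissue_spectra(rbind(a = rep(0.2, 3), b = rep(0.1, 3)))
  st <- assemble_stacked(list(J, J, J), flat)
  expect_equal(matrix_diagnostics(st$S)$rank, matrix_diagnostics(J)$rank)
})

test_that("matrix diagnostics report SVD rank and condition number", {
  d <- matrix_diagnostics(diag(5))
  expect_equal(d$rank, 5)
  expect_equal(d$condition_number, 1)
  set.seed(8)
  J <- matrix(rnorm(40), 8, 5)
  expect_equal(matrix_diagnostics(rbind(J, J))$rank,
               matrix_diagnostics(J)$rank)
  # known-rank product, cross-checked against QR rank
  L <- matrix(rnorm(40), 10, 4); Rm <- matrix(rnorm(24), 4, 6)
  M <- L %*% Rm
  expect_equal(matrix_diagnostics(M)$rank, 4)
  expect_equal(matrix_diagnostics(M)$rank, qr(M)$rank)
  expect_warning(z <- matrix_diagnostics(matrix(0, 3, 3)), "all-zero")
  expect_equal(z$rank, 0)
})

test_that("tikhonov solve matches closed forms and the lstsq limit", {
  # identity system: (I + I)^-1 rhs
  expect_equal(tikhonov_solve(diag(2), c(1, 0), 1, R = c(1, 1)), c(0.5, 0))
  set.seed(14)
  S <- matrix(rnorm(20 * 6), 20, 6)
  x0 <- rnorm(6)
  rhs <- drop(S %*% x0)
  xl <- tikhonov_solve(S, rhs, 1e-12 * sum(diag(crossprod(S))) / 6)
  expect_lt(sqrt(sum((xl - x0)^2)) / sqrt(sum(x0^2)), 1e-6)
  # direct least-squares oracle
  expect_equal(xl, drop(qr.solve(S, rhs)), tolerance = 1e-6)
  # huge lambda drives the solution to zero
  expect_lt(sum(tikhonov_solve(S, rhs, 1e12)^2), 1e-12)
  # the internal SVD path agrees with the normal-equations definition
  fac <- sceit:::tikhonov_factor(S)
  for (l in c(1e-4, 1e-1, 1)) {
    expect_equal(sceit:::tikhonov_apply(fac, rhs, l),
                 tikhonov_solve(S, rhs, l), tolerance = 1e-9)
  }
})

test_that("L-curve norms are monotone and the corner is near-optimal", {
  pr <- shaw_problem(32)
  b <- pr$b + withr::with_seed(3, stats::rnorm(32, 0, 0.01 * sqrt(mean(pr$b^2))))
  grid <- lambda_grid_default(40, -12, 2)
  fac <- sceit:::tikhonov_factor(pr$A)
  nm <- sceit:::lcurve_norms(fac, b, grid)
  expect_true(all(diff(nm$residual) >= -1e-12))
  expect_true(all(diff(nm$seminorm) <= 1e-12))
  lam <- select_lambda_lcurve(pr$A, b, grid)
  expect_identical(lam, select_lambda_lcurve(pr$A, b, grid))  # deterministic
  expect_gt(lam, min(grid)); expect_lt(lam, max(grid))
  # oracle: exhaustive scan of the true reconstruction error
  err <- vapply(grid, function(l)
    sqrt(sum((tikhonov_solve(pr$A, b, l) - pr$x)^2)), numeric(1))
  lbest <- grid[which.min(err)]
  expect_lt(abs(log10(lam / lbest)), 1)
  expect_warning(mid <- select_lambda_lcurve(pr$A, rep(0, 32), grid),
                 "all-zero")
  expect_equal(mid, grid[20])
})

test_that("DLS returns zero image for zero data and localises a target", {
  inv <- fix_inverse_mesh()
  p <- fix_protocol()
  z <- dls_reconstruct(rep(0, 192), inv, p, 0.155, num_steps = 1, lambda = 0.01)
  expect_equal(drop(z$delta_sigma), rep(0, 512))
  sf <- fix_scene_frames(position = 3, snr = 80, seed = 11)
  dv <- sf$frames$fg[, 2] - sf$frames$bg[, 2]
  rec <- dls_reconstruct(dv, inv, p, 0.155, num_steps = 1)
  tgt <- eit_target(sf$scene$target$center, sf$scene$target$semi_axes)
  met <- compute_metrics(drop(rec$delta_sigma), inv, tgt)
  expect_lt(met$pe, 0.1)
  # the target is less conductive: reconstructed change is negative there
  expect_lt(mean(drop(rec$delta_sigma)[target_elements(inv, tgt)]), 0)
})

test_that("SC refuses an underdetermined stacking", {
  inv <- fix_inverse_mesh()
  p <- fix_protocol()
  sp3 <- three_tissue_spectra()  # (T-1)*N = 1024 > M*K = 576
  bg <- matrix(1, 192, 3)
  expect_error(sc_reconstruct(bg, bg, sp3, inv, p), "underdetermined")
})

test_that("SC on identical frames returns a null fraction change", {
  inv <- fix_inverse_mesh()
  p <- fix_protocol()
  sp <- brain_tissue_spectra()
  sf <- fix_scene_frames()
  bg <- sf$frames$bg_clean
  expect_warning(
    rec <- sc_reconstruct(bg, bg, sp, inv, p, num_steps = 1),
    "all-zero")
  expect_equal(max(abs(rec$delta_F)), 0)
  expect_equal(max(abs(rec$delta_sigma)), 0)
})

test_that("SC output respects the fraction constraints at every iteration", {
  inv <- fix_inverse_mesh()
  sf <- fix_scene_frames(position = 1, snr = 60, seed = 5)
  rec <- sc_reconstruct(sf$frames$bg, sf$frames$fg, sf$scene$spectra, inv,
                        sf$scene$protocol, num_steps = 2)
  for (it in rec$iterations) {
    expect_true(all(it$F >= 0 & it$F <= 1))
    expect_equal(colSums(it$F), rep(1, 512))
    # conductivity stays inside the tissue-spectra span at each frequency
    for (i in 1:3) {
      s <- fractions_to_conductivity(it$F, sf$scene$spectra, i)
      expect_true(all(s >= min(sf$scene$spectra$values[, i]) - 1e-12))
      expect_true(all(s <= max(sf$scene$spectra$values[, i]) + 1e-12))
    }
    # the per-frequency image is exactly A(w_i) vec(delta F)
    A2 <- coefficient_matrix(sf$scene$spectra, 2, 512)
    expect_equal(it$delta_sigma[, 2],
                 drop(as.matrix(A2 %*% as.vector(it$delta_F))))
  }
})

test_that("with flat spectra SC step one matches DLS up to clamping", {
  # identical tissue contrast at all frequencies and noiseless data:
  # the stacked system is proportional to the single-frequency system,
  # so the unclamped SC image equals the DLS image up to the fraction
  # scaling (eps2 - eps1)
  inv <- fix_inverse_mesh()
  p <- fix_protocol()
  flat <- tissue_spectra(rbind(bgt = rep(0.155, 3), tgt = rep(0.120, 3)))
  scene <- make_two_tissue_scene(2, spectra = flat,
                                 forward_mesh = fix_forward_mesh(),
                                 protocol = p)
  fr <- simulate_scene_frames(scene, Inf, 1)
  lam <- 0.01
  sc <- sc_reconstruct(fr$bg, fr$fg, flat, inv, p, num_steps = 1, lambda = lam)
  dv <- rowMeans(fr$fg - fr$bg)
  J <- compute_jacobian(inv, rep(0.155, 512), p)
  dls_img <- tikhonov_solve(J, dv, lam)
  sc_f2 <- sc$iterations[[1]]$delta_F[2, ]
  # compare on elements the clamp left untouched (positive updates)
  free <- sc_f2 > 1e-6
  expect_gt(sum(free), 50)
  ratio <- dls_img[free] / sc_f2[free]
  expect_equal(ratio, rep(0.120 - 0.155, sum(free)), tolerance = 1e-6)
})
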