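test_that("two-tissue scenes place binary targets at the study offsets", {
  fwd <- fix_forward_mesh()
  p <- fix_protocol()
  offs <- c(0, 60, 120, 180, 240)
  for (pos in 0:4) {
    sc <- make_two_tissue_scene(pos, forward_mesh = fwd, protocol = p)
    expect_equal(sc$target$center, c(offs[pos + 1], 0))
    F <- sc$true_fractions
    expect_true(all(F %in% c(0, 1)))
    expect_equal(colSums(F), rep(1, 800))
    expect_gt(length(target_elements(fwd, sc$target)), 0)
  }
  # a target poking out of the disk is rejected
  expect_error(make_two_tissue_scene(4, semi_axes = c(70, 30),
                                     forward_mesh = fwd, protocol = p),
               "protrudes")
})

test_that("three-tissue scene carries a flat blood spectrum and no overlap", {
  sc <- make_three_tissue_scene(forward_mesh = fix_forward_mesh(),
                                protocol = fix_protocol())
  expect_equal(unname(sc$spectra$values["blood", ]), rep(0.7, 3))
  lbl <- apply(sc$true_fractions, 2, which.max)
  expect_setequal(unique(lbl), 1:3)
  expect_error(
    make_three_tissue_scene(blood_center = c(60, 0),
                            ischemia_center = c(-20, 0),
                            forward_mesh = fix_forward_mesh(),
                            protocol = fix_protocol()),
    "overlap")
})

test_that("scene frames are reproducible and noise-scaled", {
  sf <- fix_scene_frames()
  again <- simulate_scene_frames(sf$scene, 80, 11)
  expect_identical(sf$frames$fg, again$fg)
  expect_identical(sf$frames$bg, again$bg)
  expect_equal(dim(sf$frames$bg), c(192, 3))
  # background and foreground noise streams differ
  expect_false(identical(sf$frames$bg - sf$frames$bg_clean,
                         sf$frames$fg - sf$frames$fg_clean))
  nf <- simulate_scene_frames(sf$scene, Inf, 11)
  expect_identical(nf$bg, nf$bg_clean)
})

test_that("spectra perturbation matches its stated spread and determinism", {
  sp <- brain_tissue_spectra()
  expect_identical(perturb_spectra(sp, 0, 1), sp)
  p1 <- perturb_spectra(sp, 0.05, 3)
  expect_identical(p1$values, perturb_spectra(sp, 0.05, 3)$values)
  expect_false(identical(p1$values, perturb_spectra(sp, 0.05, 4)$values))
  expect_true(all(p1$values > 0))
  # Monte-Carlo recomputation of the relative spread
  rels <- vapply(1:2000, function(s) {
    pe <- perturb_spectra(sp, 0.05, s)
    (pe$values[1, 1] - sp$values[1, 1]) / sp$values[1, 1]
  }, numeric(1))
  expect_equal(stats::sd(rels), 0.05, tolerance = 0.05)
  expect_lt(abs(mean(rels)), 0.005)
})

test_that("three-tissue reconstruction isolates the blood target channel", {
  sc <- make_three_tissue_scene(forward_mesh = fix_forward_mesh(),
                                protocol = fix_protocol())
  fr <- simulate_scene_frames(sc, 80, 21)
  # (T-1)*N = 2*288 = 576 = M*K: solvable on a 288-element inverse mesh
  inv <- build_circular_mesh(300, 16, 288)
  rec <- sc_reconstruct(fr$bg, fr$fg, sc$spectra, inv, sc$protocol,
                        num_steps = 2)
  blood_tgt <- eit_target(c(120, 0), c(45, 30))
  isch_tgt <- eit_target(c(-120, 0), c(45, 30))
  blood_img <- rec$delta_F[3, ]
  isch_img <- rec$delta_F[2, ]
  # each tissue channel peaks inside its own target
  expect_gt(mean(blood_img[target_elements(inv, blood_tgt)]),
            5 * mean(blood_img[target_elements(inv, isch_tgt)]))
  rp_blood <- region_of_perturbation(blood_img, inv)
  cen <- colSums(element_centroids(inv)[rp_blood, , drop = FALSE] *
                   element_areas(inv)[rp_blood]) / sum(element_areas(inv)[rp_blood])
  expect_lt(sqrt(sum((cen - c(120, 0))^2)), 60)
  met_isch <- compute_metrics(isch_img, inv, isch_tgt)
  expect_lt(met_isch$pe, 0.15)
})

test_that("experiment drivers enforce the inverse-crime guard", {
  expect_error(run_numerical_validation(n_seeds = 1, targets = 0,
                                        snr_levels = 80,
                                        forward_elements = 512,
                                        inverse_elements = 512),
               "inverse crime")
})

test_that("a small validation run has the full factorial structure", {
  rep_small <- run_numerical_validation(base_seed = 5, n_seeds = 1,
                                        targets = c(0, 3), snr_levels = 80,
                                        num_steps = 2)
  tb <- rep_small$table
  expect_equal(nrow(tb), 2 * 1 * 2 * 2)  # targets x snr x algorithms x steps
  expect_setequal(tb$algorithm, c("dls", "sc"))
  expect_equal(nrow(rep_small$reductions), 2)
  # bit-reproducible with the same seeds
  rep_again <- run_numerical_validation(base_seed = 5, n_seeds = 1,
                                        targets = c(0, 3), snr_levels = 80,
                                        num_steps = 2)
  expect_identical(rep_small$table, rep_again$table)
})
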