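# small fixed mesh for metric arithmetic (16 elements, radius 10)
toy_mesh <- function() build_circular_mesh(10, 4, 16)

test_that("region of perturbation keeps the largest connected cluster", {
  m <- toy_mesh()
  img <- rep(0, 16)
  img[5] <- 1
  expect_equal(region_of_perturbation(img, m), 5)
  expect_warning(rp <- region_of_perturbation(rep(2, 16), m), "constant")
  expect_length(rp, 0)
  # two clusters above threshold: sizes 3 and 1 -> the 3-cluster wins
  adj <- sceit:::element_edge_adjacency(m)
  trio <- as.integer(unname(c(5, adj[adj[, 1] == 5, 2],
                              adj[adj[, 2] == 5, 1])))[1:3]
  img2 <- rep(0, 16)
  img2[trio] <- 1
  far <- setdiff(1:16, c(trio, as.vector(adj[adj[, 1] %in% trio | adj[, 2] %in% trio, ])))
  img2[far[1]] <- 0.9
  expect_equal(region_of_perturbation(img2, m), sort(trio))
})

test_that("a supra-threshold ring is returned whole, matching flood fill", {
  m <- build_circular_mesh(10, 4, 36)  # 3 rings
  ctr <- element_centroids(m)
  rad <- sqrt(rowSums(ctr^2))
  ring <- which(rad > m$radius / 3 & rad < 2 * m$radius / 3)
  img <- rep(0, nrow(m$elements))
  img[ring] <- 1
  rp <- region_of_perturbation(img, m)
  expect_equal(rp, sort(ring))
  # oracle agreement
  cl <- flood_clusters(m, ring)
  expect_length(cl, 1)
  expect_equal(rp, cl[[1]])
})

test_that("RP is invariant to constant offsets and positive scaling", {
  m <- toy_mesh()
  set.seed(6)
  img <- rnorm(16)
  rp <- region_of_perturbation(img, m)
  expect_equal(region_of_perturbation(img + 5, m), rp)
  expect_equal(region_of_perturbation(3 * img, m), rp)
})

test_that("metrics match independent arithmetic on the toy mesh", {
  m <- toy_mesh()
  # target: small ellipse around the centroid of element 7
  ctr <- element_centroids(m)
  tgt <- eit_target(ctr[7, ], c(1.2, 0.9))
  tgt_el <- which((ctr[, 1] - tgt$center[1])^2 / 1.2^2 +
                  (ctr[, 2] - tgt$center[2])^2 / 0.9^2 <= 1)
  img <- rep(0.02, 16)
  img[7] <- 1
  met <- compute_metrics(img, m, tgt)
  expect_equal(met$rp_elements, 7)
  # PE by hand: RP centroid is element 7's centroid (single element)
  d_rp <- sqrt(sum(ctr[7, ]^2))
  d_real <- sqrt(sum(tgt$center^2))
  expect_equal(met$pe, abs(d_rp - d_real) / 20)
  expect_equal(met$pe, 0)
  # SD by hand from the element-7 vertex bounding box
  vx <- m$nodes[m$elements[7, ], 1]
  vy <- m$nodes[m$elements[7, ], 2]
  sd_hand <- 0.5 * ((abs(diff(range(vx)) - 2.4) + abs(diff(range(vy)) - 1.8)) / 20)
  expect_equal(met$sd, sd_hand)
  # IN by hand: sd over background / |mean(target) - mean(background)|
  bg <- setdiff(1:16, tgt_el)
  in_hand <- stats::sd(img[bg]) / abs(mean(img[tgt_el]) - mean(img[bg]))
  expect_equal(met$in_, in_hand)
  expect_equal(met$te, met$pe + met$sd + met$in_)
})

test_that("metrics are invariant to image offset and positive scaling", {
  inv <- fix_inverse_mesh()
  tgt <- eit_target(c(120, 0), c(45, 30))
  set.seed(17)
  img <- rnorm(512, 0, 0.01)
  img[target_elements(inv, tgt)] <- img[target_elements(inv, tgt)] - 0.05
  m0 <- compute_metrics(img, inv, tgt)
  m_off <- compute_metrics(img + 0.3, inv, tgt)
  m_sc <- compute_metrics(4 * img, inv, tgt)
  for (f in c("pe", "sd", "in_", "te")) {
    expect_equal(m_off[[f]], m0[[f]])
    expect_equal(m_sc[[f]], m0[[f]])
  }
  expect_true(m0$pe >= 0 && m0$sd >= 0 && m0$in_ >= 0)
})

test_that("perfect reconstruction scores zero position and shape error", {
  inv <- fix_inverse_mesh()
  tgt <- eit_target(c(120, 0), c(45, 30))
  tel <- target_elements(inv, tgt)
  img <- rep(0, 512)
  img[tel] <- -0.035
  met <- compute_metrics(img, inv, tgt)
  expect_equal(sort(met$rp_elements), sort(tel))
  expect_lt(met$pe, 0.01)   # centroid shift only from mesh discretisation
  expect_lt(met$sd, 0.04)   # bounding box vs ellipse discretisation
  expect_equal(met$in_, 0)  # noiseless background
})

test_that("mean relative contrast reproduces the closed formula", {
  sp <- brain_tissue_spectra()
  # independent arithmetic from the table values
  by_hand <- 100 * abs(mean(c((0.115 - 0.151) / 0.151,
                              (0.120 - 0.155) / 0.155,
                              (0.130 - 0.175) / 0.175)))
  expect_equal(mean_relative_contrast(sp), by_hand)
  expect_equal(round(mean_relative_contrast(sp), 2), 24.05)
  same <- tissue_spectra(rbind(a = c(0.1, 0.2), b = c(0.1, 0.2)))
  expect_equal(mean_relative_contrast(same), 0)
  one <- tissue_spectra(rbind(a = 0.1, b = 0.12))
  expect_equal(mean_relative_contrast(one), 20)
})
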