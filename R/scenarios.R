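#' Build a two-tissue phantom scene
#'
#' A homogeneous disk of tissue 1 with one elliptical inclusion of tissue 2,
#' placed at one of five radial positions (0, 60, 120, 180, 240 pixels from
#' the centre) along a configurable direction (default +x, midway between
#' two electrodes). The fraction field on the forward mesh is binary:
#' elements whose centroid falls inside the ellipse are pure tissue 2.
#'
#' @param position_index Target position 0..4 (radial offsets 0, 60, 120,
#'   180, 240 px).
#' @param spectra A \code{tissue_spectra} (default the two-tissue brain
#'   spectra).
#' @param semi_axes Ellipse semi-axes (x, y) in pixels.
#' @param angle_deg Direction of the radial offset, degrees from +x.
#' @param forward_mesh Optional prebuilt forward \code{eit_mesh} (default
#'   the 800-element disk of radius 300).
#' @param protocol Optional \code{eit_protocol} (default 16-electrode
#'   opposite/adjacent at 1 mA).
#' @return Object of class \code{eit_scene}: forward mesh, protocol,
#'   spectra, target, true fraction field, position index.
#' @export
make_two_tissue_scene <- function(position_index, spectra = brain_tissue_spectra(),
                                  semi_axes = c(45, 30), angle_deg = 0,
                                  forward_mesh = NULL, protocol = NULL) {
  stopifnot(position_index %in% 0:4)
  offsets <- c(0, 60, 120, 180, 240)
  if (is.null(forward_mesh)) forward_mesh <- build_circular_mesh(300, 16, 800)
  if (is.null(protocol)) protocol <- eit_protocol()
  th <- angle_deg * pi / 180
  ctr <- offsets[position_index + 1] * c(cos(th), sin(th))
  if (sqrt(sum(ctr^2)) + max(semi_axes) > forward_mesh$radius) {
    stop("target protrudes beyond the mesh boundary")
  }
  target <- eit_target(ctr, semi_axes, tissue = 2L)
  scene_from_targets(forward_mesh, protocol, spectra, list(target),
                     position_index = position_index)
}

#' Build a three-tissue phantom scene
#'
#' Normal-tissue background with two non-overlapping elliptical targets:
#' a blood inclusion (flat 0.7 S/m spectrum) and an ischaemic inclusion.
#'
#' @param spectra Three-tissue \code{tissue_spectra} (tissue 3 = blood).
#' @param blood_center,ischemia_center Target centres (pixels).
#' @param semi_axes Shared ellipse semi-axes.
#' @inheritParams make_two_tissue_scene
#' @return An \code{eit_scene} with two targets.
#' @export
make_three_tissue_scene <- function(spectra = three_tissue_spectra(),
                                    blood_center = c(120, 0),
                                    ischemia_center = c(-120, 0),
                                    semi_axes = c(45, 30),
                                    forward_mesh = NULL, protocol = NULL) {
  stopifnot(spectra$n_tissues == 3)
  if (is.null(forward_mesh)) forward_mesh <- build_circular_mesh(300, 16, 800)
  if (is.null(protocol)) protocol <- eit_protocol()
  t_blood <- eit_target(blood_center, semi_axes, tissue = 3L)
  t_isch <- eit_target(ischemia_center, semi_axes, tissue = 2L)
  # overlap guard on the forward mesh
  if (length(intersect(target_elements(forward_mesh, t_blood),
                       target_elements(forward_mesh, t_isch)))) {
    stop("targets overlap")
  }
  for (t in list(t_blood, t_isch)) {
    if (sqrt(sum(t$center^2)) + max(t$semi_axes) > forward_mesh$radius) {
      stop("target protrudes beyond the mesh boundary")
    }
  }
  scene_from_targets(forward_mesh, protocol, spectra, list(t_isch, t_blood))
}

scene_from_targets <- function(forward_mesh, protocol, spectra, targets,
                               position_index = NA_integer_) {
  N <- nrow(forward_mesh$elements)
  F_true <- matrix(0, spectra$n_tissues, N)
  F_true[1, ] <- 1
  for (t in targets) {
    idx <- target_elements(forward_mesh, t)
    F_true[, idx] <- 0
    F_true[t$tissue, idx] <- 1
  }
  structure(list(forward_mesh = forward_mesh, protocol = protocol,
                 spectra = spectra, targets = targets,
                 target = targets[[1]], true_fractions = F_true,
                 position_index = position_index),
            class = "eit_scene")
}

#' @export
print.eit_scene <- function(x, ...) {
  cat("EIT scene: ", x$spectra$n_tissues, " tissues, ",
      length(x$targets), " target(s), forward mesh of ",
      nrow(x$forward_mesh$elements), " elements\n", sep = "")
  invisible(x)
}

#' Simulate background and foreground voltage frames for a scene
#'
#' Solves the forward problem on the scene's forward mesh at every
#' frequency, for the homogeneous background (pure tissue 1) and for the
#' true fraction field, then adds independent Gaussian noise to each frame
#' at the requested SNR. Noise seeds are derived from the base seed, the
#' frame role (background 1 / foreground 2) and the frequency index, so a
#' study can reproduce any single frame.
#'
#' @param scene An \code{eit_scene}.
#' @param snr_db Per-frame SNR in dB (\code{Inf} for noiseless data).
#' @param base_seed Integer base seed.
#' @return List with K x M matrices \code{bg} and \code{fg} and the
#'   noiseless versions \code{bg_clean}, \code{fg_clean}.
#' @export
simulate_scene_frames <- function(scene, snr_db, base_seed) {
  M <- scene$spectra$n_frequencies
  K <- nrow(scene$protocol$measurements)
  N <- nrow(scene$forward_mesh$elements)
  bgc <- matrix(0, K, M); fgc <- matrix(0, K, M)
  F_bg <- matrix(0, scene$spectra$n_tissues, N); F_bg[1, ] <- 1
  for (i in seq_len(M)) {
    sig_bg <- fractions_to_conductivity(F_bg, scene$spectra, i, validate = FALSE)
    sig_fg <- fractions_to_conductivity(scene$true_fractions, scene$spectra, i,
                                        validate = FALSE)
    bgc[, i] <- solve_forward(scene$forward_mesh, sig_bg, scene$protocol)
    fgc[, i] <- solve_forward(scene$forward_mesh, sig_fg, scene$protocol)
  }
  bg <- bgc; fg <- fgc
  for (i in seq_len(M)) {
    bg[, i] <- add_gaussian_noise(bgc[, i], snr_db, derive_seed(base_seed, 1, i))
    fg[, i] <- add_gaussian_noise(fgc[, i], snr_db, derive_seed(base_seed, 2, i))
  }
  list(bg = bg, fg = fg, bg_clean = bgc, fg_clean = fgc)
}

#' Randomly perturb tissue conductivity spectra
#'
#' Adds independent zero-mean Gaussian errors with standard deviation
#' \code{level * value} to every spectra entry, redrawing any entry that
#' would become nonpositive (bounded retries). Used on the reconstruction
#' side only, to study robustness to spectral errors.
#'
#' @param spectra A \code{tissue_spectra}.
#' @param level Relative error level (e.g. 0.05 for 5\%).
#' @param seed Integer seed.
#' @param max_retries Redraw attempts per entry before failing.
#' @return A perturbed \code{tissue_spectra}.
#' @export
perturb_spectra <- function(spectra, level, seed, max_retries = 100) {
  stopifnot(level >= 0)
  if (level == 0) return(spectra)
  v <- spectra$values
  out <- withr::with_seed(as.integer(seed), {
    w <- v
    for (idx in seq_along(v)) {
      for (try in seq_len(max_retries)) {
        cand <- v[idx] + stats::rnorm(1, 0, v[idx] * level)
        if (cand > 0) break
        cand <- NA_real_
      }
      if (is.na(cand)) stop("could not draw a positive perturbed conductivity")
      w[idx] <- cand
    }
    w
  })
  tissue_spectra(out, spectra$tissue_names, spectra$frequencies)
}

#' Run the full numerical-validation study
#'
#' Reproduces the synthetic comparison of the spectral-constraints (SC) and
#' damped-least-squares (DLS) reconstructions: five elliptical targets, two
#' SNR levels, data simulated on the forward mesh and reconstructed on a
#' distinct inverse mesh (inverse-crime guard), both algorithms at one and
#' two iteration steps, all images scored with PE/SD/IN/TE on the
#' middle-frequency conductivity-change image.
#'
#' @param base_seed Integer base seed for all noise draws.
#' @param n_seeds Noise realisations per target/SNR cell.
#' @param targets Target position indices (subset of 0:4).
#' @param snr_levels SNR levels in dB.
#' @param num_steps Maximum iteration steps (metrics are recorded at every
#'   step).
#' @param spectra Two-tissue \code{tissue_spectra}.
#' @param semi_axes Target ellipse semi-axes.
#' @param forward_elements,inverse_elements Element-count targets of the
#'   two meshes.
#' @return Object of class \code{eit_report}: \code{$table} (one row per
#'   scene x algorithm x step with metrics and matrix diagnostics),
#'   \code{$reductions} (percent reduction of each averaged metric, SC
#'   relative to DLS, per step), and \code{$config}.
#' @export
run_numerical_validation <- function(base_seed = 1, n_seeds = 5,
                                     targets = 0:4, snr_levels = c(60, 80),
                                     num_steps = 2,
                                     spectra = brain_tissue_spectra(),
                                     semi_axes = c(45, 30),
                                     forward_elements = 800,
                                     inverse_elements = 512) {
  fwd <- build_circular_mesh(300, 16, forward_elements)
  inv <- build_circular_mesh(300, 16, inverse_elements)
  if (nrow(fwd$elements) == nrow(inv$elements)) {
    stop("forward and inverse meshes must differ (inverse crime)")
  }
  protocol <- eit_protocol()
  rows <- list()
  for (tpos in targets) {
    scene <- make_two_tissue_scene(tpos, spectra, semi_axes,
                                   forward_mesh = fwd, protocol = protocol)
    tgt_inv <- eit_target(scene$target$center, scene$target$semi_axes)
    for (snr in snr_levels) {
      for (rep_i in seq_len(n_seeds)) {
        seed <- derive_seed(base_seed, tpos, round(snr), rep_i)
        fr <- simulate_scene_frames(scene, snr, seed)
        mid <- ceiling(spectra$n_frequencies / 2)
        sigma_ref <- spectra$values[1, mid]
        dls <- dls_reconstruct(fr$fg[, mid] - fr$bg[, mid], inv, protocol,
                               sigma_ref, num_steps = num_steps)
        sc <- sc_reconstruct(fr$bg, fr$fg, spectra, inv, protocol,
                             num_steps = num_steps)
        for (step in seq_len(num_steps)) {
          for (alg in c("dls", "sc")) {
            it <- if (alg == "dls") dls$iterations[[step]] else sc$iterations[[step]]
            img <- if (alg == "dls") it$delta_sigma else it$delta_sigma[, mid]
            met <- compute_metrics(img, inv, tgt_inv)
            rows[[length(rows) + 1]] <- data.frame(
              target = tpos, snr = snr, seed_rep = rep_i,
              algorithm = alg, steps = step,
              pe = met$pe, sd = met$sd, in_ = met$in_, te = met$te,
              rank = it$rank, cond = it$condition_number,
              lambda = it$lambda, amplitude = met$amplitude)
          }
        }
      }
    }
  }
  table <- do.call(rbind, rows)
  structure(list(table = table,
                 reductions = percent_reductions(table),
                 config = list(base_seed = base_seed, n_seeds = n_seeds,
                               targets = targets, snr_levels = snr_levels,
                               num_steps = num_steps, semi_axes = semi_axes,
                               forward_elements = nrow(fwd$elements),
                               inverse_elements = nrow(inv$elements))),
            class = "eit_report")
}

#' Percent metric reductions of SC relative to DLS
#'
#' Metrics are first averaged over all scenes (targets, SNR levels, noise
#' repetitions) per algorithm and step; the reduction is
#' \code{100 * (DLS - SC) / DLS} of those averages.
#'
#' @param table A metrics table as produced by
#'   \code{\link{run_numerical_validation}}.
#' @return Data frame with one row per step and columns \code{in_},
#'   \code{sd}, \code{pe}, \code{te} (percent reductions).
#' @export
percent_reductions <- function(table) {
  out <- list()
  for (step in sort(unique(table$steps))) {
    sub <- table[table$steps == step, ]
    m <- function(alg, col) mean(sub[sub$algorithm == alg, col])
    red <- function(col) 100 * (m("dls", col) - m("sc", col)) / m("dls", col)
    out[[length(out) + 1]] <- data.frame(steps = step, in_ = red("in_"),
                                         sd = red("sd"), pe = red("pe"),
                                         te = red("te"))
  }
  do.call(rbind, out)
}

#' @export
print.eit_report <- function(x, ...) {
  cat("EIT validation report: ", nrow(x$table), " scored images (",
      length(x$config$targets), " targets x ",
      length(x$config$snr_levels), " SNR levels x ",
      x$config$n_seeds, " noise seeds)\n", sep = "")
  cat("Percent reduction of averaged metrics, SC vs DLS:\n")
  print(x$reductions, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Run the spectral-error robustness study
#'
#' Simulates data from the true spectra and reconstructs with randomly
#' perturbed spectra at each error level, using paired measurement-noise
#' seeds across levels so that differences are attributable to the
#' spectral error alone.
#'
#' @param base_seed Integer base seed.
#' @param levels Relative spectral error levels (fractions; 0 is the exact
#'   baseline).
#' @param n_seeds Repetitions per level.
#' @param position_index Target position of the scene.
#' @param snr_db Measurement SNR.
#' @param num_steps SC iteration steps.
#' @param inverse_elements Inverse-mesh element target.
#' @return List of class \code{eit_spectral_report}: \code{$table} with one
#'   row per level x seed (TE and image amplitude) and \code{$summary} of
#'   per-level means.
#' @export
run_spectral_error_study <- function(base_seed = 1,
                                     levels = c(0, 0.01, 0.03, 0.05, 0.10),
                                     n_seeds = 20, position_index = 2,
                                     snr_db = 80, num_steps = 1,
                                     inverse_elements = 512) {
  scene <- make_two_tissue_scene(position_index)
  inv <- build_circular_mesh(300, 16, inverse_elements)
  if (nrow(inv$elements) == nrow(scene$forward_mesh$elements)) {
    stop("forward and inverse meshes must differ (inverse crime)")
  }
  tgt_inv <- eit_target(scene$target$center, scene$target$semi_axes)
  mid <- ceiling(scene$spectra$n_frequencies / 2)
  rows <- list()
  for (rep_i in seq_len(n_seeds)) {
    fr <- simulate_scene_frames(scene, snr_db, derive_seed(base_seed, rep_i))
    for (lv in levels) {
      sp <- perturb_spectra(scene$spectra, lv,
                            derive_seed(base_seed, rep_i, round(lv * 1000)))
      sc <- sc_reconstruct(fr$bg, fr$fg, sp, inv, scene$protocol,
                           num_steps = num_steps)
      met <- compute_metrics(sc$delta_sigma[, mid], inv, tgt_inv)
      rows[[length(rows) + 1]] <- data.frame(
        level = lv, seed_rep = rep_i, pe = met$pe, sd = met$sd,
        in_ = met$in_, te = met$te, amplitude = met$amplitude)
    }
  }
  table <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(table, table$level), function(s)
    data.frame(level = s$level[1], te = mean(s$te),
               amplitude = mean(s$amplitude))))
  rownames(summary) <- NULL
  structure(list(table = table, summary = summary,
                 config = list(base_seed = base_seed, levels = levels,
                               n_seeds = n_seeds, snr_db = snr_db,
                               num_steps = num_steps)),
            class = "eit_spectral_report")
}

#' @export
print.eit_spectral_report <- function(x, ...) {
  cat("Spectral-error robustness study (", x$config$n_seeds,
      " paired seeds per level, SNR ", x$config$snr_db, " dB):\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
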