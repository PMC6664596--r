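#' Opposite-drive, adjacent-measurement electrode protocol
#'
#' With 16 electrodes, current is injected between diametrically opposed
#' pairs (source k, sink k+8 mod 16, one injection per source electrode) and
#' voltage differences are measured between all adjacent electrode pairs not
#' involved in carrying current: 12 pairs per injection, 192 measurements in
#' total per frequency.
#'
#' @param n_electrodes Number of electrodes (even).
#' @param current_amplitude Injected current peak amplitude in amperes.
#' @return An object of class \code{eit_protocol}: list with
#'   \code{injections} (data frame of source/sink electrode indices),
#'   \code{measurements} (K x 3 matrix: injection index, measurement
#'   electrodes a and b so that the reading is \code{u[a] - u[b]}),
#'   \code{current_amplitude} and \code{n_electrodes}.
#' @export
eit_protocol <- function(n_electrodes = 16, current_amplitude = 1e-3) {
  stopifnot(n_electrodes %% 2 == 0, n_electrodes >= 8, current_amplitude > 0)
  half <- n_electrodes / 2
  src <- seq_len(n_electrodes)
  snk <- (src - 1 + half) %% n_electrodes + 1
  meas <- list()
  for (k in seq_len(n_electrodes)) {
    for (j in seq_len(n_electrodes)) {
      a <- j; b <- j %% n_electrodes + 1
      if (a == src[k] || a == snk[k] || b == src[k] || b == snk[k]) next
      meas[[length(meas) + 1]] <- c(k, a, b)
    }
  }
  meas <- do.call(rbind, meas)
  colnames(meas) <- c("injection", "a", "b")
  structure(list(
    injections = data.frame(source = src, sink = snk),
    measurements = meas,
    current_amplitude = current_amplitude,
    n_electrodes = n_electrodes
  ), class = "eit_protocol")
}

#' @export
print.eit_protocol <- function(x, ...) {
  cat("EIT protocol: ", x$n_electrodes, " electrodes, opposite drive (",
      x$current_amplitude * 1e3, " mA), adjacent measurement, K = ",
      nrow(x$measurements), "\n", sep = "")
  invisible(x)
}

# assemble the grounded stiffness matrix for a per-element conductivity
# field and solve for a set of nodal current patterns
forward_fields <- function(mesh, sigma, currents) {
  N <- nrow(mesh$elements)
  if (length(sigma) != N) stop("sigma length must equal the element count")
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("conductivity must be positive and finite")
  }
  f <- mesh$fem
  K <- Matrix::sparseMatrix(i = f$ridx, j = f$cidx,
                            x = as.vector(f$kfac * sigma),
                            dims = rep(nrow(mesh$nodes), 2))
  keep <- setdiff(seq_len(nrow(mesh$nodes)), mesh$ground_node)
  U <- matrix(0, nrow(mesh$nodes), ncol(currents))
  sol <- Matrix::solve(K[keep, keep], currents[keep, , drop = FALSE])
  U[keep, ] <- as.matrix(sol)
  U
}

electrode_current_patterns <- function(mesh, protocol) {
  n <- nrow(mesh$nodes)
  inj <- protocol$injections
  cur <- matrix(0, n, nrow(inj))
  for (k in seq_len(nrow(inj))) {
    cur[mesh$electrode_nodes[inj$source[k]], k] <- protocol$current_amplitude
    cur[mesh$electrode_nodes[inj$sink[k]], k] <- -protocol$current_amplitude
  }
  cur
}

#' Solve the EIT forward problem
#'
#' Computes boundary voltage differences for a piecewise-constant
#' conductivity field under a drive/measurement protocol, using first-order
#' triangular finite elements with point electrodes and the potential fixed
#' to zero at the central ground node.
#'
#' @param mesh An \code{eit_mesh}.
#' @param sigma Per-element conductivity (S/m), length equal to the element
#'   count; all entries positive.
#' @param protocol An \code{eit_protocol}.
#' @return Numeric vector of K measured voltage differences (volts), in
#'   protocol order.
#' @export
solve_forward <- function(mesh, sigma, protocol) {
  U <- forward_fields(mesh, sigma, electrode_current_patterns(mesh, protocol))
  m <- protocol$measurements
  na <- mesh$electrode_nodes[m[, "a"]]
  nb <- mesh$electrode_nodes[m[, "b"]]
  U[cbind(na, m[, "injection"])] - U[cbind(nb, m[, "injection"])]
}

#' Sensitivity (Jacobian) of boundary measurements to element conductivity
#'
#' Computes the K x N matrix of derivatives of each measured voltage
#' difference with respect to each element conductivity, by the adjoint
#' (compensation-theorem) method: the entry for measurement k and element n
#' is \code{-area_n * grad(u_drive) . grad(u_meas)} where \code{u_meas} is
#' the field driven by a unit current through the measurement pair.
#'
#' @inheritParams solve_forward
#' @return K x N numeric matrix, evaluated at \code{sigma}.
#' @export
compute_jacobian <- function(mesh, sigma, protocol) {
  f <- mesh$fem
  el <- mesh$elements
  Ud <- forward_fields(mesh, sigma, electrode_current_patterns(mesh, protocol))
  # unit-current adjoint fields, one per distinct adjacent electrode pair
  ne <- protocol$n_electrodes
  adj_cur <- matrix(0, nrow(mesh$nodes), ne)
  for (j in seq_len(ne)) {
    adj_cur[mesh$electrode_nodes[j], j] <- 1
    adj_cur[mesh$electrode_nodes[j %% ne + 1], j] <- -1
  }
  Um <- forward_fields(mesh, sigma, adj_cur)

  elem_grads <- function(U) {
    # constant per-element gradient of each nodal field
    gx <- matrix(0, nrow(el), ncol(U)); gy <- gx
    for (p in seq_len(ncol(U))) {
      ue <- matrix(U[el, p], nrow(el), 3)
      gx[, p] <- rowSums(f$b * ue)
      gy[, p] <- rowSums(f$c * ue)
    }
    list(x = gx, y = gy)
  }
  gd <- elem_grads(Ud)
  gm <- elem_grads(Um)

  m <- protocol$measurements
  J <- matrix(0, nrow(m), nrow(el))
  for (k in seq_len(nrow(m))) {
    d <- m[k, "injection"]; a <- m[k, "a"]
    J[k, ] <- -f$area * (gd$x[, d] * gm$x[, a] + gd$y[, d] * gm$y[, a])
  }
  J
}

#' Add white Gaussian measurement noise at a prescribed SNR
#'
#' The noise standard deviation is \code{RMS(frame) * 10^(-snr_db/20)}, i.e.
#' the SNR is defined on the RMS amplitude of the whole measurement frame.
#' Identical seeds give identical noise; the caller's RNG state is left
#' untouched.
#'
#' @param frame Numeric vector of measured voltages.
#' @param snr_db Signal-to-noise ratio in dB; \code{Inf} returns the frame
#'   unchanged.
#' @param seed Integer seed for the noise draw.
#' @return Noisy frame of the same length.
#' @export
add_gaussian_noise <- function(frame, snr_db, seed) {
  stopifnot(is.numeric(frame), length(frame) > 0)
  if (is.infinite(snr_db)) return(frame)
  sd_noise <- sqrt(mean(frame^2)) * 10^(-snr_db / 20)
  noise <- withr::with_seed(as.integer(seed), stats::rnorm(length(frame), 0, sd_noise))
  frame + noise
}

#' Derive a reproducible child seed from a base seed and integer salts
#'
#' Deterministic integer hash used to give every noise draw in a study
#' (frame role, frequency, repetition, ...) its own stream from one base
#' seed. Always returns a non-negative integer below 2^31.
#'
#' @param base Integer base seed.
#' @param ... Further integer salts.
#' @return Integer seed.
#' @export
derive_seed <- function(base, ...) {
  parts <- c(base, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + (as.numeric(p) %% 104729) + 1) %% 2147483629
  as.integer(s)
}
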