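#' Assemble the stacked multi-frequency system
#'
#' Vertically stacks the per-frequency products J(w_i) A(w_i) into the
#' (M*K) x (T*N) matrix S, and folds the reference-tissue columns via the
#' substitution f_n1 = 1 - sum_{j>=2} f_nj into the reduced
#' (M*K) x ((T-1)*N) matrix actually inverted: each reduced column is the
#' tissue-j column minus the tissue-1 column of the same element.
#'
#' @param jacobians List of M Jacobian matrices (K x N each).
#' @param spectra A \code{tissue_spectra} with M frequency columns.
#' @return Object of class \code{eit_stacked}: list with \code{S},
#'   \code{S_reduced}, \code{blocks} (per-frequency J A products),
#'   \code{n_frequencies}, \code{n_tissues}, \code{n_elements}, \code{K}.
#' @export
assemble_stacked <- function(jacobians, spectra) {
  stopifnot(is.list(jacobians), length(jacobians) >= 1,
            inherits(spectra, "tissue_spectra"))
  M <- length(jacobians)
  if (M != spectra$n_frequencies) {
    stop("number of Jacobians must match the number of frequency columns")
  }
  T_ <- spectra$n_tissues
  N <- ncol(jacobians[[1]])
  K <- nrow(jacobians[[1]])
  if (!all(vapply(jacobians, function(J) all(dim(J) == c(K, N)), logical(1)))) {
    stop("all Jacobians must share the same K x N shape")
  }
  blocks <- vector("list", M)
  red_blocks <- vector("list", M)
  for (i in seq_len(M)) {
    eps_i <- spectra$values[, i]
    J <- jacobians[[i]]
    # (J A)_{k,(n,j)} = J_{k,n} * eps_j(w_i): replicate columns and scale
    blocks[[i]] <- sweep_block(J, eps_i, N, T_)
    red_blocks[[i]] <- sweep_block(J, eps_i[-1] - eps_i[1], N, T_ - 1)
  }
  structure(list(S = do.call(rbind, blocks),
                 S_reduced = do.call(rbind, red_blocks),
                 blocks = blocks,
                 n_frequencies = M, n_tissues = T_, n_elements = N, K = K),
            class = "eit_stacked")
}

# J with each column replicated `rep_per` times and scaled by the length-
# rep_per weight vector (element-major column ordering)
sweep_block <- function(J, w, N, rep_per) {
  B <- J[, rep(seq_len(N), each = rep_per), drop = FALSE]
  B * rep(w, times = N)[col(B)]
}

#' Singular-value rank and condition number of a matrix
#'
#' Rank is the number of singular values above the tolerance
#' \code{max(dim) * eps * s_max} (overridable); the condition number is the
#' ratio of the largest singular value to the smallest one above tolerance,
#' so a rank-deficient matrix gets a finite effective condition number over
#' its significant spectrum.
#'
#' @param m Numeric matrix.
#' @param tol Optional absolute singular-value tolerance.
#' @return List with \code{rank}, \code{condition_number} and the singular
#'   values \code{singular_values}.
#' @export
matrix_diagnostics <- function(m, tol = NULL) {
  m <- as.matrix(m)
  stopifnot(length(m) > 0)
  sv <- svd(m, nu = 0, nv = 0)$d
  if (max(sv) == 0) {
    warning("all-zero matrix: rank 0, condition number undefined")
    return(list(rank = 0L, condition_number = NA_real_, singular_values = sv))
  }
  if (is.null(tol)) tol <- max(dim(m)) * .Machine$double.eps * max(sv)
  r <- sum(sv > tol)
  list(rank = r, condition_number = sv[1] / sv[r], singular_values = sv)
}

#' Default regularisation-parameter grid
#'
#' Thirty log-spaced values spanning 1e-8 to 1, on the scale of the
#' column-equilibrated normal matrix (whose trace per column is one when
#' R = diag(S'S), so the grid needs no further scaling).
#' @param n Number of grid points.
#' @param lo,hi Decade range.
#' @return Numeric vector of candidate lambda values, increasing.
#' @export
lambda_grid_default <- function(n = 30, lo = -8, hi = 0) {
  10^seq(lo, hi, length.out = n)
}

# precompute the SVD of the column-equilibrated system S %*% D^{-1/2},
# D = diag(S'S); all Tikhonov solutions and L-curve norms over a lambda
# grid then cost O(rank) each
tikhonov_factor <- function(S) {
  d <- colSums(S^2)
  d[d <= 0] <- max(d, 1) * 1e-300
  sc <- sqrt(d)
  sv <- svd(S / rep(sc, each = nrow(S)))
  list(u = sv$u, d = sv$d, v = sv$v, colscale = sc)
}

tikhonov_apply <- function(fac, rhs, lambda) {
  beta <- drop(crossprod(fac$u, rhs))
  drop(fac$v %*% (fac$d * beta / (fac$d^2 + lambda))) / fac$colscale
}

lcurve_norms <- function(fac, rhs, lambdas) {
  beta <- drop(crossprod(fac$u, rhs))
  r0sq <- max(sum(rhs^2) - sum(beta^2), 0)
  res <- vapply(lambdas, function(l) {
    sqrt(sum((lambda_filter_res(fac$d, l) * beta)^2) + r0sq)
  }, numeric(1))
  sol <- vapply(lambdas, function(l) {
    sqrt(sum((fac$d * beta / (fac$d^2 + l))^2))
  }, numeric(1))
  list(residual = res, seminorm = sol)
}

lambda_filter_res <- function(d, l) l / (d^2 + l)

#' Select a Tikhonov regularisation weight by the L-curve criterion
#'
#' Evaluates the residual norm and solution seminorm of the regularised
#' problem over a grid of candidate weights and returns the grid value at
#' the point of maximum curvature of the (log residual, log seminorm)
#' curve. Deterministic for a fixed grid.
#'
#' @param S System matrix (or a prefactored object from the internal SVD
#'   path, used by the reconstruction drivers).
#' @param rhs Measurement-change vector.
#' @param grid Candidate lambda values, increasing; see
#'   \code{\link{lambda_grid_default}}.
#' @return The selected lambda (one of the grid values). An all-zero
#'   \code{rhs} yields the mid-grid value with a warning.
#' @export
select_lambda_lcurve <- function(S, rhs, grid = lambda_grid_default()) {
  stopifnot(length(grid) >= 3)
  if (all(rhs == 0)) {
    warning("all-zero right-hand side: returning mid-grid lambda")
    return(grid[ceiling(length(grid) / 2)])
  }
  fac <- if (is.list(S) && !is.null(S$colscale)) S else tikhonov_factor(as.matrix(S))
  nm <- lcurve_norms(fac, rhs, grid)
  x <- log(pmax(nm$residual, .Machine$double.xmin))
  y <- log(pmax(nm$seminorm, .Machine$double.xmin))
  n <- length(grid)
  # discrete curvature of the parametrised curve, central differences
  dx <- (x[3:n] - x[1:(n - 2)]) / 2
  dy <- (y[3:n] - y[1:(n - 2)]) / 2
  d2x <- x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]
  d2y <- y[3:n] - 2 * y[2:(n - 1)] + y[1:(n - 2)]
  kappa <- (dx * d2y - dy * d2x) / (dx^2 + dy^2)^1.5
  kappa[!is.finite(kappa)] <- -Inf
  grid[which.max(kappa) + 1]
}

#' Tikhonov-regularised solution of a linear reconstruction step
#'
#' Solves \code{(S'S + lambda R) x = S' rhs} with the standard-Tikhonov
#' regularisation matrix \code{R = diag(S'S)} (overridable by a positive
#' diagonal).
#'
#' @param S System matrix.
#' @param rhs Right-hand-side vector.
#' @param lambda Positive regularisation weight.
#' @param R Optional diagonal of the regularisation matrix (positive).
#' @return Solution vector.
#' @export
tikhonov_solve <- function(S, rhs, lambda, R = NULL) {
  stopifnot(lambda > 0)
  S <- as.matrix(S)
  if (is.null(R)) R <- colSums(S^2)
  stopifnot(all(R > 0), length(R) == ncol(S))
  A <- crossprod(S)
  diag(A) <- diag(A) + lambda * R
  drop(solve(A, crossprod(S, rhs)))
}

recon_floor <- 1e-6

# on later Gauss-Newton steps the residual is increasingly noise-dominated
# and the discrete L-curve loses its corner; damping is therefore kept
# monotone non-decreasing across the limited iterations
restrict_grid <- function(grid, lam_prev) {
  if (is.null(lam_prev)) return(grid)
  g <- grid[grid >= lam_prev]
  if (length(g) < 3) g <- grid[grid >= max(grid[grid <= lam_prev])]
  if (length(g) < 3) g <- utils::tail(grid, 3)
  g
}

#' Damped least-squares time-difference reconstruction
#'
#' Single-frequency baseline: one Tikhonov step
#' \code{dsigma = (J'J + lambda diag(J'J))^{-1} J' dv} linearised at a
#' homogeneous reference conductivity. With \code{num_steps = 2} the
#' background is updated, the forward problem re-solved on the inverse
#' mesh, the Jacobian re-linearised, and a second step solves for the
#' residual of the predicted voltage difference.
#'
#' @param delta_v Measured voltage-difference vector (foreground minus
#'   background) at the operating frequency, length K.
#' @param mesh Inverse-mesh \code{eit_mesh}.
#' @param protocol An \code{eit_protocol}.
#' @param sigma_ref Homogeneous reference conductivity (S/m).
#' @param num_steps 1 or 2 Gauss-Newton steps.
#' @param lambda Optional fixed regularisation weight; if \code{NULL} it is
#'   re-selected by the L-curve at every step.
#' @param lambda_grid Candidate grid for the L-curve.
#' @return Object of class \code{eit_recon}; \code{$iterations} holds one
#'   entry per step with the cumulative conductivity-change image
#'   \code{delta_sigma}, the \code{lambda} used, and matrix diagnostics
#'   (\code{rank}, \code{condition_number}) of the step's Jacobian.
#' @export
dls_reconstruct <- function(delta_v, mesh, protocol, sigma_ref,
                            num_steps = 1, lambda = NULL,
                            lambda_grid = lambda_grid_default()) {
  stopifnot(num_steps >= 1, length(delta_v) == nrow(protocol$measurements))
  N <- nrow(mesh$elements)
  sigma0 <- rep(sigma_ref, N)
  sigma_k <- sigma0
  v0 <- NULL
  iterations <- vector("list", num_steps)
  delta_sigma <- rep(0, N)
  lam_prev <- NULL
  for (k in seq_len(num_steps)) {
    J <- compute_jacobian(mesh, sigma_k, protocol)
    if (k == 1) {
      rhs <- delta_v
      v0 <- solve_forward(mesh, sigma0, protocol)
    } else {
      rhs <- delta_v - (solve_forward(mesh, sigma_k, protocol) - v0)
    }
    fac <- tikhonov_factor(J)
    lam <- if (is.null(lambda)) {
      select_lambda_lcurve(fac, rhs, restrict_grid(lambda_grid, lam_prev))
    } else lambda
    lam_prev <- lam
    step <- tikhonov_apply(fac, rhs, lam)
    new_sigma <- sigma_k + step
    if (any(new_sigma <= 0)) {
      warning("nonpositive conductivity after update; flooring")
      new_sigma <- pmax(new_sigma, recon_floor * sigma_ref)
    }
    delta_sigma <- new_sigma - sigma0
    dg <- matrix_diagnostics(J)
    iterations[[k]] <- list(delta_sigma = delta_sigma, lambda = lam,
                            rank = dg$rank,
                            condition_number = dg$condition_number)
    sigma_k <- new_sigma
  }
  structure(list(algorithm = "dls",
                 delta_sigma = matrix(delta_sigma, ncol = 1),
                 iterations = iterations,
                 iterations_run = num_steps,
                 lambda_used = vapply(iterations, `[[`, numeric(1), "lambda")),
            class = "eit_recon")
}

#' Spectral-constraints multi-frequency time-difference reconstruction
#'
#' Reconstructs the frequency-independent tissue-fraction change from
#' voltage differences at all M frequencies simultaneously. Each limited
#' iteration linearises the forward problem at the current fraction field,
#' stacks the per-frequency systems J(w_i) A(w_i), solves the reduced
#' Tikhonov problem for the non-reference fraction change, clamps the
#' updated fractions into [0, 1] with unit element sums, and updates the
#' voltage residual from a forward solve on the inverse mesh.
#'
#' @param frames_bg,frames_fg K x M matrices of background and foreground
#'   voltage frames, one column per frequency.
#' @param spectra \code{tissue_spectra} used for reconstruction (pass a
#'   perturbed copy to study spectral errors; the data may have been
#'   simulated from different, true spectra).
#' @param mesh Inverse-mesh \code{eit_mesh}.
#' @param protocol An \code{eit_protocol}.
#' @param num_steps Number of limited iterations (default 2).
#' @param lambda Optional fixed regularisation weight; default L-curve per
#'   iteration.
#' @param lambda_grid Candidate grid for the L-curve.
#' @return Object of class \code{eit_recon} with \code{delta_F} (T x N
#'   fraction change), \code{delta_sigma} (N x M conductivity change per
#'   frequency, exactly A(w_i) vec(delta_F)), and per-iteration entries
#'   carrying the fraction field, images, lambda, and rank/condition
#'   diagnostics of the reduced stacked matrix.
#' @export
sc_reconstruct <- function(frames_bg, frames_fg, spectra, mesh, protocol,
                           num_steps = 2, lambda = NULL,
                           lambda_grid = lambda_grid_default()) {
  frames_bg <- as.matrix(frames_bg); frames_fg <- as.matrix(frames_fg)
  K <- nrow(protocol$measurements)
  M <- spectra$n_frequencies
  T_ <- spectra$n_tissues
  N <- nrow(mesh$elements)
  stopifnot(nrow(frames_bg) == K, ncol(frames_bg) == M,
            all(dim(frames_bg) == dim(frames_fg)), num_steps >= 1)
  if (M * K < (T_ - 1) * N) {
    stop("underdetermined stacked system: M*K = ", M * K,
         " < (T-1)*N = ", (T_ - 1) * N)
  }
  delta_v_meas <- as.vector(frames_fg - frames_bg)

  F0 <- matrix(0, T_, N)
  F0[1, ] <- 1
  Fk <- F0
  v_sim0 <- NULL
  iterations <- vector("list", num_steps)
  lam_prev <- NULL
  for (k in seq_len(num_steps)) {
    sig <- lapply(seq_len(M), function(i)
      fractions_to_conductivity(Fk, spectra, i, validate = FALSE))
    jac <- lapply(sig, function(s) compute_jacobian(mesh, s, protocol))
    v_sim <- vapply(sig, function(s) solve_forward(mesh, s, protocol),
                    numeric(K))
    if (k == 1) v_sim0 <- v_sim
    rhs <- delta_v_meas - as.vector(v_sim - v_sim0)
    stacked <- assemble_stacked(jac, spectra)
    fac <- tikhonov_factor(stacked$S_reduced)
    lam <- if (is.null(lambda)) {
      select_lambda_lcurve(fac, rhs, restrict_grid(lambda_grid, lam_prev))
    } else lambda
    lam_prev <- lam
    dF_red <- matrix(tikhonov_apply(fac, rhs, lam), T_ - 1, N)
    F_tilde <- Fk + rbind(-colSums(dF_red), dF_red)
    Fk <- clamp_fractions(F_tilde)
    dF <- Fk - F0
    dsig <- vapply(seq_len(M), function(i)
      drop(crossprod(dF, spectra$values[, i])), numeric(N))
    dg <- matrix_diagnostics(stacked$S_reduced)
    iterations[[k]] <- list(F = Fk, delta_F = dF, delta_sigma = dsig,
                            lambda = lam, rank = dg$rank,
                            condition_number = dg$condition_number)
  }
  last <- iterations[[num_steps]]
  structure(list(algorithm = "sc",
                 delta_F = last$delta_F,
                 delta_sigma = last$delta_sigma,
                 F_final = last$F,
                 iterations = iterations,
                 iterations_run = num_steps,
                 lambda_used = vapply(iterations, `[[`, numeric(1), "lambda")),
            class = "eit_recon")
}

#' @export
print.eit_recon <- function(x, ...) {
  cat("EIT reconstruction (", toupper(x$algorithm), "), ",
      x$iterations_run, " step(s), lambda = ",
      paste(signif(x$lambda_used, 3), collapse = ", "), "\n", sep = "")
  cat("  image: ", nrow(x$delta_sigma), " elements x ",
      ncol(x$delta_sigma), " frequency image(s); max |dsigma| = ",
      signif(max(abs(x$delta_sigma)), 4), " S/m\n", sep = "")
  invisible(x)
}
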