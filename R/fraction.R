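#' Tissue conductivity spectra
#'
#' A small table of per-tissue conductivities at the measurement
#' frequencies. Tissues are rows, frequencies columns.
#'
#' @param values T x M matrix of conductivities (S/m), all positive.
#' @param tissue_names Character vector of length T; row names.
#' @param frequencies Numeric vector of length M (Hz), or abstract labels.
#' @return Object of class \code{tissue_spectra}.
#' @export
tissue_spectra <- function(values, tissue_names = rownames(values),
                           frequencies = seq_len(ncol(values))) {
  values <- as.matrix(values)
  if (is.null(tissue_names)) tissue_names <- paste0("t", seq_len(nrow(values)))
  stopifnot(nrow(values) >= 2, ncol(values) >= 1,
            all(is.finite(values)), all(values > 0),
            length(tissue_names) == nrow(values))
  dimnames(values) <- list(tissue_names, NULL)
  structure(list(values = values, tissue_names = tissue_names,
                 frequencies = frequencies,
                 n_tissues = nrow(values), n_frequencies = ncol(values)),
            class = "tissue_spectra")
}

#' @export
print.tissue_spectra <- function(x, ...) {
  cat("Tissue conductivity spectra (S/m), ", x$n_tissues, " tissues x ",
      x$n_frequencies, " frequencies\n", sep = "")
  print(x$values)
  invisible(x)
}

#' Brain-tissue spectra used in the numerical validation
#'
#' Normal and ischaemic brain conductivities at the three measurement
#' frequencies (10 Hz - 100 kHz band).
#' @return A \code{tissue_spectra} with tissues \code{normal} and
#'   \code{ischemia}.
#' @export
brain_tissue_spectra <- function() {
  tissue_spectra(rbind(normal = c(0.151, 0.155, 0.175),
                       ischemia = c(0.115, 0.120, 0.130)),
                 frequencies = c(1, 2, 3))
}

#' Pomelo/cucumber spectra of the tank phantom scenario
#'
#' Saline-pomelo background and cucumber target conductivities at
#' 20/50/100 kHz, for the phantom-style synthetic scenario.
#' @return A \code{tissue_spectra}.
#' @export
phantom_tissue_spectra <- function() {
  tissue_spectra(rbind(pomelo = c(0.083, 0.105, 0.129),
                       cucumber = c(0.047, 0.065, 0.093)),
                 frequencies = c(20e3, 50e3, 100e3))
}

#' Three-tissue spectra with blood
#'
#' Brain spectra extended with blood, whose conductivity is flat at
#' 0.7 S/m across the band.
#' @return A \code{tissue_spectra} with tissues normal, ischemia, blood.
#' @export
three_tissue_spectra <- function() {
  tissue_spectra(rbind(normal = c(0.151, 0.155, 0.175),
                       ischemia = c(0.115, 0.120, 0.130),
                       blood = c(0.7, 0.7, 0.7)),
                 frequencies = c(1, 2, 3))
}

#' Validate a fraction field
#'
#' A fraction field is a T x N matrix of per-element tissue volume
#' fractions: every entry in [0, 1] and every element (column) summing
#' to one.
#' @param F T x N numeric matrix.
#' @param tol Numeric tolerance for the checks.
#' @return \code{F} invisibly; errors if the invariants fail.
#' @export
validate_fractions <- function(F, tol = 1e-8) {
  F <- as.matrix(F)
  if (any(F < -tol) || any(F > 1 + tol)) {
    stop("fraction values must lie in [0, 1]")
  }
  if (any(abs(colSums(F) - 1) > tol)) {
    stop("fractions of each element must sum to 1")
  }
  invisible(F)
}

#' Spectral coefficient matrix
#'
#' The sparse N x (T*N) block matrix that maps the column-vectorised
#' fraction field to the per-element conductivity at one frequency: row n
#' carries the T tissue conductivities at that frequency in the columns of
#' element n.
#'
#' @param spectra A \code{tissue_spectra}.
#' @param frequency_index Frequency column, 1-based.
#' @param n_elements Number of mesh elements N.
#' @return A sparse \code{dgCMatrix} of dimension N x (T*N).
#' @export
coefficient_matrix <- function(spectra, frequency_index, n_elements) {
  stopifnot(inherits(spectra, "tissue_spectra"))
  M <- spectra$n_frequencies
  if (frequency_index < 1 || frequency_index > M) {
    stop("frequency_index out of range 1..", M)
  }
  T_ <- spectra$n_tissues
  eps_i <- spectra$values[, frequency_index]
  Matrix::sparseMatrix(
    i = rep(seq_len(n_elements), each = T_),
    j = seq_len(T_ * n_elements),
    x = rep(eps_i, times = n_elements),
    dims = c(n_elements, T_ * n_elements)
  )
}

#' Map a fraction field to a conductivity field
#'
#' The conductivity of element n at frequency i is the fraction-weighted
#' sum of the tissue conductivities: \code{sigma_n = sum_j f_nj * eps_ij}.
#' Equivalent to \code{coefficient_matrix(...) \%*\% as.vector(F)}.
#'
#' @param F T x N fraction field (columns sum to 1, entries in [0, 1]).
#' @param spectra A \code{tissue_spectra}.
#' @param frequency_index Frequency column, 1-based.
#' @param validate Check the fraction invariants first (default TRUE).
#' @return Numeric conductivity vector of length N (S/m).
#' @export
fractions_to_conductivity <- function(F, spectra, frequency_index,
                                      validate = TRUE) {
  if (validate) validate_fractions(F)
  drop(crossprod(as.matrix(F), spectra$values[, frequency_index]))
}

#' Clamp an unconstrained fraction update into the feasible set
#'
#' Entries of the non-reference tissues (rows 2..T) are clipped to [0, 1];
#' if their per-element sum exceeds one they are rescaled proportionally to
#' sum to one; the reference tissue (row 1) is then set to one minus that
#' sum. The result is always a valid fraction field and the operation is
#' idempotent.
#'
#' @param F_tilde T x N matrix of unconstrained fraction values.
#' @return T x N fraction field satisfying the box and unit-sum constraints.
#' @export
clamp_fractions <- function(F_tilde) {
  F_tilde <- as.matrix(F_tilde)
  T_ <- nrow(F_tilde)
  rest <- pmin(pmax(F_tilde[-1, , drop = FALSE], 0), 1)
  s <- colSums(rest)
  over <- s > 1
  if (any(over)) {
    rest[, over] <- sweep(rest[, over, drop = FALSE], 2, s[over], "/")
    s[over] <- 1
  }
  out <- rbind(1 - s, rest)
  dimnames(out) <- dimnames(F_tilde)
  out
}

#' Drop the reference tissue from a fraction field
#'
#' Removes the first (reference) tissue row, which is redundant under the
#' unit-sum constraint; \code{expand_reference_tissue} restores it.
#'
#' @param F T x N fraction field.
#' @return (T-1) x N matrix of the non-reference rows.
#' @export
eliminate_reference_tissue <- function(F) {
  F <- as.matrix(F)
  stopifnot(nrow(F) >= 2)
  F[-1, , drop = FALSE]
}

#' @rdname eliminate_reference_tissue
#' @param reduced (T-1) x N matrix of non-reference fractions.
#' @export
expand_reference_tissue <- function(reduced) {
  reduced <- as.matrix(reduced)
  rbind(1 - colSums(reduced), reduced)
}
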