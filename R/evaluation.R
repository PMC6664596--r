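#' Region of perturbation of a reconstructed image
#'
#' Elements whose displacement from the image mean exceeds half the maximum
#' displacement, reduced to the largest edge-connected cluster (shared-edge
#' adjacency; ties broken by total area, then lowest element index).
#'
#' @param image Per-element image values, length equal to the element count.
#' @param mesh The \code{eit_mesh} the image lives on.
#' @return Integer vector of element indices. A constant image yields an
#'   empty set with a warning (metrics are then undefined).
#' @export
region_of_perturbation <- function(image, mesh) {
  stopifnot(length(image) == nrow(mesh$elements))
  dev <- image - mean(image)
  mx <- max(abs(dev))
  if (mx == 0) {
    warning("constant image: empty region of perturbation")
    return(integer(0))
  }
  cand <- which(abs(dev) > 0.5 * mx)
  adj <- element_edge_adjacency(mesh)
  keep <- adj[adj[, 1] %in% cand & adj[, 2] %in% cand, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(keep[, 1]), to = as.character(keep[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(cand)))
  comp <- igraph::components(g)
  members <- split(cand, comp$membership[as.character(cand)])
  sizes <- lengths(members)
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    areas <- vapply(members[best], function(m) sum(element_areas(mesh)[m]),
                    numeric(1))
    best <- best[order(-areas, vapply(members[best], min, numeric(1)))][1]
  }
  sort(members[[best]])
}

#' Define an elliptical target
#'
#' @param center Length-2 centre coordinates (pixels, origin at disk centre).
#' @param semi_axes Length-2 semi-axes (x, y) in pixels.
#' @param tissue Index of the tissue occupying the target (default 2).
#' @return List of class \code{eit_target}.
#' @export
eit_target <- function(center, semi_axes, tissue = 2L) {
  stopifnot(length(center) == 2, length(semi_axes) == 2, all(semi_axes > 0))
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 tissue = as.integer(tissue)),
            class = "eit_target")
}

#' Elements whose centroid falls inside an elliptical target
#' @param mesh An \code{eit_mesh}.
#' @param target An \code{eit_target}.
#' @return Integer vector of element indices.
#' @export
target_elements <- function(mesh, target) {
  ctr <- element_centroids(mesh)
  u <- (ctr[, 1] - target$center[1]) / target$semi_axes[1]
  v <- (ctr[, 2] - target$center[2]) / target$semi_axes[2]
  which(u^2 + v^2 <= 1)
}

#' Image-quality metrics of a reconstructed change image
#'
#' Position error (PE), shape deformation (SD), image noise (IN) and their
#' sum, the total error (TE), for one change image against a known
#' elliptical target:
#' \itemize{
#'   \item PE: absolute difference between the centre-distance of the
#'     reconstructed perturbation's area-weighted centroid and that of the
#'     true target, over the mesh diameter.
#'   \item SD: mean absolute difference of the x/y bounding-box extents of
#'     the reconstructed perturbation and the true ellipse, over the mesh
#'     diameter.
#'   \item IN: standard deviation of the change image over the background
#'     elements, divided by the absolute difference between the mean change
#'     over the true target elements and over the background (inverse CNR).
#' }
#'
#' @param image Per-element change image (fraction change or conductivity
#'   change), length equal to the element count.
#' @param mesh The \code{eit_mesh} the image lives on.
#' @param target An \code{eit_target} describing the true perturbation.
#' @return Object of class \code{eit_metrics}: list with \code{pe},
#'   \code{sd}, \code{in_}, \code{te}, \code{rp_elements}, and supporting
#'   quantities (centroid distances, extents, amplitude).
#' @export
compute_metrics <- function(image, mesh, target) {
  rp <- region_of_perturbation(image, mesh)
  if (!length(rp)) stop("empty region of perturbation: metrics undefined")
  d_mesh <- 2 * mesh$radius
  ar <- element_areas(mesh)[rp]
  ctr <- element_centroids(mesh)[rp, , drop = FALSE]
  cen_rp <- colSums(ctr * ar) / sum(ar)
  d_rp <- sqrt(sum(cen_rp^2))
  d_real <- sqrt(sum(target$center^2))
  pe <- abs(d_rp - d_real) / d_mesh

  # bounding-box extents from the vertices of the RP elements
  vrt <- unique(as.vector(mesh$elements[rp, , drop = FALSE]))
  lx_rp <- diff(range(mesh$nodes[vrt, 1]))
  ly_rp <- diff(range(mesh$nodes[vrt, 2]))
  lx_real <- 2 * target$semi_axes[1]
  ly_real <- 2 * target$semi_axes[2]
  sd_ <- 0.5 * (abs(lx_rp - lx_real) + abs(ly_rp - ly_real)) / d_mesh

  tgt <- target_elements(mesh, target)
  if (!length(tgt)) stop("true target covers no element of this mesh")
  bg <- setdiff(seq_len(nrow(mesh$elements)), tgt)
  contrast <- abs(mean(image[tgt]) - mean(image[bg]))
  if (contrast == 0) {
    warning("zero target-background contrast: IN is infinite")
    in_ <- Inf
  } else {
    in_ <- stats::sd(image[bg]) / contrast
  }
  structure(list(pe = pe, sd = sd_, in_ = in_, te = pe + sd_ + in_,
                 rp_elements = rp,
                 d_rp = d_rp, d_real = d_real, d_mesh = d_mesh,
                 l_rp = c(lx_rp, ly_rp), l_real = c(lx_real, ly_real),
                 amplitude = max(abs(image))),
            class = "eit_metrics")
}

#' @export
print.eit_metrics <- function(x, ...) {
  cat(sprintf("PE = %.4f  SD = %.4f  IN = %.4f  TE = %.4f  (RP: %d elements)\n",
              x$pe, x$sd, x$in_, x$te, length(x$rp_elements)))
  invisible(x)
}

#' Mean relative conductivity contrast between two tissues
#'
#' The frequency-averaged relative difference of the conductivity of
#' tissue b with respect to tissue a, reported as a percent magnitude.
#'
#' @param spectra A \code{tissue_spectra}.
#' @param tissue_a Reference tissue (row index or name).
#' @param tissue_b Contrast tissue (row index or name).
#' @return Percent magnitude (e.g. 24.05 for a 24.05\% mean contrast).
#' @export
mean_relative_contrast <- function(spectra, tissue_a = 1, tissue_b = 2) {
  va <- spectra$values[tissue_a, ]
  vb <- spectra$values[tissue_b, ]
  if (any(va == 0)) stop("reference tissue has zero conductivity")
  100 * abs(mean((vb - va) / va))
}
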