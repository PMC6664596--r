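#' Build a structured triangular mesh of a disk
#'
#' Constructs a deterministic ring-based triangulation of a circular domain.
#' Nodes are laid out on concentric rings; ring \code{r} (of \code{R}) carries
#' \code{c*r} nodes, which yields exactly \code{c*R^2} triangles. The
#' configuration \code{(c = 8, R = 10)} gives the canonical 800-element /
#' 441-node forward mesh and \code{(c = 8, R = 8)} the 512-element / 289-node
#' inverse mesh used throughout the validation study. Electrodes are placed
#' on evenly spaced boundary nodes; the whole mesh is rotated by half an
#' electrode spacing so that the +x axis falls midway between two electrodes.
#'
#' @param radius Disk radius, in pixels.
#' @param n_electrodes Number of boundary electrodes (must divide the
#'   boundary node count of the selected ring configuration).
#' @param target_elements Requested number of triangles; the builder picks the
#'   ring configuration whose element count is closest (within 10%).
#' @return An object of class \code{eit_mesh}: a list with \code{nodes}
#'   (n x 2 coordinates, origin at the disk centre), \code{elements}
#'   (E x 3 node indices, counterclockwise), \code{radius},
#'   \code{electrode_nodes} (counterclockwise node indices),
#'   \code{ground_node} (the centre node), \code{boundary_nodes}, and cached
#'   finite-element quantities (element areas, centroids, shape-function
#'   gradients).
#' @examples
#' m <- build_circular_mesh(300, 16, 512)
#' nrow(m$elements)  # 512
#' @export
build_circular_mesh <- function(radius = 300, n_electrodes = 16,
                                target_elements = 800) {
  stopifnot(radius > 0, n_electrodes >= 4, target_elements >= n_electrodes)
  best <- NULL
  for (R in 2:64) {
    cc <- round(target_elements / R^2)
    if (cc < 4) next  # ring-1 fan needs enough nodes for valid triangles
    if ((cc * R) %% n_electrodes != 0) next
    E <- cc * R^2
    if (abs(E - target_elements) > 0.1 * target_elements) next
    if (is.null(best) || abs(E - target_elements) < best$err ||
        (abs(E - target_elements) == best$err && R > best$R)) {
      best <- list(c = cc, R = R, err = abs(E - target_elements))
    }
  }
  if (is.null(best)) {
    stop("no ring configuration matches target_elements = ", target_elements,
         " with ", n_electrodes, " electrodes")
  }
  cc <- best$c; R <- best$R
  phase <- pi / n_electrodes

  nodes <- matrix(0, 1 + cc * R * (R + 1) / 2, 2)
  ring_index <- vector("list", R)  # node indices of each ring
  pos <- 1L
  for (r in seq_len(R)) {
    n_r <- cc * r
    ang <- phase + 2 * pi * (seq_len(n_r) - 1) / n_r
    idx <- pos + seq_len(n_r)
    nodes[idx, ] <- radius * r / R * cbind(cos(ang), sin(ang))
    ring_index[[r]] <- idx
    pos <- pos + n_r
  }

  elements <- matrix(0L, cc * R^2, 3)
  t0 <- 0L
  # innermost fan around the centre node
  inner <- ring_index[[1]]
  for (k in seq_len(cc)) {
    elements[t0 + k, ] <- c(1L, inner[k], inner[k %% cc + 1L])
  }
  t0 <- t0 + cc
  ring_angle <- function(idx) atan2(nodes[idx, 2], nodes[idx, 1]) %% (2 * pi)
  for (r in 2:R) {
    tri <- zip_band(ring_index[[r - 1]], ring_index[[r]],
                    ring_angle(ring_index[[r - 1]]),
                    ring_angle(ring_index[[r]]))
    elements[t0 + seq_len(nrow(tri)), ] <- tri
    t0 <- t0 + nrow(tri)
  }

  # consistent counterclockwise orientation
  a <- signed_area(nodes, elements)
  flip <- a < 0
  if (any(flip)) {
    elements[flip, 2:3] <- elements[flip, 3:2]
    a <- abs(a)
  }
  if (any(a <= 0)) stop("degenerate triangulation: zero-area element")

  boundary <- ring_index[[R]]
  estep <- length(boundary) / n_electrodes
  electrode_nodes <- boundary[1 + estep * (seq_len(n_electrodes) - 1)]

  mesh <- structure(list(
    nodes = nodes, elements = elements, radius = radius,
    electrode_nodes = electrode_nodes, ground_node = 1L,
    boundary_nodes = boundary, n_rings = R, ring_base = cc
  ), class = "eit_mesh")
  mesh$fem <- precompute_fem(mesh)
  mesh
}

# zipper triangulation of the annulus band between two node rings,
# marching both rings in angular order; yields length(inner)+length(outer)
# triangles
zip_band <- function(inner_idx, outer_idx, inner_ang, outer_ang) {
  ni <- length(inner_idx); no <- length(outer_idx)
  # unwrap so both sequences ascend from a common phase
  ia <- c(inner_ang, inner_ang[1] + 2 * pi)
  oa <- c(outer_ang, outer_ang[1] + 2 * pi)
  ii <- c(inner_idx, inner_idx[1])
  oi <- c(outer_idx, outer_idx[1])
  tris <- matrix(0L, ni + no, 3)
  i <- 1L; j <- 1L; t <- 0L
  while (i <= no || j <= ni) {
    adv_outer <- if (i > no) FALSE else if (j > ni) TRUE else oa[i + 1] <= ia[j + 1]
    t <- t + 1L
    if (adv_outer) {
      tris[t, ] <- c(oi[i], oi[i + 1L], ii[j]); i <- i + 1L
    } else {
      tris[t, ] <- c(ii[j + 1L], ii[j], oi[i]); j <- j + 1L
    }
  }
  tris
}

signed_area <- function(nodes, elements) {
  x1 <- nodes[elements[, 1], 1]; y1 <- nodes[elements[, 1], 2]
  x2 <- nodes[elements[, 2], 1]; y2 <- nodes[elements[, 2], 2]
  x3 <- nodes[elements[, 3], 1]; y3 <- nodes[elements[, 3], 2]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

# per-element linear shape-function gradients and stiffness ingredients,
# cached on the mesh so repeated assemblies only scale by conductivity
precompute_fem <- function(mesh) {
  el <- mesh$elements
  nd <- mesh$nodes
  x <- matrix(nd[el, 1], nrow(el), 3)
  y <- matrix(nd[el, 2], nrow(el), 3)
  area <- abs(signed_area(nd, el))
  # grad of nodal shape function i: (b_i, c_i)
  b <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2]) / (2 * area)
  cxy <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1]) / (2 * area)
  # unit-conductivity element stiffness entries K_ij = area*(b_i b_j + c_i c_j)
  comb <- expand.grid(i = 1:3, j = 1:3)
  kfac <- matrix(0, nrow(el), 9)
  ridx <- matrix(0L, nrow(el), 9)
  cidx <- matrix(0L, nrow(el), 9)
  for (q in seq_len(9)) {
    i <- comb$i[q]; j <- comb$j[q]
    kfac[, q] <- area * (b[, i] * b[, j] + cxy[, i] * cxy[, j])
    ridx[, q] <- el[, i]
    cidx[, q] <- el[, j]
  }
  centroid <- cbind(rowMeans(x), rowMeans(y))
  list(area = area, b = b, c = cxy, kfac = kfac,
       ridx = as.vector(ridx), cidx = as.vector(cidx), centroid = centroid)
}

#' @export
print.eit_mesh <- function(x, ...) {
  cat("EIT disk mesh: ", nrow(x$elements), " elements, ", nrow(x$nodes),
      " nodes, radius ", x$radius, " px, ",
      length(x$electrode_nodes), " electrodes\n", sep = "")
  invisible(x)
}

#' Element centroids of a mesh
#' @param mesh An \code{eit_mesh}.
#' @return E x 2 matrix of triangle centroids.
#' @export
element_centroids <- function(mesh) mesh$fem$centroid

#' Element areas of a mesh
#' @param mesh An \code{eit_mesh}.
#' @return Numeric vector of triangle areas (square pixels).
#' @export
element_areas <- function(mesh) mesh$fem$area

#' Check the Euler relation for a triangulated disk
#'
#' For a simply connected triangulated disk,
#' \code{n_elements = 2 * n_interior_nodes + n_boundary_nodes - 2}.
#' @param mesh An \code{eit_mesh}.
#' @return Logical.
#' @export
euler_relation_holds <- function(mesh) {
  nb <- length(mesh$boundary_nodes)
  ni <- nrow(mesh$nodes) - nb
  nrow(mesh$elements) == 2L * ni + nb - 2L
}

# adjacency over shared element edges; returns a two-column index matrix
element_edge_adjacency <- function(mesh) {
  if (!is.null(mesh$adj)) return(mesh$adj)
  el <- mesh$elements
  E <- nrow(el)
  edges <- rbind(el[, c(1, 2)], el[, c(2, 3)], el[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  owner <- rep(seq_len(E), 3)
  sp <- split(owner, key)
  shared <- sp[lengths(sp) == 2L]
  if (!length(shared)) return(matrix(integer(), 0, 2))
  do.call(rbind, lapply(shared, function(p) sort(p)))
}
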