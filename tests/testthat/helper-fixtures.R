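# shared fixtures, built once per test run
.fix <- new.env()

fix_protocol <- function() {
  if (is.null(.fix$protocol)) .fix$protocol <- eit_protocol()
  .fix$protocol
}

fix_small_mesh <- function() {
  if (is.null(.fix$small)) .fix$small <- build_circular_mesh(300, 16, 64)
  .fix$small
}

fix_inverse_mesh <- function() {
  if (is.null(.fix$inverse)) .fix$inverse <- build_circular_mesh(300, 16, 512)
  .fix$inverse
}

fix_forward_mesh <- function() {
  if (is.null(.fix$forward)) .fix$forward <- build_circular_mesh(300, 16, 800)
  .fix$forward
}

# a cached quick scene + frames for reconstruction-level tests
fix_scene_frames <- function(position = 2, snr = 80, seed = 11) {
  key <- paste0("sf", position, "_", snr, "_", seed)
  if (is.null(.fix[[key]])) {
    scene <- make_two_tissue_scene(position, forward_mesh = fix_forward_mesh(),
                                   protocol = fix_protocol())
    .fix[[key]] <- list(scene = scene,
                        frames = simulate_scene_frames(scene, snr, seed))
  }
  .fix[[key]]
}

# analytic potential for +/- point current sources on the boundary of a
# homogeneous disk: u(x) = I/(pi*sigma) * (ln|x-b| - ln|x-a|)
analytic_disk_voltages <- function(mesh, protocol, sigma) {
  epos <- mesh$nodes[mesh$electrode_nodes, ]
  m <- protocol$measurements
  I <- protocol$current_amplitude
  vapply(seq_len(nrow(m)), function(k) {
    inj <- m[k, 1]
    a <- epos[protocol$injections$source[inj], ]
    b <- epos[protocol$injections$sink[inj], ]
    u <- function(x) I / (pi * sigma) *
      (log(sqrt(sum((x - b)^2))) - log(sqrt(sum((x - a)^2))))
    u(epos[m[k, 2], ]) - u(epos[m[k, 3], ])
  }, numeric(1))
}

# Shaw's one-dimensional image-restoration test problem (discretised
# integral operator), the classic small ill-posed system
shaw_problem <- function(n = 32) {
  h <- pi / n
  s <- -pi / 2 + (seq_len(n) - 0.5) * h
  A <- outer(s, s, function(si, tj) {
    u <- pi * (sin(si) + sin(tj))
    (cos(si) + cos(tj))^2 * ifelse(u == 0, 1, (sin(u) / u)^2)
  }) * h
  x <- 2 * exp(-6 * (s - 0.8)^2) + exp(-6 * (s + 0.5)^2)
  list(A = A, x = x, b = drop(A %*% x))
}

# independent flood fill over shared-edge adjacency (test oracle)
flood_clusters <- function(mesh, mask_idx) {
  el <- mesh$elements
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- list()
  for (e in mask_idx) {
    for (pair in list(c(1, 2), c(2, 3), c(3, 1))) {
      k <- edge_key(el[e, pair[1]], el[e, pair[2]])
      edges[[k]] <- c(edges[[k]], e)
    }
  }
  nbr <- lapply(setNames(mask_idx, mask_idx), function(e) integer(0))
  for (es in edges) if (length(es) == 2) {
    nbr[[as.character(es[1])]] <- c(nbr[[as.character(es[1])]], es[2])
    nbr[[as.character(es[2])]] <- c(nbr[[as.character(es[2])]], es[1])
  }
  seen <- c(); out <- list()
  for (s in mask_idx) {
    if (s %in% seen) next
    queue <- s; comp <- c()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(nbr[[as.character(v)]], comp))
    }
    seen <- c(seen, comp)
    out[[length(out) + 1]] <- sort(comp)
  }
  out
}

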