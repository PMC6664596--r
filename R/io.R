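#' Write / read a mesh as plain text
#'
#' Serialises nodes, elements and electrode indices into a single
#' tab-separated file with sectioned blocks, round-trippable with
#' \code{read_mesh}.
#'
#' @param mesh An \code{eit_mesh}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# eit_mesh v1",
               paste("radius", format(mesh$radius, digits = 17)),
               paste("ground_node", mesh$ground_node),
               paste("electrode_nodes",
                     paste(mesh$electrode_nodes, collapse = "\t")),
               paste("n_nodes", nrow(mesh$nodes)),
               paste("n_elements", nrow(mesh$elements))), con)
  utils::write.table(format(mesh$nodes, digits = 17), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(mesh$elements, con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  lines <- readLines(path)
  hdr <- function(key) strsplit(lines[grep(paste0("^", key, " "), lines)[1]],
                                "[ \t]+")[[1]][-1]
  radius <- as.numeric(hdr("radius"))
  ground <- as.integer(hdr("ground_node"))
  electrodes <- as.integer(hdr("electrode_nodes"))
  nn <- as.integer(hdr("n_nodes"))
  ne <- as.integer(hdr("n_elements"))
  nodes <- as.matrix(utils::read.table(text = lines[6 + seq_len(nn)],
                                       sep = "\t")[, 1:2])
  elements <- as.matrix(utils::read.table(text = lines[6 + nn + seq_len(ne)],
                                          sep = "\t")[, 1:3])
  storage.mode(elements) <- "integer"
  dimnames(nodes) <- NULL; dimnames(elements) <- NULL
  bnd <- boundary_nodes_of(nodes, elements)
  mesh <- structure(list(nodes = nodes, elements = elements, radius = radius,
                         electrode_nodes = electrodes, ground_node = ground,
                         boundary_nodes = bnd), class = "eit_mesh")
  mesh$fem <- precompute_fem(mesh)
  mesh
}

# boundary nodes = nodes of edges owned by a single element
boundary_nodes_of <- function(nodes, elements) {
  edges <- rbind(elements[, c(1, 2)], elements[, c(2, 3)], elements[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  single <- names(which(table(key) == 1))
  sort(unique(as.integer(unlist(strsplit(single, " ")))))
}

#' Write / read tissue spectra as a tab-separated table
#'
#' One row per tissue, one column per frequency, with frequencies in the
#' header.
#' @param spectra A \code{tissue_spectra}.
#' @param path File path.
#' @return \code{path} / a \code{tissue_spectra}.
#' @export
write_spectra <- function(spectra, path) {
  df <- data.frame(tissue = spectra$tissue_names, spectra$values,
                   check.names = FALSE)
  names(df)[-1] <- as.character(spectra$frequencies)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("spectra file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  freq <- suppressWarnings(as.numeric(colnames(vals)))
  if (any(is.na(freq))) freq <- seq_len(ncol(vals))
  tissue_spectra(vals, as.character(df[[1]]), freq)
}

#' Write / read voltage frames as CSV
#'
#' Frames are stored long: one row per (role, frequency, measurement).
#' @param frames List with K x M matrices \code{bg} and \code{fg}.
#' @param path File path.
#' @return \code{path} / a list with \code{bg} and \code{fg}.
#' @export
write_frames <- function(frames, path) {
  long <- function(mat, role) data.frame(
    role = role,
    frequency = rep(seq_len(ncol(mat)), each = nrow(mat)),
    measurement = rep(seq_len(nrow(mat)), ncol(mat)),
    value = as.vector(mat))
  df <- rbind(long(frames$bg, "background"), long(frames$fg, "foreground"))
  utils::write.csv(format(df, digits = 17), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  if (!file.exists(path)) stop("frames file not found: ", path)
  df <- utils::read.csv(path, strip.white = TRUE)
  wide <- function(role) {
    sub <- df[df$role == role, ]
    K <- max(sub$measurement); M <- max(sub$frequency)
    m <- matrix(0, K, M)
    m[cbind(sub$measurement, sub$frequency)] <- as.numeric(sub$value)
    m
  }
  list(bg = wide("background"), fg = wide("foreground"))
}

default_run_config <- function() {
  list(scenario = "two_tissue", position_index = 2L, snr_db = 80,
       base_seed = 1L, num_steps = 2L, algorithms = c("sc", "dls"),
       forward_elements = 800L, inverse_elements = 512L, radius = 300,
       n_electrodes = 16L, current_amplitude = 1e-3,
       semi_axes = c(45, 30), spectra_file = NULL,
       lambda_grid = list(n = 30L, lo = -8, hi = 0))
}

#' Read a run configuration file
#'
#' A flat YAML file of scenario, mesh, protocol, noise and solver
#' parameters; unspecified keys take the package defaults.
#'
#' @param path YAML config path, or \code{NULL} for pure defaults.
#' @return Named list of resolved configuration values.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) stop("unknown config keys: ",
                              paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  stopifnot(cfg$base_seed == round(cfg$base_seed))
  cfg
}

resolve_spectra <- function(cfg) {
  if (!is.null(cfg$spectra_file)) return(read_spectra(cfg$spectra_file))
  if (identical(cfg$scenario, "phantom")) return(phantom_tissue_spectra())
  if (identical(cfg$scenario, "three_tissue")) return(three_tissue_spectra())
  brain_tissue_spectra()
}

config_scene <- function(cfg) {
  spectra <- resolve_spectra(cfg)
  fwd <- build_circular_mesh(cfg$radius, cfg$n_electrodes, cfg$forward_elements)
  protocol <- eit_protocol(cfg$n_electrodes, cfg$current_amplitude)
  if (identical(cfg$scenario, "three_tissue")) {
    make_three_tissue_scene(spectra, forward_mesh = fwd, protocol = protocol)
  } else {
    make_two_tissue_scene(cfg$position_index, spectra,
                          semi_axes = cfg$semi_axes,
                          forward_mesh = fwd, protocol = protocol)
  }
}

#' Simulate a scene from a configuration and write it to disk
#'
#' Writes the forward mesh, spectra, true fraction field and the noisy
#' voltage frames under \code{out_dir}.
#'
#' @param config_path YAML config path (\code{NULL} for defaults).
#' @param out_dir Output directory (created if missing).
#' @return The output directory, invisibly.
#' @export
cli_simulate <- function(config_path = NULL, out_dir = "eit_run") {
  cfg <- read_run_config(config_path)
  scene <- config_scene(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  frames <- simulate_scene_frames(scene, cfg$snr_db, cfg$base_seed)
  write_mesh(scene$forward_mesh, file.path(out_dir, "forward_mesh.tsv"))
  write_spectra(scene$spectra, file.path(out_dir, "spectra.tsv"))
  write_frames(frames, file.path(out_dir, "frames.csv"))
  utils::write.table(scene$true_fractions,
                     file.path(out_dir, "true_fractions.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  tg <- scene$target
  yaml::write_yaml(list(center = tg$center, semi_axes = tg$semi_axes,
                        tissue = tg$tissue, snr_db = cfg$snr_db,
                        base_seed = cfg$base_seed,
                        n_electrodes = cfg$n_electrodes,
                        current_amplitude = cfg$current_amplitude,
                        inverse_elements = cfg$inverse_elements,
                        radius = cfg$radius,
                        K = nrow(scene$protocol$measurements),
                        M = scene$spectra$n_frequencies),
                   file.path(out_dir, "scene.yaml"))
  message("simulated ", nrow(scene$protocol$measurements), " measurements x ",
          scene$spectra$n_frequencies, " frequencies x 2 frames at ",
          cfg$snr_db, " dB into ", out_dir)
  invisible(out_dir)
}

read_scene_meta <- function(run_dir) {
  f <- file.path(run_dir, "scene.yaml")
  if (!file.exists(f)) stop("no simulated scene at ", run_dir)
  yaml::read_yaml(f)
}

#' Reconstruct a simulated run from disk
#'
#' @param run_dir Directory produced by \code{\link{cli_simulate}}.
#' @param algorithm \code{"sc"} or \code{"dls"}.
#' @param num_steps Iteration steps.
#' @return The \code{eit_recon} object, invisibly; the image is also
#'   written to \code{<run_dir>/image_<algorithm>.tsv}.
#' @export
cli_reconstruct <- function(run_dir, algorithm = c("sc", "dls"),
                            num_steps = 2) {
  algorithm <- match.arg(algorithm)
  meta <- read_scene_meta(run_dir)
  frames <- read_frames(file.path(run_dir, "frames.csv"))
  spectra <- read_spectra(file.path(run_dir, "spectra.tsv"))
  inv <- build_circular_mesh(meta$radius, meta$n_electrodes,
                             meta$inverse_elements)
  protocol <- eit_protocol(meta$n_electrodes, meta$current_amplitude)
  mid <- ceiling(spectra$n_frequencies / 2)
  rec <- if (algorithm == "sc") {
    sc_reconstruct(frames$bg, frames$fg, spectra, inv, protocol, num_steps)
  } else {
    dls_reconstruct(frames$fg[, mid] - frames$bg[, mid], inv, protocol,
                    spectra$values[1, mid], num_steps)
  }
  img <- if (algorithm == "sc") rec$delta_sigma else rec$delta_sigma
  utils::write.table(format(img, digits = 17),
                     file.path(run_dir, paste0("image_", algorithm, ".tsv")),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  message(toupper(algorithm), ": max |dsigma| = ",
          signif(max(abs(rec$delta_sigma)), 4), " S/m")
  invisible(rec)
}

#' Score a reconstructed run against its scene
#'
#' @param run_dir Directory holding a simulated scene and at least one
#'   reconstructed image.
#' @param algorithm Which image to score.
#' @return The \code{eit_metrics}, invisibly; also appended to
#'   \code{<run_dir>/metrics.tsv}.
#' @export
cli_evaluate <- function(run_dir, algorithm = c("sc", "dls")) {
  algorithm <- match.arg(algorithm)
  meta <- read_scene_meta(run_dir)
  img_path <- file.path(run_dir, paste0("image_", algorithm, ".tsv"))
  if (!file.exists(img_path)) stop("no reconstructed image at ", img_path)
  img <- as.matrix(utils::read.table(img_path, sep = "\t"))
  inv <- build_circular_mesh(meta$radius, meta$n_electrodes,
                             meta$inverse_elements)
  if (nrow(img) != nrow(inv$elements)) {
    stop("image/mesh mismatch: ", nrow(img), " values vs ",
         nrow(inv$elements), " elements")
  }
  mid <- ceiling(ncol(img) / 2)
  tgt <- eit_target(unlist(meta$center), unlist(meta$semi_axes))
  met <- compute_metrics(img[, mid], inv, tgt)
  row <- data.frame(algorithm = algorithm, pe = met$pe, sd = met$sd,
                    in_ = met$in_, te = met$te)
  out <- file.path(run_dir, "metrics.tsv")
  utils::write.table(row, out, sep = "\t", row.names = FALSE,
                     col.names = !file.exists(out), append = file.exists(out),
                     quote = FALSE)
  print(met)
  invisible(met)
}

#' Plot a per-element image on its mesh
#'
#' Fills each triangle with a diverging colour mapped to the image value;
#' annotates the maximum range of change.
#'
#' @param image Per-element values.
#' @param mesh The \code{eit_mesh}.
#' @param main Plot title.
#' @export
plot_eit_image <- function(image, mesh, main = "") {
  stopifnot(length(image) == nrow(mesh$elements))
  rng <- max(abs(image - mean(image)), .Machine$double.eps)
  pal <- grDevices::colorRampPalette(c("#2166ac", "#f7f7f7", "#b2182b"))(101)
  idx <- 1 + round(50 * (1 + (image - mean(image)) / rng))
  graphics::plot(NA, xlim = c(-1, 1) * mesh$radius,
                 ylim = c(-1, 1) * mesh$radius, asp = 1, axes = FALSE,
                 xlab = "", ylab = "", main = main)
  for (e in seq_len(nrow(mesh$elements))) {
    v <- mesh$elements[e, ]
    graphics::polygon(mesh$nodes[v, 1], mesh$nodes[v, 2],
                      col = pal[idx[e]], border = NA)
  }
  graphics::mtext(sprintf("max range of change: %.3g",
                          max(image) - min(image)), side = 1, line = 0)
  invisible(NULL)
}
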