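#' Configuration for the synthetic connectome generator
#'
#' The generator emulates the statistical structure the deviation analysis
#' assumes in real SIFT2-weighted connectomes: a shared anatomical template
#' with distance-decaying edge weights on bilateral, brain-shaped geometry,
#' and per-subject multiplicative (lognormal) edge noise with stable per-edge
#' mean and coefficient of variation.
#'
#' @param n_nodes Number of regions (default 84, the Desikan-Killiany count).
#' @param n_controls Reference cohort size (default 12).
#' @param base_weight Template weight of a zero-length connection (streamline
#'   count scale, default 1000).
#' @param decay_scale Exponential decay scale of weight with centroid
#'   distance, mm (default 35).
#' @param density Fraction of node pairs kept as edges, strongest first
#'   (default 0.35).
#' @param subject_noise_cv Coefficient of variation of the multiplicative
#'   lognormal subject noise (default 0.15); the noise has mean 1 so per-edge
#'   sample means converge to the template weight.
#' @param icv_mean,icv_sd Per-subject total intracranial volume distribution,
#'   mm^3.
#' @param seed Base seed; every generated object is deterministic given it.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_nodes = 84, n_controls = 12,
                             base_weight = 1000, decay_scale = 35,
                             density = 0.35, subject_noise_cv = 0.15,
                             icv_mean = 1.45e6, icv_sd = 1e5, seed = 1L) {
  if (n_nodes < 3) stop_config("need at least 3 nodes")
  if (n_controls < 2) stop_config("need at least 2 controls")
  if (!(density > 0 && density <= 1)) stop_config("density must be in (0, 1]")
  if (base_weight <= 0 || decay_scale <= 0) {
    stop_config("base_weight and decay_scale must be positive")
  }
  if (subject_noise_cv < 0) stop_config("subject_noise_cv must be >= 0")
  structure(list(n_nodes = as.integer(n_nodes),
                 n_controls = as.integer(n_controls),
                 base_weight = base_weight, decay_scale = decay_scale,
                 density = density, subject_noise_cv = subject_noise_cv,
                 icv_mean = icv_mean, icv_sd = icv_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Mirror-symmetric node geometry: centroids sampled uniformly inside a
# brain-sized half-ellipsoid (semi-axes 70 x 85 x 60 mm, x is left-right)
# and reflected across the midsagittal plane; odd counts add midline nodes.
sample_geometry <- function(n_nodes) {
  n_right <- n_nodes %/% 2
  n_mid <- n_nodes - 2 * n_right
  semi <- c(70, 85, 60)
  draw_in_ellipsoid <- function(k, x_min = 0) {
    out <- matrix(NA_real_, 0, 3)
    while (nrow(out) < k) {
      cand <- cbind(runif(4 * k, x_min, 1), runif(4 * k, -1, 1),
                    runif(4 * k, -1, 1))
      keep <- rowSums(cand^2) <= 1
      out <- rbind(out, cand[keep, , drop = FALSE])
    }
    sweep(out[seq_len(k), , drop = FALSE], 2, semi, `*`)
  }
  right <- draw_in_ellipsoid(n_right, x_min = 0.08)
  coords <- rbind(right * cbind(rep(-1, n_right), 1, 1), right)
  hemi <- c(rep("left", n_right), rep("right", n_right))
  lab <- c(sprintf("region_%02d_L", seq_len(n_right)),
           sprintf("region_%02d_R", seq_len(n_right)))
  if (n_mid > 0) {
    mid <- draw_in_ellipsoid(n_mid)
    mid[, 1] <- 0
    coords <- rbind(coords, mid)
    hemi <- c(hemi, rep("midline", n_mid))
    lab <- c(lab, sprintf("region_%02d_M", seq_len(n_mid)))
  }
  tibble::tibble(index = seq_len(n_nodes) - 1L, label = lab,
                 hemisphere = hemi,
                 x = coords[, 1], y = coords[, 2], z = coords[, 3])
}

#' Generate the synthetic template connectome and node table
#'
#' Template edge weights follow a distance decay,
#' `w_ij = base_weight * exp(-dist_ij / decay_scale)`, thresholded to the
#' target density by keeping the strongest candidate edges. Deterministic
#' given the configured seed.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `weights` (template connectivity matrix) and `nodes`
#'   (node table).
#' @export
generate_template <- function(cfg) {
  with_seed(cfg$seed, {
    nodes <- sample_geometry(cfg$n_nodes)
    geo <- as.matrix(stats::dist(as.matrix(nodes[, c("x", "y", "z")])))
    w <- cfg$base_weight * exp(-geo / cfg$decay_scale)
    diag(w) <- 0
    m <- cfg$n_nodes * (cfg$n_nodes - 1) / 2
    n_keep <- round(cfg$density * m)
    if (n_keep < 1) stop_config("density keeps no edges at this size")
    ut <- w[upper.tri(w)]
    if (n_keep < m) {
      thr <- sort(ut, decreasing = TRUE)[n_keep]
      w[w < thr] <- 0
    }
    diag(w) <- 0
    list(weights = as_connectome(w, subject_id = "template"), nodes = nodes)
  })
}

lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a healthy-control cohort from a template
#'
#' Each control is the template multiplied, edge by edge (symmetrically), by
#' lognormal noise with mean 1 and the configured coefficient of variation.
#' Also draws a per-subject total intracranial volume.
#'
#' @param template Output of [generate_template()].
#' @param cfg A [synthetic_config()].
#' @param ids Optional subject ids (default `control_01`, ...).
#' @return Named list of control connectivity matrices, each with an `icv`
#'   attribute.
#' @export
generate_cohort <- function(template, cfg, ids = NULL) {
  w0 <- template$weights
  n <- nrow(w0)
  if (is.null(ids)) ids <- sprintf("control_%02d", seq_len(cfg$n_controls))
  with_seed(cfg$seed + 1L, {
    lapply(stats::setNames(seq_along(ids), ids), function(k) {
      noise <- matrix(1, n, n)
      ut <- upper.tri(noise)
      noise[ut] <- lognormal_noise(sum(ut), cfg$subject_noise_cv)
      noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
      icv <- max(rnorm(1, cfg$icv_mean, cfg$icv_sd), cfg$icv_mean / 2)
      as_connectome(w0 * noise, subject_id = ids[[k]], icv = icv)
    })
  })
}

#' Inject a focal lesion into a connectome
#'
#' Models the network consequence of a focal lesion at the matrix level: all
#' edges incident to the target nodes are attenuated by a factor `a` (or
#' zeroed when `severed = TRUE`). Targets are given either as 0-based node
#' indices or as a spatial center + radius in mm against the node table. The
#' returned mask marks exactly the effectively altered edges (nonzero weight,
#' `a < 1` or severed) in the upper triangle.
#'
#' @param w Connectivity matrix of the pre-lesion subject.
#' @param target_nodes Integer vector of 0-based node indices.
#' @param center,radius Alternative spatial target: nodes within `radius` mm
#'   of `center` (length-3, mm); requires `nodes`.
#' @param nodes Node table (needed for `center`/`radius` targeting).
#' @param attenuation Multiplier `a` in `[0, 1]` (default 0.3).
#' @param severed Zero out instead of attenuating.
#' @return List with `weights` (lesioned matrix), `mask` (logical N x N,
#'   upper triangle marks altered edges), and `target_nodes` (0-based).
#' @export
inject_lesion <- function(w, target_nodes = NULL, center = NULL,
                          radius = NULL, nodes = NULL,
                          attenuation = 0.3, severed = FALSE) {
  n <- nrow(w)
  if (is.null(target_nodes)) {
    if (is.null(center) || is.null(radius) || is.null(nodes)) {
      stop_value("give target_nodes, or center + radius + nodes")
    }
    d <- sqrt(colSums((t(as.matrix(nodes[, c("x", "y", "z")])) - center)^2))
    target_nodes <- which(d <= radius) - 1L
  }
  if (length(target_nodes) == 0L) {
    stop_value("lesion has no target nodes")
  }
  if (any(target_nodes < 0 | target_nodes >= n)) {
    stop_value("lesion target node index out of range")
  }
  if (!(attenuation >= 0 && attenuation <= 1)) {
    stop_value("attenuation must be in [0, 1]")
  }
  t1 <- target_nodes + 1L
  a <- if (severed) 0 else attenuation
  hit <- matrix(FALSE, n, n)
  hit[t1, ] <- TRUE
  hit[, t1] <- TRUE
  diag(hit) <- FALSE
  out <- w
  out[hit] <- out[hit] * a
  mask <- hit & (w > 0) & (a < 1)
  mask[lower.tri(mask, diag = TRUE)] <- FALSE
  list(weights = as_connectome(out,
                               subject_id = paste0(attr(w, "subject_id"),
                                                   "_lesioned"),
                               icv = attr(w, "icv")),
       mask = mask, target_nodes = sort(as.integer(target_nodes)))
}

#' Write a complete synthetic study to disk
#'
#' Generates the template, the control cohort, and a patient (optionally
#' lesioned), writes the matrices, node table, a ready-to-use YAML manifest,
#' and a ground-truth JSON (lesion targets and altered edges), and returns the
#' paths.
#'
#' @param dir Output directory (created if missing).
#' @param cfg A [synthetic_config()]; presets: `"default84"` uses the
#'   defaults, `"tiny10"` a 10-node, 6-control cohort for fast tests.
#' @param preset Optional preset name overriding `cfg`.
#' @param lesion `NULL` for a non-lesioned patient, or a list with any of
#'   `target_nodes`, `attenuation`, `severed`, `n_targets` (random targets).
#' @return List with `manifest` (path), `cohort` (loaded `graphme_cohort`),
#'   and `ground_truth`.
#' @export
simulate_cohort <- function(dir, cfg = synthetic_config(),
                            preset = NULL, lesion = NULL) {
  if (!is.null(preset)) {
    cfg <- switch(preset,
      default84 = synthetic_config(seed = cfg$seed),
      tiny10 = synthetic_config(n_nodes = 10, n_controls = 6,
                                density = 0.6, seed = cfg$seed),
      stop_config(paste0("unknown preset: ", preset)))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  template <- generate_template(cfg)
  controls <- generate_cohort(template, cfg)
  patient0 <- generate_cohort(template, synthetic_config(
    n_nodes = cfg$n_nodes, n_controls = 2, base_weight = cfg$base_weight,
    decay_scale = cfg$decay_scale, density = cfg$density,
    subject_noise_cv = cfg$subject_noise_cv, icv_mean = cfg$icv_mean,
    icv_sd = cfg$icv_sd, seed = cfg$seed + 1000L),
    ids = c("patient", "unused"))[["patient"]]
  gt <- list(lesion = FALSE)
  if (!is.null(lesion)) {
    targets <- lesion$target_nodes
    if (is.null(targets)) {
      n_t <- lesion$n_targets %||% 4L
      targets <- with_seed(cfg$seed + 2000L,
                           sort(sample.int(cfg$n_nodes, n_t) - 1L))
    }
    les <- inject_lesion(patient0, target_nodes = targets,
                         attenuation = lesion$attenuation %||% 0.3,
                         severed = isTRUE(lesion$severed))
    patient0 <- les$weights
    attr(patient0, "subject_id") <- "patient"
    idx <- which(les$mask, arr.ind = TRUE)
    gt <- list(lesion = TRUE, target_nodes = les$target_nodes,
               attenuation = lesion$attenuation %||% 0.3,
               severed = isTRUE(lesion$severed),
               altered_edges = data.frame(i = idx[, "row"] - 1L,
                                          j = idx[, "col"] - 1L))
  }
  write_node_table(template$nodes, file.path(dir, "nodes.csv"))
  ctl_files <- character(0)
  icv_map <- list()
  for (id in names(controls)) {
    f <- paste0(id, ".csv")
    write_connectivity_matrix(controls[[id]], file.path(dir, f))
    ctl_files <- c(ctl_files, f)
    icv_map[[id]] <- attr(controls[[id]], "icv")
  }
  write_connectivity_matrix(patient0, file.path(dir, "patient.csv"))
  icv_map[["patient"]] <- attr(patient0, "icv")
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(node_table = "nodes.csv",
                        controls = as.list(ctl_files),
                        patient = "patient.csv",
                        icv = icv_map), manifest)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  cohort <- suppressMessages(suppressWarnings(load_cohort(manifest)))
  list(manifest = manifest, cohort = cohort, ground_truth = gt,
       config = cfg)
}
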