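#' Run the full single-subject profiling pipeline
#'
#' Loads a cohort manifest, computes the eight-metric profile for the patient
#' and every control, builds the GraphMe profile report and radar plot,
#' runs the regional deviation analysis (edgewise and nodewise z-scores with
#' FDR, hub comparison), and writes all outputs plus a run log recording
#' every parameter. Repeated runs with the same manifest and seed produce
#' identical numeric outputs.
#'
#' @param manifest Path to a cohort manifest (see [load_cohort()]), or an
#'   already-loaded `graphme_cohort`.
#' @param out_dir Output directory (created if missing).
#' @param seed Seed controlling the null-model ensemble.
#' @param icv_mode,ci_method See [graphme_profile()].
#' @param fdr_q,hub_fraction,reference_hubs See [connectome_deviation()].
#' @param n_nulls,rewires_per_edge See [normalized_clustering()].
#' @param plot_format `"png"`, `"svg"`, or `"pdf"`.
#' @return List (invisible) with the computed `profile`, `deviation`,
#'   `patient_metrics`, `control_metrics`, and the output `files`.
#' @export
run_full_profile <- function(manifest, out_dir, seed = 1L,
                             icv_mode = "none", ci_method = "t_mean",
                             fdr_q = 0.05, hub_fraction = 0.10,
                             reference_hubs = "group_average",
                             n_nulls = 100, rewires_per_edge = 10,
                             plot_format = "png") {
  cohort <- if (inherits(manifest, "graphme_cohort")) {
    manifest
  } else {
    load_cohort(manifest)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prof_of <- function(w) {
    connectome_metrics(w, nodes = cohort$nodes, n_nulls = n_nulls,
                       rewires_per_edge = rewires_per_edge, seed = seed)
  }
  patient_metrics <- prof_of(cohort$patient)
  control_metrics <- lapply(cohort$controls, prof_of)
  profile <- graphme_profile(patient_metrics, control_metrics,
                             icv_mode = icv_mode, ci_method = ci_method)
  deviation <- connectome_deviation(cohort$patient, cohort$controls,
                                    nodes = cohort$nodes, fdr_q = fdr_q,
                                    hub_fraction = hub_fraction,
                                    reference_hubs = reference_hubs)
  files <- list(
    report = file.path(out_dir, "profile_report.json"),
    plot = file.path(out_dir, paste0("graphme.", plot_format)),
    edges = file.path(out_dir, "edges.csv"),
    nodes = file.path(out_dir, "nodes.csv"),
    summary = file.path(out_dir, "summary.json"),
    metrics = file.path(out_dir, "subject_metrics.csv"),
    log = file.path(out_dir, "run_log.txt"))
  write_profile_report(profile, files$report)
  render_graphme(profile, files$plot)
  write_edge_csv(deviation, files$edges)
  write_node_csv(deviation, files$nodes)
  write_metrics_csv(c(list(patient_metrics), unname(control_metrics)),
                    files$metrics)
  summary <- c(as.list(deviation$summary),
               list(hubs_gained = deviation$hub_changes$gained,
                    hubs_lost = deviation$hub_changes$lost))
  jsonlite::write_json(summary, files$summary, auto_unbox = TRUE, digits = NA)
  params <- list(manifest = if (is.character(manifest)) manifest else "<cohort>",
                 out_dir = out_dir, seed = seed, icv_mode = icv_mode,
                 ci_method = ci_method, fdr_q = fdr_q,
                 hub_fraction = hub_fraction,
                 reference_hubs = reference_hubs, n_nulls = n_nulls,
                 rewires_per_edge = rewires_per_edge,
                 plot_format = plot_format,
                 n_regions = cohort$n, n_controls = length(cohort$controls),
                 patient = attr(cohort$patient, "subject_id"))
  writeLines(c("graphme run parameters",
               sprintf("  %s = %s", names(params),
                       vapply(params, function(v) {
                         paste(format(v, digits = 12), collapse = ",")
                       }, character(1)))),
             files$log)
  invisible(list(profile = profile, deviation = deviation,
                 patient_metrics = patient_metrics,
                 control_metrics = control_metrics, files = files))
}

#' Write the GraphMe profile report as JSON
#'
#' Schema: `{subject, ci_method, icv_mode, metrics: {name: {raw, displayed,
#' band: [lo, hi], category}}}`.
#'
#' @param profile A `graphme_profile`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_profile_report <- function(profile, path) {
  metrics <- stats::setNames(lapply(seq_len(nrow(profile)), function(k) {
    list(raw = profile$raw[k], displayed = profile$displayed[k],
         band = c(profile$ci_low[k], profile$ci_high[k]),
         control_mean = profile$control_mean[k],
         category = profile$category[k])
  }), profile$metric)
  jsonlite::write_json(list(subject = attr(profile, "subject_id"),
                            ci_method = attr(profile, "ci_method"),
                            icv_mode = attr(profile, "icv_mode"),
                            n_controls = attr(profile, "n_controls"),
                            metrics = metrics),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the deviation edge list as CSV
#'
#' One row per tested upper-triangle edge with 1-based node numbers, labels
#' when available, weight, z, p, adjusted q, and significance.
#'
#' @param deviation A `connectome_deviation`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_edge_csv <- function(deviation, path) {
  e <- deviation$edges
  out <- data.frame(node_i = e$i + 1L, node_j = e$j + 1L,
                    node_i_label = e$node_i_label %||% paste0("node_", e$i + 1L),
                    node_j_label = e$node_j_label %||% paste0("node_", e$j + 1L),
                    weight = e$weight, z = e$z, p = e$p, q = e$q_value,
                    significant = e$significant, sign = e$sign)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the deviation node list as CSV
#'
#' @inheritParams write_edge_csv
#' @return `path`, invisibly.
#' @export
write_node_csv <- function(deviation, path) {
  nd <- deviation$nodes
  out <- data.frame(node = nd$index + 1L,
                    label = nd$label %||% paste0("node_", nd$index + 1L),
                    strength = nd$strength, strength_z = nd$z,
                    p = nd$p, q = nd$q_value, significant = nd$significant,
                    betweenness = nd$betweenness, is_hub = nd$is_hub)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the per-subject metric table as CSV
#'
#' One row per subject with the eight global metrics, the unreachable-pair
#' count, and the null-model seed.
#'
#' @param profiles List of `metric_profile` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(profiles, path) {
  rows <- dplyr::bind_rows(lapply(profiles, glance))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
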