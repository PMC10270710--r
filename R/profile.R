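#' Transform a metric profile for display
#'
#' Characteristic path length, normalized clustering, and mean betweenness
#' are "lower is better" metrics; they are inverted (`1/x`) so that a larger
#' value on every radar axis reads as better network structure. Head-size
#' correction is then applied to every metric according to `icv_mode`:
#' `"none"` (default; appropriate for synthetic cohorts), `"divide"`
#' (metric / ICV, the conventional size correction), or `"multiply"`
#' (metric * ICV). The same transform must be applied to patient and
#' controls before banding.
#'
#' @param values Named vector of the eight metrics (see
#'   [connectome_metrics()]) or a `metric_profile`.
#' @param icv Total intracranial volume, mm^3 (required unless
#'   `icv_mode = "none"`; taken from the profile when available).
#' @param icv_mode One of `"none"`, `"divide"`, `"multiply"`.
#' @return Named vector of displayed metric values.
#' @export
display_transform <- function(values, icv = NULL,
                              icv_mode = c("none", "divide", "multiply")) {
  icv_mode <- match.arg(icv_mode)
  if (inherits(values, "metric_profile")) {
    icv <- icv %||% values$icv
    values <- values$globals
  }
  stopifnot(all(metric_names() %in% names(values)))
  values <- values[metric_names()]
  inv <- inverted_metrics()
  if (any(!is.na(values[inv]) & values[inv] == 0)) {
    stop_metric_undefined("cannot invert a zero-valued metric for display")
  }
  values[inv] <- 1 / values[inv]
  if (icv_mode != "none") {
    if (is.null(icv)) {
      stop_config(sprintf("icv_mode = '%s' requires an ICV value", icv_mode))
    }
    values <- switch(icv_mode, divide = values / icv, multiply = values * icv)
  }
  values
}

#' Healthy-control reference band
#'
#' Per-metric control mean with a 95% interval, computed on display-transformed
#' control profiles. `ci_method` selects the interval: `"t_mean"` (default)
#' is the t-based confidence interval of the mean,
#' `mean +- t(0.975, n-1) * sd / sqrt(n)`; `"normal_mean"` uses 1.96 in place
#' of the t quantile; `"prediction"` is the t prediction interval for one new
#' individual, `mean +- t(0.975, n-1) * sd * sqrt(1 + 1/n)`, the statistically
#' appropriate choice when classifying a single patient.
#'
#' @param control_values Matrix or data frame of transformed control profiles,
#'   one row per control, columns named by metric; or a list of
#'   `metric_profile` objects (then `icv`/`icv_mode` apply).
#' @param ci_method One of `"t_mean"`, `"normal_mean"`, `"prediction"`.
#' @inheritParams display_transform
#' @return A tibble (class `reference_band`) with columns `metric`, `mean`,
#'   `ci_low`, `ci_high`, `n_controls`.
#' @export
reference_band <- function(control_values,
                           ci_method = c("t_mean", "normal_mean", "prediction"),
                           icv = NULL, icv_mode = "none") {
  ci_method <- match.arg(ci_method)
  if (is.list(control_values) && !is.data.frame(control_values) &&
      inherits(control_values[[1]], "metric_profile")) {
    control_values <- do.call(rbind, lapply(control_values, function(p) {
      display_transform(p, icv = icv, icv_mode = icv_mode)
    }))
  }
  control_values <- as.matrix(control_values)
  n <- nrow(control_values)
  if (n < 2) stop_cohort("reference band needs at least 2 control profiles")
  mu <- colMeans(control_values)
  s <- apply(control_values, 2, sd)
  if (any(s == 0)) {
    warn(paste0("zero-variance metric(s): band collapses to the mean for ",
                paste(colnames(control_values)[s == 0], collapse = ", ")),
         class = "graphme_zero_variance_warning")
  }
  half <- switch(ci_method,
    t_mean = qt(0.975, n - 1) * s / sqrt(n),
    normal_mean = 1.96 * s / sqrt(n),
    prediction = qt(0.975, n - 1) * s * sqrt(1 + 1 / n))
  structure(tibble::tibble(metric = colnames(control_values),
                           mean = unname(mu),
                           ci_low = unname(mu - half),
                           ci_high = unname(mu + half),
                           n_controls = n),
            class = c("reference_band", "tbl_df", "tbl", "data.frame"),
            ci_method = ci_method)
}

#' Categorize a metric value against the reference band
#'
#' `infra-normal` below the interval, `supra-normal` above it, `normal`
#' within it; the interval boundaries count as normal.
#'
#' @param value Displayed metric value(s).
#' @param ci_low,ci_high Band limits (recycled against `value`).
#' @return Character vector in `{"infra-normal", "normal", "supra-normal"}`.
#' @export
categorize_metric <- function(value, ci_low, ci_high) {
  ifelse(value < ci_low, "infra-normal",
         ifelse(value > ci_high, "supra-normal", "normal"))
}

#' Build the GraphMe profile report for one patient
#'
#' Display-transforms the patient and control profiles identically, builds the
#' control reference band, and categorizes each of the eight metrics.
#'
#' @param patient_profile `metric_profile` of the patient.
#' @param control_profiles List of control `metric_profile`s.
#' @param icv_table Optional named vector/list of ICV per subject id (falls
#'   back to the ICV stored on each profile).
#' @inheritParams display_transform
#' @inheritParams reference_band
#' @return An object of class `graphme_profile`: a tibble with columns
#'   `metric`, `raw`, `displayed`, `control_mean`, `ci_low`, `ci_high`,
#'   `category`.
#' @export
graphme_profile <- function(patient_profile, control_profiles,
                            icv_mode = "none", ci_method = "t_mean",
                            icv_table = NULL) {
  get_icv <- function(p) {
    icv_table[[p$subject_id]] %||% p$icv
  }
  band <- reference_band(
    do.call(rbind, lapply(control_profiles, function(p) {
      display_transform(p, icv = get_icv(p), icv_mode = icv_mode)
    })),
    ci_method = ci_method)
  displayed <- display_transform(patient_profile,
                                 icv = get_icv(patient_profile),
                                 icv_mode = icv_mode)
  raw <- unname(patient_profile$globals[metric_names()])
  disp <- unname(displayed[metric_names()])
  ord <- match(metric_names(), band$metric)
  out <- tibble::tibble(
    metric = metric_names(),
    raw = raw,
    displayed = disp,
    control_mean = band$mean[ord],
    ci_low = band$ci_low[ord],
    ci_high = band$ci_high[ord],
    category = categorize_metric(disp, band$ci_low[ord], band$ci_high[ord]))
  structure(out,
            class = c("graphme_profile", "tbl_df", "tbl", "data.frame"),
            subject_id = patient_profile$subject_id,
            icv_mode = icv_mode, ci_method = ci_method,
            n_controls = length(control_profiles))
}

#' @export
print.graphme_profile <- function(x, ...) {
  cat(sprintf("<graphme_profile> patient '%s' vs %d controls (%s, icv %s)\n",
              attr(x, "subject_id"), attr(x, "n_controls"),
              attr(x, "ci_method"), attr(x, "icv_mode")))
  NextMethod()
}

#' @rdname graphme_profile
#' @param x A `graphme_profile`.
#' @param ... Unused.
#' @method glance graphme_profile
#' @export
glance.graphme_profile <- function(x, ...) {
  tibble::tibble(subject_id = attr(x, "subject_id"),
                 n_controls = attr(x, "n_controls"),
                 ci_method = attr(x, "ci_method"),
                 icv_mode = attr(x, "icv_mode"),
                 n_normal = sum(x$category == "normal"),
                 n_infra = sum(x$category == "infra-normal"),
                 n_supra = sum(x$category == "supra-normal"))
}

# Rescale each metric axis to [0, 1] against the spread of everything that
# must be visible on it (band and patient), so the eight heterogeneous scales
# share one radar.
scale_axes <- function(report) {
  lo <- pmin(report$ci_low, report$displayed)
  hi <- pmax(report$ci_high, report$displayed)
  span <- hi - lo
  span[span == 0] <- 1
  pad <- 0.15 * span
  lo <- lo - pad
  span <- span + 2 * pad
  dplyr::mutate(report,
                axis_patient = (.data$displayed - lo) / span,
                axis_mean = (.data$control_mean - lo) / span,
                axis_low = (.data$ci_low - lo) / span,
                axis_high = (.data$ci_high - lo) / span)
}

#' Radar (GraphMe) plot of a patient profile
#'
#' Eight axes, one per metric, each scaled to the control distribution; the
#' blue shade is the 95% interval, the dark-blue polygon the control mean,
#' and the red polygon the patient.
#'
#' @param object A `graphme_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot graphme_profile
#' @export
autoplot.graphme_profile <- function(object, ...) {
  rpt <- scale_axes(object)
  k <- nrow(rpt)
  rpt$angle <- 2 * pi * (seq_len(k) - 1) / k
  close_poly <- function(df) df[c(seq_len(nrow(df)), 1), ]
  xy <- function(r, a) list(x = r * sin(a), y = r * cos(a))
  band <- close_poly(rpt)
  ring <- close_poly(rpt)
  pat <- close_poly(rpt)
  band_poly <- rbind(
    data.frame(x = xy(band$axis_high, band$angle)$x,
               y = xy(band$axis_high, band$angle)$y),
    data.frame(x = rev(xy(band$axis_low, band$angle)$x),
               y = rev(xy(band$axis_low, band$angle)$y)))
  spokes <- data.frame(x = 0, y = 0,
                       xend = 1.05 * sin(rpt$angle),
                       yend = 1.05 * cos(rpt$angle))
  labels <- data.frame(x = 1.22 * sin(rpt$angle), y = 1.22 * cos(rpt$angle),
                       metric = gsub("_", "\n", rpt$metric))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = spokes,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          color = "grey80") +
    ggplot2::geom_polygon(data = band_poly,
                          ggplot2::aes(.data$x, .data$y),
                          fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_path(data = data.frame(xy(ring$axis_mean, ring$angle)),
                       ggplot2::aes(.data$x, .data$y),
                       color = "darkblue", linewidth = 0.8) +
    ggplot2::geom_path(data = data.frame(xy(pat$axis_patient, pat$angle)),
                       ggplot2::aes(.data$x, .data$y),
                       color = "red", linewidth = 0.9) +
    ggplot2::geom_point(data = data.frame(xy(rpt$axis_patient, rpt$angle)),
                        ggplot2::aes(.data$x, .data$y), color = "red") +
    ggplot2::geom_text(data = labels,
                       ggplot2::aes(.data$x, .data$y, label = .data$metric),
                       size = 3, lineheight = 0.8) +
    ggplot2::coord_equal(xlim = c(-1.45, 1.45), ylim = c(-1.45, 1.45)) +
    ggplot2::theme_void() +
    ggplot2::ggtitle(paste0("GraphMe profile: ", attr(object, "subject_id")))
}

#' Render the GraphMe plot to a file
#'
#' The device is chosen from the file extension (`.png`, `.svg`, or `.pdf`).
#'
#' @param report A `graphme_profile`.
#' @param path Output image path.
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
render_graphme <- function(report, path, width = 7, height = 7) {
  p <- autoplot(report)
  ext <- tolower(sub(".*\\.", "", path))
  ok <- try({
    switch(ext,
      png = grDevices::png(path, width = width, height = height,
                           units = "in", res = 150),
      svg = grDevices::svg(path, width = width, height = height),
      pdf = grDevices::pdf(path, width = width, height = height),
      stop_config(paste0("unsupported image format: .", ext)))
    print(p)
    grDevices::dev.off()
  }, silent = TRUE)
  if (inherits(ok, "try-error") || !file.exists(path)) {
    abort(paste0("could not write plot to ", path), class = "graphme_io_error")
  }
  invisible(path)
}
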