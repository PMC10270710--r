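#' Read a connectivity matrix from delimited text
#'
#' Connectome matrices are square, symmetric, non-negative weight tables
#' (here: SIFT2-filtered streamline counts) written without a header row.
#' Comma, tab, and whitespace delimiters are auto-detected. The diagonal is
#' forced to zero and round-off asymmetry up to a relative tolerance of 1e-6
#' is repaired by averaging `(A + t(A)) / 2`; larger asymmetry is an error.
#'
#' @param path Path to a delimited text file holding an N x N numeric table.
#' @param delimiter `NULL` for auto-detection, or a single delimiter character.
#' @param subject_id Subject identifier attached to the matrix; defaults to
#'   the file name without extension.
#' @param icv Optional total intracranial volume (mm^3) for this subject.
#' @return A numeric N x N matrix with attributes `subject_id` and `icv`,
#'   validated symmetric with a zero diagonal.
#' @export
read_connectivity_matrix <- function(path, delimiter = NULL,
                                     subject_id = NULL, icv = NULL) {
  if (!file.exists(path)) stop_value(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_format(paste0("empty matrix file: ", path))
  if (is.null(delimiter)) {
    delimiter <- if (grepl(",", lines[[1]], fixed = TRUE)) {
      ","
    } else if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ""
  }
  rows <- lapply(lines, function(l) {
    fields <- if (identical(delimiter, "")) {
      strsplit(trimws(l), "[[:space:]]+")[[1]]
    } else {
      strsplit(l, delimiter, fixed = TRUE)[[1]]
    }
    suppressWarnings(as.numeric(fields))
  })
  ncols <- vapply(rows, length, integer(1))
  if (length(unique(ncols)) != 1L) {
    stop_format("ragged rows: matrix file is not a rectangular table")
  }
  w <- do.call(rbind, rows)
  if (anyNA(w)) stop_format("non-numeric entries in matrix file")
  if (nrow(w) != ncol(w)) {
    stop_format(sprintf("matrix is not square: %d x %d", nrow(w), ncol(w)))
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  as_connectome(w, subject_id = subject_id, icv = icv)
}

#' Validate a weight matrix as a connectome
#'
#' @param w Square numeric matrix of non-negative edge weights.
#' @inheritParams read_connectivity_matrix
#' @return The validated matrix (zero diagonal, exactly symmetric) with
#'   `subject_id` and `icv` attributes.
#' @export
as_connectome <- function(w, subject_id = "subject", icv = NULL) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) stop_format("connectivity matrix must be square")
  if (!all(is.finite(w))) stop_value("connectivity matrix has non-finite entries")
  if (any(w < 0)) stop_value("connectivity matrix has negative weights")
  mx <- max(w)
  asym <- max(abs(w - t(w)))
  if (mx > 0 && asym / mx > 1e-6) {
    stop_symmetry(sprintf(
      "asymmetry beyond tolerance: max|A - t(A)|/max(A) = %.3g", asym / mx))
  }
  w <- (w + t(w)) / 2
  diag(w) <- 0
  zero_rows <- which(rowSums(w) == 0)
  if (length(zero_rows) > 0 && nrow(w) > 1) {
    warn(sprintf("%d fully disconnected node(s): %s",
                 length(zero_rows),
                 paste(zero_rows, collapse = ", ")),
         class = "graphme_disconnected_warning")
  }
  dimnames(w) <- NULL
  attr(w, "subject_id") <- subject_id
  if (!is.null(icv)) {
    if (!is.numeric(icv) || length(icv) != 1L || !is.finite(icv) || icv <= 0) {
      stop_value("icv must be a single positive number (mm^3)")
    }
    attr(w, "icv") <- as.numeric(icv)
  }
  w
}

#' Write a connectivity matrix to delimited text
#'
#' Values are written at 12 significant digits so that reading the file back
#' reproduces the matrix to that precision.
#'
#' @param w Connectivity matrix.
#' @param path Output file path.
#' @param delimiter Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_connectivity_matrix <- function(w, path, delimiter = ",") {
  txt <- apply(w, 1, function(r) {
    paste(formatC(r, digits = 12, format = "g"), collapse = delimiter)
  })
  writeLines(txt, path)
  invisible(path)
}

#' Read a node table
#'
#' The node table names the parcellation regions (for the reference analyses,
#' the 84 cortical and subcortical regions of the Desikan-Killiany atlas) and
#' carries the centroid coordinates in mm that greedy geometric navigation
#' requires. Expected header columns: `index,label,hemisphere,x,y,z` with
#' contiguous 0-based indices, unique labels, hemisphere in
#' `left`/`right`/`midline`, and finite coordinates.
#'
#' @param path CSV file path.
#' @return A tibble with columns `index`, `label`, `hemisphere`, `x`, `y`, `z`.
#' @export
read_node_table <- function(path) {
  if (!file.exists(path)) stop_value(paste0("file not found: ", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_node_table(tibble::as_tibble(df))
}

validate_node_table <- function(df) {
  needed <- c("index", "label", "hemisphere", "x", "y", "z")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop_format(paste0("node table missing column(s): ",
                       paste(missing, collapse = ", ")))
  }
  df <- df[needed]
  n <- nrow(df)
  if (n < 3) stop_value("node table needs at least 3 regions")
  if (!identical(sort(as.integer(df$index)), 0:(n - 1))) {
    stop_value("node indices must be contiguous 0..N-1")
  }
  df <- df[order(df$index), ]
  if (anyDuplicated(df$label)) {
    stop_value(paste0("duplicate region label(s): ",
                      paste(unique(df$label[duplicated(df$label)]),
                            collapse = ", ")))
  }
  if (!all(df$hemisphere %in% c("left", "right", "midline"))) {
    stop_value("hemisphere must be one of left, right, midline")
  }
  coords <- as.matrix(df[, c("x", "y", "z")])
  if (!is.numeric(coords) || !all(is.finite(coords))) {
    stop_value("node coordinates must all be finite numbers (mm)")
  }
  df$index <- as.integer(df$index)
  tibble::as_tibble(df)
}

#' Write a node table
#'
#' @param nodes Node table as returned by [read_node_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_node_table <- function(nodes, path) {
  write.csv(nodes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a patient-versus-controls cohort from a manifest
#'
#' The manifest is a YAML (or JSON) file with keys `node_table` (path),
#' `controls` (list of matrix paths), `patient` (matrix path), and an optional
#' `icv` mapping of subject id to total intracranial volume in mm^3. Paths are
#' resolved relative to the manifest location. All matrices must share the
#' node-table dimension and at least two controls are required so that a
#' per-edge standard deviation exists.
#'
#' @param manifest Path to the manifest file.
#' @return An object of class `graphme_cohort`: a list with elements
#'   `patient`, `controls` (named list), `nodes`, and `n`.
#' @export
load_cohort <- function(manifest) {
  if (!file.exists(manifest)) stop_value(paste0("file not found: ", manifest))
  spec <- yaml::read_yaml(manifest)
  for (key in c("node_table", "controls", "patient")) {
    if (is.null(spec[[key]])) {
      stop_format(paste0("manifest missing key: ", key))
    }
  }
  base <- dirname(normalizePath(manifest))
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(base, p)
  }
  icv_map <- spec$icv %||% list()
  nodes <- read_node_table(resolve(spec$node_table))
  n <- nrow(nodes)
  read_one <- function(p) {
    id <- sub("\\.[^.]*$", "", basename(p))
    m <- read_connectivity_matrix(resolve(p), subject_id = id,
                                  icv = icv_map[[id]])
    if (nrow(m) != n) {
      stop_dimension(sprintf(
        "matrix %s is %d x %d but node table has %d regions",
        id, nrow(m), ncol(m), n))
    }
    m
  }
  if (length(spec$controls) < 2) {
    stop_cohort("at least 2 control matrices are required")
  }
  controls <- lapply(unlist(spec$controls), read_one)
  names(controls) <- vapply(controls, attr, character(1), "subject_id")
  patient <- read_one(spec$patient)
  if (attr(patient, "subject_id") %in% names(controls)) {
    stop_cohort("patient id also appears among the controls")
  }
  message(sprintf("cohort loaded: N = %d regions, %d controls, patient '%s'",
                  n, length(controls), attr(patient, "subject_id")))
  structure(list(patient = patient, controls = controls,
                 nodes = nodes, n = n),
            class = "graphme_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.graphme_cohort <- function(x, ...) {
  cat(sprintf("<graphme_cohort> %d regions, %d controls, patient '%s'\n",
              x$n, length(x$controls), attr(x$patient, "subject_id")))
  invisible(x)
}
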