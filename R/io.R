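# File formats: event histograms as a versioned plain-text named-dataset
# container, reduced profiles as '#'-commented delimited text, run
# configuration as YAML.  All round-trips are lossless (integer counts
# exact; profile floats at 9 significant digits).

HIST_FORMAT_VERSION <- 1L
PROFILE_FORMAT_VERSION <- 1L

#' Write an event histogram to a text container file
#'
#' The format is a versioned plain-text container: a header of `key: value`
#' lines (dimensions, exposure, geometry, provenance), an
#' `energy_bin_edges_keV:` dataset line, then a `counts:` dataset holding
#' the integer counts in column-major order of the
#' `[n_rows, n_cols, n_energy_bins]` array (row index varying fastest).
#'
#' @param hist An `event_histogram`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_histogram <- function(hist, path) {
  d <- dim(hist$counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# ssaxs event histogram",
    paste0("format_version: ", HIST_FORMAT_VERSION),
    paste0("n_rows: ", d[1]),
    paste0("n_cols: ", d[2]),
    paste0("n_energy_bins: ", d[3]),
    paste0("exposure_s: ", format(hist$exposure, digits = 15)),
    paste0("pixel_pitch_mm: ", format(hist$geom$pixel_pitch, digits = 15)),
    paste0("sdd_mm: ", format(hist$geom$sdd, digits = 15)),
    paste0("beam_center_row: ", format(hist$geom$beam_center[1], digits = 15)),
    paste0("beam_center_col: ", format(hist$geom$beam_center[2], digits = 15)),
    paste0("template: ", if (is.null(hist$meta$template)) "unknown" else hist$meta$template),
    paste0("seed: ", if (is.null(hist$meta$seed)) "NA" else hist$meta$seed),
    paste0("energy_bin_edges_keV: ",
           paste(format(hist$energy_bin_edges, digits = 15), collapse = " ")),
    "counts:"), con)
  v <- as.vector(hist$counts)
  idx <- seq(1, length(v), by = 20L)
  writeLines(vapply(idx, function(i)
    paste(v[i:min(i + 19L, length(v))], collapse = " "), character(1)), con)
  invisible(path)
}

#' Read an event histogram from a text container file
#'
#' @param path File written by [write_event_histogram()].
#' @return An `event_histogram`.
#' @export
read_event_histogram <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  ci <- which(lines == "counts:")
  if (length(ci) != 1) stop("malformed histogram file: missing 'counts:' dataset")
  hdr <- lines[seq_len(ci - 1L)]
  kv <- regmatches(hdr, regexec("^([A-Za-z0-9_]+):\\s*(.*)$", hdr))
  bad <- which(vapply(kv, length, integer(1)) != 3L)
  if (length(bad)) stop("malformed histogram file: cannot parse header line ", bad[1])
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- vapply(kv, `[`, character(1), 3)
  names(vals) <- keys
  need <- c("format_version", "n_rows", "n_cols", "n_energy_bins",
            "exposure_s", "pixel_pitch_mm", "sdd_mm", "beam_center_row",
            "beam_center_col", "energy_bin_edges_keV")
  miss <- setdiff(need, keys)
  if (length(miss)) stop("malformed histogram file: missing dataset '", miss[1], "'")
  d <- as.integer(vals[c("n_rows", "n_cols", "n_energy_bins")])
  edges <- as.numeric(strsplit(vals[["energy_bin_edges_keV"]], "\\s+")[[1]])
  if (length(edges) != d[3] + 1L)
    stop("malformed histogram file: dataset 'energy_bin_edges_keV' has wrong length")
  counts <- suppressWarnings(
    as.numeric(unlist(strsplit(lines[(ci + 1L):length(lines)], "\\s+"))))
  counts <- counts[!is.na(counts)]
  if (length(counts) != prod(d))
    stop("malformed histogram file: dataset 'counts' has ", length(counts),
         " values, expected ", prod(d))
  geom <- detector_geometry(d[1], d[2],
                            pixel_pitch = as.numeric(vals[["pixel_pitch_mm"]]),
                            sdd = as.numeric(vals[["sdd_mm"]]),
                            beam_center = as.numeric(vals[c("beam_center_row",
                                                            "beam_center_col")]))
  seed <- vals[["seed"]]
  event_histogram(array(counts, dim = d), edges,
                  as.numeric(vals[["exposure_s"]]), geom,
                  meta = list(template = unname(vals[["template"]]),
                              seed = if (is.na(suppressWarnings(as.integer(seed)))) NULL
                                     else as.integer(seed)))
}

#' Write a reduced profile as commented delimited text
#'
#' Header lines prefixed `#` carry provenance (format version, energy
#' window, bin width, seed, totals); data rows are
#' `q_center counts sigma n_cells` at 9 significant digits.
#'
#' @param profile A `qprofile`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_qprofile <- function(profile, path) {
  m <- profile$meta
  hdr <- c(
    "# ssaxs q profile",
    paste0("# format_version: ", PROFILE_FORMAT_VERSION),
    if (!is.null(m$energy_window))
      paste0("# energy_window_keV: ", paste(m$energy_window, collapse = " ")),
    if (!is.null(m$q_bin_width)) paste0("# q_bin_width: ", m$q_bin_width),
    if (!is.null(m$seed)) paste0("# seed: ", m$seed),
    if (!is.null(m$template)) paste0("# template: ", m$template),
    if (!is.null(m$windowed_total)) paste0("# windowed_total: ", m$windowed_total),
    if (!is.null(m$dropped_counts)) paste0("# dropped_counts: ", m$dropped_counts),
    if (!is.null(m$background_scale)) paste0("# background_scale: ",
                                             format(m$background_scale, digits = 9)),
    "# columns: q_center counts sigma n_cells")
  rows <- sprintf("%s %s %s %d",
                  formatC(profile$q, digits = 9, format = "g"),
                  formatC(profile$counts, digits = 9, format = "g"),
                  formatC(profile$sigma, digits = 9, format = "g"),
                  profile$n_cells)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a reduced profile written by [write_qprofile()]
#'
#' @param path Profile text file.
#' @return A `qprofile`.
#' @export
read_qprofile <- function(path) {
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  data_idx <- which(!is_hdr & nzchar(trimws(lines)))
  if (length(data_idx) == 0) stop("malformed profile file: no data rows")
  fields <- strsplit(trimws(lines[data_idx]), "\\s+")
  nf <- vapply(fields, length, integer(1))
  if (any(nf != 4L))
    stop("parse error in profile file at line ", data_idx[which(nf != 4L)[1]],
         ": expected 4 fields (q_center counts sigma n_cells)")
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 4,
              byrow = TRUE)
  if (any(!is.finite(m[, c(1, 4)])))
    stop("parse error in profile file: non-numeric q_center or n_cells")
  if (is.unsorted(m[, 1], strictly = TRUE))
    stop("validation error: q_center column must be strictly increasing")
  meta <- list()
  hdr <- lines[is_hdr]
  grab <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(hit)) trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1])) else NULL
  }
  for (key in c("seed", "template", "windowed_total", "dropped_counts",
                "q_bin_width", "background_scale")) {
    v <- grab(key)
    if (!is.null(v)) {
      num <- suppressWarnings(as.numeric(v))
      meta[[key]] <- if (is.na(num)) v else num
    }
  }
  ew <- grab("energy_window_keV")
  if (!is.null(ew)) meta$energy_window <- as.numeric(strsplit(ew, "\\s+")[[1]])
  qprofile(m[, 1], m[, 2], m[, 3], as.integer(m[, 4]), meta = meta)
}

#' Default run configuration
#'
#' Nested configuration covering every pipeline stage; serialize with
#' [write_run_config()] / [read_run_config()] (YAML).
#'
#' @param study `"syringe"` or `"phantom"`.
#' @return Named nested list of class `run_config`.
#' @export
default_run_config <- function(study = c("syringe", "phantom")) {
  study <- match.arg(study)
  cfg <- list(
    format_version = 1L,
    geometry = list(n_rows = 80L, n_cols = 80L, pixel_pitch_mm = 0.25,
                    sdd_mm = 214, beam_center_row = 39.5,
                    beam_center_col = 39.5),
    spectrum = list(kvp = 50, e_min = 5, bin_width = 1),
    acquisition = list(exposure = if (study == "syringe") 600 else 1200,
                       flux_scale = 1.7e5,
                       sample_thickness = if (study == "syringe") 6.4 else 10,
                       sample_density = 677, attenuation_enabled = TRUE,
                       energy_blur_sd = 0, seed = 1L),
    reduction = list(energy_window = c(30, 45), q_min = 1.3, q_max = 28,
                     q_bin_width = 1.2),
    detection = list(min_snr = 3, tolerance = 1.2),
    scene = list(study = study, variant = "unheated",
                 beta_sheet_fraction = 1.0, amyloid_weight = 1.0)
  )
  class(cfg) <- "run_config"
  cfg
}

RUN_CONFIG_KEYS <- list(
  geometry = c("n_rows", "n_cols", "pixel_pitch_mm", "sdd_mm",
               "beam_center_row", "beam_center_col"),
  spectrum = c("kvp", "e_min", "bin_width"),
  acquisition = c("exposure", "flux_scale", "sample_thickness",
                  "sample_density", "attenuation_enabled", "energy_blur_sd",
                  "seed"),
  reduction = c("energy_window", "q_min", "q_max", "q_bin_width"),
  detection = c("min_snr", "tolerance"),
  scene = c("study", "variant", "beta_sheet_fraction", "amyloid_weight",
            "concentration"))

#' Validate a run configuration
#'
#' Rejects unknown blocks and keys and physically invalid values with
#' actionable messages.
#'
#' @param cfg A `run_config` list.
#' @return `cfg`, invisibly, or an error.
#' @export
validate_run_config <- function(cfg) {
  known_blocks <- c("format_version", names(RUN_CONFIG_KEYS))
  extra <- setdiff(names(cfg), known_blocks)
  if (length(extra)) stop("unknown config block(s): ", paste(extra, collapse = ", "))
  for (blk in names(RUN_CONFIG_KEYS)) {
    if (is.null(cfg[[blk]])) stop("missing config block '", blk, "'")
    bad <- setdiff(names(cfg[[blk]]), RUN_CONFIG_KEYS[[blk]])
    if (length(bad))
      stop("unknown key(s) in config block '", blk, "': ",
           paste(bad, collapse = ", "))
  }
  a <- cfg$acquisition
  if (a$exposure < 0) stop("acquisition.exposure must be >= 0 (seconds)")
  if (a$flux_scale < 0) stop("acquisition.flux_scale must be >= 0")
  r <- cfg$reduction
  if (r$energy_window[1] >= r$energy_window[2])
    stop("reduction.energy_window must be ordered (low < high), got ",
         paste(r$energy_window, collapse = ", "))
  if (r$q_min >= r$q_max) stop("reduction.q_min must be < reduction.q_max")
  if (r$q_bin_width <= 0) stop("reduction.q_bin_width must be > 0")
  g <- cfg$geometry
  if (g$sdd_mm <= 0 || g$pixel_pitch_mm <= 0)
    stop("geometry.sdd_mm and geometry.pixel_pitch_mm must be > 0")
  if (!cfg$scene$study %in% c("syringe", "phantom"))
    stop("scene.study must be 'syringe' or 'phantom'")
  invisible(cfg)
}

#' @rdname default_run_config
#' @param cfg A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

# Short deterministic hash of a config (provenance stamping).
config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 0xFFFFFFFF)
}
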