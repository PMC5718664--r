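# Scan-level and series-level orchestration: run every metric applicable
# to the modules present, assemble a QA report with provenance, and emit
# JSON / CSV outputs.

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

read_sidecar <- function(dir) {
  p <- file.path(dir, "manifest.json")
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else NULL
}

phantom_from_manifest <- function(manifest) {
  if (is.null(manifest$phantom)) return(NULL)
  catphan_phantom(modules = manifest$phantom$modules,
                  annulus = isTRUE(manifest$phantom$annulus))
}

skipped <- function(reason) list(skipped = TRUE, reason = reason)

#' Analyse one CATPHAN scan and assemble a QA report
#'
#' Runs every metric whose module is present in the phantom definition
#' (noise and uniformity on CTP486, CNR and insert CT numbers on CTP404,
#' high-contrast resolution on CTP528, low-contrast detectability on
#' CTP515); metrics for absent modules are marked skipped.  When `input`
#' is a directory written by [simulate_scan()], the sidecar manifest
#' supplies the phantom configuration, protocol and seed.
#'
#' @param input A series directory, `volume_image`, or `qa_volume`.
#' @param phantom Optional `phantom_definition`; overrides the sidecar.
#' @param config Named list of analysis options passed to the measurement
#'   functions (`peripheral_frac`, `n_slices`, `threshold`, `k_rose`,
#'   `tolerance`).
#' @return A `qa_report` list with `scan_id`, `protocol`, `total_mas`,
#'   `metrics` and `provenance`.
#' @export
analyze_scan <- function(input, phantom = NULL, config = list()) {
  manifest <- NULL
  scan_id <- "volume"
  if (is.character(input)) {
    if (!dir.exists(input)) stop_qa("io_error", "cannot read series at %s", input)
    manifest <- read_sidecar(input)
    scan_id <- basename(normalizePath(input))
    input <- read_series(input)
  }
  phantom <- phantom %||% phantom_from_manifest(manifest) %||% catphan_phantom()
  vol <- as_qa_volume(input, phantom)
  has <- function(kind) !is.null(phantom_module(phantom, kind))
  n_slices <- config$n_slices %||% 1
  pf <- config$peripheral_frac %||% 0.7
  metrics <- list()
  noise <- NULL
  if (has("CTP486")) {
    noise <- measure_noise(vol, peripheral_frac = pf, n_slices = n_slices)
    ur <- measure_uniformity(vol, peripheral_frac = pf,
                             tolerance = config$tolerance %||% 5,
                             n_slices = n_slices)
    metrics$noise_hu <- as.numeric(noise)
    metrics$uniformity <- list(ui_hu = ur$ui, classification = ur$classification)
  } else {
    metrics$noise_hu <- skipped("no CTP486 module")
    metrics$uniformity <- skipped("no CTP486 module")
  }
  if (has("CTP404")) {
    cnr <- measure_cnr(vol, n_slices = n_slices)
    metrics$cnr <- as.numeric(cnr)
    st <- pixel_stability_single(vol, n_slices)
    metrics$insert_means_hu <- st
  } else {
    metrics$cnr <- skipped("no CTP404 module")
    metrics$insert_means_hu <- skipped("no CTP404 module")
  }
  metrics$max_resolvable_lp_cm <- if (has("CTP528"))
    measure_resolution(vol, threshold = config$threshold %||% 0.2)$max_resolvable
  else skipped("no CTP528 module")
  metrics$low_contrast_visible <- if (has("CTP515")) {
    lc <- measure_low_contrast(vol, noise = if (is.null(noise)) NULL else as.numeric(noise),
                               k_rose = config$k_rose %||% 3, n_slices = n_slices)
    as.list(lc$visible_counts)
  } else skipped("no CTP515 module")
  structure(list(
    scan_id = scan_id,
    protocol = manifest$protocol %||% (vol$phantom$name %||% NA_character_),
    total_mas = manifest$total_mas %||% NA_real_,
    metrics = metrics,
    provenance = list(seed = manifest$seed %||% NA_integer_,
                      config_hash = config_hash(config),
                      tool_version = as.character(utils::packageVersion("catphanqa")))),
    class = "qa_report")
}

# per-insert ROI means on a single scan (helper for reports)
pixel_stability_single <- function(vol, n_slices = 1) {
  mod <- phantom_module(vol$phantom, "CTP404")
  slices <- module_slices(vol, "CTP404", n_slices)
  ctr <- locate_center(vol, slices[1])
  means <- vapply(seq_len(nrow(mod$inserts)), function(i) {
    ins <- mod$inserts[i, ]
    th <- ins$angle_deg * pi / 180
    roi_multi(vol, ctr + ins$radius_mm * c(cos(th), sin(th)), 6, slices)$mean
  }, 0)
  as.list(stats::setNames(means, mod$inserts$material))
}

#' Write a QA report as JSON
#'
#' @param report A `qa_report` from [analyze_scan()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_qa_report <- function(report, path) {
  stopifnot(inherits(report, "qa_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @export
print.qa_report <- function(x, ...) {
  cat(sprintf("QA report for %s (protocol %s, %.4g mAs)\n",
              x$scan_id, x$protocol, x$total_mas))
  m <- x$metrics
  fmt <- function(v) {
    if (is.list(v) && isTRUE(v$skipped)) return(paste("skipped:", v$reason))
    if (is.list(v)) v <- lapply(v, function(e) if (is.numeric(e)) signif(e, 4) else e)
    u <- unlist(v)
    if (is.numeric(u)) u <- signif(u, 4)
    if (!is.null(names(u)) && any(names(u) != ""))
      u <- paste(names(u), u, sep = "=")
    paste(u, collapse = ", ")
  }
  for (nm in names(m)) cat(sprintf("  %-24s %s\n", nm, fmt(m[[nm]])))
  invisible(x)
}

#' Analyse an mAs series from a scan manifest
#'
#' The manifest (CSV or data.frame) lists one scan per row with columns
#' `series_path`, `protocol`, `setting`, `phantom_size` and optionally
#' `total_mas` (otherwise taken from each scan's sidecar manifest or
#' recomputed from the protocol preset).  Produces the per-insert
#' stability curves and ranges plus noise-vs-mAs and CNR-vs-mAs tables.
#'
#' @param manifest Path to a manifest CSV or an equivalent data.frame.
#' @param base_dir Directory series paths are relative to (default: the
#'   manifest's directory).
#' @param phantom Optional `phantom_definition` used for all scans.
#' @param n_slices Number of adjacent slices to average over.
#' @return A `series_result` list: `stability` ([pixel_stability()]
#'   result), `noise_table`, `cnr_table`.
#' @export
analyze_series <- function(manifest, base_dir = NULL, phantom = NULL,
                           n_slices = 1) {
  if (is.character(manifest)) {
    base_dir <- base_dir %||% dirname(manifest)
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  }
  base_dir <- base_dir %||% "."
  if (nrow(manifest) < 2)
    stop_qa("incompatible_series", "a series needs at least 2 scans")
  if (length(unique(manifest$phantom_size)) > 1)
    stop_qa("incompatible_series", "inconsistent phantom sizes in one series")
  scans <- vector("list", nrow(manifest))
  rows_noise <- rows_cnr <- list()
  for (i in seq_len(nrow(manifest))) {
    dir_i <- file.path(base_dir, manifest$series_path[i])
    side <- read_sidecar(dir_i)
    ph <- phantom %||% phantom_from_manifest(side) %||% catphan_phantom()
    vol <- as_qa_volume(read_series(dir_i), ph)
    mas <- manifest$total_mas[i] %||% side$total_mas
    if (is.null(mas) || is.na(mas))
      mas <- protocol_total_mas(get_protocol(manifest$protocol[i]),
                                manifest$setting[i])
    scans[[i]] <- list(volume = vol, total_mas = mas)
    if (!is.null(phantom_module(ph, "CTP486")))
      rows_noise[[length(rows_noise) + 1]] <-
        data.frame(total_mas = mas,
                   noise_hu = as.numeric(measure_noise(vol, n_slices = n_slices)))
    if (!is.null(phantom_module(ph, "CTP404")))
      rows_cnr[[length(rows_cnr) + 1]] <-
        data.frame(total_mas = mas,
                   cnr = as.numeric(measure_cnr(vol, n_slices = n_slices)))
  }
  tab <- function(rows) if (length(rows)) {
    t <- do.call(rbind, rows); t[order(t$total_mas), , drop = FALSE]
  } else NULL
  structure(list(stability = pixel_stability(scans, n_slices = n_slices),
                 noise_table = tab(rows_noise),
                 cnr_table = tab(rows_cnr)),
            class = "series_result")
}

#' Write series-analysis tables as CSV
#'
#' Writes `stability_curves.csv`, `stability_ranges.csv` and, when
#' available, `noise_vs_mas.csv` / `cnr_vs_mas.csv` into `dir`.
#'
#' @param result A `series_result` from [analyze_series()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_series_tables <- function(result, dir) {
  stopifnot(inherits(result, "series_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(result$stability$curves, "stability_curves.csv")
  wr(data.frame(material = names(result$stability$ranges),
                range_hu = as.numeric(result$stability$ranges)),
     "stability_ranges.csv")
  if (!is.null(result$noise_table)) wr(result$noise_table, "noise_vs_mas.csv")
  if (!is.null(result$cnr_table)) wr(result$cnr_table, "cnr_vs_mas.csv")
  invisible(paths)
}
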