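#' Total tube output of a CBCT acquisition
#'
#' The tube current-time product accumulated over an acquisition:
#' `ma * (ms_per_frame / 1000) * n_frames` (mAs).
#'
#' @param ma Tube current (mA).
#' @param ms_per_frame Exposure time per projection frame (ms).
#' @param n_frames Number of projection frames.
#' @return Total mAs (numeric).
#' @examples
#' total_mas(80, 32, 630)   # 1612.8
#' total_mas(10, 10, 361)   # 36.1
#' @export
total_mas <- function(ma, ms_per_frame, n_frames) {
  if (!is_number(ma) || !is_number(ms_per_frame) || !is_number(n_frames) ||
      ma <= 0 || ms_per_frame <= 0 || n_frames <= 0)
    stop_qa("invalid_protocol", "ma, ms_per_frame and n_frames must be positive numbers")
  ma * (ms_per_frame / 1000) * n_frames
}

#' Nyquist bound on resolvable line-pair frequency
#'
#' The highest spatial frequency representable at a given reconstructed
#' pixel pitch: one line pair needs at least two pixels, so the bound is
#' `10 / (2 * pitch)` lp/cm.  The rounded value (half-up to an integer
#' lp/cm) is the bound as read off a bar-pattern gauge.
#'
#' @param pixel_pitch In-plane pixel pitch (mm).
#' @return List with `exact` and `rounded` bounds (lp/cm).
#' @examples
#' nyquist_bound(1.0)   # exact 5.0, rounded 5
#' nyquist_bound(0.88)  # exact 5.68, rounded 6
#' @export
nyquist_bound <- function(pixel_pitch) {
  if (!is_number(pixel_pitch) || pixel_pitch <= 0)
    stop_qa("invalid_argument", "pixel_pitch must be a positive number")
  exact <- 10 / (2 * pixel_pitch)
  list(exact = exact, rounded = as.integer(round_half_up(exact)))
}

scan_protocol <- function(name, system, kvp, settings, n_frames, fan_mode,
                          collimator_or_filter, voxel_size_mm,
                          printed_total_mas) {
  stopifnot(system %in% c("XVI", "OBI"), nrow(settings) == length(printed_total_mas))
  structure(list(
    name = name, system = system, kvp = kvp,
    settings = settings,                 # data.frame: ma, ms_per_frame
    n_frames = n_frames, fan_mode = fan_mode,
    collimator_or_filter = collimator_or_filter,
    voxel_size_mm = voxel_size_mm,
    printed_total_mas = printed_total_mas
  ), class = "scan_protocol")
}

#' Built-in XVI and OBI clinical scan protocols
#'
#' The four manufacturer-supplied XVI protocols (head & neck, prostate,
#' pelvis, chest; four mAs settings each) and the two OBI scanning modes
#' (full-fan / half-fan with full / half bow-tie filters; six mAs settings
#' each), with kVp, per-frame exposure settings, frame counts, and
#' reconstructed voxel sizes.
#'
#' @return Named list of `scan_protocol` objects.
#' @examples
#' names(builtin_protocols())
#' protocol_total_mas(builtin_protocols()[["obi-full-fan"]])
#' @export
builtin_protocols <- function() {
  st <- function(ma, ms) data.frame(ma = ma, ms_per_frame = ms)
  list(
    "xvi-head-neck" = scan_protocol(
      "xvi-head-neck", "XVI", 100,
      st(c(10, 10, 25, 20), c(10, 20, 10, 20)), 361, "full-fan", "S20",
      c(1, 1, 1), c(36.1, 72.2, 90.25, 144.4)),
    "xvi-prostate" = scan_protocol(
      "xvi-prostate", "XVI", 120,
      st(c(25, 25, 40, 50), c(20, 40, 32, 40)), 650, "half-fan", "M10",
      c(1, 1, 1), c(325, 650, 832, 1300)),
    "xvi-pelvis" = scan_protocol(
      "xvi-pelvis", "XVI", 120,
      st(c(25, 25, 40, 40), c(20, 40, 32, 40)), 650, "half-fan", "M20",
      c(1, 1, 1), c(325, 650, 832, 1040)),
    "xvi-chest" = scan_protocol(
      "xvi-chest", "XVI", 120,
      st(c(25, 25, 40, 50), c(20, 40, 32, 40)), 650, "half-fan", "L20",
      c(1, 1, 1), c(325, 650, 832, 1300)),
    "obi-full-fan" = scan_protocol(
      "obi-full-fan", "OBI", 125,
      st(c(10, 25, 50, 50, 80, 80), c(10, 20, 20, 30, 25, 32)), 630,
      "full-fan", "full bow-tie", c(0.47, 0.47, 2.5),
      c(63, 315, 630, 945, 1260, 1612.8)),
    "obi-half-fan" = scan_protocol(
      "obi-half-fan", "OBI", 125,
      st(c(10, 25, 50, 50, 80, 80), c(10, 20, 20, 30, 25, 32)), 630,
      "half-fan", "half bow-tie", c(0.88, 0.88, 2.5),
      c(63, 315, 630, 945, 1260, 1612.8))
  )
}

#' Look up a built-in protocol by name
#'
#' @param name Protocol name, e.g. `"obi-full-fan"` or `"xvi-chest"`.
#' @return A `scan_protocol`.
#' @export
get_protocol <- function(name) {
  p <- builtin_protocols()[[name]]
  if (is.null(p))
    stop_qa("configuration_error", "unknown protocol '%s' (available: %s)",
            name, paste(names(builtin_protocols()), collapse = ", "))
  p
}

#' Recomputed total mAs of a protocol's settings
#'
#' @param protocol A `scan_protocol`.
#' @param setting Optional setting index (1-based); default all settings.
#' @return Total mAs value(s) recomputed from (mA, ms/frame, frames).
#' @export
protocol_total_mas <- function(protocol, setting = NULL) {
  stopifnot(inherits(protocol, "scan_protocol"))
  s <- protocol$settings
  idx <- setting %||% seq_len(nrow(s))
  if (any(idx < 1 | idx > nrow(s)))
    stop_qa("invalid_protocol", "setting index out of range for '%s'", protocol$name)
  vapply(idx, function(i)
    total_mas(s$ma[i], s$ms_per_frame[i], protocol$n_frames), 0)
}

#' @export
print.scan_protocol <- function(x, ...) {
  cat(sprintf("%s [%s, %s, %g kVp, %s, %d frames, voxel %s mm]\n",
              x$name, x$system, x$fan_mode, x$kvp, x$collimator_or_filter,
              x$n_frames, paste(x$voxel_size_mm, collapse = "x")))
  cat("  total mAs:", paste(protocol_total_mas(x), collapse = ", "), "\n")
  invisible(x)
}
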