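#' CATPHAN sensitometry materials and their nominal CT numbers
#'
#' The seven insert materials of the CTP404 module plus water, with the
#' nominal CT numbers (HU) supplied by the phantom manufacturer.
#'
#' @return A data.frame with columns `name` and `nominal_ct` (HU).
#' @examples
#' catphan_materials()
#' @export
catphan_materials <- function() {
  data.frame(
    name = c("air", "pmp", "ldpe", "water", "polystyrene",
             "acrylic", "delrin", "teflon"),
    nominal_ct = c(-1000, -200, -100, 0, -35, 120, 340, 990),
    stringsAsFactors = FALSE
  )
}

material_ct <- function(name) {
  m <- catphan_materials()
  i <- match(name, m$name)
  if (anyNA(i)) stop_qa("configuration_error", "unknown material: %s",
                        paste(name[is.na(i)], collapse = ", "))
  m$nominal_ct[i]
}

# CTP404: seven 12 mm sensitometry inserts equally spaced on a 60 mm-radius
# circle.  Angles are a fixed documented layout; metrics depend only on the
# ROI/insert correspondence, not on absolute angles.
ctp404_layout <- function(z_offset = 0) {
  mats <- c("air", "pmp", "ldpe", "polystyrene", "acrylic", "delrin", "teflon")
  list(kind = "CTP404", z_offset = z_offset,
       inserts = data.frame(
         material = mats,
         nominal_ct = material_ct(mats),
         radius_mm = 60,
         angle_deg = 90 + (seq_along(mats) - 1) * 360 / length(mats),
         diameter_mm = 12,
         stringsAsFactors = FALSE))
}

ctp486_layout <- function(z_offset = 30) {
  list(kind = "CTP486", z_offset = z_offset)
}

# CTP528: bar groups of 1..21 lp/cm on a 55 mm-radius circle.  Each group
# has 4 line pairs (bar width 5/f mm), bars 8 mm long radially, pattern
# running tangentially; groups are laid out consecutively along the arc
# with a 6 mm gap, starting 8 degrees off the x axis so no group is
# grid-aligned.  Bars are aluminium-like, +1000 HU over the background.
ctp528_layout <- function(z_offset = 70, n_pairs = 4, bar_length = 8,
                          group_radius = 55, margin = 6, start_deg = 8,
                          bar_contrast = 1000) {
  f <- 1:21
  width <- n_pairs * 10 / f
  s <- cumsum(c(0, head(width + margin, -1)))
  list(kind = "CTP528", z_offset = z_offset,
       line_pair_groups = data.frame(
         freq_lp_cm = f,
         bar_width_mm = 5 / f,
         n_pairs = n_pairs,
         width_mm = width,
         bar_length_mm = bar_length,
         radius_mm = group_radius,
         angle_deg = start_deg + (s + width / 2) / group_radius * 180 / pi,
         contrast_hu = bar_contrast))
}

# CTP515: 27 supra-slice low-contrast discs, 3 contrast levels (1.0, 0.5,
# 0.3 % of the 1000-HU scale = 10, 5, 3 HU) x 9 diameters, one level per
# arc.  Arc radii and angular stagger are a fixed documented layout.
ctp515_layout <- function(z_offset = 110) {
  lev <- c(1.0, 0.5, 0.3)
  rad <- c(35, 58, 80)
  d <- c(2, 3, 4, 5, 6, 7, 8, 9, 15)
  discs <- do.call(rbind, lapply(seq_along(lev), function(i) {
    data.frame(contrast_pct = lev[i],
               contrast_hu = lev[i] * 10,
               diameter_mm = d,
               radius_mm = rad[i],
               angle_deg = (i - 1) * 40 / 3 + (seq_along(d) - 1) * 40)
  }))
  list(kind = "CTP515", z_offset = z_offset, discs = discs)
}

module_layout <- function(kind, ...) {
  switch(kind,
         CTP404 = ctp404_layout(...),
         CTP486 = ctp486_layout(...),
         CTP528 = ctp528_layout(...),
         CTP515 = ctp515_layout(...),
         stop_qa("configuration_error", "unknown module kind: %s", kind))
}

#' Geometric model of the CATPHAN 504 phantom
#'
#' Builds a `phantom_definition`: a 200 mm-diameter cylinder of
#' water-equivalent background holding the requested modules, optionally
#' wrapped in the 320 mm body annulus used to mimic body attenuation.
#'
#' @param modules Character vector of module kinds to include, out of
#'   `"CTP404"`, `"CTP486"`, `"CTP528"`, `"CTP515"`.
#' @param annulus Logical; include the 320 mm uniformity body annulus
#'   ("large phantom").
#' @param annulus_ct CT number (HU) of the annulus material
#'   (water-equivalent by default).
#' @return An object of class `phantom_definition`.
#' @examples
#' ph <- catphan_phantom()
#' ph$diameter_mm
#' @export
catphan_phantom <- function(modules = c("CTP404", "CTP486", "CTP528", "CTP515"),
                            annulus = FALSE, annulus_ct = 0) {
  modules <- match.arg(modules, several.ok = TRUE)
  structure(list(
    diameter_mm = 200,
    annulus_diameter_mm = if (annulus) 320 else NA_real_,
    annulus_ct = annulus_ct,
    background_ct = 0,
    module_thickness_mm = 25,
    modules = lapply(modules, module_layout)
  ), class = "phantom_definition")
}

#' Build a phantom definition from a configuration
#'
#' @param config Either a list with elements `modules` (character vector)
#'   and optionally `annulus` (logical) and `annulus_ct` (HU), or a path to
#'   a YAML/JSON file holding such a list.
#' @return A `phantom_definition`, as [catphan_phantom()].
#' @examples
#' build_phantom(list(modules = "CTP404", annulus = TRUE))
#' @export
build_phantom <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_qa("configuration_error", "config must be a list or file path")
  catphan_phantom(
    modules = unlist(config$modules) %||% c("CTP404", "CTP486", "CTP528", "CTP515"),
    annulus = isTRUE(config$annulus),
    annulus_ct = config$annulus_ct %||% 0)
}

#' Write a phantom definition to a YAML configuration file
#'
#' Serializes the reconstructible part of a phantom definition (module
#' kinds, annulus presence and CT) so `build_phantom(path)` recreates it.
#'
#' @param phantom A `phantom_definition`.
#' @param path Output YAML file path.
#' @return `path`, invisibly.
#' @export
write_phantom_config <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom_definition"))
  yaml::write_yaml(list(
    modules = vapply(phantom$modules, `[[`, "", "kind"),
    annulus = !is.na(phantom$annulus_diameter_mm),
    annulus_ct = phantom$annulus_ct), path)
  invisible(path)
}

phantom_module <- function(phantom, kind) {
  for (m in phantom$modules) if (m$kind == kind) return(m)
  NULL
}

phantom_outer_radius <- function(phantom) {
  if (!is.na(phantom$annulus_diameter_mm)) phantom$annulus_diameter_mm / 2
  else phantom$diameter_mm / 2
}

#' @export
print.phantom_definition <- function(x, ...) {
  cat(sprintf("CATPHAN phantom: %.0f mm diameter%s\n", x$diameter_mm,
              if (!is.na(x$annulus_diameter_mm))
                sprintf(" + %.0f mm body annulus (%g HU)",
                        x$annulus_diameter_mm, x$annulus_ct) else ""))
  for (m in x$modules)
    cat(sprintf("  %s at z = %g mm\n", m$kind, m$z_offset))
  invisible(x)
}
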