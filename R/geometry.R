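#' Cylinder-phantom skin grid
#'
#' Lays a square lattice of dosimeter points on the irradiated flat face
#' of a cylindrical tissue-equivalent phantom (default: 32-cm diameter,
#' 17.5-cm thickness, 1.5-cm point pitch, matching the gridded OSLD
#' phantom the validation campaign used). Candidate lattice points on a
#' (2*floor(radius/spacing)+1)^2 grid are kept when they fall inside the
#' face disc.
#'
#' Coordinate convention (patient supine, head-first): +z cranial, +x
#' patient-left, +y anterior. The gridded face lies in the y = 0 plane,
#' centered on the isocenter, with outward normal (0, -1, 0) facing the
#' under-table source; the phantom body occupies y in (0, length].
#'
#' @param radius face radius, cm (default 16).
#' @param length cylinder thickness, cm (default 17.5).
#' @param spacing lattice pitch, cm (default 1.5); must be < radius.
#' @return An object of class `phantom_grid`: list with `radius`,
#'   `length`, `spacing`, and `points`, a data.frame with 0-based grid
#'   indices `i`,`j` (row-major ordering), positions `x`,`y`,`z` (cm) and
#'   outward normal `nx`,`ny`,`nz`.
#' @export
build_grid <- function(radius = 16, length = 17.5, spacing = 1.5) {
  if (radius <= 0 || length <= 0 || spacing <= 0) {
    stop("phantom dimensions must be positive")
  }
  if (spacing >= radius) stop("spacing must be smaller than the radius")
  n <- floor(radius / spacing)
  idx <- -n:n
  pts <- expand.grid(j = idx, i = idx)[, c("i", "j")]  # row-major in i
  x <- pts$j * spacing   # j indexes patient-left (x)
  z <- pts$i * spacing   # i indexes cranial (z)
  keep <- x^2 + z^2 <= radius^2 + 1e-9
  pts <- pts[keep, ]
  points <- data.frame(i = pts$i + n, j = pts$j + n,  # 0-based indices
                       x = x[keep], y = 0, z = z[keep],
                       nx = 0, ny = -1, nz = 0)
  rownames(points) <- NULL
  structure(list(radius = radius, length = length, spacing = spacing,
                 points = points),
            class = "phantom_grid")
}

#' @export
print.phantom_grid <- function(x, ...) {
  cat(sprintf("<phantom_grid> r = %g cm, thickness %g cm, pitch %g cm, %d points\n",
              x$radius, x$length, x$spacing, nrow(x$points)))
  invisible(x)
}

rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}
rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' Beam geometry from an irradiation event
#'
#' Places the focal spot and collimation pyramid implied by the event's
#' gantry angles, source-to-isocenter distance and field size. At gantry
#' (0, 0) the source sits under the table at distance `sod` below the
#' isocenter, pointing anterior (+y). The primary gantry angle rotates
#' the source about the cranial (z) axis (axial plane), the secondary
#' about the patient-left (x) axis (sagittal plane), both right-handed.
#' Table offsets move the patient relative to the beam, so in phantom
#' coordinates the beam is translated by minus the offset.
#'
#' The collimated field is a rectangular pyramid with half-angles
#' atan((field_side/2)/sod) about the central axis.
#'
#' @param event an [irradiation_event()].
#' @return An object of class `beam_geometry`: `source_position` (cm),
#'   unit `central_axis` (source towards isocenter), transverse unit
#'   vectors `e_w`, `e_h`, `half_angle_w`, `half_angle_h` (radians) and
#'   `d_ref` (cm).
#' @export
beam_from_event <- function(event) {
  validate_event(event)
  R <- rot_z(event$gantry_primary_deg * pi / 180) %*%
    rot_x(event$gantry_secondary_deg * pi / 180)
  axis <- as.numeric(R %*% c(0, 1, 0))          # beam direction
  e_w <- as.numeric(R %*% c(1, 0, 0))           # field-width direction
  e_h <- as.numeric(R %*% c(0, 0, 1))           # field-height direction
  shift <- -c(event$table_lateral_cm, event$table_height_cm,
              event$table_longitudinal_cm)
  src <- -event$sod * axis + shift
  structure(list(source_position = src, central_axis = axis,
                 e_w = e_w, e_h = e_h,
                 half_angle_w = atan((event$field_w_iso / 2) / event$sod),
                 half_angle_h = atan((event$field_h_iso / 2) / event$sod),
                 d_ref = event$d_ref, sod = event$sod),
            class = "beam_geometry")
}

#' Table and pad slab configuration
#'
#' Describes the patient table and mattress pad as uniform horizontal
#' slabs below the phantom face (normal along y). Defaults: a 1.5-mm
#' Al-equivalent table composite and a 70-mm low-density foam pad, with
#' the pad's top surface 7 cm below the face and the table immediately
#' beneath the pad. Either slab may be absent.
#'
#' @param table_present,pad_present logical.
#' @param table_thickness_mm,pad_thickness_mm slab thicknesses, mm.
#' @param table_material,pad_material material names in the attenuation
#'   tables.
#' @param pad_top_y_cm y of the pad's top surface, cm (below the face).
#' @return list of class `slab_config`.
#' @export
slab_config <- function(table_present = FALSE, pad_present = FALSE,
                        table_thickness_mm = 1.5, pad_thickness_mm = 70,
                        table_material = "table_composite",
                        pad_material = "pad_foam",
                        pad_top_y_cm = -7) {
  pad_bot <- pad_top_y_cm - pad_thickness_mm / 10
  structure(list(
    table_present = table_present, pad_present = pad_present,
    table_material = table_material, pad_material = pad_material,
    table_thickness_mm = table_thickness_mm,
    pad_thickness_mm = pad_thickness_mm,
    pad_y = c(pad_bot, pad_top_y_cm),
    table_y = c(pad_bot - table_thickness_mm / 10, pad_bot)),
    class = "slab_config")
}

#' Read a slab configuration from YAML
#'
#' Expects top-level keys `table:` and `pad:`, each with `present`,
#' `material`, `thickness_mm`.
#'
#' @param path YAML file path.
#' @return a [slab_config()].
#' @export
read_slab_config <- function(path) {
  y <- yaml::read_yaml(path)
  g <- function(part, key, default) {
    v <- y[[part]][[key]]
    if (is.null(v)) default else v
  }
  slab_config(
    table_present = isTRUE(g("table", "present", FALSE)),
    pad_present = isTRUE(g("pad", "present", FALSE)),
    table_thickness_mm = g("table", "thickness_mm", 1.5),
    pad_thickness_mm = g("pad", "thickness_mm", 70),
    table_material = g("table", "material", "table_composite"),
    pad_material = g("pad", "material", "pad_foam"))
}

# path length (mm) through a horizontal slab band [y0, y1] for segments
# from source y ys to point y yp with unit-ray y component ry.
slab_path_mm <- function(ys, yp, y0, y1, thickness_mm, ry) {
  crosses <- pmin(ys, yp) <= y0 + 1e-12 & pmax(ys, yp) >= y1 - 1e-12
  ifelse(crosses & abs(ry) > 1e-12, thickness_mm / abs(ry), 0)
}

#' Ray-trace a beam onto a phantom grid
#'
#' For every grid point, decides whether the ray from the focal spot to
#' the point lies inside the rectangular collimation pyramid and whether
#' the point faces the source (outward normal against the ray; grazing
#' rays with normal.ray = 0 are classified out-of-field), and records the
#' source-to-point distance, the incidence angle on the face, and the
#' path lengths through the table and pad slabs the segment traverses.
#'
#' @param beam a [beam_from_event()] geometry.
#' @param grid a [build_grid()] phantom grid.
#' @param slabs a [slab_config()]; default: no table, no pad.
#' @return An object of class `trace_result`: data.frame with `i`, `j`,
#'   `in_field`, `d_skin` (cm), `incidence_deg`, `table_path_mm`,
#'   `pad_path_mm`.
#' @export
trace_beam <- function(beam, grid, slabs = slab_config()) {
  p <- grid$points
  src <- beam$source_position
  # source inside the cylinder body is a degenerate geometry
  if (src[2] > 0 && src[2] < grid$length &&
      src[1]^2 + src[3]^2 < grid$radius^2) {
    stop("beam source lies inside the phantom")
  }
  vx <- p$x - src[1]; vy <- p$y - src[2]; vz <- p$z - src[3]
  d <- sqrt(vx^2 + vy^2 + vz^2)
  u <- vx * beam$central_axis[1] + vy * beam$central_axis[2] +
    vz * beam$central_axis[3]
  w <- vx * beam$e_w[1] + vy * beam$e_w[2] + vz * beam$e_w[3]
  h <- vx * beam$e_h[1] + vy * beam$e_h[2] + vz * beam$e_h[3]
  in_pyramid <- u > 0 &
    abs(w) <= u * tan(beam$half_angle_w) + 1e-12 &
    abs(h) <= u * tan(beam$half_angle_h) + 1e-12
  ndotr <- (p$nx * vx + p$ny * vy + p$nz * vz) / d
  facing <- ndotr < 0                         # grazing -> out of field
  in_field <- in_pyramid & facing
  inc <- acos(pmin(1, pmax(-1, -ndotr))) * 180 / pi
  ry <- vy / d
  tp <- if (slabs$table_present) {
    slab_path_mm(src[2], p$y, slabs$table_y[1], slabs$table_y[2],
                 slabs$table_thickness_mm, ry)
  } else 0
  pp <- if (slabs$pad_present) {
    slab_path_mm(src[2], p$y, slabs$pad_y[1], slabs$pad_y[2],
                 slabs$pad_thickness_mm, ry)
  } else 0
  res <- data.frame(i = p$i, j = p$j, in_field = in_field, d_skin = d,
                    incidence_deg = inc,
                    table_path_mm = rep_len(tp, nrow(p)),
                    pad_path_mm = rep_len(pp, nrow(p)))
  structure(list(grid = grid, beam = beam, points = res),
            class = "trace_result")
}

#' Grid indices irradiated by both of two traced fields
#'
#' The spatial intersection of two fields on the same grid: indices
#' in-field in both traces. An empty intersection is a valid result
#' (disjoint fields).
#'
#' @param traceA,traceB `trace_result`s on the same grid.
#' @return data.frame with columns `i`, `j` of the overlap points.
#' @export
two_field_overlap <- function(traceA, traceB) {
  ga <- traceA$grid; gb <- traceB$grid
  if (!isTRUE(all.equal(ga$points[c("i", "j")], gb$points[c("i", "j")])) ||
      ga$spacing != gb$spacing) {
    stop("traces are not on the same grid")
  }
  both <- traceA$points$in_field & traceB$points$in_field
  traceA$points[both, c("i", "j")]
}
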