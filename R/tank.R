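# Virtual tank geometry: circular arena, feeding ports, sensor beam regions,
# zones, and an optional divider wall.
#
# Coordinates: origin at the tank center, +x toward the port at 0 degrees,
# units cm, 2-D (the camera views the tank from below, so the analysis plane
# is planar).

#' Describe a circular training tank
#'
#' Defaults mirror a 30 cm diameter circular tank with two feeding ports on
#' opposite sides (180 degrees apart), one beam-break proximity sensor per
#' port, and three analysis zones at increasing distance from the active
#' feeder location.
#'
#' @param radius tank radius in cm (default 15).
#' @param port_angles angles (degrees) of the feeding ports on the rim.
#' @param sensor_regions list of [sensor_region()]; by default one per port,
#'   a 2 cm beam disc whose edge sits 1 cm inside the rim.
#' @param zone_boundaries two distances (cm) from the active port splitting
#'   the tank into zones 1 (closest), 2, and 3.
#' @param divider optional list `(offset, gap_center, gap_width)` describing a
#'   chord wall perpendicular to the port axis at `offset` cm from the
#'   center, pierced by a gap of `gap_width` cm centered `gap_center` cm off
#'   the tank's midline.  Default `NULL` (no divider).
#' @return a `tank_geometry` object.
#' @export
tank_geometry <- function(radius = 15, port_angles = c(0, 180),
                          sensor_regions = NULL,
                          zone_boundaries = c(10, 20),
                          divider = NULL) {
  if (!is.numeric(radius) || radius <= 0) stopf("'radius' must be > 0")
  if (length(port_angles) < 1) stopf("at least one port is required")
  if (is.null(sensor_regions)) {
    sensor_regions <- lapply(seq_along(port_angles), function(i) {
      th <- port_angles[i] * pi / 180
      sensor_region(paste0("s", i),
                    center = (radius - 3) * c(cos(th), sin(th)),
                    radius = 2)
    })
  }
  if (!all(vapply(sensor_regions, inherits, logical(1), "sensor_region")))
    stopf("sensor_regions must be a list of sensor_region objects")
  for (s in sensor_regions) {
    if (sqrt(sum(s$center^2)) + s$radius > radius + 1e-9)
      stopf("sensor '%s' does not lie within the tank", s$sensor_id)
  }
  if (length(zone_boundaries) != 2 || !(0 < zone_boundaries[1]) ||
      !(zone_boundaries[1] < zone_boundaries[2]) ||
      !(zone_boundaries[2] < 2 * radius))
    stopf("zone_boundaries must satisfy 0 < b1 < b2 < 2 * radius")
  if (!is.null(divider)) {
    divider <- modifyList(list(offset = 5, gap_center = 5, gap_width = 4),
                          divider)
  }
  structure(list(radius = as.numeric(radius),
                 port_angles = as.numeric(port_angles),
                 sensor_regions = sensor_regions,
                 zone_boundaries = as.numeric(zone_boundaries),
                 divider = divider),
            class = "tank_geometry")
}

#' Define a circular beam-break sensor region
#'
#' The infra-red proximity sensor is modeled as a disc: a fish whose centroid
#' enters the disc breaks the beam and raises the sensor line.
#'
#' @param sensor_id label.
#' @param center `(x, y)` in cm.
#' @param radius disc radius in cm (default 2).
#' @return a `sensor_region` object.
#' @export
sensor_region <- function(sensor_id, center, radius = 2) {
  if (!is.numeric(center) || length(center) != 2)
    stopf("sensor center must be (x, y)")
  if (!is.numeric(radius) || radius <= 0) stopf("sensor radius must be > 0")
  structure(list(sensor_id = as.character(sensor_id),
                 center = as.numeric(center), radius = as.numeric(radius)),
            class = "sensor_region")
}

#' Rim location of a feeding port
#'
#' @param tank a `tank_geometry`.
#' @param port port index (into `tank$port_angles`).
#' @return `(x, y)` in cm on the tank rim.
#' @export
port_location <- function(tank, port = 1) {
  th <- tank$port_angles[port] * pi / 180
  tank$radius * c(cos(th), sin(th))
}

#' Which sensors are triggered by a set of positions?
#'
#' @param positions a 2-column matrix or data.frame of `(x, y)` positions, cm.
#' @param tank a `tank_geometry`.
#' @return character vector of triggered `sensor_id`s (the set of sensors
#'   whose beam disc contains at least one position).
#' @export
sense <- function(positions, tank) {
  stopifnot(inherits(tank, "tank_geometry"))
  positions <- as.matrix(positions)
  if (nrow(positions) == 0) return(character(0))
  hit <- vapply(tank$sensor_regions, function(s) {
    d2 <- (positions[, 1] - s$center[1])^2 + (positions[, 2] - s$center[2])^2
    any(d2 <= s$radius^2, na.rm = TRUE)
  }, logical(1))
  vapply(tank$sensor_regions[hit], `[[`, character(1), "sensor_id")
}

# Per-frame logical matrix (frames x sensors) of beam states for one
# individual's path; used by the engine to build sensor_high/low events.
sense_frames <- function(xy, tank) {
  out <- matrix(FALSE, nrow(xy), length(tank$sensor_regions))
  colnames(out) <- vapply(tank$sensor_regions, `[[`, character(1), "sensor_id")
  for (j in seq_along(tank$sensor_regions)) {
    s <- tank$sensor_regions[[j]]
    d2 <- (xy[, 1] - s$center[1])^2 + (xy[, 2] - s$center[2])^2
    out[, j] <- !is.na(d2) & d2 <= s$radius^2
  }
  out
}
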