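# Geometry of the eye-tracking rig: corneal-reflection model, projection
# of pupil positions onto the monitor plane, and conversion of monitor
# coordinates to angular eye position.
#
# Conventions (fixed here, relied on by every downstream sector rule):
#   * the eye centre is the origin of the eye reference frame;
#   * +azimuth is temporal (toward the monitor on the animal's right),
#     +elevation is dorsal (up);
#   * the monitor plane basis is (ex, ey) with ex horizontal (+azimuth)
#     and ey vertical (+elevation).

#' Rig geometry description
#'
#' @param eye_radius radius of the eye treated as a spherical mirror, cm
#'   (default 0.1682).
#' @param monitor_distance distance from the eye centre to the monitor, cm
#'   (default 15).
#' @param led_position position of the infrared LED in the eye reference
#'   frame, cm (3-vector). The default places it on the camera axis.
#' @param monitor_normal unit 3-vector normal of the monitor plane,
#'   pointing at the eye centre (the monitor is not rotated relative to
#'   the eye). Default `c(-1, 0, 0)`: the monitor sits on the +x side.
#' @param camera_direction unit 3-vector from the eye toward the camera;
#'   default `NULL` means the camera is coaxial with the LED
#'   (LED mounted next to the lens).
#' @return An object of class `rig_geometry`.
#' @export
rig_geometry <- function(eye_radius = 0.1682,
                         monitor_distance = 15,
                         led_position = c(20, 0, 0),
                         monitor_normal = c(-1, 0, 0),
                         camera_direction = NULL) {
  if (!is_pos_scalar(eye_radius)) stop_invalid_config("eye_radius must be > 0")
  if (!is_pos_scalar(monitor_distance)) stop_invalid_config("monitor distance must be > 0")
  if (length(led_position) != 3 || sqrt(sum(led_position^2)) < 1e-12) {
    stop_invalid_config("led_position must be a nonzero 3-vector")
  }
  n <- monitor_normal / sqrt(sum(monitor_normal^2))
  if (!is.null(camera_direction)) {
    camera_direction <- camera_direction / sqrt(sum(camera_direction^2))
  }
  structure(list(eye_radius = eye_radius,
                 monitor_distance = monitor_distance,
                 led_position = as.numeric(led_position),
                 monitor_normal = n,
                 camera_direction = camera_direction),
            class = "rig_geometry")
}

# Orthonormal in-plane basis of the monitor: ex points toward +azimuth,
# ey toward +elevation (global up, (0, 0, 1)).
monitor_basis <- function(rig) {
  n <- rig$monitor_normal
  up <- c(0, 0, 1)
  ex <- pracma_cross(n, up)
  if (sqrt(sum(ex^2)) < 1e-12) stop_invalid_config("monitor normal may not be vertical")
  ex <- ex / sqrt(sum(ex^2))
  ey <- pracma_cross(ex, n)
  ey <- ey / sqrt(sum(ey^2))
  list(ex = ex, ey = ey, n = n, centre = -rig$monitor_distance * n)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Ellipse fit record
#'
#' Parameters of an ellipse fitted to the tracked pupil or corneal
#' reflection on one video frame, expressed in the eye reference frame.
#'
#' @param center_x,center_y ellipse centre (cm).
#' @param half_width,half_height half-axes (cm); must be positive when the
#'   fit is valid.
#' @param phi rotation angle around the centre (radians).
#' @param valid logical; invalid fits (tracking failures) propagate as
#'   missing frames.
#' @return An object of class `ellipse_fit`.
#' @export
ellipse_fit <- function(center_x, center_y, half_width = 0.05,
                        half_height = 0.05, phi = 0, valid = TRUE) {
  if (valid && (!is_pos_scalar(half_width) || !is_pos_scalar(half_height))) {
    stop_invalid_input("half-axes must be positive for a valid fit")
  }
  structure(list(center_x = center_x, center_y = center_y,
                 half_width = half_width, half_height = half_height,
                 phi = phi, valid = isTRUE(valid)),
            class = "ellipse_fit")
}

#' Corneal reflection point on the spherical eye
#'
#' Treats the eye as a spherical mirror and returns the point on its
#' surface where the specular reflection of the (distant) LED appears to
#' the camera. For a distant source and distant camera the surface normal
#' at the glint bisects the directions toward the LED and toward the
#' camera, so the reflection point is `eye_radius` times the unit bisector.
#'
#' @param rig a [rig_geometry()].
#' @return 3-vector in the eye reference frame (cm); its norm equals
#'   `rig$eye_radius`.
#' @export
corneal_reflection_vector <- function(rig) {
  led <- rig$led_position
  nl <- sqrt(sum(led^2))
  if (nl < 1e-12) stop_invalid_config("LED at the eye centre: degenerate geometry")
  u_led <- led / nl
  u_cam <- if (is.null(rig$camera_direction)) u_led else rig$camera_direction
  bis <- u_led + u_cam
  nb <- sqrt(sum(bis^2))
  if (nb < 1e-12) stop_invalid_config("LED opposite the camera: degenerate geometry")
  rig$eye_radius * bis / nb
}

#' Project a pupil fit onto the monitor plane
#'
#' Translates the pupil centre into the eye reference frame by aligning
#' the observed corneal-reflection fit with the model reflection point
#' from [corneal_reflection_vector()], lifts the 2d pupil position onto
#' the eye sphere, and intersects the ray from the eye centre through that
#' point with the monitor plane.
#'
#' The 2d fit coordinates are interpreted in the camera image plane, whose
#' axes are taken to coincide with the monitor basis (camera coaxial with
#' the monitor axis); real-rig camera calibration is an adapter concern.
#'
#' @param pupil,cr [ellipse_fit()] objects for the pupil and the corneal
#'   reflection on one frame.
#' @param rig a [rig_geometry()].
#' @return Named numeric `c(x, y)` in monitor-plane cm, or `c(NA, NA)` if
#'   either fit is invalid (missing frame propagation).
#' @export
project_pupil_to_monitor <- function(pupil, cr, rig) {
  if (!inherits(pupil, "ellipse_fit") || !inherits(cr, "ellipse_fit")) {
    stop_invalid_input("pupil and cr must be ellipse_fit objects")
  }
  if (!pupil$valid || !cr$valid) return(c(x = NA_real_, y = NA_real_))
  b <- monitor_basis(rig)
  crv <- corneal_reflection_vector(rig)
  # model CR in image-plane coordinates
  cr_model <- c(sum(crv * b$ex), sum(crv * b$ey))
  offset <- cr_model - c(cr$center_x, cr$center_y)
  p2 <- c(pupil$center_x, pupil$center_y) + offset
  r2 <- sum(p2^2)
  R <- rig$eye_radius
  if (r2 >= R^2) {
    # pupil centre off the eye sphere: tracking artifact, propagate missing
    return(c(x = NA_real_, y = NA_real_))
  }
  # lift onto the sphere, toward the camera/monitor side
  p3 <- p2[1] * b$ex + p2[2] * b$ey + sqrt(R^2 - r2) * (-b$n)
  denom <- sum(p3 * b$n)
  if (abs(denom) < 1e-12) {
    abort_sc("gaze ray parallel to the monitor plane", "saccadescope_out_of_range")
  }
  t <- sum(b$centre * b$n) / denom
  if (t <= 0) {
    abort_sc("gaze ray points away from the monitor", "saccadescope_out_of_range")
  }
  hit <- t * p3
  rel <- hit - b$centre
  c(x = sum(rel * b$ex), y = sum(rel * b$ey))
}

#' Convert monitor-plane position to angular eye position
#'
#' Azimuth `a` satisfies `tan(a) = x / d`; elevation `e` satisfies
#' `tan(e) = y / sqrt(x^2 + d^2)`, with `d` the eye-to-monitor distance.
#'
#' @param x,y monitor-plane coordinates (cm); `x` positive temporal,
#'   `y` positive dorsal.
#' @param d eye-to-monitor distance (cm), > 0.
#' @return Named numeric `c(azimuth_deg, elevation_deg)`.
#' @export
position_to_angles <- function(x, y, d = 15) {
  if (!is_pos_scalar(d)) stop_invalid_config("monitor distance must be > 0")
  a <- atan2(x, d)
  e <- atan(y / sqrt(x^2 + d^2))
  c(azimuth_deg = rad2deg(a), elevation_deg = rad2deg(e))
}

#' Inverse of [position_to_angles()]
#'
#' @param azimuth_deg,elevation_deg angular position (degrees),
#'   `|angle| < 90`.
#' @param d eye-to-monitor distance (cm).
#' @return Named numeric `c(x, y)` in monitor-plane cm.
#' @export
angles_to_position <- function(azimuth_deg, elevation_deg, d = 15) {
  if (!is_pos_scalar(d)) stop_invalid_config("monitor distance must be > 0")
  x <- d * tan(deg2rad(azimuth_deg))
  y <- tan(deg2rad(elevation_deg)) * sqrt(x^2 + d^2)
  c(x = x, y = y)
}

#' Convert an ellipse-fit table to a gaze trace
#'
#' Applies [project_pupil_to_monitor()] and [position_to_angles()] frame by
#' frame. Input rows must be ordered by frame; invalid fits yield missing
#' frames.
#'
#' @param pupil_fits,cr_fits data frames with columns `center_x`,
#'   `center_y`, `half_width`, `half_height`, `phi`, `valid` (one row per
#'   frame).
#' @param rig a [rig_geometry()].
#' @param frame_rate frames per second of the video.
#' @return A [gaze_trace()].
#' @export
fits_to_gaze_trace <- function(pupil_fits, cr_fits, rig, frame_rate = 30) {
  n <- nrow(pupil_fits)
  if (nrow(cr_fits) != n) stop_invalid_input("fit tables must have equal rows")
  az <- el <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- ellipse_fit(pupil_fits$center_x[i], pupil_fits$center_y[i],
                     pupil_fits$half_width[i], pupil_fits$half_height[i],
                     pupil_fits$phi[i], isTRUE(pupil_fits$valid[i]))
    g <- ellipse_fit(cr_fits$center_x[i], cr_fits$center_y[i],
                     cr_fits$half_width[i], cr_fits$half_height[i],
                     cr_fits$phi[i], isTRUE(cr_fits$valid[i]))
    xy <- project_pupil_to_monitor(p, g, rig)
    if (!any(is.na(xy))) {
      ang <- position_to_angles(xy[["x"]], xy[["y"]], rig$monitor_distance)
      az[i] <- ang[["azimuth_deg"]]
      el[i] <- ang[["elevation_deg"]]
    }
  }
  gaze_trace(az, el, frame_rate)
}
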