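#' Rasterize a centroid path into grayscale frames
#'
#' Renders a dark filled ellipse (the body) at each centroid position on a
#' bright background with optional additive Gaussian noise, emulating the
#' raw video input of the tracking stage. The ellipse's major axis is
#' oriented along the instantaneous heading of travel.
#'
#' @param path centroid track from [generate_path()] (columns `time_s`,
#'   `x_um`, `y_um`).
#' @param body_length_px,body_width_px full major/minor axis of the body
#'   ellipse in pixels.
#' @param um_per_px scale factor converting track micrometers to pixels.
#' @param dim frame size `c(width, height)` in pixels.
#' @param bg,fg background and body intensities (0-255).
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param offset_px pixel offset `c(x, y)` added to the converted track so
#'   the path can be centered in the frame.
#' @return 8-bit integer array `height x width x frames`, with the frame
#'   times as attribute `time_s`. Warns if the body leaves the frame in
#'   more than 10\% of frames.
#' @export
rasterize_walker <- function(path, body_length_px = 50, body_width_px = 20,
                             um_per_px = 5, dim = c(200, 150), bg = 220,
                             fg = 40, noise_sd = 0, offset_px = NULL) {
  w <- dim[1]; h <- dim[2]
  xs <- path$x_um / um_per_px
  ys <- path$y_um / um_per_px
  if (is.null(offset_px)) {
    offset_px <- c(w / 2 - mean(range(xs)), h / 2 - mean(range(ys)))
  }
  xs <- xs + offset_px[1]
  ys <- ys + offset_px[2]

  # heading per frame from the displacement to the next frame (last frame
  # reuses the previous heading); constant-heading paths stay exact
  dx <- c(diff(xs), NA); dy <- c(diff(ys), NA)
  ang <- atan2(dy, dx)                  # screen angle of travel, radians
  ang[is.na(ang) | (dx == 0 & dy == 0)] <- NA
  ang <- fill_forward(ang, default = 0)

  a <- body_length_px / 2; b <- body_width_px / 2
  out_of_frame <- xs - a < 0 | xs + a > w | ys - a < 0 | ys + a > h
  if (mean(out_of_frame) > 0.10) {
    warning(sprintf("body out of frame in %.0f%% of frames",
                    100 * mean(out_of_frame)), call. = FALSE)
  }

  px <- matrix(rep(seq_len(w), each = h), nrow = h)   # column index
  py <- matrix(rep(seq_len(h), times = w), nrow = h)  # row index
  stack <- array(0L, c(h, w, length(xs)))
  for (i in seq_along(xs)) {
    ca <- cos(ang[i]); sa <- sin(ang[i])
    u <- (px - xs[i]) * ca + (py - ys[i]) * sa
    v <- -(px - xs[i]) * sa + (py - ys[i]) * ca
    frame <- matrix(bg, h, w)
    frame[(u / a)^2 + (v / b)^2 <= 1] <- fg
    if (noise_sd > 0) frame <- frame + stats::rnorm(length(frame), 0, noise_sd)
    stack[, , i] <- as.integer(pmin(pmax(round(frame), 0), 255))
  }
  attr(stack, "time_s") <- path$time_s
  stack
}

fill_forward <- function(x, default = 0) {
  if (all(is.na(x))) return(rep(default, length(x)))
  first <- which(!is.na(x))[1]
  x[seq_len(first - 1)] <- x[first]
  for (i in seq_along(x)[-1]) if (is.na(x[i])) x[i] <- x[i - 1]
  x
}
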