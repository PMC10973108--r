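#' Area-of-interest layout of the face image
#'
#' Defines the pixel geometry of the four zones: a rectangle around the
#' eyes, a rectangle around the mouth, the face region (whose remainder
#' after removing the two rectangles is the rest-of-face zone, RoF), and
#' everything else (`Other`). Rectangles are 0-based, half-open
#' `c(x0, y0, x1, y1)` with `x0 <= x < x1`, origin at the top-left of the
#' image; a point on a shared boundary belongs to the zone with the lower
#' index (Eyes before Mouth before RoF).
#'
#' @param image_size `c(width, height)` in pixels.
#' @param eyes,mouth,face Rectangles `c(x0, y0, x1, y1)`. `eyes` and `mouth`
#'   must be disjoint and inside `face`; `face` must be inside the image.
#' @return An object of class `aoi_layout`.
#' @export
#' @examples
#' aoi_layout(c(64, 64), eyes = c(16, 12, 48, 24),
#'            mouth = c(20, 36, 44, 48), face = c(8, 4, 56, 60))
aoi_layout <- function(image_size, eyes, mouth, face) {
  chk_rect <- function(r, nm) {
    if (!is.numeric(r) || length(r) != 4L || any(!is.finite(r)))
      stop(nm, " must be c(x0, y0, x1, y1)", call. = FALSE)
    if (r[1] >= r[3] || r[2] >= r[4])
      stop(nm, " rectangle has non-positive area", call. = FALSE)
    r
  }
  stopifnot(is.numeric(image_size), length(image_size) == 2L,
            all(image_size >= 1))
  eyes <- chk_rect(eyes, "eyes"); mouth <- chk_rect(mouth, "mouth")
  face <- chk_rect(face, "face")
  inside <- function(inner, outer)
    inner[1] >= outer[1] && inner[2] >= outer[2] &&
    inner[3] <= outer[3] && inner[4] <= outer[4]
  if (!inside(face, c(0, 0, image_size)))
    stop("face region must lie inside the image", call. = FALSE)
  if (!inside(eyes, face) || !inside(mouth, face))
    stop("eyes and mouth rectangles must lie inside the face region",
         call. = FALSE)
  overlap <- eyes[1] < mouth[3] && mouth[1] < eyes[3] &&
    eyes[2] < mouth[4] && mouth[2] < eyes[4]
  if (overlap)
    stop("eyes and mouth rectangles must be disjoint", call. = FALSE)
  structure(list(image_size = as.numeric(image_size), eyes = eyes,
                 mouth = mouth, face = face),
            class = "aoi_layout")
}

#' @export
print.aoi_layout <- function(x, ...) {
  cat(sprintf("<aoi_layout %dx%d eyes=[%s] mouth=[%s] face=[%s]>\n",
              x$image_size[1], x$image_size[2],
              paste(x$eyes, collapse = ","),
              paste(x$mouth, collapse = ","),
              paste(x$face, collapse = ",")))
  invisible(x)
}

#' Classify pixel coordinates into zones
#'
#' @param layout An [aoi_layout()].
#' @param x,y Pixel coordinates (0-based, origin top-left); vectors of equal
#'   length.
#' @return Character vector of zone labels; coordinates outside the image
#'   map to `"Other"`.
#' @export
zone_at <- function(layout, x, y) {
  stopifnot(length(x) == length(y))
  in_rect <- function(r) x >= r[1] & x < r[3] & y >= r[2] & y < r[4]
  out <- rep("Other", length(x))
  out[in_rect(layout$face)] <- "RoF"
  out[in_rect(layout$mouth)] <- "Mouth"
  out[in_rect(layout$eyes)] <- "Eyes"
  on_screen <- x >= 0 & x < layout$image_size[1] &
    y >= 0 & y < layout$image_size[2]
  out[!on_screen] <- "Other"
  out
}

# Integer zone mask (height x width), entries 1..4 in canonical zone order.
zone_mask <- function(layout) {
  w <- layout$image_size[1]; h <- layout$image_size[2]
  xs <- rep(0:(w - 1L), each = h)
  ys <- rep(0:(h - 1L), times = w)
  matrix(zone_index(zone_at(layout, xs, ys)), nrow = h, ncol = w)
}

check_gray <- function(img, what = "image") {
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0L)
    stop(what, " must be a non-empty 2-D numeric matrix of gray intensities",
         call. = FALSE)
  if (any(!is.finite(img)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(img)
}

# Gaussian blur with a kernel radius capped so it fits inside the image
# (EBImage::filter2 requires the filter to be no larger than the image).
gauss_blur <- function(img, sigma) {
  r <- 2 * ceiling(3 * sigma) + 1
  m <- min(dim(img))
  cap <- if (m %% 2 == 0) m - 1L else m
  r <- min(r, cap)
  if (r < 3) return(img)
  EBImage::gblur(img, sigma = sigma, radius = r)
}

# One center-surround map: |G(sigma_c) * I - G(sigma_s) * I|.
# Exposed internally so tests can compare a single scale against a direct
# convolution oracle.
center_surround <- function(img, sigma_c, sigma_s) {
  abs(gauss_blur(img, sigma_c) - gauss_blur(img, sigma_s))
}

#' Static (center-surround) saliency map
#'
#' Intensity-channel center-surround saliency: the image is smoothed at
#' three center scales (sigma 1, 2, 4 px) and, for each, two coarser
#' surround scales (2x and 4x the center sigma); the absolute
#' center-surround differences are max-normalized per scale and averaged.
#' Contours and isolated contrasts score high, flat regions score zero; the
#' map is invariant to adding a constant to the image.
#'
#' @param frame 2-D numeric matrix of gray intensities in \[0, 1\], indexed
#'   `[y + 1, x + 1]` (rows = image rows from the top).
#' @return Non-negative saliency matrix of the same size.
#' @export
#' @examples
#' static_saliency(matrix(0.5, 16, 16))  # flat image -> all zero
static_saliency <- function(frame) {
  check_gray(frame, "frame")
  centers <- c(1, 2, 4)
  ratios <- c(2, 4)
  acc <- matrix(0, nrow(frame), ncol(frame))
  k <- 0L
  for (sc in centers) {
    for (r in ratios) {
      m <- center_surround(frame, sc, sc * r)
      mx <- max(m)
      # threshold guards against amplifying numerical noise on flat scales
      if (mx > 1e-9) m <- m / mx else m[] <- 0
      acc <- acc + m
      k <- k + 1L
    }
  }
  acc / k
}

#' Dynamic (motion) saliency map
#'
#' Frame-difference motion energy: the squared intensity of each pixel is
#' computed in both frames and the per-pixel absolute difference of the
#' squares is returned. Static regions score zero. The first frame of a
#' sequence pairs with itself (all-zero map).
#'
#' @param frame,frame_prev Gray matrices of identical size, intensities in
#'   \[0, 1\].
#' @return Non-negative motion-saliency matrix.
#' @export
#' @examples
#' a <- matrix(0.5, 8, 8); b <- a; b[4, 4] <- 0.3
#' dynamic_saliency(b, a)[4, 4]  # |0.3^2 - 0.5^2| = 0.16
dynamic_saliency <- function(frame, frame_prev) {
  check_gray(frame, "frame"); check_gray(frame_prev, "frame_prev")
  if (!identical(dim(frame), dim(frame_prev)))
    stop("frames must have identical dimensions", call. = FALSE)
  abs(frame^2 - frame_prev^2)
}

#' Average a saliency map inside each zone
#'
#' @param map Saliency matrix matching the layout's image size (rows =
#'   height, columns = width).
#' @param layout An [aoi_layout()].
#' @return Named numeric vector of 4 per-zone mean values. A zone with zero
#'   pixel area yields 0 with a warning.
#' @export
aggregate_aoi <- function(map, layout) {
  check_gray(map, "map")
  if (nrow(map) != layout$image_size[2] || ncol(map) != layout$image_size[1])
    stop("map size does not match the layout image size", call. = FALSE)
  mask <- zone_mask(layout)
  out <- numeric(N_ZONES)
  for (z in seq_len(N_ZONES)) {
    sel <- mask == z
    if (!any(sel)) {
      warning("zone ", ZONES[z], " has zero area; mean set to 0",
              call. = FALSE)
      out[z] <- 0
    } else {
      out[z] <- mean(map[sel])
    }
  }
  setNames(out, ZONES)
}

#' Bottom-up zone distribution from per-zone saliency means
#'
#' Each set of per-zone means is normalized to a distribution; the two are
#' mixed as `theta * static + (1 - theta) * dynamic`. A component whose
#' means are all zero contributes a uniform distribution (it carries no
#' preference); if both are all zero the result is uniform with a warning,
#' so blank inter-trial frames do not halt a simulation.
#'
#' @param static_means,dynamic_means Non-negative numeric vectors of 4
#'   per-zone means.
#' @param theta Weight of the static component, in \[0, 1\].
#' @return A `zone_distribution` with role `"bottom_up"`.
#' @export
#' @examples
#' bottom_up_distribution(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.7, 0.1, 0.1), 0.5)
bottom_up_distribution <- function(static_means, dynamic_means, theta) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
      theta < 0 || theta > 1)
    stop("theta must lie in [0, 1]", call. = FALSE)
  sm <- as.numeric(static_means); dm <- as.numeric(dynamic_means)
  if (length(sm) != N_ZONES || length(dm) != N_ZONES ||
      any(sm < 0) || any(dm < 0) || any(!is.finite(c(sm, dm))))
    stop("saliency means must be 4 finite non-negative values each",
         call. = FALSE)
  if (sum(sm) <= 0 && sum(dm) <= 0) {
    warning("both saliency streams are all-zero; using a uniform ",
            "bottom-up distribution", call. = FALSE)
    return(zone_distribution(rep(1 / N_ZONES, N_ZONES), "bottom_up"))
  }
  ps <- if (sum(sm) > 0) sm / sum(sm) else rep(1 / N_ZONES, N_ZONES)
  pd <- if (sum(dm) > 0) dm / sum(dm) else rep(1 / N_ZONES, N_ZONES)
  zone_distribution(theta * ps + (1 - theta) * pd, "bottom_up")
}

#' Per-zone saliency streams from an image sequence
#'
#' Runs the full bottom-up front end over a sequence of gray frames: static
#' and dynamic saliency maps per frame, averaged inside each zone. The
#' dynamic map of the first frame is all zero (it pairs with itself).
#'
#' @param frames List of gray matrices of identical size (>= 2 frames).
#' @param layout An [aoi_layout()].
#' @return An `aoi_saliency_stream`: list with `static` and `dynamic`
#'   n-by-4 matrices (rows = steps, columns = zones).
#' @export
stream_from_frames <- function(frames, layout) {
  if (!is.list(frames) || length(frames) < 2L)
    stop("at least 2 frames are required", call. = FALSE)
  dims <- lapply(frames, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all frames must have identical dimensions", call. = FALSE)
  n <- length(frames)
  st <- matrix(0, n, N_ZONES, dimnames = list(NULL, ZONES))
  dy <- matrix(0, n, N_ZONES, dimnames = list(NULL, ZONES))
  for (i in seq_len(n)) {
    st[i, ] <- aggregate_aoi(static_saliency(frames[[i]]), layout)
    prev <- if (i == 1L) frames[[i]] else frames[[i - 1L]]
    dy[i, ] <- aggregate_aoi(dynamic_saliency(frames[[i]], prev), layout)
  }
  aoi_saliency_stream(st, dy)
}

#' Construct a per-zone saliency stream
#'
#' @param static,dynamic n-by-4 non-negative matrices of per-step, per-zone
#'   mean saliencies (columns in canonical zone order).
#' @return An object of class `aoi_saliency_stream`.
#' @export
aoi_saliency_stream <- function(static, dynamic) {
  static <- as.matrix(static); dynamic <- as.matrix(dynamic)
  if (!identical(dim(static), dim(dynamic)) || ncol(static) != N_ZONES)
    stop("static and dynamic must be n-by-4 matrices of equal size",
         call. = FALSE)
  if (any(static < 0) || any(dynamic < 0) ||
      any(!is.finite(static)) || any(!is.finite(dynamic)))
    stop("saliency means must be finite and non-negative", call. = FALSE)
  colnames(static) <- colnames(dynamic) <- ZONES
  structure(list(static = static, dynamic = dynamic, n_steps = nrow(static)),
            class = "aoi_saliency_stream")
}

#' @export
print.aoi_saliency_stream <- function(x, ...) {
  cat(sprintf("<aoi_saliency_stream %d steps>\n", x$n_steps))
  invisible(x)
}

# n-by-4 matrix of bottom-up distributions for every step of a stream.
bottom_up_matrix <- function(stream, theta) {
  norm_rows <- function(m) {
    s <- rowSums(m)
    out <- m / ifelse(s > 0, s, 1)
    out[s <= 0, ] <- 1 / N_ZONES
    out
  }
  theta * norm_rows(stream$static) + (1 - theta) * norm_rows(stream$dynamic)
}
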