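#' Render a synthetic grayscale frame stack with a known head position
#'
#' Builds a fixture for the tracking pipeline: every frame is a static
#' smooth background plus an animal-shaped bright ellipse whose major-axis
#' tip sits at the requested head position, optionally corrupted by
#' Gaussian pixel noise. The planted head path is recorded as ground truth.
#' Intensities are on the 8-bit scale `[0, 255]`.
#'
#' @param head_path numeric matrix (frames x 2) of head positions `(x, y)`
#'   in pixel coordinates (x = column, y = row); must stay inside the image.
#' @param image_size `c(rows, cols)` of each frame.
#' @param blob_shape list with elements `a` (semi-major axis, px), `b`
#'   (semi-minor axis, px), `angle` (orientation of the major axis, radians;
#'   the head tip is at `center + a * (cos angle, sin angle)`), and
#'   `intensity` (added brightness).
#' @param noise_sd SD of iid Gaussian pixel noise (intensity units).
#' @param port_axis unit 2-vector of the nose-port axis.
#' @param seed optional integer seed for the noise.
#' @param include_blob set `FALSE` to render the bare background (used to
#'   validate background estimation).
#' @return list of class `frame_stack`: `frames` (list of matrices),
#'   `ground_truth_head` (frames x 2), `port_axis`, `background`.
#' @export
render_synthetic_frames <- function(head_path,
                                    image_size = c(120, 160),
                                    blob_shape = list(a = 18, b = 9,
                                                      angle = 0, intensity = 160),
                                    noise_sd = 0,
                                    port_axis = c(1, 0),
                                    seed = NULL,
                                    include_blob = TRUE) {
  head_path <- matrix(as.numeric(head_path), ncol = 2)
  nr <- image_size[1]; nc <- image_size[2]
  if (2 * blob_shape$a >= min(nr, nc)) {
    stop("configuration error: blob larger than image")
  }
  if (any(head_path[, 1] < 1 | head_path[, 1] > nc |
            head_path[, 2] < 1 | head_path[, 2] > nr)) {
    stop("input error: head_path must lie inside image bounds")
  }
  if (!is.null(seed)) set.seed(seed)

  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  background <- 30 + 10 * sin(2 * pi * rows / nr) * cos(2 * pi * cols / nc) +
    0.05 * cols
  ca <- cos(blob_shape$angle); sa <- sin(blob_shape$angle)

  frames <- vector("list", nrow(head_path))
  for (f in seq_len(nrow(head_path))) {
    img <- background
    if (include_blob) {
      cx <- head_path[f, 1] - blob_shape$a * ca
      cy <- head_path[f, 2] - blob_shape$a * sa
      u <- (cols - cx) * ca + (rows - cy) * sa
      v <- -(cols - cx) * sa + (rows - cy) * ca
      inside <- (u / blob_shape$a)^2 + (v / blob_shape$b)^2 <= 1
      img[inside] <- img[inside] + blob_shape$intensity
    }
    if (noise_sd > 0) {
      img <- img + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    }
    frames[[f]] <- pmin(pmax(img, 0), 255)
  }
  structure(
    list(frames = frames, ground_truth_head = head_path,
         port_axis = port_axis / sqrt(sum(port_axis^2)),
         background = pmin(pmax(background, 0), 255)),
    class = "frame_stack"
  )
}
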