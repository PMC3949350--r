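#' Tracker configuration
#'
#' Parameters of the head-tracking pipeline: background-subtraction
#' threshold, minimum blob size, background estimator and the rule used to
#' decide which end of the body blob's principal axis is the head.
#'
#' @param threshold intensity difference (8-bit units) above which a pixel
#'   counts as animal.
#' @param min_blob_area smallest accepted blob, pixels (>= 1).
#' @param background_method per-pixel `"median"` (robust to the animal's
#'   transit) or `"mean"` over frames.
#' @param tip_disambiguation `"nearest_previous"` picks the axis endpoint
#'   closest to the previous head position; `"max_x"` picks the endpoint
#'   with the larger x (used when no history is available).
#' @param max_gap longest run of missing detections (frames) filled by
#'   linear interpolation; longer gaps flag the track unusable.
#' @return object of class `tracker_config`.
#' @export
tracker_config <- function(threshold = 40, min_blob_area = 20,
                           background_method = c("median", "mean"),
                           tip_disambiguation = c("nearest_previous", "max_x"),
                           max_gap = 5) {
  if (threshold < 0 || threshold > 255) stop("threshold outside valid intensity range")
  if (min_blob_area < 1) stop("min_blob_area must be >= 1")
  structure(
    list(threshold = threshold, min_blob_area = min_blob_area,
         background_method = match.arg(background_method),
         tip_disambiguation = match.arg(tip_disambiguation),
         max_gap = max_gap),
    class = "tracker_config"
  )
}

#' Estimate the static background of a frame stack
#'
#' Per-pixel median (default) or mean across frames. The median recovers
#' the clean scene whenever the animal occupies each pixel in fewer than
#' half of the frames.
#'
#' @param frames a `frame_stack` or a list of equally sized matrices.
#' @param method `"median"` or `"mean"`.
#' @return background matrix, same size as the frames.
#' @export
estimate_background <- function(frames, method = c("median", "mean")) {
  method <- match.arg(method)
  if (inherits(frames, "frame_stack")) frames <- frames$frames
  if (length(frames) == 0) stop("input error: empty frame stack")
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])
  flat <- vapply(frames, as.numeric, numeric(nr * nc))
  bg <- if (method == "median") {
    apply(flat, 1, median)
  } else {
    rowMeans(flat)
  }
  matrix(bg, nr, nc)
}

#' Segment the animal as the largest connected component
#'
#' Thresholds the absolute background-subtracted image and keeps the
#' largest 8-connected component, provided it reaches `min_blob_area`.
#' An empty mask (no pixel above threshold, or largest blob too small) is
#' returned as an all-`FALSE` matrix.
#'
#' @param frame,background matrices of identical shape.
#' @param config a [tracker_config()].
#' @return logical matrix, `TRUE` on the animal blob.
#' @export
segment_animal <- function(frame, background, config = tracker_config()) {
  if (!all(dim(frame) == dim(background))) {
    stop("input error: frame and background shapes differ")
  }
  bw <- abs(frame - background) > config$threshold
  if (!any(bw)) return(matrix(FALSE, nrow(frame), ncol(frame)))
  lab <- EBImage::bwlabel(bw * 1)
  lab <- as.matrix(lab)
  areas <- tabulate(lab[lab > 0])
  best <- which.max(areas)
  if (areas[best] < config$min_blob_area) {
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  }
  lab == best
}

#' Head position as a principal-axis endpoint of the body mask
#'
#' Finds the blob's largest axis from the second-order moments of the mask
#' pixels and returns the extreme mask pixel at one end of that axis. The
#' end corresponding to the head is chosen by the configured rule: nearest
#' to the previous head position, or (without history) the endpoint with
#' larger x. Near-circular masks have no well-defined major axis; the
#' returned point then carries attribute `degenerate = TRUE`.
#'
#' @param mask logical matrix, non-empty.
#' @param prev_head previous `(x, y)` head position or `NULL`.
#' @param config a [tracker_config()].
#' @return numeric `(x, y)` in pixels, possibly with attribute `degenerate`.
#' @export
extract_head_position <- function(mask, prev_head = NULL,
                                  config = tracker_config()) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("missing detection: empty mask")
  x <- idx[, 2]; y <- idx[, 1]
  if (nrow(idx) == 1) {
    return(structure(c(x, y), degenerate = TRUE))
  }
  cx <- mean(x); cy <- mean(y)
  C <- cov(cbind(x, y))
  eg <- eigen(C, symmetric = TRUE)
  v <- eg$vectors[, 1]
  degenerate <- eg$values[1] < 1.05 * max(eg$values[2], .Machine$double.eps)
  proj <- (x - cx) * v[1] + (y - cy) * v[2]
  i_hi <- which.max(proj); i_lo <- which.min(proj)
  ends <- rbind(c(x[i_hi], y[i_hi]), c(x[i_lo], y[i_lo]))
  pick <- if (!is.null(prev_head) &&
                config$tip_disambiguation == "nearest_previous") {
    d <- rowSums(sweep(ends, 2, prev_head)^2)
    which.min(d)
  } else {
    which.max(ends[, 1])
  }
  structure(ends[pick, ], degenerate = degenerate)
}

#' Project 2-D positions onto the port axis
#'
#' Returns the scalar component of each position along the (unit) axis on
#' which the nose ports are aligned; motion orthogonal to that axis is
#' discarded.
#'
#' @param positions numeric matrix (n x 2) or length-2 vector of `(x, y)`.
#' @param port_axis unit 2-vector.
#' @return numeric vector of 1-D positions, pixels.
#' @export
project_to_port_axis <- function(positions, port_axis = c(1, 0)) {
  nrm <- sqrt(sum(port_axis^2))
  if (nrm < 1e-12) stop("input error: zero port axis")
  if (abs(nrm - 1) > 1e-8) stop("input error: port_axis must have unit norm")
  positions <- matrix(as.numeric(positions), ncol = 2)
  as.numeric(positions %*% port_axis)
}

#' Track head position through a frame stack
#'
#' Full pipeline: estimate the background, segment the animal in every
#' frame, extract the principal-axis head tip (disambiguated against the
#' previous frame's position), fill missing detections by linear
#' interpolation up to `config$max_gap` consecutive frames, and project the
#' result onto the port axis.
#'
#' @param stack a `frame_stack` or list of matrices.
#' @param config a [tracker_config()].
#' @param init_head optional `(x, y)` hint for the first frame's tip
#'   disambiguation.
#' @param port_axis unit 2-vector; defaults to the stack's own axis when
#'   available.
#' @return list: `positions` (frames x 2 matrix of `(x, y)`, possibly with
#'   interpolated rows), `trajectory` (1-D port-axis positions), `usable`
#'   (FALSE when unfillable gaps remain), `n_missing` (frames without a
#'   detection).
#' @export
track_frames <- function(stack, config = tracker_config(), init_head = NULL,
                         port_axis = NULL) {
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  if (is.null(port_axis)) {
    port_axis <- if (inherits(stack, "frame_stack")) stack$port_axis else c(1, 0)
  }
  bg <- estimate_background(frames, config$background_method)
  n <- length(frames)
  pos <- matrix(NA_real_, n, 2)
  prev <- init_head
  for (f in seq_len(n)) {
    mask <- segment_animal(frames[[f]], bg, config)
    if (any(mask)) {
      h <- extract_head_position(mask, prev_head = prev, config = config)
      pos[f, ] <- h
      prev <- as.numeric(h)
    }
  }
  n_missing <- sum(is.na(pos[, 1]))
  if (n_missing > 0 && n_missing < n) {
    pos[, 1] <- zoo::na.approx(pos[, 1], maxgap = config$max_gap, na.rm = FALSE)
    pos[, 2] <- zoo::na.approx(pos[, 2], maxgap = config$max_gap, na.rm = FALSE)
  }
  usable <- !anyNA(pos)
  list(positions = pos,
       trajectory = if (usable) project_to_port_axis(pos, port_axis) else
         as.numeric(pos %*% port_axis),
       usable = usable,
       n_missing = n_missing)
}
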