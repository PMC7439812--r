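#' Read a binary leaf mask from a PNG or TIFF file
#'
#' Grayscale or color images are averaged to one channel and thresholded;
#' by default the threshold is chosen by Otsu's method, so grayscale scans
#' of silhouettes work as well as strict 0/1 masks.  File row order
#' (top-down) is converted to the package's y-up convention: the returned
#' matrix is indexed `[y, x]` with row 1 the bottom image row.
#'
#' @param path PNG or TIFF file.
#' @param threshold gray level in `[0, 1]` above which a pixel is foreground,
#'   or `NULL` for Otsu's method.
#' @return binary mask matrix.
#' @export
readMask <- function(path, threshold = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 3) img <- rowMeans(img, dims = 2)
  if (is.null(threshold)) {
    threshold <- if (length(unique(as.vector(img))) <= 2) 0.5
      else EBImage::otsu(EBImage::Image(t(img)))
  }
  mask <- matrix(as.integer(img > threshold), nrow(img), ncol(img))
  mask[rev(seq_len(nrow(mask))), , drop = FALSE]  # top-down file -> y-up
}

#' Write a binary mask as a PNG file
#'
#' @param mask binary mask matrix (y-up).
#' @param path output PNG path.
#' @export
writeMask <- function(mask, path) {
  assertMask(mask)
  png::writePNG(matrix(as.numeric(mask[rev(seq_len(nrow(mask))), ]),
                       nrow(mask), ncol(mask)), path)
  invisible(path)
}

# Largest foreground connected component (EBImage bwlabel does the labeling;
# EBImage images are [x, y], hence the transposes).
largestComponent <- function(mask) {
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask)))))
  if (max(lab) == 0) return(mask * 0L)
  tab <- tabulate(lab[lab > 0])
  matrix(as.integer(lab == which.max(tab)), nrow(mask), ncol(mask))
}

# Fill interior holes: background components not connected to the border
# become foreground.
fillHoles <- function(mask) {
  bg <- 1L - mask
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(bg)))))
  H <- nrow(lab); W <- ncol(lab)
  borderLabs <- unique(c(lab[1, ], lab[H, ], lab[, 1], lab[, W]))
  hole <- lab > 0 & !(lab %in% borderLabs)
  out <- mask
  out[hole] <- 1L
  out
}

#' Extract the ordered outer contour of a binary mask
#'
#' Traces the crack boundary of the largest foreground connected component
#' (marching-squares style, foreground kept on the left), emitting each
#' boundary pixel once per visit.  The result is the ordered, closed,
#' counter-clockwise (y-up convention) list of foreground pixels that touch
#' the exterior background through a 4-neighbor side.  Interior holes are
#' ignored; smaller components are discarded.
#'
#' @param mask binary mask matrix (`[y, x]`, y-up).
#' @return `n x 2` matrix of `(x, y)` pixel coordinates.
#' @export
extractContour <- function(mask) {
  assertMask(mask)
  if (sum(mask) == 0) stop("no foreground pixels in mask")
  comp <- largestComponent(mask)
  # degenerate if the component has no interior pixel anywhere
  H <- nrow(comp); W <- ncol(comp)
  pad <- matrix(0L, H + 2, W + 2); pad[2:(H + 1), 2:(W + 1)] <- comp
  interior <- pad[2:(H + 1), 2:(W + 1)] == 1L &
    pad[3:(H + 2), 2:(W + 1)] == 1L & pad[1:H, 2:(W + 1)] == 1L &
    pad[2:(H + 1), 3:(W + 2)] == 1L & pad[2:(H + 1), 1:W] == 1L
  if (!any(interior))
    stop("degenerate shape: component is thinner than 2 px everywhere")
  pts <- traceCrack(comp)
  if (nrow(pts) < 8)
    stop("degenerate shape: fewer than 8 boundary pixels")
  pts
}

# Crack-following contour tracer.  Walks pixel-corner lattice edges with
# foreground on the left (counter-clockwise, y-up), emitting the foreground
# pixel to the left of each forward step.  Corner (a, b) is the lower-left
# corner of pixel (x = a, y = b).
traceCrack <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  fg <- function(y, x) y >= 1 && y <= H && x >= 1 && x <= W && mask[y, x] == 1L
  idx <- which(mask == 1L, arr.ind = TRUE)
  r0 <- min(idx[, 1]); c0 <- min(idx[idx[, 1] == r0, 2])
  a <- c0; b <- r0
  dir <- 1L  # 1 = +x, 2 = +y, 3 = -x, 4 = -y
  cap <- 16L * (H + W)
  px <- integer(cap); py <- integer(cap); n <- 0L
  emit <- function(x, y) {
    if (n == length(px)) { px <<- c(px, integer(cap)); py <<- c(py, integer(cap)) }
    n <<- n + 1L; px[n] <<- x; py[n] <<- y
  }
  steps <- 0L
  repeat {
    if (dir == 1L) {          # +x: fg above the crack (row b), bg below
      if (fg(b - 1, a)) dir <- 4L
      else if (fg(b, a)) { emit(a, b); a <- a + 1L }
      else dir <- 2L
    } else if (dir == 3L) {   # -x: fg below (row b-1), bg above
      if (fg(b, a - 1)) dir <- 2L
      else if (fg(b - 1, a - 1)) { emit(a - 1L, b - 1L); a <- a - 1L }
      else dir <- 4L
    } else if (dir == 2L) {   # +y: fg left (col a-1), bg right
      if (fg(b, a)) dir <- 1L
      else if (fg(b, a - 1)) { emit(a - 1L, b); b <- b + 1L }
      else dir <- 3L
    } else {                  # -y: fg right (col a), bg left
      if (fg(b - 1, a - 1)) dir <- 3L
      else if (fg(b - 1, a)) { emit(a, b - 1L); b <- b - 1L }
      else dir <- 1L
    }
    if (a == c0 && b == r0 && dir == 1L && n > 0L) break
    steps <- steps + 1L
    if (steps > 64L * H * W) stop("contour tracing did not terminate")
  }
  pts <- cbind(x = px[seq_len(n)], y = py[seq_len(n)])
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) > 1 && all(pts[1, ] == pts[nrow(pts), ]))
    pts <- pts[-nrow(pts), , drop = FALSE]
  pts
}

#' Centroid of contour points
#'
#' The arithmetic mean of the ordered boundary coordinates (a boundary-point
#' mean, not an area centroid).
#'
#' @param points `n x 2` matrix of `(x, y)` coordinates.
#' @return numeric `(x, y)`.
#' @export
computeCentroid <- function(points) {
  points <- rbind(points)
  if (nrow(points) < 1) stop("need at least one contour point")
  c(mean(points[, 1]), mean(points[, 2]))
}

#' Compute the normalized centroid contour distance signature
#'
#' For each ordered boundary point the Euclidean distance to the centroid is
#' computed and divided by the maximum distance, making the signature scale
#' invariant; angles are measured counter-clockwise from the reference axis,
#' the ray from the centroid to the farthest boundary point, making it
#' rotation invariant.  The signature is circular: index arithmetic wraps
#' around the traversal.
#'
#' @param points ordered closed contour, `n x 2` matrix of `(x, y)`.
#' @param centroid optional `(x, y)`; defaults to [computeCentroid()].
#' @return object of class `contourSignature` with elements `points`,
#'   `centroid`, `distances`, `normDistances`, `angles` (degrees in
#'   `[0, 360)`), and `refIndex`.
#' @export
computeSignature <- function(points, centroid = computeCentroid(points)) {
  points <- rbind(points)
  if (nrow(points) < 3) stop("need at least 3 contour points")
  dx <- points[, 1] - centroid[1]
  dy <- points[, 2] - centroid[2]
  d <- sqrt(dx^2 + dy^2)
  dmax <- max(d)
  if (dmax == 0) stop("zero-radius shape: all points coincide with centroid")
  ref <- argmaxTol(d)
  ux <- dx[ref]; uy <- dy[ref]
  ang <- wrapAngle(atan2(ux * dy - uy * dx, ux * dx + uy * dy) * 180 / pi)
  ang[ref] <- 0
  structure(list(points = points, centroid = centroid, distances = d,
                 normDistances = d / dmax, angles = ang, refIndex = ref),
            class = "contourSignature")
}

#' One-call CCD signature of a mask
#'
#' @param mask binary mask matrix.
#' @return a `contourSignature` (see [computeSignature()]).
#' @export
ccdSignature <- function(mask) {
  computeSignature(extractContour(mask))
}

#' @export
print.contourSignature <- function(x, ...) {
  cat("CCD signature:", length(x$distances), "contour points, centroid (",
      round(x$centroid[1], 2), ",", round(x$centroid[2], 2),
      "), max distance", round(max(x$distances), 2), "px\n")
  invisible(x)
}

#' @export
plot.contourSignature <- function(x, ...) {
  ord <- order(x$angles)
  plot(x$angles[ord], x$normDistances[ord], type = "l",
       xlab = "angle from reference axis (deg)",
       ylab = "normalized centroid distance", ...)
  invisible(x)
}

#' Write a signature as CSV plus a JSON sidecar
#'
#' The CSV has columns `angle_deg` and `norm_distance`, one row per contour
#' point in traversal order; centroid and reference index go to
#' `<path>.json`.
#'
#' @param sig a `contourSignature`.
#' @param path output CSV path.
#' @export
writeSignature <- function(sig, path) {
  write.csv(data.frame(angle_deg = sig$angles,
                       norm_distance = sig$normDistances),
            path, row.names = FALSE)
  jsonlite::write_json(list(centroid = sig$centroid,
                            ref_index = sig$refIndex),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a signature written by [writeSignature()]
#'
#' @param path CSV path.
#' @return list with `angles`, `normDistances`, and, when the sidecar is
#'   present, `centroid` and `refIndex`.
#' @export
readSignature <- function(path) {
  df <- read.csv(path)
  out <- list(angles = df$angle_deg, normDistances = df$norm_distance)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    out$centroid <- meta$centroid
    out$refIndex <- meta$ref_index
  }
  out
}
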