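#' Convert a slice image to grayscale
#'
#' Fixed ITU-R 601 luma weights (0.299 R + 0.587 G + 0.114 B) so masks are
#' bit-reproducible across platforms. Grayscale input passes through
#' unchanged (idempotent); the intensity scale ([0, 1] or [0, 255]) is
#' preserved.
#'
#' @param image A numeric matrix (already grayscale) or an h x w x 3+
#'   array (RGB; extra channels such as alpha are ignored).
#' @return A numeric matrix of luminance values.
#' @export
to_grayscale <- function(image) {
  if (length(image) == 0) stop("empty image", call. = FALSE)
  if (is.matrix(image)) return(image)
  if (is.array(image) && length(dim(image)) == 3) {
    if (dim(image)[3] < 3) return(image[, , 1])
    return(0.299 * image[, , 1] + 0.587 * image[, , 2] +
             0.114 * image[, , 3])
  }
  stop("image must be a matrix or a 3-channel array", call. = FALSE)
}

#' Threshold a grayscale image into a foreground mask
#'
#' Foreground is every pixel strictly above the threshold — a bright slice
#' on a dark background by default; set `invert = TRUE` for the opposite
#' polarity. When no threshold is given it is selected by Otsu's
#' between-class variance criterion (the standard choice for bimodal
#' slice-on-background scenes), on a 256-level histogram.
#'
#' @param gray Numeric matrix; values in [0, 1] or [0, 255].
#' @param threshold Fixed threshold on the same scale as `gray`, or `NULL`
#'   for Otsu.
#' @param invert If TRUE the foreground is below-threshold.
#' @return Logical matrix, TRUE = foreground. A constant image with Otsu
#'   selection yields an all-background mask with a warning.
#' @export
binarize <- function(gray, threshold = NULL, invert = FALSE) {
  if (!is.matrix(gray)) stop("gray must be a single-channel matrix",
                             call. = FALSE)
  scale <- if (max(gray) > 1) 255 else 1
  if (is.null(threshold)) {
    if (max(gray) == min(gray)) {
      warning("constant image: Otsu threshold is degenerate", call. = FALSE)
      return(matrix(invert, nrow(gray), ncol(gray)))
    }
    clipped <- pmin(pmax(gray / scale, 0), 1)  # otsu needs [0, 1]
    threshold <- scale * EBImage::otsu(EBImage::Image(clipped),
                                       range = c(0, 1), levels = 256)
  }
  if (invert) gray < threshold else gray > threshold
}

# 4-connected labelling of a logical mask (EBImage's bwlabel is
# 4-connected; verified by its treatment of diagonal contacts)
label4 <- function(mask) {
  storage.mode(mask) <- "integer"
  matrix(as.integer(EBImage::imageData(EBImage::bwlabel(mask))),
         nrow(mask), ncol(mask))
}

# 8-connected labelling: merge 4-connected labels that touch diagonally
label8 <- function(mask) {
  l <- label4(mask)
  n <- max(l)
  if (n <= 1) return(l)
  nr <- nrow(l); nc <- ncol(l)
  a <- l[-nr, -nc]; b <- l[-1, -1]   # "\" diagonal neighbours
  c_ <- l[-1, -nc]; d <- l[-nr, -1]  # "/" diagonal neighbours
  pairs <- rbind(
    cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b]),
    cbind(c_[c_ > 0 & d > 0 & c_ != d], d[c_ > 0 & d > 0 & c_ != d])
  )
  if (nrow(pairs) == 0) return(l)
  g <- igraph::add_edges(igraph::make_empty_graph(n, directed = FALSE),
                         as.vector(t(pairs)))
  map <- igraph::components(g)$membership
  out <- l
  out[l > 0] <- map[l[l > 0]]
  out
}

#' Fill enclosed holes in a foreground mask
#'
#' Background components (4-connectivity) that do not reach the raster
#' border are enclosed by foreground and become foreground. Never removes
#' foreground, so the area can only grow; idempotent.
#'
#' @param mask Logical matrix, TRUE = foreground.
#' @return Logical matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  bg <- label4(!mask)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0]
  mask | (bg > 0 & !(bg %in% border_labels))
}

#' Remove small spurious foreground components
#'
#' Components are 8-connected (diagonal contact joins). Components smaller
#' than `min_area` pixels are removed; with `keep_largest` (the default)
#' only the single largest surviving component — the slice — is retained.
#' Equal-sized candidates are resolved toward the component containing the
#' earliest pixel in column-major (top-to-bottom, then left-to-right)
#' order. Idempotent; an empty mask passes through.
#'
#' @param mask Logical matrix, TRUE = foreground.
#' @param min_area Minimum component area in pixels.
#' @param keep_largest Keep only the largest component.
#' @return Filtered logical matrix.
#' @export
filter_particles <- function(mask, min_area = 0, keep_largest = TRUE) {
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  if (min_area < 0) stop("min_area must be non-negative", call. = FALSE)
  if (!any(mask)) return(mask)
  l <- label8(mask)
  sizes <- tabulate(l[l > 0])
  keep <- which(sizes >= min_area)
  if (keep_largest && length(keep) > 0) {
    biggest <- keep[sizes[keep] == max(sizes[keep])]
    if (length(biggest) > 1) {
      # column-major position of each tied component's first pixel
      first_px <- vapply(biggest, function(lab) which(l == lab)[1],
                         numeric(1))
      biggest <- biggest[which.min(first_px)]
    }
    keep <- biggest
  }
  matrix(l %in% keep, nrow(mask), ncol(mask))
}

#' Area shrinkage ratio
#'
#' `S(t) = A(t) / A(0)`: current slice pixel area relative to the initial
#' frame's.
#'
#' @param area_t Current area in pixels (>= 0).
#' @param area_0 Reference (initial) area in pixels (> 0).
#' @return Dimensionless shrinkage. Vectorised over `area_t`.
#' @export
shrinkage <- function(area_t, area_0) {
  if (length(area_0) != 1 || !is.finite(area_0) || area_0 <= 0) {
    stop("area_0 must be a single positive number", call. = FALSE)
  }
  if (any(area_t < 0)) stop("area_t must be non-negative", call. = FALSE)
  area_t / area_0
}

#' Read a slice image from file
#'
#' PNG via the png package, TIFF via the tiff package (chosen by file
#' extension). Values come back in [0, 1].
#'
#' @param path Image file path.
#' @return Matrix (grayscale) or 3-D array (colour).
#' @export
read_slice_image <- function(path) {
  if (!file.exists(path)) stop("no such image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the tiff package is required to read TIFF frames",
           call. = FALSE)
    }
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: .", ext, " (use PNG or TIFF)",
         call. = FALSE)
  }
}

#' Measure shrinkage over an image series
#'
#' Applies the full measurement pipeline — grayscale conversion,
#' thresholding, hole filling, particle filtering, pixel counting — to
#' every frame with one shared parameter set. The first frame defines the
#' reference area, so its shrinkage is exactly 1. A frame whose mask comes
#' out empty is recorded as shrinkage 0 with a warning and processing
#' continues.
#'
#' @param frames A list of images (matrices or RGB arrays) or a character
#'   vector of PNG/TIFF paths, in temporal order.
#' @param threshold,invert Passed to [binarize()] (default: Otsu,
#'   bright-on-dark).
#' @param min_area,keep_largest Passed to [filter_particles()].
#' @param roi Optional rectangular region of interest
#'   `c(row_min, row_max, col_min, col_max)` applied to every frame
#'   before segmentation; `NULL` (default) uses the full raster.
#' @return A tibble with columns `k`, `area_px`, `shrinkage`.
#' @export
#' @examples
#' stack <- generate_image_stack(kmax = 3, size = 96, r0 = 36, seed = 1)
#' process_frames(stack$frames)
process_frames <- function(frames, threshold = NULL, invert = FALSE,
                           min_area = 50, keep_largest = TRUE,
                           roi = NULL) {
  if (is.character(frames)) frames <- lapply(frames, read_slice_image)
  if (length(frames) < 1) stop("need at least one frame", call. = FALSE)
  if (!is.null(roi) && (length(roi) != 4 || roi[1] > roi[2] ||
                        roi[3] > roi[4])) {
    stop("roi must be c(row_min, row_max, col_min, col_max)",
         call. = FALSE)
  }
  areas <- vapply(seq_along(frames), function(k) {
    gray <- to_grayscale(frames[[k]])
    if (!is.null(roi)) {
      gray <- gray[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
    }
    mask <- binarize(gray, threshold = threshold, invert = invert)
    mask <- fill_holes(mask)
    mask <- filter_particles(mask, min_area = min_area,
                             keep_largest = keep_largest)
    a <- sum(mask)
    if (a == 0) {
      warning("frame ", k, ": empty mask, recording shrinkage 0",
              call. = FALSE)
    }
    a
  }, numeric(1))
  if (areas[1] == 0) {
    stop("reference frame has an empty mask; cannot define shrinkage",
         call. = FALSE)
  }
  tibble::tibble(
    k = seq_along(frames),
    area_px = as.integer(areas),
    shrinkage = shrinkage(areas, areas[1])
  )
}
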