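#' Convert an RGB raster to 8-bit grayscale
#'
#' Uses the ITU-R BT.601 luminance weights (0.299, 0.587, 0.114), rounds to
#' the nearest integer and clips to \[0, 255\].
#'
#' @param image Numeric array of dimension `height x width x 3` with values in
#'   \[0, 255\], or an already-gray `height x width` matrix (returned rounded
#'   and clipped unchanged otherwise).
#' @return An integer-valued `height x width` matrix of gray levels in
#'   \[0, 255\].
#' @examples
#' px <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' to_grayscale(px) # 76
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) {
    if (length(image) == 0) stopf("empty image: dimensions %s", paste(dim(image), collapse = "x"))
    return(pmin(pmax(round(image), 0), 255))
  }
  d <- dim(image)
  if (is.null(d) || length(d) != 3 || d[3] != 3) {
    stopf("expected an RGB array (h x w x 3), got dimensions %s",
          paste(d %||% length(image), collapse = "x"))
  }
  if (d[1] < 1 || d[2] < 1) stopf("empty image: dimensions %s", paste(d, collapse = "x"))
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  pmin(pmax(round(g), 0), 255)
}

#' Local binary pattern code of a single pixel
#'
#' Thresholds each of the `P` circular neighbors against the center gray value
#' and packs the comparison bits into an integer:
#' `code = sum_p s(g_p - g_c) 2^p` with `s(x) = 1` iff `x >= 0`. Neighbor `p`
#' contributes bit `p`; the package convention places `p = 0` at the east
#' neighbor and proceeds counter-clockwise.
#'
#' @param center Gray value of the center pixel, in \[0, 255\].
#' @param neighbors Ordered vector of `P` neighbor gray values.
#' @return Integer code in `[0, 2^P - 1]`.
#' @examples
#' lbp_code(100, rep(100, 8)) # 255: s(0) = 1
#' lbp_code(100, c(90, 110, 100, 95, 120, 80, 100, 101)) # 214
#' @export
lbp_code <- function(center, neighbors) {
  p <- length(neighbors)
  if (p < 1) stopf("neighbors must be a non-empty vector")
  sum(as.integer(neighbors >= center) * 2^(seq_len(p) - 1))
}

#' Canonical rotation-invariant form of an LBP code
#'
#' Circularly rotates the `P`-bit pattern and returns the minimum value over
#' all `P` rotations. Codes in the same rotation orbit share a canonical form,
#' which makes descriptors built on canonical codes invariant to image
#' rotation (a 90 degree rotation of the image cyclically shifts the 8-neighbor
#' ring by two positions).
#'
#' @param code Integer vector of LBP codes in `[0, 2^P - 1]`.
#' @param P Number of neighbors (bits), default 8.
#' @return Integer vector of canonical codes, same length as `code`.
#' @examples
#' min_rotation(128) # 1
#' min_rotation(6)   # 3
#' @export
min_rotation <- function(code, P = 8) {
  code <- as.integer(code)
  if (any(is.na(code)) || any(code < 0) || any(code >= 2^P)) {
    stopf("code out of range [0, %d]", 2^P - 1)
  }
  mask <- as.integer(2^P - 1)
  best <- code
  rot <- code
  for (r in seq_len(P - 1)) {
    rot <- bitwAnd(bitwOr(bitwShiftR(code, r), bitwShiftL(code, P - r)), mask)
    best <- pmin(best, rot)
  }
  best
}

#' Build the LBP-to-rotation-class mapping
#'
#' Partitions the `2^P` LBP codes into cyclic-rotation orbits and assigns
#' contiguous class indices `0..C-1` in ascending order of the orbit's
#' canonical (minimal) code. For `P = 8` there are exactly 36 classes; the
#' 36-bin histogram over these classes is the LBPri descriptor.
#'
#' @param P Number of neighbors, default 8.
#' @return An object of class `ri_mapping`: a list with `table` (integer
#'   vector of length `2^P`, `table[code + 1]` = class index), `n_classes`,
#'   and `P`.
#' @examples
#' m <- build_ri_mapping()
#' m$n_classes # 36
#' @export
build_ri_mapping <- function(P = 8) {
  codes <- 0:(2^P - 1)
  canon <- min_rotation(codes, P = P)
  levels <- sort(unique(canon))
  structure(
    list(
      table = match(canon, levels) - 1L,
      n_classes = length(levels),
      P = as.integer(P)
    ),
    class = "ri_mapping"
  )
}

# LBP codes for every interior pixel of a gray matrix, vectorized.
# Neighbor p = 0 is east; the ring proceeds counter-clockwise (row index
# grows downward, so "north" is row - 1). Border pixels lack a full
# 8-neighborhood and are skipped.
lbp_codes <- function(gray) {
  h <- nrow(gray)
  w <- ncol(gray)
  if (h < 3 || w < 3) stopf("block too small for LBP: %dx%d (need at least 3x3)", h, w)
  ri <- 2:(h - 1)
  ci <- 2:(w - 1)
  ctr <- gray[ri, ci, drop = FALSE]
  offs <- list(
    c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L),
    c(0L, -1L), c(1L, -1L), c(1L, 0L), c(1L, 1L)
  )
  code <- matrix(0L, h - 2, w - 2)
  for (p in 0:7) {
    o <- offs[[p + 1]]
    nb <- gray[ri + o[1], ci + o[2], drop = FALSE]
    code <- code + bitwShiftL(1L, p) * (nb >= ctr)
  }
  code
}

check_gray_block <- function(block) {
  if (!is.matrix(block)) {
    d <- dim(block)
    if (!is.null(d) && length(d) == 3) return(check_gray_block(to_grayscale(block)))
    stopf("expected a gray matrix or RGB array")
  }
  if (nrow(block) < 3 || ncol(block) < 3) {
    stopf("block too small for LBP: %dx%d (need at least 3x3)", nrow(block), ncol(block))
  }
  if (any(block < 0) || any(block > 255)) stopf("gray values must lie in [0, 255]")
  block
}

#' LBP and rotation-invariant LBP histograms of a gray block
#'
#' `lbp_histogram()` counts, for each of the 256 LBP codes, how many interior
#' pixels of the block produce that code (`P = 8`, `R = 1`); the total equals
#' the interior pixel count `(h - 2)(w - 2)`. `lbpri_histogram()` aggregates
#' the same counts through the rotation-class mapping into 36 bins.
#'
#' @param block Gray-level matrix (values in \[0, 255\]), at least 3x3.
#' @param params List with `P` and `R`; only `P = 8`, `R = 1` is supported.
#' @param mapping An `ri_mapping` from [build_ri_mapping()]; computed on the
#'   fly when omitted.
#' @return Integer count vector of length 256 (`lbp_histogram`) or
#'   `mapping$n_classes` (`lbpri_histogram`).
#' @examples
#' b <- matrix(100, 10, 10)
#' h <- lbp_histogram(b)
#' h[256] # all 64 interior pixels code to 255
#' @export
lbp_histogram <- function(block, params = list(P = 8, R = 1)) {
  block <- check_gray_block(block)
  if (!identical(as.integer(params$P %||% 8L), 8L) ||
      !identical(as.integer(params$R %||% 1L), 1L)) {
    stopf("only P = 8, R = 1 is supported")
  }
  codes <- lbp_codes(block)
  tabulate(codes + 1L, nbins = 256L)
}

#' @rdname lbp_histogram
#' @export
lbpri_histogram <- function(block, params = list(P = 8, R = 1), mapping = NULL) {
  mapping <- mapping %||% ri_mapping_cached()
  h <- lbp_histogram(block, params)
  as.integer(rowsum(h, mapping$table + 1L)[, 1])
}

# the P = 8 mapping is fixed; build it once per session
.histonto_cache <- new.env(parent = emptyenv())
ri_mapping_cached <- function() {
  if (is.null(.histonto_cache$ri)) .histonto_cache$ri <- build_ri_mapping(8)
  .histonto_cache$ri
}

#' Column names of the 292-value block descriptor
#'
#' @return Character vector `lbp_000..lbp_255, ri_00..ri_35`.
#' @export
descriptor_names <- function() {
  c(sprintf("lbp_%03d", 0:255), sprintf("ri_%02d", 0:35))
}

#' Describe a block with the concatenated LBP|LBPri texture descriptor
#'
#' Computes the 256-bin LBP histogram and the 36-bin LBPri histogram of a
#' (nominally 100x100) gray block and concatenates them into a single
#' 292-value feature vector. By default each sub-histogram is L1-normalized
#' (sums to 1) before concatenation so descriptors are comparable across
#' block sizes and stable as SVM inputs; set `normalize = FALSE` for raw
#' interior-pixel counts.
#'
#' @param block Gray matrix or RGB array; RGB input is converted with
#'   [to_grayscale()].
#' @param normalize L1-normalize each sub-histogram (default `TRUE`).
#' @param mapping Optional precomputed [build_ri_mapping()] result.
#' @return Named numeric vector of length 292 (names from
#'   [descriptor_names()]).
#' @examples
#' d <- describe_block(matrix(sample(0:255, 1e4, TRUE), 100, 100))
#' length(d) # 292
#' sum(d)    # 2: each sub-histogram sums to 1
#' @export
describe_block <- function(block, normalize = TRUE, mapping = NULL) {
  block <- check_gray_block(block)
  mapping <- mapping %||% ri_mapping_cached()
  codes <- lbp_codes(block)
  lbp <- tabulate(codes + 1L, nbins = 256L)
  ri <- as.integer(rowsum(lbp, mapping$table + 1L)[, 1])
  if (normalize) {
    n <- sum(lbp)
    lbp <- lbp / n
    ri <- ri / n
  }
  stats::setNames(c(lbp, ri), descriptor_names())
}

#' Read and write images and descriptor tables
#'
#' `read_image()` loads a PNG into a `height x width x 3` array of 8-bit
#' values in \[0, 255\]; gray PNGs are expanded to three identical channels.
#' `write_image()` is the inverse. `write_descriptors()` stores a matrix of
#' block descriptors as CSV with the stable 292-column header
#' `lbp_000..ri_35`; `read_descriptors()` loads it back.
#'
#' @param path File path.
#' @param image Array `h x w x 3` (values 0-255).
#' @param x Descriptor matrix (`n x 292`) as produced by stacking
#'   [describe_block()] rows.
#' @return `read_image()` an RGB array; `read_descriptors()` a numeric
#'   matrix with 292 named columns.
#' @export
read_image <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 2) raw <- array(rep(raw, 3), dim = c(dim(raw), 3))
  if (dim(raw)[3] > 3) raw <- raw[, , 1:3, drop = FALSE] # drop alpha
  round(raw * 255)
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 255) / 255, target = path)
  invisible(path)
}

#' @rdname read_image
#' @export
write_descriptors <- function(x, path) {
  x <- as.matrix(x)
  if (ncol(x) != 292) stopf("descriptor table must have 292 columns, got %d", ncol(x))
  colnames(x) <- descriptor_names()
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_image
#' @export
read_descriptors <- function(path) {
  x <- as.matrix(utils::read.csv(path, check.names = FALSE))
  if (ncol(x) != 292) stopf("descriptor table must have 292 columns, got %d", ncol(x))
  colnames(x) <- descriptor_names()
  x
}
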