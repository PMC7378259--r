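#' Tile an image into fixed-size square blocks
#'
#' Splits an image into non-overlapping `block_size x block_size` blocks in
#' row-major order starting from the top-left corner. Trailing rows/columns
#' that do not fill a whole block are discarded, so a 2048x1536 pixel image
#' tiles to a 15-row x 20-column grid (floor division on each axis).
#'
#' @param image Gray matrix or RGB array (`h x w x 3`), at least
#'   `block_size` pixels in each dimension.
#' @param block_size Block side length in pixels (default 100).
#' @return An object of class `block_grid`: list with `blocks` (row-major
#'   list of sub-rasters), `nrow`, `ncol`, `block_size`. Block `(i, j)`
#'   covers pixel rows `[(i-1) s + 1, i s]` and columns `[(j-1) s + 1, j s]`.
#' @examples
#' g <- tile_image(matrix(0, 250, 130))
#' c(g$nrow, g$ncol) # 2 rows x 1 column
#' @export
tile_image <- function(image, block_size = 100) {
  d <- dim(image)
  if (is.null(d) || !(length(d) %in% c(2, 3))) stopf("expected a matrix or h x w x 3 array")
  h <- d[1]
  w <- d[2]
  if (h < block_size || w < block_size) {
    stopf("image (%dx%d) smaller than one %dx%d block", h, w, block_size, block_size)
  }
  m <- h %/% block_size
  n <- w %/% block_size
  blocks <- vector("list", m * n)
  k <- 1L
  for (i in seq_len(m)) {
    rr <- ((i - 1L) * block_size + 1L):(i * block_size)
    for (j in seq_len(n)) {
      cc <- ((j - 1L) * block_size + 1L):(j * block_size)
      blocks[[k]] <- if (length(d) == 2) image[rr, cc] else image[rr, cc, , drop = FALSE]
      k <- k + 1L
    }
  }
  structure(
    list(blocks = blocks, nrow = m, ncol = n, block_size = as.integer(block_size)),
    class = "block_grid"
  )
}

#' @export
print.block_grid <- function(x, ...) {
  cat(sprintf(
    "<block_grid> %d rows x %d cols (%d blocks of %dx%d px)\n",
    x$nrow, x$ncol, length(x$blocks), x$block_size, x$block_size
  ))
  invisible(x)
}

#' Label matrix of a block-classified image
#'
#' A `label_matrix` holds one tissue label per block of a tiled image,
#' together with a per-cell provenance flag recording which stage produced
#' the label: `"classifier"` (cascade SVM output), `"corrected"`
#' (knowledge-base organ correction), `"epithelium"` (epithelium detection)
#' or `"truth"` (fixture ground truth).
#'
#' @param labels Character matrix of tissue label mnemonics (see
#'   [tissue_labels()]).
#' @param provenance Single string or character matrix of the same shape.
#' @return An object of class `label_matrix` (a character matrix with a
#'   `provenance` attribute).
#' @seealso [classify_image()], [refine()], [write_label_matrix()]
#' @export
label_matrix <- function(labels, provenance = "classifier") {
  if (!is.matrix(labels) || !is.character(labels)) stopf("labels must be a character matrix")
  check_labels(labels)
  if (is.character(provenance) && length(provenance) == 1) {
    provenance <- matrix(provenance, nrow(labels), ncol(labels))
  }
  if (!identical(dim(provenance), dim(labels))) stopf("provenance shape must match labels")
  structure(labels, provenance = provenance, class = c("label_matrix", "matrix"))
}

provenance <- function(x) attr(x, "provenance")

# rebuild a label_matrix after editing labels/provenance in place
set_cells <- function(x, idx, label, prov) {
  p <- provenance(x)
  y <- unclass(x)
  attr(y, "provenance") <- NULL
  y[idx] <- label
  p[idx] <- prov
  label_matrix(y, p)
}

#' @export
print.label_matrix <- function(x, ...) {
  cat(sprintf("<label_matrix> %d x %d blocks\n", nrow(x), ncol(x)))
  tab <- table(factor(as.character(x), levels = tissue_labels()))
  cat(paste(sprintf("%s:%d", names(tab), tab), collapse = "  "), "\n")
  print(matrix(as.character(x), nrow(x), ncol(x)), quote = FALSE)
  invisible(x)
}

#' Read and write label matrices
#'
#' CSV form: one line per grid row, comma-separated label mnemonics, no
#' header (provenance is not stored). JSON form: labels and provenance as
#' row-major arrays plus the grid shape.
#'
#' @param x A [label_matrix()].
#' @param path File path; format chosen by extension (`.csv` or `.json`).
#' @return `read_label_matrix()` returns a `label_matrix` (CSV input gets
#'   provenance `"classifier"`).
#' @export
write_label_matrix <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(
      nrow = nrow(x), ncol = ncol(x),
      labels = apply(unclass(x), 1, as.character, simplify = FALSE),
      provenance = apply(provenance(x), 1, as.character, simplify = FALSE)
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE)
  } else {
    writeLines(apply(unclass(x), 1, paste, collapse = ","), path)
  }
  invisible(path)
}

#' @rdname write_label_matrix
#' @export
read_label_matrix <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    as_mat <- function(v) {
      if (is.matrix(v)) v else matrix(unlist(v), obj$nrow, obj$ncol, byrow = TRUE)
    }
    return(label_matrix(as_mat(obj$labels), as_mat(obj$provenance)))
  }
  rows <- strsplit(trimws(readLines(path)), ",")
  rows <- rows[lengths(rows) > 0]
  n <- unique(lengths(rows))
  if (length(n) != 1) stopf("ragged label CSV: row lengths %s", paste(n, collapse = ", "))
  label_matrix(matrix(trimws(unlist(rows)), length(rows), n, byrow = TRUE))
}
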