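# Independent oracles and shared fixtures for the test suite.

# Brute-force cyclic-rotation canonicalization of an 8-bit code, implemented
# on explicit bit vectors (independent of the package's shift-based path).
oracle_min_rotation <- function(code) {
  bits <- as.integer(intToBits(code))[1:8]
  vals <- vapply(0:7, function(r) {
    # rotate bit p -> (p - r) mod 8
    rot <- if (r == 0) bits else c(bits[(r + 1):8], bits[1:r])
    sum(rot * 2^(0:7))
  }, numeric(1))
  min(vals)
}

# Brute-force LBP code via the sign-sum definition, no bit operators.
oracle_lbp_code <- function(center, neighbors) {
  s <- ifelse(neighbors - center >= 0, 1, 0)
  sum(s * 2^(seq_along(neighbors) - 1))
}

# Reference per-pixel LBP histogram on a small block: explicit double loop
# over interior pixels with the documented neighbor ordering (p = 0 east,
# counter-clockwise).
oracle_lbp_histogram <- function(block) {
  offs <- list(
    c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
    c(0, -1), c(1, -1), c(1, 0), c(1, 1)
  )
  h <- integer(256)
  for (i in 2:(nrow(block) - 1)) {
    for (j in 2:(ncol(block) - 1)) {
      nb <- vapply(offs, function(o) block[i + o[1], j + o[2]], numeric(1))
      code <- oracle_lbp_code(block[i, j], nb)
      h[code + 1] <- h[code + 1] + 1
    }
  }
  h
}

random_gray_block <- function(n = 16, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(sample(0:255, n * n, replace = TRUE), n, n)
}

# clockwise 90-degree rotation of a matrix
rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

# Small cascade model trained on separable fixture blocks, cached per test
# run (training is deterministic, so sharing it across tests is safe).
.test_cache <- new.env(parent = emptyenv())

fixture_descriptor_set <- function(seeds) {
  cls <- classifier_labels()
  X <- do.call(rbind, lapply(cls, function(cl) {
    t(vapply(seeds, function(s) describe_block(generate_block(cl, s)), numeric(292)))
  }))
  list(x = X, y = rep(cls, each = length(seeds)))
}

small_cascade_model <- function() {
  if (is.null(.test_cache$model)) {
    train <- fixture_descriptor_set(1:10)
    .test_cache$model <- train_cascade(train$x, train$y, cascade_config(seed = 42L))
  }
  .test_cache$model
}

small_validation_set <- function() {
  if (is.null(.test_cache$val)) .test_cache$val <- fixture_descriptor_set(11:15)
  .test_cache$val
}

# label matrix wrapper for plain label vectors (1 x n grids), used to score
# block collections with the matrix-based metrics
as_label_row <- function(labels, provenance = "classifier") {
  label_matrix(matrix(labels, nrow = 1), provenance)
}

# classifier-view of a truth matrix: the EP ring renders (and classifies)
# as light region, and provenance is the classifier's
classifier_view <- function(truth) {
  lab <- matrix(as.character(truth), nrow(truth), ncol(truth))
  lab[lab == "EP"] <- "LR"
  label_matrix(lab, "classifier")
}
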