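#' Configuration for the cascade SVM
#'
#' Hyperparameters for the two classification stages. Stage 1 is a five-class
#' linear-kernel SVM over `{C1, MA, HE, LC, LR}` where `C1` merges the two
#' texture-wise similar smooth-muscle classes (elastic artery and large
#' vein). Stage 2 is a binary polynomial-kernel SVM consulted only when
#' stage 1 emits `C1`, separating `EA` from `LV`.
#'
#' @param cost1,cost2 Soft-margin cost for stage 1 / stage 2 (default 100:
#'   the L1-normalized descriptors have per-feature magnitude around 1/256,
#'   so the linear margin needs a high cost to tighten on such small-scale
#'   inputs; at cost 1 the five-class stage visibly underfits).
#' @param degree Polynomial degree of the stage-2 kernel (default 3).
#' @param gamma Kernel coefficient for stage 2; default `1/292` (libsvm's
#'   `1/dim` scaling).
#' @param coef0 Stage-2 polynomial offset (default 1, so low-order terms
#'   contribute).
#' @param seed Integer recorded with the model; training itself is
#'   deterministic for fixed inputs.
#' @return A list of class `cascade_config`.
#' @export
cascade_config <- function(cost1 = 100, cost2 = 100, degree = 3,
                           gamma = 1 / 292, coef0 = 1, seed = 1L) {
  structure(
    list(cost1 = cost1, cost2 = cost2, degree = degree,
         gamma = gamma, coef0 = coef0, seed = as.integer(seed)),
    class = "cascade_config"
  )
}

# fixed stage-1 class order; also the deterministic tie-break order used by
# libsvm's one-vs-one voting (earlier level wins vote ties)
stage1_levels <- function() c("HE", "MA", "LC", "LR", "C1")

as_descriptor_matrix <- function(descriptors) {
  if (is.list(descriptors) && !is.data.frame(descriptors)) {
    descriptors <- do.call(rbind, descriptors)
  }
  x <- as.matrix(descriptors)
  if (ncol(x) != 292) {
    stopf("descriptors must have 292 columns (LBP 256 + LBPri 36), got %d", ncol(x))
  }
  colnames(x) <- descriptor_names()
  x
}

#' Train the cascade SVM block classifier
#'
#' Relabels `EA`/`LV` examples to the merged class `C1`, fits the five-class
#' linear stage on all examples, then fits the polynomial stage on the
#' `EA`/`LV` subset alone. If only one (or neither) of `EA`/`LV` is present,
#' stage 2 is skipped with a warning and `C1` predictions fall back to the
#' single class seen (or error if neither was seen, since `C1` then cannot
#' occur).
#'
#' @param descriptors `n x 292` matrix (or list of descriptor vectors) from
#'   [describe_block()].
#' @param labels Character vector of `n` labels, each one of
#'   [classifier_labels()].
#' @param config A [cascade_config()].
#' @return An object of class `cascade_model`.
#' @examples
#' \donttest{
#' blocks <- lapply(classifier_labels(), function(cl)
#'   lapply(1:5, function(s) generate_block(cl, seed = s)))
#' X <- do.call(rbind, lapply(unlist(blocks, recursive = FALSE), describe_block))
#' y <- rep(classifier_labels(), each = 5)
#' model <- train_cascade(X, y)
#' }
#' @export
train_cascade <- function(descriptors, labels, config = cascade_config()) {
  x <- as_descriptor_matrix(descriptors)
  labels <- as.character(labels)
  check_labels(labels, allowed = classifier_labels())
  if (nrow(x) != length(labels)) stopf("one descriptor per label required")
  if (length(unique(labels)) < 2) stopf("need at least 2 classes to train")

  y1 <- ifelse(labels %in% c("EA", "LV"), "C1", labels)
  lev1 <- intersect(stage1_levels(), unique(y1))
  stage1 <- e1071::svm(
    x = x, y = factor(y1, levels = lev1),
    kernel = "linear", cost = config$cost1, scale = FALSE
  )

  sub <- labels %in% c("EA", "LV")
  have <- intersect(c("EA", "LV"), unique(labels[sub]))
  stage2 <- NULL
  fallback <- NULL
  if (length(have) == 2) {
    stage2 <- e1071::svm(
      x = x[sub, , drop = FALSE], y = factor(labels[sub], levels = c("EA", "LV")),
      kernel = "polynomial", degree = config$degree, gamma = config$gamma,
      coef0 = config$coef0, cost = config$cost2, scale = FALSE
    )
  } else if (length(have) == 1) {
    warning("only ", have, " examples present: stage 2 skipped, C1 maps to ", have,
            call. = FALSE)
    fallback <- have
  }

  structure(
    list(
      stage1 = stage1, stage2 = stage2, stage2_fallback = fallback,
      feature_names = descriptor_names(), config = config,
      seed = config$seed, classes = sort(unique(labels)),
      schema = model_schema_version()
    ),
    class = "cascade_model"
  )
}

model_schema_version <- function() "cascade-1"

#' @export
print.cascade_model <- function(x, ...) {
  cat("<cascade_model>\n")
  cat("  stage 1: linear SVM over", paste(x$stage1$levels, collapse = ", "), "\n")
  cat("  stage 2:",
      if (is.null(x$stage2)) paste("absent (fallback:", x$stage2_fallback %||% "none", ")")
      else "polynomial SVM over EA, LV", "\n")
  cat("  trained on classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' Classify block descriptors with a trained cascade model
#'
#' `classify_blocks()` labels each row of a descriptor matrix; stage 2 is
#' consulted exactly for the rows stage 1 assigns to the merged `C1` class,
#' so the final label set is always a subset of [classifier_labels()] and
#' `C1` never escapes. `classify_block()` is the single-descriptor
#' convenience form.
#'
#' @param model A [train_cascade()] model.
#' @param descriptors `n x 292` matrix (or single descriptor vector of
#'   length 292).
#' @param d A single descriptor vector (length 292).
#' @return Character vector of tissue labels (`classify_block()`: length 1).
#' @export
classify_blocks <- function(model, descriptors) {
  if (!inherits(model, "cascade_model")) stopf("model must be a cascade_model")
  if (is.vector(descriptors) && is.numeric(descriptors)) {
    descriptors <- matrix(descriptors, nrow = 1)
  }
  x <- as_descriptor_matrix(descriptors)
  out <- as.character(predict(model$stage1, x))
  c1 <- out == "C1"
  if (any(c1)) {
    if (!is.null(model$stage2)) {
      out[c1] <- as.character(predict(model$stage2, x[c1, , drop = FALSE]))
    } else if (!is.null(model$stage2_fallback)) {
      out[c1] <- model$stage2_fallback
    } else {
      stopf("stage 1 emitted C1 but no stage 2 is available")
    }
  }
  out
}

#' @rdname classify_blocks
#' @export
classify_block <- function(model, d) {
  if (length(d) != 292) stopf("descriptor must have length 292, got %d", length(d))
  classify_blocks(model, d)[1]
}

#' Classify a whole histological image block by block
#'
#' Converts the image to grayscale, tiles it into `block_size x block_size`
#' blocks (trailing partial blocks discarded), describes every block with
#' [describe_block()] and labels it with the cascade model. The result is the
#' image's label matrix: cell `(i, j)` is the label of the block covering
#' pixel rows/columns `(i, j)` of the grid, with provenance `"classifier"`.
#'
#' @param model A [train_cascade()] model.
#' @param image RGB array (`h x w x 3`) or gray matrix, values 0-255.
#' @param block_size Block side in pixels (default 100).
#' @return A [label_matrix()] of shape `floor(h/s) x floor(w/s)`.
#' @export
classify_image <- function(model, image, block_size = 100) {
  gray <- if (is.matrix(image)) image else to_grayscale(image)
  grid <- tile_image(gray, block_size = block_size)
  x <- t(vapply(grid$blocks, describe_block, numeric(292)))
  labs <- classify_blocks(model, x)
  label_matrix(matrix(labs, grid$nrow, grid$ncol, byrow = TRUE), "classifier")
}

#' Persist and restore cascade models
#'
#' Models are stored as a versioned RDS archive; loading verifies the schema
#' version and restores a model whose predictions are bit-identical to the
#' saved one.
#'
#' @param model A `cascade_model`.
#' @param path File path (conventionally `.rds`).
#' @return `load_model()` returns the restored `cascade_model`.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "cascade_model")) stopf("model must be a cascade_model")
  saveRDS(list(schema = model$schema, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  obj <- tryCatch(readRDS(path), error = function(e) {
    stopf("cannot read model archive %s: %s", path, conditionMessage(e))
  })
  if (!is.list(obj) || is.null(obj$schema)) stopf("not a cascade model archive: %s", path)
  if (!identical(obj$schema, model_schema_version())) {
    stopf(
      "unsupported model schema version '%s' (this build reads '%s')",
      obj$schema, model_schema_version()
    )
  }
  obj$model
}
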