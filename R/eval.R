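#' Confusion matrix between predicted and true label matrices
#'
#' Cross-tabulates cells over the seven tissue labels. Rows are truth,
#' columns are prediction; entry `(i, j)` counts cells whose true label is
#' `i` and predicted label is `j`. Row sums therefore equal the per-class
#' truth counts.
#'
#' @param pred,truth Label matrices (or plain character matrices) of
#'   identical shape.
#' @return A 7x7 integer matrix with dimnames `truth` x `predicted`.
#' @export
confusion_matrix <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    stopf("shape mismatch: pred %s vs truth %s",
          paste(dim(pred), collapse = "x"), paste(dim(truth), collapse = "x"))
  }
  check_labels(as.character(pred))
  check_labels(as.character(truth))
  lv <- tissue_labels()
  tab <- table(
    truth = factor(as.character(truth), levels = lv),
    predicted = factor(as.character(pred), levels = lv)
  )
  m <- matrix(as.integer(tab), length(lv), length(lv),
              dimnames = list(truth = lv, predicted = lv))
  m
}

#' Per-class F-score of a block classification
#'
#' One-vs-rest over cells: precision `P = TP / (TP + FP)`, recall
#' `R = TP / (TP + FN)`, `F = 2PR / (P + R)`. `F = 0` when the class occurs
#' (in prediction or truth) but `P + R = 0`; `NA` (undefined) when the class
#' is absent from both prediction and truth — a class that never appears is
#' not a zero-score class, it simply cannot be scored.
#'
#' @param pred,truth Label matrices of identical shape.
#' @param class A tissue label mnemonic.
#' @return F-score in \[0, 1\], or `NA` if undefined.
#' @export
f_score <- function(pred, truth, class) {
  check_labels(class)
  cm <- confusion_matrix(pred, truth)
  f_from_confusion(cm, class)
}

f_from_confusion <- function(cm, class) {
  tp <- cm[class, class]
  fp <- sum(cm[, class]) - tp
  fn <- sum(cm[class, ]) - tp
  if (tp + fp + fn == 0) return(NA_real_)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Evaluation report for a block classification
#'
#' Computes the 7x7 confusion matrix, per-class precision/recall/F-score,
#' micro-averaged accuracy (trace over total) and the macro F-score over the
#' classes that are defined (present in prediction or truth; absent classes
#' are excluded from the macro average).
#'
#' @param pred,truth Label matrices of identical shape, or lists of such
#'   matrices (pooled cell-wise into one report).
#' @return An object of class `eval_report`: list with `confusion`,
#'   `per_class` (data.frame), `accuracy`, `macro_f`, `n`.
#' @examples
#' truth <- label_matrix(matrix(c("HE", "HE", "LC", "LC"), 2, 2), "truth")
#' eval_report(truth, truth)$accuracy # 1
#' @export
eval_report <- function(pred, truth) {
  if (!is.list(pred)) pred <- list(pred)
  if (!is.list(truth)) truth <- list(truth)
  if (length(pred) != length(truth)) stopf("pred and truth lists differ in length")
  cm <- Reduce(`+`, Map(confusion_matrix, pred, truth))
  lv <- tissue_labels()
  per_class <- data.frame(
    label = lv,
    truth_n = as.integer(rowSums(cm)),
    pred_n = as.integer(colSums(cm)),
    precision = NA_real_, recall = NA_real_, f = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(lv)) {
    cl <- lv[i]
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    if (tp + fp + fn == 0) next
    per_class$precision[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    per_class$recall[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    per_class$f[i] <- f_from_confusion(cm, cl)
  }
  structure(
    list(
      confusion = cm,
      per_class = per_class,
      accuracy = sum(diag(cm)) / max(sum(cm), 1),
      macro_f = mean(per_class$f, na.rm = TRUE),
      n = sum(cm)
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat(sprintf("<eval_report> %d blocks, accuracy %.3f, macro F %.3f\n",
              x$n, x$accuracy, x$macro_f))
  pc <- x$per_class
  pc$precision <- round(pc$precision, digits)
  pc$recall <- round(pc$recall, digits)
  pc$f <- round(pc$f, digits)
  print(pc, row.names = FALSE)
  invisible(x)
}

#' Serialize an evaluation report
#'
#' JSON carries the full report (confusion matrix, per-class metrics,
#' aggregates); CSV carries the per-class table only.
#'
#' @param report An [eval_report()].
#' @param path Output path, `.json` or `.csv`.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(report$per_class, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(
        labels = tissue_labels(),
        confusion = apply(report$confusion, 1, as.integer, simplify = FALSE),
        per_class = report$per_class,
        accuracy = report$accuracy,
        macro_f = report$macro_f,
        n = report$n
      ),
      path, auto_unbox = TRUE, digits = NA, na = "null"
    )
  }
  invisible(path)
}

# class palette (RGB 0-255): HE green, LC blue, MA violet, LV yellow,
# EA orange, LR fuchsia, EP pink
label_palette <- function() {
  list(
    HE = c(0, 166, 81), LC = c(46, 91, 207), MA = c(146, 61, 198),
    LV = c(242, 222, 44), EA = c(245, 130, 32), LR = c(255, 0, 255),
    EP = c(255, 153, 181)
  )
}

#' Render class and hit/miss overlays for a classified image
#'
#' Paints each block with a translucent class color (heart green, loose
#' connective blue, muscular artery violet, large vein yellow, elastic
#' artery orange, light regions fuchsia, epithelium pink). When a truth
#' matrix is supplied, a second panel frames each block green (hit) or red
#' (miss).
#'
#' @param image RGB array (`h x w x 3`, 0-255) tiling to `pred`'s shape.
#' @param pred A [label_matrix()].
#' @param truth Optional [label_matrix()] of the same shape.
#' @param alpha Overlay opacity in \[0, 1\] (default 0.5).
#' @param path Optional path prefix; writes `<path>_classes.png` and, when
#'   truth is given, `<path>_hits.png`.
#' @return List with `classes` (RGB array) and `hits` (RGB array or
#'   `NULL`), invisibly when `path` is supplied.
#' @export
render_overlay <- function(image, pred, truth = NULL, alpha = 0.5, path = NULL) {
  d <- dim(image)
  if (length(d) != 3) stopf("image must be an RGB array")
  s_r <- d[1] %/% nrow(pred)
  s_c <- d[2] %/% ncol(pred)
  if (s_r < 1 || s_c < 1 || s_r != s_c) {
    stopf("image (%dx%d) does not tile to the %dx%d label grid",
          d[1], d[2], nrow(pred), ncol(pred))
  }
  if (!is.null(truth) && !identical(dim(truth), dim(pred))) {
    stopf("truth shape %s does not match pred shape %s",
          paste(dim(truth), collapse = "x"), paste(dim(pred), collapse = "x"))
  }
  s <- s_r
  pal <- label_palette()
  classes <- image
  for (i in seq_len(nrow(pred))) {
    rr <- ((i - 1) * s + 1):(i * s)
    for (j in seq_len(ncol(pred))) {
      cc <- ((j - 1) * s + 1):(j * s)
      col <- pal[[as.character(unclass(pred)[i, j])]]
      if (is.null(col)) stopf("no palette entry for label '%s'", unclass(pred)[i, j])
      for (ch in 1:3) {
        classes[rr, cc, ch] <- (1 - alpha) * classes[rr, cc, ch] + alpha * col[ch]
      }
    }
  }
  hits <- NULL
  if (!is.null(truth)) {
    hits <- classes
    bw <- max(2, s %/% 16) # border width in px
    for (i in seq_len(nrow(pred))) {
      rr <- ((i - 1) * s + 1):(i * s)
      for (j in seq_len(ncol(pred))) {
        cc <- ((j - 1) * s + 1):(j * s)
        col <- if (unclass(pred)[i, j] == unclass(truth)[i, j]) c(0, 200, 0) else c(220, 0, 0)
        edge_r <- c(head(rr, bw), tail(rr, bw))
        edge_c <- c(head(cc, bw), tail(cc, bw))
        for (ch in 1:3) {
          hits[edge_r, cc, ch] <- col[ch]
          hits[rr, edge_c, ch] <- col[ch]
        }
      }
    }
  }
  out <- list(classes = round(classes), hits = if (is.null(hits)) NULL else round(hits))
  if (!is.null(path)) {
    write_image(out$classes, paste0(path, "_classes.png"))
    if (!is.null(out$hits)) write_image(out$hits, paste0(path, "_hits.png"))
    return(invisible(out))
  }
  out
}

#' Compare classification reports before and after refinement
#'
#' Convenience wrapper producing the side-by-side evaluation: one report for
#' the raw classifier output and one for the refined matrices, against the
#' same ground truth.
#'
#' @param pred,refined,truth Label matrices or lists of label matrices.
#' @return List of class `eval_comparison` with `before`, `after`, and
#'   `delta_f` (named per-class F-score differences, after minus before).
#' @export
compare_reports <- function(pred, refined, truth) {
  before <- eval_report(pred, truth)
  after <- eval_report(refined, truth)
  delta <- after$per_class$f - before$per_class$f
  names(delta) <- tissue_labels()
  structure(list(before = before, after = after, delta_f = delta),
            class = "eval_comparison")
}

#' @export
print.eval_comparison <- function(x, ...) {
  cat("== before refinement ==\n")
  print(x$before)
  cat("== after refinement ==\n")
  print(x$after)
  cat("delta F (after - before):\n")
  print(round(x$delta_f, 3))
  invisible(x)
}
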