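#' Tissue label vocabulary
#'
#' The pipeline works with seven block-level tissue labels:
#' \describe{
#'   \item{EA}{smooth muscle of the elastic artery}
#'   \item{LV}{smooth muscle of the large vein}
#'   \item{MA}{smooth muscle of the muscular artery}
#'   \item{HE}{cardiac muscle of the heart}
#'   \item{LC}{loose connective tissue (veins, arteries and heart)}
#'   \item{LR}{light regions (lumina, background)}
#'   \item{EP}{flat simple epithelial tissue}
#' }
#' The cascade classifier only ever emits the first six; `EP` is produced
#' exclusively by the knowledge-base refinement stage. The four *discriminant*
#' labels (`EA`, `LV`, `MA`, `HE`) each implicate a single organ; `LC` and
#' `LR` occur in every organ and carry no organ identity.
#'
#' @return A character vector of label mnemonics, in the fixed order used by
#'   confusion matrices and reports.
#' @examples
#' tissue_labels()
#' discriminant_labels()
#' @export
tissue_labels <- function() c("EA", "LV", "MA", "HE", "LC", "LR", "EP")

#' @rdname tissue_labels
#' @export
classifier_labels <- function() c("EA", "LV", "MA", "HE", "LC", "LR")

#' @rdname tissue_labels
#' @export
discriminant_labels <- function() c("EA", "LV", "MA", "HE")

# organ term <-> discriminant label lookup tables
.label_to_organ <- c(
  EA = "ElasticArtery",
  LV = "LargeVein",
  MA = "MuscularArtery",
  HE = "Heart"
)
.organ_to_label <- stats::setNames(names(.label_to_organ), .label_to_organ)

#' Map a tissue label to the organ it implicates
#'
#' Discriminant labels map to their organ term in the knowledge-base
#' vocabulary; non-discriminant labels (`LC`, `LR`) and the derived `EP` label
#' are not associated with any organ and map to `NA`.
#'
#' @param label Character vector of tissue label mnemonics.
#' @return Character vector of organ terms (`"Heart"`, `"ElasticArtery"`,
#'   `"MuscularArtery"`, `"LargeVein"`) or `NA` where no organ is implicated.
#' @examples
#' organ_of(c("HE", "LC", "EP"))
#' @export
organ_of <- function(label) {
  check_labels(label)
  out <- unname(.label_to_organ[label])
  out
}

#' @rdname organ_of
#' @param organ Character vector of organ terms.
#' @export
label_for_organ <- function(organ) {
  bad <- setdiff(organ, names(.organ_to_label))
  if (length(bad) > 0) {
    stopf("unknown organ term(s): %s", paste(bad, collapse = ", "))
  }
  unname(.organ_to_label[organ])
}

check_labels <- function(label, allowed = tissue_labels()) {
  bad <- setdiff(unique(label), allowed)
  if (length(bad) > 0) {
    stopf(
      "invalid tissue label(s): %s (expected one of %s)",
      paste(bad, collapse = ", "), paste(allowed, collapse = ", ")
    )
  }
  invisible(label)
}
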