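#' Count occurrences of the discriminant classes in a label matrix
#'
#' Counts how many blocks carry each of the four organ-implicating labels
#' (`EA`, `LV`, `MA`, `HE`). The non-discriminant labels (`LC`, `LR`) and the
#' derived `EP` label are ignored: they occur in every organ and carry no
#' organ identity.
#'
#' @param matrix A [label_matrix()].
#' @return Named integer vector over `EA, LV, MA, HE`.
#' @export
count_occurrences <- function(matrix) {
  check_labels(as.character(matrix))
  tab <- table(factor(as.character(matrix), levels = discriminant_labels()))
  stats::setNames(as.integer(tab), discriminant_labels())
}

#' Rank organs by discriminant-class occurrence
#'
#' Orders the organs whose discriminant class occurs at least once,
#' descending by block count. Ties are broken by the fixed priority
#' `HE > MA > EA > LV` (heart first: cardiac muscle is the least confusable
#' texture) and reported with a warning, since a tie means the occurrence
#' evidence alone cannot order the organs.
#'
#' @param table Named count vector from [count_occurrences()].
#' @return Character vector of organ terms, most frequent first; empty when
#'   all counts are zero (no correction is possible without a dominant
#'   organ).
#' @export
rank_organs <- function(table) {
  stopifnot(all(discriminant_labels() %in% names(table)))
  tab <- table[discriminant_labels()]
  tab <- tab[tab > 0]
  if (length(tab) == 0) return(character())
  prio <- c(HE = 1, MA = 2, EA = 3, LV = 4)
  ord <- order(-as.numeric(tab), prio[names(tab)])
  ranked <- names(tab)[ord]
  if (anyDuplicated(tab) > 0 && length(unique(tab)) < length(tab)) {
    warning("occurrence tie among {", paste(names(tab), collapse = ", "),
            "}: broken by fixed priority HE > MA > EA > LV", call. = FALSE)
  }
  organ_of(ranked)
}

#' Build presence-query rules from ranked organs
#'
#' For every ordered pair of ranked organs `(A, B)` with `A` ranked above
#' `B`, emits the query triple `(A, hasPresenceOf, B)`: "does a sample of
#' the better-supported organ contain the wall of the less-supported one?".
#' `k` ranked organs yield `k (k - 1) / 2` rules.
#'
#' @param ranked Organ terms from [rank_organs()], most frequent first.
#' @return A data.frame of class `rule_set` with columns `subject`,
#'   `predicate`, `object`, `subject_rank`, `object_rank`.
#' @examples
#' build_rules(c("Heart", "ElasticArtery"))
#' @export
build_rules <- function(ranked) {
  ranked <- as.character(ranked)
  for (o in ranked) check_term(o, "organs", "organ")
  if (anyDuplicated(ranked)) stopf("ranked organ list contains duplicates")
  k <- length(ranked)
  if (k < 2) {
    rules <- data.frame(
      subject = character(), predicate = character(), object = character(),
      subject_rank = integer(), object_rank = integer(), stringsAsFactors = FALSE
    )
    return(structure(rules, class = c("rule_set", "data.frame")))
  }
  pairs <- which(upper.tri(matrix(TRUE, k, k)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  rules <- data.frame(
    subject = ranked[pairs[, "row"]],
    predicate = "hasPresenceOf",
    object = ranked[pairs[, "col"]],
    subject_rank = as.integer(pairs[, "row"]),
    object_rank = as.integer(pairs[, "col"]),
    stringsAsFactors = FALSE
  )
  structure(rules, class = c("rule_set", "data.frame"))
}

#' Apply presence rules: reclassify impossible organ labels
#'
#' Queries each rule against the knowledge base in order. When the answer is
#' empty (the subject organ has no asserted presence of the object organ),
#' every block bearing the object organ's discriminant label is reclassified
#' to loose connective tissue (`LC`, provenance `"corrected"`) — organ false
#' positives arise on connective tissue, so that is the best replacement
#' label. A non-empty answer validates the initial classification and leaves
#' the cells untouched. A single pass is made; occurrence counts are not
#' recomputed between rules.
#'
#' @param matrix A [label_matrix()].
#' @param rules A [build_rules()] rule set (normally built from this
#'   matrix's own occurrence table).
#' @param kb A `histo_kb`.
#' @return The corrected [label_matrix()].
#' @export
apply_rules <- function(matrix, rules, kb) {
  out <- matrix
  if (nrow(rules) == 0) return(out)
  for (r in seq_len(nrow(rules))) {
    if (!ask_presence(kb, rules$subject[r], rules$object[r])) {
      lab <- label_for_organ(rules$object[r])
      idx <- which(as.character(out) == lab)
      if (length(idx) > 0) out <- set_cells(out, idx, "LC", "corrected")
    }
  }
  out
}

#' Find large light-region components
#'
#' Identifies 4-connected components of `LR` cells with at least `min_size`
#' members — the "ten or more consecutive blocks" criterion that makes a
#' light region a plausible lumen rather than inter-tissue background.
#'
#' @param matrix A [label_matrix()].
#' @param min_size Minimum component size in blocks (default 10).
#' @return List of components, largest first. Each component is a list with
#'   `cells` (two-column matrix of row/col indices), `size`, and `boundary`
#'   (the member cells with at least one 4-neighbor outside the component).
#' @export
find_light_components <- function(matrix, min_size = 10) {
  lab <- as.character(matrix)
  m <- nrow(matrix)
  n <- ncol(matrix)
  is_lr <- matrix(lab == "LR", m, n)
  comp <- matrix(0L, m, n)
  ncomp <- 0L
  for (start in which(is_lr & comp == 0L)) {
    if (comp[start] != 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    comp[start] <- ncomp
    while (length(queue) > 0) {
      cur <- queue[1]
      queue <- queue[-1]
      i <- (cur - 1L) %% m + 1L
      j <- (cur - 1L) %/% m + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- i + d[1]
        jj <- j + d[2]
        if (ii >= 1 && ii <= m && jj >= 1 && jj <= n) {
          nxt <- (jj - 1L) * m + ii
          if (is_lr[nxt] && comp[nxt] == 0L) {
            comp[nxt] <- ncomp
            queue <- c(queue, nxt)
          }
        }
      }
    }
  }
  comps <- list()
  for (k in seq_len(ncomp)) {
    idx <- which(comp == k)
    if (length(idx) < min_size) next
    cells <- cbind(row = (idx - 1L) %% m + 1L, col = (idx - 1L) %/% m + 1L)
    on_boundary <- vapply(seq_len(nrow(cells)), function(q) {
      i <- cells[q, 1]
      j <- cells[q, 2]
      nb <- rbind(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
      inside <- nb[, 1] >= 1 & nb[, 1] <= m & nb[, 2] >= 1 & nb[, 2] <= n
      if (any(!inside)) return(TRUE)
      any(comp[cbind(nb[inside, 1], nb[inside, 2])] != k)
    }, logical(1))
    comps[[length(comps) + 1]] <- list(
      cells = cells, size = length(idx),
      boundary = cells[on_boundary, , drop = FALSE]
    )
  }
  comps[order(-vapply(comps, `[[`, numeric(1), "size"))]
}

# 4-neighbor labels of a set of cells, with the neighbor coordinates
neighbor_cells <- function(cells, m, n) {
  nb <- rbind(
    cbind(cells[, 1] - 1L, cells[, 2]),
    cbind(cells[, 1] + 1L, cells[, 2]),
    cbind(cells[, 1], cells[, 2] - 1L),
    cbind(cells[, 1], cells[, 2] + 1L)
  )
  src <- rep(seq_len(nrow(cells)), 4)
  keep <- nb[, 1] >= 1 & nb[, 1] <= m & nb[, 2] >= 1 & nb[, 2] <= n
  list(nb = nb[keep, , drop = FALSE], src = src[keep])
}

#' Does a light component qualify as a candidate lumen?
#'
#' A large light region only suggests epithelium when its neighbourhood
#' contains muscle: at least one cell 4-adjacent to the component must carry
#' a label in `qualifying_classes`. This eliminates false positives from
#' light regions lying between loose connective tissue or near the tunica
#' adventitia. The default set is the four muscle classes; the listed
#' smooth-muscle organs plus cardiac muscle (epithelium is detected in heart
#' images too, where the lining is the endocardium).
#'
#' @param component One component from [find_light_components()].
#' @param matrix The [label_matrix()] the component was found in.
#' @param qualifying_classes Labels that qualify the neighbourhood (default
#'   `EA, LV, MA, HE`).
#' @return `TRUE` or `FALSE`.
#' @export
qualifies_for_epithelium <- function(component, matrix,
                                     qualifying_classes = discriminant_labels()) {
  nb <- neighbor_cells(component$cells, nrow(matrix), ncol(matrix))
  any(as.character(matrix)[(nb$nb[, 2] - 1L) * nrow(matrix) + nb$nb[, 1]] %in%
        qualifying_classes)
}

#' Recognise epithelial tissue along lumen/muscle boundaries
#'
#' For each qualifying light component (size >= `min_size`, muscle in its
#' neighbourhood), the knowledge base is asked which epithelium type lines
#' the dominant organ of the matrix. When the answer is non-empty, the
#' component cells lying on the limit between light region and muscle —
#' i.e. `LR` cells with at least one 4-neighbor in `qualifying_classes` —
#' are relabeled `EP` with provenance `"epithelium"`. An empty answer (no
#' `hasEpithelium` fact, or no dominant organ) leaves the matrix unchanged:
#' there is then a high probability the image contains no epithelial tissue.
#'
#' @inheritParams qualifies_for_epithelium
#' @param matrix A [label_matrix()], normally already organ-corrected.
#' @param kb A `histo_kb`.
#' @param min_size Minimum light-component size in blocks (default 10).
#' @return The [label_matrix()] with epithelium marked.
#' @export
detect_epithelium <- function(matrix, kb, min_size = 10,
                              qualifying_classes = discriminant_labels()) {
  comps <- find_light_components(matrix, min_size = min_size)
  if (length(comps) == 0) return(matrix)
  counts <- count_occurrences(matrix)
  ranked <- suppressWarnings(rank_organs(counts))
  if (length(ranked) == 0) return(matrix)
  ep <- epithelium_of(kb, ranked[1])
  if (is.null(ep)) return(matrix)
  m <- nrow(matrix)
  out <- matrix
  for (comp in comps) {
    if (!qualifies_for_epithelium(comp, out, qualifying_classes)) next
    nb <- neighbor_cells(comp$cells, m, ncol(matrix))
    touches <- as.character(out)[(nb$nb[, 2] - 1L) * m + nb$nb[, 1]] %in% qualifying_classes
    edge <- unique(nb$src[touches])
    if (length(edge) > 0) {
      idx <- (comp$cells[edge, 2] - 1L) * m + comp$cells[edge, 1]
      out <- set_cells(out, idx, "EP", "epithelium")
    }
  }
  out
}

#' Refine a classified label matrix with the knowledge base
#'
#' The full refinement pass, in order: (1) organ correction — occurrences of
#' the discriminant classes are counted, presence rules are built from the
#' organ ranking and queried against the knowledge base, and impossible
#' organ labels are reclassified to `LC` ([apply_rules()]); (2) epithelium
#' recognition on the corrected matrix ([detect_epithelium()]). The pass is
#' idempotent: refining an already-refined matrix changes nothing.
#'
#' @param matrix Classifier-produced [label_matrix()].
#' @param kb A `histo_kb`, e.g. [default_kb()].
#' @param min_size Minimum light-component size for epithelium candidacy.
#' @param qualifying_classes Muscle classes that qualify a light region's
#'   neighbourhood.
#' @return The refined [label_matrix()].
#' @examples
#' lab <- matrix("LC", 5, 8)
#' lab[2:4, 2:7] <- "HE"
#' lab[3, 3:5] <- "EA" # impossible: elastic artery inside a heart sample
#' refined <- refine(label_matrix(lab), default_kb())
#' table(as.character(refined))
#' @export
refine <- function(matrix, kb, min_size = 10,
                   qualifying_classes = discriminant_labels()) {
  counts <- count_occurrences(matrix)
  ranked <- suppressWarnings(rank_organs(counts))
  out <- apply_rules(matrix, build_rules(ranked), kb)
  detect_epithelium(out, kb, min_size = min_size,
                    qualifying_classes = qualifying_classes)
}

#' Calibrate the light-region size threshold against ground truth
#'
#' Exhaustively searches the candidate thresholds `t` and returns the one
#' minimising the total annotation error
#' `Ae(t) = sum_i | rho_g_i - rho_i(t) |`, where `rho_i(t)` is the label
#' matrix the pipeline produces with threshold `t` and `rho_g_i` the
#' corresponding ground truth. For categorical matrices the absolute
#' difference is realised as the Hamming distance (number of disagreeing
#' cells). Ties are broken toward the smallest threshold.
#'
#' @param problem A [calibration_problem()].
#' @return List with `t_star` (winning threshold), `ae` (named numeric
#'   vector of errors per candidate).
#' @export
calibrate_threshold <- function(problem) {
  if (!inherits(problem, "calibration_problem")) {
    stopf("problem must be a calibration_problem")
  }
  cand <- problem$candidates
  if (length(cand) == 0) stopf("empty candidate set")
  ae <- vapply(cand, function(t) {
    outs <- problem$outputs(t)
    if (length(outs) != length(problem$truths)) {
      stopf("outputs(t = %s) returned %d matrices for %d ground truths",
            t, length(outs), length(problem$truths))
    }
    sum(vapply(seq_along(outs), function(i) {
      hamming_distance(problem$truths[[i]], outs[[i]])
    }, numeric(1)))
  }, numeric(1))
  names(ae) <- as.character(cand)
  best <- min(ae)
  list(t_star = cand[which(ae == best)[1]], ae = ae)
}

#' @rdname calibrate_threshold
#' @param truths List of ground-truth [label_matrix()] objects.
#' @param outputs Function of one argument `t` returning the list of
#'   automatic label matrices produced with threshold `t` (same length and
#'   order as `truths`).
#' @param candidates Integer vector of thresholds to sweep.
#' @export
calibration_problem <- function(truths, outputs, candidates) {
  if (length(truths) == 0) stopf("need at least one ground truth")
  if (!is.function(outputs)) stopf("outputs must be a function of t")
  candidates <- sort(unique(as.integer(candidates)))
  structure(
    list(truths = truths, outputs = outputs, candidates = candidates),
    class = "calibration_problem"
  )
}

#' Hamming distance between two label matrices
#'
#' @param a,b Label matrices of identical shape.
#' @return Number of cells where the labels disagree.
#' @export
hamming_distance <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stopf("shape mismatch: %s vs %s", paste(dim(a), collapse = "x"),
          paste(dim(b), collapse = "x"))
  }
  sum(as.character(a) != as.character(b))
}
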