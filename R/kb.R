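# Closed-world triple store over a fixed cardiovascular histology vocabulary.
# Queries answer by membership only: a fact that was never asserted is
# "empty", and the refinement stage reads emptiness as "anatomically
# impossible, reclassify". No subsumption inference is performed (none is
# needed for the correction and epithelium-recognition behaviour).

KB_PREFIX <- "ch"
KB_NAMESPACE <- "http://example.org/cardiohisto#"

#' The controlled vocabulary of the histology knowledge base
#'
#' @return A list with the registered `organs`, `tissues`, `epithelia` and
#'   `predicates`. Terms outside this vocabulary are rejected by every
#'   knowledge-base operation.
#' @export
kb_vocabulary <- function() {
  list(
    organs = c("Heart", "ElasticArtery", "MuscularArtery", "LargeVein"),
    tissues = c("CardiacMuscle", "SmoothMuscle", "LooseConnective", "EpithelialLining"),
    epithelia = c("FlatSimpleEpithelium"),
    predicates = c("hasPresenceOf", "hasEpithelium")
  )
}

check_term <- function(term, kinds = c("organs", "tissues", "epithelia", "predicates"),
                       what = "term") {
  voc <- kb_vocabulary()
  ok <- unlist(voc[kinds], use.names = FALSE)
  if (length(term) != 1 || !term %in% ok) {
    stopf("unregistered %s '%s' (vocabulary: %s)", what, as.character(term)[1],
          paste(ok, collapse = ", "))
  }
  term
}

#' Create an empty knowledge base
#'
#' A `histo_kb` is a finite, duplicate-free set of
#' `(subject, predicate, object)` triples over a closed vocabulary of
#' cardiovascular organs, tissues, epithelium types and the predicates
#' `hasPresenceOf` / `hasEpithelium`. Subjects must be organs;
#' `hasPresenceOf` objects must be organs and `hasEpithelium` objects must be
#' epithelium types. Terms outside the vocabulary are rejected, which keeps
#' "unknown term" errors distinct from legitimate empty answers.
#'
#' @return An object of class `histo_kb`.
#' @seealso [default_kb()], [kb_assert()], [ask_presence()], [epithelium_of()]
#' @export
kb_new <- function() {
  structure(
    list(triples = data.frame(
      subject = character(), predicate = character(), object = character(),
      stringsAsFactors = FALSE
    )),
    class = "histo_kb"
  )
}

#' Assert a triple in a knowledge base
#'
#' @param kb A `histo_kb`.
#' @param subject An organ term.
#' @param predicate `"hasPresenceOf"` or `"hasEpithelium"`.
#' @param object An organ term (for `hasPresenceOf`) or an epithelium type
#'   (for `hasEpithelium`).
#' @return The updated `histo_kb` (duplicate assertions are no-ops).
#' @export
kb_assert <- function(kb, subject, predicate, object) {
  if (!inherits(kb, "histo_kb")) stopf("kb must be a histo_kb")
  check_term(subject, "organs", "subject")
  check_term(predicate, "predicates", "predicate")
  if (predicate == "hasPresenceOf") {
    check_term(object, "organs", "object")
  } else {
    check_term(object, "epithelia", "object")
  }
  t <- kb$triples
  dup <- t$subject == subject & t$predicate == predicate & t$object == object
  if (!any(dup)) {
    kb$triples <- rbind(t, data.frame(
      subject = subject, predicate = predicate, object = object,
      stringsAsFactors = FALSE
    ))
  }
  kb
}

#' Number of triples in a knowledge base
#' @param kb A `histo_kb`.
#' @export
kb_size <- function(kb) nrow(kb$triples)

#' @export
print.histo_kb <- function(x, ...) {
  cat(sprintf("<histo_kb> %d triple(s)\n", kb_size(x)))
  if (kb_size(x) > 0) {
    print(x$triples, row.names = FALSE)
  }
  invisible(x)
}

#' The default cardiovascular knowledge base
#'
#' Encodes the facts the refinement stage relies on:
#' \itemize{
#'   \item No cross-organ `hasPresenceOf` facts among the four organs:
#'     histological samples of the heart, elastic artery, muscular artery and
#'     large vein are prepared per organ, so a slide of one organ does not
#'     contain the wall of another. Under closed-world semantics every
#'     cross-organ presence query therefore answers empty, which triggers
#'     reclassification of the impossible organ labels.
#'   \item `hasEpithelium` facts mapping each of the four organs to
#'     `FlatSimpleEpithelium` (the endothelium/endocardium lining vessel and
#'     heart lumina).
#' }
#' Users modelling, e.g., vasa vasorum can assert additional presence facts
#' with [kb_assert()] or via a Turtle file to suppress the correction.
#'
#' @return A `histo_kb`.
#' @examples
#' kb <- default_kb()
#' ask_presence(kb, "Heart", "ElasticArtery") # FALSE: empty answer
#' epithelium_of(kb, "Heart")                 # "FlatSimpleEpithelium"
#' @export
default_kb <- function() {
  kb <- kb_new()
  for (organ in kb_vocabulary()$organs) {
    kb <- kb_assert(kb, organ, "hasEpithelium", "FlatSimpleEpithelium")
  }
  kb
}

#' Query organ co-presence (closed world)
#'
#' Answers whether the fact `(organA, hasPresenceOf, organB)` is asserted.
#' An absent fact yields `FALSE` — the closed-world "empty answer" that the
#' refinement stage interprets as an impossible configuration. Unregistered
#' terms raise a vocabulary error rather than returning empty.
#'
#' @param kb A `histo_kb`.
#' @param organA,organB Organ terms.
#' @return `TRUE` if the fact is asserted, `FALSE` (empty) otherwise.
#' @export
ask_presence <- function(kb, organA, organB) {
  if (!inherits(kb, "histo_kb")) stopf("kb must be a histo_kb")
  check_term(organA, "organs", "organ")
  check_term(organB, "organs", "organ")
  t <- kb$triples
  any(t$subject == organA & t$predicate == "hasPresenceOf" & t$object == organB)
}

#' Epithelium type lining an organ
#'
#' Returns the epithelium type linked to `organ` by `hasEpithelium`, or
#' `NULL` when no such fact exists — the empty answer, read as "high
#' probability that the image contains no epithelial tissue". Conflicting
#' facts (two different types for one organ) raise an integrity error.
#'
#' @param kb A `histo_kb`.
#' @param organ An organ term.
#' @return A single epithelium term, or `NULL`.
#' @export
epithelium_of <- function(kb, organ) {
  if (!inherits(kb, "histo_kb")) stopf("kb must be a histo_kb")
  check_term(organ, "organs", "organ")
  t <- kb$triples
  hit <- unique(t$object[t$subject == organ & t$predicate == "hasEpithelium"])
  if (length(hit) == 0) return(NULL)
  if (length(hit) > 1) {
    stopf("integrity error: %s has %d conflicting epithelium facts (%s)",
          organ, length(hit), paste(hit, collapse = ", "))
  }
  hit
}

#' Save and load a knowledge base as Turtle
#'
#' Serializes the triple set as Turtle with a fixed namespace prefix. The
#' reader accepts exactly this subset: one `@prefix` declaration, blank
#' lines, `#` comment lines, and one `prefix:Subject prefix:predicate
#' prefix:Object .` statement per line. Unknown terms or predicates are
#' rejected with the offending line number; the round trip preserves the
#' triple set exactly.
#'
#' @param kb A `histo_kb`.
#' @param path Path to a `.ttl` file.
#' @return `load_kb()` returns a `histo_kb`.
#' @export
save_kb <- function(kb, path) {
  if (!inherits(kb, "histo_kb")) stopf("kb must be a histo_kb")
  t <- kb$triples
  lines <- c(
    sprintf("@prefix %s: <%s> .", KB_PREFIX, KB_NAMESPACE),
    "",
    sprintf("%s:%s %s:%s %s:%s .",
            KB_PREFIX, t$subject, KB_PREFIX, t$predicate, KB_PREFIX, t$object)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname save_kb
#' @export
load_kb <- function(path) {
  if (!file.exists(path)) stopf("knowledge base file not found: %s", path)
  lines <- readLines(path)
  prefix <- KB_PREFIX
  kb <- kb_new()
  triple_re <- "^(\\w+):(\\w+)\\s+(\\w+):(\\w+)\\s+(\\w+):(\\w+)\\s*\\.\\s*$"
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#")) next
    if (startsWith(line, "@prefix")) {
      m <- regmatches(line, regexec("^@prefix\\s+(\\w+):\\s*<([^>]*)>\\s*\\.$", line))[[1]]
      if (length(m) != 3) stopf("line %d: malformed @prefix declaration", i)
      prefix <- m[2]
      next
    }
    m <- regmatches(line, regexec(triple_re, line))[[1]]
    if (length(m) != 7) stopf("line %d: malformed triple: %s", i, line)
    used <- m[c(2, 4, 6)]
    if (any(used != prefix)) {
      stopf("line %d: unknown prefix '%s' (declared: '%s')",
            i, used[used != prefix][1], prefix)
    }
    kb <- tryCatch(
      kb_assert(kb, m[3], m[5], m[7]),
      error = function(e) stopf("line %d: %s", i, conditionMessage(e))
    )
  }
  kb
}
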