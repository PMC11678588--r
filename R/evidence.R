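# Direct-versus-indirect evidence classification and its evaluation
# against ground-truth labels.

#' Classify a node's evidence as direct or indirect
#'
#' A node's evidence for the target disease(s) is \code{"direct"} if a
#' length-1 triple (in either direction) links it to at least one target;
#' otherwise it is \code{"indirect"}, provided the node is connected to a
#' target within \code{depth} hops at all (the classification is based on
#' the shortest metapath link to the target nodes).
#'
#' @param graph a [KnowledgeGraph-class].
#' @param cui concept identifier to classify.
#' @param targets character vector of target cuis.
#' @param depth connectivity check horizon for the indirect case
#'   (default 2, the study's search depth).
#' @return \code{"direct"} or \code{"indirect"}.
#' @export
classifyEvidence <- function(graph, cui, targets, depth = 2L) {
  if (!cui %in% graph@nodes$cui) kgStop("kgLookupError", "unknown cui: %s", cui)
  for (t in targets) {
    if (!t %in% graph@nodes$cui) kgStop("kgLookupError", "unknown target cui: %s", t)
  }
  tr <- graph@triples
  direct <- any((tr$head == cui & tr$tail %in% targets) |
                (tr$tail == cui & tr$head %in% targets))
  if (direct) return("direct")
  nb <- neighborhood(graph, cui, depth)
  if (!any(targets %in% nb)) {
    kgStop("kgClassificationError",
           "node %s is not connected to any target within %d hops", cui, depth)
  }
  "indirect"
}

#' Evaluate direct/indirect predictions against truth labels
#'
#' Confusion counts and precision, recall, F-measure and accuracy of
#' predicted versus true evidence labels. Metrics with a zero denominator
#' are reported as \code{NA} (not applicable), never silently 0. Full
#' precision is retained; a \code{rounded} element carries the 2-decimal
#' values used for reporting.
#'
#' @param predictions data.frame with columns \code{predicted} and
#'   \code{truth} (values \code{"direct"}/\code{"indirect"}); extra
#'   columns such as \code{cui} and \code{disease} are allowed and used in
#'   error messages.
#' @param positiveClass the class counted as positive (default
#'   \code{"direct"}).
#' @return list of class \code{EvaluationReport}: \code{tp}, \code{fp},
#'   \code{fn}, \code{tn}, \code{precision}, \code{recall},
#'   \code{f_measure}, \code{accuracy}, \code{rounded}.
#' @examples
#' evaluateEvidence(data.frame(predicted = c("direct", "direct"),
#'                             truth = c("direct", "indirect")))
#' @export
evaluateEvidence <- function(predictions, positiveClass = "direct") {
  predictions <- as.data.frame(predictions)
  if (!nrow(predictions)) kgStop("kgInputError", "no predictions to evaluate")
  stopifnot(all(c("predicted", "truth") %in% names(predictions)))
  vocab <- c("direct", "indirect")
  stopifnot(positiveClass %in% vocab)
  bad <- !(predictions$predicted %in% vocab)
  if (any(bad)) {
    kgStop("kgInputError", "invalid predicted label(s): %s",
           paste(unique(predictions$predicted[bad]), collapse = ", "))
  }
  missing <- is.na(predictions$truth) | !(predictions$truth %in% vocab)
  if (any(missing)) {
    who <- if ("cui" %in% names(predictions)) {
      paste(predictions$cui[missing], collapse = ", ")
    } else {
      paste(which(missing), collapse = ", ")
    }
    kgStop("kgInputError", "missing or invalid truth label(s) for: %s", who)
  }
  pos <- predictions$predicted == positiveClass
  tru <- predictions$truth == positiveClass
  tp <- sum(pos & tru); fp <- sum(pos & !tru)
  fn <- sum(!pos & tru); tn <- sum(!pos & !tru)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  accuracy <- (tp + tn) / (tp + fp + fn + tn)
  out <- list(tp = tp, fp = fp, fn = fn, tn = tn,
              precision = precision, recall = recall,
              f_measure = f, accuracy = accuracy,
              positive_class = positiveClass,
              rounded = round(c(precision = precision, recall = recall,
                                f_measure = f, accuracy = accuracy), 2))
  class(out) <- "EvaluationReport"
  out
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("EvaluationReport (positive class: %s)\n", x$positive_class))
  cat(sprintf("  tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp, x$fn, x$tn))
  r <- x$rounded
  cat(sprintf("  precision=%s recall=%s F=%s accuracy=%s\n",
              format(r["precision"]), format(r["recall"]),
              format(r["f_measure"]), format(r["accuracy"])))
  invisible(x)
}

#' F-measure from precision and recall
#'
#' Harmonic mean \eqn{2PR/(P+R)}; used both in evaluation and to recompute
#' published F-measures from printed precision/recall pairs.
#'
#' @param precision,recall numeric in \eqn{[0, 1]}.
#' @return numeric F-measure.
#' @export
fMeasure <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), NA_real_)
}

#' Read or write evidence label files
#'
#' CSV with header \code{cui,disease,predicted,evaluator,truth}; the slot
#' for external (LLM) or human evaluator labels in the pipeline.
#'
#' @param path CSV path.
#' @return data.frame of labels.
#' @export
readEvidenceLabels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cui", "disease", "predicted", "evaluator", "truth")
  if (!all(need %in% names(df))) {
    kgStop("kgParseError", "label file must have columns %s",
           paste(need, collapse = ", "))
  }
  df
}

#' @rdname readEvidenceLabels
#' @param labels data.frame of labels to write.
#' @export
writeEvidenceLabels <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
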