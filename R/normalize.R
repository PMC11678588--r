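# Per-simulation normalization of HeteSim scores, top-percentile selection,
# and cross-disease composite aggregation.

#' Normalize a per-disease score table
#'
#' HeteSim scores are only comparable within one simulation, so each
#' disease's score table is standardized before cross-disease comparison:
#' z-scores remove the mean and scale to unit variance (population standard
#' deviation -- the table is the full population of returned nodes), and
#' percentiles use the Hazen definition \eqn{100 (r - 0.5) / n} with
#' average ranks for ties. A single-row table gets \code{z = 0},
#' \code{percentile = 50}; a zero-variance table gets all \code{z = 0} with
#' a warning.
#'
#' @param scores data.frame with columns \code{cui} and \code{raw_score}
#'   (columns \code{source_cui}/\code{hetesim} from [rankSources()] are
#'   accepted and renamed).
#' @return data.frame with columns \code{cui}, \code{raw_score}, \code{z},
#'   \code{percentile}.
#' @examples
#' normalizeScores(data.frame(cui = c("a", "b", "c"), raw_score = 1:3))
#' @export
normalizeScores <- function(scores) {
  scores <- as.data.frame(scores)
  if ("source_cui" %in% names(scores) && !"cui" %in% names(scores)) {
    scores$cui <- scores$source_cui
  }
  if ("hetesim" %in% names(scores) && !"raw_score" %in% names(scores)) {
    scores$raw_score <- scores$hetesim
  }
  stopifnot(all(c("cui", "raw_score") %in% names(scores)))
  if (!nrow(scores)) kgStop("kgInputError", "score table is empty")
  x <- as.numeric(scores$raw_score)
  n <- length(x)
  if (n == 1L) {
    z <- 0
    pct <- 50
  } else {
    s <- popSD(x)
    if (s == 0) {
      warning("all raw scores identical; z set to 0")
      z <- rep(0, n)
    } else {
      z <- (x - mean(x)) / s
    }
    pct <- 100 * (rank(x, ties.method = "average") - 0.5) / n
  }
  data.frame(cui = as.character(scores$cui), raw_score = x,
             z = z, percentile = pct)
}

#' Select the top percentile of a ranked table
#'
#' The \eqn{\lceil n \cdot pct / 100 \rceil} highest-scoring nodes; ties at
#' the threshold are broken by ascending cui, so the result has exactly
#' that size and is deterministic.
#'
#' @param table data.frame with columns \code{cui} and \code{raw_score}
#'   (e.g., from [normalizeScores()]).
#' @param pct percentage in \eqn{(0, 100]} (default 1, the study setting).
#' @return character vector of selected cuis (sorted).
#' @export
topPercent <- function(table, pct = 1) {
  stopifnot(pct > 0, pct <= 100)
  table <- as.data.frame(table)
  if ("source_cui" %in% names(table) && !"cui" %in% names(table)) {
    table$cui <- table$source_cui
  }
  if ("hetesim" %in% names(table) && !"raw_score" %in% names(table)) {
    table$raw_score <- table$hetesim
  }
  n <- nrow(table)
  if (!n) return(character(0))
  k <- ceiling(n * pct / 100)
  o <- order(-as.numeric(table$raw_score), as.character(table$cui),
             method = "radix")
  sort(as.character(table$cui[o[seq_len(k)]]))
}

#' Cross-disease composite scores
#'
#' One row per source node present in at least one disease table; the
#' composite is the arithmetic mean of the node's per-disease HeteSim
#' scores over the diseases where it appears (so a single-disease node's
#' composite equals its HeteSim score). Composites are computed on raw
#' HeteSim scores, not on z or percentile.
#'
#' @param perDisease named list (disease label -> score table with columns
#'   \code{cui}/\code{raw_score}, or \code{source_cui}/\code{hetesim}).
#' @return data.frame with columns \code{cui}, \code{diseases}
#'   (semicolon-joined labels), \code{n_diseases}, \code{composite};
#'   sorted by composite descending, ties by ascending cui.
#' @examples
#' compositeScores(list(
#'   AD = data.frame(cui = "GRN", raw_score = 0.888),
#'   ALS = data.frame(cui = "GRN", raw_score = 0.934),
#'   FTD = data.frame(cui = "GRN", raw_score = 0.988)))
#' @export
compositeScores <- function(perDisease) {
  stopifnot(is.list(perDisease), length(perDisease) >= 1L,
            !is.null(names(perDisease)))
  long <- list()
  for (d in names(perDisease)) {
    tab <- as.data.frame(perDisease[[d]])
    if ("source_cui" %in% names(tab) && !"cui" %in% names(tab)) {
      tab$cui <- tab$source_cui
    }
    if ("hetesim" %in% names(tab) && !"raw_score" %in% names(tab)) {
      tab$raw_score <- tab$hetesim
    }
    if (!nrow(tab)) next
    long[[d]] <- data.frame(cui = as.character(tab$cui),
                            disease = d,
                            score = as.numeric(tab$raw_score))
  }
  if (!length(long)) {
    return(data.frame(cui = character(0), diseases = character(0),
                      n_diseases = integer(0), composite = numeric(0)))
  }
  long <- do.call(rbind, long)
  sp <- split(long, long$cui)
  out <- data.frame(
    cui = names(sp),
    diseases = vapply(sp, function(g) paste(g$disease[order(match(g$disease, names(perDisease)))],
                                            collapse = ";"), ""),
    n_diseases = vapply(sp, nrow, 0L),
    composite = vapply(sp, function(g) mean(g$score), 0)
  )
  out <- out[order(-out$composite, out$cui, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
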