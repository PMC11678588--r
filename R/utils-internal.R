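# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; published percentage tables in
#' this field are conventionally rounded half away from zero, so Venn shares
#' use this rule.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @keywords internal
roundHalfAway <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Population standard deviation (divide by n, not n - 1).
popSD <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# stop() with a classed condition so callers/tests can match on class.
kgStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "kgError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Split a comma-joined pmid field into a sorted unique character vector.
splitPmids <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  sort(unique(strsplit(x, ",", fixed = TRUE)[[1L]]))
}

joinPmids <- function(x) paste(sort(unique(x)), collapse = ",")

# Canonical name of the exclusive pairwise Venn region for labels a and b,
# ordered by their position in the label vector.
pairKey <- function(a, b, labels) {
  paste(labels[sort(match(c(a, b), labels))], collapse = "_")
}
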