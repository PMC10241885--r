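#' Genetic-model score vectors
#'
#' The Cochran-Armitage trend test scores the three genotype classes with a
#' vector (X0, X1, X2).  The optimal choices under the classical penetrance
#' models are fixed: recessive (0,0,1), additive (0,1/2,1), dominant (0,1,1).
#'
#' @param label one of `"recessive"`, `"additive"`, `"dominant"` (prefixes
#'   accepted).
#' @return An object of class `score_vector`: list with `label` and numeric
#'   `x` of length 3.
#' @examples
#' score_vector("additive")$x   # 0 0.5 1
#' @export
score_vector <- function(label = c("recessive", "additive", "dominant")) {
  label <- match.arg(label)
  x <- switch(label,
              recessive = c(0, 0, 1),
              additive  = c(0, 0.5, 1),
              dominant  = c(0, 1, 1))
  structure(list(label = label, x = x), class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("score_vector(%s): (%s)\n", x$label,
              paste(format(x$x), collapse = ", ")))
  invisible(x)
}

# The three canonical scores, in the fixed order used throughout.
canonical_scores <- function() {
  list(recessive = score_vector("recessive"),
       additive  = score_vector("additive"),
       dominant  = score_vector("dominant"))
}

as_score_vector <- function(score) {
  if (inherits(score, "score_vector")) return(score)
  if (is.character(score) && length(score) == 1L) return(score_vector(score))
  stop("expected a score_vector or a model label", call. = FALSE)
}
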