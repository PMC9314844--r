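#' Latent population state
#'
#' Integer counts in the nine life-history classes -- yearlings (`Y`),
#' pre-breeders of ages 2--6 (`P2`--`P6`), first-time breeders (`F`, locals
#' plus immigrants), experienced breeders (`E`) and skippers (`S`) -- for one
#' or more years. Stored as a 9 x n_years integer matrix with class names as
#' row names.
#'
#' @param counts numeric vector of length 9 (one year) or a 9 x n_years
#'   matrix; rows/elements in the order `Y, P2, P3, P4, P5, P6, F, E, S`.
#'
#' @return An object of class `population_state` (integer matrix).
#' @export
#' @examples
#' population_state(c(Y = 359, P2 = 233, P3 = 164, P4 = 79, P5 = 30, P6 = 8,
#'                    F = 366, E = 1371, S = 188))
population_state <- function(counts) {
  if (is.vector(counts)) counts <- matrix(counts, nrow = 9L)
  if (!is.matrix(counts) || nrow(counts) != 9L) {
    bp_stop("'counts' must be a length-9 vector or a 9 x n_years matrix")
  }
  if (anyNA(counts) || any(counts < 0)) {
    bp_stop("population counts must be non-negative")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bp_stop("population counts must be integers")
  }
  m <- matrix(as.integer(round(counts)), nrow = 9L,
              dimnames = list(CLASSES, colnames(counts)))
  structure(m, class = c("population_state", "matrix"))
}

#' Number of breeders per year
#'
#' The derived total `B = F + E` (first-time plus experienced breeders).
#'
#' @param state a `population_state` or a 9-row matrix.
#' @return integer vector of breeder numbers, one per year.
#' @export
breeders <- function(state) {
  if (is.vector(state)) state <- matrix(state, nrow = 9L)
  unname(state[7L, ] + state[8L, ])
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("Population state: %d year(s)\n", ncol(x)))
  print(unclass(x)[, seq_len(min(ncol(x), 8L)), drop = FALSE])
  if (ncol(x) > 8L) cat("...\n")
  cat("Breeders (F + E):", paste(head(breeders(x), 8L), collapse = " "), "\n")
  invisible(x)
}
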