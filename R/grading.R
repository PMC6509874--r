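#' Combination-index grading table
#'
#' The semiquantitative grading of synergism and antagonism by combination
#' index (CI), in the Chou-style expanded form: bins are left-closed,
#' right-open, so e.g. CI = 1.45 grades as "antagonism" and CI = 1.0 as
#' "nearly additive".
#'
#' @return A tibble with columns `lower`, `upper`, `description`, `symbols`.
#' @export
ci_grading_table <- function() {
  tibble(
    lower = c(0, 0.1, 0.3, 0.7, 0.85, 0.90, 1.10, 1.20, 1.45, 3.3, 10),
    upper = c(0.1, 0.3, 0.7, 0.85, 0.90, 1.10, 1.20, 1.45, 3.3, 10, Inf),
    description = c(
      "very strong synergism", "strong synergism", "synergism",
      "moderate synergism", "slight synergism", "nearly additive",
      "slight antagonism", "moderate antagonism", "antagonism",
      "strong antagonism", "very strong antagonism"
    ),
    symbols = c(
      "+ + + + +", "+ + + +", "+ + +", "+ +", "+", "+ -",
      "-", "- -", "- - -", "- - - -", "- - - - -"
    )
  )
}

#' Grade a combination index
#'
#' Looks up one or more CI values in the [ci_grading_table()] (left-closed,
#' right-open bins).
#'
#' @param ci Numeric vector of combination indices (> 0).
#' @return A tibble with columns `ci`, `description`, `symbols`.
#' @examples
#' grade_ci(c(0.05, 1.0, 1.45))
#' @export
grade_ci <- function(ci) {
  stopifnot(is.numeric(ci), all(is.finite(ci)), all(ci > 0))
  tab <- ci_grading_table()
  bin <- findInterval(ci, tab$lower) # left-closed right-open by construction
  tibble(ci = ci, description = tab$description[bin], symbols = tab$symbols[bin])
}
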