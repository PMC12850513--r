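#' Health states of the pain-severity Markov model
#'
#' The model tracks a closed cohort of chronic low back pain patients over
#' three mutually exclusive pain-severity states defined on the 0-10 numeric
#' rating scale (NRS): mild (NRS < 4), moderate (4 <= NRS < 7) and severe
#' (NRS >= 7). There is no death state: the modelled population is
#' working-age and background mortality is excluded.
#'
#' @return Character vector of the three state labels, in model order.
#' @export
#' @examples
#' health_states()
health_states <- function() c("mild", "moderate", "severe")

#' NRS intervals defining the severity states
#'
#' Half-open intervals \code{[lo, hi)} on the 0-10 numeric rating scale that
#' partition it into the three model states (the severe upper bound is
#' closed at 10).
#'
#' @return A data.frame with columns \code{state}, \code{nrs_lo},
#'   \code{nrs_hi}.
#' @export
nrs_cutoffs <- function() {
  data.frame(
    state  = health_states(),
    nrs_lo = c(0, 4, 7),
    nrs_hi = c(4, 7, 10),
    stringsAsFactors = FALSE
  )
}

#' Classify an NRS score into a severity state
#'
#' @param nrs Numeric vector of NRS scores in [0, 10].
#' @return Character vector of state labels.
#' @export
#' @examples
#' classify_nrs(c(2, 5.5, 9))
classify_nrs <- function(nrs) {
  stopifnot(is.numeric(nrs), all(nrs >= 0 & nrs <= 10))
  ifelse(nrs < 4, "mild", ifelse(nrs < 7, "moderate", "severe"))
}

arms <- function() c("PPT", "PT")

match_arm <- function(arm) match.arg(toupper(arm), arms())

match_state <- function(state) match.arg(tolower(state), health_states())
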