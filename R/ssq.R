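#' The 16 Simulator Sickness Questionnaire items and factor memberships
#'
#' The SSQ groups its 16 symptoms into three non-mutually-exclusive
#' factors — nausea (N), oculomotor (O) and disorientation (D) — each
#' containing seven items; five symptoms (general discomfort, difficulty
#' focusing, nausea, difficulty concentrating, blurred vision) load on two
#' factors and are counted in both.
#'
#' @return A 16-row tibble `(item, label, nausea, oculomotor,
#'   disorientation)` with logical factor-membership columns.
#' @export
ssq_items <- function() {
  tibble::tribble(
    ~item, ~label,                     ~nausea, ~oculomotor, ~disorientation,
    1L, "general discomfort",          TRUE,  TRUE,  FALSE,
    2L, "fatigue",                     FALSE, TRUE,  FALSE,
    3L, "headache",                    FALSE, TRUE,  FALSE,
    4L, "eyestrain",                   FALSE, TRUE,  FALSE,
    5L, "difficulty focusing",         FALSE, TRUE,  TRUE,
    6L, "increased salivation",        TRUE,  FALSE, FALSE,
    7L, "sweating",                    TRUE,  FALSE, FALSE,
    8L, "nausea",                      TRUE,  FALSE, TRUE,
    9L, "difficulty concentrating",    TRUE,  TRUE,  FALSE,
    10L, "fullness of head",           FALSE, FALSE, TRUE,
    11L, "blurred vision",             FALSE, TRUE,  TRUE,
    12L, "dizziness (eyes open)",      FALSE, FALSE, TRUE,
    13L, "dizziness (eyes closed)",    FALSE, FALSE, TRUE,
    14L, "vertigo",                    FALSE, FALSE, TRUE,
    15L, "stomach awareness",          TRUE,  FALSE, FALSE,
    16L, "burping",                    TRUE,  FALSE, FALSE
  )
}

check_ratings <- function(ratings) {
  if (length(ratings) != 16) abort("An SSQ response has exactly 16 item ratings.")
  if (anyNA(ratings) || any(!ratings %in% 0:3)) {
    abort("SSQ ratings must all be integers in {0, 1, 2, 3}.")
  }
  as.numeric(ratings)
}

#' Sum SSQ item ratings into the three factor scores
#'
#' @param ratings Numeric vector of 16 item ratings (0-3) in the canonical
#'   item order of [ssq_items()].
#' @return Named numeric vector `c(N, O, D)`; each lies in \[0, 21\].
#' @examples
#' r <- rep(0, 16); r[8] <- 2   # only the "nausea" symptom, rated 2
#' ssq_factor_sums(r)           # counts in both N and D
#' @export
ssq_factor_sums <- function(ratings) {
  ratings <- check_ratings(ratings)
  it <- ssq_items()
  c(N = sum(ratings[it$nausea]),
    O = sum(ratings[it$oculomotor]),
    D = sum(ratings[it$disorientation]))
}

#' Weighted total SSQ score
#'
#' Combines the factor sums with the standard SSQ weights:
#' `total = (N * 9.54 + O * 7.58 + D * 13.92) * 3.74`.
#'
#' @param N,O,D Non-negative factor sums (vectorized).
#' @return Numeric total score(s).
#' @examples
#' ssq_total_score(1, 0, 0)  # 35.6796
#' @export
ssq_total_score <- function(N, O, D) {
  if (any(c(N, O, D) < 0)) abort("Factor sums must be non-negative.")
  (N * 9.54 + O * 7.58 + D * 13.92) * 3.74
}

#' Score a table of SSQ responses
#'
#' Takes a data frame with one row per response and the 16 item columns
#' `item01` ... `item16`, and appends the factor sums `N`, `O`, `D` and the
#' weighted `ssq_total`.
#'
#' @param data Data frame of responses (e.g. from [simulate_ssq()]).
#' @return `data` as a tibble with `N`, `O`, `D`, `ssq_total` appended.
#' @export
score_ssq <- function(data) {
  cols <- sprintf("item%02d", 1:16)
  if (!all(cols %in% names(data))) {
    abort("`data` must contain the 16 item columns item01..item16.")
  }
  m <- as.matrix(data[, cols])
  apply(m, 1, check_ratings)
  it <- ssq_items()
  N <- as.numeric(m %*% it$nausea)
  O <- as.numeric(m %*% it$oculomotor)
  D <- as.numeric(m %*% it$disorientation)
  dplyr::mutate(tibble::as_tibble(data),
                N = N, O = O, D = D,
                ssq_total = ssq_total_score(N, O, D))
}
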