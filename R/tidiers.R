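#' Tidy a fitted motion-sickness classifier
#'
#' Returns the interpretable pieces of each learner as a tibble: LDA
#' scaling coefficients, tree split variables, or SVM support-vector
#' summaries.
#'
#' @param x An `ms_model`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate` (plus
#'   learner-specific columns).
#' @export
tidy.ms_model <- function(x, ...) {
  switch(
    x$spec$kind,
    lda = tibble::tibble(term = rownames(x$fit$scaling),
                         estimate = as.numeric(x$fit$scaling[, 1])),
    tree = {
      fr <- x$fit$frame
      sp <- fr[fr$var != "<leaf>", , drop = FALSE]
      tibble::tibble(term = as.character(sp$var), estimate = sp$n)
    },
    {
      w <- t(x$fit$coefs) %*% x$fit$SV
      if (x$spec$kind == "svm_linear") {
        tibble::tibble(term = colnames(x$fit$SV), estimate = as.numeric(w))
      } else {
        tibble::tibble(term = "n_support_vectors",
                       estimate = x$fit$tot.nSV)
      }
    })
}

#' One-row summary of a fitted motion-sickness classifier
#'
#' @param x An `ms_model`.
#' @param ... Unused.
#' @return One-row tibble `(kind, n_train, n_features, standardized,
#'   box_constraint)`.
#' @export
glance.ms_model <- function(x, ...) {
  tibble::tibble(kind = x$spec$kind, n_train = x$n_train,
                 n_features = length(x$features),
                 standardized = x$spec$standardize,
                 box_constraint = x$spec$box_constraint)
}

#' One-row summary of a classifier evaluation
#'
#' @param x An `ms_eval` tibble.
#' @param ... Unused.
#' @return One-row tibble of the headline metrics.
#' @export
glance.ms_eval <- function(x, ...) {
  tibble::as_tibble(x)[, c("classifier", "split", "n", "accuracy",
                           "sensitivity", "specificity", "auc")]
}

#' Tidy a cohort statistics report
#'
#' The report is already one test per row; `tidy()` strips the class and
#' returns it as a plain tibble.
#'
#' @param x An `ms_stats_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ms_stats_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ms_stats_report")
  tibble::as_tibble(out)
}
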