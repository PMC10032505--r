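# Rank-based accuracy metrics: Harrell's C for censored survival, ROC-AUC
# for binary outcomes.

#' Harrell's concordance index
#'
#' Over all comparable pairs (i, j) with \code{times[i] < times[j]} and
#' \code{events[i] == 1}, the fraction in which the shorter survivor has the
#' strictly higher risk score; prediction ties count 1/2.  Pairs with equal
#' times are not comparable (Harrell's convention).
#'
#' @param risk_scores predicted risk, higher = shorter expected survival.
#' @param times observed follow-up times.
#' @param events event indicators in \{0, 1\}.
#' @return C-index in [0, 1]; error if no pair is comparable.
#' @examples
#' concordance_index(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1))  # 1
#' @export
concordance_index <- function(risk_scores, times, events) {
  n <- length(times)
  stopifnot(length(risk_scores) == n, length(events) == n)
  conc <- 0
  npairs <- 0
  for (i in seq_len(n)) {
    if (events[i] != 1) next
    longer <- times > times[i]
    k <- sum(longer)
    if (k == 0) next
    npairs <- npairs + k
    conc <- conc + sum(risk_scores[i] > risk_scores[longer]) +
      0.5 * sum(risk_scores[i] == risk_scores[longer])
  }
  if (npairs == 0)
    stop("no comparable pairs: C-index undefined")
  conc / npairs
}

#' ROC area under the curve (Mann-Whitney form)
#'
#' Probability that a uniformly drawn positive outranks a uniformly drawn
#' negative; score ties count 1/2.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels in \{0, 1\}; both classes must be present.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute ROC-AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
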