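# Translation of outcome-adjacent edges into odds ratios. The per-point OR
# is the exponentiated raw-unit coefficient of the symptom in the outcome
# node's regression (per 1-point item increase); edge *presence* is decided
# by the combined standardized adjacency under the configured edge rule.

#' Odds-ratio table for outcome-adjacent symptoms
#'
#' For every symptom, reports the per-point odds ratio of attaining the
#' outcome relative to not attaining it: `exp(raw coefficient)` from the
#' outcome node's regression when the symptom-outcome edge is retained in
#' the network, and exactly 1 when it is not. Optionally merges bootstrap
#' inclusion proportions and OR percentile bounds (bCI).
#'
#' @param model A fitted [estimate_network()] result.
#' @param bootstrap Optional [bootstrap_network()] summary for the same
#'   cohort/configuration.
#' @return A data frame with one row per symptom: `item`, `edge_weight`
#'   (combined standardized weight), `per_point_or`, `direction`
#'   (`"positive"`/`"negative"`, `NA` for absent edges), and, when bootstrap
#'   results are supplied, `inclusion_proportion`, `bci_low`, `bci_high`.
#' @export
odds_ratio_table <- function(model, bootstrap = NULL) {
  labels <- model$node_labels
  p1 <- length(labels)
  if (labels[p1] != "remission") stop_noa("model does not contain the outcome node")
  p <- p1 - 1L
  edge_w <- model$adjacency[seq_len(p), p1]
  raw_out <- model$nodewise_fits[[p1]]$coefficients[labels[seq_len(p)]]
  retained <- edge_w != 0
  or <- ifelse(retained, exp(raw_out), 1)
  tab <- data.frame(
    item = labels[seq_len(p)],
    edge_weight = unname(edge_w),
    per_point_or = unname(or),
    direction = ifelse(!retained, NA_character_,
                       ifelse(or >= 1, "positive", "negative")),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (!is.null(bootstrap)) {
    stopifnot(inherits(bootstrap, "bootstrap_summary"))
    ot <- bootstrap$or_table
    tab$inclusion_proportion <- ot$inclusion_proportion[match(tab$item, ot$item)]
    tab$bci_low <- ot$or_low[match(tab$item, ot$item)]
    tab$bci_high <- ot$or_high[match(tab$item, ot$item)]
  }
  tab
}

#' Cumulative odds over a k-point item increase
#'
#' A per-point odds ratio compounds multiplicatively: a k-point score
#' increase changes the odds by `per_point_or^k`. The phrased fold is the
#' "times more/less likely" magnitude used in clinical reporting: the fold
#' change itself when it is at least 1, otherwise its reciprocal, rounded to
#' one decimal. An OR of 0.75 over 4 points gives a fold change of 0.316,
#' phrased as 3.2 times less likely.
#'
#' @param per_point_or Positive per-point odds ratio.
#' @param k_points Non-negative integer score difference.
#' @return A list with `fold_change` (`per_point_or^k_points`, unrounded) and
#'   `phrased_fold` (reporting magnitude, one decimal).
#' @export
cumulative_odds <- function(per_point_or, k_points) {
  if (!is.numeric(per_point_or) || per_point_or <= 0) {
    stop_noa("per_point_or must be a positive scalar")
  }
  if (k_points < 0) stop_noa("k_points must be >= 0")
  fold <- per_point_or^k_points
  phrased <- round(if (fold >= 1) fold else 1 / fold, 1)
  list(fold_change = fold, phrased_fold = phrased)
}

#' Per-point percent change in the odds
#'
#' Expresses a per-point odds ratio as a signed percentage change, rounded
#' to the nearest integer for reporting: OR 0.75 is a 25% decrease (-25),
#' OR 1.31 a 31% increase (+31).
#'
#' @param per_point_or Positive per-point odds ratio.
#' @return Signed integer percentage.
#' @export
percent_odds_change <- function(per_point_or) {
  if (!is.numeric(per_point_or) || per_point_or <= 0) {
    stop_noa("per_point_or must be a positive scalar")
  }
  round((per_point_or - 1) * 100)
}
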