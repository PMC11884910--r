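# Bootstrap edge stability: nonparametric case resamples of patients, each
# refit with the full estimation pipeline (fresh cross-validation folds per
# resample), summarised as per-edge inclusion proportions and percentile
# intervals. The percentile intervals are *bootstrapped* confidence intervals
# (bCI): regularization biases every parameter (and its resampling
# distribution) towards zero, so they are descriptive and not coverage-valid.

#' Bootstrap settings
#'
#' @param n_boot Number of case resamples (default 500).
#' @param seed RNG seed; identical seeds give identical summaries.
#' @param percentile_low,percentile_high Percentile bounds for the intervals
#'   (defaults 2.5 and 97.5).
#' @return A list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_boot = 500L, seed = 1L,
                             percentile_low = 2.5, percentile_high = 97.5) {
  if (n_boot < 1L) stop_noa("n_boot must be >= 1")
  if (!(percentile_low >= 0 && percentile_low < percentile_high &&
        percentile_high <= 100)) {
    stop_noa("need 0 <= percentile_low < percentile_high <= 100")
  }
  structure(list(n_boot = as.integer(n_boot), seed = as.integer(seed),
                 percentile_low = percentile_low,
                 percentile_high = percentile_high),
            class = "bootstrap_config")
}

#' Bootstrap the estimated network
#'
#' Draws `n_boot` nonparametric case resamples (patients with replacement,
#' same n), refits the whole network on each (with a fresh, deterministically
#' seeded cross-validation fold assignment), and summarises per-edge
#' stability. Resamples in which only one outcome class survives are skipped
#' and excluded from `n_effective`. For outcome-adjacent edges the per-point
#' odds ratio is recorded per resample, with OR = 1 whenever the edge is
#' regularized away — so OR intervals can touch exactly 1 when an edge is
#' unstable.
#'
#' @param cohort A [cohort_table()].
#' @param est_config An [estimation_config()].
#' @param boot_config A [bootstrap_config()].
#' @return An object of class `bootstrap_summary`: `inclusion_proportion`
#'   (node x node matrix), `weight_low`/`weight_high` (percentile bounds of
#'   the resampled standardized edge weights), `or_table` (per symptom: bCI
#'   bounds of the per-point odds ratio and the outcome-edge inclusion
#'   proportion), `n_effective`, and the configs.
#' @export
bootstrap_network <- function(cohort, est_config = estimation_config(),
                              boot_config = bootstrap_config()) {
  n <- n_patients(cohort)
  if (length(unique(cohort$outcome)) < 2L) {
    stop_noa("both outcome classes must be present")
  }
  p <- n_items(cohort$scale)
  p1 <- p + 1L
  B <- boot_config$n_boot
  labels <- node_labels_of(cohort)

  resample_seeds <- with_seed(boot_config$seed,
                              sample.int(.Machine$integer.max - 1L, B))

  weights <- array(NA_real_, dim = c(p1, p1, B))
  ors <- matrix(NA_real_, p, B, dimnames = list(labels[seq_len(p)], NULL))
  effective <- logical(B)

  for (b in seq_len(B)) {
    idx <- with_seed(resample_seeds[b], sample.int(n, n, replace = TRUE))
    outcome_b <- cohort$outcome[idx]
    if (length(unique(outcome_b)) < 2L) next
    cohort_b <- new_cohort_table(
      cohort$scores[idx, , drop = FALSE], outcome_b,
      moderator = if (is.null(cohort$moderator)) NULL else cohort$moderator[idx],
      scale = cohort$scale, discretized = cohort$discretized
    )
    cfg_b <- est_config
    cfg_b$cv_seed <- resample_seeds[b] %% 100000L
    net_b <- suppressWarnings(estimate_network(cohort_b, cfg_b))
    weights[, , b] <- net_b$adjacency
    or_b <- rep(1, p)
    edge_on <- net_b$adjacency[seq_len(p), p1] != 0
    raw_out <- net_b$nodewise_fits[[p1]]$coefficients  # named by symptom
    or_b[edge_on] <- exp(raw_out[labels[seq_len(p)]][edge_on])
    ors[, b] <- or_b
    effective[b] <- TRUE
  }

  n_eff <- sum(effective)
  if (n_eff == 0L) stop_noa("no effective resamples: every resample had a single outcome class")
  w_eff <- weights[, , effective, drop = FALSE]

  probs <- c(boot_config$percentile_low, boot_config$percentile_high) / 100
  inclusion <- apply(w_eff != 0, c(1, 2), mean)
  weight_low <- apply(w_eff, c(1, 2), quantile, probs = probs[1])
  weight_high <- apply(w_eff, c(1, 2), quantile, probs = probs[2])
  dimnames(inclusion) <- dimnames(weight_low) <- dimnames(weight_high) <-
    list(labels, labels)

  or_eff <- ors[, effective, drop = FALSE]
  or_table <- data.frame(
    item = labels[seq_len(p)],
    inclusion_proportion = inclusion[seq_len(p), p1],
    or_low = apply(or_eff, 1, quantile, probs = probs[1]),
    or_high = apply(or_eff, 1, quantile, probs = probs[2]),
    row.names = NULL, stringsAsFactors = FALSE
  )

  structure(
    list(node_labels = labels,
         inclusion_proportion = inclusion,
         weight_low = weight_low, weight_high = weight_high,
         or_table = or_table,
         n_effective = n_eff,
         est_config = est_config, boot_config = boot_config),
    class = "bootstrap_summary"
  )
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("<bootstrap_summary> %d effective resamples of %d\n",
              x$n_effective, x$boot_config$n_boot))
  cat(sprintf("  percentile bounds: %.1f / %.1f (bCI; regularization-biased, not coverage-valid)\n",
              x$boot_config$percentile_low, x$boot_config$percentile_high))
  ot <- x$or_table[x$or_table$inclusion_proportion > 0, , drop = FALSE]
  if (nrow(ot)) {
    cat("  outcome-adjacent edge stability:\n")
    for (r in seq_len(nrow(ot))) {
      cat(sprintf("    %-26s included %3.0f%%  OR bCI = %.2f-%.2f\n",
                  ot$item[r], 100 * ot$inclusion_proportion[r],
                  ot$or_low[r], ot$or_high[r]))
    }
  }
  invisible(x)
}
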