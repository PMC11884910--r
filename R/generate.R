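# Synthetic-cohort generator: a conditional-Gaussian pairwise network over
# latent symptom severities, a logistic model for the binary outcome, and an
# optional binary moderator that shifts selected pairwise weights and/or
# outcome coefficients. This is the estimation model class run forward, so
# parameter recovery is a well-posed check of the estimator.

#' Construct a ground-truth generating model
#'
#' The latent symptoms follow a conditional-Gaussian pairwise model: each
#' symptom's full conditional is normal with mean
#' `intercept_i + sum_j w_ij x_j` and shared standard deviation `residual_sd`.
#' The implied joint distribution is multivariate normal with precision matrix
#' `(I - W) / residual_sd^2`, which must be positive definite; this is checked
#' at construction (and at both moderator levels when edge shifts are
#' present). The binary outcome is Bernoulli with
#' `logit p = outcome_intercept + sum_i beta_i x_i`.
#'
#' @param pairwise_weights Symmetric numeric matrix with zero diagonal; the
#'   ground-truth conditional dependence network.
#' @param item_intercepts Numeric vector of conditional intercepts
#'   (default 0).
#' @param residual_sd Positive scalar, shared conditional standard deviation
#'   (default 1).
#' @param outcome_intercept Scalar intercept of the outcome logit.
#' @param outcome_coefficients Numeric vector of per-unit log-odds
#'   contributions of each latent symptom to the outcome.
#' @param moderator_shifts Optional list with elements `edges` (symmetric
#'   zero-diagonal matrix of additive weight shifts applied when the
#'   moderator equals 1) and/or `outcome` (vector of additive shifts to the
#'   outcome coefficients). Supplying this (even with all-zero shifts) makes
#'   simulated cohorts include a Bernoulli(0.5) moderator.
#'
#' @return An object of class `generating_model`.
#' @seealso [sample_cohort()], [default_paper_like_model()]
#' @export
generating_model <- function(pairwise_weights,
                             item_intercepts = rep(0, nrow(pairwise_weights)),
                             residual_sd = 1,
                             outcome_intercept = 0,
                             outcome_coefficients = rep(0, nrow(pairwise_weights)),
                             moderator_shifts = NULL) {
  W <- as.matrix(pairwise_weights)
  p <- nrow(W)
  if (ncol(W) != p) stop_noa("pairwise_weights must be square")
  if (max(abs(W - t(W))) > 1e-10) stop_noa("pairwise_weights must be symmetric")
  if (any(diag(W) != 0)) stop_noa("pairwise_weights must have zero diagonal")
  if (length(item_intercepts) != p || length(outcome_coefficients) != p) {
    stop_noa("item_intercepts and outcome_coefficients must have length %d", p)
  }
  if (!is.numeric(residual_sd) || residual_sd <= 0) {
    stop_noa("residual_sd must be a positive scalar")
  }
  if (!is.null(moderator_shifts)) {
    if (!is.list(moderator_shifts)) stop_noa("moderator_shifts must be a list")
    es <- moderator_shifts$edges %||% matrix(0, p, p)
    os <- moderator_shifts$outcome %||% rep(0, p)
    es <- as.matrix(es)
    if (!identical(dim(es), c(p, p)) || max(abs(es - t(es))) > 1e-10 ||
        any(diag(es) != 0)) {
      stop_noa("moderator_shifts$edges must be a symmetric %d x %d matrix with zero diagonal", p, p)
    }
    if (length(os) != p) stop_noa("moderator_shifts$outcome must have length %d", p)
    moderator_shifts <- list(edges = es, outcome = as.numeric(os))
  }

  check_proper(W, residual_sd, "pairwise_weights")
  if (!is.null(moderator_shifts)) {
    check_proper(W + moderator_shifts$edges, residual_sd,
                 "pairwise_weights + moderator edge shifts")
  }

  structure(
    list(
      n_items = p,
      pairwise_weights = W,
      item_intercepts = as.numeric(item_intercepts),
      residual_sd = residual_sd,
      outcome_intercept = outcome_intercept,
      outcome_coefficients = as.numeric(outcome_coefficients),
      moderator_shifts = moderator_shifts
    ),
    class = "generating_model"
  )
}

# The joint over latent symptoms is proper iff (I - W)/sigma^2 is positive
# definite; failure is a construction-time error, never silent divergence.
check_proper <- function(W, residual_sd, what) {
  ev <- eigen(diag(nrow(W)) - W, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) {
    stop_noa("improper model: precision matrix for %s is not positive definite (min eigenvalue %.3g)",
             what, min(ev) / residual_sd^2)
  }
  invisible(TRUE)
}

# Marginal mean vector and covariance of the latent symptoms at a moderator
# level (0 = base weights).
latent_moments <- function(model, level = 0L) {
  W <- model$pairwise_weights
  if (level == 1L && !is.null(model$moderator_shifts)) {
    W <- W + model$moderator_shifts$edges
  }
  A <- diag(model$n_items) - W
  mu <- solve(A, model$item_intercepts)
  Sigma <- model$residual_sd^2 * solve(A)
  list(mu = as.numeric(mu), sd = sqrt(diag(Sigma)), Sigma = Sigma)
}

#' Simulation settings for the cohort generator
#'
#' @param n_patients Number of retained Gibbs draws (one per patient).
#' @param seed RNG seed; identical seeds give byte-identical cohorts.
#' @param burn_in Sweeps discarded before the first retained draw
#'   (default 200).
#' @param thinning Sweeps between retained draws (default 5); together with
#'   `burn_in` this keeps the lag-1 autocorrelation of retained chains low.
#' @param discretize If `TRUE` (default), latent values are affinely mapped
#'   onto each item's score range, rounded and clipped; if `FALSE`, the
#'   continuous latents are returned (useful for estimator oracles and chain
#'   diagnostics).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients, seed = 1L, burn_in = 200L, thinning = 5L,
                       discretize = TRUE) {
  if (n_patients < 1L) stop_noa("n_patients must be >= 1")
  if (burn_in < 0L) stop_noa("burn_in must be >= 0")
  if (thinning < 1L) stop_noa("thinning must be >= 1")
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 burn_in = as.integer(burn_in), thinning = as.integer(thinning),
                 discretize = isTRUE(discretize)),
            class = "sim_config")
}

#' Simulate a cohort from a known generating model
#'
#' Draws latent symptom vectors by single-chain Gibbs sampling (each node from
#' its conditional normal), retaining one state per patient after `burn_in`
#' initial sweeps and `thinning` sweeps between patients. When the model has
#' moderator shifts, each patient's moderator is Bernoulli(0.5) and that
#' patient's sweeps use the shifted weights. The outcome is then drawn
#' Bernoulli with the model's logistic rule applied to the patient's latent
#' values. With `discretize = TRUE` each latent value is mapped from
#' `[mu - 2.5 sd, mu + 2.5 sd]` (base-level marginal moments) onto the item's
#' score range, rounded and clipped, which keeps all response categories
#' populated.
#'
#' The continuous latent draws are always attached as `attr(, "latent")` for
#' chain diagnostics.
#'
#' @param model A [generating_model()].
#' @param scale A [symptom_scale()] with `model$n_items` items.
#' @param config A [sim_config()].
#' @return A [cohort_table()]; when `discretize = FALSE` the scores slot holds
#'   the continuous latents and range validation is skipped.
#' @export
sample_cohort <- function(model, scale = hrsd17_scale(), config) {
  if (n_items(scale) != model$n_items) {
    stop_noa("scale has %d items but the model has %d", n_items(scale), model$n_items)
  }
  p <- model$n_items
  n <- config$n_patients
  moderated <- !is.null(model$moderator_shifts)
  W0 <- model$pairwise_weights
  W1 <- if (moderated) W0 + model$moderator_shifts$edges else W0
  mom <- latent_moments(model, 0L)

  sim <- with_seed(config$seed, {
    moderator <- if (moderated) rbinom(n, 1L, 0.5) else integer(n)
    X <- gibbs_chain_cpp(W0, W1, model$item_intercepts, model$residual_sd,
                         mom$mu, as.integer(moderator),
                         config$burn_in, config$thinning)
    eta <- model$outcome_intercept + as.numeric(X %*% model$outcome_coefficients)
    if (moderated && any(model$moderator_shifts$outcome != 0)) {
      eta <- eta + moderator * as.numeric(X %*% model$moderator_shifts$outcome)
    }
    outcome <- rbinom(n, 1L, plogis(eta))
    list(X = X, outcome = outcome, moderator = moderator)
  })

  X <- sim$X
  colnames(X) <- scale_labels(scale)
  if (config$discretize) {
    scores <- X
    for (j in seq_len(p)) {
      lo <- mom$mu[j] - 2.5 * mom$sd[j]
      hi <- mom$mu[j] + 2.5 * mom$sd[j]
      mx <- scale$items$max_score[j]
      sc <- round((X[, j] - lo) / (hi - lo) * mx)
      scores[, j] <- pmin(pmax(sc, 0), mx)
    }
    storage.mode(scores) <- "integer"
    cohort <- new_cohort_table(scores, sim$outcome,
                               moderator = if (moderated) sim$moderator else NULL,
                               scale = scale, discretized = TRUE)
  } else {
    cohort <- new_cohort_table(X, sim$outcome,
                               moderator = if (moderated) sim$moderator else NULL,
                               scale = scale, discretized = FALSE)
  }
  attr(cohort, "latent") <- X
  cohort
}

#' Reference generating model with three outcome-predictive symptoms
#'
#' A 17-item model mirroring the headline structure reported for ECT
#' remission prediction: a sparse, mostly positive symptom-symptom network
#' organised into clinically plausible clusters (mood/guilt/suicidality,
#' insomnia triad, anxiety, somatic), and exactly three nonzero outcome
#' coefficients — negative on suicidality (`log 0.75`), positive on
#' retardation (`log 1.21`) and hypochondriasis (`log 1.31`). The outcome
#' intercept is set so that the remission rate at the latent mean is about
#' 62%.
#'
#' @param seed Integer; jitters the symptom-symptom edge weights (multiplied
#'   by U(0.85, 1.15) factors) so repeated studies do not share one fixed
#'   truth. Outcome coefficients are never jittered.
#' @param moderator_edge_shift Optional named shift for moderation studies: a
#'   `list(i =, j =, delta =)` added to edge (i, j) when the moderator is 1.
#'   Pass `delta = 0` to include a null moderator.
#' @return A [generating_model()] for 17 items.
#' @export
default_paper_like_model <- function(seed = 1L, moderator_edge_shift = NULL) {
  p <- 17L
  edges <- rbind(
    c(1, 2, 0.20),  # depressed mood - guilt
    c(1, 3, 0.15),  # depressed mood - suicidality
    c(2, 3, 0.20),  # guilt - suicidality
    c(4, 5, 0.25), c(5, 6, 0.25), c(4, 6, 0.15),  # insomnia triad
    c(1, 7, 0.15),  # depressed mood - work/activities
    c(7, 8, 0.20),  # work/activities - retardation
    c(8, 9, -0.10), # retardation - agitation
    c(9, 10, 0.20), # agitation - psychic anxiety
    c(10, 11, 0.20),
    c(11, 12, 0.15),
    c(12, 13, 0.20),
    c(13, 16, 0.15),
    c(13, 15, 0.15),
    c(11, 15, 0.15), # somatic anxiety - hypochondriasis
    c(15, 17, 0.10)  # hypochondriasis - insight
  )
  W <- matrix(0, p, p)
  jitter <- with_seed(seed, stats::runif(nrow(edges), 0.85, 1.15))
  for (k in seq_len(nrow(edges))) {
    w <- edges[k, 3] * jitter[k]
    W[edges[k, 1], edges[k, 2]] <- w
    W[edges[k, 2], edges[k, 1]] <- w
  }

  beta <- rep(0, p)
  beta[3] <- log(0.75)   # suicidality
  beta[8] <- log(1.21)   # retardation
  beta[15] <- log(1.31)  # hypochondriasis

  shifts <- NULL
  if (!is.null(moderator_edge_shift)) {
    es <- matrix(0, p, p)
    i <- moderator_edge_shift$i
    j <- moderator_edge_shift$j
    es[i, j] <- es[j, i] <- moderator_edge_shift$delta
    shifts <- list(edges = es)
  }

  # intercept targets ~62% remission at the latent mean (here the origin)
  mu <- solve(diag(p) - W, rep(0, p))
  intercept <- qlogis(0.621) - sum(beta * mu)

  generating_model(
    pairwise_weights = W,
    item_intercepts = rep(0, p),
    residual_sd = 1,
    outcome_intercept = intercept,
    outcome_coefficients = beta,
    moderator_shifts = shifts
  )
}

#' Independence generating model
#'
#' All pairwise weights and outcome coefficients zero: symptoms are mutually
#' independent and carry no information about the outcome. Used as the null
#' model for false-positive rate checks.
#'
#' @param p Number of items (default 17).
#' @param remission_rate Marginal outcome probability (default 0.621).
#' @param moderated If `TRUE`, attach all-zero moderator shifts so cohorts
#'   include a null moderator.
#' @return A [generating_model()].
#' @export
independence_model <- function(p = 17L, remission_rate = 0.621,
                               moderated = FALSE) {
  generating_model(
    pairwise_weights = matrix(0, p, p),
    outcome_intercept = qlogis(remission_rate),
    moderator_shifts = if (moderated) list(edges = matrix(0, p, p)) else NULL
  )
}

#' @export
print.generating_model <- function(x, ...) {
  ne <- sum(x$pairwise_weights[upper.tri(x$pairwise_weights)] != 0)
  cat(sprintf("<generating_model> %d items, %d symptom-symptom edges, %d outcome coefficients%s\n",
              x$n_items, ne, sum(x$outcome_coefficients != 0),
              if (!is.null(x$moderator_shifts)) ", moderated" else ""))
  invisible(x)
}
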