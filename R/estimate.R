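# Mixed graphical model estimation by nodewise L1-regularized regression.
# Each symptom is regressed (gaussian family) on all other symptoms plus the
# binary outcome; the outcome is regressed on all symptoms (binomial family).
# The penalty is selected per node by k-fold cross-validation at the minimum
# of the mean out-of-fold error, and the nodewise fits are combined into one
# signed weighted network under the AND (default) or OR edge rule.

#' Estimation settings for the mixed graphical model
#'
#' @param n_folds Number of cross-validation folds (default 10).
#' @param lambda_grid_size Number of penalty values on the log-spaced grid
#'   from each node's `lambda_max` (smallest penalty zeroing all
#'   coefficients) downwards (default 50).
#' @param lambda_min_ratio Ratio of the smallest to the largest grid value
#'   (default 0.01).
#' @param edge_rule `"AND"` (edge kept only when both nodewise regressions
#'   retain it; default) or `"OR"`.
#' @param cv_seed Seed for the fold assignment; fixed seed means identical
#'   folds and hence identical selected penalties.
#' @param standardize Standardize predictors before penalization
#'   (default `TRUE`); coefficients are reported in raw units and on the
#'   standardized scale either way.
#' @return A list of class `estimation_config`.
#' @export
estimation_config <- function(n_folds = 10L, lambda_grid_size = 50L,
                              lambda_min_ratio = 0.01, edge_rule = c("AND", "OR"),
                              cv_seed = 1L, standardize = TRUE) {
  edge_rule <- match.arg(edge_rule)
  if (n_folds < 2L) stop_noa("n_folds must be >= 2")
  if (lambda_min_ratio <= 0 || lambda_min_ratio >= 1) {
    stop_noa("lambda_min_ratio must be in (0, 1)")
  }
  structure(list(n_folds = as.integer(n_folds),
                 lambda_grid_size = as.integer(lambda_grid_size),
                 lambda_min_ratio = lambda_min_ratio,
                 edge_rule = edge_rule,
                 cv_seed = as.integer(cv_seed),
                 standardize = isTRUE(standardize)),
            class = "estimation_config")
}

# Design matrix over all network nodes: item scores then the outcome column.
node_matrix <- function(cohort) {
  D <- cbind(cohort$scores, remission = cohort$outcome)
  storage.mode(D) <- "double"
  D
}

node_labels_of <- function(cohort) c(scale_labels(cohort$scale), "remission")

#' Fit one nodewise regularized regression
#'
#' Regresses node `node` on all other nodes with an L1 penalty. Symptom nodes
#' use least squares (gaussian family); the outcome node uses logistic
#' deviance (binomial family) with fold assignment stratified by outcome so
#' both classes appear in every fold. The penalty is chosen at the minimum of
#' the mean out-of-fold error over a log-spaced grid, unless `lambda` is
#' supplied (e.g. `0` for an unregularized fit).
#'
#' Constant predictor columns are excluded from the regression with a warning
#' and receive coefficient zero.
#'
#' @param cohort A [cohort_table()].
#' @param node Node index: `1..p` for symptoms, `p + 1` for the outcome.
#' @param config An [estimation_config()].
#' @param lambda Optional fixed penalty overriding cross-validation.
#' @return An object of class `nodewise_fit` with raw-unit and standardized
#'   coefficients, the selected penalty, and the cross-validation error
#'   curve.
#' @export
fit_nodewise <- function(cohort, node, config = estimation_config(),
                         lambda = NULL) {
  D <- node_matrix(cohort)
  labels <- node_labels_of(cohort)
  p1 <- ncol(D)
  if (node < 1L || node > p1) stop_noa("node must be in 1..%d", p1)
  family <- if (node == p1) "binomial" else "gaussian"

  y <- D[, node]
  X <- D[, -node, drop = FALSE]
  if (family == "binomial" && length(unique(y)) < 2L) {
    stop_noa("outcome node has a single class; cannot estimate")
  }

  sds <- apply(X, 2, sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning(sprintf("constant predictor(s) excluded from the regression for node '%s': %s",
                    labels[node], paste(colnames(X)[!keep], collapse = ", ")),
            call. = FALSE)
  }
  Xk <- X[, keep, drop = FALSE]
  if (ncol(Xk) < 1L) stop_noa("no non-constant predictors for node '%s'", labels[node])

  if (is.null(lambda)) {
    foldid <- make_foldid(nrow(D), config$n_folds, fold_seed(config$cv_seed, labels[node]),
                          strata = if (family == "binomial") y else NULL)
    cvfit <- glmnet::cv.glmnet(
      Xk, y, family = family, foldid = foldid,
      nlambda = config$lambda_grid_size,
      lambda.min.ratio = config$lambda_min_ratio,
      standardize = config$standardize
    )
    selected_lambda <- cvfit$lambda.min
    cf <- as.numeric(coef(cvfit, s = "lambda.min"))
    cv_curve <- data.frame(lambda = cvfit$lambda, cv_error = cvfit$cvm,
                           cv_sd = cvfit$cvsd, n_nonzero = cvfit$nzero)
  } else {
    if (lambda < 0) stop_noa("lambda must be >= 0")
    # Warm-started path down to the requested penalty; glmnet needs a
    # decreasing sequence to converge reliably at small/zero lambda.
    init <- glmnet::glmnet(Xk, y, family = family,
                           nlambda = config$lambda_grid_size,
                           lambda.min.ratio = config$lambda_min_ratio,
                           standardize = config$standardize)
    lmax <- max(init$lambda, lambda)
    path <- exp(seq(log(lmax), log(max(lmax * 1e-4, 1e-8)), length.out = 60))
    path <- sort(unique(c(path, lambda)), decreasing = TRUE)
    fit <- glmnet::glmnet(Xk, y, family = family, lambda = path,
                          standardize = config$standardize, thresh = 1e-12,
                          maxit = 1e6)
    selected_lambda <- lambda
    cf <- as.numeric(coef(fit, s = lambda, exact = FALSE))
    cv_curve <- NULL
  }

  intercept <- cf[1]
  raw <- numeric(ncol(X))
  names(raw) <- colnames(X)
  raw[keep] <- cf[-1]

  # standardized scale: coefficient of a standardized predictor for a
  # standardized (gaussian) response; for the binomial node the response is
  # left on the logit scale.
  y_sd <- if (family == "gaussian") sd(y) else 1
  if (y_sd == 0) y_sd <- 1  # zero-variance response: all coefficients are 0
  std <- raw * sds / y_sd

  structure(
    list(node = node, label = labels[node], family = family,
         coefficients = raw, coefficients_std = std,
         intercept = intercept, selected_lambda = selected_lambda,
         cv_error_curve = cv_curve, predictor_sds = sds, response_sd = y_sd),
    class = "nodewise_fit"
  )
}

# Edge-rule combination on a square matrix B of standardized nodewise
# coefficients (B[i, j] = coefficient of predictor j in the regression of
# node i). Returns the signed weighted adjacency and a flag matrix for pairs
# retained with conflicting signs.
combine_from_matrix <- function(B, rule = c("AND", "OR")) {
  rule <- match.arg(rule)
  p1 <- nrow(B)
  adj <- matrix(0, p1, p1, dimnames = dimnames(B))
  undef <- matrix(FALSE, p1, p1, dimnames = dimnames(B))
  for (i in seq_len(p1 - 1)) {
    for (j in seq((i + 1), p1)) {
      bi <- B[i, j]
      bj <- B[j, i]
      if (rule == "AND") {
        if (bi != 0 && bj != 0) {
          if (sign(bi) == sign(bj)) {
            w <- sign(bi) * mean(c(abs(bi), abs(bj)))
          } else {
            w <- mean(c(abs(bi), abs(bj)))
            undef[i, j] <- undef[j, i] <- TRUE
          }
          adj[i, j] <- adj[j, i] <- w
        }
      } else {
        if (bi != 0 || bj != 0) {
          w <- mean(c(bi, bj))
          if (bi != 0 && bj != 0 && sign(bi) != sign(bj)) {
            undef[i, j] <- undef[j, i] <- TRUE
          }
          adj[i, j] <- adj[j, i] <- w
        }
      }
    }
  }
  list(adjacency = adj, sign_undefined = undef)
}

#' Combine nodewise fits into a signed weighted adjacency matrix
#'
#' Under the AND rule an edge (i, j) is nonzero only when regression i
#' retained predictor j *and* regression j retained predictor i; its weight
#' is the mean of the two standardized coefficient magnitudes carrying their
#' shared sign. If the two coefficients disagree in sign the edge is kept at
#' the mean magnitude and flagged sign-undefined. Under the OR rule an edge
#' is present when either regression retained it, with weight equal to the
#' mean over both positions (a single retained coefficient of 0.30 gives
#' weight 0.15).
#'
#' @param fits List of [fit_nodewise()] results, one per node, in node order.
#' @param rule `"AND"` or `"OR"`.
#' @return A list with `adjacency` (symmetric, zero diagonal) and
#'   `sign_undefined` (logical matrix).
#' @export
combine_edges <- function(fits, rule = c("AND", "OR")) {
  rule <- match.arg(rule)
  p1 <- length(fits)
  labels <- vapply(fits, `[[`, character(1), "label")
  B <- matrix(0, p1, p1, dimnames = list(labels, labels))
  for (i in seq_len(p1)) {
    cf <- fits[[i]]$coefficients_std
    if (length(cf) != p1 - 1L) {
      stop_noa("fit for node %d has %d coefficients; expected %d",
               i, length(cf), p1 - 1L)
    }
    B[i, -i] <- cf
  }
  combine_from_matrix(B, rule)
}

#' Estimate the full mixed graphical model
#'
#' Runs [fit_nodewise()] for every node (all symptoms plus the outcome),
#' combines the fits under the configured edge rule, and computes per-node
#' predictability. Also records the smallest retained edge weight in
#' magnitude — the resolution below which absent edges are uninformative
#' (anything smaller could have been regularized away).
#'
#' @param cohort A [cohort_table()] with at least 30 rows and both outcome
#'   classes present.
#' @param config An [estimation_config()].
#' @return An object of class `network_model` with elements `node_labels`,
#'   `node_types`, `adjacency`, `sign_undefined`, `nodewise_fits`,
#'   `predictability`, `smallest_retained_weight`, `config`, `n`.
#' @export
estimate_network <- function(cohort, config = estimation_config()) {
  n <- n_patients(cohort)
  if (n < 30L) stop_noa("need at least 30 patients; got %d", n)
  if (length(unique(cohort$outcome)) < 2L) {
    stop_noa("both outcome classes must be present")
  }
  p1 <- n_items(cohort$scale) + 1L
  fits <- lapply(seq_len(p1), function(i) fit_nodewise(cohort, i, config))
  comb <- combine_edges(fits, config$edge_rule)

  nz <- abs(comb$adjacency[upper.tri(comb$adjacency)])
  nz <- nz[nz > 0]

  model <- structure(
    list(node_labels = node_labels_of(cohort),
         node_types = c(rep("continuous", p1 - 1L), "categorical"),
         adjacency = comb$adjacency,
         sign_undefined = comb$sign_undefined,
         nodewise_fits = fits,
         predictability = NULL,
         smallest_retained_weight = if (length(nz)) min(nz) else NA_real_,
         config = config,
         n = n),
    class = "network_model"
  )
  model$predictability <- compute_predictability(model, cohort)
  model
}

#' Per-node predictability
#'
#' For continuous (symptom) nodes: the in-sample proportion of variance
#' explained by the nodewise prediction (1 - RSS/TSS), floored at 0. For the
#' categorical outcome node: accuracy normalized against always guessing the
#' modal class, `(accuracy - modal frequency) / (1 - modal frequency)`,
#' floored at 0. A zero-variance node has predictability 0 by definition.
#'
#' @param model A fitted [estimate_network()] result.
#' @param cohort The cohort the model was fitted on (same schema).
#' @return Named numeric vector in `[0, 1]`, one value per node.
#' @export
compute_predictability <- function(model, cohort) {
  D <- node_matrix(cohort)
  p1 <- ncol(D)
  out <- numeric(p1)
  names(out) <- model$node_labels
  for (i in seq_len(p1)) {
    fit <- model$nodewise_fits[[i]]
    y <- D[, i]
    eta <- fit$intercept + as.numeric(D[, -i, drop = FALSE] %*% fit$coefficients)
    if (fit$family == "gaussian") {
      tss <- sum((y - mean(y))^2)
      if (tss == 0) { out[i] <- 0; next }
      r2 <- 1 - sum((y - eta)^2) / tss
      out[i] <- min(1, max(0, r2))
    } else {
      phat <- plogis(eta)
      acc <- mean((phat >= 0.5) == (y == 1))
      modal <- max(mean(y == 1), mean(y == 0))
      out[i] <- if (modal >= 1) 0 else max(0, (acc - modal) / (1 - modal))
    }
  }
  out
}

#' @export
print.network_model <- function(x, ...) {
  ne <- sum(x$adjacency[upper.tri(x$adjacency)] != 0)
  cat(sprintf("<network_model> %d nodes, %d edges (%s rule), n = %d\n",
              length(x$node_labels), ne, x$config$edge_rule, x$n))
  if (!is.na(x$smallest_retained_weight)) {
    cat(sprintf("  smallest retained |weight|: %.4f\n", x$smallest_retained_weight))
  }
  oc <- x$adjacency[, "remission"]
  adj <- names(oc)[oc != 0 & names(oc) != "remission"]
  if (length(adj)) {
    cat("  outcome-adjacent symptoms:\n")
    for (s in adj) {
      cat(sprintf("    %-26s edge %+0.3f\n", s, oc[s]))
    }
  } else {
    cat("  no outcome-adjacent symptoms retained\n")
  }
  invisible(x)
}
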