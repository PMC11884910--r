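# Shared fixtures, built once per test run.

scale17 <- hrsd17_scale()

# a small 5-item scale for cheap estimation tests
scale5 <- symptom_scale(
  c("mood", "guilt", "sleep", "fatigue", "insight"),
  max_score = c(4, 4, 4, 4, 2)
)

model5 <- function(seed = 1) {
  W <- matrix(0, 5, 5)
  W[1, 2] <- W[2, 1] <- 0.3
  W[2, 3] <- W[3, 2] <- 0.25
  W[3, 4] <- W[4, 3] <- 0.3
  beta <- c(0, 0.5, 0, -0.5, 0)
  generating_model(W, outcome_intercept = 0.3, outcome_coefficients = beta)
}

# moderately sized cohorts reused across tests
cohort5 <- sample_cohort(model5(), scale5, sim_config(400, seed = 11))
cohort17 <- sample_cohort(default_paper_like_model(seed = 1), scale17,
                          sim_config(500, seed = 21))

# minimal hand-built network_model, for serialization and odds-ratio tests
fake_network <- function(adjacency, predictability = NULL, raw_outcome = NULL,
                         sign_undefined = NULL) {
  p1 <- nrow(adjacency)
  labels <- rownames(adjacency)
  if (is.null(labels)) {
    labels <- c(paste0("item", seq_len(p1 - 1)), "remission")
    dimnames(adjacency) <- list(labels, labels)
  }
  if (is.null(predictability)) {
    predictability <- stats::setNames(rep(0, p1), labels)
  }
  if (is.null(sign_undefined)) {
    sign_undefined <- matrix(FALSE, p1, p1, dimnames = dimnames(adjacency))
  }
  fits <- vector("list", p1)
  if (!is.null(raw_outcome)) {
    fits[[p1]] <- list(node = p1, label = labels[p1], family = "binomial",
                       coefficients = raw_outcome)
  }
  structure(
    list(node_labels = labels,
         node_types = c(rep("continuous", p1 - 1), "categorical"),
         adjacency = adjacency, sign_undefined = sign_undefined,
         nodewise_fits = fits, predictability = predictability,
         smallest_retained_weight = {
           nz <- abs(adjacency[upper.tri(adjacency)])
           nz <- nz[nz > 0]
           if (length(nz)) min(nz) else NA_real_
         },
         config = estimation_config(), n = 100L),
    class = "network_model"
  )
}

# a fake nodewise fit carrying given standardized coefficients
fake_fit <- function(label, std, node = NA_integer_) {
  structure(list(node = node, label = label, family = "gaussian",
                 coefficients = std, coefficients_std = std,
                 intercept = 0, selected_lambda = 0.1,
                 cv_error_curve = NULL),
            class = "nodewise_fit")
}
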