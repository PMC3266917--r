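# SVM pair-classifier with Platt sigmoid calibration. The posterior model
# is P(interact | f) = 1 / (1 + exp(A*f + B)) where f is the SVM decision
# value; (A, B) minimize the negative log-likelihood of the training data
# with Platt's regularized target values. A is expected negative when
# larger decision values associate with the interacting class.

#' Fit Platt's sigmoid to decision values
#'
#' Estimates (A, B) of P(y = 1 | f) = 1 / (1 + exp(A f + B)) by minimizing
#' the negative log-likelihood with regularized targets
#' t+ = (N+ + 1) / (N+ + 2) and t- = 1 / (N- + 2), using a damped Newton
#' method with backtracking line search. Deterministic given its inputs.
#'
#' @param decision_values Numeric vector of classifier decision values.
#' @param labels Logical (or 0/1) vector: \code{TRUE} for the positive
#'   ("interact") class.
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class \code{platt_fit}: list with \code{A},
#'   \code{B}, \code{converged}, \code{iterations}, \code{nll} (negative
#'   log-likelihood at the optimum).
#' @export
#' @examples
#' f <- seq(-3, 3, length.out = 200)
#' y <- f + rnorm(200, sd = 0.5) > 0
#' fit_platt(f, y)
fit_platt <- function(decision_values, labels, tol = 1e-10, max_iter = 100L) {
  f <- as.numeric(decision_values)
  y <- as.logical(labels)
  stopifnot(length(f) == length(y), !anyNA(f), !anyNA(y))
  n_pos <- sum(y)
  n_neg <- length(y) - n_pos
  if (n_pos == 0L || n_neg == 0L) stop("calibration requires both classes")

  t_hi <- (n_pos + 1) / (n_pos + 2)
  t_lo <- 1 / (n_neg + 2)
  t <- ifelse(y, t_hi, t_lo)

  nll <- function(A, B) {
    x <- A * f + B
    # (t - 1) x + log(1 + e^x), evaluated stably on both tails
    sum(ifelse(x >= 0, t * x + log1p(exp(-x)), (t - 1) * x + log1p(exp(x))))
  }

  A <- 0
  B <- log((n_neg + 1) / (n_pos + 1))
  fval <- nll(A, B)
  sigma <- 1e-12   # Hessian ridge
  min_step <- 1e-10
  converged <- FALSE
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    x <- A * f + B
    p <- ifelse(x >= 0, exp(-x) / (1 + exp(-x)), 1 / (1 + exp(x)))
    q <- 1 - p
    d2 <- p * q
    h11 <- sum(f * f * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(f * d2)
    d1 <- t - p
    g1 <- sum(f * d1)
    g2 <- sum(d1)
    if (max(abs(g1), abs(g2)) < tol) {
      converged <- TRUE
      break
    }
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    while (step >= min_step) {
      newA <- A + step * dA
      newB <- B + step * dB
      newf <- nll(newA, newB)
      if (newf < fval + 1e-4 * step * gd) {
        A <- newA; B <- newB; fval <- newf
        break
      }
      step <- step / 2
    }
    if (step < min_step) break  # line search failed; accept current point
  }
  structure(list(A = A, B = B, converged = converged, iterations = iter,
                 nll = fval),
            class = "platt_fit")
}

#' @export
print.platt_fit <- function(x, ...) {
  cat(sprintf("Platt sigmoid fit: A = %.6g, B = %.6g (NLL %.6g, %d iterations%s)\n",
              x$A, x$B, x$nll, x$iterations,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

# Sigmoid posterior for decision values under a Platt fit, stable on both
# tails.
platt_probability <- function(A, B, f) {
  x <- A * f + B
  ifelse(x >= 0, exp(-x) / (1 + exp(-x)), 1 / (1 + exp(x)))
}

#' Default SVM hyperparameters
#'
#' RBF kernel on the (already min-max-normalized) pair descriptors. The
#' default bandwidth follows the median heuristic: the typical squared
#' Euclidean distance between two 686-dimensional pair descriptors is of
#' order 20-30, so gamma is set near its reciprocal. Use
#' \code{hyperparams = NULL} in \code{\link{train_svm}} to select both
#' values by a small grid on an inner holdout instead.
#'
#' @param cost Soft-margin cost C.
#' @param gamma RBF bandwidth.
#' @return Named list with \code{cost} and \code{gamma}.
#' @export
svm_hyperparams <- function(cost = 10, gamma = 0.05) {
  stopifnot(cost > 0, gamma > 0)
  list(cost = cost, gamma = gamma)
}

# Fit the raw SVM on a feature matrix. Labels enter as a factor with
# "interact" first so that positive decision values favour interaction.
fit_raw_svm <- function(X, y, hp) {
  e1071::svm(X, factor(y, levels = c("interact", "non-interact")),
             kernel = "radial", cost = hp$cost, gamma = hp$gamma,
             scale = FALSE, probability = FALSE)
}

# Decision values oriented so that larger = more likely "interact",
# regardless of libsvm's internal label order.
oriented_decision_values <- function(svm_fit, X) {
  pred <- stats::predict(svm_fit, X, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  sign <- if (startsWith(colnames(dv)[1], "interact")) 1 else -1
  sign * as.numeric(dv[, 1])
}

# Small grid search for (cost, gamma) on one stratified inner holdout.
select_hyperparams <- function(X, y, seed,
                               costs = c(1, 10, 100),
                               gammas = c(0.01, 0.05, 0.25)) {
  idx <- with_seed(seed, stratified_split(y, frac = 2 / 3))
  best <- NULL
  best_acc <- -Inf
  for (cost in costs) {
    for (gamma in gammas) {
      hp <- svm_hyperparams(cost, gamma)
      fit <- fit_raw_svm(X[idx, , drop = FALSE], y[idx], hp)
      dv <- oriented_decision_values(fit, X[-idx, , drop = FALSE])
      acc <- mean((dv > 0) == (y[-idx] == "interact"))
      if (acc > best_acc) {
        best_acc <- acc
        best <- hp
      }
    }
  }
  best
}

#' Train the interaction pair classifier
#'
#' Featurizes every labeled pair as a 686-dimensional conjoint-triad pair
#' descriptor, fits an RBF-kernel SVM, and calibrates posterior
#' probabilities by fitting Platt's sigmoid to out-of-sample decision
#' values collected over an internal stratified split (3 folds by default),
#' which avoids the optimistic calibration a refit on training decision
#' values would give. The final SVM is refit on all pairs.
#'
#' @param data Labeled pair data frame (columns \code{id_a}, \code{id_b},
#'   \code{label} with labels \code{"interact"} / \code{"non-interact"}).
#' @param db A \code{\link{protein_db}} resolving every id to a sequence.
#' @param hyperparams List from \code{\link{svm_hyperparams}}, or
#'   \code{NULL} to select (cost, gamma) by a small grid on an inner
#'   holdout.
#' @param map Residue class map used for featurization.
#' @param calibration_folds Internal folds for collecting decision values
#'   for Platt fitting.
#' @param seed Integer seed controlling the internal splits.
#' @return An object of class \code{ppi_model}.
#' @export
train_svm <- function(data, db, hyperparams = svm_hyperparams(),
                      map = residue_class_map(), calibration_folds = 3L,
                      seed = 20120126L) {
  data <- validate_pairs(data)
  y <- data$label
  n_pos <- sum(y == "interact")
  n_neg <- sum(y == "non-interact")
  if (n_pos == 0L || n_neg == 0L) {
    stop("training data must contain both classes")
  }
  if (n_pos < 10L || n_neg < 10L) {
    warning("fewer than 10 examples in a class; the model will be unstable")
  }
  X <- pair_feature_matrix(data$id_a, data$id_b, db, map)

  if (is.null(hyperparams)) {
    hyperparams <- select_hyperparams(X, y, seed = seed)
  }

  # out-of-fold decision values for calibration
  folds <- with_seed(seed + 1L, stratified_folds(y, k = calibration_folds))
  dv <- numeric(length(y))
  for (k in seq_len(calibration_folds)) {
    tr <- folds != k
    fit_k <- fit_raw_svm(X[tr, , drop = FALSE], y[tr], hyperparams)
    dv[!tr] <- oriented_decision_values(fit_k, X[!tr, , drop = FALSE])
  }
  platt <- fit_platt(dv, y == "interact")
  if (platt$A > 0) {
    warning("fitted Platt slope A is positive: the classifier anti-learns ",
            "on this data")
  }
  svm_fit <- fit_raw_svm(X, y, hyperparams)
  structure(list(svm = svm_fit, platt = platt, hyperparams = hyperparams,
                 fingerprint = map_fingerprint(map), map = map,
                 seed = seed, n_pairs = nrow(data),
                 class_counts = c(interact = n_pos, `non-interact` = n_neg)),
            class = "ppi_model")
}

#' @export
print.ppi_model <- function(x, ...) {
  cat("interaction pair classifier (RBF SVM + Platt calibration)\n")
  cat(sprintf("  trained on %d pairs (%d interact / %d non-interact)\n",
              x$n_pairs, x$class_counts[1], x$class_counts[2]))
  cat(sprintf("  cost = %g, gamma = %g; Platt A = %.4g, B = %.4g\n",
              x$hyperparams$cost, x$hyperparams$gamma,
              x$platt$A, x$platt$B))
  invisible(x)
}

# Batch posterior probabilities for a matrix of pair descriptors.
predict_prob_matrix <- function(model, X) {
  dv <- oriented_decision_values(model$svm, X)
  platt_probability(model$platt$A, model$platt$B, dv)
}

#' Posterior interaction probability for a sequence pair
#'
#' Featurizes both sequences, scores the pair with the SVM decision
#' function, and maps the decision value through the calibrated sigmoid.
#' With \code{symmetrize = TRUE} (the default) the probabilities of the two
#' orderings \code{[vA || vB]} and \code{[vB || vA]} are averaged, making
#' the output invariant to argument order.
#'
#' @param model A \code{ppi_model} from \code{\link{train_svm}}.
#' @param seqA,seqB Amino-acid sequences.
#' @param symmetrize Average over both pair orderings.
#' @param map Residue class map; must match the one the model was trained
#'   with.
#' @return Probability in [0, 1] that the two proteins interact.
#' @export
predict_probability <- function(model, seqA, seqB, symmetrize = TRUE,
                                map = residue_class_map()) {
  check_fingerprint(model, map)
  vA <- triad_vector(seqA, map)$values
  vB <- triad_vector(seqB, map)$values
  X <- rbind(c(vA, vB), c(vB, vA))
  colnames(X) <- c(paste0("A.", triad_labels()), paste0("B.", triad_labels()))
  p <- predict_prob_matrix(model, X)
  if (symmetrize) mean(p) else p[1]
}

check_fingerprint <- function(model, map) {
  if (!identical(model$fingerprint, map_fingerprint(map))) {
    stop("model was trained under a different residue-class table; ",
         "refusing to predict")
  }
  invisible(TRUE)
}

#' Persist / restore a trained model
#'
#' The archive stores the SVM fit, the Platt parameters, the hyperparameters
#' and the residue-class fingerprint; a reloaded model reproduces
#' predictions bit-for-bit.
#'
#' @param model A \code{ppi_model}.
#' @param path File path for the model archive.
#' @return \code{load_model} returns the restored \code{ppi_model}.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ppi_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ppi_model")) stop("file does not contain a ppi_model")
  model
}

# ---- seeded sampling helpers ---------------------------------------------

# Run expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Indices of a stratified training split keeping `frac` of each class.
stratified_split <- function(y, frac) {
  idx <- integer()
  for (cls in unique(y)) {
    members <- which(y == cls)
    take <- max(1L, floor(length(members) * frac))
    idx <- c(idx, sample(members, take))
  }
  sort(idx)
}

# Stratified fold assignment: within each class, a random permutation is
# dealt round-robin, so per-class fold sizes differ by at most one.
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    members <- which(y == cls)
    folds[sample(members)] <- rep_len(seq_len(k), length(members))
  }
  folds
}
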