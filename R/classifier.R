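# Repeated stratified-split L2 logistic regression scoring.
#
# Each iteration draws a fresh stratified 2:1 train/test split (the class
# ratio is maintained in both sets), fits an L2-regularized logistic
# regression on the training portion with the conventional default strength
# (inverse strength C = 1), and records the predicted sRNA probabilities of
# the test RNAs. An RNA's sRNA score is the mean of its probabilities over
# the iterations in which it fell in the test set.

#' Logistic-model probability
#'
#' `p = 1 / (1 + exp(-(beta0 + sum(beta_i x_i))))`.
#'
#' @param weights Numeric vector of feature weights (named or in feature
#'   order).
#' @param intercept Intercept term.
#' @param X Numeric matrix, columns in the weight order.
#' @return Probability per row.
#' @export
logistic_prob <- function(weights, intercept, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(weights))
    stop("feature dimension (", ncol(X), ") does not match weights (",
         length(weights), ")")
  stats::plogis(intercept + drop(X %*% weights))
}

# Single L2-regularized logistic fit via glmnet ridge. With
# lambda = 1/(C * n) and standardize = FALSE this minimizes
#   (1/n) sum log-loss + (1/(2 C n)) ||beta||^2,
# the conventional default objective (C = 1), intercept unpenalized.
.fit_l2_logistic <- function(X, y, C = 1) {
  lambda <- 1 / (C * nrow(X))
  fit <- withCallingHandlers(
    glmnet::glmnet(X, y, family = "binomial", alpha = 0, lambda = lambda,
                   standardize = FALSE, thresh = 1e-10, maxit = 1e6),
    warning = function(w) {
      # glmnet notes when a class has < 8 training observations; routine for
      # small positive classes under stratified splitting
      if (grepl("fewer than 8\\s+observations", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  b <- as.numeric(stats::coef(fit))
  list(intercept = b[1], weights = b[-1])
}

#' Iteration plan for the repeated-split scheme
#'
#' @param n_iterations Number of train/test refits (published default 10000).
#' @param train_fraction Training fraction (default 2/3, the 2:1 split).
#' @param seed Master seed; per-iteration seeds are derived from it, so
#'   results are reproducible and independent of evaluation order.
#' @param C Inverse regularization strength of the logistic fit (default 1).
#' @return List of class `"iteration_plan"`.
#' @export
iteration_plan <- function(n_iterations = 10000L, train_fraction = 2 / 3,
                           seed = 1L, C = 1) {
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  structure(list(n_iterations = as.integer(n_iterations),
                 train_fraction = train_fraction, seed = as.integer(seed),
                 C = C), class = "iteration_plan")
}

# Stratified split: round(train_fraction * n) per class into training.
.stratified_split <- function(pos_idx, neg_idx, train_fraction) {
  tp <- sample(pos_idx, round(train_fraction * length(pos_idx)))
  tn <- sample(neg_idx, round(train_fraction * length(neg_idx)))
  train <- c(tp, tn)
  list(train = train,
       test = setdiff(c(pos_idx, neg_idx), train))
}

#' Run the repeated stratified-split logistic regression
#'
#' @param features Feature data frame (with `rna` column) or numeric matrix
#'   with named rows; only the six feature columns are used.
#' @param labels `"label_set"` or character vector parallel to rows.
#' @param plan An [iteration_plan()].
#' @param feature_cols Feature columns used by the model.
#' @param keep_iterations Keep the per-iteration test probabilities (a sparse
#'   accumulation; needed for per-iteration ROC/PR curves).
#' @return List of class `"srna_iterations"`: `coefficients` (matrix
#'   `n_iterations x (1 + n_features)`, intercept first), `scores` (data frame
#'   `rna`, `mean_probability`, `n_test_appearances`, `rank`, `label`; ranked
#'   by descending score, ties broken by name), `plan`, `feature_cols`, and
#'   optionally `iteration_probs` (list of per-iteration named probability
#'   vectors).
#' @export
run_iterations <- function(features, labels, plan = iteration_plan(),
                           feature_cols = .feature_names,
                           keep_iterations = FALSE) {
  X <- .feature_matrix(features, feature_cols)
  lab <- .row_labels(features, labels, nrow(X))
  if (any(!is.finite(X))) stop("feature matrix contains non-finite values")
  y <- as.integer(lab == "known_sRNA")
  if (sum(y) < 2 || sum(1 - y) < 2)
    stop("need at least two RNAs per class")
  rnas <- if (!is.null(rownames(X))) rownames(X) else as.character(seq_len(nrow(X)))

  n_iter <- plan$n_iterations
  set.seed(plan$seed)
  iter_seeds <- sample.int(.Machine$integer.max, n_iter)

  pos_idx <- which(y == 1)
  neg_idx <- which(y == 0)
  prob_sum <- numeric(nrow(X))
  n_test <- integer(nrow(X))
  coefs <- matrix(NA_real_, n_iter, 1L + ncol(X),
                  dimnames = list(NULL, c("(Intercept)", colnames(X))))
  iter_probs <- if (keep_iterations) vector("list", n_iter) else NULL

  for (i in seq_len(n_iter)) {
    set.seed(iter_seeds[i])
    sp <- .stratified_split(pos_idx, neg_idx, plan$train_fraction)
    fit <- .fit_l2_logistic(X[sp$train, , drop = FALSE], y[sp$train], plan$C)
    coefs[i, ] <- c(fit$intercept, fit$weights)
    p <- logistic_prob(fit$weights, fit$intercept, X[sp$test, , drop = FALSE])
    prob_sum[sp$test] <- prob_sum[sp$test] + p
    n_test[sp$test] <- n_test[sp$test] + 1L
    if (keep_iterations) iter_probs[[i]] <- stats::setNames(p, rnas[sp$test])
  }

  mean_prob <- ifelse(n_test > 0, prob_sum / n_test, NA_real_)
  scores <- data.frame(rna = rnas, mean_probability = mean_prob,
                       n_test_appearances = n_test, label = lab,
                       stringsAsFactors = FALSE, row.names = NULL)
  scores <- rank_scores(scores)
  structure(list(coefficients = coefs, scores = scores, plan = plan,
                 feature_cols = colnames(X), iteration_probs = iter_probs),
            class = "srna_iterations")
}

#' Rank scored RNAs
#'
#' Descending mean probability; ties broken lexicographically by RNA name for
#' determinism. Rank 1 is the strongest sRNA candidate.
#'
#' @param scores Data frame with `rna` and `mean_probability`.
#' @return The data frame sorted by rank, with a `rank` column.
#' @export
rank_scores <- function(scores) {
  ord <- order(-scores$mean_probability, scores$rna)
  scores <- scores[ord, , drop = FALSE]
  scores$rank <- seq_len(nrow(scores))
  rownames(scores) <- NULL
  scores
}

#' Feature-contribution decomposition
#'
#' Reparametrizes the averaged model on z-scored features: the linear
#' predictor `beta0 + sum(beta_i x_i)` equals
#' `(beta0 + sum(beta_i m_i)) + sum(beta_i s_i zscore(x_i))`, where `m_i` and
#' `s_i` are the mean and standard deviation of feature `i`. The products
#' `beta_i * s_i` are on a common scale and comparable across features; their
#' signs equal the signs of the raw weights.
#'
#' @param iterations An `"srna_iterations"` result (its coefficient matrix is
#'   averaged), or a numeric coefficient vector `c(intercept, weights)`.
#' @param features Feature data frame or matrix the model was trained on.
#' @param feature_cols Feature columns.
#' @return Data frame of class `"contribution_table"`: `feature`, `weight`
#'   (averaged beta), `mean`, `sd`, `contribution` (`weight * sd`); the
#'   adjusted intercept is attached as attribute `adjusted_intercept`, the raw
#'   averaged intercept as `intercept`.
#' @export
contribution_transform <- function(iterations, features,
                                   feature_cols = .feature_names) {
  if (inherits(iterations, "srna_iterations")) {
    cbar <- colMeans(iterations$coefficients)
    feature_cols <- iterations$feature_cols
  } else {
    cbar <- as.numeric(iterations)
  }
  X <- .feature_matrix(features, feature_cols)
  if (length(cbar) != 1L + ncol(X)) stop("coefficient length mismatch")
  b0 <- cbar[1]; b <- cbar[-1]
  m <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  if (any(s == 0))
    stop("constant feature(s): ", paste(colnames(X)[s == 0], collapse = ", "))
  out <- data.frame(feature = colnames(X), weight = unname(b),
                    mean = unname(m), sd = unname(s),
                    contribution = unname(b * s),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "intercept") <- unname(b0)
  attr(out, "adjusted_intercept") <- unname(b0 + sum(b * m))
  class(out) <- c("contribution_table", "data.frame")
  out
}

#' Probabilities from a contribution table (z-score form)
#'
#' Evaluates `sigmoid(adjusted_intercept + sum(contribution_i * z_i))` with
#' `z_i = (x_i - mean_i) / sd_i`. Algebraically identical to the raw-scale
#' model; exposed so the identity can be verified.
#'
#' @param ct A `"contribution_table"`.
#' @param features Feature data frame or matrix.
#' @return Probability per row.
#' @export
contribution_prob <- function(ct, features) {
  X <- .feature_matrix(features, ct$feature)
  Z <- sweep(sweep(X, 2, ct$mean, "-"), 2, ct$sd, "/")
  stats::plogis(attr(ct, "adjusted_intercept") + drop(Z %*% ct$contribution))
}

# ---- evaluation -------------------------------------------------------------

#' ROC and precision-recall curves for sRNA scores
#'
#' Thresholds sweep all distinct score values. The ROC area is trapezoidal;
#' the PR curve is reported pointwise at each threshold with average precision
#' as its summary.
#'
#' @param scores Numeric score vector, or a scores data frame with
#'   `mean_probability` and `label` (as produced by [run_iterations()]).
#' @param labels Character labels parallel to `scores` (ignored when `scores`
#'   is a data frame carrying labels).
#' @return List of class `"srna_curves"`: `roc` (data frame `threshold`,
#'   `fpr`, `tpr`), `pr` (`threshold`, `recall`, `precision`), `auc`,
#'   `average_precision`, `n_pos`, `n_neg`.
#' @export
evaluate_scores <- function(scores, labels = NULL) {
  if (is.data.frame(scores)) {
    labels <- scores$label
    s <- scores$mean_probability
  } else s <- as.numeric(scores)
  y <- as.integer(labels == "known_sRNA")
  if (all(y == 1) || all(y == 0)) stop("both classes required for evaluation")
  ord <- order(-s)
  y <- y[ord]; s <- s[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  n_pos <- sum(y); n_neg <- sum(1 - y)
  # collapse tied scores to one operating point
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]; thr <- s[keep]
  tpr <- c(0, tp / n_pos); fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  precision <- tp / (tp + fp); recall <- tp / n_pos
  # average precision: sum over positives of precision at their thresholds
  ap <- sum(diff(c(0, recall)) * precision)
  structure(list(
    roc = data.frame(threshold = c(Inf, thr), fpr = fpr, tpr = tpr),
    pr = data.frame(threshold = thr, recall = recall, precision = precision),
    auc = auc, average_precision = ap, n_pos = n_pos, n_neg = n_neg),
    class = "srna_curves")
}

#' Relabeling evaluation
#'
#' Recomputes precision-recall after augmenting the positive set with newly
#' discovered sRNAs that had been labeled `other_RNA`, quantifying how much
#' precision was underestimated by incomplete annotation. `assess_only` keeps
#' the trained scores and re-evaluates; `retrain` reruns the iterations with
#' the augmented labels first.
#'
#' @param iterations An `"srna_iterations"` result.
#' @param features Feature input used for training (needed for `retrain`).
#' @param labels_extra Character vector of RNA names to relabel as
#'   `known_sRNA` (names absent from the scores are skipped with a warning).
#' @param mode `"assess_only"` or `"retrain"`.
#' @return List: `curves` (an `"srna_curves"`), `scores` (the score table
#'   under the augmented labels), `mode`, `n_relabeled`.
#' @export
relabel_evaluate <- function(iterations, features = NULL, labels_extra,
                             mode = c("assess_only", "retrain")) {
  mode <- match.arg(mode)
  sc <- iterations$scores
  unknown <- setdiff(labels_extra, sc$rna)
  if (length(unknown) > 0)
    warning("relabeled RNA(s) absent from scores skipped: ",
            paste(unknown, collapse = ", "))
  labels_extra <- intersect(labels_extra, sc$rna)
  aug <- ifelse(sc$rna %in% labels_extra, "known_sRNA", sc$label)
  if (mode == "retrain") {
    if (is.null(features)) stop("retrain mode needs the feature input")
    full <- stats::setNames(aug, sc$rna)
    X <- .feature_matrix(features, iterations$feature_cols)
    lab2 <- full[rownames(X)]
    it2 <- run_iterations(features, lab2, iterations$plan,
                          iterations$feature_cols)
    sc <- it2$scores
    aug <- sc$label
  } else {
    sc$label <- aug
  }
  list(curves = evaluate_scores(sc$mean_probability, aug), scores = sc,
       mode = mode, n_relabeled = length(labels_extra))
}

#' Robustness sweep over iteration counts and split ratios
#'
#' Reruns the scoring under alternative numbers of iterations and train
#' fractions and reports the Spearman rank correlation of the resulting
#' scores against the default setting, mirroring the published check that
#' the ranking is insensitive to these parameters.
#'
#' @param features Feature input.
#' @param labels Labels.
#' @param iteration_counts Integer vector of iteration counts to try.
#' @param train_fractions Numeric vector of training fractions to try.
#' @param plan Baseline [iteration_plan()]; its `n_iterations` and
#'   `train_fraction` define the reference setting.
#' @param feature_cols Feature columns.
#' @return Data frame: `setting`, `n_iterations`, `train_fraction`,
#'   `rank_correlation` (Spearman, vs the baseline scores). The baseline row
#'   has correlation 1. The per-setting score tables are attached as
#'   attribute `scores`.
#' @export
robustness_sweep <- function(features, labels, iteration_counts = integer(0),
                             train_fractions = numeric(0),
                             plan = iteration_plan(),
                             feature_cols = .feature_names) {
  if (any(train_fractions <= 0 | train_fractions >= 1))
    stop("train fractions must lie in (0, 1)")
  base <- run_iterations(features, labels, plan, feature_cols)
  base_s <- stats::setNames(base$scores$mean_probability, base$scores$rna)
  settings <- rbind(
    data.frame(n_iterations = plan$n_iterations,
               train_fraction = plan$train_fraction),
    data.frame(n_iterations = as.integer(iteration_counts),
               train_fraction = plan$train_fraction),
    data.frame(n_iterations = plan$n_iterations,
               train_fraction = train_fractions))
  settings <- unique(settings)
  out <- settings
  out$setting <- paste0("iter", settings$n_iterations, "_frac",
                        signif(settings$train_fraction, 3))
  out$rank_correlation <- NA_real_
  tables <- vector("list", nrow(settings))
  for (i in seq_len(nrow(settings))) {
    if (settings$n_iterations[i] == plan$n_iterations &&
        settings$train_fraction[i] == plan$train_fraction) {
      res <- base
    } else {
      p <- iteration_plan(settings$n_iterations[i],
                          settings$train_fraction[i], plan$seed, plan$C)
      res <- run_iterations(features, labels, p, feature_cols)
    }
    s <- stats::setNames(res$scores$mean_probability, res$scores$rna)
    out$rank_correlation[i] <-
      stats::cor(base_s, s[names(base_s)], method = "spearman")
    tables[[i]] <- res$scores
  }
  attr(out, "scores") <- stats::setNames(tables, out$setting)
  out[, c("setting", "n_iterations", "train_fraction", "rank_correlation")]
}
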