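# The user-facing model object: srna_fit() runs the whole per-condition
# pipeline (aggregation -> features -> screen -> repeated-split logistic
# scoring -> contributions -> curves) and returns a classed object with the
# usual modelling methods.

#' Fit the sRNA prediction model to one RIL-seq condition
#'
#' Runs the full pipeline on one condition's S-chimera records: per-RNA
#' interaction profiles, the six features (four first-layer, two
#' second-layer), the Mann-Whitney/correlation feature screen, repeated
#' stratified-split L2 logistic regression scoring, the feature-contribution
#' decomposition, and ROC/PR evaluation of the mean probabilities.
#'
#' @param records A `"chimera_records"` data frame (one condition), e.g. from
#'   [read_schimera_table()] or [generate_rilseq()].
#' @param labels A `"label_set"`; RNAs without a label default to
#'   `other_RNA`.
#' @param genome `DNAStringSet` from [read_genome()], for U-tract extraction.
#' @param n_iterations Number of train/test refits (published default 10000).
#' @param train_fraction Training fraction (default 2/3, the 2:1 split).
#' @param seed Master seed driving all randomness.
#' @param C Inverse L2 regularization strength (default 1, the conventional
#'   default).
#' @param flank U-tract window extension in nt (default 50).
#' @param screen Run the feature screen (default TRUE). The model is always
#'   fit on all six features; the screen result documents their
#'   discriminative power.
#' @param keep_iterations Keep per-iteration test probabilities (for
#'   per-iteration curves).
#' @return Object of class `"srna_fit"` with elements `features` (per-RNA
#'   feature data frame), `profiles`, `totals`, `screen`, `iterations`
#'   (`"srna_iterations"`), `scores`, `contributions`, `curves`
#'   (`"srna_curves"`), `pca`, `condition`, `plan`, `call`.
#' @seealso [summary.srna_fit()], [predict.srna_fit()], [plot.srna_fit()],
#'   [assemble_report()]
#' @export
srna_fit <- function(records, labels, genome, n_iterations = 10000L,
                     train_fraction = 2 / 3, seed = 1L, C = 1, flank = 50L,
                     screen = TRUE, keep_iterations = FALSE) {
  cl <- match.call()
  profiles <- aggregate_profiles(records)
  totals <- dataset_totals(records)
  feats <- second_layer(profiles, first_layer(profiles, totals, genome, flank))
  lab <- resolve_labels(labels, feats$rna)
  scr <- if (screen) screen_features(feats, lab) else NULL
  plan <- iteration_plan(n_iterations, train_fraction, seed, C)
  its <- run_iterations(feats, lab, plan, keep_iterations = keep_iterations)
  ct <- contribution_transform(its, feats)
  curves <- evaluate_scores(its$scores)
  pca <- pca_project(feats)
  structure(list(features = feats, profiles = profiles, totals = totals,
                 screen = scr, iterations = its, scores = its$scores,
                 contributions = ct, curves = curves, pca = pca,
                 condition = profiles$condition, plan = plan, call = cl),
            class = "srna_fit")
}

#' @export
print.srna_fit <- function(x, ...) {
  cat("sRNA prediction fit (condition: ", x$condition, ")\n", sep = "")
  cat("  RNAs: ", nrow(x$scores), " (",
      sum(x$scores$label == "known_sRNA"), " known sRNAs, ",
      sum(x$scores$label == "other_RNA"), " other RNAs)\n", sep = "")
  cat("  chimeric fragments: ", x$totals$total_fragments,
      "; unique interactions: ", x$totals$total_unique_interactions, "\n",
      sep = "")
  cat("  iterations: ", x$plan$n_iterations, " (train fraction ",
      signif(x$plan$train_fraction, 3), ", seed ", x$plan$seed, ")\n",
      sep = "")
  cat("  mean-probability ROC AUC: ", signif(x$curves$auc, 4), "\n", sep = "")
  invisible(x)
}

#' Summarize an sRNA fit
#'
#' @param object An `"srna_fit"`.
#' @param n_top Number of top-ranked unlabeled RNAs to display.
#' @param ... Unused.
#' @export
summary.srna_fit <- function(object, n_top = 10L, ...) {
  out <- list(condition = object$condition,
              n_rnas = nrow(object$scores),
              n_srnas = sum(object$scores$label == "known_sRNA"),
              auc = object$curves$auc,
              average_precision = object$curves$average_precision,
              contributions = object$contributions,
              screen = if (!is.null(object$screen)) object$screen$tests,
              top_candidates = utils::head(
                object$scores[object$scores$label == "other_RNA", ], n_top))
  class(out) <- "summary.srna_fit"
  out
}

#' @export
print.summary.srna_fit <- function(x, ...) {
  cat("sRNA prediction fit — condition:", x$condition, "\n")
  cat(sprintf("%d RNAs (%d known sRNAs); ROC AUC %.3f, average precision %.3f\n",
              x$n_rnas, x$n_srnas, x$auc, x$average_precision))
  cat("\nFeature contributions (weight x sd, comparable across features):\n")
  print(x$contributions, row.names = FALSE)
  cat(sprintf("adjusted intercept: %.3f\n",
              attr(x$contributions, "adjusted_intercept")))
  if (!is.null(x$screen)) {
    cat("\nMann-Whitney screen (Bonferroni-adjusted):\n")
    print(x$screen, row.names = FALSE)
  }
  cat("\nTop-ranked RNAs not labeled as sRNAs:\n")
  print(x$top_candidates, row.names = FALSE)
  invisible(x)
}

#' Averaged model coefficients
#'
#' @param object An `"srna_fit"`.
#' @param ... Unused.
#' @return Named vector: intercept followed by the six feature weights,
#'   averaged over the iterations.
#' @export
coef.srna_fit <- function(object, ...) {
  colMeans(object$iterations$coefficients)
}

#' Predict sRNA probabilities with the averaged model
#'
#' @param object An `"srna_fit"`.
#' @param newdata Feature data frame or matrix (six feature columns); when
#'   omitted, the fitted mean probabilities (test-set averages) are returned.
#' @param ... Unused.
#' @export
predict.srna_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  cbar <- coef(object)
  X <- .feature_matrix(newdata, object$iterations$feature_cols)
  stats::setNames(logistic_prob(cbar[-1], cbar[1], X), rownames(X))
}

#' @export
fitted.srna_fit <- function(object, ...) {
  stats::setNames(object$scores$mean_probability, object$scores$rna)
}

#' Response residuals of the sRNA fit
#'
#' @param object An `"srna_fit"`.
#' @param ... Unused.
#' @return Named vector `y - p`: 1 minus the score for known sRNAs, minus the
#'   score for other RNAs. Large positive residuals are sRNAs the model
#'   misses; large negative residuals are unlabeled RNAs the model considers
#'   sRNA-like — the candidate surface.
#' @export
residuals.srna_fit <- function(object, ...) {
  y <- as.integer(object$scores$label == "known_sRNA")
  stats::setNames(y - object$scores$mean_probability, object$scores$rna)
}

#' Simulate labels from the fitted probabilities
#'
#' Draws Bernoulli labels from each RNA's mean sRNA probability.
#'
#' @param object An `"srna_fit"`.
#' @param nsim Number of simulated label vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Data frame, one column per simulation, rows named by RNA.
#' @export
simulate.srna_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$scores$mean_probability
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$scores$rna
  out
}

#' Plot an sRNA fit
#'
#' @param x An `"srna_fit"`.
#' @param type `"roc"`, `"pr"`, `"rank"` (scores by rank, sRNAs highlighted)
#'   or `"pca"` (robust-scaled 2-D projection with feature loadings).
#' @param ... Passed to the underlying plot call.
#' @export
plot.srna_fit <- function(x, type = c("roc", "pr", "rank", "pca"), ...) {
  type <- match.arg(type)
  if (type == "roc") {
    plot(x$curves$roc$fpr, x$curves$roc$tpr, type = "l",
         xlab = "False positive rate", ylab = "True positive rate",
         main = sprintf("ROC (AUC = %.3f)", x$curves$auc), ...)
    graphics::abline(0, 1, lty = 2, col = "red")
  } else if (type == "pr") {
    plot(x$curves$pr$recall, x$curves$pr$precision, type = "l",
         xlab = "Recall", ylab = "Precision", ylim = c(0, 1),
         main = sprintf("Precision-recall (AP = %.3f)",
                        x$curves$average_precision), ...)
    graphics::abline(h = x$curves$n_pos / (x$curves$n_pos + x$curves$n_neg),
                     lty = 2, col = "red")
  } else if (type == "rank") {
    is_pos <- x$scores$label == "known_sRNA"
    plot(x$scores$rank, x$scores$mean_probability,
         col = ifelse(is_pos, "darkorange", "purple"),
         pch = ifelse(is_pos, 19, 1), xlab = "Rank", ylab = "sRNA score",
         main = "Ranked sRNA scores", ...)
    graphics::legend("topright", legend = c("known sRNA", "other RNA"),
                     col = c("darkorange", "purple"), pch = c(19, 1))
  } else {
    co <- x$pca$coordinates
    is_pos <- x$scores$label[match(rownames(co), x$scores$rna)] == "known_sRNA"
    plot(co[, 1], co[, 2], col = ifelse(is_pos, "darkorange", "purple"),
         pch = ifelse(is_pos, 19, 1),
         xlab = sprintf("PC1 (%.0f%%)", 100 * x$pca$explained_variance[1]),
         ylab = sprintf("PC2 (%.0f%%)", 100 * x$pca$explained_variance[2]),
         main = "Robust-scaled PCA", ...)
    sc <- max(abs(co[, 1:2])) * 0.8
    graphics::arrows(0, 0, sc * x$pca$loadings[, 1], sc * x$pca$loadings[, 2],
                     length = 0.08, col = "grey30")
    graphics::text(sc * x$pca$loadings[, 1], sc * x$pca$loadings[, 2],
                   rownames(x$pca$loadings), cex = 0.7, pos = 3)
  }
  invisible(x)
}

#' Export all pipeline tables for a fit
#'
#' Writes the feature matrix, score table, contribution table, screen report,
#' interaction edge list and curve points as TSV files.
#'
#' @param fit An `"srna_fit"`.
#' @param dir Output directory (created if missing).
#' @param records The records the fit was built from (for the edge list);
#'   optional.
#' @return Named vector of written paths, invisibly.
#' @export
export_results <- function(fit, dir, records = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(features = file.path(dir, "features.tsv"),
             scores = file.path(dir, "scores.tsv"),
             contributions = file.path(dir, "contributions.tsv"),
             roc = file.path(dir, "roc_curve.tsv"),
             pr = file.path(dir, "pr_curve.tsv"))
  write_tsv(fit$features, paths["features"])
  write_tsv(fit$scores, paths["scores"])
  ct <- as.data.frame(fit$contributions)
  ct$adjusted_intercept <- attr(fit$contributions, "adjusted_intercept")
  write_tsv(ct, paths["contributions"])
  write_tsv(fit$curves$roc, paths["roc"])
  write_tsv(fit$curves$pr, paths["pr"])
  if (!is.null(fit$screen)) {
    paths["screen"] <- file.path(dir, "feature_screen.tsv")
    write_tsv(fit$screen$tests, paths["screen"])
  }
  if (!is.null(records)) {
    paths["edges"] <- file.path(dir, "edge_list.tsv")
    write_edge_list(interaction_graph(records), paths["edges"])
  }
  invisible(paths)
}
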