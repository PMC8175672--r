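# First- and second-layer features and the feature-screening procedure.
#
# Six features describe each RNA:
#   f_total_chimeras        log10(N / total fragments in the data set)
#   f_unique_interactions   log10(k / total unique interactions)
#   f_sic                   Second-In-Chimera score, S - 1/k
#   f_utract                longest U run within +/-50 nt of the RNA's segments
#   f_med_interactor_degree median over interactors of their f_unique_interactions
#   f_med_interactor_sic    median over interactors of their SIC score
# The first four are first-layer (properties of the RNA's own chimeras and
# sequence); the last two are second-layer (properties of its partners).

.feature_names <- c("f_total_chimeras", "f_unique_interactions", "f_sic",
                    "f_utract", "f_med_interactor_degree",
                    "f_med_interactor_sic")

#' Second-In-Chimera (SIC) score
#'
#' `SIC = S - 1/k`, where `S` is the fraction of an RNA's chimeric fragments
#' in which it is the second RNA of the chimera and `k` its number of distinct
#' interaction partners. The `1/k` penalty keeps RNAs with few interactions
#' from reaching high scores on thin evidence; SIC can be negative, and lies
#' in `[-1, 1)`.
#'
#' @param S Second-position fraction in `[0, 1]` (vectorized).
#' @param k Number of distinct partners, `>= 1`.
#' @return `S - 1/k`.
#' @export
sic_score <- function(S, k) {
  if (any(k < 1)) stop("k must be >= 1")
  if (any(S < 0 | S > 1)) stop("S must lie in [0, 1]")
  S - 1 / k
}

#' Longest U-tract near an RNA's chimera segments
#'
#' Each segment is extended by `flank` nucleotides on both sides (clipped to
#' the replicon), the sense-strand transcript sequence is taken (reverse
#' complement for minus-strand segments; T read as U), and the longest run of
#' consecutive U over all extended segments is returned. A long U run marks a
#' rho-independent terminator U-tract, the Hfq-bound 3' feature typical of
#' sRNAs.
#'
#' @param segments Data frame of intervals (`replicon`, `start`, `end`,
#'   `strand`; 0-based half-open).
#' @param genome `DNAStringSet` from [read_genome()].
#' @param flank Extension in nt on each side (default 50).
#' @return Integer, the maximum U-run length (0 if no U).
#' @export
utract_length <- function(segments, genome, flank = 50L) {
  stopifnot(nrow(segments) >= 1, flank >= 0)
  best <- 0L
  for (i in seq_len(nrow(segments))) {
    rep_id <- segments$replicon[i]
    if (!rep_id %in% names(genome)) stop("unknown replicon: ", rep_id)
    len <- length(genome[[rep_id]])
    if (segments$start[i] < 0 || segments$end[i] > len)
      stop("segment [", segments$start[i], ",", segments$end[i],
           ") outside replicon '", rep_id, "'")
    s <- max(0L, segments$start[i] - as.integer(flank))
    e <- min(len, segments$end[i] + as.integer(flank))
    seq <- fetch_sequence(genome, rep_id, s, e, segments$strand[i])
    best <- max(best, .longest_run(seq, "T"))
  }
  best
}

.longest_run <- function(seq, base) {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  hits <- r$lengths[r$values == base]
  if (length(hits) == 0) 0L else as.integer(max(hits))
}

#' First-layer features
#'
#' @param profiles An `"rna_profiles"` object from [aggregate_profiles()].
#' @param totals Output of [dataset_totals()] for the same condition.
#' @param genome `DNAStringSet`; U-tracts are read from it.
#' @param flank U-tract window extension (default 50 nt).
#' @return Data frame with `rna`, `condition`, raw aggregates (`N`, `k`,
#'   `n_second`, `S`) and `f_total_chimeras`, `f_unique_interactions`,
#'   `f_sic`, `f_utract`.
#' @export
first_layer <- function(profiles, totals, genome, flank = 50L) {
  if (totals$total_fragments <= 0 || totals$total_unique_interactions <= 0)
    stop("data-set totals must be positive")
  p <- profiles$profiles
  p$f_total_chimeras <- log10(p$N / totals$total_fragments)
  p$f_unique_interactions <- log10(p$k / totals$total_unique_interactions)
  p$f_sic <- sic_score(p$S, p$k)
  p$f_utract <- vapply(p$rna, function(rna)
    utract_length(profiles$segments[[rna]], genome, flank), integer(1))
  p
}

#' Second-layer features
#'
#' Each interactor of an RNA carries first-layer values; the second layer
#' summarizes them: the median over interactors of their normalized unique-
#' interaction count, and the median of their SIC scores. For a true sRNA
#' these medians are low — its partners are targets, not sRNAs. The interactor
#' set never includes the RNA itself. Medians of even-sized sets are the
#' midpoint of the two central values.
#'
#' @param profiles An `"rna_profiles"` object.
#' @param first Data frame from [first_layer()].
#' @return `first` with `f_med_interactor_degree` and `f_med_interactor_sic`
#'   appended: the completed six-feature matrix.
#' @export
second_layer <- function(profiles, first) {
  xb <- stats::setNames(first$f_unique_interactions, first$rna)
  xc <- stats::setNames(first$f_sic, first$rna)
  med <- function(v, rna) {
    ints <- setdiff(profiles$interactors[[rna]], rna)
    if (length(ints) == 0)
      stop("RNA '", rna, "' has no interactors; cannot form second layer")
    stats::median(v[ints])
  }
  first$f_med_interactor_degree <- vapply(first$rna, function(r) med(xb, r), 1)
  first$f_med_interactor_sic <- vapply(first$rna, function(r) med(xc, r), 1)
  first
}

#' Compute the full six-feature matrix for one condition
#'
#' Convenience wrapper: aggregation, totals, first and second layer.
#'
#' @param records A `"chimera_records"` data frame (one condition).
#' @param genome `DNAStringSet`.
#' @param flank U-tract window extension (default 50 nt).
#' @return Data frame with raw aggregates and all six features, one row per
#'   RNA.
#' @export
srna_features <- function(records, genome, flank = 50L) {
  prof <- aggregate_profiles(records)
  tot <- dataset_totals(records)
  second_layer(prof, first_layer(prof, tot, genome, flank))
}

# ---- feature screening ------------------------------------------------------

#' Mann-Whitney feature screen
#'
#' Compares each feature's distribution between known sRNAs and other RNAs by
#' a two-tailed Mann-Whitney U test, with Bonferroni correction. The
#' Bonferroni factor defaults to 18, the size of the full candidate-feature
#' set from which the six shipped features were distilled, so re-screening a
#' subset keeps the published correction; override via `m_tests`.
#'
#' @param features Feature data frame (from [srna_features()]) or a numeric
#'   matrix with feature columns.
#' @param labels Character vector of `"known_sRNA"` / `"other_RNA"` parallel
#'   to the rows (or a `"label_set"` resolved against `features$rna`).
#' @param m_tests Bonferroni factor (default 18).
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @param feature_cols Columns to screen (default the six feature columns).
#' @return Data frame: `feature`, `p_raw`, `p_adjusted`, `pass`, `reason`.
#' @export
mann_whitney_screen <- function(features, labels, m_tests = 18L,
                                alpha = 0.05, feature_cols = .feature_names) {
  X <- .feature_matrix(features, feature_cols)
  labels <- .row_labels(features, labels, nrow(X))
  if (m_tests < ncol(X))
    stop("m_tests must be >= the number of features screened")
  pos <- labels == "known_sRNA"
  if (!any(pos) || all(pos)) stop("both label groups must be non-empty")
  res <- lapply(colnames(X), function(f) {
    x <- X[pos, f]; y <- X[!pos, f]
    if (stats::sd(c(x, y)) == 0)
      return(data.frame(feature = f, p_raw = NA_real_, p_adjusted = NA_real_,
                        pass = FALSE, reason = "constant feature",
                        stringsAsFactors = FALSE))
    # exact p for small tie-free samples, normal approximation otherwise
    # (the tie warning is routine for integer-valued features)
    p <- withCallingHandlers(
      stats::wilcox.test(x, y, alternative = "two.sided")$p.value,
      warning = function(w) {
        if (grepl("exact p-value", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    data.frame(feature = f, p_raw = p, p_adjusted = min(1, p * m_tests),
               pass = min(1, p * m_tests) < alpha, reason = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Cluster features by correlation and pick representatives
#'
#' Pearson correlations are computed between every feature pair; features are
#' clustered as connected components of the graph linking pairs with
#' `|r| >= threshold`, and one representative per cluster is selected — the
#' first by `priority` (default the canonical feature order).
#'
#' @param features Feature data frame or matrix.
#' @param threshold Absolute-correlation linkage threshold (default 0.8).
#' @param priority Character vector; earlier names win representative status.
#' @param feature_cols Columns to cluster.
#' @return List with `correlation` (matrix), `cluster` (named integer vector),
#'   `representative` (named logical vector).
#' @export
correlation_cluster <- function(features, threshold = 0.8,
                                priority = .feature_names,
                                feature_cols = NULL) {
  if (is.null(feature_cols))
    feature_cols <- intersect(.feature_names,
                              colnames(if (is.matrix(features)) features
                                       else as.matrix(features[vapply(features, is.numeric, TRUE)])))
  X <- .feature_matrix(features, feature_cols)
  if (ncol(X) < 2) stop("need at least two features to cluster")
  const <- apply(X, 2, stats::sd) == 0
  if (any(const)) {
    warning("constant feature(s) excluded from clustering: ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  r <- stats::cor(X)
  cl <- cluster_from_cor(r, threshold)
  rep_flag <- stats::setNames(rep(FALSE, ncol(X)), colnames(X))
  ord <- c(intersect(priority, colnames(X)),
           setdiff(colnames(X), priority))
  for (comp in unique(cl)) {
    members <- names(cl)[cl == comp]
    rep_flag[ord[ord %in% members][1]] <- TRUE
  }
  list(correlation = r, cluster = cl, representative = rep_flag)
}

#' Connected components of the |r| >= threshold feature graph
#'
#' @param cormat Square correlation matrix with dimnames.
#' @param threshold Absolute-correlation linkage threshold.
#' @return Named integer vector of component ids.
#' @export
cluster_from_cor <- function(cormat, threshold) {
  n <- ncol(cormat)
  adj <- abs(cormat) >= threshold
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  stats::setNames(comp, colnames(cormat))
}

#' Run the full feature screen
#'
#' Mann-Whitney screen followed by correlation clustering of the passing
#' features.
#'
#' @inheritParams mann_whitney_screen
#' @inheritParams correlation_cluster
#' @return List of class `"feature_screen"`: `tests` (screen table),
#'   `correlation`, `cluster`, `representative`, `selected` (names of
#'   representative passing features).
#' @export
screen_features <- function(features, labels, m_tests = 18L, alpha = 0.05,
                            threshold = 0.8, priority = .feature_names,
                            feature_cols = .feature_names) {
  tests <- mann_whitney_screen(features, labels, m_tests, alpha, feature_cols)
  passing <- tests$feature[tests$pass]
  out <- list(tests = tests, correlation = NULL, cluster = NULL,
              representative = NULL, selected = passing)
  if (length(passing) >= 2) {
    cc <- correlation_cluster(features, threshold, priority, passing)
    out$correlation <- cc$correlation
    out$cluster <- cc$cluster
    out$representative <- cc$representative
    out$selected <- names(cc$representative)[cc$representative]
  }
  class(out) <- "feature_screen"
  out
}

# Coerce feature input to a numeric matrix of the requested columns.
.feature_matrix <- function(features, feature_cols) {
  if (is.matrix(features)) {
    missing <- setdiff(feature_cols, colnames(features))
    if (length(missing) > 0)
      stop("missing feature column(s): ", paste(missing, collapse = ", "))
    return(features[, feature_cols, drop = FALSE])
  }
  missing <- setdiff(feature_cols, names(features))
  if (length(missing) > 0)
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  X <- as.matrix(features[, feature_cols, drop = FALSE])
  if (!is.null(features$rna)) rownames(X) <- features$rna
  X
}

# Resolve labels argument against features rows.
.row_labels <- function(features, labels, n) {
  if (inherits(labels, "label_set")) {
    if (is.data.frame(features) && !is.null(features$rna))
      return(resolve_labels(labels, features$rna, quiet = TRUE))
    stop("a label_set needs an 'rna' column in the features to resolve against")
  }
  if (length(labels) != n)
    stop("labels must be parallel to feature rows")
  as.character(labels)
}
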