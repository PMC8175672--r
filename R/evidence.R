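# Candidate reporting: PCA projection, target-hub flags, biogenesis evidence
# (TSS / RNase E cleavage) and CLASH cross-support.

#' Robust-scaled 2-D PCA projection of the feature matrix
#'
#' Features are robust-scaled per column (median-centered, divided by the
#' interquartile range) before projection onto the first two principal
#' components; loadings are returned for feature-vector overlay plots.
#' Zero-IQR columns cannot be scaled and are left unscaled (median-centered
#' only) with a warning.
#'
#' @param features Feature data frame or matrix.
#' @param feature_cols Feature columns.
#' @return List of class `"srna_pca"`: `coordinates` (matrix `n x 2`),
#'   `loadings` (matrix `n_features x 2`), `explained_variance` (fraction per
#'   component, all components).
#' @export
pca_project <- function(features, feature_cols = .feature_names) {
  X <- .feature_matrix(features, feature_cols)
  if (nrow(X) < 3) stop("PCA needs at least 3 RNAs")
  med <- apply(X, 2, stats::median)
  iqr <- apply(X, 2, stats::IQR)
  if (any(iqr == 0)) {
    warning("zero-IQR feature(s) left unscaled: ",
            paste(colnames(X)[iqr == 0], collapse = ", "))
    iqr[iqr == 0] <- 1
  }
  Z <- sweep(sweep(X, 2, med, "-"), 2, iqr, "/")
  pc <- stats::prcomp(Z, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(coordinates = pc$x[, 1:2, drop = FALSE],
                 loadings = pc$rotation[, 1:2, drop = FALSE],
                 explained_variance = ev), class = "srna_pca")
}

#' Flag target hubs
#'
#' A target hub is an RNA interacting with at least `threshold` distinct
#' known sRNAs (default 4) — the class most prone to misclassification as a
#' sRNA, which the second-layer features are designed to reject. The flag is
#' independent of the RNA's own label.
#'
#' @param profiles An `"rna_profiles"` object (its interactor sets are used).
#' @param labels `"label_set"` or named character vector.
#' @param threshold Minimum number of distinct known-sRNA partners.
#' @return Data frame: `rna`, `n_srna_partners`, `hub`.
#' @export
flag_target_hubs <- function(profiles, labels, threshold = 4L) {
  rnas <- names(profiles$interactors)
  all_names <- unique(c(rnas, unlist(profiles$interactors)))
  lab <- if (inherits(labels, "label_set"))
    resolve_labels(labels, all_names, quiet = TRUE) else labels
  srnas <- names(lab)[lab == "known_sRNA"]
  n <- vapply(profiles$interactors,
              function(p) length(intersect(p, srnas)), 1L)
  data.frame(rna = rnas, n_srna_partners = unname(n),
             hub = unname(n) >= threshold, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Biogenesis evidence near a candidate sRNA
#'
#' Searches for transcription start sites and RNase E cleavage sites in the
#' strand-aware window from `upstream_window` nt upstream of the candidate's
#' 5' end down to its 3' end. A TSS hit supports independent transcription; a
#' cleavage hit supports processing from the hosting transcript; neither
#' leaves the candidate's biogenesis unexplained.
#'
#' @param rna_interval One-row data frame (`replicon`, `start`, `end`,
#'   `strand`; 0-based half-open). Both ends must be known; otherwise the
#'   result is `"indeterminate"`.
#' @param tss `"site_table"` of kind TSS (or `NULL`).
#' @param cleavage `"site_table"` of kind RNaseE_cleavage (or `NULL`).
#' @param upstream_window Window extension upstream of the 5' end (default
#'   50 nt).
#' @return List: `tss_support`, `cleavage_support` (0-based site start
#'   positions in the window), `category` one of
#'   `"independent_transcription"`, `"processed"`, `"both"`, `"unexplained"`,
#'   `"indeterminate"`.
#' @export
biogenesis_evidence <- function(rna_interval, tss = NULL, cleavage = NULL,
                                upstream_window = 50L) {
  if (nrow(rna_interval) != 1 || is.na(rna_interval$start) ||
      is.na(rna_interval$end))
    return(list(tss_support = integer(0), cleavage_support = integer(0),
                category = "indeterminate"))
  if (rna_interval$strand == "+") {
    win_start <- rna_interval$start - upstream_window
    win_end <- rna_interval$end                    # [5'-50, 3'] inclusive
  } else {
    win_start <- rna_interval$start
    win_end <- rna_interval$end + upstream_window  # 5' end is the right edge
  }
  hits <- function(sites) {
    if (is.null(sites) || nrow(sites) == 0) return(integer(0))
    sel <- sites$replicon == rna_interval$replicon &
      sites$strand == rna_interval$strand &
      sites$start >= win_start & sites$start < win_end
    sort(sites$start[sel])
  }
  t_hits <- hits(tss)
  c_hits <- hits(cleavage)
  category <- if (length(t_hits) > 0 && length(c_hits) > 0) "both"
  else if (length(t_hits) > 0) "independent_transcription"
  else if (length(c_hits) > 0) "processed"
  else "unexplained"
  list(tss_support = t_hits, cleavage_support = c_hits, category = category)
}

#' CLASH cross-support for a candidate
#'
#' A candidate is supported by CLASH chimera data if some CLASH segment on the
#' same replicon and strand has both its start and its end within `tolerance`
#' nt (inclusive) of the candidate's coordinates.
#'
#' @param rna_interval One-row interval data frame.
#' @param clash `"site_table"` of kind CLASH_segment.
#' @param tolerance Maximum per-end distance in nt (default 50).
#' @return Logical flag.
#' @export
clash_overlap <- function(rna_interval, clash, tolerance = 50L) {
  if (is.null(clash) || nrow(clash) == 0) return(FALSE)
  sel <- clash$replicon == rna_interval$replicon &
    clash$strand == rna_interval$strand &
    abs(clash$start - rna_interval$start) <= tolerance &
    abs(clash$end - rna_interval$end) <= tolerance
  any(sel)
}

#' Assemble the candidate report
#'
#' Combines per-condition scores into one row per RNA, flags target hubs, and
#' lists novel-sRNA candidates: RNAs labeled `other_RNA` that, in at least one
#' condition, rank above the median-ranked known sRNA or within
#' `rank_window` ranks of some known sRNA. (The published scan is manual —
#' ranked RNAs are read top-down for names above or near known sRNAs; this
#' parameterization makes the rule reproducible.)
#'
#' @param score_tables Named list (by condition) of score data frames from
#'   [run_iterations()].
#' @param hub_flags Optional data frame from [flag_target_hubs()].
#' @param evidence Optional named list (by RNA) of [biogenesis_evidence()]
#'   results.
#' @param clash_flags Optional named logical vector (by RNA) of
#'   [clash_overlap()] results.
#' @param rank_window Vicinity window in ranks (default 5).
#' @return List of class `"candidate_report"`: `report` (one row per RNA:
#'   per-condition scores/ranks, hub flag, evidence columns) and `candidates`
#'   (subset passing the candidate rule, best rank first).
#' @export
assemble_report <- function(score_tables, hub_flags = NULL, evidence = NULL,
                            clash_flags = NULL, rank_window = 5L) {
  stopifnot(length(score_tables) >= 1, !is.null(names(score_tables)))
  rnas <- sort(unique(unlist(lapply(score_tables, `[[`, "rna"))))
  rep_df <- data.frame(rna = rnas, stringsAsFactors = FALSE)
  label <- rep(NA_character_, length(rnas))
  candidate <- rep(FALSE, length(rnas))
  for (cond in names(score_tables)) {
    sc <- score_tables[[cond]]
    i <- match(rnas, sc$rna)
    rep_df[[paste0("score_", cond)]] <- sc$mean_probability[i]
    rep_df[[paste0("rank_", cond)]] <- sc$rank[i]
    label[!is.na(i)] <- sc$label[i[!is.na(i)]]
    srna_ranks <- sc$rank[sc$label == "known_sRNA"]
    if (length(srna_ranks) == 0) next
    med_rank <- stats::median(srna_ranks)
    near <- vapply(sc$rank, function(r) any(abs(r - srna_ranks) <= rank_window),
                   TRUE)
    hit <- sc$label == "other_RNA" & (sc$rank < med_rank | near)
    candidate[match(sc$rna[hit], rnas)] <- TRUE
  }
  rep_df$label <- label
  if (!is.null(hub_flags)) {
    i <- match(rnas, hub_flags$rna)
    rep_df$n_srna_partners <- hub_flags$n_srna_partners[i]
    rep_df$hub <- hub_flags$hub[i]
  }
  if (!is.null(evidence)) {
    rep_df$biogenesis <- vapply(rnas, function(r)
      if (!is.null(evidence[[r]])) evidence[[r]]$category else NA_character_,
      "")
    rep_df$tss_support <- vapply(rnas, function(r)
      if (!is.null(evidence[[r]]))
        paste(evidence[[r]]$tss_support, collapse = ",") else "", "")
    rep_df$cleavage_support <- vapply(rnas, function(r)
      if (!is.null(evidence[[r]]))
        paste(evidence[[r]]$cleavage_support, collapse = ",") else "", "")
  }
  if (!is.null(clash_flags))
    rep_df$clash_support <- unname(clash_flags[rnas])
  rep_df$candidate <- candidate & rep_df$label == "other_RNA"
  cands <- rep_df[rep_df$candidate, , drop = FALSE]
  rank_cols <- grep("^rank_", names(cands), value = TRUE)
  if (nrow(cands) > 0 && length(rank_cols) > 0) {
    best <- do.call(pmin, c(cands[rank_cols], na.rm = TRUE))
    cands <- cands[order(best, cands$rna), , drop = FALSE]
  }
  rownames(rep_df) <- rownames(cands) <- NULL
  structure(list(report = rep_df, candidates = cands),
            class = "candidate_report")
}
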