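# Aggregation of chimera records into per-RNA interaction profiles and an
# undirected interaction graph with orientation counts on the edges.
#
# Conventions: N counts every fragment involving the RNA once (self-chimera
# fragments also once); n_second counts fragments in which the RNA is the
# second of the chimera, so sum(n_second) over RNAs equals the total fragment
# count; k counts distinct non-self partners. (A,B) and (B,A) rows are two
# orientations of one unordered interaction.

#' Aggregate chimera records into per-RNA interaction profiles
#'
#' For every RNA appearing in the records: `N` = total supporting chimeric
#' fragments, `n_second` = fragments in which the RNA is second in the
#' chimera, `S = n_second / N`, `k` = number of distinct interaction partners
#' (self-chimeras excluded). Genomic segments are the strand-aware union of
#' the RNA's chimera-end intervals, kept for U-tract extraction and evidence
#' windows.
#'
#' RNAs appearing only in self-chimeras would have `k = 0`; such profiles are
#' dropped with a warning since every downstream feature presumes at least one
#' interactor.
#'
#' @param records A `"chimera_records"` data frame (one condition).
#' @return List of class `"rna_profiles"` with elements `profiles` (data
#'   frame: `rna`, `condition`, `N`, `k`, `n_second`, `S`), `interactors`
#'   (named list of partner-name character vectors), `segments` (named list
#'   of merged-interval data frames), `condition`.
#' @export
aggregate_profiles <- function(records) {
  if (nrow(records) == 0) {
    warning("no chimera records to aggregate")
    return(structure(list(
      profiles = data.frame(rna = character(), condition = character(),
                            N = integer(), k = integer(), n_second = integer(),
                            S = numeric(), stringsAsFactors = FALSE),
      interactors = list(), segments = list(), condition = NA_character_),
      class = "rna_profiles"))
  }
  cond <- unique(records$condition)
  if (length(cond) != 1)
    stop("records span multiple conditions (", paste(cond, collapse = ", "),
         "); aggregate each condition separately")
  rec <- as.data.frame(records)

  rnas <- sort(unique(c(rec$first_rna, rec$second_rna)))
  idx <- stats::setNames(seq_along(rnas), rnas)
  N <- integer(length(rnas))
  n_second <- integer(length(rnas))
  partners <- stats::setNames(vector("list", length(rnas)), rnas)

  fi <- idx[rec$first_rna]
  si <- idx[rec$second_rna]
  for (r in seq_len(nrow(rec))) {
    n <- rec$n_fragments[r]
    if (rec$is_self[r]) {
      N[fi[r]] <- N[fi[r]] + n          # fragments counted once
      n_second[fi[r]] <- n_second[fi[r]] + n
    } else {
      N[fi[r]] <- N[fi[r]] + n
      N[si[r]] <- N[si[r]] + n
      n_second[si[r]] <- n_second[si[r]] + n
      partners[[fi[r]]] <- c(partners[[fi[r]]], rec$second_rna[r])
      partners[[si[r]]] <- c(partners[[si[r]]], rec$first_rna[r])
    }
  }
  partners <- lapply(partners, function(p) sort(unique(p)))
  k <- vapply(partners, length, 1L)

  segments <- .merge_segments(rec, rnas)

  keep <- k >= 1L
  if (any(!keep))
    warning(sum(!keep), " RNA(s) present only in self-chimeras dropped: ",
            paste(utils::head(rnas[!keep], 5), collapse = ", "))

  structure(list(
    profiles = data.frame(rna = rnas[keep], condition = cond,
                          N = N[keep], k = k[keep],
                          n_second = n_second[keep],
                          S = n_second[keep] / N[keep],
                          stringsAsFactors = FALSE, row.names = NULL),
    interactors = partners[keep],
    segments = segments[rnas[keep]],
    condition = cond), class = "rna_profiles")
}

# Union (per replicon+strand interval merge) of each RNA's chimera-end
# intervals, via GenomicRanges::reduce.
.merge_segments <- function(rec, rnas) {
  ends <- rbind(
    data.frame(rna = rec$first_rna, replicon = rec$first_replicon,
               start = rec$first_start, end = rec$first_end,
               strand = rec$first_strand, stringsAsFactors = FALSE),
    data.frame(rna = rec$second_rna, replicon = rec$second_replicon,
               start = rec$second_start, end = rec$second_end,
               strand = rec$second_strand, stringsAsFactors = FALSE))
  gr <- GenomicRanges::GRanges(ends$replicon,
                               IRanges::IRanges(ends$start + 1L, ends$end),
                               strand = ends$strand)
  red <- GenomicRanges::reduce(S4Vectors::split(gr, factor(ends$rna, rnas)))
  flat <- BiocGenerics::unlist(red, use.names = FALSE)
  df <- data.frame(
    rna = rep(names(red), S4Vectors::elementNROWS(red)),
    replicon = as.character(GenomicRanges::seqnames(flat)),
    start = GenomicRanges::start(flat) - 1L,
    end = GenomicRanges::end(flat),
    strand = as.character(GenomicRanges::strand(flat)),
    stringsAsFactors = FALSE)
  out <- split(df[, -1], factor(df$rna, rnas))
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

#' Data-set totals used as feature normalizers
#'
#' @param records A `"chimera_records"` data frame.
#' @return List with `total_fragments` (each fragment counted once, not once
#'   per endpoint) and `total_unique_interactions` (distinct unordered
#'   non-self RNA pairs).
#' @export
dataset_totals <- function(records) {
  if (nrow(records) == 0) stop("no records; totals undefined")
  rec <- as.data.frame(records)
  pair_key <- ifelse(rec$first_rna <= rec$second_rna,
                     paste(rec$first_rna, rec$second_rna, sep = "\r"),
                     paste(rec$second_rna, rec$first_rna, sep = "\r"))
  list(total_fragments = sum(rec$n_fragments),
       total_unique_interactions = length(unique(pair_key[!rec$is_self])))
}

#' Build the undirected interaction graph with orientation counts
#'
#' (A,B) and (B,A) record rows merge into one edge; fragment counts are kept
#' per orientation so that Second-In-Chimera accounting is preserved.
#'
#' @param records A `"chimera_records"` data frame.
#' @return Data frame of class `"interaction_graph"`: `rna_a`, `rna_b`
#'   (lexicographic, `rna_a < rna_b`), `fragments_ab` (fragments with `rna_a`
#'   first), `fragments_ba` (with `rna_b` first). Self-chimeras are excluded.
#' @export
interaction_graph <- function(records) {
  rec <- as.data.frame(records)
  rec <- rec[!rec$is_self, , drop = FALSE]
  if (nrow(rec) == 0) {
    g <- data.frame(rna_a = character(), rna_b = character(),
                    fragments_ab = integer(), fragments_ba = integer(),
                    stringsAsFactors = FALSE)
    class(g) <- c("interaction_graph", "data.frame")
    return(g)
  }
  a <- pmin(rec$first_rna, rec$second_rna)
  b <- pmax(rec$first_rna, rec$second_rna)
  ab_orient <- rec$first_rna == a      # TRUE: a is first
  key <- paste(a, b, sep = "\r")
  fab <- tapply(ifelse(ab_orient, rec$n_fragments, 0L), key, sum)
  fba <- tapply(ifelse(ab_orient, 0L, rec$n_fragments), key, sum)
  parts <- do.call(rbind, strsplit(names(fab), "\r", fixed = TRUE))
  g <- data.frame(rna_a = parts[, 1], rna_b = parts[, 2],
                  fragments_ab = as.integer(fab), fragments_ba = as.integer(fba),
                  stringsAsFactors = FALSE, row.names = NULL)
  g <- g[order(g$rna_a, g$rna_b), , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("interaction_graph", "data.frame")
  g
}

#' Write the interaction-graph edge list
#'
#' @param graph An `"interaction_graph"`.
#' @param path Output TSV path.
#' @export
write_edge_list <- function(graph, path) {
  write_tsv(as.data.frame(graph), path)
}
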