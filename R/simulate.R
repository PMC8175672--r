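# Synthetic RIL-seq fixtures: S-chimera tables, a genome, labels and ground
# truth with the statistical structure the predictor exploits — planted sRNAs
# with many partners, high second-in-chimera fractions and long terminator
# U-tracts, versus targets with few partners and low second fractions.

#' Configuration for the synthetic RIL-seq generator
#'
#' Defaults track the scale of real per-condition S-chimera data sets (tens
#' of known sRNAs against ~10^3 other RNAs, ~20 partners per sRNA, small
#' per-pair fragment counts, sRNAs second in ~90% of their chimeras, 5-9 nt
#' planted terminator U-tracts versus a <=3 nt background).
#'
#' @param n_srnas Number of planted sRNAs (>= 3; stratified splitting needs
#'   it).
#' @param n_targets Number of target RNAs (>= `n_srnas`).
#' @param seed Seed; all draws are reproducible from it.
#' @param partner_mean,partner_size Negative-binomial mean/size of the number
#'   of partners per sRNA.
#' @param frag_mu,frag_size Fragments per sRNA-target pair are
#'   `1 + NB(mu = frag_mu, size = frag_size)`.
#' @param p_second_srna,p_second_target Propensity of an sRNA / target to be
#'   the second RNA of a chimeric fragment; in an sRNA-target pair the sRNA is
#'   second with probability `p_second_srna / (p_second_srna +
#'   p_second_target)`, and target-target pairs are oriented symmetrically.
#' @param srna_utract,target_utract Integer vectors of planted U-run lengths
#'   to sample from (background runs are capped at 2 nt).
#' @return List of class `"generator_config"`.
#' @export
generator_config <- function(n_srnas = 30L, n_targets = 1200L, seed = 1L,
                             partner_mean = 20, partner_size = 5,
                             frag_mu = 4, frag_size = 1,
                             p_second_srna = 0.9, p_second_target = 0.1,
                             srna_utract = 5:9, target_utract = 0:3) {
  if (n_srnas < 3) stop("n_srnas must be >= 3")
  if (n_targets < n_srnas) stop("n_targets must be >= n_srnas")
  stopifnot(p_second_srna >= 0, p_second_srna <= 1,
            p_second_target >= 0, p_second_target <= 1,
            p_second_srna + p_second_target > 0)
  structure(list(n_srnas = as.integer(n_srnas),
                 n_targets = as.integer(n_targets), seed = as.integer(seed),
                 partner_mean = partner_mean, partner_size = partner_size,
                 frag_mu = frag_mu, frag_size = frag_size,
                 p_second_srna = p_second_srna,
                 p_second_target = p_second_target,
                 srna_utract = as.integer(srna_utract),
                 target_utract = as.integer(target_utract)),
            class = "generator_config")
}

# genome layout: each RNA owns a 220-nt slot; its 120-nt segment sits at
# offset 50, so the +/-50 U-tract window never leaves the slot.
.slot_width <- 220L
.seg_offset <- 50L
.seg_width <- 120L

# Random genome with U/A runs capped at 2 nt so that planted runs are the
# only long U-tracts, then exact runs planted 5 nt downstream of each
# segment's sense 3' end (one guard base keeps runs from extending).
.build_genome_seq <- function(n_slots) {
  s <- paste(sample(c("A", "C", "G", "T"), n_slots * .slot_width,
                    replace = TRUE), collapse = "")
  s <- gsub("TTT", "TTC", s, fixed = TRUE)
  s <- gsub("AAA", "AAG", s, fixed = TRUE)
  s
}

.plant_run <- function(chars, seg, utract) {
  if (utract < 1) return(chars)
  if (seg$strand == "+") {
    at <- seg$end + 5L            # 0-based positions [at, at+utract)
    chars[at + seq_len(utract)] <- "T"
    chars[at] <- "G"                       # guard bases
    chars[at + utract + 1L] <- "G"
  } else {
    at <- seg$start - 5L - utract          # sense U = genomic A, reversed
    chars[at + seq_len(utract)] <- "A"
    chars[at] <- "G"
    chars[at + utract + 1L] <- "G"
  }
  chars
}

#' Generate a synthetic RIL-seq data set
#'
#' Each planted sRNA draws a partner count and a set of target partners; each
#' pair draws a supporting-fragment count and splits its fragments between
#' the two chimera orientations (the sRNA second with high probability).
#' Targets untouched by any sRNA are connected pairwise by background
#' target-target interactions so that every RNA appears in the data. The
#' genome carries each RNA's segment with its planted U-run at the sense 3'
#' end.
#'
#' @param config A [generator_config()].
#' @return List of class `"ril_simulation"`: `records`
#'   (`"chimera_records"`), `genome` (`DNAStringSet`, one replicon
#'   `"chrom"`), `labels` (`"label_set"`), `truth` (data frame of planted
#'   parameters per RNA), `config`.
#' @export
generate_rilseq <- function(config = generator_config()) {
  set.seed(config$seed)
  srnas <- sprintf("srna_%02d", seq_len(config$n_srnas))
  targets <- sprintf("tgt_%04d", seq_len(config$n_targets))
  rnas <- c(srnas, targets)
  n <- length(rnas)

  seg <- data.frame(
    rna = rnas,
    replicon = "chrom",
    start = .seg_offset + (seq_len(n) - 1L) * .slot_width,
    end = .seg_offset + (seq_len(n) - 1L) * .slot_width + .seg_width,
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE)

  utract <- c(sample(config$srna_utract, config$n_srnas, replace = TRUE),
              sample(config$target_utract, config$n_targets, replace = TRUE))

  chars <- strsplit(.build_genome_seq(n), "", fixed = TRUE)[[1]]
  for (i in seq_len(n)) chars <- .plant_run(chars, seg[i, ], utract[i])
  genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(genome) <- "chrom"

  p_srna_second <- config$p_second_srna /
    (config$p_second_srna + config$p_second_target)

  rows <- list()
  planted_k <- integer(config$n_srnas)
  for (i in seq_len(config$n_srnas)) {
    k <- stats::rnbinom(1, size = config$partner_size, mu = config$partner_mean)
    k <- max(1L, min(config$n_targets, k))
    planted_k[i] <- k
    partners <- sample(targets, k)
    for (tg in partners) {
      nf <- 1L + stats::rnbinom(1, size = config$frag_size, mu = config$frag_mu)
      n_sec <- stats::rbinom(1, nf, p_srna_second)
      if (n_sec > 0)
        rows[[length(rows) + 1L]] <- c(tg, srnas[i], n_sec)
      if (nf - n_sec > 0)
        rows[[length(rows) + 1L]] <- c(srnas[i], tg, nf - n_sec)
    }
  }
  # background pairs covering targets with no sRNA partner
  used <- unique(unlist(lapply(rows, function(r) r[1:2])))
  orphan <- setdiff(targets, used)
  for (tg in orphan) {
    other <- sample(setdiff(targets, tg), 1)
    nf <- 1L + stats::rnbinom(1, size = 1, mu = 1)
    n_sec <- stats::rbinom(1, nf, 0.5)   # symmetric orientation
    if (n_sec > 0) rows[[length(rows) + 1L]] <- c(other, tg, n_sec)
    if (nf - n_sec > 0) rows[[length(rows) + 1L]] <- c(tg, other, nf - n_sec)
  }

  rec <- .rows_to_records(rows, seg, "synthetic")
  labels <- label_set(stats::setNames(
    c(rep("known_sRNA", config$n_srnas), rep("other_RNA", config$n_targets)),
    rnas))
  truth <- data.frame(
    rna = rnas,
    label = unclass(labels),
    planted_utract = utract,
    planted_k = c(planted_k, rep(NA_integer_, config$n_targets)),
    p_second = c(rep(p_srna_second, config$n_srnas),
                 rep(1 - p_srna_second, config$n_targets)),
    segment = format_position(seg$start, seg$end, seg$strand),
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(records = rec, genome = genome, labels = labels,
                 truth = truth, segments = seg, config = config),
            class = "ril_simulation")
}

.rows_to_records <- function(rows, seg, condition) {
  m <- do.call(rbind, rows)
  fi <- match(m[, 1], seg$rna)
  si <- match(m[, 2], seg$rna)
  chimera_records(data.frame(
    condition = condition,
    first_rna = m[, 1], first_replicon = seg$replicon[fi],
    first_start = seg$start[fi], first_end = seg$end[fi],
    first_strand = seg$strand[fi],
    second_rna = m[, 2], second_replicon = seg$replicon[si],
    second_start = seg$start[si], second_end = seg$end[si],
    second_strand = seg$strand[si],
    n_fragments = as.integer(m[, 3]),
    stringsAsFactors = FALSE))
}

#' Plant hard-to-classify cases into a simulation
#'
#' Adds the two RNA classes most prone to misclassification: decoy target
#' hubs — new `other_RNA`s interacting with several distinct planted sRNAs,
#' mostly first in their chimeras, a couple of them with long U-tracts and
#' heavy fragment counts (the kind that can still fool the classifier) — and
#' sponge-like positives — new `known_sRNA`s with a single sRNA partner and
#' an extreme second-position fraction, one with heavy fragment support
#' (recoverable) and one with modest support (expected to be missed).
#'
#' With `n_hubs = 0` and `n_sponges = 0` the simulation is returned
#' unchanged.
#'
#' @param sim A `"ril_simulation"` from [generate_rilseq()].
#' @param n_hubs Number of decoy hubs (default 18).
#' @param hub_srna_partners Distinct sRNA partners per hub (default 5).
#' @param n_strong_hubs How many hubs additionally get a long U-tract and
#'   heavy fragment counts (default 2).
#' @param n_sponges 0, 1 or 2 sponges; the first is the heavy one (default 2).
#' @param sponge_fragments Fragment counts of the heavy and modest sponge.
#' @return The augmented `"ril_simulation"`; added RNA names are recorded in
#'   `truth$hard_case` (`"hub"`, `"strong_hub"`, `"sponge_extreme"`,
#'   `"sponge_modest"`, `""`).
#' @export
plant_hard_cases <- function(sim, n_hubs = 18L, hub_srna_partners = 5L,
                             n_strong_hubs = 2L, n_sponges = 2L,
                             sponge_fragments = c(500L, 8L)) {
  if (n_hubs == 0 && n_sponges == 0) return(sim)
  config <- sim$config
  if (hub_srna_partners > config$n_srnas)
    stop("hub_srna_partners exceeds the number of planted sRNAs")
  set.seed((config$seed + 1000003L) %% .Machine$integer.max)
  srnas <- sim$truth$rna[sim$truth$label == "known_sRNA" &
                           !grepl("^sponge", sim$truth$rna)]

  new_names <- character(0)
  new_labels <- character(0)
  hard_kind <- character(0)
  if (n_hubs > 0) {
    hubs <- sprintf("hub_%02d", seq_len(n_hubs))
    new_names <- c(new_names, hubs)
    new_labels <- c(new_labels, rep("other_RNA", n_hubs))
    hard_kind <- c(hard_kind,
                   ifelse(seq_len(n_hubs) <= n_strong_hubs, "strong_hub", "hub"))
  }
  if (n_sponges > 0) {
    sp <- c("sponge_extreme", "sponge_modest")[seq_len(n_sponges)]
    new_names <- c(new_names, sp)
    new_labels <- c(new_labels, rep("known_sRNA", n_sponges))
    hard_kind <- c(hard_kind, sp)
  }

  n_old <- nrow(sim$segments)
  n_new <- length(new_names)
  new_seg <- data.frame(
    rna = new_names, replicon = "chrom",
    start = .seg_offset + (n_old + seq_len(n_new) - 1L) * .slot_width,
    end = .seg_offset + (n_old + seq_len(n_new) - 1L) * .slot_width + .seg_width,
    strand = sample(c("+", "-"), n_new, replace = TRUE),
    stringsAsFactors = FALSE)
  new_utract <- integer(n_new)
  new_utract[hard_kind == "hub"] <- sample(config$target_utract,
                                           sum(hard_kind == "hub"),
                                           replace = TRUE)
  new_utract[hard_kind == "strong_hub"] <- 8L
  new_utract[grepl("^sponge", hard_kind)] <- 8L

  ext <- strsplit(.build_genome_seq(n_new), "", fixed = TRUE)[[1]]
  base_len <- length(sim$genome[["chrom"]])
  for (i in seq_len(n_new)) {
    local_seg <- new_seg[i, ]
    local_seg$start <- local_seg$start - base_len
    local_seg$end <- local_seg$end - base_len
    ext <- .plant_run(ext, local_seg, new_utract[i])
  }
  genome <- Biostrings::DNAStringSet(paste0(as.character(sim$genome[["chrom"]]),
                                            paste(ext, collapse = "")))
  names(genome) <- "chrom"

  seg <- rbind(sim$segments, new_seg)
  p_srna_second <- config$p_second_srna /
    (config$p_second_srna + config$p_second_target)
  rows <- list()
  for (i in seq_len(n_new)) {
    if (hard_kind[i] %in% c("hub", "strong_hub")) {
      heavy <- hard_kind[i] == "strong_hub"
      partners <- sample(srnas, hub_srna_partners)
      for (sr in partners) {
        nf <- 1L + stats::rnbinom(1, size = config$frag_size,
                                  mu = if (heavy) 6 * config$frag_mu
                                       else config$frag_mu)
        n_sec <- stats::rbinom(1, nf, p_srna_second)  # the sRNA is second
        if (n_sec > 0)
          rows[[length(rows) + 1L]] <- c(new_names[i], sr, n_sec)
        if (nf - n_sec > 0)
          rows[[length(rows) + 1L]] <- c(sr, new_names[i], nf - n_sec)
      }
    } else {
      nf <- sponge_fragments[match(hard_kind[i],
                                   c("sponge_extreme", "sponge_modest"))]
      partner <- sample(srnas, 1)       # sponges pair with one sRNA
      n_sec <- stats::rbinom(1, nf, 0.95)  # sponge nearly always second
      if (n_sec > 0)
        rows[[length(rows) + 1L]] <- c(partner, new_names[i], n_sec)
      if (nf - n_sec > 0)
        rows[[length(rows) + 1L]] <- c(new_names[i], partner, nf - n_sec)
    }
  }
  new_rec <- .rows_to_records(rows, seg, unique(sim$records$condition))
  rec <- chimera_records(rbind(as.data.frame(sim$records)[
    , setdiff(names(sim$records), "is_self")],
    as.data.frame(new_rec)[, setdiff(names(new_rec), "is_self")]))

  labels <- label_set(c(stats::setNames(unclass(sim$labels), names(sim$labels)),
                        stats::setNames(new_labels, new_names)))
  if (is.null(sim$truth$hard_case)) sim$truth$hard_case <- ""
  truth <- rbind(sim$truth,
                 data.frame(rna = new_names, label = new_labels,
                            planted_utract = new_utract,
                            planted_k = NA_integer_,
                            p_second = ifelse(grepl("sponge", hard_kind),
                                              0.95, 1 - p_srna_second),
                            segment = format_position(new_seg$start,
                                                      new_seg$end,
                                                      new_seg$strand),
                            hard_case = hard_kind,
                            stringsAsFactors = FALSE))
  structure(list(records = rec, genome = genome, labels = labels,
                 truth = truth, segments = seg, config = config),
            class = "ril_simulation")
}

#' Write a simulation to disk
#'
#' Writes the S-chimera table (default dialect), genome FASTA, label TSV and
#' ground-truth TSV.
#'
#' @param sim A `"ril_simulation"`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the four paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(chimeras = file.path(dir, "schimeras.tsv"),
             genome = file.path(dir, "genome.fa"),
             labels = file.path(dir, "labels.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_schimera_table(sim$records, paths["chimeras"])
  Biostrings::writeXStringSet(sim$genome, paths["genome"])
  write_labels(sim$labels, paths["labels"])
  write_tsv(sim$truth, paths["truth"])
  invisible(paths)
}
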