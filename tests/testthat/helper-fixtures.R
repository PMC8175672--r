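# Shared fixtures, built in code at test time.

# Three-record toy: (first, second, fragments) = (A,B,5), (C,A,3), (A,D,2).
# Hand enumeration: A has N = 10, k = 3, n_second = 3, S = 0.3;
# totals are 10 fragments and 3 unique interactions.
toy_records <- function(condition = "toy") {
  seg <- list(A = c(100L, 160L, "+"), B = c(300L, 360L, "+"),
              C = c(500L, 560L, "-"), D = c(700L, 760L, "+"))
  row <- function(f, s, n) {
    data.frame(condition = condition,
               first_rna = f, first_replicon = "chr",
               first_start = as.integer(seg[[f]][1]),
               first_end = as.integer(seg[[f]][2]),
               first_strand = seg[[f]][3],
               second_rna = s, second_replicon = "chr",
               second_start = as.integer(seg[[s]][1]),
               second_end = as.integer(seg[[s]][2]),
               second_strand = seg[[s]][3],
               n_fragments = n, stringsAsFactors = FALSE)
  }
  chimera_records(rbind(row("A", "B", 5L), row("C", "A", 3L),
                        row("A", "D", 2L)))
}

# 1-kb all-C genome (no U runs) for the toy records.
toy_genome <- function() {
  g <- Biostrings::DNAStringSet(paste(rep("C", 1000), collapse = ""))
  names(g) <- "chr"
  g
}

# Genome with an arbitrary sequence on one replicon named "chr".
genome_from_seq <- function(seq, name = "chr") {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- name
  g
}

# Scaled-down generator preset for fast unit tests.
small_config <- function(seed = 101L) {
  generator_config(n_srnas = 5L, n_targets = 100L, partner_mean = 6,
                   seed = seed)
}

# Memoised small simulation + features (several files reuse it).
.small_cache <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(.small_cache$sim)) .small_cache$sim <- generate_rilseq(small_config())
  .small_cache$sim
}
small_features <- function() {
  if (is.null(.small_cache$feats)) {
    sim <- small_sim()
    .small_cache$feats <- srna_features(sim$records, sim$genome)
  }
  .small_cache$feats
}

# Independent brute-force oracle: expands every record into individual
# fragments and tabulates per-RNA aggregates by direct enumeration, with no
# shared code with aggregate_profiles().
brute_force_profiles <- function(records) {
  rec <- as.data.frame(records)
  frags <- rec[rep(seq_len(nrow(rec)), rec$n_fragments), c("first_rna", "second_rna")]
  rnas <- sort(unique(c(rec$first_rna, rec$second_rna)))
  out <- lapply(rnas, function(r) {
    involved <- frags$first_rna == r | frags$second_rna == r
    second <- frags$second_rna == r
    partners <- unique(c(frags$second_rna[frags$first_rna == r],
                         frags$first_rna[frags$second_rna == r]))
    partners <- setdiff(partners, r)
    data.frame(rna = r, N = sum(involved), n_second = sum(second),
               k = length(partners), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$S <- out$n_second / out$N
  out
}
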