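test_that("SIC score follows S - 1/k with its bounds", {
  expect_equal(sic_score(1, 10), 0.9)
  expect_equal(sic_score(0.5, 2), 0)
  expect_equal(sic_score(0, 1), -1)
  expect_error(sic_score(0.5, 0), "k")
  expect_error(sic_score(1.2, 3), "S")
  # bound property over the aggregated small simulation
  p <- aggregate_profiles(small_sim()$records)$profiles
  s <- sic_score(p$S, p$k)
  expect_true(all(s >= -1 & s < 1))
  expect_equal(s, p$S - 1 / p$k)
})

test_that("U-tract length is the longest sense-strand U run in the flanked window", {
  # segment [4,12) on "AAAAGCTTTTAGCC...": longest T run = 4 within +/-2
  g <- genome_from_seq("AAAAGCTTTTAGCCCCCCCC")
  seg <- genomic_interval("chr", 4, 12, "+")
  expect_equal(utract_length(seg, g, flank = 2), 4L)
  # no U at all
  expect_equal(utract_length(genomic_interval("chr", 0, 4, "+"), g, flank = 0), 0L)

  # strand symmetry: genomic TTTTT is a U-tract only on the plus strand
  g2 <- genome_from_seq("GGTTTTTGG")
  seg_p <- genomic_interval("chr", 2, 7, "+")
  seg_m <- genomic_interval("chr", 2, 7, "-")
  expect_equal(utract_length(seg_p, g2, flank = 0), 5L)
  expect_equal(utract_length(seg_m, g2, flank = 0), 0L)
  # and genomic AAAAA reads as U on the minus strand
  g3 <- genome_from_seq("GGAAAAAGG")
  expect_equal(utract_length(genomic_interval("chr", 2, 7, "-"), g3, flank = 0), 5L)

  # flank extension reaches a run outside the segment
  g4 <- genome_from_seq("TTTTTTACGTACGTACGT")
  expect_equal(utract_length(genomic_interval("chr", 8, 12, "+"), g4, flank = 0), 1L)
  expect_equal(utract_length(genomic_interval("chr", 8, 12, "+"), g4, flank = 10), 6L)

  expect_error(utract_length(genomic_interval("chr", 8, 30, "+"), g4),
               "outside")
})

test_that("U-tract is invariant to segment order and overlapping splits", {
  g <- genome_from_seq(paste0(strrep("C", 40), "TTTTTTT", strrep("C", 40)))
  a <- genomic_interval("chr", 10, 30, "+")
  b <- genomic_interval("chr", 50, 70, "+")
  expect_equal(utract_length(rbind(a, b), g, flank = 10),
               utract_length(rbind(b, a), g, flank = 10))
  # splitting a segment into overlapping halves covering the same window
  whole <- genomic_interval("chr", 10, 70, "+")
  halves <- rbind(genomic_interval("chr", 10, 45, "+"),
                  genomic_interval("chr", 35, 70, "+"))
  expect_equal(utract_length(whole, g, flank = 10),
               utract_length(halves, g, flank = 10))
})

test_that("first-layer features follow the normalized log10 definitions", {
  prof <- aggregate_profiles(toy_records())
  tot <- dataset_totals(toy_records())
  fl <- first_layer(prof, tot, toy_genome())
  a <- fl[fl$rna == "A", ]
  # A carries all 10 fragments and all 3 interactions: log10(1) = 0
  expect_equal(a$f_total_chimeras, 0)
  expect_equal(a$f_unique_interactions, 0)
  expect_equal(a$f_sic, 0.3 - 1 / 3)
  expect_equal(a$f_utract, 0L)           # all-C genome
  b <- fl[fl$rna == "B", ]
  expect_equal(b$f_total_chimeras, log10(5 / 10))
  expect_equal(b$f_unique_interactions, log10(1 / 3))
  expect_error(first_layer(prof, list(total_fragments = 0,
                                      total_unique_interactions = 3),
                           toy_genome()), "positive")
})

test_that("second-layer features are medians over the interactor set", {
  fl <- second_layer(aggregate_profiles(toy_records()),
                     first_layer(aggregate_profiles(toy_records()),
                                 dataset_totals(toy_records()), toy_genome()))
  a <- fl[fl$rna == "A", ]
  # A's interactors B, C, D all have k = 1 -> median of three equal values
  expect_equal(a$f_med_interactor_degree, log10(1 / 3))
  # their SIC values are {0, -1, 0}: median 0
  expect_equal(a$f_med_interactor_sic, 0)
  # single-interactor RNAs inherit A's values
  b <- fl[fl$rna == "B", ]
  expect_equal(b$f_med_interactor_degree, a$f_unique_interactions)
  expect_equal(b$f_med_interactor_sic, a$f_sic)
  # even-sized interactor sets take the midpoint of the two central values:
  # adding record (D,B,1) gives B the interactors {A, D} with hand-computed
  # SIC values 0.3 - 1/3 and 2/3 - 1/2, and degrees log10(3/4), log10(2/4)
  ext <- as.data.frame(toy_records())[, -13]
  extra <- ext[1, ]
  extra$first_rna <- "D"; extra$second_rna <- "B"
  extra$first_start <- 700L; extra$first_end <- 760L
  extra$second_start <- 300L; extra$second_end <- 360L
  extra$n_fragments <- 1L
  rec4 <- chimera_records(rbind(ext, extra))
  f4 <- srna_features(rec4, toy_genome())
  b4 <- f4[f4$rna == "B", ]
  expect_equal(b4$f_med_interactor_sic, ((0.3 - 1 / 3) + (2 / 3 - 1 / 2)) / 2)
  expect_equal(b4$f_med_interactor_degree, (log10(3 / 4) + log10(2 / 4)) / 2)
  # completeness: all six features present and finite on the simulation
  feats <- small_features()
  cols <- c("f_total_chimeras", "f_unique_interactions", "f_sic", "f_utract",
            "f_med_interactor_degree", "f_med_interactor_sic")
  expect_true(all(cols %in% names(feats)))
  expect_true(all(is.finite(as.matrix(feats[cols]))))
  expect_true(all(feats$f_total_chimeras <= 0))
  expect_true(all(feats$f_unique_interactions <= 0))
})

test_that("Mann-Whitney screen separates planted groups and fails nulls", {
  # fully separated 5 vs 5: exact two-sided p is 2 / choose(10, 5), which
  # survives a 6-fold Bonferroni correction but not an 18-fold one
  x <- data.frame(f = c(1:5, 101:105), rna = letters[1:10])
  lab <- rep(c("other_RNA", "known_sRNA"), each = 5)
  res <- mann_whitney_screen(x, lab, m_tests = 6, feature_cols = "f")
  expect_equal(res$p_raw, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$p_adjusted, res$p_raw * 6)
  expect_true(res$pass)
  res18 <- mann_whitney_screen(x, lab, m_tests = 18, feature_cols = "f")
  expect_equal(res18$p_adjusted, res18$p_raw * 18)
  expect_false(res18$pass)

  # identical distributions: adjusted p saturates at 1
  y <- data.frame(f = rep(1:20, 2), rna = paste0("r", 1:40))
  res0 <- mann_whitney_screen(y, rep(c("known_sRNA", "other_RNA"), each = 20),
                              m_tests = 18, feature_cols = "f")
  expect_false(res0$pass)
  expect_equal(res0$p_adjusted, 1)

  # constant feature reported as failure with a reason
  z <- data.frame(f = rep(1, 10), rna = letters[1:10])
  resc <- mann_whitney_screen(z, lab, m_tests = 18, feature_cols = "f")
  expect_false(resc$pass)
  expect_match(resc$reason, "constant")

  expect_error(mann_whitney_screen(x, lab, m_tests = 0, feature_cols = "f"),
               "m_tests")
  expect_error(mann_whitney_screen(x, rep("known_sRNA", 10), feature_cols = "f"),
               "non-empty")

  # planted separation on the scaled-down preset: all p-values defined; the
  # strongly planted U-tract clears the 18-fold Bonferroni bar even with 5
  # positives (full power needs the full-scale set, exercised elsewhere)
  feats <- small_features()
  lab2 <- resolve_labels(small_sim()$labels, feats$rna)
  scr <- mann_whitney_screen(feats, lab2)
  expect_true(all(is.finite(scr$p_raw)))
  expect_true(scr$pass[scr$feature == "f_utract"])
  expect_true(all(scr$p_raw[scr$feature %in%
                              c("f_total_chimeras", "f_sic")] < 0.05))
})

test_that("correlation clustering links components at |r| >= threshold", {
  # handcrafted correlation matrix: 1-2 and 2-3 linked, 4 isolated
  r <- diag(4)
  r[1, 2] <- r[2, 1] <- 0.9
  r[2, 3] <- r[3, 2] <- -0.9   # absolute correlation links too
  r[1, 3] <- r[3, 1] <- 0.5
  dimnames(r) <- list(letters[1:4], letters[1:4])
  cl <- cluster_from_cor(r, 0.8)
  expect_equal(unname(cl[1:3]), rep(cl[["a"]], 3))  # one chained component
  expect_equal(length(unique(cl)), 2L)

  # exact affine copies cluster together with one representative
  set.seed(9)
  d <- data.frame(u = rnorm(50))
  d$v <- 3 * d$u - 1
  d$w <- rnorm(50)
  cc <- correlation_cluster(d, threshold = 0.8, priority = c("u", "v", "w"),
                            feature_cols = c("u", "v", "w"))
  expect_equal(cc$cluster[["u"]], cc$cluster[["v"]])
  expect_true(cc$representative[["u"]])
  expect_false(cc$representative[["v"]])
  expect_true(cc$representative[["w"]])

  # independent features stay in singleton clusters
  set.seed(10)
  ind <- as.data.frame(matrix(rnorm(500 * 3), 500, 3))
  names(ind) <- c("x1", "x2", "x3")
  cc2 <- correlation_cluster(ind, threshold = 0.8,
                             priority = names(ind), feature_cols = names(ind))
  expect_equal(length(unique(cc2$cluster)), 3L)

  # constant features are excluded with a warning
  ind$x3 <- 1
  expect_warning(correlation_cluster(ind, feature_cols = names(ind),
                                     priority = names(ind)), "constant")
})
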