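test_that("substring partition: chunking, remainder dropping, arithmetic oracle", {
  set.seed(19)
  g <- genome_record("g", random_dna(1000))
  regions <- data.frame(contig_id = "g", start = c(100L, 400L),
                        end = c(220L, 449L))   # 120 bp and 49 bp
  s <- partition_substrings(g, regions, width = 50)
  expect_equal(sum(s$class_label == "repeat"), 2L)  # 120 -> 2, 49 -> 0
  # non-repeat segments: 100, 180, 551 -> 2 + 3 + 11 chunks
  expect_equal(sum(s$class_label == "non_repeat"),
               100 %/% 50 + 180 %/% 50 + 551 %/% 50)
  expect_true(all(rowSums(s[, c("N_A", "N_T", "N_C", "N_G")]) == 50))
  expect_true(sum(nrow(s)) * 50 <= nchar(g$seq))
  expect_error(partition_substrings(g, regions, width = 0), "width")
})

test_that("kruskal_wallis: closed-form case and reference-implementation oracle", {
  kw <- kruskal_wallis(c(1, 2, 3), c(4, 5, 6))
  expect_equal(kw[["H"]], 3.8571, tolerance = 1e-4)
  expect_equal(kw[["p"]], 0.0495, tolerance = 1e-2)
  expect_equal(kruskal_wallis(c(1, 2), c(1, 2)),
               c(H = 0, p = 1), tolerance = 1e-12)
  set.seed(37)
  for (i in 1:100) {
    a <- sample(0:20, sample(3:30, 1), replace = TRUE)  # heavy ties
    b <- sample(0:20, sample(3:30, 1), replace = TRUE)
    if (length(unique(c(a, b))) == 1L) next
    ref <- stats::kruskal.test(list(a, b))
    got <- kruskal_wallis(a, b)
    expect_equal(got[["H"]], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got[["p"]], ref$p.value, tolerance = 1e-10)
  }
})

test_that("benjamini_yekutieli: hand-computed cases and p.adjust oracle", {
  expect_equal(benjamini_yekutieli(0.03), 0.03)
  expect_equal(benjamini_yekutieli(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.0833333, 4), tolerance = 1e-5)
  set.seed(41)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    got <- benjamini_yekutieli(p)
    expect_equal(got, p.adjust(p, method = "BY"), tolerance = 1e-12)
    expect_true(all(got >= p))
    # order invariance
    perm <- sample(length(p))
    expect_equal(benjamini_yekutieli(p[perm]), got[perm])
  }
})

test_that("identical substrings in both classes give p_adj = 1", {
  chunk <- strrep("ACGTA", 10)                  # 50 bp
  g <- genome_record("g", strrep(chunk, 6))
  regions <- data.frame(contig_id = "g", start = 0L, end = 150L)
  res <- tr_composition_test(g, regions)
  expect_true(all(res$p_adj == 1))
  expect_equal(res$mean_repeat, res$mean_nonrepeat)
})

test_that("composition test warns and skips with fewer than 2 samples per class", {
  g <- genome_record("g", random_dna(300))
  regions <- data.frame(contig_id = "g", start = 0L, end = 60L)
  expect_warning(res <- tr_composition_test(g, regions), "skipped")
  expect_true(all(is.na(res$p_adj)))
})

test_that("codon usage: toy ORF counting, ratios, absent codons", {
  cds <- c(o = "ATGCCACCACCAAAATAA")
  iv <- list(o = data.frame(start = 1L, end = 4L))
  tab <- codon_usage(cds, iv)
  expect_equal(tab$freq_in[tab$codon == "CCA"], 1)
  expect_equal(tab$ratio[tab$codon == "AAA"], 0)
  absent <- tab$codon[tab$absent_in_aatr]
  expect_true(all(c("AAA", "ATG", "TAA") %in% absent))
  expect_equal(sum(tab$freq_in), 1, tolerance = 1e-12)
  expect_equal(sum(tab$freq_out), 1, tolerance = 1e-12)
  expect_error(codon_usage(cds, list(o = data.frame(start = 1L, end = 9L))),
               "interval")
})

test_that("codon usage: whitelist-planted aaTRs leave the other 54 codons absent", {
  whitelist <- c("CCA", "ACA", "GAA", "AAA", "GAT", "AAG", "ACT", "CCT",
                 "GAG", "ACC")
  set.seed(43)
  in_part <- paste(sample(whitelist, 60, replace = TRUE), collapse = "")
  out_part <- paste(rep(names(Biostrings::GENETIC_CODE), 3), collapse = "")
  cds <- c(o = paste0(in_part, out_part))
  iv <- list(o = data.frame(start = 0L, end = 60L))
  tab <- codon_usage(cds, iv)
  expect_equal(sum(tab$absent_in_aatr), 64L - length(whitelist))
})

test_that("positional nucleotide frequencies normalize and match a tally oracle", {
  res <- positional_nt_frequency(rep("CCA", 5), c("ATG", "TAA"))
  expect_equal(res$aatr["C", "pos1"], 1)
  expect_equal(res$aatr["A", "pos3"], 1)
  expect_true(all(abs(colSums(res$aatr) - 1) < 1e-12))
  expect_true(all(abs(colSums(res$other) - 1) < 1e-12))
  set.seed(47)
  codons <- sample(names(Biostrings::GENETIC_CODE), 1000, replace = TRUE)
  got <- positional_nt_frequency(codons, codons)$aatr
  for (p in 1:3) {
    for (b in c("A", "T", "G", "C")) {
      expect_equal(got[b, p], mean(substr(codons, p, p) == b))
    }
  }
})

test_that("aa enrichment: degenerate proteome, planted enrichment, normalization", {
  aatrs <- data.frame(unit = "P", copies = 4L)
  res <- aa_enrichment(aatrs, c(p1 = "PPPP"))
  expect_equal(res$ratio[res$aa == "P"], 1)
  expect_true(all(is.na(res$ratio[res$aa != "P"])))
  expect_equal(sum(res$freq_aatr), 1, tolerance = 1e-12)

  # planted 2x K enrichment
  set.seed(53)
  prot <- vapply(1:40, function(i) {
    paste(sample(c("K", "E", "P", "T"), 100, replace = TRUE,
                 prob = c(0.25, 0.25, 0.25, 0.25)), collapse = "")
  }, character(1))
  names(prot) <- paste0("p", 1:40)
  units <- vapply(1:30, function(i) {
    paste(sample(c("K", "E", "P", "T"), 6, replace = TRUE,
                 prob = c(0.5, 1 / 6, 1 / 6, 1 / 6)), collapse = "")
  }, character(1))
  res2 <- aa_enrichment(data.frame(unit = units, copies = 4L), prot)
  expect_equal(res2$ratio[res2$aa == "K"], 2, tolerance = 0.25)
  # ordered by disorder propensity
  expect_equal(res2$aa, names(sort(top_idp)))
})

test_that("snp bias summary: assignment, empty table, planted 14/18 tally", {
  regions <- data.frame(contig_id = "g", start = 100L, end = 200L)
  v1 <- data.frame(contig_id = "g", position = 150L, ref_base = "G",
                   alt_base = "A", count = 1L)
  res <- snp_bias_summary(v1, regions)
  expect_equal(res$tr["G", "A"], 1L)
  expect_equal(sum(res$tr), 1L)
  expect_equal(sum(res$non_tr), 0L)

  v0 <- v1[0, ]
  res0 <- snp_bias_summary(v0, regions)
  expect_equal(sum(res0$tr) + sum(res0$non_tr), 0L)

  set.seed(59)
  pos_in <- sample(100:199, 18)
  v <- data.frame(contig_id = "g", position = pos_in,
                  ref_base = rep(c("G", "C", "T"), c(14, 2, 2)),
                  alt_base = "A", count = 1L)
  res2 <- snp_bias_summary(v, regions)
  expect_equal(res2$tr["G", "A"] / sum(res2$tr), 14 / 18)

  vbad <- data.frame(contig_id = "g", position = 10000L, ref_base = "G",
                     alt_base = "A", count = 1L)
  g <- genome_record("g", random_dna(300))
  expect_warning(snp_bias_summary(vbad, regions, g), "bounds")
})
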