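# Windowed divergence, substitution classification, Ka/Ks, contingency.

test_that("window layout and densities match direct counting", {
  same <- strrep("ACGT", 50)
  tr <- window_snp_density(same, same)
  expect_true(all(tr$raw == 0))
  expect_equal(tr$start, seq(0, 100, by = 25))  # 200 columns -> 5 windows

  # every 10th base differs: interior windows are exactly 0.10
  a <- strrep("A", 1000)
  bv <- rep("A", 1000)
  bv[seq(10, 1000, by = 10)] <- "C"
  tr <- window_snp_density(a, paste(bv, collapse = ""))
  expect_true(all(tr$raw == 0.10))

  expect_error(window_snp_density("ACGT", "ACG"), "length")
  expect_error(window_snp_density(same, same, window = 10, step = 20),
               "window")
})

test_that("window densities equal brute-force counts on random alignments with masking", {
  withr::with_seed(55, {
    for (i in 1:5) {
      p <- simulate_diverged_pair(2000, 0.05)
      # inject masked columns
      av <- strsplit(p$a, "")[[1]]; bv <- strsplit(p$b, "")[[1]]
      av[sample(2000, 30)] <- "N"
      bv[sample(2000, 30)] <- "-"
      a <- paste(av, collapse = ""); b <- paste(bv, collapse = "")
      got <- window_snp_density(a, b)
      want <- brute_force_window_density(a, b, 100, 25)
      expect_equal(got$start, want$start)
      expect_equal(got$raw, want$raw)
    }
  })
})

test_that("background correction subtracts the pooled background rate", {
  a <- strrep("A", 1000)
  bv <- rep("A", 1000); bv[seq(50, 1000, by = 50)] <- "G"
  tr <- window_snp_density(a, paste(bv, collapse = ""))
  expect_true(all(tr$raw == 0.02))

  # background with exactly 400 differences over 60 kb
  bg_b <- rep("A", 60000); bg_b[seq_len(400) * 150] <- "T"
  bg <- list(list(strrep("A", 60000), paste(bg_b, collapse = "")))
  corr <- background_correct(tr, bg)
  expect_equal(attr(corr, "background"), 400 / 60000)
  expect_equal(corr$corrected, rep(0.02 - 400 / 60000, nrow(corr)))

  # zero background leaves the track unchanged
  none <- background_correct(tr, list(list(a, a)))
  expect_equal(none$corrected, none$raw)
  expect_error(background_correct(tr, list()), "empty")
})

test_that("codon pair classification follows pathway averaging", {
  gat_gac <- classify_substitutions(codon_alignment("GAT", "GAC"))
  expect_equal(gat_gac$aa_changing, 0)  # Asp -> Asp
  expect_equal(gat_gac$silent, 1)

  gat_gaa <- classify_substitutions(codon_alignment("GAT", "GAA"))
  expect_equal(gat_gaa$aa_changing, 1)  # Asp -> Glu
  expect_equal(gat_gaa$silent, 0)

  # TTT -> GTA: pathways (nonsyn, syn) and (nonsyn, nonsyn), average (1.5, 0.5)
  r <- classify_substitutions(codon_alignment("TTT", "GTA"))
  expect_equal(r$aa_changing, 1.5)
  expect_equal(r$silent, 0.5)
  expect_equal(r$aa_changing_int, 2L)  # half away from zero
  expect_equal(r$silent_int, 1L)

  # codons with N or gap are skipped
  rskip <- classify_substitutions(codon_alignment("GATNNNA--", "GACTTTA--"))
  expect_equal(rskip$n_codons_compared, 1)
  expect_equal(rskip$silent, 1)

  expect_error(codon_alignment("TAAGAT", "TAAGAT"), "stop")
  expect_error(codon_alignment("GAT", "GAX"), "alphabet")
})

test_that("pathway-averaged counts conserve total differences and sites sum to 3 per codon", {
  withr::with_seed(202, {
    for (i in 1:5) {
      aln <- simulate_neutral_pair(300, 120)
      cl <- classify_substitutions(aln)
      cods <- macrospace:::aligned_codons(aln)
      nt_diffs <- sum(mapply(function(x, y) {
        sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
      }, cods$a, cods$b))
      expect_equal(cl$aa_changing + cl$silent, nt_diffs)
      sites <- ng_sites(aln)
      expect_equal(sites$N + sites$S, 3 * sites$n_codons)
    }
  })
})

test_that("Ka/Ks handles identical sequences, saturation and uncorrected mode", {
  aln <- codon_alignment("GATTTCAAG", "GATTTCAAG")
  r <- ka_ks(aln)
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
  expect_true(r$undefined)
  expect_true(is.na(r$ka_ks))

  # saturated silent proportion flags the correction as undefined
  sat <- ka_ks_from_counts(1, 10, N = 100, S = 10)
  expect_true(sat$undefined)

  raw <- ka_ks_from_counts(6, 2, N = 60, S = 20, correction = "none")
  expect_equal(raw$Ka, 0.1)
  expect_equal(raw$Ks, 0.1)
  expect_equal(raw$ka_ks, 1)

  expect_error(ka_ks_from_counts(1, 1, N = 0, S = 10), "site totals")
})

test_that("the substitution table round-trips screen-style counts", {
  aln <- simulate_coding_pair(coding_pair_spec(400, 10, 5), seed = 21,
                              id = "PPP1R15")
  tab <- substitution_table(list(ka_ks(aln)))
  expect_equal(tab$gene, "PPP1R15")
  expect_equal(tab$aa_changing, 10L)
  expect_equal(tab$silent, 5L)

  path <- tempfile(fileext = ".tsv")
  write_substitution_table(tab, path)
  fields <- strsplit(readLines(path)[2], "\t")[[1]]
  expect_equal(fields[1:3], c("PPP1R15", "10", "5"))
})

test_that("the substitution-class contingency test matches hand-computed expectations", {
  # identical ratios: no heterogeneity
  even <- data.frame(gene = c("g1", "g2"),
                     aa_changing = c(10L, 20L), silent = c(5L, 10L))
  expect_equal(suppressWarnings(substitution_contingency(even))$statistic,
               0)

  tab <- data.frame(gene = c("g1", "g2"),
                    aa_changing = c(10L, 2L), silent = c(5L, 23L))
  expect_warning(got <- substitution_contingency(tab), "expected counts")
  # expected counts from the margins
  e <- outer(c(15, 25), c(12, 28)) / 40
  o <- rbind(c(10, 5), c(2, 23))
  expect_equal(got$statistic, sum((o - e)^2 / e))
  expect_equal(got$df, 1)

  expect_error(substitution_contingency(tab[1, ]), "2 genes")
  zero <- data.frame(gene = c("a", "b"), aa_changing = c(0L, 0L),
                     silent = c(0L, 0L))
  expect_error(substitution_contingency(zero), "all-zero")
})

test_that("the candidate-gene table carries the screen hits and runs with df = n - 1", {
  tab <- candidate_gene_substitutions()
  expect_equal(nrow(tab), 9)
  expect_equal(tab$aa_changing[tab$gene == "PPP1R15"], 10L)
  expect_equal(tab$silent[tab$gene == "PPP1R15"], 5L)
  expect_equal(sum(tab$screen_hit), 6)
  hits <- tab[tab$screen_hit, ]
  got <- suppressWarnings(substitution_contingency(hits))
  expect_equal(got$df, 5)
  expect_gt(got$statistic, 0)
})
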