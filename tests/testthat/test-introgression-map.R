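# Diagnostic SNP calling, windowed donor frequency, region segmentation,
# gene annotation.

toy_table <- function(pos, allele, n = 20) {
  bases <- c("A", "C", "G", "T")
  m <- matrix(0L, length(pos), 4, dimnames = list(NULL, bases))
  m[cbind(seq_along(pos), match(allele, bases))] <- n
  data.frame(chrom = "chr1", pos = pos, m)
}

test_that("diagnostic SNP calling keeps fixed differences and drops polymorphism", {
  a <- toy_table(c(100, 200), c("A", "C"))
  expect_equal(nrow(call_diagnostic_snps(a, a)), 0)

  b <- toy_table(c(100, 200), c("T", "C"))
  snps <- call_diagnostic_snps(a, b)
  expect_equal(snps$pos, 100)
  expect_equal(snps$donor_allele, "A")
  expect_equal(snps$recipient_allele, "T")

  # 5 fixed differences + 3 sites polymorphic within species A
  a8 <- toy_table(c(1:5 * 100, 600, 700, 800),
                  c("A", "A", "C", "G", "T", "A", "C", "G"))
  b8 <- toy_table(c(1:5 * 100, 600, 700, 800),
                  c("C", "G", "T", "A", "C", "A", "C", "G"))
  a8[6:8, "T"] <- 5L
  a8[6, "A"] <- 15L; a8[7, "C"] <- 15L; a8[8, "G"] <- 15L
  snps <- call_diagnostic_snps(a8, b8)
  expect_equal(snps$pos, 1:5 * 100)

  # min_count excludes thin sites
  thin <- toy_table(100, "A", n = 1)
  other <- toy_table(100, "G", n = 20)
  expect_equal(nrow(call_diagnostic_snps(thin, other, min_count = 2)), 0)
  expect_error(call_diagnostic_snps(toy_table(1, "A"),
                                    toy_table(2, "C")),
               "no shared sites")
})

test_that("window frequencies pool reads as ratio of sums and respect min_snps", {
  snps <- diagnostic_snp_table(data.frame(
    chrom = "chr1", pos = c(1000, 2000), donor_allele = "A",
    recipient_allele = "T"))
  counts <- structure(data.frame(chrom = "chr1", pos = c(1000, 2000),
                                 depth = c(20, 40),
                                 donor_reads = c(10, 30)),
                      class = c("pool_counts", "data.frame"))
  tr <- donor_frequency_windows(snps, counts, window_bp = 1e4,
                                step_bp = 1e4, min_snps = 2)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$freq, 40 / 60)

  # below min_snps the window is missing
  tr2 <- donor_frequency_windows(snps, counts, window_bp = 1e4,
                                 step_bp = 1e4, min_snps = 3)
  expect_true(is.na(tr2$freq))

  # saturated and empty pools
  sat <- counts; sat$donor_reads <- sat$depth
  expect_equal(donor_frequency_windows(snps, sat, 1e4, 1e4, 1)$freq, 1)
  zero <- counts; zero$donor_reads <- 0L
  expect_equal(donor_frequency_windows(snps, zero, 1e4, 1e4, 1)$freq, 0)

  # SNP input order is irrelevant
  shuf <- counts[2:1, ]
  expect_equal(donor_frequency_windows(snps, shuf, 1e4, 1e4, 1)$freq,
               donor_frequency_windows(snps, counts, 1e4, 1e4, 1)$freq)

  expect_error(donor_frequency_windows(snps, counts[1, , drop = FALSE]),
               "cover")
})

track_from_freqs <- function(freqs, window = 100) {
  structure(data.frame(chrom = "chr1",
                       start = (seq_along(freqs) - 1) * window,
                       end = seq_along(freqs) * window,
                       n_snps = 10, depth = 100, donor_reads = 0,
                       freq = freqs),
            class = c("frequency_track", "data.frame"))
}

test_that("region segmentation merges runs across small gaps", {
  expect_equal(nrow(detect_regions(track_from_freqs(rep(0, 8)))), 0)

  all1 <- detect_regions(track_from_freqs(rep(1, 8)), min_windows = 3)
  expect_equal(nrow(all1), 1)
  expect_equal(c(all1$start, all1$end), c(0, 800))

  # one below-threshold window inside the run is bridged
  tr <- track_from_freqs(c(0, 0, 0.6, 0.7, 0.1, 0.8, 0, 0))
  reg <- detect_regions(tr, threshold = 0.5, min_windows = 2,
                        max_gap_windows = 1)
  expect_equal(nrow(reg), 1)
  expect_equal(c(reg$start, reg$end), c(200, 600))
  expect_equal(reg$n_windows, 3)

  # a 2-window gap splits the run at max_gap 1
  tr2 <- track_from_freqs(c(0.6, 0.7, 0, 0, 0.8, 0.9, 0.6))
  reg2 <- detect_regions(tr2, threshold = 0.5, min_windows = 2,
                         max_gap_windows = 1)
  expect_equal(nrow(reg2), 2)
  expect_equal(reg2$start, c(0, 400))

  # short runs below min_windows are dropped
  expect_equal(nrow(detect_regions(track_from_freqs(c(0, 0.9, 0.9, 0)),
                                   min_windows = 3)), 0)
})

test_that("region segmentation is idempotent on its own output", {
  tr <- track_from_freqs(c(0, 0.4, 0.6, 0.7, 0.1, 0.8, 0.9, 0, 0.3))
  reg <- detect_regions(tr, threshold = 0.5, min_windows = 2,
                        max_gap_windows = 1)
  # rebuild a track carrying each region's mean over its windows
  freqs <- rep(0, 9)
  for (i in seq_len(nrow(reg))) {
    w <- (reg$start[i] / 100 + 1):(reg$end[i] / 100)
    freqs[w] <- reg$mean_freq[i]
  }
  reg2 <- detect_regions(track_from_freqs(freqs), threshold = 0.5,
                         min_windows = 2, max_gap_windows = 1)
  expect_equal(reg2$start, reg$start)
  expect_equal(reg2$end, reg$end)
})

test_that("regions are annotated by >= 1 bp overlap under half-open bounds", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=geneA",
    "chr1\tsrc\tgene\t2501\t3000\t.\t-\t.\tID=geneB",
    "chr1\tsrc\tgene\t9001\t9500\t.\t+\t.\tID=geneC"), gff)
  genes <- read_gene_annotation(gff)
  expect_length(genes, 3)

  regions <- data.frame(chrom = "chr1", start = 1500, end = 2600,
                        n_windows = 3, mean_freq = 0.6)
  ann <- annotate_regions(regions, genes)
  expect_equal(ann$n_genes, 2)
  expect_setequal(strsplit(ann$genes, ",")[[1]], c("geneA", "geneB"))

  # region [0, 1000) abuts geneA (1-based 1001..2000): no overlap
  abut <- data.frame(chrom = "chr1", start = 0, end = 1000)
  expect_equal(annotate_regions(abut, genes)$n_genes, 0)
  # but [0, 1001) overlaps its first base
  touch <- data.frame(chrom = "chr1", start = 0, end = 1001)
  expect_equal(annotate_regions(touch, genes)$n_genes, 1)

  expect_warning(
    ann2 <- annotate_regions(data.frame(chrom = "chrZ", start = 0,
                                        end = 100), genes),
    "absent")
  expect_equal(ann2$n_genes, 0)

  empty <- detect_regions(track_from_freqs(rep(0, 4)))
  expect_equal(nrow(annotate_regions(empty, genes)), 0)
})

test_that("a pure recipient pool produces no regions at the default threshold", {
  map <- chromosome_map(data.frame(
    name = c("chr1", "mito"), length_bp = c(2e7, 19517),
    morgans = c(1, 0), class = c("autosome", "mitochondrial")))
  pop <- recipient_population(30, map)
  snps <- evenly_spaced_snps(map, 1000)
  pc <- pool_counts(pop, snps, mean_depth = 50, map = map, seed = 8)
  tr <- donor_frequency_windows(snps, pc, chrom_lengths = c(chr1 = 2e7))
  expect_equal(nrow(detect_regions(tr)), 0)
})
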