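# Backcross forward simulator: F1s, meiosis, generations, selection,
# pooled readout.

one_chrom_map <- function(length_bp = 1e6, morgans = 1) {
  chromosome_map(data.frame(
    name = c("chr1", "mito"),
    length_bp = c(length_bp, 19517),
    morgans = c(morgans, 0),
    class = c("autosome", "mitochondrial")))
}

test_that("F1s are uniformly heterozygous with donor mitochondria", {
  map <- default_chromosome_map()
  pop <- make_f1(5, map)
  for (ind in pop) {
    expect_equal(donor_fraction(ind, map, "autosome"), 0.5)
    expect_equal(donor_fraction(ind, map, "X"), 0.5)
    expect_equal(ind$mito, 1L)
    # X: one donor and one recipient haplotype
    x <- ind$nuc$chrX
    expect_equal(sort(vapply(x, function(h) h$origin[1], integer(1))),
                 c(0L, 1L))
  }
})

test_that("meiosis respects genetic length zero, homozygosity and female-only recombination", {
  map0 <- one_chrom_map(morgans = 0)
  f1 <- make_f1(1, map0)[[1]]
  withr::with_seed(1, {
    g <- meiosis(f1, map0)
    # no crossovers: the gamete is an unmodified parental haplotype
    expect_true(identical(g$chr1, f1$nuc$chr1[[1]]) ||
                  identical(g$chr1, f1$nuc$chr1[[2]]))
  })

  map1 <- one_chrom_map(morgans = 2)
  hom <- f1
  hom$nuc$chr1[[2]] <- hom$nuc$chr1[[1]]
  withr::with_seed(2, {
    g <- meiosis(hom, map1)
    expect_identical(g$chr1$origin, hom$nuc$chr1[[1]]$origin)
    expect_identical(g$chr1$end, hom$nuc$chr1[[1]]$end)
  })

  male <- f1
  male$sex <- "M"
  expect_error(meiosis(male, map1), "male parent")
})

test_that("crossover counts follow the Poisson law on a 1-Morgan chromosome", {
  map <- one_chrom_map(morgans = 1)
  f1 <- make_f1(1, map)[[1]]
  withr::with_seed(31, {
    # in a fully heterozygous parent every crossover leaves an origin
    # switch, so switches count crossovers exactly
    switches <- vapply(1:10000, function(i) {
      length(meiosis(f1, map)$chr1$origin) - 1L
    }, integer(1))
  })
  se <- 1 / sqrt(10000)
  expect_lt(abs(mean(switches) - 1), 3 * se)
})

test_that("tracts tile every chromosome after every generation", {
  map <- default_chromosome_map()
  loci <- data.frame(chrom = "chr2", pos = 6e6)
  sch <- introgression_scheme(g = 3, selection = TRUE, loci = loci,
                              pop_size = 30, sib_generations = 2)
  run <- run_introgression(sch, map, seed = 17)
  for (ind in run$population) {
    for (chrom in names(ind$nuc)) {
      for (h in ind$nuc[[chrom]])
        expect_true(macrospace:::tracts_valid(h, map[chrom, "length_bp"]))
    }
    expect_equal(ind$mito, 1L)
    if (ind$sex == "M") expect_length(ind$nuc$chrX, 1)
    else expect_length(ind$nuc$chrX, 2)
  }
  expect_true(all(run$trace$mito_donor == 1))
})

test_that("Mendelian transmission and selection guarantees at a single locus", {
  map <- one_chrom_map(1e6, morgans = 0.5)
  locus <- data.frame(chrom = "chr1", pos = 5e5)
  f1 <- make_f1(50, map)

  # selection off: donor allele probability 1/2 at any locus
  sch_off <- introgression_scheme(g = 1, selection = FALSE, pop_size = 400,
                                  sib_generations = 0)
  withr::with_seed(5, {
    off <- backcross_generation(f1, sch_off, map)
  })
  carry <- vapply(off, function(i) {
    any(vapply(i$nuc$chr1, function(h) origin_at(h, 5e5) == 1L,
               logical(1)))
  }, logical(1))
  se <- sqrt(0.25 / 400)
  expect_lt(abs(mean(carry) - 0.5), 3 * se)

  # selection on: every survivor carries the donor allele
  sch_on <- introgression_scheme(g = 1, selection = TRUE, loci = locus,
                                 pop_size = 100, sib_generations = 0)
  withr::with_seed(6, {
    sel <- backcross_generation(f1, sch_on, map)
  })
  carry <- vapply(sel, function(i) {
    any(vapply(i$nuc$chr1, function(h) origin_at(h, 5e5) == 1L,
               logical(1)))
  }, logical(1))
  expect_true(all(carry))
})

test_that("selection at a lost locus drives the line extinct with a generation index", {
  map <- one_chrom_map(1e6, morgans = 0.5)
  mothers <- recipient_population(3, map)
  for (m in mothers) expect_equal(m$sex, "F")
  sch <- introgression_scheme(g = 1, selection = TRUE,
                              loci = data.frame(chrom = "chr1", pos = 100),
                              pop_size = 2, sib_generations = 0)
  expect_error(
    withr::with_seed(9, backcross_generation(mothers, sch, map,
                                             generation = 4)),
    "extinct.*generation 4")
})

test_that("donor fraction halves per backcross generation (small-scale check)", {
  map <- default_chromosome_map()
  sch <- introgression_scheme(g = 3, selection = FALSE, pop_size = 60,
                              sib_generations = 0)
  runs <- lapply(1:25, function(i) run_introgression(sch, map, seed = 200 + i))
  finals <- vapply(runs, function(r) {
    r$trace$donor_autosome[r$trace$generation == 3]
  }, numeric(1))
  se <- stats::sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 2^-4), 3 * se)
  # population X fraction follows its own recursion: halving in females,
  # one-generation lag in males
  fx <- vapply(runs, function(r) {
    r$trace$donor_x[r$trace$generation == 3]
  }, numeric(1))
  rec <- donor_fraction_recursion(3)
  se_x <- stats::sd(fx) / sqrt(length(fx))
  expect_lt(abs(mean(fx) - rec$x_population[rec$generation == 3]),
            3 * se_x)
})

test_that("g = 0 returns an F1 population at donor fraction one half", {
  map <- default_chromosome_map()
  sch <- introgression_scheme(g = 0, selection = FALSE, pop_size = 10,
                              sib_generations = 0)
  run <- run_introgression(sch, map, seed = 1)
  expect_equal(nrow(run$trace), 1)
  expect_equal(run$trace$donor_autosome, 0.5)
})

test_that("pooled counts reflect pool allele frequencies through Poisson-binomial sampling", {
  map <- one_chrom_map(1e6, morgans = 0.5)

  # pure recipient pool: zero donor reads everywhere
  pop0 <- recipient_population(40, map)
  snps <- evenly_spaced_snps(map, 1000)
  pc0 <- pool_counts(pop0, snps, mean_depth = 30, map = map, seed = 3)
  expect_true(all(pc0$donor_reads == 0))
  expect_true(all(pc0$pool_donor_alleles == 0))

  # F1 pool: every female heterozygous, true frequency 1/2 at all SNPs
  pop1 <- make_f1(30, map)
  pc1 <- pool_counts(pop1, snps, mean_depth = 50, map = map, seed = 4)
  expect_true(all(pc1$pool_donor_alleles / pc1$pool_alleles == 0.5))
  f_hat <- sum(pc1$donor_reads) / sum(pc1$depth)
  se <- sqrt(0.25 / sum(pc1$depth))
  expect_lt(abs(f_hat - 0.5), 3 * se)

  expect_error(pool_counts(list(), snps, map = map), "empty population")
})

test_that("donor tract length at a locus measures linked drag", {
  map <- one_chrom_map(1e7, morgans = 1)
  locus <- data.frame(chrom = "chr1", pos = 5e6)
  sch <- introgression_scheme(g = 4, selection = TRUE, loci = locus,
                              pop_size = 50, sib_generations = 0)
  run <- run_introgression(sch, map, seed = 77)
  d <- donor_tract_length_at(run$population, "chr1", 5e6)
  expect_equal(d$carrier_fraction, 1)
  expect_true(d$mean_length_bp > 0 && d$mean_length_bp <= 1e7)
})
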