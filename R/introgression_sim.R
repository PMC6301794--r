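# Forward simulator of phenotype-based backcross introgression:
# F1 hybridisation (donor mothers x recipient fathers), repeated
# backcrossing of hybrid females to recipient males under diet selection
# at tolerance loci, sib-mating, and a pooled-sequencing readout.

#' Chromosome map for the introgression simulator
#'
#' @param chrom data.frame with columns `name`, `length_bp` (physical
#'   length), `morgans` (genetic length; expected crossovers per
#'   meiosis), `class` (`"autosome"`, `"X"` or `"mitochondrial"`).
#' @return an object of class `chromosome_map`.
#' @details Exactly one mitochondrial element is required and its genetic
#'   length must be 0. Coordinates are 0-based half-open internally.
#' @export
chromosome_map <- function(chrom) {
  chrom <- as.data.frame(chrom)
  req <- c("name", "length_bp", "morgans", "class")
  if (!all(req %in% names(chrom)))
    stopf("chromosome map needs columns: %s", paste(req, collapse = ", "))
  if (any(chrom$length_bp <= 0)) stopf("chromosome lengths must be > 0")
  if (any(chrom$morgans < 0)) stopf("genetic lengths must be >= 0")
  if (!all(chrom$class %in% c("autosome", "X", "mitochondrial")))
    stopf("unknown inheritance class")
  mito <- chrom$class == "mitochondrial"
  if (sum(mito) != 1) stopf("exactly one mitochondrial element required")
  if (chrom$morgans[mito] != 0)
    stopf("mitochondrial genetic length must be 0")
  if (anyDuplicated(chrom$name)) stopf("duplicated chromosome names")
  rownames(chrom) <- chrom$name
  structure(chrom, class = c("chromosome_map", "data.frame"))
}

#' Default Drosophila-like chromosome map
#'
#' Two major autosomes, the X, and the mitochondrion. Genetic lengths
#' default to 1.1 Morgans for each major autosome and 0.7 for the X
#' (crossovers Poisson, no interference; females only - Drosophila males
#' are achiasmatic). Chromosome 4 and heterochromatin are ignored.
#'
#' @return a [chromosome_map()].
#' @export
default_chromosome_map <- function() {
  chromosome_map(data.frame(
    name = c("chr2", "chr3", "chrX", "mito"),
    length_bp = c(48e6, 52e6, 23e6, 19517),
    morgans = c(1.1, 1.1, 0.7, 0),
    class = c("autosome", "autosome", "X", "mitochondrial")))
}

#' Reduced single-arm map for mapping experiments
#'
#' One 25-Mb autosome arm (2R-like, 0.55 Morgans) plus the mitochondrion;
#' keeps replicated end-to-end mapping simulations cheap while preserving
#' the physical and genetic scale of the arm carrying the sugar-tolerance
#' introgression.
#'
#' @return a [chromosome_map()].
#' @export
arm_2R_map <- function() {
  chromosome_map(data.frame(
    name = c("chr2R", "mito"),
    length_bp = c(25e6, 19517),
    morgans = c(0.55, 0),
    class = c("autosome", "mitochondrial")))
}

map_nuclear <- function(map) map$name[map$class != "mitochondrial"]
map_autosomes <- function(map) map$name[map$class == "autosome"]
map_x <- function(map) map$name[map$class == "X"]

#' Introgression crossing scheme
#'
#' Parameters of the phenotype-based introgression: the number of
#' backcross generations (10 in the original design), whether diet
#' selection is applied, the tolerance loci required for survival on the
#' selective diet, the selection model, census size per generation, and
#' the number of terminal sib-mating generations (3 in the original
#' design).
#'
#' @param g number of backcross generations (>= 0).
#' @param selection apply selection at the tolerance loci.
#' @param loci data.frame with columns `chrom`, `pos` (0-based bp) of
#'   tolerance loci; may be empty when `selection = FALSE`.
#' @param model `"all_required"` (default: survival requires at least one
#'   donor allele at every locus - a dominant tolerance allele) or
#'   `"independent"` (an offspring lacking the donor allele at locus i
#'   survives with probability `surv_prob[i]`; carriers always survive).
#' @param surv_prob per-locus escape survival probabilities for the
#'   independent model.
#' @param pop_size offspring census per generation (default 200; the
#'   original crosses kept over 100 backcross females per generation).
#' @param sib_generations terminal sib-mating generations (default 3).
#' @return an object of class `introgression_scheme`.
#' @export
introgression_scheme <- function(g = 10,
                                 selection = TRUE,
                                 loci = data.frame(chrom = character(),
                                                   pos = numeric()),
                                 model = c("all_required", "independent"),
                                 surv_prob = NULL,
                                 pop_size = 200,
                                 sib_generations = 3) {
  model <- match.arg(model)
  if (!is_count(g)) stopf("g must be a non-negative integer")
  if (!is_count(sib_generations)) stopf("sib_generations must be >= 0")
  if (!is_count(pop_size) || pop_size < 1) stopf("pop_size must be >= 1")
  loci <- as.data.frame(loci)
  if (selection && nrow(loci) == 0)
    stopf("selection requires at least one tolerance locus")
  if (model == "independent") {
    if (is.null(surv_prob)) surv_prob <- rep(0, nrow(loci))
    if (length(surv_prob) != nrow(loci) ||
        any(surv_prob < 0 | surv_prob > 1))
      stopf("surv_prob must give one probability in [0,1] per locus")
  }
  structure(list(g = g, selection = selection, loci = loci,
                 model = model, surv_prob = surv_prob,
                 pop_size = pop_size,
                 sib_generations = sib_generations),
            class = "introgression_scheme")
}

check_loci <- function(loci, map) {
  for (i in seq_len(nrow(loci))) {
    chrom <- loci$chrom[i]
    if (!chrom %in% rownames(map)) stopf("locus on unknown chromosome %s", chrom)
    if (loci$pos[i] < 0 || loci$pos[i] >= map[chrom, "length_bp"])
      stopf("locus outside chromosome bounds")
  }
  invisible(TRUE)
}

# ---- individuals -----------------------------------------------------

new_individual <- function(sex, nuc, mito) {
  list(sex = sex, nuc = nuc, mito = mito)
}

#' Make an F1 hybrid population
#'
#' Crosses donor-species mothers to recipient-species fathers: every F1
#' is heterozygous donor/recipient along every autosome, F1 females carry
#' one donor and one recipient X, and all F1 mitochondria are of donor
#' (maternal) origin. Only females are produced, matching their exclusive
#' use in the backcross scheme (F1 males from this cross are not used).
#'
#' @param n number of F1 females.
#' @param map a [chromosome_map()].
#' @return list of individuals (the population).
#' @export
make_f1 <- function(n, map = default_chromosome_map()) {
  if (!is_count(n) || n < 1) stopf("n must be > 0")
  template <- {
    nuc <- list()
    for (chrom in map_autosomes(map)) {
      L <- map[chrom, "length_bp"]
      nuc[[chrom]] <- list(tracts_uniform(L, "donor"),
                           tracts_uniform(L, "recipient"))
    }
    for (chrom in map_x(map)) {
      L <- map[chrom, "length_bp"]
      nuc[[chrom]] <- list(tracts_uniform(L, "donor"),
                           tracts_uniform(L, "recipient"))
    }
    new_individual("F", nuc, DONOR)
  }
  rep(list(template), n)
}

#' One female meiosis
#'
#' Draws a gamete from a female: per chromosome the crossover count is
#' Poisson in the genetic length (no interference), breakpoints are
#' uniform on the physical length, and the gamete is spliced from the two
#' parental haplotypes. Males are rejected: Drosophila males are
#' achiasmatic, and the crossing scheme only ever recombines through
#' hybrid females.
#'
#' @param female an individual of sex `"F"`.
#' @param map a [chromosome_map()].
#' @return named list of one `ancestry_tracts` haplotype per nuclear
#'   chromosome.
#' @export
meiosis <- function(female, map = default_chromosome_map()) {
  if (female$sex != "F")
    stopf("male parent passed where recombination requested")
  gamete <- list()
  for (chrom in map_nuclear(map)) {
    haps <- female$nuc[[chrom]]
    L <- map[chrom, "length_bp"]
    k <- stats::rpois(1L, map[chrom, "morgans"])
    bps <- if (k > 0) stats::runif(k, 0, L) else numeric(0)
    first <- sample.int(2L, 1L)
    gamete[[chrom]] <- tracts_recombine(haps[[1]], haps[[2]], bps, first)
  }
  gamete
}

# Male gamete: no recombination; a random whole haplotype per autosome.
# The father's single X goes to daughters only.
male_gamete <- function(male, map, daughter) {
  gamete <- list()
  for (chrom in map_autosomes(map)) {
    haps <- male$nuc[[chrom]]
    gamete[[chrom]] <- haps[[sample.int(length(haps), 1L)]]
  }
  if (daughter)
    for (chrom in map_x(map)) gamete[[chrom]] <- male$nuc[[chrom]][[1]]
  gamete
}

# Offspring survival under the scheme's selection model.
offspring_survives <- function(ind, scheme, map) {
  if (!scheme$selection) return(TRUE)
  for (i in seq_len(nrow(scheme$loci))) {
    chrom <- scheme$loci$chrom[i]
    pos <- scheme$loci$pos[i]
    if (!chrom %in% names(ind$nuc)) {
      carries <- FALSE
    } else {
      carries <- any(vapply(ind$nuc[[chrom]],
                            function(h) origin_at(h, pos) == DONOR,
                            logical(1)))
    }
    if (!carries) {
      if (scheme$model == "all_required") return(FALSE)
      if (stats::runif(1) >= scheme$surv_prob[i]) return(FALSE)
    }
  }
  TRUE
}

# ---- generations -----------------------------------------------------

#' One backcross generation
#'
#' Crosses the females of the current population to pure recipient males:
#' each offspring receives one recombinant maternal gamete and one pure
#' recipient paternal gamete (daughters additionally get the recipient
#' paternal X); offspring sex is random; mitochondria remain donor
#' origin. When selection is on, offspring survive according to the
#' scheme's selection model; failure to assemble the census within the
#' attempt budget signals population extinction.
#'
#' @param population list of individuals; its females are the mothers.
#' @param scheme an [introgression_scheme()].
#' @param map a [chromosome_map()].
#' @param generation generation index, used in the extinction error.
#' @return offspring population of `scheme$pop_size` individuals.
#' @export
backcross_generation <- function(population, scheme,
                                 map = default_chromosome_map(),
                                 generation = NA) {
  mothers <- Filter(function(i) i$sex == "F", population)
  if (length(mothers) == 0) stopf("no females available to backcross")
  check_loci(scheme$loci, map)
  offspring <- vector("list", scheme$pop_size)
  n_done <- 0L
  attempts <- 0L
  max_attempts <- scheme$pop_size * 1000L
  while (n_done < scheme$pop_size) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stopf("population extinct under selection at generation %s",
            generation)
    mother <- mothers[[sample.int(length(mothers), 1L)]]
    gam <- meiosis(mother, map)
    sex <- if (stats::runif(1) < 0.5) "F" else "M"
    nuc <- list()
    for (chrom in map_autosomes(map)) {
      L <- map[chrom, "length_bp"]
      nuc[[chrom]] <- list(gam[[chrom]], tracts_uniform(L, "recipient"))
    }
    for (chrom in map_x(map)) {
      L <- map[chrom, "length_bp"]
      nuc[[chrom]] <- if (sex == "F")
        list(gam[[chrom]], tracts_uniform(L, "recipient"))
      else list(gam[[chrom]])
    }
    child <- new_individual(sex, nuc, mother$mito)
    if (!offspring_survives(child, scheme, map)) next
    n_done <- n_done + 1L
    offspring[[n_done]] <- child
  }
  offspring
}

# One sib-mating generation: random brother-sister pairs within the line.
sib_generation <- function(population, scheme,
                           map = default_chromosome_map(),
                           generation = NA) {
  mothers <- Filter(function(i) i$sex == "F", population)
  fathers <- Filter(function(i) i$sex == "M", population)
  if (length(mothers) == 0 || length(fathers) == 0)
    stopf("sib mating requires both sexes in the population")
  offspring <- vector("list", scheme$pop_size)
  n_done <- 0L
  attempts <- 0L
  max_attempts <- scheme$pop_size * 1000L
  while (n_done < scheme$pop_size) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stopf("population extinct under selection at generation %s",
            generation)
    mother <- mothers[[sample.int(length(mothers), 1L)]]
    father <- fathers[[sample.int(length(fathers), 1L)]]
    mgam <- meiosis(mother, map)
    sex <- if (stats::runif(1) < 0.5) "F" else "M"
    pgam <- male_gamete(father, map, daughter = sex == "F")
    nuc <- list()
    for (chrom in map_autosomes(map))
      nuc[[chrom]] <- list(mgam[[chrom]], pgam[[chrom]])
    for (chrom in map_x(map)) {
      nuc[[chrom]] <- if (sex == "F") list(mgam[[chrom]], pgam[[chrom]])
      else list(mgam[[chrom]])
    }
    child <- new_individual(sex, nuc, mother$mito)
    if (!offspring_survives(child, scheme, map)) next
    n_done <- n_done + 1L
    offspring[[n_done]] <- child
  }
  offspring
}

# ---- whole runs and summaries ----------------------------------------

#' Autosomal (or X) donor-genome fraction of an individual
#'
#' Length-weighted fraction of the genome of donor origin, averaged over
#' haplotypes of the chromosomes of the requested class.
#'
#' @param ind an individual.
#' @param map a [chromosome_map()].
#' @param class `"autosome"` or `"X"`.
#' @return fraction in `[0, 1]`.
#' @export
donor_fraction <- function(ind, map = default_chromosome_map(),
                           class = c("autosome", "X")) {
  class <- match.arg(class)
  chroms <- if (class == "autosome") map_autosomes(map) else map_x(map)
  tot_len <- 0; donor_len <- 0
  for (chrom in chroms) {
    L <- map[chrom, "length_bp"]
    for (h in ind$nuc[[chrom]]) {
      tot_len <- tot_len + L
      donor_len <- donor_len + tracts_donor_fraction(h) * L
    }
  }
  if (tot_len == 0) return(NA_real_)
  donor_len / tot_len
}

population_donor_fraction <- function(population, map, class = "autosome") {
  mean(vapply(population, donor_fraction, numeric(1), map = map,
              class = class))
}

#' Run the full phenotype-based introgression
#'
#' Executes F1 hybridisation, `g` backcross generations to recipient
#' males (with selection if configured), and terminal sib-mating, and
#' records the mean donor-genome fraction per generation. Deterministic
#' under a fixed seed.
#'
#' @param scheme an [introgression_scheme()].
#' @param map a [chromosome_map()].
#' @param seed integer seed.
#' @return list with `population` (final), `trace` (data.frame with
#'   columns `generation`, `phase`, `donor_autosome`, `donor_x`,
#'   `mito_donor` - the fraction of individuals with donor mitochondria,
#'   1 throughout by construction), and the `scheme`.
#' @export
run_introgression <- function(scheme, map = default_chromosome_map(),
                              seed = NULL) {
  stopifnot(inherits(scheme, "introgression_scheme"))
  check_loci(scheme$loci, map)
  with_seed_if(seed, {
    pop <- make_f1(scheme$pop_size, map)
    trace <- list(trace_row(pop, map, 0L, "f1"))
    if (scheme$g > 0) for (gen in seq_len(scheme$g)) {
      pop <- backcross_generation(pop, scheme, map, generation = gen)
      trace[[length(trace) + 1L]] <- trace_row(pop, map, gen, "backcross")
    }
    if (scheme$sib_generations > 0)
      for (sg in seq_len(scheme$sib_generations)) {
        pop <- sib_generation(pop, scheme, map,
                              generation = scheme$g + sg)
        trace[[length(trace) + 1L]] <-
          trace_row(pop, map, scheme$g + sg, "sib")
      }
    list(population = pop, trace = do.call(rbind, trace),
         scheme = scheme)
  })
}

trace_row <- function(pop, map, generation, phase) {
  has_x <- length(map_x(map)) > 0
  data.frame(
    generation = generation, phase = phase,
    donor_autosome = population_donor_fraction(pop, map, "autosome"),
    donor_x = if (has_x) population_donor_fraction(pop, map, "X")
    else NA_real_,
    mito_donor = mean(vapply(pop, function(i) i$mito == DONOR,
                             logical(1))))
}

#' Analytic donor-fraction recursion without selection
#'
#' Expected donor fraction by generation under pure backcrossing to
#' recipient males with no selection. Each backcross halves the expected
#' maternal contribution: autosomes start at 1/2 in the F1 and follow
#' `f[k+1] = f[k]/2`. The X has its own recursion: a female's X pair is
#' a recombinant maternal gamete plus a recipient paternal X, so the
#' female X follows the same halving (`x_f[k+1] = x_f[k]/2`), while a
#' male carries only the maternal gamete, unhalved
#' (`x_m[k+1] = x_f[k]`); a sex-balanced population averages the two.
#'
#' @param g number of backcross generations.
#' @return data.frame with columns `generation` (0..g), `autosome`,
#'   `x_female`, `x_male` (NA at generation 0: the F1s used are female),
#'   and `x_population` (sex-balanced mean).
#' @export
donor_fraction_recursion <- function(g) {
  f_auto <- 0.5 * 0.5^(0:g)
  x_f <- 0.5 * 0.5^(0:g)
  x_m <- c(NA_real_, 0.5^(1:g))  # = x_f of the previous generation
  data.frame(generation = 0:g, autosome = f_auto,
             x_female = x_f, x_male = x_m,
             x_population = ifelse(is.na(x_m), x_f, (x_f + x_m) / 2))
}

#' Donor tract length at a locus
#'
#' Mean physical length of the donor ancestry tract containing a locus,
#' over all haplotypes in the population that are donor at the locus.
#' Under selection at the locus this measures linked drag: the retained
#' donor segment shortens as backcross generations accumulate
#' recombination events near the locus.
#'
#' @param population list of individuals.
#' @param chrom chromosome name.
#' @param pos 0-based position.
#' @return list with `mean_length_bp`, `n_haplotypes` (donor at the
#'   locus), and `carrier_fraction` (individuals with >= 1 donor allele
#'   at the locus).
#' @export
donor_tract_length_at <- function(population, chrom, pos) {
  lens <- numeric(0)
  carriers <- 0L
  for (ind in population) {
    hit <- FALSE
    for (h in ind$nuc[[chrom]]) {
      if (origin_at(h, pos) == DONOR) {
        b <- tract_bounds_at(h, pos)
        lens <- c(lens, b[["end"]] - b[["start"]])
        hit <- TRUE
      }
    }
    if (hit) carriers <- carriers + 1L
  }
  list(mean_length_bp = if (length(lens)) mean(lens) else NA_real_,
       n_haplotypes = length(lens),
       carrier_fraction = carriers / length(population))
}

#' Write donor ancestry tracts as BED
#'
#' One record per donor tract (0-based half-open), named
#' `ind<i>_hap<j>`.
#'
#' @param population list of individuals.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ancestry_bed <- function(population, path) {
  rows <- list()
  for (i in seq_along(population)) {
    ind <- population[[i]]
    for (chrom in names(ind$nuc)) {
      for (j in seq_along(ind$nuc[[chrom]])) {
        tr <- ind$nuc[[chrom]][[j]]
        starts <- tracts_starts(tr)
        donor <- tr$origin == DONOR
        if (!any(donor)) next
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom,
          start = format(starts[donor], scientific = FALSE, trim = TRUE),
          end = format(tr$end[donor], scientific = FALSE, trim = TRUE),
          name = sprintf("ind%d_hap%d", i, j))
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = character(),
               end = character(), name = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pooled-sequencing readout of a population
#'
#' Emulates pooled resequencing of females from the line: a pool of
#' `n_pooled_females` females is sampled, and at every species-diagnostic
#' SNP the sequencing depth is Poisson around `mean_depth` with the
#' donor-allele read count Binomial in the pool's true donor allele
#' frequency.
#'
#' @param population list of individuals (females are sampled from it).
#' @param snps a [diagnostic_snp_table()] (1-based `pos`).
#' @param mean_depth mean sequencing depth per SNP.
#' @param n_pooled_females females pooled (default 30); capped at the
#'   number available.
#' @param map a [chromosome_map()] for bounds checking.
#' @param seed integer seed.
#' @return a `pool_counts` data.frame: `chrom`, `pos` (1-based),
#'   `depth`, `donor_reads`, plus the sequencing-noise-free truth for the
#'   sampled pool: `pool_alleles` (haplotypes in the pool) and
#'   `pool_donor_alleles` (of donor origin at the SNP).
#' @export
pool_counts <- function(population, snps, mean_depth = 50,
                        n_pooled_females = 30,
                        map = default_chromosome_map(), seed = NULL) {
  if (length(population) == 0) stopf("empty population")
  stopifnot(inherits(snps, "diagnostic_snp_table"))
  for (chrom in unique(snps$chrom)) {
    if (!chrom %in% rownames(map)) stopf("SNP on unknown chromosome %s", chrom)
    if (any(snps$pos[snps$chrom == chrom] > map[chrom, "length_bp"]))
      stopf("SNP position outside chromosome bounds")
  }
  females <- Filter(function(i) i$sex == "F", population)
  if (length(females) == 0) stopf("no females to pool")
  with_seed_if(seed, {
    n_pool <- min(n_pooled_females, length(females))
    pool <- females[sample.int(length(females), n_pool)]
    donor_alleles <- integer(nrow(snps))
    total_alleles <- integer(nrow(snps))
    for (chrom in unique(snps$chrom)) {
      sel <- which(snps$chrom == chrom)
      pos0 <- snps$pos[sel] - 1  # internal 0-based
      for (ind in pool) {
        for (h in ind$nuc[[chrom]]) {
          donor_alleles[sel] <- donor_alleles[sel] +
            (origin_at(h, pos0) == DONOR)
          total_alleles[sel] <- total_alleles[sel] + 1L
        }
      }
    }
    freq <- ifelse(total_alleles > 0, donor_alleles / total_alleles, 0)
    depth <- stats::rpois(nrow(snps), mean_depth)
    donor_reads <- stats::rbinom(nrow(snps), depth, freq)
    structure(data.frame(chrom = snps$chrom, pos = snps$pos,
                         depth = depth, donor_reads = donor_reads,
                         pool_alleles = total_alleles,
                         pool_donor_alleles = donor_alleles),
              class = c("pool_counts", "data.frame"))
  })
}

#' Read / write pooled counts as tab-separated text
#'
#' @param x a `pool_counts` data.frame.
#' @param path file path.
#' @return `read_pool_counts` returns a `pool_counts` data.frame;
#'   `write_pool_counts` returns `path` invisibly.
#' @export
write_pool_counts <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool_counts
#' @export
read_pool_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (any(df$donor_reads < 0) || any(df$donor_reads > df$depth))
    stopf("donor_reads must lie in [0, depth]")
  structure(df, class = c("pool_counts", "data.frame"))
}
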