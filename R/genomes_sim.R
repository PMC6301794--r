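#' Specification of a pair of diverged parental genomes
#'
#' Describes the two parental species' genomes for the synthetic-data
#' generator: chromosome sizes, the genome-wide density of fixed
#' interspecies differences, and the density of within-species
#' polymorphism (which exercises the diagnostic-SNP exclusion rule).
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param fixed_diff_density expected fixed interspecies differences per
#'   bp, in `[0, 1]`.
#' @param polymorphism_density expected within-species polymorphic sites
#'   per bp, in `[0, 1]`; default one tenth of the fixed-difference
#'   density.
#' @param n_sampled chromosomes sampled per species when tabulating
#'   allele counts (default 20).
#' @return an object of class `parental_genome_spec`.
#' @export
parental_genome_spec <- function(chrom_lengths,
                                 fixed_diff_density,
                                 polymorphism_density =
                                   fixed_diff_density / 10,
                                 n_sampled = 20) {
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == ""))
    stopf("chrom_lengths must be a named vector")
  if (any(chrom_lengths <= 0)) stopf("chromosome lengths must be > 0")
  for (d in c(fixed_diff_density, polymorphism_density))
    if (d < 0 || d > 1) stopf("densities must lie in [0, 1]")
  structure(list(chrom_lengths = chrom_lengths,
                 fixed_diff_density = fixed_diff_density,
                 polymorphism_density = polymorphism_density,
                 n_sampled = n_sampled),
            class = "parental_genome_spec")
}

#' Simulate genotype tables for two diverged parental species
#'
#' Places fixed interspecies differences and within-species polymorphic
#' sites along each chromosome (site counts Poisson in density x length,
#' positions uniform), and tabulates per-base allele counts for a sample
#' of chromosomes from each species. Fixed differences are monomorphic
#' for different bases in the two species; polymorphic sites segregate at
#' an intermediate frequency within one randomly chosen species and are
#' monomorphic in the other. The two site classes are disjoint.
#'
#' @param spec a [parental_genome_spec()].
#' @param seed integer seed.
#' @return a list with genotype tables `species_a` and `species_b`
#'   (data.frames with columns `chrom`, `pos` (1-based), `A`, `C`, `G`,
#'   `T` sampled-chromosome counts, identical site sets), suitable for
#'   [call_diagnostic_snps()].
#' @export
simulate_parental_genomes <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "parental_genome_spec"))
  bases <- c("A", "C", "G", "T")
  n <- spec$n_sampled
  with_seed_if(seed, {
    rows_a <- list(); rows_b <- list()
    for (chrom in names(spec$chrom_lengths)) {
      len <- spec$chrom_lengths[[chrom]]
      n_fixed <- stats::rpois(1L, spec$fixed_diff_density * len)
      n_poly <- stats::rpois(1L, spec$polymorphism_density * len)
      pos <- sample.int(len, min(n_fixed + n_poly, len))
      fixed_pos <- sort(pos[seq_len(min(n_fixed, length(pos)))])
      poly_pos <- sort(setdiff(pos, fixed_pos))
      n_sites <- length(fixed_pos) + length(poly_pos)
      if (n_sites == 0) next

      mk <- function(pos) {
        m <- matrix(0L, length(pos), 4, dimnames = list(NULL, bases))
        data.frame(chrom = rep(chrom, length(pos)), pos = pos, m)
      }
      ta <- mk(c(fixed_pos, poly_pos)); tb <- mk(c(fixed_pos, poly_pos))

      nf <- length(fixed_pos)
      if (nf > 0) {
        ref <- sample(4L, nf, replace = TRUE)
        alt <- 1L + (ref - 1L + sample(3L, nf, replace = TRUE)) %% 4L
        ta[cbind(seq_len(nf), 2L + ref)] <- n
        tb[cbind(seq_len(nf), 2L + alt)] <- n
      }
      np <- length(poly_pos)
      if (np > 0) {
        idx <- nf + seq_len(np)
        anc <- sample(4L, np, replace = TRUE)
        der <- 1L + (anc - 1L + sample(3L, np, replace = TRUE)) %% 4L
        in_a <- stats::runif(np) < 0.5
        # derived-allele count strictly intermediate: segregating
        k <- 1L + stats::rbinom(np, n - 2L, 0.3)
        for (j in seq_len(np)) {
          if (in_a[j]) {
            ta[idx[j], 2L + anc[j]] <- n - k[j]
            ta[idx[j], 2L + der[j]] <- k[j]
            tb[idx[j], 2L + anc[j]] <- n
          } else {
            tb[idx[j], 2L + anc[j]] <- n - k[j]
            tb[idx[j], 2L + der[j]] <- k[j]
            ta[idx[j], 2L + anc[j]] <- n
          }
        }
      }
      ord <- order(ta$pos)
      rows_a[[chrom]] <- ta[ord, , drop = FALSE]
      rows_b[[chrom]] <- tb[ord, , drop = FALSE]
    }
    empty <- data.frame(chrom = character(), pos = integer(),
                        A = integer(), C = integer(), G = integer(),
                        T = integer())
    a <- if (length(rows_a)) do.call(rbind, rows_a) else empty
    b <- if (length(rows_b)) do.call(rbind, rows_b) else empty
    rownames(a) <- rownames(b) <- NULL
    list(species_a = a, species_b = b)
  })
}

#' Read / write a genotype table as tab-separated text
#'
#' Genotype tables hold 1-based positions and per-base counts of sampled
#' chromosomes (`A`, `C`, `G`, `T` columns).
#'
#' @param x genotype table data.frame.
#' @param path file path.
#' @return `read_genotype_table` returns the data.frame;
#'   `write_genotype_table` returns `path` invisibly.
#' @export
write_genotype_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_table
#' @export
read_genotype_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Simulate an aligned pair of diverged genomic sequences
#'
#' Generates a random nucleotide sequence and a partner differing at each
#' position independently with probability `diff_rate` - an idealised
#' pair of aligned interspecies consensus sequences with a uniform
#' substitution process, used to exercise windowed divergence and
#' background correction.
#'
#' @param n_bases alignment length.
#' @param diff_rate per-position difference probability in `[0, 1]`.
#' @param seed integer seed.
#' @return list with character strings `a` and `b` of length `n_bases`.
#' @export
simulate_diverged_pair <- function(n_bases, diff_rate, seed = NULL) {
  if (diff_rate < 0 || diff_rate > 1) stopf("diff_rate must be in [0, 1]")
  bases <- c("A", "C", "G", "T")
  with_seed_if(seed, {
    a <- sample(bases, n_bases, replace = TRUE)
    b <- a
    flip <- stats::runif(n_bases) < diff_rate
    n_flip <- sum(flip)
    if (n_flip > 0) {
      shift <- sample.int(3L, n_flip, replace = TRUE)
      b[flip] <- bases[1L + (match(a[flip], bases) - 1L + shift) %% 4L]
    }
    list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
  })
}
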