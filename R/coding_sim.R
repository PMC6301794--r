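# Synthetic coding-sequence pairs with controlled substitution classes.

#' Specification of a synthetic coding-sequence pair
#'
#' Describes a pair of aligned coding sequences to be generated with
#' exact target counts of amino-acid-changing and silent nucleotide
#' substitutions, for exercising the substitution-classification and
#' Ka/Ks machinery.
#'
#' @param n_codons number of codons.
#' @param n_aa_changing target count of amino-acid-changing
#'   (nonsynonymous) substitutions.
#' @param n_silent target count of silent (synonymous) substitutions.
#' @return an object of class `coding_pair_spec`.
#' @details Each substitution occupies its own codon (one nucleotide
#'   change per substituted codon), so
#'   `n_aa_changing + n_silent <= n_codons` is required and the
#'   classification of the generated pair recovers the targets exactly.
#' @export
coding_pair_spec <- function(n_codons, n_aa_changing, n_silent) {
  if (!is_count(n_codons) || n_codons < 1)
    stopf("n_codons must be a positive integer")
  if (!is_count(n_aa_changing) || !is_count(n_silent))
    stopf("target counts must be non-negative integers")
  if (n_aa_changing + n_silent > n_codons)
    stopf("infeasible targets: %d substitutions exceed %d codons",
          n_aa_changing + n_silent, n_codons)
  structure(list(n_codons = n_codons,
                 n_aa_changing = n_aa_changing,
                 n_silent = n_silent),
            class = "coding_pair_spec")
}

# Single-nucleotide sense-codon neighbours, split by effect.
codon_neighbours <- function() {
  ct <- codon_tables()
  if (!is.null(ct$syn_nb)) return(ct)
  bases <- c("A", "C", "G", "T")
  syn_nb <- list(); nonsyn_nb <- list()
  for (codon in ct$sense) {
    syn <- character(); nonsyn <- character()
    for (j in 1:3) for (b in setdiff(bases, substr(codon, j, j))) {
      x <- codon; substr(x, j, j) <- b
      if (ct$aa[[x]] == "*") next
      if (ct$aa[[x]] == ct$aa[[codon]]) syn <- c(syn, x)
      else nonsyn <- c(nonsyn, x)
    }
    syn_nb[[codon]] <- syn
    nonsyn_nb[[codon]] <- nonsyn
  }
  ct$syn_nb <- syn_nb
  ct$nonsyn_nb <- nonsyn_nb
  ct
}

#' Simulate a coding-sequence pair with exact substitution targets
#'
#' Generates a random sense-codon sequence and derives a partner sequence
#' carrying exactly the requested numbers of amino-acid-changing and
#' silent single-nucleotide substitutions, each in its own codon and none
#' creating a stop codon. Applying [classify_substitutions()] to the
#' output recovers the targets exactly.
#'
#' @param spec a [coding_pair_spec()].
#' @param seed integer seed.
#' @param id identifier for the alignment.
#' @return a [codon_alignment()].
#' @export
simulate_coding_pair <- function(spec, seed = NULL, id = "pair") {
  stopifnot(inherits(spec, "coding_pair_spec"))
  ct <- codon_neighbours()
  syn_capable <- names(ct$syn_nb)[lengths(ct$syn_nb) > 0]
  nonsyn_capable <- names(ct$nonsyn_nb)[lengths(ct$nonsyn_nb) > 0]
  with_seed_if(seed, {
    cods <- sample(ct$sense, spec$n_codons, replace = TRUE)
    # guarantee enough codons that admit a silent single-nt change
    capable <- cods %in% syn_capable
    deficit <- spec$n_silent - sum(capable)
    if (deficit > 0) {
      swap <- sample(which(!capable), deficit)
      cods[swap] <- sample(syn_capable, deficit, replace = TRUE)
    }
    free <- seq_along(cods)
    silent_at <- integer(); aa_at <- integer()
    if (spec$n_silent > 0) {
      pool <- free[cods[free] %in% syn_capable]
      silent_at <- sample(pool, spec$n_silent)
      free <- setdiff(free, silent_at)
    }
    if (spec$n_aa_changing > 0) {
      pool <- free[cods[free] %in% nonsyn_capable]
      if (length(pool) < spec$n_aa_changing)
        stopf("infeasible targets: too few codons admit a nonsynonymous change")
      aa_at <- sample(pool, spec$n_aa_changing)
    }
    derived <- cods
    for (i in silent_at)
      derived[i] <- sample(ct$syn_nb[[cods[i]]], 1L)
    for (i in aa_at)
      derived[i] <- sample(ct$nonsyn_nb[[cods[i]]], 1L)
    codon_alignment(paste(cods, collapse = ""),
                    paste(derived, collapse = ""), id = id)
  })
}

#' Simulate a neutrally diverged coding-sequence pair
#'
#' Applies `n_subs` random single-nucleotide substitutions (uniform over
#' positions and alternative bases, multiple hits per codon allowed) to a
#' random sense-codon sequence, rejecting only changes that create a stop
#' codon. Because acceptance is indifferent to the amino-acid effect, the
#' expected Ka/Ks of the pair is 1, which calibrates the Ka/Ks estimator.
#'
#' @param n_codons number of codons.
#' @param n_subs number of substitutions to apply.
#' @param seed integer seed.
#' @param id identifier for the alignment.
#' @return a [codon_alignment()].
#' @export
simulate_neutral_pair <- function(n_codons, n_subs, seed = NULL,
                                  id = "neutral") {
  ct <- codon_tables()
  bases <- c("A", "C", "G", "T")
  with_seed_if(seed, {
    cods <- sample(ct$sense, n_codons, replace = TRUE)
    derived <- cods
    applied <- 0L
    while (applied < n_subs) {
      i <- sample.int(n_codons, 1L)
      j <- sample.int(3L, 1L)
      b <- sample(setdiff(bases, substr(derived[i], j, j)), 1L)
      x <- derived[i]; substr(x, j, j) <- b
      if (ct$aa[[x]] == "*") next
      derived[i] <- x
      applied <- applied + 1L
    }
    codon_alignment(paste(cods, collapse = ""),
                    paste(derived, collapse = ""), id = id)
  })
}

#' Read / write a codon alignment as aligned FASTA
#'
#' The FASTA file holds two records of equal length.
#'
#' @param aln a [codon_alignment()].
#' @param path file path.
#' @param frame frame offset passed to [codon_alignment()] when reading.
#' @return `write_codon_alignment_fasta` returns `path` invisibly;
#'   `read_codon_alignment_fasta` returns a [codon_alignment()].
#' @export
write_codon_alignment_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "codon_alignment"))
  set <- Biostrings::DNAStringSet(c(aln$seq_a, aln$seq_b))
  names(set) <- paste0(aln$id, c("_a", "_b"))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_codon_alignment_fasta
#' @export
read_codon_alignment_fasta <- function(path, frame = 0) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 2) stopf("expected exactly two FASTA records")
  id <- sub("_a$", "", names(set)[1])
  codon_alignment(as.character(set[[1]]), as.character(set[[2]]),
                  frame = frame, id = id)
}
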