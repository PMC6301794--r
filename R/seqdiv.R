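# Sequence-divergence analytics: sliding-window SNP density with
# background correction, Nei-Gojobori substitution classification,
# Ka/Ks with Jukes-Cantor correction, and contingency tests on
# substitution classes.

# ---- codon machinery -------------------------------------------------

# Lazily built lookup tables derived from the standard genetic code:
# codon -> amino acid, per-codon synonymous site fractions (Nei-Gojobori,
# mutations to stop codons excluded from the denominator), and a cache of
# pathway-averaged classifications for codon pairs.
.codon_env <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(.codon_env$aa)) return(.codon_env)
  gc <- Biostrings::GENETIC_CODE
  .codon_env$aa <- gc
  .codon_env$codons <- names(gc)
  .codon_env$sense <- names(gc)[gc != "*"]
  bases <- c("A", "C", "G", "T")
  syn_sites <- numeric(length(gc))
  names(syn_sites) <- names(gc)
  for (codon in names(gc)) {
    if (gc[[codon]] == "*") next
    frac <- 0
    for (j in 1:3) {
      alt <- setdiff(bases, substr(codon, j, j))
      muts <- vapply(alt, function(b) {
        x <- codon; substr(x, j, j) <- b; x
      }, character(1))
      keep <- gc[muts] != "*"
      if (any(keep))
        frac <- frac + sum(gc[muts[keep]] == gc[[codon]]) / sum(keep)
    }
    syn_sites[[codon]] <- frac
  }
  .codon_env$syn_sites <- syn_sites
  .codon_env$pair_cache <- new.env(parent = emptyenv())
  .codon_env
}

# All permutations of 1..n for n <= 3 (mutational-pathway orders).
path_orders <- function(n) {
  switch(n,
         list(1L),
         list(c(1L, 2L), c(2L, 1L)),
         list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
              c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
}

# Pathway-averaged (nonsynonymous, synonymous) counts for one ordered
# sense-codon pair. Minimal mutational pathways between the codons are
# enumerated; pathways passing through a stop codon are excluded from the
# average. If every pathway is blocked by a stop, the pair is counted by
# the minimum-nonsynonymous-change pathway and flagged.
classify_codon_pair <- function(from, to) {
  ct <- codon_tables()
  key <- paste0(from, to)
  hit <- ct$pair_cache[[key]]
  if (!is.null(hit)) return(hit)
  diffs <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  if (length(diffs) == 0) {
    res <- list(nonsyn = 0, syn = 0, flagged = FALSE)
  } else {
    to_chars <- strsplit(to, "")[[1]]
    paths <- list()       # (nonsyn, syn) per stop-free pathway
    all_paths <- list()   # per pathway ignoring stops, for the fallback
    for (ord in path_orders(length(diffs))) {
      cur <- from; ns <- 0L; s <- 0L; blocked <- FALSE
      for (p in diffs[ord]) {
        nxt <- cur
        substr(nxt, p, p) <- to_chars[p]
        if (ct$aa[[nxt]] == "*") blocked <- TRUE
        if (ct$aa[[nxt]] == ct$aa[[cur]]) s <- s + 1L else ns <- ns + 1L
        cur <- nxt
      }
      all_paths[[length(all_paths) + 1L]] <- c(ns, s)
      if (!blocked) paths[[length(paths) + 1L]] <- c(ns, s)
    }
    if (length(paths) > 0) {
      m <- do.call(rbind, paths)
      res <- list(nonsyn = mean(m[, 1]), syn = mean(m[, 2]),
                  flagged = FALSE)
    } else {
      m <- do.call(rbind, all_paths)
      best <- m[which.min(m[, 1]), ]
      res <- list(nonsyn = best[[1]], syn = best[[2]], flagged = TRUE)
    }
  }
  ct$pair_cache[[key]] <- res
  res
}

# ---- codon alignments ------------------------------------------------

#' Construct a pairwise codon alignment
#'
#' Holds two equal-length aligned coding sequences in frame. Alphabet is
#' ACGTN plus `-` for gaps; codons are read as consecutive aligned column
#' triplets after discarding `frame` leading columns. Neither ungapped
#' translation may contain an internal stop codon.
#'
#' @param seq_a,seq_b aligned nucleotide sequences (character strings or
#'   anything coercible via `as.character`), equal length.
#' @param frame number of alignment columns to skip before the first
#'   codon (0, 1 or 2).
#' @param id identifier carried into downstream tables.
#' @return an object of class `codon_alignment`.
#' @export
codon_alignment <- function(seq_a, seq_b, frame = 0, id = "pair") {
  a <- toupper(as.character(seq_a))
  b <- toupper(as.character(seq_b))
  if (nchar(a) != nchar(b)) stopf("aligned sequences differ in length")
  if (!frame %in% 0:2) stopf("frame must be 0, 1 or 2")
  if (grepl("[^ACGTN-]", a) || grepl("[^ACGTN-]", b))
    stopf("alphabet must be ACGTN-")
  aln <- structure(list(seq_a = a, seq_b = b, frame = frame, id = id),
                   class = "codon_alignment")
  ct <- codon_tables()
  for (s in list(a, b)) {
    cod <- clean_codons(gsub("-", "", s))
    tr <- ct$aa[cod[!grepl("N", cod)]]
    if (length(tr) > 1 && any(tr[-length(tr)] == "*"))
      stopf("internal stop codon in ungapped translation")
  }
  aln
}

# Split a sequence into complete codons, dropping a trailing partial one.
clean_codons <- function(s) {
  n <- nchar(s) %/% 3
  if (n == 0) return(character())
  substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

# Aligned codon columns of both sequences (after frame offset), dropping
# the trailing partial triplet.
aligned_codons <- function(aln) {
  a <- substring(aln$seq_a, aln$frame + 1)
  b <- substring(aln$seq_b, aln$frame + 1)
  list(a = clean_codons(a), b = clean_codons(b))
}

#' Classify nucleotide substitutions in a codon alignment
#'
#' Counts amino-acid-changing (nonsynonymous) and silent (synonymous)
#' nucleotide differences between two aligned coding sequences by
#' Nei-Gojobori pathway averaging: for each differing codon pair, all
#' minimal mutational pathways are enumerated, pathways passing through a
#' stop codon are excluded, and the per-pathway (nonsynonymous,
#' synonymous) step counts are averaged with equal weights. Codons
#' containing `N` or an alignment gap in either sequence are skipped.
#'
#' @param aln a [codon_alignment()].
#' @return an object of class `substitution_counts`: a list with `id`,
#'   fractional pathway-averaged counts `aa_changing` and `silent`,
#'   integers `aa_changing_int` / `silent_int` (rounded half away from
#'   zero), `n_codons_compared`, and `n_flagged` (codon pairs whose every
#'   pathway crosses a stop, counted by minimum-change assignment).
#' @export
classify_substitutions <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  cods <- aligned_codons(aln)
  skip <- grepl("[N-]", cods$a) | grepl("[N-]", cods$b)
  a <- cods$a[!skip]; b <- cods$b[!skip]
  ns <- 0; s <- 0; flagged <- 0L
  differ <- which(a != b)
  for (i in differ) {
    r <- classify_codon_pair(a[i], b[i])
    ns <- ns + r$nonsyn
    s <- s + r$syn
    if (r$flagged) flagged <- flagged + 1L
  }
  structure(list(id = aln$id,
                 aa_changing = ns,
                 silent = s,
                 aa_changing_int = as.integer(round_half_away(ns)),
                 silent_int = as.integer(round_half_away(s)),
                 n_codons_compared = length(a),
                 n_flagged = flagged),
            class = "substitution_counts")
}

#' Nonsynonymous and synonymous site counts (Nei-Gojobori)
#'
#' For each compared codon, each of its three positions contributes the
#' fraction of possible non-stop single-nucleotide changes that are
#' synonymous to the synonymous site total (remainder to nonsynonymous),
#' so N + S equals three times the number of compared codons. Sites are
#' averaged over the two sequences.
#'
#' @param aln a [codon_alignment()].
#' @return list with elements `N` (nonsynonymous sites), `S` (synonymous
#'   sites) and `n_codons`.
#' @export
ng_sites <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  ct <- codon_tables()
  cods <- aligned_codons(aln)
  skip <- grepl("[N-]", cods$a) | grepl("[N-]", cods$b)
  a <- cods$a[!skip]; b <- cods$b[!skip]
  s_sites <- (sum(ct$syn_sites[a]) + sum(ct$syn_sites[b])) / 2
  n_cod <- length(a)
  list(N = 3 * n_cod - s_sites, S = s_sites, n_codons = n_cod)
}

#' Ka/Ks from a codon alignment
#'
#' Computes per-site proportions pN and pS from Nei-Gojobori pathway
#' counts and site totals, applies the Jukes-Cantor multiple-hit
#' correction \eqn{K = -\frac{3}{4}\log(1 - \frac{4p}{3})}, and reports
#' the Ka/Ks ratio. The ratio is flagged undefined when Ks = 0; the
#' correction is flagged undefined when a proportion reaches 3/4.
#'
#' @param aln a [codon_alignment()].
#' @param correction `"jukes-cantor"` (default) or `"none"` for
#'   uncorrected pN/pS.
#' @return an object of class `kaks_result`: a list with `id`, the counts
#'   from [classify_substitutions()], site totals `N` and `S`, `pN`,
#'   `pS`, `Ka`, `Ks`, `ka_ks`, and logical `undefined` (TRUE when the
#'   ratio or correction is undefined).
#' @export
ka_ks <- function(aln, correction = c("jukes-cantor", "none")) {
  correction <- match.arg(correction)
  counts <- classify_substitutions(aln)
  sites <- ng_sites(aln)
  ka_ks_from_counts(counts$aa_changing, counts$silent,
                    sites$N, sites$S, id = aln$id,
                    correction = correction)
}

#' @rdname ka_ks
#' @param n_nonsyn,n_syn substitution counts (may be fractional,
#'   pathway-averaged).
#' @param N,S nonsynonymous and synonymous site totals (> 0).
#' @param id identifier for the output record.
#' @export
ka_ks_from_counts <- function(n_nonsyn, n_syn, N, S, id = "pair",
                              correction = c("jukes-cantor", "none")) {
  correction <- match.arg(correction)
  if (N <= 0 || S <= 0) stopf("site totals N and S must be > 0")
  pN <- n_nonsyn / N
  pS <- n_syn / S
  jc <- function(p) {
    if (p >= 3 / 4) return(NA_real_)
    if (correction == "none") p else -3 / 4 * log1p(-4 * p / 3)
  }
  Ka <- jc(pN); Ks <- jc(pS)
  undefined <- is.na(Ka) || is.na(Ks) || Ks == 0
  ratio <- if (undefined) NA_real_ else Ka / Ks
  structure(list(id = id, aa_changing = n_nonsyn, silent = n_syn,
                 N = N, S = S, pN = pN, pS = pS,
                 Ka = Ka, Ks = Ks, ka_ks = ratio,
                 undefined = undefined),
            class = "kaks_result")
}

# ---- substitution tables and contingency tests -----------------------

#' Tabulate substitution counts across genes
#'
#' Builds the per-gene table of amino-acid-changing and silent
#' substitution counts (and Ka/Ks where available) in the layout used for
#' interspecies candidate-gene comparisons: one row per gene, integer
#' counts, ratio column.
#'
#' @param x a list of `substitution_counts` and/or `kaks_result` objects.
#' @return data.frame with columns `gene`, `aa_changing`, `silent`,
#'   `ka_ks`.
#' @export
substitution_table <- function(x) {
  rows <- lapply(x, function(r) {
    data.frame(gene = r$id,
               aa_changing = as.integer(round_half_away(r$aa_changing)),
               silent = as.integer(round_half_away(r$silent)),
               ka_ks = if (!is.null(r$ka_ks)) r$ka_ks else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname substitution_table
#' @param path file path for the tab-separated output.
#' @export
write_substitution_table <- function(x, path) {
  df <- if (is.data.frame(x)) x else substitution_table(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Published substitution counts for the sugar-tolerance candidate genes
#'
#' Counts of amino-acid-changing and silent nucleotide differences
#' between the *D. simulans* and *D. sechellia* coding sequences of the
#' nine candidate genes recovered in the sugar-tolerance RNAi screen,
#' with the published Ka/Ks ratios. PPP1R15 stands out with 10
#' amino-acid-changing against 5 silent differences (Ka/Ks = 0.58,
#' consistent with relaxed purifying selection); the published ratios
#' rest on per-gene site totals that are not part of the table, so they
#' are carried as reported values, not recomputed. `screen_hit` marks the
#' six genes with strong sugar-intolerance knockdown phenotypes.
#'
#' @return data.frame with columns `gene`, `aa_changing`, `silent`,
#'   `ka_ks`, `screen_hit`.
#' @export
candidate_gene_substitutions <- function() {
  data.frame(
    gene = c("PPP1R15", "Pi3K59F", "CG4882", "Taldo", "Dpit47",
             "GlcT-1", "bonsai", "mRpL43", "SERCA"),
    aa_changing = c(10L, 2L, 4L, 1L, 4L, 3L, 2L, 1L, 6L),
    silent = c(5L, 23L, 8L, 6L, 9L, 10L, 8L, 13L, 16L),
    ka_ks = c(0.58, 0.03, 0.15, 0.05, 0.13, 0.01, 0.13, 0.03, 0.13),
    screen_hit = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE,
                   TRUE))
}

#' Contingency test on substitution classes across genes
#'
#' Pearson chi-squared test of homogeneity on the genes x
#' \{amino-acid-changing, silent\} contingency table, asking whether the
#' ratio of amino-acid-changing to silent differences varies among genes
#' (as it does when one gene, like PPP1R15, has experienced relaxed
#' purifying selection). Degrees of freedom are `n_genes - 1`. A warning
#' is emitted when any expected cell count falls below 5.
#'
#' @param counts data.frame with columns `gene`, `aa_changing`, `silent`
#'   (e.g. from [substitution_table()] or
#'   [candidate_gene_substitutions()]).
#' @return list with `statistic` (chi-squared), `df`, `p_value`, and the
#'   `expected` matrix.
#' @export
substitution_contingency <- function(counts) {
  counts <- as.data.frame(counts)
  if (nrow(counts) < 2) stopf("at least 2 genes required")
  m <- as.matrix(counts[, c("aa_changing", "silent")])
  if (any(m < 0) || any(m != floor(m))) stopf("counts must be non-negative integers")
  if (sum(m) == 0) stopf("all-zero contingency table")
  rownames(m) <- counts$gene
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  if (any(ht$expected < 5))
    warnf("expected counts below 5; chi-squared approximation is rough")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = ht$expected)
}

# ---- sliding-window divergence ---------------------------------------

#' Sliding-window nucleotide difference density
#'
#' Computes the frequency of nucleotide differences between two aligned
#' sequences in windows of `window` alignment columns slid forward in
#' steps of `step` columns (defaults 100 and 25). Columns where either
#' sequence has `N` or a gap are masked: they count neither as
#' differences nor toward the window's denominator. Windows whose
#' denominator is zero are reported as missing. Partial terminal windows
#' are discarded.
#'
#' @param seq_a,seq_b aligned sequences, equal length.
#' @param window window size in alignment columns.
#' @param step step size in columns; `window >= step > 0`.
#' @return a `density_track` data.frame with columns `start`, `end`
#'   (0-based half-open column coordinates), `n_diff`, `n_sites`
#'   (unmasked columns), `raw` (differences per unmasked column) and
#'   `corrected` (NA until [background_correct()] is applied).
#' @export
window_snp_density <- function(seq_a, seq_b, window = 100, step = 25) {
  a <- toupper(as.character(seq_a)); b <- toupper(as.character(seq_b))
  if (nchar(a) != nchar(b)) stopf("aligned sequences differ in length")
  if (step <= 0 || window < step) stopf("need window >= step > 0")
  len <- nchar(a)
  if (len < window) stopf("alignment shorter than one window")
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  masked <- av %in% c("N", "-") | bv %in% c("N", "-")
  diff <- (av != bv) & !masked
  cd <- c(0, cumsum(diff)); cm <- c(0, cumsum(!masked))
  starts <- seq(0L, len - window, by = step)
  n_diff <- cd[starts + window + 1L] - cd[starts + 1L]
  n_sites <- cm[starts + window + 1L] - cm[starts + 1L]
  raw <- ifelse(n_sites > 0, n_diff / n_sites, NA_real_)
  structure(data.frame(start = starts, end = starts + window,
                       n_diff = n_diff, n_sites = n_sites,
                       raw = raw, corrected = NA_real_),
            class = c("density_track", "data.frame"))
}

#' Background-correct a window density track
#'
#' Estimates the genomic background difference frequency from a set of
#' aligned background region pairs (pooled as total differences over
#' total unmasked bases) and subtracts it from every window's raw
#' density. Corrected values may be negative.
#'
#' @param track a `density_track` from [window_snp_density()].
#' @param background a list of aligned background pairs; each element is
#'   a list or character vector of two equal-length aligned sequences.
#' @return the track with its `corrected` column filled in, and the
#'   estimated background rate in attribute `"background"`.
#' @export
background_correct <- function(track, background) {
  stopifnot(inherits(track, "density_track"))
  if (length(background) == 0) stopf("empty background set")
  tot_diff <- 0; tot_sites <- 0
  for (pair in background) {
    a <- toupper(as.character(pair[[1]]))
    b <- toupper(as.character(pair[[2]]))
    if (nchar(a) != nchar(b))
      stopf("background pair sequences differ in length")
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    masked <- av %in% c("N", "-") | bv %in% c("N", "-")
    tot_diff <- tot_diff + sum(av != bv & !masked)
    tot_sites <- tot_sites + sum(!masked)
  }
  if (tot_sites == 0) stopf("background regions are fully masked")
  bg <- tot_diff / tot_sites
  track$corrected <- track$raw - bg
  attr(track, "background") <- bg
  track
}

#' Write a density track as bedGraph
#'
#' @param track a `density_track`.
#' @param path output path.
#' @param chrom chromosome name for the bedGraph records.
#' @param value which column to write: `"raw"` or `"corrected"`.
#' @return `path`, invisibly. Missing windows are skipped.
#' @export
write_density_bedgraph <- function(track, path, chrom = "region",
                                   value = c("raw", "corrected")) {
  value <- match.arg(value)
  v <- track[[value]]
  keep <- !is.na(v)
  df <- data.frame(chrom = chrom, start = track$start[keep],
                   end = track$end[keep], value = v[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
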