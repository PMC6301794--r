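# Introgression-region mapping from pooled donor-allele frequencies at
# species-diagnostic SNPs: windowed frequency tracks, threshold-run
# segmentation, and gene annotation of the resulting regions.

#' Construct a table of species-diagnostic SNPs
#'
#' Species-diagnostic SNPs are sites fixed for different alleles in the
#' donor and recipient species; the donor-allele frequency at these sites
#' assigns local ancestry to a pooled sample.
#'
#' @param x data.frame with columns `chrom`, `pos` (1-based),
#'   `donor_allele`, `recipient_allele`.
#' @return the validated table with class `diagnostic_snp_table`, sorted
#'   by chromosome and position.
#' @export
diagnostic_snp_table <- function(x) {
  req <- c("chrom", "pos", "donor_allele", "recipient_allele")
  if (!all(req %in% names(x)))
    stopf("diagnostic SNP table needs columns: %s",
          paste(req, collapse = ", "))
  x <- as.data.frame(x)[, req]
  if (any(x$pos < 1)) stopf("positions are 1-based and must be >= 1")
  if (any(x$donor_allele == x$recipient_allele))
    stopf("donor and recipient alleles must differ")
  x <- x[order(x$chrom, x$pos), , drop = FALSE]
  dup <- duplicated(x[, c("chrom", "pos")])
  if (any(dup)) stopf("duplicated SNP positions")
  rownames(x) <- NULL
  class(x) <- c("diagnostic_snp_table", "data.frame")
  x
}

#' Regularly spaced diagnostic SNPs along chromosomes
#'
#' Convenience constructor for simulation studies: one diagnostic SNP
#' every `spacing_bp` along each chromosome of a map (density 1/kb at the
#' default spacing of 1000).
#'
#' @param map a [chromosome_map()]; the mitochondrion is skipped.
#' @param spacing_bp distance between consecutive SNPs.
#' @return a [diagnostic_snp_table()] with alternating A/T alleles.
#' @export
evenly_spaced_snps <- function(map, spacing_bp = 1000) {
  rows <- lapply(map_nuclear(map), function(chrom) {
    pos <- seq(spacing_bp, map[chrom, "length_bp"], by = spacing_bp)
    data.frame(chrom = chrom, pos = pos,
               donor_allele = "A", recipient_allele = "T")
  })
  diagnostic_snp_table(do.call(rbind, rows))
}

#' Call species-diagnostic SNPs from two parental genotype tables
#'
#' Returns the sites where the two species' samples are each monomorphic
#' (no within-species polymorphism) for different alleles, with at least
#' `min_count` observed chromosomes per species. Sites polymorphic within
#' either species are excluded - they cannot diagnose ancestry. Species A
#' is taken as the donor.
#'
#' @param table_a,table_b genotype tables (columns `chrom`, `pos`, `A`,
#'   `C`, `G`, `T` allele counts), e.g. from
#'   [simulate_parental_genomes()].
#' @param min_count minimum observed chromosomes per species at a site.
#' @return a [diagnostic_snp_table()] with species A's allele as
#'   `donor_allele`.
#' @export
call_diagnostic_snps <- function(table_a, table_b, min_count = 1) {
  bases <- c("A", "C", "G", "T")
  key_a <- paste(table_a$chrom, table_a$pos)
  key_b <- paste(table_b$chrom, table_b$pos)
  shared <- intersect(key_a, key_b)
  if (length(shared) == 0) stopf("no shared sites between the tables")
  a <- table_a[match(shared, key_a), , drop = FALSE]
  b <- table_b[match(shared, key_b), , drop = FALSE]
  ma <- as.matrix(a[, bases]); mb <- as.matrix(b[, bases])
  mono_a <- rowSums(ma > 0) == 1 & rowSums(ma) >= min_count
  mono_b <- rowSums(mb > 0) == 1 & rowSums(mb) >= min_count
  allele_a <- bases[max.col(ma)]
  allele_b <- bases[max.col(mb)]
  keep <- mono_a & mono_b & allele_a != allele_b
  diagnostic_snp_table(data.frame(
    chrom = a$chrom[keep], pos = a$pos[keep],
    donor_allele = allele_a[keep], recipient_allele = allele_b[keep]))
}

#' Windowed donor-allele frequency track
#'
#' Averages pooled donor-allele counts in genomic windows: per window the
#' frequency is the ratio of summed donor reads to summed depth over the
#' SNPs inside (ratio of sums, robust to uneven depth). Windows holding
#' fewer than `min_snps` SNPs are reported missing. SNP input order is
#' irrelevant.
#'
#' @param snps a [diagnostic_snp_table()].
#' @param counts a `pool_counts` table covering the SNPs (matched by
#'   chromosome and position).
#' @param window_bp window size (default 100 kb).
#' @param step_bp step between window starts (default 100 kb:
#'   non-overlapping); `window_bp >= step_bp > 0`.
#' @param min_snps minimum SNPs per window (default 5).
#' @param chrom_lengths optional named vector of chromosome lengths;
#'   windows then tile each whole chromosome instead of stopping at the
#'   last SNP.
#' @return a `frequency_track` data.frame: `chrom`, `start`, `end`
#'   (0-based half-open), `n_snps`, `depth`, `donor_reads`, `freq` (NA
#'   when `n_snps < min_snps` or depth is 0).
#' @export
donor_frequency_windows <- function(snps, counts, window_bp = 1e5,
                                    step_bp = 1e5, min_snps = 5,
                                    chrom_lengths = NULL) {
  stopifnot(inherits(snps, "diagnostic_snp_table"))
  if (nrow(snps) == 0) stopf("empty SNP set")
  if (step_bp <= 0 || window_bp < step_bp)
    stopf("need window_bp >= step_bp > 0")
  key_s <- paste(snps$chrom, snps$pos)
  key_c <- paste(counts$chrom, counts$pos)
  idx <- match(key_s, key_c)
  if (anyNA(idx)) stopf("counts do not cover the SNP table")
  depth <- counts$depth[idx]
  donor <- counts$donor_reads[idx]
  out <- list()
  for (chrom in unique(snps$chrom)) {
    sel <- snps$chrom == chrom
    pos0 <- snps$pos[sel] - 1
    d <- depth[sel]; dr <- donor[sel]
    span <- if (!is.null(chrom_lengths)) chrom_lengths[[chrom]]
    else max(pos0) + 1
    starts <- seq(0, max(0, span - 1), by = step_bp)
    starts <- starts[starts < span]
    ends <- pmin(starts + window_bp, span)
    n_snps <- tot_d <- tot_r <- numeric(length(starts))
    for (w in seq_along(starts)) {
      inw <- pos0 >= starts[w] & pos0 < ends[w]
      n_snps[w] <- sum(inw)
      tot_d[w] <- sum(d[inw])
      tot_r[w] <- sum(dr[inw])
    }
    freq <- ifelse(n_snps >= min_snps & tot_d > 0, tot_r / tot_d,
                   NA_real_)
    out[[chrom]] <- data.frame(chrom = chrom, start = starts,
                               end = ends, n_snps = n_snps,
                               depth = tot_d, donor_reads = tot_r,
                               freq = freq)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("frequency_track", "data.frame")
  res
}

#' Segment introgressed regions from a frequency track
#'
#' Finds maximal runs of windows whose donor frequency reaches
#' `threshold`, allowing interruptions of up to `max_gap_windows`
#' below-threshold or missing windows, and keeps runs containing at
#' least `min_windows` qualifying windows. Region bounds run from the
#' first qualifying window's start to the last one's end. The default
#' threshold 0.25 splits absence (frequency 0) from a heterozygous
#' introgression segregating in the pool (expected frequency 0.5).
#'
#' @param track a `frequency_track` from [donor_frequency_windows()].
#' @param threshold minimum donor frequency for a qualifying window.
#' @param min_windows minimum qualifying windows per region (default 3).
#' @param max_gap_windows maximum consecutive non-qualifying windows
#'   bridged inside a region (default 1).
#' @return data.frame of regions, class `introgression_regions`:
#'   `chrom`, `start`, `end` (0-based half-open), `n_windows`
#'   (qualifying), `mean_freq` (mean frequency of qualifying windows),
#'   sorted and non-overlapping per chromosome. Zero rows when nothing
#'   qualifies.
#' @export
detect_regions <- function(track, threshold = 0.25, min_windows = 3,
                           max_gap_windows = 1) {
  out <- list()
  for (chrom in unique(track$chrom)) {
    tr <- track[track$chrom == chrom, , drop = FALSE]
    tr <- tr[order(tr$start), , drop = FALSE]
    hit <- !is.na(tr$freq) & tr$freq >= threshold
    idx <- which(hit)
    if (length(idx) == 0) next
    # group qualifying windows: a new region starts when the gap of
    # non-qualifying windows since the previous hit exceeds max_gap
    grp <- cumsum(c(1L, diff(idx) > max_gap_windows + 1L))
    for (g in unique(grp)) {
      members <- idx[grp == g]
      if (length(members) < min_windows) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom,
        start = tr$start[members[1]],
        end = tr$end[members[length(members)]],
        n_windows = length(members),
        mean_freq = mean(tr$freq[members]))
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_windows = integer(), mean_freq = numeric())
  rownames(res) <- NULL
  class(res) <- c("introgression_regions", "data.frame")
  res
}

#' Annotate regions with overlapping genes
#'
#' Counts and lists the genes whose span overlaps each region by at
#' least 1 bp. Regions are 0-based half-open, so a gene starting exactly
#' at a region's end does not overlap.
#'
#' @param regions an `introgression_regions` data.frame (or any
#'   data.frame with `chrom`, `start`, `end` in 0-based half-open
#'   coordinates).
#' @param genes a [GenomicRanges::GRanges] of gene spans (e.g. from
#'   [read_gene_annotation()]), with gene identifiers in `gene_id`
#'   metadata or in `names()`.
#' @return the regions with added columns `n_genes` and `genes`
#'   (comma-separated identifiers). Regions on chromosomes absent from
#'   the annotation get a warning and a zero count.
#' @export
annotate_regions <- function(regions, genes) {
  regions <- as.data.frame(regions)
  n <- nrow(regions)
  regions$n_genes <- integer(n)
  regions$genes <- character(n)
  if (n == 0) return(regions)
  ids <- if (!is.null(genes$gene_id)) as.character(genes$gene_id)
  else if (!is.null(names(genes))) names(genes)
  else as.character(seq_along(genes))
  known <- as.character(GenomicRanges::seqnames(genes))
  for (i in seq_len(n)) {
    if (!regions$chrom[i] %in% known) {
      warnf("chromosome %s absent from annotation; skipped",
            regions$chrom[i])
      next
    }
    # region [start, end) 0-based -> 1-based closed [start+1, end]
    q <- GenomicRanges::GRanges(
      regions$chrom[i],
      IRanges::IRanges(regions$start[i] + 1, regions$end[i]))
    hits <- GenomicRanges::findOverlaps(q, genes, minoverlap = 1L)
    hit_ids <- unique(ids[S4Vectors_subjectHits(hits)])
    regions$n_genes[i] <- length(hit_ids)
    regions$genes[i] <- paste(hit_ids, collapse = ",")
  }
  regions
}

# subjectHits without importing all of S4Vectors
S4Vectors_subjectHits <- function(hits) {
  getExportedValue("S4Vectors", "subjectHits")(hits)
}

#' Read gene annotation from GFF3 or BED
#'
#' Reads gene spans from a GFF3 file (keeping `type == "gene"` records
#' when present) or a BED file, as a GRanges for [annotate_regions()].
#'
#' @param path file path; format inferred from the extension
#'   (`.gff`/`.gff3` vs `.bed`).
#' @return a [GenomicRanges::GRanges] with a `gene_id` metadata column.
#' @export
read_gene_annotation <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    gr$gene_id <- if (!is.null(gr$name)) gr$name
    else as.character(seq_along(gr))
    return(gr)
  }
  gr <- rtracklayer::import(path, format = "GFF3")
  if (!is.null(gr$type) && any(gr$type == "gene"))
    gr <- gr[gr$type == "gene"]
  gr$gene_id <- if (!is.null(gr$ID)) as.character(gr$ID)
  else if (!is.null(gr$Name)) as.character(gr$Name)
  else as.character(seq_along(gr))
  gr
}

#' Write a frequency track as bedGraph
#'
#' @param track a `frequency_track`.
#' @param path output path.
#' @return `path`, invisibly. Missing windows are skipped.
#' @export
write_frequency_bedgraph <- function(track, path) {
  keep <- !is.na(track$freq)
  df <- data.frame(chrom = track$chrom[keep],
                   start = format(track$start[keep],
                                  scientific = FALSE, trim = TRUE),
                   end = format(track$end[keep], scientific = FALSE,
                                trim = TRUE),
                   value = track$freq[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write introgression regions as BED
#'
#' BED5 records (0-based half-open) with the mean donor frequency as the
#' score.
#'
#' @param regions an `introgression_regions` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  df <- data.frame(chrom = regions$chrom,
                   start = format(regions$start, scientific = FALSE,
                                  trim = TRUE),
                   end = format(regions$end, scientific = FALSE,
                                trim = TRUE),
                   name = sprintf("region%d", seq_len(nrow(regions))),
                   score = regions$mean_freq)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a diagnostic SNP table as minimal VCF v4.2
#'
#' One record per SNP with the recipient allele as REF, the donor allele
#' as ALT, and the donor allele frequency (if counts are supplied) in
#' `INFO/AF`.
#'
#' @param snps a [diagnostic_snp_table()].
#' @param path output path.
#' @param counts optional `pool_counts` matched by chromosome/position.
#' @return `path`, invisibly.
#' @export
write_diagnostic_vcf <- function(snps, path, counts = NULL) {
  stopifnot(inherits(snps, "diagnostic_snp_table"))
  info <- rep(".", nrow(snps))
  if (!is.null(counts)) {
    idx <- match(paste(snps$chrom, snps$pos),
                 paste(counts$chrom, counts$pos))
    af <- ifelse(counts$depth[idx] > 0,
                 counts$donor_reads[idx] / counts$depth[idx], NA)
    info <- ifelse(is.na(af), ".", sprintf("AF=%.6g", af))
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Donor allele frequency\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                  snps$chrom, as.integer(snps$pos),
                  snps$recipient_allele, snps$donor_allele, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}
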