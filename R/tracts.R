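# Ancestry tract sets: the genome model of the backcross simulator.
#
# A haplotype of one chromosome is a partition of [0, L) into half-open
# tracts, each of donor or recipient origin, stored run-length style as
# a vector of tract end positions plus an origin code per tract
# (1 = donor, 0 = recipient). Tracts tile the chromosome exactly and
# adjacent tracts differ in origin after normalisation.

DONOR <- 1L
RECIPIENT <- 0L

#' Construct a single-origin ancestry tract set
#'
#' @param length_bp chromosome length in bp.
#' @param origin `"donor"` or `"recipient"` (or the internal codes 1/0).
#' @return an `ancestry_tracts` object covering `[0, length_bp)`.
#' @export
tracts_uniform <- function(length_bp, origin = c("recipient", "donor")) {
  if (is.character(origin)) {
    origin <- match.arg(origin)
    origin <- if (origin == "donor") DONOR else RECIPIENT
  }
  new_tracts(length_bp, origin = as.integer(origin))
}

new_tracts <- function(end, origin) {
  structure(list(end = as.numeric(end), origin = as.integer(origin)),
            class = "ancestry_tracts")
}

tracts_length <- function(tr) tr$end[length(tr$end)]

tracts_starts <- function(tr) c(0, tr$end[-length(tr$end)])

# Merge adjacent tracts of equal origin and drop zero-width tracts.
tracts_normalize <- function(tr) {
  keep <- tr$end > tracts_starts(tr)
  end <- tr$end[keep]; origin <- tr$origin[keep]
  if (length(end) > 1) {
    same <- c(origin[-1] == origin[-length(origin)], FALSE)
    end <- end[!same]; origin <- origin[!same]
  }
  new_tracts(end, origin)
}

# Invariant check used by tests: tracts tile [0, L) exactly, sorted,
# positive width, alternating origin.
tracts_valid <- function(tr, length_bp) {
  length(tr$end) == length(tr$origin) &&
    length(tr$end) >= 1 &&
    !is.unsorted(tr$end, strictly = TRUE) &&
    all(tr$end > tracts_starts(tr)) &&
    isTRUE(all.equal(tracts_length(tr), length_bp)) &&
    all(tr$origin %in% c(DONOR, RECIPIENT)) &&
    (length(tr$origin) < 2 || all(diff(tr$origin) != 0))
}

#' Ancestry origin at positions along a haplotype
#'
#' @param tr an `ancestry_tracts` object.
#' @param pos 0-based positions in `[0, L)` (vectorised).
#' @return integer vector: 1 for donor, 0 for recipient.
#' @export
origin_at <- function(tr, pos) {
  if (any(pos < 0) || any(pos >= tracts_length(tr)))
    stopf("position outside chromosome bounds")
  tr$origin[findInterval(pos, tr$end) + 1L]
}

# Donor fraction of a haplotype (length-weighted).
tracts_donor_fraction <- function(tr) {
  widths <- tr$end - tracts_starts(tr)
  sum(widths[tr$origin == DONOR]) / tracts_length(tr)
}

# Bounds [start, end) of the tract containing pos.
tract_bounds_at <- function(tr, pos) {
  i <- findInterval(pos, tr$end) + 1L
  c(start = tracts_starts(tr)[i], end = tr$end[i])
}

# Splice a gamete haplotype from two parental haplotypes: segments
# between consecutive crossover breakpoints are copied from alternating
# parents, starting from haplotype `first`.
tracts_recombine <- function(h1, h2, breakpoints, first = 1L) {
  L <- tracts_length(h1)
  if (length(breakpoints) == 0)
    return(if (first == 1L) h1 else h2)
  bounds <- c(sort(breakpoints), L)
  haps <- list(h1, h2)
  src_idx <- (first - 1L + seq_along(bounds) - 1L) %% 2L + 1L
  ends <- numeric(0); origins <- integer(0)
  a <- 0
  for (k in seq_along(bounds)) {
    b <- bounds[k]
    if (b > a) {
      src <- haps[[src_idx[k]]]
      starts <- tracts_starts(src)
      sel <- which(src$end > a & starts < b)
      ends <- c(ends, pmin(src$end[sel], b))
      origins <- c(origins, src$origin[sel])
    }
    a <- b
  }
  tracts_normalize(new_tracts(ends, origins))
}
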