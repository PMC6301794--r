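# Gene-set overlap and multiple-testing statistics.

#' Hypergeometric gene-set overlap test
#'
#' Tests whether two gene sets drawn from a common universe share more
#' members than expected by chance. With universe size \eqn{U}, set
#' sizes \eqn{|A|} and \eqn{|B|}, and observed overlap \eqn{k}, the
#' enrichment p-value is the upper tail \eqn{P(X \ge k)} of the
#' hypergeometric distribution, evaluated in log space so that extreme
#' enrichments (p well below 1e-300) stay finite. The depletion tail
#' \eqn{P(X \le k)} is available via `tail = "depletion"`.
#'
#' @param set_a,set_b character vectors of identifiers; must be subsets
#'   of `universe`.
#' @param universe character vector of all identifiers considered.
#' @param tail `"enrichment"` (default) or `"depletion"`.
#' @return list of class `gene_set_overlap`: `n_a`, `n_b`, `n_universe`,
#'   `k` (observed overlap), `expected` overlap, `fold_enrichment`,
#'   `pct_of_a` (= 100 k / |A|), `p_value`, `log10_p`.
#' @export
overlap_test <- function(set_a, set_b, universe,
                         tail = c("enrichment", "depletion")) {
  tail <- match.arg(tail)
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  universe <- unique(as.character(universe))
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stopf("sets must be contained in the universe")
  u <- length(universe); na <- length(set_a); nb <- length(set_b)
  k <- length(intersect(set_a, set_b))
  log_p <- if (tail == "enrichment")
    stats::phyper(k - 1, na, u - na, nb, lower.tail = FALSE,
                  log.p = TRUE)
  else
    stats::phyper(k, na, u - na, nb, lower.tail = TRUE, log.p = TRUE)
  expected <- na * nb / u
  structure(list(n_a = na, n_b = nb, n_universe = u, k = k,
                 expected = expected,
                 fold_enrichment = if (expected > 0) k / expected
                 else NA_real_,
                 pct_of_a = if (na > 0) 100 * k / na else NA_real_,
                 p_value = exp(log_p),
                 log10_p = log_p / log(10)),
            class = "gene_set_overlap")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector, with
#' monotonicity enforcement; preserves input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
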