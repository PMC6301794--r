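# Independent oracles used to check package computations.

# Exhaustive pupariation-index maximum: loop, no vectorised shortcut.
brute_force_pupind <- function(time_h, cum_pupae) {
  best <- -Inf; best_t <- NA
  for (i in seq_along(time_h)) {
    r <- cum_pupae[i] / time_h[i]
    if (r > best) {
      best <- r
      best_t <- time_h[i]
    }
  }
  list(pupind = best, t_star = best_t)
}

# Random valid cumulative pupariation series on the standard schedule.
random_series <- function(times = standard_obs_times(), n_larvae = 30) {
  inc <- stats::rmultinom(1, stats::rbinom(1, n_larvae, stats::runif(1)),
                          rep(1, length(times)))[, 1]
  cumsum(inc)
}

# Per-window mismatch counting by direct substring comparison.
brute_force_window_density <- function(a, b, window, step) {
  len <- nchar(a)
  starts <- seq(0, len - window, by = step)
  raw <- numeric(length(starts))
  for (w in seq_along(starts)) {
    sa <- strsplit(substr(a, starts[w] + 1, starts[w] + window), "")[[1]]
    sb <- strsplit(substr(b, starts[w] + 1, starts[w] + window), "")[[1]]
    usable <- !(sa %in% c("N", "-") | sb %in% c("N", "-"))
    raw[w] <- if (sum(usable) > 0) sum(sa[usable] != sb[usable]) / sum(usable)
    else NA_real_
  }
  data.frame(start = starts, raw = raw)
}

# Pathway-enumeration oracle for codon substitution classification:
# recursively enumerates orders of applying the differing positions,
# translating with the standard genetic code.
oracle_classify_pair <- function(from, to) {
  code <- Biostrings::GENETIC_CODE
  f <- strsplit(from, "")[[1]]; t <- strsplit(to, "")[[1]]
  diffs <- which(f != t)
  if (length(diffs) == 0) return(c(nonsyn = 0, syn = 0))
  enumerate <- function(cur, remaining) {
    if (length(remaining) == 0) return(list(c(0, 0, 0)))  # ns, s, stop
    out <- list()
    for (p in remaining) {
      nxt <- cur
      nxt[p] <- t[p]
      hit_stop <- code[[paste(nxt, collapse = "")]] == "*"
      ns <- as.integer(code[[paste(nxt, collapse = "")]] !=
                         code[[paste(cur, collapse = "")]])
      for (rest in enumerate(nxt, setdiff(remaining, p)))
        out[[length(out) + 1L]] <-
          c(ns + rest[1], (1 - ns) + rest[2], hit_stop + rest[3])
    }
    out
  }
  paths <- do.call(rbind, enumerate(f, diffs))
  valid <- paths[paths[, 3] == 0, , drop = FALSE]
  if (nrow(valid) > 0)
    c(nonsyn = mean(valid[, 1]), syn = mean(valid[, 2]))
  else {
    best <- paths[which.min(paths[, 1]), ]
    c(nonsyn = best[1], syn = best[2])
  }
}

# Exact upper-tail hypergeometric probability by direct enumeration of
# the overlap distribution (binomial coefficients, no distribution
# functions).
oracle_hyper_upper <- function(k, n_a, n_b, u) {
  j <- max(0, n_a + n_b - u):min(n_a, n_b)
  pmf <- choose(n_a, j) * choose(u - n_a, n_b - j) / choose(u, n_b)
  sum(pmf[j >= k])
}

# Step-up Benjamini-Hochberg adjustment written out directly.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- running
  }
  adj
}

# Pure-recipient female population for false-positive controls.
recipient_population <- function(n, map) {
  ind <- make_f1(1, map)[[1]]
  for (chrom in names(ind$nuc))
    for (j in seq_along(ind$nuc[[chrom]]))
      ind$nuc[[chrom]][[j]] <- tracts_uniform(map[chrom, "length_bp"],
                                              "recipient")
  ind$mito <- 0L
  rep(list(ind), n)
}
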