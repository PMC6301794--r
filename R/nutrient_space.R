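# Nutrient-space phenotype statistics: pupariation index, survival and
# development time, diet calories, diet-axis correlations, omega-squared
# effect sizes, and genotype difference surfaces.

#' Pupariation index of one vial series
#'
#' The pupariation index (Pupind) of a vial is the maximum rate of
#' pupariation over the observation schedule:
#' \deqn{\mathrm{Pupind} = \max\{p_t / t : t = 24, 48, \ldots, 408\}}
#' where \eqn{p_t} is the cumulative number of larvae pupariated at
#' observation time \eqn{t} hours after egg laying. A single statistic,
#' in larvae per hour, that rewards both fast development and high
#' survival. When several observation times attain the maximum, the
#' earliest is reported.
#'
#' @param time_h observation times in hours (positive, increasing).
#' @param cum_pupae cumulative pupae counts at those times.
#' @return list with `pupind` (larvae/hour) and `t_star` (the earliest
#'   maximising observation time, hours).
#' @export
compute_pupind <- function(time_h, cum_pupae) {
  if (length(time_h) == 0) stopf("empty series")
  if (length(time_h) != length(cum_pupae)) stopf("length mismatch")
  rate <- cum_pupae / time_h
  i <- which.max(rate)  # which.max takes the earliest tie
  list(pupind = rate[i], t_star = time_h[i])
}

#' Survival fraction and development time of one vial series
#'
#' Survival is the final cumulative count divided by the number of larvae
#' seeded. Development time is the earliest observation time at which the
#' cumulative count reaches half the final count - the median
#' time-to-pupariation of the survivors under 24-h interval censoring.
#' Alternatives: `"midpoint"` averages the interval midpoints of all
#' pupariation events; `"first"` is the time of the first pupa.
#'
#' @param time_h observation times in hours.
#' @param cum_pupae cumulative pupae counts.
#' @param n_larvae larvae seeded.
#' @param devtime one of `"median"` (default), `"midpoint"`, `"first"`.
#' @return list with `survival` in `[0, 1]` and `dev_time_h` (NA when no
#'   larva pupariated).
#' @export
compute_survival_devtime <- function(time_h, cum_pupae, n_larvae,
                                     devtime = c("median", "midpoint",
                                                 "first")) {
  devtime <- match.arg(devtime)
  if (length(time_h) == 0) stopf("empty series")
  p_final <- cum_pupae[length(cum_pupae)]
  survival <- p_final / n_larvae
  if (p_final == 0)
    return(list(survival = survival, dev_time_h = NA_real_))
  dt <- switch(
    devtime,
    median = time_h[which(cum_pupae >= p_final / 2)[1]],
    first = time_h[which(cum_pupae > 0)[1]],
    midpoint = {
      new_p <- diff(c(0, cum_pupae))
      lower <- c(0, time_h[-length(time_h)])
      sum(new_p * (lower + time_h) / 2) / p_final
    })
  list(survival = survival, dev_time_h = dt)
}

#' Per-vial nutrient-space metrics of a grid assay
#'
#' Applies [compute_pupind()] and [compute_survival_devtime()] to every
#' vial of a grid assay.
#'
#' @param assay a [grid_assay()].
#' @param devtime development-time definition, see
#'   [compute_survival_devtime()].
#' @return data.frame with one row per vial: `genotype`, `yeast_pct`,
#'   `sucrose_pct`, `vial`, `n_larvae`, `pupind`, `t_star`, `survival`,
#'   `dev_time_h`.
#' @export
vial_metrics <- function(assay, devtime = "median") {
  assay <- grid_assay(assay)
  key <- vial_key(assay)
  idx <- split(seq_len(nrow(assay)), key)
  rows <- lapply(idx, function(i) {
    d <- assay[i, , drop = FALSE]
    pp <- compute_pupind(d$time_h, d$cum_pupae)
    sd <- compute_survival_devtime(d$time_h, d$cum_pupae, d$n_larvae[1],
                                   devtime = devtime)
    data.frame(genotype = d$genotype[1], yeast_pct = d$yeast_pct[1],
               sucrose_pct = d$sucrose_pct[1], vial = d$vial[1],
               n_larvae = d$n_larvae[1],
               pupind = pp$pupind, t_star = pp$t_star,
               survival = sd$survival, dev_time_h = sd$dev_time_h)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$genotype, out$yeast_pct, out$sucrose_pct,
                   out$vial), ]
  rownames(out) <- NULL
  out
}

#' Estimated caloric content of a yeast/sucrose diet
#'
#' Energy density of a diet in kcal per 100 g, from its yeast and sucrose
#' percentages (w/v): 3.25 kcal per gram of baker's yeast and 4.06 kcal
#' per gram of sucrose, rounded half away from zero to one decimal. The
#' arithmetic is carried out on an integer-scaled form so decimal
#' half-way cases (e.g. 5% yeast / 15% sucrose = 77.15) round upward
#' regardless of binary floating-point representation.
#'
#' @param yeast_pct,sucrose_pct diet composition in % w/v (grams per
#'   100 g); non-negative, vectorised.
#' @return kcal per 100 g, one decimal.
#' @export
diet_calories <- function(yeast_pct, sucrose_pct) {
  if (any(yeast_pct < 0) || any(sucrose_pct < 0))
    stopf("diet percentages must be non-negative")
  # 3.25 = 650/200 and 4.06 = 812/200 kcal/g; value in tenths of kcal is
  # (650*y + 812*s)/20, exact for grid-style inputs
  tenths <- (650 * yeast_pct + 812 * sucrose_pct) / 20
  floor(tenths + 0.5 + 1e-8 * pmax(1, tenths)) / 10
}

#' Calorie surface of a diet grid
#'
#' @param yeast_levels,sucrose_levels axis levels in % w/v.
#' @return a [diet_surface()] of kcal/100 g values (yeast levels as rows,
#'   sucrose levels as columns).
#' @export
calorie_surface <- function(yeast_levels = c(1.25, 2.5, 5, 10, 20),
                            sucrose_levels = c(0, 5, 10, 15, 20)) {
  m <- outer(yeast_levels, sucrose_levels, diet_calories)
  diet_surface(yeast_levels, sucrose_levels, m)
}

#' Correlate a nutrient-space metric against a diet axis
#'
#' Pearson correlation of vial-level metric values against the yeast or
#' sucrose percentage of the diet, with the two-sided p-value from the t
#' transform. This is the statistic behind the observation that a
#' sugar-intolerant genotype's development time correlates positively,
#' and its survival negatively, with dietary sucrose. Setting
#' `by_cell = TRUE` correlates diet-cell means instead of vial
#' replicates.
#'
#' @param metrics vial-metric table from [vial_metrics()].
#' @param metric column to correlate (`"pupind"`, `"survival"`,
#'   `"dev_time_h"`, ...).
#' @param axis `"yeast"` or `"sucrose"`.
#' @param by_cell correlate per-diet cell means rather than vials.
#' @return data.frame with `metric`, `axis`, `r`, `p_value`, `n` (finite
#'   points used). `r` is NA with a warning when either side has zero
#'   variance.
#' @export
correlate_metric <- function(metrics, metric,
                             axis = c("yeast", "sucrose"),
                             by_cell = FALSE) {
  axis <- match.arg(axis)
  axis_col <- if (axis == "yeast") "yeast_pct" else "sucrose_pct"
  y <- metrics[[metric]]
  x <- metrics[[axis_col]]
  if (by_cell) {
    cell <- paste(metrics$yeast_pct, metrics$sucrose_pct, sep = "\r")
    y <- tapply(y, cell, mean, na.rm = TRUE)
    x <- tapply(x, cell, function(v) v[1])
    y <- as.numeric(y); x <- as.numeric(x)
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stopf("fewer than 3 finite points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warnf("zero variance: correlation undefined")
    return(data.frame(metric = metric, axis = axis, r = NA_real_,
                      p_value = NA_real_, n = length(x)))
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  data.frame(metric = metric, axis = axis, r = unname(ht$estimate),
             p_value = ht$p.value, n = length(x))
}

#' Omega-squared effect sizes from a factorial ANOVA
#'
#' Estimates, for each term of a fixed-effects ANOVA, the proportion of
#' total variance attributable to the effect:
#' \deqn{\omega^2 = \frac{SS_{effect} - df_{effect}\, MS_{error}}
#'                      {SS_{total} + MS_{error}}}
#' computed from the sequential (Type I) sum-of-squares decomposition,
#' which is orthogonal on the balanced diet grids this package targets; a
#' warning is emitted for unbalanced layouts. The raw estimator is
#' reported alongside a version clamped to `[0, 1]` (the raw estimator is
#' slightly negative about half the time under a null effect, and only
#' the raw version has mean zero there).
#'
#' @param formula model formula, e.g.
#'   `pupind ~ factor(sucrose_pct) * factor(yeast_pct)`.
#' @param data data.frame of replicate-level observations (e.g. from
#'   [vial_metrics()]).
#' @return data.frame with one row per term: `effect`, `df`, `sum_sq`,
#'   `omega_sq_raw`, `omega_sq` (clamped).
#' @export
omega_squared <- function(formula, data) {
  mf <- stats::model.frame(formula, data = data)
  fac <- mf[-1]
  if (any(vapply(fac, function(f) length(unique(f)), 1L) < 2))
    stopf("every factor needs at least 2 levels")
  counts <- table(do.call(interaction, c(fac, drop = TRUE)))
  if (length(unique(as.integer(counts))) > 1)
    warnf("unbalanced layout: sequential SS decomposition is order-dependent")
  fit <- stats::aov(formula, data = data)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  resid_row <- terms == "Residuals"
  if (!any(resid_row))
    stopf("no replication: error mean square undefined")
  ms_error <- tab[resid_row, "Mean Sq"]
  ss_total <- sum(tab[, "Sum Sq"])
  eff <- which(!resid_row)
  raw <- (tab[eff, "Sum Sq"] - tab[eff, "Df"] * ms_error) /
    (ss_total + ms_error)
  data.frame(effect = terms[eff],
             df = tab[eff, "Df"],
             sum_sq = tab[eff, "Sum Sq"],
             omega_sq_raw = raw,
             omega_sq = pmin(pmax(raw, 0), 1),
             row.names = NULL)
}

# ---- diet surfaces ---------------------------------------------------

#' Diet-grid surface of a metric
#'
#' A matrix of values over the yeast x sucrose grid, with yeast levels as
#' rows and sucrose levels as columns.
#'
#' @param yeast_levels,sucrose_levels axis levels (% w/v), strictly
#'   increasing.
#' @param values numeric matrix, `length(yeast_levels)` rows by
#'   `length(sucrose_levels)` columns.
#' @return an object of class `diet_surface`.
#' @export
diet_surface <- function(yeast_levels, sucrose_levels, values) {
  values <- as.matrix(values)
  if (nrow(values) != length(yeast_levels) ||
      ncol(values) != length(sucrose_levels))
    stopf("surface matrix shape does not match axis levels")
  if (any(diff(yeast_levels) <= 0) || any(diff(sucrose_levels) <= 0))
    stopf("axis levels must be strictly increasing")
  dimnames(values) <- list(yeast = as.character(yeast_levels),
                           sucrose = as.character(sucrose_levels))
  structure(list(yeast = yeast_levels, sucrose = sucrose_levels,
                 values = values),
            class = "diet_surface")
}

#' Average a vial metric into a diet surface
#'
#' @param metrics vial-metric table from [vial_metrics()].
#' @param metric column to average per diet cell.
#' @return a [diet_surface()] of per-cell means (vials averaged; cells
#'   with no finite value are NA).
#' @export
metric_surface <- function(metrics, metric = "pupind") {
  ys <- sort(unique(metrics$yeast_pct))
  ss <- sort(unique(metrics$sucrose_pct))
  m <- matrix(NA_real_, length(ys), length(ss))
  for (i in seq_along(ys)) for (j in seq_along(ss)) {
    v <- metrics[[metric]][metrics$yeast_pct == ys[i] &
                             metrics$sucrose_pct == ss[j]]
    v <- v[is.finite(v)]
    if (length(v) > 0) m[i, j] <- mean(v)
  }
  diet_surface(ys, ss, m)
}

#' Difference between two genotype surfaces
#'
#' Cell-wise `a - b` (or `|a - b|`), used to chart where in the diet
#' space one genotype out-performs the other. Missing cells propagate.
#'
#' @param a,b [diet_surface()] objects on identical axes.
#' @param absolute take the absolute difference.
#' @return a [diet_surface()].
#' @export
difference_surface <- function(a, b, absolute = FALSE) {
  stopifnot(inherits(a, "diet_surface"), inherits(b, "diet_surface"))
  if (!identical(a$yeast, b$yeast) || !identical(a$sucrose, b$sucrose))
    stopf("surfaces are on different diet axes")
  d <- a$values - b$values
  if (absolute) d <- abs(d)
  diet_surface(a$yeast, a$sucrose, d)
}

#' Read / write a diet surface as a TSV matrix
#'
#' Rows are yeast levels, columns sucrose levels; the first column holds
#' the yeast level and the header the sucrose levels.
#'
#' @param x a [diet_surface()].
#' @param path file path.
#' @return `write_diet_surface` returns `path` invisibly;
#'   `read_diet_surface` returns a [diet_surface()].
#' @export
write_diet_surface <- function(x, path) {
  stopifnot(inherits(x, "diet_surface"))
  df <- data.frame(yeast_pct = x$yeast, x$values, check.names = FALSE)
  names(df)[-1] <- as.character(x$sucrose)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_diet_surface
#' @export
read_diet_surface <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  diet_surface(df[[1]], as.numeric(names(df)[-1]),
               as.matrix(df[, -1, drop = FALSE]))
}
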