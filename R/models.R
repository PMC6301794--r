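#' Genotype diet-response model for the grid-assay simulator
#'
#' Parameterises how one genotype's larval development time and survival
#' respond to the yeast and sucrose content of the diet. Development time
#' is log-normal around a location that shifts linearly with the two diet
#' axes; survival to pupariation is Bernoulli per larva with a logistic
#' probability in the two axes.
#'
#' @param dev_base_h baseline development-time location in hours, at
#'   0% yeast and 0% sucrose (before clamping at `dev_min_h`).
#' @param dev_sucrose_slope change in the development-time location per
#'   percentage point of sucrose (hours / %); positive for a
#'   sugar-intolerant genotype whose development slows on sugar.
#' @param dev_yeast_slope change per percentage point of yeast
#'   (hours / %); negative, since dietary protein speeds development.
#' @param surv_intercept intercept of the survival logit.
#' @param surv_sucrose_slope survival logit slope per % sucrose
#'   (negative for a sugar-intolerant genotype).
#' @param surv_yeast_slope survival logit slope per % yeast.
#' @param dev_sdlog dispersion of development time (standard deviation on
#'   the log-hours scale); must be >= 0, 0 gives deterministic timing.
#' @param dev_min_h lower clamp on the development-time location (hours);
#'   larvae cannot pupariate faster than this physiological floor.
#' @param label genotype label carried into simulated assay tables.
#'
#' @return an object of class `genotype_diet_model`.
#' @seealso [model_sugar_tolerant()], [model_sugar_intolerant()] for
#'   ready-made parameterisations, [simulate_grid_assay()].
#' @export
genotype_diet_model <- function(dev_base_h,
                                dev_sucrose_slope,
                                dev_yeast_slope,
                                surv_intercept,
                                surv_sucrose_slope,
                                surv_yeast_slope,
                                dev_sdlog,
                                dev_min_h = 26,
                                label = "genotype") {
  if (!is.numeric(dev_sdlog) || length(dev_sdlog) != 1L || dev_sdlog < 0)
    stopf("dev_sdlog must be a single non-negative number")
  if (!is.numeric(dev_base_h) || dev_base_h <= 0)
    stopf("dev_base_h must be positive")
  structure(
    list(dev_base_h = dev_base_h,
         dev_sucrose_slope = dev_sucrose_slope,
         dev_yeast_slope = dev_yeast_slope,
         surv_intercept = surv_intercept,
         surv_sucrose_slope = surv_sucrose_slope,
         surv_yeast_slope = surv_yeast_slope,
         dev_sdlog = dev_sdlog,
         dev_min_h = dev_min_h,
         label = label),
    class = "genotype_diet_model")
}

#' Reference diet-response parameterisations
#'
#' Two invented parameter sets emulating the qualitative reaction norms of
#' a sugar-tolerant dietary generalist (D. simulans-like: development and
#' survival respond to yeast but are indifferent to sucrose up to 20%) and
#' a sugar-intolerant specialist (D. sechellia-like: development slows and
#' survival collapses as dietary sucrose rises, with near-complete
#' lethality at 20% yeast / 20% sucrose).
#'
#' @return a [genotype_diet_model()].
#' @export
model_sugar_tolerant <- function() {
  genotype_diet_model(
    dev_base_h = 170, dev_sucrose_slope = 0, dev_yeast_slope = -4.5,
    surv_intercept = 0.2, surv_sucrose_slope = 0, surv_yeast_slope = 0.16,
    dev_sdlog = 0.12, label = "tolerant")
}

#' @rdname model_sugar_tolerant
#' @export
model_sugar_intolerant <- function() {
  genotype_diet_model(
    dev_base_h = 160, dev_sucrose_slope = 3.5, dev_yeast_slope = -4.0,
    surv_intercept = 1.2, surv_sucrose_slope = -0.35,
    surv_yeast_slope = 0.14,
    dev_sdlog = 0.12, label = "intolerant")
}

#' The diet grid used throughout the package
#'
#' The standard 5 x 5 yeast-by-sucrose grid: baker's yeast at 1.25, 2.5,
#' 5, 10 and 20% w/v crossed with sucrose at 0, 5, 10, 15 and 20% w/v.
#'
#' @return a data.frame with columns `yeast_pct` and `sucrose_pct`
#'   (25 rows).
#' @export
standard_diet_grid <- function() {
  expand.grid(yeast_pct = c(1.25, 2.5, 5, 10, 20),
              sucrose_pct = c(0, 5, 10, 15, 20),
              KEEP.OUT.ATTRS = FALSE)
}

#' The standard pupariation observation schedule
#'
#' Vials are scored every 24 h from 24 h to 408 h after egg laying.
#'
#' @return numeric vector of observation times in hours.
#' @export
standard_obs_times <- function() seq(24, 408, by = 24)

# Location (hours) of the development-time distribution on one diet.
model_dev_location <- function(model, yeast_pct, sucrose_pct) {
  loc <- model$dev_base_h +
    model$dev_sucrose_slope * sucrose_pct +
    model$dev_yeast_slope * yeast_pct
  pmax(loc, model$dev_min_h)
}

# Per-larva survival probability on one diet.
model_survival_prob <- function(model, yeast_pct, sucrose_pct) {
  stats::plogis(model$surv_intercept +
                  model$surv_sucrose_slope * sucrose_pct +
                  model$surv_yeast_slope * yeast_pct)
}
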