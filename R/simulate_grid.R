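#' Simulate a diet-grid pupariation assay
#'
#' Forward-simulates cumulative pupariation counts for replicate vials of
#' larvae across a yeast-by-sucrose diet grid under a
#' [genotype_diet_model()]. Each larva independently survives with the
#' model's logistic probability for its diet and, if it survives,
#' pupariates at a log-normally distributed time; a vial's record is the
#' cumulative count of pupariated larvae at each observation time.
#'
#' @param model a [genotype_diet_model()].
#' @param diets data.frame with columns `yeast_pct`, `sucrose_pct`
#'   (default [standard_diet_grid()]).
#' @param n_reps replicate vials per diet (default 5).
#' @param n_larvae larvae seeded per vial (default 30).
#' @param obs_times strictly increasing observation times in hours
#'   (default [standard_obs_times()]).
#' @param seed integer seed; identical seeds give identical output.
#' @return a [grid_assay()] table.
#' @export
simulate_grid_assay <- function(model,
                                diets = standard_diet_grid(),
                                n_reps = 5,
                                n_larvae = 30,
                                obs_times = standard_obs_times(),
                                seed = NULL) {
  stopifnot(inherits(model, "genotype_diet_model"))
  diets <- as.data.frame(diets)
  if (nrow(diets) == 0) stopf("empty diet list")
  if (!all(c("yeast_pct", "sucrose_pct") %in% names(diets)))
    stopf("diets must have columns yeast_pct and sucrose_pct")
  if (!is_count(n_larvae) || n_larvae < 1) stopf("n_larvae must be > 0")
  if (!is_count(n_reps) || n_reps < 1) stopf("n_reps must be > 0")
  if (length(obs_times) < 1 || any(diff(obs_times) <= 0))
    stopf("obs_times must be strictly increasing")

  with_seed_if(seed, {
    out <- vector("list", nrow(diets) * n_reps)
    i <- 0L
    for (d in seq_len(nrow(diets))) {
      y <- diets$yeast_pct[d]
      s <- diets$sucrose_pct[d]
      p_surv <- model_survival_prob(model, y, s)
      loc <- model_dev_location(model, y, s)
      for (r in seq_len(n_reps)) {
        n_surv <- stats::rbinom(1L, n_larvae, p_surv)
        if (n_surv > 0) {
          # dev_sdlog == 0 degenerates to a point mass at loc
          times <- sort(stats::rlnorm(n_surv, meanlog = log(loc),
                                      sdlog = model$dev_sdlog))
          cum <- findInterval(obs_times, times)
        } else {
          cum <- integer(length(obs_times))
        }
        i <- i + 1L
        out[[i]] <- data.frame(
          genotype = model$label, yeast_pct = y, sucrose_pct = s,
          vial = r, time_h = obs_times, cum_pupae = cum,
          n_larvae = n_larvae)
      }
    }
    grid_assay(do.call(rbind, out))
  })
}
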