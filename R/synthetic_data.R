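#' Synthetic blood PK dataset
#'
#' Generates an observed blood concentration series from biexponential truth
#' with multiplicative lognormal measurement noise:
#' `C_obs(t) = C_true(t) * exp(eps)`, `eps ~ Normal(0, sigma)` with
#' `sigma = sqrt(log(1 + cv^2))` so the empirical coefficient of variation
#' equals `cv`. The generating truth travels with the dataset as attribute
#' `truth`.
#'
#' @param truth list with `A`, `B`, `alpha`, `beta` (concentration units and
#'   1/min).
#' @param times_min sampling schedule; defaults to [blood_sampling_times()].
#' @param cv lognormal coefficient of variation (fraction; 0 = noiseless).
#' @param seed integer seed.
#' @return a [concentration_series()] with attribute `truth`.
#' @examples
#' truth <- list(A = 90, B = 10, alpha = log(2) / 1.6, beta = log(2) / 139.4)
#' s <- make_blood_dataset(truth, cv = 0.1, seed = 1)
#' @export
make_blood_dataset <- function(truth, times_min = blood_sampling_times(),
                               cv = 0.1, seed = 1) {
  stopifnot(all(c("A", "B", "alpha", "beta") %in% names(truth)), cv >= 0)
  set.seed(seed)
  ctrue <- truth$A * exp(-truth$alpha * times_min) +
    truth$B * exp(-truth$beta * times_min)
  obs <- if (cv > 0)
    ctrue * exp(rnorm(length(times_min), 0, lognormal_sigma(cv))) else ctrue
  out <- concentration_series(times_min, obs, tissue = "blood")
  attr(out, "truth") <- truth
  out
}

#' Biodistribution snapshot times
#'
#' Imaging snapshot times (0.5, 1, 2, 3.5 h) plus 24 h to exercise the full
#' simulation window, in minutes.
#' @return numeric vector of minutes.
#' @export
biodistribution_times <- function() c(0.5, 1, 2, 3.5, 24) * 60

#' Synthetic organ biodistribution dataset
#'
#' Forward-simulates the PBPK model under the supplied truth, samples the
#' organ concentration curves at the biodistribution snapshot times, and
#' applies multiplicative lognormal noise per point. Organs reported: heart,
#' liver, spleen, lung, kidney, tumor and blood.
#'
#' @param phys a `physiology` (the truth physiology).
#' @param tp a `transport_params` (the truth kinetics).
#' @param times_min snapshot times; defaults to [biodistribution_times()].
#' @param cv lognormal CV of the measurement noise (0 = noiseless).
#' @param seed integer seed.
#' @return named list of [concentration_series()] (one per tissue, %ID/g;
#'   blood %ID/mL) with attribute `truth = list(phys, tp)`.
#' @export
make_biodistribution_dataset <- function(phys, tp,
                                         times_min = biodistribution_times(),
                                         cv = 0.1, seed = 1) {
  stopifnot(cv >= 0)
  set.seed(seed)
  tissues <- c("heart", "liver", "spleen", "lung", "kidney", "tumor", "blood")
  grid <- sort(unique(c(0, times_min)))
  traj <- pbpk_simulate(phys, tp, times_min = grid)
  conc <- organ_concentrations(traj)
  out <- list()
  for (ti in tissues) {
    v <- conc[conc$tissue == ti, ]
    y <- v$pctID_per_g[match(times_min, v$time_min)]
    if (cv > 0) y <- y * exp(rnorm(length(y), 0, lognormal_sigma(cv)))
    out[[ti]] <- concentration_series(times_min, y, tissue = ti)
  }
  attr(out, "truth") <- list(phys = phys, tp = tp)
  out
}

#' Synthetic virtual-mouse cohort
#'
#' Draws a cohort per [population_spec()]: body weights uniform over the
#' population range, per-mouse transport parameters jittered lognormally at
#' the interindividual CV. Each mouse record carries its own truth.
#'
#' @param pop a [population_spec()].
#' @param phys_template reference `physiology`.
#' @param tp typical `transport_params`.
#' @return list of per-mouse records: `id`, `weight_g`, `phys`, `tp`.
#' @examples
#' cohort <- make_cohort(population_spec(n_mice = 5, seed = 2),
#'                       mouse_physiology(), default_transport_params())
#' vapply(cohort, `[[`, numeric(1), "weight_g")
#' @export
make_cohort <- function(pop, phys_template = mouse_physiology(),
                        tp = default_transport_params()) {
  stopifnot(inherits(pop, "population_spec"))
  set.seed(pop$seed)
  lapply(seq_len(pop$n_mice), function(i) {
    mouse <- draw_mouse(phys_template, tp, pop)
    c(list(id = i), mouse)
  })
}
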