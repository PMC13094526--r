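ORGANS <- c("heart", "liver", "spleen", "lung", "kidney", "tumor", "rest")

#' Load or scale a mouse physiology
#'
#' Reads the reference physiology table (organ volumes, regional blood flows,
#' vascular volume fractions, blood volume, cardiac output for a 20 g mouse)
#' and optionally rescales every volume and flow linearly to a different body
#' weight.
#'
#' @param body_weight_g target body weight in grams; `NULL` keeps the
#'   reference weight.
#' @param file path to a physiology JSON file; defaults to the shipped
#'   20 g reference table.
#' @return object of class `physiology`: list with `body_weight_g`,
#'   `cardiac_output_mL_min`, `blood_volume_mL` and per-organ `volume_mL`,
#'   `flow_mL_min`, `vascular_fraction` vectors named by organ.
#' @export
mouse_physiology <- function(body_weight_g = NULL,
                             file = system.file("extdata",
                                                "physiology-mouse20g.json",
                                                package = "radnc")) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  org <- raw$organs
  phys <- list(
    body_weight_g = raw$body_weight_g,
    cardiac_output_mL_min = raw$cardiac_output_mL_min,
    blood_volume_mL = raw$blood_volume_mL,
    volume_mL = vapply(ORGANS, function(o) org[[o]]$volume_mL, numeric(1)),
    flow_mL_min = vapply(ORGANS, function(o) org[[o]]$flow_mL_min, numeric(1)),
    vascular_fraction = vapply(ORGANS, function(o) org[[o]]$vascular_fraction,
                               numeric(1))
  )
  class(phys) <- "physiology"
  if (!is.null(body_weight_g)) phys <- scale_physiology(phys, body_weight_g)
  validate_physiology(phys)
  phys
}

#' Rescale a physiology to a new body weight
#'
#' Volumes, flows, blood volume and cardiac output scale proportionally to
#' body weight; vascular fractions are weight-invariant.
#'
#' @param phys a `physiology`.
#' @param body_weight_g new body weight (g).
#' @return rescaled `physiology`.
#' @export
scale_physiology <- function(phys, body_weight_g) {
  stopifnot(inherits(phys, "physiology"), body_weight_g > 0)
  s <- body_weight_g / phys$body_weight_g
  phys$body_weight_g <- body_weight_g
  phys$cardiac_output_mL_min <- phys$cardiac_output_mL_min * s
  phys$blood_volume_mL <- phys$blood_volume_mL * s
  phys$volume_mL <- phys$volume_mL * s
  phys$flow_mL_min <- phys$flow_mL_min * s
  phys
}

validate_physiology <- function(phys) {
  if (any(phys$volume_mL <= 0) || phys$blood_volume_mL <= 0)
    stop("all volumes must be > 0")
  if (any(phys$vascular_fraction <= 0 | phys$vascular_fraction >= 1))
    stop("vascular fractions must lie in (0, 1)")
  if (sum(phys$flow_mL_min) > phys$cardiac_output_mL_min * (1 + 1e-9))
    stop("sum of organ flows exceeds cardiac output")
  invisible(phys)
}

#' Load nanocluster transport parameters
#'
#' Per-organ permeability-surface-area products (PA), tissue:blood partition
#' coefficients (K), irreversible sequestration rate constants (liver/spleen
#' reticuloendothelial trapping, tumor receptor-mediated retention), renal
#' clearance, and the tumor uptake enhancement multiplier that represents
#' receptor targeting.
#'
#' @param file path to a transport JSON file; defaults to the shipped
#'   non-targeted defaults.
#' @return object of class `transport_params`: list with named vectors
#'   `PA_mL_min`, `K`, `k_seq_min` over organs, scalars
#'   `renal_clearance_CL_mL_min` and `tumor_uptake_enhancement`.
#' @export
default_transport_params <- function(file = system.file("extdata",
                                                        "transport-default.json",
                                                        package = "radnc")) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  tp <- list(
    PA_mL_min = unlist(raw$permeability_PA_mL_min)[ORGANS],
    K = unlist(raw$partition_K)[ORGANS],
    k_seq_min = unlist(raw$sequestration_k_min)[ORGANS],
    renal_clearance_CL_mL_min = raw$renal_clearance_CL_mL_min,
    tumor_uptake_enhancement = raw$tumor_uptake_enhancement
  )
  class(tp) <- "transport_params"
  validate_transport(tp)
  tp
}

validate_transport <- function(tp) {
  if (any(tp$PA_mL_min < 0) || any(tp$K < 0) || any(tp$k_seq_min < 0) ||
      tp$renal_clearance_CL_mL_min < 0 || tp$tumor_uptake_enhancement < 0)
    stop("all transport parameters must be >= 0")
  if (any(tp$K[tp$PA_mL_min > 0] == 0))
    stop("partition K must be > 0 wherever PA > 0")
  invisible(tp)
}

#' Apply the tumor targeting enhancement
#'
#' Returns a copy of the transport parameters with tumor PA and tumor
#' sequestration multiplied by the enhancement factor, modelling the
#' receptor-targeted probe as the plain probe with linearly enhanced tumor
#' uptake.
#'
#' @param tp a `transport_params`.
#' @param factor multiplier; defaults to the set's own
#'   `tumor_uptake_enhancement`.
#' @return modified `transport_params` (with `tumor_uptake_enhancement`
#'   reset to 1 so the factor is not applied twice).
#' @export
apply_tumor_enhancement <- function(tp, factor = tp$tumor_uptake_enhancement) {
  stopifnot(inherits(tp, "transport_params"), factor >= 0)
  tp$PA_mL_min["tumor"] <- tp$PA_mL_min["tumor"] * factor
  tp$k_seq_min["tumor"] <- tp$k_seq_min["tumor"] * factor
  tp$tumor_uptake_enhancement <- 1
  tp
}

#' Build the PBPK right-hand side
#'
#' Eight compartments: a single well-mixed blood pool plus seven organs
#' (heart, liver, spleen, lung, kidney, tumor, rest), each split into a
#' vascular and a tissue sub-compartment with membrane-limited exchange.
#' For organ i with amounts in %ID and concentrations = amount/volume:
#'
#' \deqn{dA_{vas,i}/dt = Q_i (C_{blood} - C_{vas,i}) - PA_i (C_{vas,i} - C_{tis,i}/K_i)}
#' \deqn{dA_{tis,i}/dt = PA_i (C_{vas,i} - C_{tis,i}/K_i) - k_{seq,i} A_{tis,i}}
#'
#' Sequestered material accumulates in a bound pool inside the tissue. Blood
#' receives all vascular returns and loses `CL * C_blood` to a cumulative
#' urine sink. Total amount (all sub-compartments + urine) is conserved.
#'
#' @param phys a `physiology`.
#' @param tp a `transport_params`.
#' @return object of class `pbpk_model`: list with the deSolve-compatible
#'   `rhs(t, y, parms)`, the state template `state0`, and the inputs.
#' @export
pbpk_model <- function(phys, tp) {
  validate_physiology(phys)
  validate_transport(tp)
  V_vas <- phys$vascular_fraction * phys$volume_mL
  V_tis <- (1 - phys$vascular_fraction) * phys$volume_mL
  Q <- phys$flow_mL_min
  PA <- tp$PA_mL_min
  K <- tp$K
  kseq <- tp$k_seq_min
  CL <- tp$renal_clearance_CL_mL_min
  Vb <- phys$blood_volume_mL
  n <- length(ORGANS)
  i_vas <- 2 + seq_len(n)
  i_tis <- 2 + n + seq_len(n)
  i_bnd <- 2 + 2 * n + seq_len(n)

  rhs <- function(t, y, parms) {
    Cb <- y[1] / Vb
    Cvas <- y[i_vas] / V_vas
    Ctis <- y[i_tis] / V_tis
    exch <- PA * (Cvas - Ctis / K)
    dvas <- Q * (Cb - Cvas) - exch
    dtis <- exch - kseq * y[i_tis]
    dbnd <- kseq * y[i_tis]
    dblood <- sum(Q * (Cvas - Cb)) - CL * Cb
    durine <- CL * Cb
    list(c(dblood, durine, dvas, dtis, dbnd))
  }
  state0 <- setNames(
    numeric(2 + 3 * n),
    c("blood", "urine", paste0("vas_", ORGANS), paste0("tis_", ORGANS),
      paste0("bnd_", ORGANS))
  )
  structure(list(rhs = rhs, state0 = state0, phys = phys, tp = tp),
            class = "pbpk_model")
}

#' Simulate nanocluster disposition
#'
#' Solves the PBPK system with the full dose placed in blood at time zero,
#' using a stiff-capable integrator (lsoda, rtol 1e-8, atol 1e-10 %ID).
#'
#' @param phys a `physiology` (or a `pbpk_model`, in which case `tp` is
#'   ignored).
#' @param tp a `transport_params`.
#' @param dose_pctID injected dose, default 100 %ID.
#' @param times_min output time grid in minutes (default 0-1440, i.e. 24 h).
#' @return object of class `pbpk_trajectory`: the deSolve matrix as a data
#'   frame (columns `time`, `blood`, `urine`, `vas_*`, `tis_*`, `bnd_*`, all
#'   amounts in %ID) with the model attached as an attribute.
#' @examples
#' traj <- pbpk_simulate(mouse_physiology(), default_transport_params(),
#'                       times_min = seq(0, 240, by = 10))
#' head(organ_concentrations(traj))
#' @export
pbpk_simulate <- function(phys, tp = NULL, dose_pctID = 100,
                          times_min = seq(0, 1440, by = 5)) {
  model <- if (inherits(phys, "pbpk_model")) phys else pbpk_model(phys, tp)
  stopifnot(dose_pctID > 0, all(times_min >= 0), !is.unsorted(times_min))
  y0 <- model$state0
  y0["blood"] <- dose_pctID
  # the bolus is given at t = 0 regardless of the requested output grid
  prepend0 <- times_min[1] > 0
  times <- if (prepend0) c(0, times_min) else times_min
  sol <- deSolve::lsoda(y = y0, times = times, func = model$rhs,
                        parms = NULL, rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0)
    stop("PBPK solver failure (istate = ", attr(sol, "istate")[1],
         "); parameters: CL = ", model$tp$renal_clearance_CL_mL_min,
         ", PA = [", paste(signif(model$tp$PA_mL_min, 3), collapse = ", "), "]")
  out <- as.data.frame(unclass(sol))
  if (prepend0) out <- out[-1, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "model") <- model
  class(out) <- c("pbpk_trajectory", "data.frame")
  out
}

#' Per-tissue concentrations from a trajectory
#'
#' Collapses vascular + tissue + bound amounts per organ and divides by organ
#' mass (1 g = 1 mL assumed) to give %ID/g; blood is reported as %ID/mL.
#'
#' @param traj a `pbpk_trajectory`.
#' @return long data frame with columns `time_min`, `tissue`, `pctID`,
#'   `pctID_per_g` (urine appears with `pctID` only).
#' @export
organ_concentrations <- function(traj) {
  stopifnot(inherits(traj, "pbpk_trajectory"))
  model <- attr(traj, "model")
  phys <- model$phys
  pieces <- lapply(ORGANS, function(o) {
    amt <- traj[[paste0("vas_", o)]] + traj[[paste0("tis_", o)]] +
      traj[[paste0("bnd_", o)]]
    data.frame(time_min = traj$time, tissue = o, pctID = amt,
               pctID_per_g = amt / phys$volume_mL[[o]])
  })
  blood <- data.frame(time_min = traj$time, tissue = "blood",
                      pctID = traj$blood,
                      pctID_per_g = traj$blood / phys$blood_volume_mL)
  urine <- data.frame(time_min = traj$time, tissue = "urine",
                      pctID = traj$urine, pctID_per_g = NA_real_)
  do.call(rbind, c(pieces, list(blood, urine)))
}

#' Total amount accounted for at each time
#'
#' @param traj a `pbpk_trajectory`.
#' @return numeric vector: blood + urine + all organ sub-compartments, %ID.
#' @export
mass_balance <- function(traj) {
  stopifnot(inherits(traj, "pbpk_trajectory"))
  cols <- setdiff(names(traj), "time")
  rowSums(as.data.frame(traj)[, cols, drop = FALSE])
}

#' Specify a virtual mouse population
#'
#' @param n_mice number of virtual mice (>= 2).
#' @param weight_range_g two-element interval of body weights; must lie
#'   within (10, 40) g.
#' @param interindividual_cv lognormal coefficient of variation applied to
#'   every transport parameter per mouse (fraction, >= 0).
#' @param seed integer seed.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(n_mice = 500, weight_range_g = c(15, 25),
                            interindividual_cv = 0.2, seed = 1) {
  stopifnot(n_mice >= 2, length(weight_range_g) == 2,
            weight_range_g[1] <= weight_range_g[2],
            weight_range_g[1] > 10, weight_range_g[2] < 40,
            interindividual_cv >= 0)
  structure(list(n_mice = as.integer(n_mice),
                 weight_range_g = as.numeric(weight_range_g),
                 interindividual_cv = interindividual_cv,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# internal: draw one virtual mouse (weight-scaled physiology + jittered
# transport); used by population_simulate and make_cohort
draw_mouse <- function(phys_template, tp, pop) {
  w <- runif(1, pop$weight_range_g[1], pop$weight_range_g[2])
  phys_i <- scale_physiology(phys_template, w)
  tp_i <- tp
  if (pop$interindividual_cv > 0) {
    sig <- lognormal_sigma(pop$interindividual_cv)
    jit <- function(x) x * exp(rnorm(length(x), 0, sig))
    tp_i$PA_mL_min <- jit(tp_i$PA_mL_min)
    tp_i$K <- jit(tp_i$K)
    tp_i$k_seq_min <- jit(tp_i$k_seq_min)
    tp_i$renal_clearance_CL_mL_min <- jit(tp_i$renal_clearance_CL_mL_min)
  }
  list(weight_g = w, phys = phys_i, tp = tp_i)
}

#' Virtual-population simulation with prediction bands
#'
#' Draws a cohort of virtual mice (body weight uniform over the population
#' range, organ volumes and flows scaled proportionally, transport
#' parameters jittered lognormally at the stated CV), simulates each, and
#' summarises per-tissue concentration trajectories as the median and
#' 2.5/97.5 percentile band - the 95% prediction interval.
#'
#' @param phys_template reference `physiology` (scaled per mouse).
#' @param tp `transport_params` for the typical mouse.
#' @param pop a [population_spec()].
#' @param times_min output grid (minutes).
#' @return data frame with columns `time_min`, `tissue`, `p2.5`, `median`,
#'   `p97.5` (all %ID/g; blood in %ID/mL, urine in %ID).
#' @export
population_simulate <- function(phys_template, tp, pop,
                                times_min = seq(0, 1440, by = 15)) {
  stopifnot(inherits(pop, "population_spec"))
  set.seed(pop$seed)
  tissues <- c(ORGANS, "blood", "urine")
  acc <- array(NA_real_, dim = c(length(times_min), length(tissues), pop$n_mice),
               dimnames = list(NULL, tissues, NULL))
  for (m in seq_len(pop$n_mice)) {
    mouse <- draw_mouse(phys_template, tp, pop)
    traj <- pbpk_simulate(mouse$phys, mouse$tp, times_min = times_min)
    conc <- organ_concentrations(traj)
    for (ti in tissues) {
      v <- conc[conc$tissue == ti, ]
      acc[, ti, m] <- if (ti == "urine") v$pctID else v$pctID_per_g
    }
  }
  out <- expand.grid(time_min = times_min, tissue = tissues,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  qs <- apply(acc, c(1, 2), quantile, probs = c(0.025, 0.5, 0.975))
  out$p2.5 <- as.vector(qs[1, , ])
  out$median <- as.vector(qs[2, , ])
  out$p97.5 <- as.vector(qs[3, , ])
  out
}

#' Mean fold error between predicted and observed PK metrics
#'
#' Fold error is the ratio predicted/observed per metric; the conventional
#' PBPK acceptability band is 0.5 to 2.0 (inclusive at both ends).
#'
#' @param predicted,observed named numeric vectors with matching names;
#'   observed values must be > 0.
#' @param band acceptability interval, default `c(0.5, 2)`.
#' @return list with `fold_errors` (named vector) and `pass` (all within the
#'   band).
#' @examples
#' mean_fold_error(c(AUC = 120, Cmax = 9), c(AUC = 100, Cmax = 10))
#' @export
mean_fold_error <- function(predicted, observed, band = c(0.5, 2)) {
  if (is.null(names(predicted)) || is.null(names(observed)))
    stop("predicted and observed must be named")
  missing <- setdiff(names(observed), names(predicted))
  if (length(missing)) stop("missing predicted metric: ",
                            paste(missing, collapse = ", "))
  if (any(observed <= 0)) stop("observed metrics must be > 0")
  fe <- predicted[names(observed)] / observed
  list(fold_errors = fe, pass = all(fe >= band[1] & fe <= band[2]))
}
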