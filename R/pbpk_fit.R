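# map a fit-parameter name ("renal_CL", "PA.liver", "K.tumor",
# "k_seq.tumor") onto a transport_params object
set_transport_param <- function(tp, name, value) {
  if (name == "renal_CL") {
    tp$renal_clearance_CL_mL_min <- value
  } else {
    parts <- strsplit(name, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[2] %in% ORGANS)
      stop("unknown transport parameter: ", name)
    field <- switch(parts[1],
                    PA = "PA_mL_min", K = "K", k_seq = "k_seq_min",
                    stop("unknown transport parameter: ", name))
    tp[[field]][parts[2]] <- value
  }
  tp
}

get_transport_param <- function(tp, name) {
  if (name == "renal_CL") return(tp$renal_clearance_CL_mL_min)
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  field <- switch(parts[1], PA = "PA_mL_min", K = "K", k_seq = "k_seq_min",
                  stop("unknown transport parameter: ", name))
  unname(tp[[field]][parts[2]])
}

#' Fit transport parameters to observed biodistribution data
#'
#' Bounded nonlinear least squares on log-transformed transport parameters,
#' minimising log-scale residuals between simulated and observed tissue
#' concentrations across all supplied series. Parameters are named
#' `"renal_CL"`, `"PA.<organ>"`, `"K.<organ>"` or `"k_seq.<organ>"`.
#'
#' Structural identifiability is checked before fitting: a parameter tied to
#' an organ whose concentration series is absent from `observed` is flagged
#' (and, when every observation comes from a single tissue, the whole fit is
#' flagged) in the `non_identifiable` field rather than raising an error.
#'
#' @param observed named list of [concentration_series()], keyed by tissue
#'   (organ names and/or `"blood"`); at least 2 tissues with >= 4 time points
#'   each are recommended.
#' @param phys the `physiology` the data were generated under.
#' @param init starting `transport_params`.
#' @param fit_params character vector of parameter names to optimise.
#' @param dose_pctID injected dose (default 100 %ID).
#' @param restarts maximum number of Levenberg-Marquardt restarts (each
#'   restart resets the trust region; restarting stops as soon as the
#'   deviance no longer improves).
#' @param control a [minpack.lm::nls.lm.control()] list for each LM run.
#' @return object of class `pbpk_fit`: list with `tp` (fitted
#'   `transport_params`), `estimates` (named vector), `converged`,
#'   `non_identifiable` (character), `residual_ss`, `message`.
#' @export
fit_transport_params <- function(observed, phys, init,
                                 fit_params = c("renal_CL", "PA.liver",
                                                "PA.kidney", "PA.tumor",
                                                "k_seq.tumor"),
                                 dose_pctID = 100, restarts = 8,
                                 control = minpack.lm::nls.lm.control(
                                   maxiter = 300, ftol = 1e-12,
                                   ptol = 1e-12)) {
  stopifnot(is.list(observed), length(observed) >= 1,
            inherits(phys, "physiology"), inherits(init, "transport_params"))
  tissues <- names(observed)
  if (is.null(tissues) || any(!nzchar(tissues)))
    stop("observed must be a named list keyed by tissue")
  bad <- setdiff(tissues, c(ORGANS, "blood"))
  if (length(bad)) stop("unknown tissue in observed: ", paste(bad, collapse = ", "))

  non_ident <- character(0)
  fit_organs <- vapply(strsplit(fit_params, ".", fixed = TRUE), function(p)
    if (length(p) == 2) p[2] else NA_character_, character(1))
  for (i in seq_along(fit_params)) {
    if (!is.na(fit_organs[i]) && !fit_organs[i] %in% tissues)
      non_ident <- c(non_ident, fit_params[i])
  }
  if (length(unique(tissues)) < 2) {
    warning("all observations come from a single tissue; the fit is ",
            "structurally non-identifiable")
    non_ident <- unique(c(non_ident, fit_params))
  }

  all_times <- sort(unique(c(0, unlist(lapply(observed, `[[`, "time_min")))))
  obs_vec <- unlist(lapply(observed, `[[`, "conc"))
  idx <- lapply(observed, function(s) match(s$time_min, all_times))

  predict_fn <- function(tp) {
    traj <- pbpk_simulate(phys, tp, dose_pctID = dose_pctID,
                          times_min = all_times)
    conc <- organ_concentrations(traj)
    unlist(lapply(seq_along(observed), function(k) {
      v <- conc[conc$tissue == tissues[k], "pctID_per_g"]
      v[idx[[k]]]
    }))
  }

  p0 <- log(pmax(vapply(fit_params, get_transport_param, numeric(1),
                        tp = init), 1e-8))
  resid_fn <- function(p) {
    tp <- init
    for (i in seq_along(fit_params))
      tp <- set_transport_param(tp, fit_params[i], exp(p[i]))
    pred <- predict_fn(tp)
    log(pmax(pred, 1e-9)) - log(pmax(obs_vec, 1e-9))
  }
  # Levenberg-Marquardt with restarts: a fresh start resets the trust
  # region, which reliably escapes the premature ptol stops this landscape
  # produces in its curved valleys
  lo <- rep(log(1e-6), length(p0))
  hi <- rep(log(1e3), length(p0))
  fit <- minpack.lm::nls.lm(par = p0, lower = lo, upper = hi, fn = resid_fn,
                            control = control)
  for (r in seq_len(restarts)) {
    refit <- minpack.lm::nls.lm(par = fit$par, lower = lo, upper = hi,
                                fn = resid_fn, control = control)
    improved <- refit$deviance < fit$deviance * (1 - 1e-10)
    fit <- refit
    if (!improved) break
  }
  est <- setNames(exp(fit$par), fit_params)
  tp_fit <- init
  for (i in seq_along(fit_params))
    tp_fit <- set_transport_param(tp_fit, fit_params[i], est[[i]])
  structure(
    list(tp = tp_fit, estimates = est, converged = fit$info %in% 1:4,
         non_identifiable = non_ident, residual_ss = fit$deviance,
         message = fit$message),
    class = "pbpk_fit"
  )
}

#' @export
print.pbpk_fit <- function(x, ...) {
  cat("<pbpk_fit>", if (!x$converged) "(NOT converged)", "\n")
  print(signif(x$estimates, 4))
  if (length(x$non_identifiable))
    cat("  non-identifiable:", paste(x$non_identifiable, collapse = ", "), "\n")
  invisible(x)
}

#' Exposure metrics for one tissue of a PBPK trajectory
#'
#' Trapezoidal AUC over `[0, t_end]` and the maximum concentration of a
#' simulated tissue curve, used for fold-error validation of the model.
#'
#' @param traj a `pbpk_trajectory`.
#' @param tissue tissue name (organ or `"blood"`).
#' @param t_end_min upper AUC limit in minutes (default 240, i.e. the 4 h
#'   window used for tumor exposure comparisons).
#' @return named vector `c(AUC = ..., Cmax = ...)` in %ID/g * min and %ID/g.
#' @export
pbpk_exposure <- function(traj, tissue, t_end_min = 240) {
  conc <- organ_concentrations(traj)
  v <- conc[conc$tissue == tissue & conc$time_min <= t_end_min + 1e-9, ]
  if (nrow(v) < 2) stop("trajectory does not cover the requested window")
  tm <- v$time_min
  y <- v$pctID_per_g
  c(AUC = sum(diff(tm) * (head(y, -1) + tail(y, -1)) / 2), Cmax = max(y))
}
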