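# shared fixtures, built in code

# printed half-life pairs for the targeted (RGD) and plain probes
rgd_truth <- function() list(A = 90, B = 10,
                             alpha = log(2) / 1.6, beta = log(2) / 139.4)
plain_truth <- function() list(A = 90, B = 10,
                               alpha = log(2) / 2.7, beta = log(2) / 65.2)

# toy stopping model with linear range R(E) = E um in every medium
toy_stopping <- function(a = 1, p = 1) {
  structure(
    data.frame(
      kind = rep(c("alpha", "recoil", "beta"), each = 2),
      material = rep(c("water", "gold"), 3),
      a = a, p = p, valid_lo = 1e-6, valid_hi = 100
    ),
    class = c("stopping_model", "data.frame")
  )
}

# single alpha-emitter chain: A -> stable
toy_alpha_chain <- function(energy_keV = 1000, half_life_s = 1) {
  decay_chain(list(
    nuclide("A", half_life_s,
            list(emission_spec("alpha", energy_keV),
                 emission_spec("recoil", energy_keV * 4 / 207)),
            mass_number = 211),
    nuclide("Astar", Inf, mass_number = 207)
  ))
}

# lognormally jittered transport parameters for robustness sweeps
jitter_transport <- function(tp, cv = 0.5) {
  sig <- sqrt(log(1 + cv^2))
  jit <- function(x) x * exp(rnorm(length(x), 0, sig))
  tp$PA_mL_min <- jit(tp$PA_mL_min)
  tp$K <- jit(tp$K)
  tp$k_seq_min <- jit(tp$k_seq_min)
  tp$renal_clearance_CL_mL_min <- jit(tp$renal_clearance_CL_mL_min)
  tp
}
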