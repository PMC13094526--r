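#' Construct a nuclide
#'
#' A nuclide bundles a half-life with its per-decay emission list. Stable
#' nuclides carry an infinite half-life and an empty emission list.
#'
#' @param name text identifier, e.g. `"Ra-223"`.
#' @param half_life_s half-life in seconds; `Inf` (or `NULL`) for stable.
#' @param emissions list of emission specs created with [emission_spec()].
#' @param mass_number integer mass number (used for recoil kinematics).
#' @param gamma_energy_keV mean photon (gamma + X-ray) energy emitted per
#'   decay, in keV. Not transported; only used as an optional term in the
#'   dosimetry energy denominator.
#' @return an object of class `nuclide`.
#' @export
nuclide <- function(name, half_life_s, emissions = list(), mass_number = NA_integer_,
                    gamma_energy_keV = 0) {
  if (is.null(half_life_s)) half_life_s <- Inf
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(half_life_s) || length(half_life_s) != 1L || half_life_s <= 0)
    stop("half_life_s must be a single positive number (Inf for stable)")
  if (is.finite(half_life_s) == FALSE && length(emissions) > 0)
    stop("stable nuclides must have an empty emission list")
  structure(
    list(name = name, half_life_s = half_life_s, emissions = emissions,
         mass_number = as.integer(mass_number),
         gamma_energy_keV = gamma_energy_keV),
    class = "nuclide"
  )
}

#' Construct an emission specification
#'
#' @param kind one of `"alpha"`, `"beta"`, `"recoil"`. Beta energies are mean
#'   spectral energies; recoil entries describe the daughter nucleus set in
#'   motion by an alpha emission.
#' @param energy_keV emission energy in keV (must be >= 0).
#' @param probability emission probability per decay, in (0, 1].
#' @return an object of class `emission_spec`.
#' @export
emission_spec <- function(kind, energy_keV, probability = 1) {
  kind <- match.arg(kind, c("alpha", "beta", "recoil"))
  if (!is.numeric(energy_keV) || energy_keV < 0) stop("energy_keV must be >= 0")
  if (!is.numeric(probability) || probability <= 0 || probability > 1)
    stop("probability must be in (0, 1]")
  structure(list(kind = kind, energy_keV = energy_keV, probability = probability),
            class = "emission_spec")
}

#' Construct a linear decay chain
#'
#' The chain is ordered from the parent to a stable terminus and must be
#' strictly linear (single branch). Minor branches below a percent, such as
#' the Bi-211 beta branch, are folded into the main path.
#'
#' @param nuclides list of [nuclide()] objects, parent first, stable last.
#' @return an object of class `decay_chain`.
#' @export
decay_chain <- function(nuclides) {
  stopifnot(is.list(nuclides), length(nuclides) >= 1L)
  ok <- vapply(nuclides, inherits, logical(1), "nuclide")
  if (!all(ok)) stop("all chain members must be nuclide objects")
  n <- length(nuclides)
  last <- nuclides[[n]]
  if (is.finite(last$half_life_s))
    stop("the last chain member must be stable (infinite half-life)")
  if (n > 1L) {
    radio <- nuclides[seq_len(n - 1L)]
    if (any(!vapply(radio, function(x) is.finite(x$half_life_s), logical(1))))
      stop("only the terminal chain member may be stable")
  }
  structure(list(nuclides = nuclides), class = "decay_chain")
}

#' @export
print.decay_chain <- function(x, ...) {
  nm <- vapply(x$nuclides, `[[`, character(1), "name")
  cat("<decay_chain> ", paste(nm, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

chain_names <- function(chain) vapply(chain$nuclides, `[[`, character(1), "name")

chain_lambdas <- function(chain) {
  hl <- vapply(chain$nuclides, `[[`, numeric(1), "half_life_s")
  ifelse(is.finite(hl), log(2) / hl, 0)
}

#' Load the Ra-223 decay chain
#'
#' Reads the nuclear-data file shipped with the package (half-lives,
#' main-branch alpha energies, mean beta energies, mean per-decay photon
#' energies) and attaches the kinematic recoil emission to every alpha decay:
#' the daughter nucleus receives `E_alpha * m_alpha / m_daughter`, evaluated
#' with mass numbers, which lands in the 100-200 keV window for the whole
#' chain.
#'
#' @param file path to a chain JSON file; defaults to the shipped
#'   `chain-ra223.json`.
#' @return a [decay_chain()] for
#'   Ra-223 -> Rn-219 -> Po-215 -> Pb-211 -> Bi-211 -> Tl-207 -> Pb-207.
#' @examples
#' ch <- ra223_chain()
#' emissions_per_chain_decay(ch)
#' @export
ra223_chain <- function(file = system.file("extdata", "chain-ra223.json",
                                           package = "radnc")) {
  raw <- jsonlite::read_json(file, simplifyVector = FALSE)
  entries <- raw$nuclides
  nucs <- vector("list", length(entries))
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    ems <- lapply(e$emissions, function(s)
      emission_spec(s$kind, s$energy_keV, s$probability))
    # attach recoil partner for each alpha emission: daughter is entry i+1
    alpha_idx <- which(vapply(ems, function(s) s$kind == "alpha", logical(1)))
    if (length(alpha_idx) > 0) {
      if (i == length(entries)) stop("alpha emitter cannot be the chain terminus")
      A_daughter <- entries[[i + 1L]]$mass_number
      for (j in alpha_idx) {
        ems[[length(ems) + 1L]] <- emission_spec(
          "recoil",
          energy_keV = ems[[j]]$energy_keV * 4 / A_daughter,
          probability = ems[[j]]$probability
        )
      }
    }
    hl <- e$half_life_s
    nucs[[i]] <- nuclide(e$name, if (is.null(hl)) Inf else hl, ems,
                         mass_number = e$mass_number,
                         gamma_energy_keV = e$gamma_energy_keV)
  }
  decay_chain(nucs)
}

#' Bateman solution for a linear decay chain
#'
#' Evaluates the closed-form Bateman solution for every chain member at the
#' requested times. Atom number is conserved: for a chain ending in a stable
#' nuclide the column sums equal `sum(n0)` at every time.
#'
#' Near-degenerate decay constants (relative difference below 1e-9) make the
#' closed form numerically singular; when `perturb_degenerate = TRUE` (the
#' default) the later constant is nudged by 1e-6 relative with a warning,
#' otherwise an error is raised.
#'
#' @param chain a [decay_chain()].
#' @param n0 initial atom counts: either a single number (all atoms in the
#'   parent) or a named vector over chain members.
#' @param t vector of times in seconds (>= 0).
#' @param perturb_degenerate perturb near-equal decay constants instead of
#'   erroring.
#' @return a data frame of class `activity_table` with columns `time_s`,
#'   `<nuclide>_atoms` and `<nuclide>_Bq` for each chain member
#'   (activity = lambda * atoms; zero for the stable terminus).
#' @examples
#' ch <- ra223_chain()
#' bateman_atoms(ch, n0 = 1e9, t = c(0, 3600, 86400))
#' @export
bateman_atoms <- function(chain, n0, t, perturb_degenerate = TRUE) {
  stopifnot(inherits(chain, "decay_chain"))
  if (any(t < 0)) stop("t must be >= 0")
  nm <- chain_names(chain)
  n <- length(nm)
  if (is.null(names(n0))) {
    if (length(n0) == 1L) {
      n0 <- setNames(c(n0, rep(0, n - 1L)), nm)
    } else if (length(n0) == n) {
      n0 <- setNames(as.numeric(n0), nm)
    } else stop("n0 must be a scalar, a full-length vector, or named")
  } else {
    bad <- setdiff(names(n0), nm)
    if (length(bad)) stop("unknown nuclide in n0: ", paste(bad, collapse = ", "))
    full <- setNames(rep(0, n), nm)
    full[names(n0)] <- n0
    n0 <- full
  }
  if (any(n0 < 0)) stop("n0 must be non-negative")

  lam <- chain_lambdas(chain)
  # resolve degenerate pairs among all members (stable lambda = 0 is unique)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    denom <- max(abs(lam[i]), abs(lam[j]))
    if (denom > 0 && abs(lam[i] - lam[j]) / denom < 1e-9) {
      if (!perturb_degenerate)
        stop("numerically degenerate decay constants for ", nm[i], " and ", nm[j])
      warning("perturbing near-degenerate decay constant of ", nm[j],
              " by 1e-6 relative")
      lam[j] <- lam[j] * (1 + 1e-6)
    }
  }

  atoms <- matrix(0, nrow = length(t), ncol = n, dimnames = list(NULL, nm))
  for (j in seq_len(n)) {
    if (n0[j] == 0) next
    for (i in j:n) {
      prod_lam <- if (i > j) prod(lam[j:(i - 1L)]) else 1
      ks <- j:i
      s <- 0
      for (k in ks) {
        den <- prod(lam[setdiff(ks, k)] - lam[k])
        if (i == j) den <- 1
        s <- s + exp(-lam[k] * t) / den
      }
      atoms[, i] <- atoms[, i] + n0[j] * prod_lam * s
    }
  }
  act <- sweep(atoms, 2, lam, `*`)
  out <- data.frame(time_s = t, check.names = FALSE)
  for (i in seq_len(n)) out[[paste0(nm[i], "_atoms")]] <- atoms[, i]
  for (i in seq_len(n)) out[[paste0(nm[i], "_Bq")]] <- act[, i]
  class(out) <- c("activity_table", "data.frame")
  out
}

#' Decay-correct an activity
#'
#' Applies `A(dt) = A0 * 2^(-dt / t_half)`. A negative `dt` back-corrects an
#' activity to an earlier reference time, as done when normalising
#' gamma-counter measurements to injection time.
#'
#' @param activity0 activity at the reference time (any unit; the unit passes
#'   through).
#' @param nuclide a [nuclide()] object, or the name of a member of the
#'   Ra-223 chain (e.g. `"Ra-223"`).
#' @param dt_s elapsed time in seconds (may be negative).
#' @return corrected activity in the input unit.
#' @examples
#' ra <- ra223_chain()$nuclides[[1]]
#' decay_correct(29, ra, 11.4 * 86400)  # one half-life: 14.5 uCi
#' @export
decay_correct <- function(activity0, nuclide, dt_s) {
  if (is.character(nuclide)) {
    ch <- ra223_chain()
    idx <- match(nuclide, chain_names(ch))
    if (is.na(idx)) stop("unknown nuclide name: ", nuclide)
    nuclide <- ch$nuclides[[idx]]
  }
  stopifnot(inherits(nuclide, "nuclide"))
  if (!is.finite(nuclide$half_life_s))
    stop("cannot decay-correct a stable nuclide")
  activity0 * 2^(-dt_s / nuclide$half_life_s)
}

#' Expected emissions per complete chain decay
#'
#' Sums per-nuclide emission probabilities down the chain: the expected number
#' of each emission kind released when one parent atom decays through to the
#' stable terminus. For the Ra-223 chain this is 4 alphas, 2 betas and
#' 4 recoil nuclei.
#'
#' @param chain a [decay_chain()].
#' @return named numeric vector with entries `alpha`, `beta`, `recoil`.
#' @export
emissions_per_chain_decay <- function(chain) {
  stopifnot(inherits(chain, "decay_chain"))
  out <- c(alpha = 0, beta = 0, recoil = 0)
  for (nuc in chain$nuclides) for (e in nuc$emissions)
    out[e$kind] <- out[e$kind] + e$probability
  out
}

#' Radiolabeling efficiency and specific activity
#'
#' Labeling efficiency is the activity retained on the nanocluster product as
#' a percentage of the total activity initially added; specific activity is
#' product activity per mg of gold.
#'
#' @param activity_on_product activity measured on the purified product (uCi).
#' @param activity_total total activity initially added (uCi, > 0).
#' @param mass_au_mg gold mass of the product (mg, > 0).
#' @return list with `efficiency_pct` and `specific_activity_uCi_mg`.
#' @examples
#' labeling_metrics(23.6, 29.0, 4.27)
#' @export
labeling_metrics <- function(activity_on_product, activity_total, mass_au_mg) {
  if (activity_total <= 0) stop("activity_total must be > 0")
  if (mass_au_mg <= 0) stop("mass_au_mg must be > 0")
  if (activity_on_product < 0) stop("activity_on_product must be >= 0")
  if (activity_on_product > activity_total)
    stop("product activity cannot exceed the total activity added")
  list(
    efficiency_pct = 100 * activity_on_product / activity_total,
    specific_activity_uCi_mg = activity_on_product / mass_au_mg
  )
}
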