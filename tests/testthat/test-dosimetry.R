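test_that("each chain decay yields 4 alphas, 4 recoils and 2 betas", {
  ev <- sample_chain_events(ra223_chain(), n_decays = 1, seed = 3)
  expect_identical(unname(table(ev$kind)["alpha"]), 4L)
  expect_identical(unname(table(ev$kind)["recoil"]), 4L)
  expect_identical(unname(table(ev$kind)["beta"]), 2L)
})

test_that("recoils are anti-parallel to their alphas and inside 100-200 keV", {
  ev <- sample_chain_events(ra223_chain(), n_decays = 50, seed = 4)
  rec <- ev[ev$kind == "recoil", ]
  expect_true(all(rec$energy_MeV * 1e3 >= 100 & rec$energy_MeV * 1e3 <= 200))
  # first decay's recoil carries E_alpha * 4 / 219
  ra <- rec[rec$nuclide == "Ra-223", ]
  expect_equal(unique(ra$energy_MeV), 5.716 * 4 / 219, tolerance = 1e-12)
  # pair each recoil with the alpha of the same decay and nuclide
  al <- ev[ev$kind == "alpha", ]
  key <- paste(al$decay_id, al$nuclide)
  m <- match(paste(rec$decay_id, rec$nuclide), key)
  dots <- unname(rowSums(rec[, c("ux", "uy", "uz")] * al[m, c("ux", "uy", "uz")]))
  expect_equal(dots, rep(-1, nrow(rec)), tolerance = 1e-12)
  expect_equal(rec$px, al$px[m])
})

test_that("the event stream is deterministic under a seed", {
  e1 <- sample_chain_events(ra223_chain(), n_decays = 20, seed = 9)
  e2 <- sample_chain_events(ra223_chain(), n_decays = 20, seed = 9)
  expect_identical(e1, e2)
  e3 <- sample_chain_events(ra223_chain(), n_decays = 20, seed = 10)
  expect_false(identical(e1$px, e3$px))
})

test_that("a linear-range toy particle deposits proportionally to path length", {
  # R(E) = E um: 1 MeV travelling 0.4 um of water leaves 0.4 MeV there
  geom <- shell_geometry("water", shell_thickness_nm = 0,
                         source_radius_nm = 1e-3,
                         phantom_half_width_um = 0.4)
  ev <- data.frame(decay_id = 1, nuclide = "T", kind = "alpha",
                   energy_MeV = 1, px = 0, py = 0, pz = 0,
                   ux = 0, uy = 0, uz = 1)
  segs <- transport_particle(ev, geom, toy_stopping())
  expect_equal(sum(segs$deposit_MeV), 0.4, tolerance = 1e-6)
  expect_equal(segs$E_out_MeV[3], 0.6, tolerance = 1e-6)
  expect_true(is.na(attr(segs, "r_stop_um")))  # escapes the phantom

  # full containment: everything is deposited and the particle stops at R(E)
  geom2 <- shell_geometry("water", 0, 1e-3, phantom_half_width_um = 5)
  segs2 <- transport_particle(ev, geom2, toy_stopping())
  expect_equal(sum(segs2$deposit_MeV), 1, tolerance = 1e-9)
  expect_equal(attr(segs2, "r_stop_um"), 1, tolerance = 1e-6)
})

test_that("a zero-thickness shell absorbs nothing", {
  tally <- run_experiment(shell_geometry("gold", 0), n_decays = 200, seed = 1)
  expect_identical(tally$energy_in_shell_keV, 0)
})

test_that("tally energy is conserved", {
  tally <- run_experiment(shell_geometry("gold", 10), n_decays = 500, seed = 2)
  total <- tally$energy_in_shell_keV + tally$energy_in_source_keV +
    tally$energy_in_water_keV + tally$energy_escaped_keV
  expect_equal(total / tally$energy_particles_keV, 1, tolerance = 1e-9)
  # per the tally invariant, within 0.1% including the denominator convention
  expect_lt(abs(total - tally$energy_emitted_keV) / tally$energy_emitted_keV,
            0.001)
})

test_that("a toy single-alpha chain stops at its water range", {
  # R(E) = 50 * E um at 1 MeV -> 50 um stop radius
  st <- toy_stopping(a = 50, p = 1)
  tally <- run_experiment(shell_geometry("water", 0, phantom_half_width_um = 80),
                          chain = toy_alpha_chain(energy_keV = 1000),
                          n_decays = 300, seed = 5, stopping = st)
  rs <- alpha_range_summary(tally)
  expect_equal(rs$mean_stop_radius_um, 50, tolerance = 1e-3)
  expect_equal(rs$max_stop_radius_um, 50, tolerance = 1e-2)
})

test_that("gold absorbs more than water and thicker shells absorb more", {
  th <- c(2, 10, 100, 1000, 10000)
  frac <- function(mat) vapply(th, function(x)
    run_experiment(shell_geometry(mat, x), n_decays = 800,
                   seed = 11)$shell_fraction, numeric(1))
  fg <- frac("gold")
  fw <- frac("water")
  expect_true(all(diff(fg) > 0))
  expect_true(all(diff(fw) > 0))
  expect_true(all(fg > fw))
})

test_that("thicker gold shells shorten the mean alpha stopping radius", {
  r10 <- alpha_range_summary(run_experiment(shell_geometry("gold", 10),
                                            n_decays = 400, seed = 6))
  r5000 <- alpha_range_summary(run_experiment(shell_geometry("gold", 5000),
                                              n_decays = 400, seed = 6))
  expect_lt(r5000$mean_stop_radius_um, r10$mean_stop_radius_um)
})

test_that("run_experiment is reproducible and its profile integrates the water dose", {
  t1 <- run_experiment(shell_geometry("gold", 10), n_decays = 300, seed = 8)
  t2 <- run_experiment(shell_geometry("gold", 10), n_decays = 300, seed = 8)
  expect_equal(t1$shell_fraction, t2$shell_fraction)
  expect_equal(sum(t1$profile$keV_per_decay) * t1$n_decays,
               t1$energy_in_water_keV, tolerance = 1e-9)
})

test_that("energies outside the stopping validity window are clamped with a warning", {
  geom <- shell_geometry("water", 0, phantom_half_width_um = 150)
  ev <- data.frame(decay_id = 1, nuclide = "T", kind = "alpha",
                   energy_MeV = 50, px = 0, py = 0, pz = 0,
                   ux = 0, uy = 0, uz = 1)
  expect_warning(transport_particle(ev, geom), "clamping")
})

test_that("geometry construction enforces nesting", {
  expect_error(shell_geometry("gold", 10, phantom_half_width_um = 0.005),
               "enclose")
  expect_error(shell_geometry("gold", -1), "shell_thickness_nm")
})
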