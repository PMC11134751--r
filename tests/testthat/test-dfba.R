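toy <- make_toy_model()
p0 <- kinetic_parameters()

test_that("glucose uptake kinetics switch the low-affinity system at 75 g/L", {
  expect_equal(glucose_uptake_bound(0, p0), 0)
  p <- kinetic_parameters(vmax_glc_high = 2, km_glc_high = 0.1)
  expect_equal(glucose_uptake_bound(70, p), 2 * 70 / 70.1, tolerance = 1e-12)
  expect_equal(glucose_uptake_bound(70, p), 1.9971, tolerance = 1e-4)
  # above the threshold both terms contribute
  both <- glucose_uptake_bound(80, p)
  expect_equal(both, 2 * 80 / 80.1 + p$vmax_glc_low * 80 / (p$km_glc_low + 80),
               tolerance = 1e-12)
  expect_gt(both, glucose_uptake_bound(75, p))
})

test_that("xylose uptake is passive-only while glucose exceeds 5 mM", {
  # 80 g/L glucose is ~444 mM: transporter off
  expect_equal(xylose_uptake_bound(40, 444, p0), p0$k_passive_xyl * 40,
               tolerance = 1e-12)
  expect_equal(xylose_uptake_bound(0, 1, p0), 0)
  # below the threshold both routes add
  expect_equal(xylose_uptake_bound(10, 1, p0),
               p0$k_passive_xyl * 10 + p0$vmax_xyl * 10 / (p0$km_xyl + 10),
               tolerance = 1e-12)
})

test_that("kinetic bounds are written onto the right reactions", {
  st <- fermentation_state(t = 10, glucose = 80, xylose = 40, phosphate = 1)
  m <- apply_kinetic_bounds(toy, st, p0)
  rx <- function(model, id, col) model$reactions[[col]][model$reactions$id == id]
  expect_equal(rx(m, "EX_glc__D_e", "lower_bound"),
               -glucose_uptake_bound(80, p0), tolerance = 1e-12)
  expect_equal(rx(m, "EX_xyl__D_e", "lower_bound"),
               -p0$k_passive_xyl * 40, tolerance = 1e-12)
  expect_equal(rx(m, "ATPM", "lower_bound"), 1.9)
  expect_equal(rx(m, "EX_pi_e", "lower_bound"), -p0$vmax_pi)
  # phosphate exhausted: uptake closed, and growth becomes P-limited
  st0 <- fermentation_state(t = 10, glucose = 80, xylose = 40, phosphate = 0)
  m0 <- apply_kinetic_bounds(toy, st0, p0)
  expect_equal(rx(m0, "EX_pi_e", "lower_bound"), 0)
  expect_equal(fba(m0)$objective_value, 0, tolerance = 1e-6)
  # original model untouched
  expect_equal(rx(toy, "ATPM", "lower_bound"), 0)
  # zero-concentration state closes all substrate uptakes
  stz <- fermentation_state(t = 10, glucose = 0, xylose = 0, phosphate = 0)
  mz <- apply_kinetic_bounds(toy, stz, p0)
  expect_equal(rx(mz, "EX_glc__D_e", "lower_bound"), 0)
  expect_equal(rx(mz, "EX_xyl__D_e", "lower_bound"), 0)
  # a model without the needed roles errors by role name
  expect_error(apply_kinetic_bounds(
    make_toy_model(toy_spec(include_xylose_path = FALSE)), st, p0), "xylose")
})

test_that("one Euler step follows the forward-difference arithmetic", {
  st <- fermentation_state(t = 10, biomass = 1, glucose = 80, xylose = 40,
                           phosphate = 1)
  # phosphate unconstrained here so glucose is the binding substrate
  p0 <- kinetic_parameters(vmax_pi = 10)
  nxt <- dfba_step(toy, st, p0, dt = 0.1)
  d <- attr(nxt, "diagnostics")
  expect_equal(nxt$t, 10.1)
  expect_equal(nxt$biomass, 1 * (1 + d$mu * 0.1), tolerance = 1e-12)
  # glucose drawdown equals flux * biomass * dt * M / 1000 with the uptake
  # pinned at its kinetic bound by optimality
  expect_equal(st$glucose - nxt$glucose,
               glucose_uptake_bound(80, p0) * 1 * 0.1 * 180.16 / 1000,
               tolerance = 1e-9)
  # worked example: 2 mmol/gDW/h for 1 h at 1 gDW/L is 0.36032 g/L
  expect_equal(2 * 1 * 1 * 180.16 / 1000, 0.36032)
})

test_that("sequential sugar use: no transporter-mediated xylose above 5 mM glucose", {
  traj <- run_dfba(toy, p0, fermentation_state(t = 10, glucose = 80,
                                               xylose = 40, phosphate = 1),
                   t_end = 25, dt = 0.25)
  d <- attr(traj, "diagnostics")
  high_glc <- d$glucose_mM > p0$xyl_repression_threshold
  expect_true(any(high_glc))
  expect_true(all(d$xyl_transporter_bound[high_glc] == 0))
  # glucose never increases; xylose never increases
  expect_true(all(diff(traj$glucose) <= 1e-9))
  expect_true(all(diff(traj$xylose) <= 1e-9))
  # biomass never decreases
  expect_true(all(diff(traj$biomass) >= -1e-9))
})

test_that("a zero inoculum stays flat", {
  traj <- run_dfba(toy, p0, fermentation_state(t = 10, biomass = 0,
                                               glucose = 80, xylose = 40,
                                               phosphate = 1),
                   t_end = 12, dt = 0.5)
  expect_true(all(traj$glucose == 80))
  expect_true(all(traj$biomass == 0))
  expect_true(all(traj$citrate == 0))
})

test_that("substrate exhaustion terminates the run cleanly, never negative", {
  # tiny sugar pools, maintenance kept: the LP must eventually fail
  lowsub <- fermentation_state(t = 10, biomass = 2, glucose = 0.2,
                               xylose = 0.05, phosphate = 0.5)
  traj <- run_dfba(toy, p0, lowsub, t_end = 60, dt = 0.5)
  expect_true(all(traj$glucose >= 0 & traj$xylose >= 0 &
                    traj$phosphate >= 0 & traj$citrate >= 0))
  term <- attr(traj, "termination")
  expect_true(term == "t_end" || grepl("infeasible", term))
  expect_lt(max(traj$t), 60 + 1e-9)
})

test_that("the objective switches to citrate after phosphate exhaustion", {
  traj <- run_dfba(toy, p0, fermentation_state(t = 10, glucose = 80,
                                               xylose = 40, phosphate = 0.2),
                   t_end = 20, dt = 0.25)
  d <- attr(traj, "diagnostics")
  expect_true(any(d$phase == "citrate"))
  post <- traj$citrate[traj$t > min(d$t[d$phase == "citrate"])]
  expect_true(all(diff(post) > -1e-12))
  expect_gt(max(traj$citrate), 0)
})

test_that("halving dt changes toy endpoints by less than 1%", {
  # slow, phosphate-limited growth keeps the Euler truncation error small
  # and no depletion event is crossed inside the window
  p_slow <- kinetic_parameters(vmax_pi = 0.02)
  init <- fermentation_state(t = 10, glucose = 40, xylose = 10, phosphate = 5)
  t1 <- run_dfba(toy, p_slow, init, t_end = 16, dt = 0.4)
  t2 <- run_dfba(toy, p_slow, init, t_end = 16, dt = 0.2)
  for (v in c("biomass", "glucose", "citrate")) {
    a <- t1[[v]][nrow(t1)]
    b <- t2[[v]][nrow(t2)]
    expect_lt(abs(a - b) / max(abs(b), 1e-6), 0.01)
  }
})

test_that("carbon recovery stays at one on the balanced toy run", {
  traj <- run_dfba(toy, p0, fermentation_state(t = 10, glucose = 40,
                                               xylose = 20, phosphate = 0.5),
                   t_end = 22, dt = 0.2)
  cb <- carbon_balance(traj, toy)
  expect_true(all(abs(cb$recovery[!is.na(cb$recovery)] - 1) < 1e-3))
  # no consumption yet -> recovery undefined, reported as NA
  expect_true(is.na(cb$recovery[1]))
  # a deliberately unbalanced biomass carbon flags recovery != 1
  cb_bad <- carbon_balance(traj, biomass_carbon = 2 * biomass_carbon_content(toy))
  expect_gt(max(abs(cb_bad$recovery[!is.na(cb_bad$recovery)] - 1)), 0.05)
})

test_that("trajectory plots build with and without measured overlays", {
  traj <- run_dfba(toy, p0, t_end = 12, dt = 0.5)
  gg <- autoplot(traj)
  expect_s3_class(gg, "ggplot")
  gg2 <- autoplot(traj, measured = tibble::tibble(t = c(10, 11),
                                                  glucose = c(80, 79)))
  expect_s3_class(gg2, "ggplot")
})

test_that("lag-phase padding reports constant pre-start states", {
  traj <- run_dfba(toy, p0, t_end = 12, dt = 0.5, include_lag = TRUE)
  lag <- traj[traj$t < p0$t_start, ]
  expect_true(all(lag$glucose == traj$glucose[traj$t == p0$t_start]))
  expect_true(all(lag$phase == "lag"))
})
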