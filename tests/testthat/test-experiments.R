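# Experiment drivers: ensembles, fiber runs, sweeps and count prediction.
# Unit tests run miniature configurations (seconds per member); the
# desk-scale acceptance runs live in test-acceptance.R.

tiny_cfg <- function(n_steps = 3L, g_final = 1.15) {
  sim_config(
    slab = slab_spec(Lx = 12, Ly = 12, Hcore = 6, tcortex = 1, dx = 1.5,
                     core_layers = 3L),
    schedule = growth_schedule(n_steps = n_steps, g_final = g_final))
}

test_that("ensembles are deterministic and aggregate their members", {
  ens <- run_ensemble(2L, tiny_cfg(), seeds = c(4L, 4L))
  expect_equal(ens$counts[1], ens$counts[2])     # identical seeds
  expect_equal(ens$mean, mean(ens$counts))
  expect_equal(ens$min, min(ens$counts))
  expect_equal(ens$max, max(ens$counts))
  expect_match(ens$fingerprint, "^[0-9a-f]{8}$")
  expect_equal(ens$seeds, c(4L, 4L))
  expect_error(run_ensemble(1L, tiny_cfg()), "n >= 2")
})

test_that("ensemble members with different seeds see different fields", {
  r1 <- simulate_and_detect(tiny_cfg(), seed = 1L)
  r2 <- simulate_and_detect(tiny_cfg(), seed = 2L)
  expect_false(r1$omega == r2$omega)
  s1 <- r1$trajectory$surfaces[[length(r1$trajectory$surfaces)]]
  s2 <- r2$trajectory$surfaces[[length(r2$trajectory$surfaces)]]
  expect_false(isTRUE(all.equal(s1$vertices, s2$vertices)))
})

test_that("fiber experiments compare fiber and control arms per seed", {
  tpl <- y_fiber_template(c(6, 6), length = 4, radius = 1.2)
  tab <- run_fiber_experiment(list(tpl), seeds = 1L, config = tiny_cfg(),
                              capture_radius = 5)
  expect_equal(nrow(tab), 2)                      # fiber + control
  expect_setequal(tab$arm, c("fiber", "control"))
  expect_type(tab$captured, "logical")
  ## with zero growth everywhere no hinge can form: capture rate 0
  cfg0 <- tiny_cfg()
  cfg0$schedule <- growth_schedule(n_steps = 1L, g_final = 1,
                                   g_ct = 0, g_af = 0)
  tab0 <- run_fiber_experiment(list(tpl), seeds = 1L, config = cfg0)
  expect_true(all(!tab0$captured))
  ## the same seed with vs without fibers produces different geometry
  r_f <- simulate_and_detect(tiny_cfg(), seed = 3L, templates = list(tpl))
  r_0 <- simulate_and_detect(tiny_cfg(), seed = 3L)
  sf <- r_f$trajectory$surfaces[[length(r_f$trajectory$surfaces)]]
  s0 <- r_0$trajectory$surfaces[[length(r_0$trajectory$surfaces)]]
  expect_false(isTRUE(all.equal(sf$vertices, s0$vertices)))
})

test_that("sweeps record densities and fit the stated trend form", {
  sw <- run_thickness_area_sweep(c(1, 1.4), c(12), config = tiny_cfg(),
                                 patch_side = 60)
  expect_equal(nrow(sw$data), 2)
  ## patch clipped to the domain: density = count / patch area
  expect_equal(sw$data$patch_area_mm2, c(144, 144))
  expect_equal(sw$data$density_per_cm2,
               sw$data$count_patch / (sw$data$patch_area_mm2 / 100))
  expect_named(sw$coef, c("a", "b"))
  expect_true(is.finite(sw$thickness_r2))
  expect_error(run_thickness_area_sweep(1.5, 12, config = tiny_cfg()),
               "2 thickness")
})

test_that("count prediction evaluates the fitted trend and flags extrapolation", {
  fit <- structure(list(
    coef = c(a = 0.01, b = 0.001),
    t_range = c(1, 2), area_range = c(144, 576)),
    class = "sweep_result")
  p1 <- predict_count(area_cm2 = 3, tcortex = 1.5, fit)   # 300 mm2, inside
  expect_false(p1$extrapolated)
  expect_equal(p1$count, 300 * (0.01 / 1.5 + 0.001))
  ## doubling the area at fixed thickness increases the prediction
  p2 <- predict_count(area_cm2 = 5, tcortex = 1.5, fit)
  expect_gt(p2$count, p1$count)
  ## thinner cortex predicts more hinges for the same area
  p3 <- predict_count(area_cm2 = 3, tcortex = 1.1, fit)
  expect_gt(p3$count, p1$count)
  ## outside the fitted hull the flag is raised
  expect_true(suppressWarnings(
    predict_count(area_cm2 = 20, tcortex = 1.5, fit))$extrapolated)
  expect_error(predict_count(3, 1.5, fit = list()), "sweep_result")
})
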