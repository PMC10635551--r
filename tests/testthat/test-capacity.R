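test_that("bisection brackets a step-function feasibility frontier", {
  oracle <- function(N) list(slv = if (N <= 100) 0 else N - 100,
                             allocation = NULL)
  r <- binary_search_capacity(oracle, c(0, 200), scale = 0.5, tol = 0.5)
  expect_gte(r$N_opt, 99.5)
  expect_lte(r$N_opt, 100)
  # always-feasible: converges to the top of the expanded bracket
  r2 <- suppressWarnings(binary_search_capacity(
    function(N) list(slv = 0, allocation = NULL), c(0, 50), N_hat = 200,
    scale = 0.5, tol = 0.5))
  expect_gt(r2$N_opt, 200 - 1)
  # the probe position changes the path, not the answer
  r3 <- binary_search_capacity(oracle, c(0, 200), scale = 0.1, tol = 0.5)
  r4 <- binary_search_capacity(oracle, c(0, 200), scale = 0.9, tol = 0.5)
  expect_lt(abs(r3$N_opt - r4$N_opt), 0.5)
  expect_false(isTRUE(all.equal(r3$trace$N[1], r4$trace$N[1])))
  # bracket width decreases strictly
  expect_true(all(diff(r$trace$width) < 0))
})

test_that("deterministic assessment matches hand-solved capacities", {
  fit <- assess_capacity(fixture("toy_4_3_path"), "deterministic",
                         tol = 0.05, control = quiet_mh(seed = 1))
  expect_equal(fit$N_opt, 960 / 105, tolerance = 0.06 / (960 / 105))
  expect_equal(unname(coef(fit)), fit$N_opt)
  fit2 <- assess_capacity(one_activity_instance(), "deterministic",
                          tol = 0.05)
  expect_equal(fit2$N_opt, 16, tolerance = 0.05 / 16)
})

test_that("the returned allocation is a feasibility certificate", {
  fit <- assess_capacity(fixture("toy_4_3_path"), "deterministic",
                         tol = 0.05, control = quiet_mh(seed = 1))
  expect_equal(slv(fit$allocation, fit$instance, "deterministic")$total, 0)
  fs <- assess_capacity(fixture("toy_4_3_path"), "stochastic",
                        n_scenarios = 30, seed = 5, tol = 0.1,
                        control = quiet_mh(seed = 5))
  expect_equal(slv(fs$allocation, fs$instance, "stochastic",
                   fs$state)$total, 0)
})

test_that("point-mass durations give stochastic = deterministic capacity", {
  inst <- fixture("toy_4_3_path")
  fd <- assess_capacity(inst, "deterministic", tol = 0.1,
                        control = quiet_mh(seed = 2))
  fs <- suppressWarnings(
    assess_capacity(inst, "stochastic", n_scenarios = 30, seed = 2,
                    tol = 0.1, control = quiet_mh(seed = 2)))
  expect_lt(abs(fs$N_opt - fd$N_opt), 2 * 0.1)
})

test_that("duration variability forces buffering below the mean capacity", {
  # symmetric two-point durations; at SL = 0.99 the high realisations
  # must fit, so the stochastic capacity drops strictly below N_DET
  hosp <- hospital(list(treatment_area("w", list(
    treatment_space("s1", 480, 0.99), treatment_space("s2", 480, 0.99)))))
  cat_ <- pathway_catalog(list(pathway("g", "p", list(
    activity("a1", dist_piecewise(c(49.9, 50.1, 69.9, 70.1),
                                  c(0.5, 0, 0.5)), c("s1", "s2")),
    activity("a2", dist_piecewise(c(34.9, 35.1, 54.9, 55.1),
                                  c(0.5, 0, 0.5)), "s1")))))
  inst <- shca_instance(hosp, cat_, case_mix(c(g = 1), list(g = c(p = 1))))
  fd <- assess_capacity(inst, "deterministic", tol = 0.1,
                        control = quiet_mh(seed = 4))
  fs <- assess_capacity(inst, "stochastic", n_scenarios = 200, seed = 4,
                        tol = 0.1, control = quiet_mh(seed = 4))
  expect_lt(fs$N_opt, fd$N_opt)
})

test_that("capacity is non-increasing in the service level on a fixed pool", {
  inst <- generate_instance(n_areas = 1, spaces_per_area = 2, n_types = 2,
                            acts_per_path = 2, families = "piecewise",
                            tail_heaviness = 1, seed = 8)
  pool <- scenario_pool(inst, 200, seed = 8)
  caps <- vapply(c(0.8, 0.9, 0.95, 0.99), function(sl) {
    suppressWarnings(assess_capacity(
      set_service_level(inst, sl), "stochastic", pool = pool, seed = 8,
      tol = 0.25, control = quiet_mh(seed = 8)))$N_opt
  }, numeric(1))
  expect_true(all(diff(caps) <= 1e-9))
})

test_that("risk sweeps tabulate replications with distinct seeds", {
  inst <- fixture("toy_4_3_path")
  sw <- risk_sweep(inst, risk_levels = 0.1, scenario_counts = 20,
                   replications = 3, seed = 1, tol = 0.2,
                   control = quiet_mh(steps = 30, n_controls = 10))
  expect_equal(nrow(sw), 3)
  expect_length(unique(sw$seed), 3)
  sm <- summary(sw)
  expect_true(all(c("min", "mean", "max") %in% names(sm$cells)))
  expect_gte(sm$capacity_range, 0)
})

test_that("the sweep capacity range mirrors the published arithmetic", {
  totals <- fixture("table3_totals")
  expect_equal(round(max(totals) - min(totals)), 4281)
})

test_that("caseload tables apply the mix to each capacity column", {
  mix <- fixture("table2_mix")
  tab <- caseload_table(fixture("table3_totals"), mix)
  as20 <- tab[tab$type == "Acute Surgical", "risk20"]
  expect_equal(round(as20, 2), 394.08)
  expect_equal(unname(unlist(tab[tab$type == "Total", -1])),
               unname(fixture("table3_totals")), tolerance = 1e-9)
})

test_that("fit methods print, summarise and plot without error", {
  fit <- assess_capacity(fixture("toy_4_3_path"), "deterministic",
                         tol = 0.2)
  expect_output(print(fit), "capacity")
  expect_output(print(summary(fit)), "Caseload")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
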