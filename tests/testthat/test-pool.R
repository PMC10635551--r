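# three-space instance with one activity usable everywhere
three_space_instance <- function() {
  hosp <- hospital(list(treatment_area("w", list(
    treatment_space("s1", 480), treatment_space("s2", 480),
    treatment_space("s3", 480)))))
  cat_ <- pathway_catalog(list(pathway("g", "p", list(
    activity("a", dist_point(30), c("s1", "s2", "s3"))))))
  shca_instance(hosp, cat_, case_mix(c(g = 1), list(g = c(p = 1))))
}

alloc_for <- function(inst, values) {
  al <- shcapacity:::new_allocation(inst)
  for (rid in names(values)) al["a", rid] <- values[[rid]]
  al
}

test_that("point-mass pools store the constant value everywhere", {
  inst <- one_activity_instance()
  pool <- scenario_pool(inst, n_scenarios = 2, seed = 1)
  expect_true(all(unlist(pool$samples) == 60))
  expect_equal(nrow(pool$samples$a), 2)
  expect_gte(ncol(pool$samples$a), ceiling(16) + 1)
})

test_that("the pool is bit-reproducible from its seed", {
  inst <- generate_instance(tail_heaviness = 1, seed = 4)
  p1 <- scenario_pool(inst, 20, seed = 123)
  p2 <- scenario_pool(inst, 20, seed = 123)
  expect_identical(p1$samples, p2$samples)
  p3 <- scenario_pool(inst, 20, seed = 124)
  expect_false(identical(p1$samples, p3$samples))
})

test_that("the memory guard refuses oversized pools with guidance", {
  inst <- generate_instance(seed = 2)
  expect_error(scenario_pool(inst, 500, seed = 1, max_values = 100),
               "fewer scenarios")
})

test_that("lookup lists realise the worked 0.3-shift example", {
  inst <- three_space_instance()
  pool <- scenario_pool_from_samples(
    list(a = matrix(rep(1:12, each = 2), nrow = 2)))
  al <- alloc_for(inst, c(s1 = 3.42, s2 = 2.21, s3 = 1.9))
  st <- lookup_state(pool, al, inst)
  expect_identical(st$lists$a$s1, 1:4)
  expect_identical(st$lists$a$s2, 5:7)
  expect_identical(st$lists$a$s3, 8:9)
  # shift 0.3 occurrences from s1 to s3
  al2 <- alloc_for(inst, c(s1 = 3.12, s2 = 2.21, s3 = 2.2))
  st2 <- sync_lookups(st, al2, pairs = list(c("a", "s1"), c("a", "s3")))
  expect_identical(st2$lists$a$s1, 1:4)   # ceiling unchanged
  expect_identical(st2$lists$a$s2, 5:7)   # untouched
  expect_identical(st2$lists$a$s3, 8:10)  # grown by the lowest unused index
  expect_true(shcapacity:::lookup_state_check(st2, al2))
})

test_that("list lengths follow the ceiling of the allocation", {
  inst <- three_space_instance()
  pool <- scenario_pool_from_samples(list(a = matrix(5, 2, 12)))
  al <- alloc_for(inst, c(s1 = 2.2))
  st <- lookup_state(pool, al, inst)
  expect_length(st$lists$a$s1, 3)
  # 2.2 -> 1.7: ceiling 3 -> 2, one index released
  al["a", "s1"] <- 1.7
  st <- sync_lookups(st, al, pairs = list(c("a", "s1")))
  expect_length(st$lists$a$s1, 2)
  # 1.7 -> 2.0: ceiling still 2, no index change
  al["a", "s1"] <- 2.0
  st2 <- sync_lookups(st, al, pairs = list(c("a", "s1")))
  expect_identical(st2$lists$a$s1, st$lists$a$s1)
  # 2.0 -> 1.0: trailing index released
  al["a", "s1"] <- 1.0
  st3 <- sync_lookups(st2, al, pairs = list(c("a", "s1")))
  expect_identical(st3$lists$a$s1, st2$lists$a$s1[1])
  expect_true(shcapacity:::lookup_state_check(st3, al))
})

test_that("exhausting pool slack grows the pool deterministically", {
  inst <- one_activity_instance(avail = 480)
  pool <- scenario_pool(inst, 3, seed = 9)
  w0 <- ncol(pool$samples$a)
  al <- shcapacity:::new_allocation(inst)
  al["a", "s1"] <- w0 + 3.5
  st <- lookup_state(pool, al, inst)
  expect_length(st$lists$a$s1, w0 + 4)
  # grown columns equal those of a pool generated wide from scratch
  big <- shcapacity:::pool_grow(pool, inst, "a", ncol(st$pool$samples$a))
  expect_identical(st$pool$samples$a, big$samples$a)
})

test_that("evaluation is invariant across unrelated perturbations", {
  inst <- fixture("toy_4_3")
  pool <- scenario_pool(inst, 10, seed = 2)
  cl <- caseload_from_N(17, inst$mix, inst$catalog)
  al <- greedy_allocate(cl, inst)
  st <- lookup_state(pool, al, inst)
  u_a1 <- occupancy_scenario(al, st, "s2")
  # perturb a2's list (unrelated to s2, which only hosts a1) and revert
  al2 <- al; al2["a2", "s1"] <- 3.3
  st <- sync_lookups(st, al2, pairs = list(c("a2", "s1")))
  st <- sync_lookups(st, al, pairs = list(c("a2", "s1")))
  expect_identical(occupancy_scenario(al, st, "s2"), u_a1)
})
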