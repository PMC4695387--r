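test_that("transition matrix encodes independent per-plasmid loss", {
  m1 <- marker_set("URA3")
  T1 <- build_transition_matrix(m1, c(URA3 = 0.5))
  expect_equal(T1["1", ], c("1" = 0.5, "0" = 0.5))
  expect_equal(T1["0", ], c("1" = 0, "0" = 1))

  # zero rates: identity
  T0 <- build_transition_matrix(HLUM, rep(0, 4))
  expect_equal(unname(T0), diag(16))

  # k=2 product entries
  m2 <- marker_set(c("A", "B"))
  T2 <- build_transition_matrix(m2, c(A = 0.1, B = 0.2))
  expect_equal(T2["11", "11"], 0.9 * 0.8)
  expect_equal(T2["11", "00"], 0.1 * 0.2)
  expect_equal(T2["11", "10"], 0.9 * 0.2)
  expect_equal(T2["11", "01"], 0.1 * 0.8)

  expect_error(build_transition_matrix(m2, c(A = 0.1)), "missing")
})

test_that("transition rows are stochastic and plasmids are never regained", {
  set.seed(7)
  for (i in 1:10) {
    k <- sample(1:5, 1)
    mk <- marker_set(paste0("M", seq_len(k)))
    T <- build_transition_matrix(mk, runif(k))
    expect_equal(unname(rowSums(T)), rep(1, 2^k), tolerance = 1e-12)
    space <- rownames(T)
    for (s in space) {
      gains <- retained_count(colnames(T)) > retained_count(s) |
        vapply(colnames(T), function(d) {
          any(strsplit(d, "")[[1]] == "1" & strsplit(s, "")[[1]] == "0")
        }, logical(1))
      expect_true(all(T[s, gains] == 0))
    }
  }
})

test_that("one population step matches its closed forms and oracle", {
  m1 <- marker_set("URA3")
  T1 <- build_transition_matrix(m1, c(URA3 = 0.5))
  s0 <- composition_vector(c("1" = 1), m1)

  # neutral: f' = f T
  s1 <- step_population(s0, T1, scenario_config("neutral"), m1)
  expect_equal(as.numeric(s1), c(0.5, 0.5))

  # identity transition: fixed point in any regime
  Tid <- build_transition_matrix(m1, c(URA3 = 0))
  for (reg in c("neutral", "no_cooperation", "cooperation")) {
    expect_equal(as.numeric(step_population(s0, Tid, scenario_config(reg), m1)),
                 as.numeric(s0))
  }

  # no_cooperation: dividing prototrophs spawn equal arrested mass
  s1nc <- step_population(s0, T1, scenario_config("no_cooperation"), m1)
  orc <- oracle_step(list("1" = 1, "0" = 0), m1, c(URA3 = 0.5),
                     regime = "no_cooperation")
  expect_equal(as.numeric(s1nc), unname(orc), tolerance = 1e-12)
  expect_equal(as.numeric(s1nc["1"]), 0.5)
})

test_that("deterministic recursion matches the segregation checkpoints", {
  r <- equal_rates_from_total(0.11, 4)
  traj <- simulate_deterministic(HLUM, rep(r, 4), generations = 57)
  segregated_21 <- 1 - traj$freq["21", "1111"]
  segregated_57 <- 1 - traj$freq["57", "1111"]
  expect_gt(segregated_21, 0.90)
  expect_gt(segregated_57, 0.99)
  # marginal retention of the full prototroph class is 0.89^g exactly
  expect_equal(traj$freq["21", "1111"], 0.89^21, tolerance = 1e-12)
})

test_that("neutral marginals follow the closed form (1-m)^g", {
  set.seed(11)
  for (k in 1:4) {
    mk <- marker_set(paste0("M", seq_len(k)))
    rates <- runif(k, 0, 0.3)
    traj <- simulate_deterministic(mk, rates, generations = 12)
    space <- colnames(traj$freq)
    bits <- t(vapply(strsplit(space, ""), function(b) b == "1", logical(k)))
    if (k == 1) bits <- matrix(bits, ncol = 1)
    for (g in c(0, 3, 12)) {
      for (i in seq_len(k)) {
        marg <- sum(traj$freq[as.character(g), bits[, i]])
        expect_equal(marg, marginal_retention(rates[i], g),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("deterministic recursion equals the daughter-enumeration oracle", {
  set.seed(23)
  for (k in 1:3) {
    mk <- marker_set(paste0("M", seq_len(k)))
    rates <- setNames(runif(k, 0, 0.4), mk$id)
    for (reg in c("neutral", "no_cooperation")) {
      traj <- simulate_deterministic(mk, rates, scenario_config(reg),
                                     generations = 8)
      orc <- oracle_trajectory(mk, rates, 8, regime = reg)
      expect_equal(traj$freq, orc, tolerance = 1e-12)
    }
  }
})

test_that("prototroph frequency decreases monotonically under neutral drift", {
  r <- equal_rates_from_total(0.11, 4)
  traj <- simulate_deterministic(HLUM, rep(r, 4), generations = 30)
  proto <- traj$freq[, "1111"]
  expect_true(all(diff(proto) < 0))
  # zero rate: constant
  flat <- simulate_deterministic(HLUM, rep(0, 4), generations = 5)
  expect_true(all(flat$freq[, "1111"] == 1))
})

test_that("frequency mass never flows towards higher retention", {
  r <- equal_rates_from_total(0.3, 4)
  traj <- simulate_deterministic(HLUM, rep(r, 4), generations = 20)
  k <- 4
  losses <- k - retained_count(colnames(traj$freq))
  cum_lost <- t(apply(traj$freq, 1, function(f)
    vapply(0:k, function(l) sum(f[losses >= l]), numeric(1))))
  # cumulative mass at >= l losses is non-decreasing over generations
  expect_true(all(apply(cum_lost, 2, function(col) all(diff(col) >= -1e-12))))
})

test_that("certain loss of every plasmid collapses a non-cooperating colony", {
  m1 <- marker_set("URA3")
  traj <- simulate_deterministic(m1, c(URA3 = 1),
                                 scenario_config("no_cooperation"),
                                 generations = 5)
  expect_identical(traj$status, "collapsed")
  expect_equal(nrow(traj$freq), 6L)  # padded to full length
})

test_that("fully supplemented no-cooperation behaves exactly as neutral", {
  r <- equal_rates_from_total(0.2, 4)
  neutral <- simulate_deterministic(HLUM, rep(r, 4), generations = 15)
  fed <- simulate_deterministic(
    HLUM, rep(r, 4),
    scenario_config("no_cooperation",
                    supplemented = c("histidine", "leucine", "uracil",
                                     "methionine")),
    generations = 15)
  expect_equal(fed$freq, neutral$freq, tolerance = 1e-12)
})

test_that("every trajectory state is a proper frequency vector", {
  set.seed(5)
  for (reg in c("neutral", "no_cooperation")) {
    traj <- simulate_deterministic(HLUM, runif(4, 0, 0.2),
                                   scenario_config(reg), generations = 25)
    expect_equal(unname(rowSums(traj$freq)), rep(1, 26), tolerance = 1e-9)
    expect_true(all(traj$freq >= 0))
  }
})

test_that("rate helpers match their closed forms", {
  expect_equal(marginal_retention(0, 10), 1)
  expect_equal(marginal_retention(0.02, 10), 0.8171, tolerance = 5e-5)
  expect_equal(total_segregation_rate(c(0, 0, 0)), 0)
  expect_equal(total_segregation_rate(c(0.5, 1)), 1)
  r <- equal_rates_from_total(0.11, 4)
  expect_equal(r, 0.0287, tolerance = 2e-3)
  expect_equal(total_segregation_rate(rep(r, 4)), 0.11, tolerance = 1e-12)
  # 57 doublings at total retention 0.89/division: 99.87% segregated
  expect_equal(1 - marginal_retention(0.11, 57), 0.9987, tolerance = 5e-5)
})

test_that("fitness-weighted regime requires weights and respects them", {
  m1 <- marker_set("URA3")
  expect_error(scenario_config("fitness_weighted"), "fitness")
  T1 <- build_transition_matrix(m1, c(URA3 = 0))
  s0 <- validate_composition(c("1" = 1, "0" = 1), m1)
  # prototrophs divide twice as fast; with no segregation they enrich
  sc <- scenario_config("fitness_weighted", fitness = c("1" = 1, "0" = 0.5))
  s1 <- step_population(s0, T1, sc, m1)
  expect_gt(as.numeric(s1["1"]), 0.5)
  # hand computation: prototroph mass 2*0.5*1 = 1; auxotroph mass =
  # arrested 0.5*0.5 + dividing 2*0.5*0.5 = 0.75; frequency 1/1.75
  expect_equal(as.numeric(s1["1"]), 1 / 1.75, tolerance = 1e-12)
})
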