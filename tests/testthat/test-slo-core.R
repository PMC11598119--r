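test_that("temperature schedule runs from 1 to 0 and is strictly decreasing", {
  expect_equal(temperature(0, 10000), 1)
  expect_equal(temperature(10000, 10000), 0)
  expect_equal(temperature(5000, 10000), 1 - 10000 / 15000)
  for (M in c(1, 7, 100)) {
    vals <- temperature(0:M, M)
    expect_equal(vals[1], 1)
    expect_equal(vals[M + 1], 0)
    expect_true(all(diff(vals) < 0))
  }
  expect_error(temperature(11, 10), "t")
  expect_error(temperature(0, 0), "max_t")
  expect_error(temperature(-1, 10), "t")
})

test_that("behavioral control is u * (1 - temp) and validates its inputs", {
  expect_equal(behavioral_control(1, 0.7), 0)
  expect_equal(behavioral_control(0, 1), 1)
  expect_equal(behavioral_control(0.6, 0.5), 0.2)
  expect_error(behavioral_control(1.2, 0.5), "temp")
  expect_error(behavioral_control(0.5, -0.1), "u")
})

test_that("initialization fills the box, populates all four roles and finds the king", {
  p <- slo_problem(function(x) sum(x^2), dim = 3, lower = 0, upper = 1)
  cfg <- slo_config(pop_size = 20, max_iter = 10, seed = 11)
  set.seed(cfg$seed)
  sw <- initialize_population(p, cfg)
  expect_equal(nrow(sw$territories), 20)
  expect_true(all(sw$territories >= 0 & sw$territories <= 1))
  expect_equal(sw$eval_count, 20L)
  expect_equal(sum(sw$gender == "male"), 10)
  for (pool in sw$pools) expect_gt(length(pool), 0)
  expect_equal(sw$king_index, which.min(sw$fitness))
  expect_equal(sw$fitness, apply(sw$territories, 1, p$objective))
  # partners link co-residing members to the opposite gender
  cr <- which(sw$arrangement == "coresiding")
  expect_true(all(!is.na(sw$partner[cr])))
  expect_true(all(sw$gender[sw$partner[cr]] != sw$gender[cr]))

  set.seed(cfg$seed)
  sw2 <- initialize_population(p, cfg)
  expect_identical(sw$territories, sw2$territories)
  expect_identical(sw$arrangement, sw2$arrangement)

  cfg100 <- slo_config(pop_size = 100, max_iter = 10, seed = 5)
  set.seed(cfg100$seed)
  sw100 <- initialize_population(p, cfg100)
  expect_equal(sum(sw100$gender == "male"), 50)
  expect_equal(min(sw100$fitness), sw100$fitness[sw100$king_index])

  expect_error(slo_config(pop_size = 3, max_iter = 10), "pop_size")
})

test_that("delineation move matches hand arithmetic and its limits", {
  p <- slo_problem(function(x) sum(x^2), dim = 1, lower = 0, upper = 1)
  cfg <- slo_config(pop_size = 4, max_iter = 10)
  # equal fitness: ratio factor ~ 1/4; step = 0.5 * 0.8 * 0.25 = 0.1
  cand <- delineation_candidate(0.3, 1, 1, p, cfg, sign = 1, rand = 0.8)
  expect_equal(cand, 0.4, tolerance = 1e-9)
  # zero draw with lower = 0: no step regardless of sign
  expect_equal(delineation_candidate(0.3, 1, 1, p, cfg, sign = -1, rand = 0),
               0.3)
  # self fitness -> infinity: factor -> 1, step magnitude -> c1 * rand
  cand <- delineation_candidate(0.3, 1e12, 1, p, cfg, sign = 1, rand = 0.4)
  expect_equal(cand, 0.3 + 0.5 * 0.4, tolerance = 1e-6)
  # multiply reading retained behind ratio_mode
  cfg_m <- slo_config(pop_size = 4, max_iter = 10, ratio_mode = "multiply")
  cand <- delineation_candidate(0.1, 1, 1, p, cfg_m, sign = 1, rand = 0.2)
  expect_equal(cand, min(1, 0.1 + 0.5 * 0.2 * 4), tolerance = 1e-9)
})

test_that("relocation and dispute moves match hand arithmetic", {
  p <- slo_problem(function(x) sum(x^2), dim = 1, lower = 0, upper = 1)
  cfg <- slo_config(pop_size = 4, max_iter = 10)
  # peer variant
  expect_equal(relocation_candidate(0.8, 0.2, 0.5, p, cfg,
                                    sign = 1, noise = 1), 0.95)
  # king variant is the same formula with the king as reference
  expect_equal(relocation_candidate(0.2, 0.6, 0.8, p, cfg,
                                    sign = 1, noise = -1), 0.36)
  # zero difference or zero bc: no move
  expect_equal(relocation_candidate(0.4, 0.4, 0.7, p, cfg,
                                    sign = 1, noise = 2), 0.4)
  expect_equal(relocation_candidate(0.8, 0.2, 0, p, cfg,
                                    sign = -1, noise = 2), 0.8)

  expect_equal(dispute_candidate_king(0.3, 0.5, 0.2, p, cfg,
                                      sign = 1, noise = 2), 0.51)
  expect_equal(dispute_candidate_king(0.5, 0.5, 0, p, cfg,
                                      sign = 1, noise = 3), 0.5)
  expect_equal(dispute_candidate_king(0.1, 0.5, 0.2, p, cfg,
                                      sign = 1, noise = 0), 0.5)
  expect_equal(dispute_candidate_rival(0.1, 0.5, 1, 1, 0, p, cfg,
                                       sign = 1, noise = 1),
               0.51, tolerance = 1e-9)
  # rival at the king with temp 0: zero bracket
  expect_equal(dispute_candidate_rival(0.5, 0.5, 2, 1, 0, p, cfg,
                                       sign = 1, noise = 1.5), 0.5)
})

test_that("candidates are always clipped into the box", {
  p <- slo_problem(function(x) sum(x^2), dim = 4, lower = -1, upper = 1)
  cfg <- slo_config(pop_size = 4, max_iter = 10)
  set.seed(99)
  for (rep in 1:50) {
    self <- runif(4, -1, 1); other <- runif(4, -1, 1)
    cand <- relocation_candidate(self, other, runif(1), p, cfg,
                                 noise = rnorm(4, sd = 50))
    expect_true(all(cand >= -1 & cand <= 1))
    cand <- dispute_candidate_king(self, other, runif(1, 0, 0.8), p, cfg,
                                   noise = rnorm(4, sd = 50))
    expect_true(all(cand >= -1 & cand <= 1))
  }
})

test_that("greedy update accepts strictly better candidates only", {
  p <- sphere_problem(2, lower = -2, upper = 2)
  cfg <- slo_config(pop_size = 4, max_iter = 10, seed = 2)
  set.seed(cfg$seed)
  sw <- initialize_population(p, cfg)
  sw$territories[1, ] <- c(1, 1); sw$fitness[1] <- 2
  sw$king_index <- which.min(sw$fitness)

  worse <- greedy_update(sw, 1, c(2, 2), p)
  expect_equal(worse$territories[1, ], c(1, 1))
  expect_equal(worse$eval_count, sw$eval_count + 1L)

  better <- greedy_update(sw, 1, c(0.5, 0.5), p)
  expect_equal(better$fitness[1], 0.5)
  if (0.5 < min(sw$fitness)) expect_equal(better$king_index, 1L)
  expect_lte(min(better$fitness), min(sw$fitness))

  # non-finite objective: candidate rejected with a warning
  bad <- slo_problem(function(x) if (x[1] > 0) NaN else sum(x^2),
                     dim = 2, lower = -2, upper = 2)
  expect_warning(rej <- greedy_update(sw, 1, c(1, 0), bad), "non-finite")
  expect_equal(rej$territories[1, ], c(1, 1))
})

test_that("one iteration of each phase matches the straight-line oracle", {
  p <- sphere_problem(3)
  base <- slo_config(pop_size = 8, max_iter = 100, seed = 31)

  run_both <- function(cfg, iteration) {
    set.seed(cfg$seed)
    sw <- initialize_population(p, cfg)
    sw$iteration <- iteration
    set.seed(cfg$seed + 1000)
    mine <- slo_step(sw, p, cfg)
    set.seed(cfg$seed + 1000)
    ref <- oracle_step(sw, p, cfg)
    expect_equal(mine$territories, ref$territories, tolerance = 1e-12)
    expect_equal(mine$fitness, ref$fitness, tolerance = 1e-12)
    expect_identical(mine$king_index, ref$king_index)
  }

  run_both(base, 0L)                                   # delineation (temp = 1)
  reloc <- base; reloc$gate_threshold <- 1             # force relocation
  run_both(reloc, 50L)                                 # temp = 1/3
  disp <- base; disp$gate_threshold <- 0               # force dispute
  run_both(disp, 50L)
})

test_that("the oracle also matches under negative fitness and multiply mode", {
  neg <- slo_problem(function(x) sum(x^2) - 10, dim = 3, lower = -5, upper = 5)
  cfg <- slo_config(pop_size = 8, max_iter = 100, seed = 17,
                    ratio_mode = "multiply")
  set.seed(cfg$seed)
  sw <- initialize_population(neg, cfg)
  set.seed(cfg$seed + 1)
  mine <- slo_step(sw, neg, cfg)            # delineation uses the ratio factor
  set.seed(cfg$seed + 1)
  ref <- oracle_step(sw, neg, cfg)
  expect_equal(mine$territories, ref$territories, tolerance = 1e-12)

  disp <- cfg; disp$gate_threshold <- 0
  sw$iteration <- 60L
  set.seed(cfg$seed + 2)
  mine <- slo_step(sw, neg, disp)
  set.seed(cfg$seed + 2)
  ref <- oracle_step(sw, neg, disp)
  expect_equal(mine$territories, ref$territories, tolerance = 1e-12)
})

test_that("full runs keep the population invariants", {
  p <- sphere_problem(2)
  cfg <- slo_config(pop_size = 8, max_iter = 60, seed = 7)
  set.seed(cfg$seed)
  sw <- initialize_population(p, cfg)
  roles <- list(sw$gender, sw$arrangement, sw$partner)
  for (it in 1:60) {
    sw <- slo_step(sw, p, cfg)
    expect_true(all(sw$territories >= p$lower & sw$territories <= p$upper))
    expect_equal(sw$king_index, which.min(sw$fitness))
  }
  expect_identical(list(sw$gender, sw$arrangement, sw$partner), roles)
  expect_equal(sw$iteration, 60L)
})

test_that("optimization is seeded-deterministic with a non-increasing history", {
  p <- sphere_problem(2)
  cfg <- slo_config(pop_size = 8, max_iter = 50, seed = 3)
  r1 <- slo_optimize(p, cfg)
  r2 <- slo_optimize(p, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best_territory, r2$best_territory)
  expect_length(r1$history, 51)
  expect_true(all(diff(r1$history) <= 0))
  expect_equal(r1$best_fitness, r1$history[51])
  expect_equal(r1$evals, 8L + 8L * 50L)

  const <- slo_problem(function(x) 0, dim = 2, lower = 0, upper = 1)
  rc <- slo_optimize(const, cfg)
  expect_true(all(rc$history == 0))

  # caller RNG state is restored
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(slo_optimize(p, cfg)); after <- runif(3)
  expect_identical(before, after)
})
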