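#' Temperature schedule
#'
#' Deterministic schedule `1 - 2 t / (t + max_t)` decreasing from 1 at
#' iteration 0 to 0 at iteration `max_t`. High temperature activates the
#' delineation phase; low temperature activates relocation and disputes.
#'
#' @param t Current iteration, `0 <= t <= max_t`.
#' @param max_t Total number of iterations (positive).
#' @return Temperature value in `[0, 1]`, strictly decreasing in `t`.
#' @examples
#' temperature(0, 100)    # 1
#' temperature(100, 100)  # 0
#' @export
temperature <- function(t, max_t) {
  if (length(max_t) != 1L || !is.finite(max_t) || max_t <= 0)
    stop("`max_t` must be a single positive number")
  if (any(!is.finite(t)) || any(t < 0) || any(t > max_t))
    stop("`t` must lie in [0, max_t]")
  1 - 2 * t / (t + max_t)
}

#' Behavioral control value
#'
#' The random scalar `u * (1 - temp)` that, compared against the gate
#' threshold (together with a second uniform draw), decides whether a
#' low-temperature iteration performs neighborhood relocation or a dispute.
#'
#' @param temp Temperature in `[0, 1]`.
#' @param u Uniform draw in `[0, 1]`; drawn from the current RNG if omitted.
#' @return Value in `[0, 1]`.
#' @export
behavioral_control <- function(temp, u = stats::runif(1)) {
  if (!is.finite(temp) || temp < 0 || temp > 1)
    stop("`temp` must lie in [0, 1]")
  if (!is.finite(u) || u < 0 || u > 1)
    stop("`u` must lie in [0, 1]")
  u * (1 - temp)
}

# Random sign per dimension: uniform < 0.5 -> +1, else -1.
.rand_sign <- function(n) {
  s <- rep(1, n)
  s[stats::runif(n) >= 0.5] <- -1
  s
}

# Fitness-ratio factor of the delineation move: r = mate / self.
.delineation_factor <- function(self_fitness, mate_fitness, eps, ratio_mode) {
  r <- mate_fitness / (self_fitness + eps)
  if (ratio_mode == "divide") 1 / (r + 1)^2 else (r + 1)^2
}

# Fitness-ratio factor of the dispute-rival move: q = self / rival.
.dispute_factor <- function(self_fitness, rival_fitness, eps, ratio_mode) {
  q <- self_fitness / (rival_fitness + eps)
  if (ratio_mode == "divide") 1 / (q + 1) else (q + 1)
}

#' Delineation move: candidate territory near an opposite-gender mate
#'
#' High-temperature move. The candidate is built around the mate's territory
#' with a per-dimension random step scaled by the bounds and damped by a
#' fitness-ratio factor, so individuals settle near opposite-gender members
#' of the same living arrangement:
#' `candidate = mate + s * c1 * ((upper - lower) * rand + lower) * g`,
#' with `s` a random sign per dimension, `rand` fresh uniforms, and
#' `g = 1/(r + 1)^2` where `r = mate_fitness / (self_fitness + eps)`
#' (under the default `ratio_mode = "divide"`).
#'
#' @param mate Territory (numeric vector) of the selected opposite-gender
#'   member with the same living arrangement.
#' @param self_fitness,mate_fitness Objective values of the moving member and
#'   the mate (shift both by the population minimum first if the objective can
#'   go negative).
#' @param problem An [slo_problem()].
#' @param config An [slo_config()].
#' @param sign,rand Optional pre-drawn sign (+/-1) and uniform vectors of
#'   length `problem$dim`; drawn from the current RNG when `NULL`. The draw
#'   order when `NULL` is signs first, then uniforms.
#' @return Candidate territory clipped to the box.
#' @export
delineation_candidate <- function(mate, self_fitness, mate_fitness,
                                  problem, config,
                                  sign = NULL, rand = NULL) {
  d <- problem$dim
  if (is.null(sign)) sign <- .rand_sign(d)
  if (is.null(rand)) rand <- stats::runif(d)
  g <- .delineation_factor(self_fitness, mate_fitness, config$eps,
                           config$ratio_mode)
  step <- sign * config$c1_explore *
    ((problem$upper - problem$lower) * rand + problem$lower) * g
  .clip(mate + step, problem$lower, problem$upper)
}

#' Relocation move: candidate territory shifted along a peer or king offset
#'
#' Low-temperature local move. The same formula serves both variants: with
#' `toward` a same-gender co-residing rival's territory it is the peer
#' relocation; with `toward` the leopard king's territory it is the
#' king-directed relocation applied to males:
#' `candidate = self + s * c1 * bc * noise * (self - toward)`,
#' with `noise` fresh standard normals per dimension.
#'
#' @param self Territory of the moving member.
#' @param toward Territory of the rival (peer variant) or of the king.
#' @param bc Behavioral-control value of the iteration.
#' @param problem An [slo_problem()].
#' @param config An [slo_config()].
#' @param sign,noise Optional pre-drawn sign and standard-normal vectors;
#'   drawn (signs first) from the current RNG when `NULL`.
#' @return Candidate territory clipped to the box.
#' @export
relocation_candidate <- function(self, toward, bc, problem, config,
                                 sign = NULL, noise = NULL) {
  d <- problem$dim
  if (is.null(sign)) sign <- .rand_sign(d)
  if (is.null(noise)) noise <- stats::rnorm(d)
  cand <- self + sign * config$c1_explore * bc * noise * (self - toward)
  .clip(cand, problem$lower, problem$upper)
}

#' Dispute move around the leopard king
#'
#' Low-temperature exploitation move available to every member:
#' `candidate = king + s * c1 * noise * ((1 - temp) * king - self)`.
#'
#' @param self Territory of the moving member.
#' @param king Territory of the leopard king (current best).
#' @param temp Temperature of the iteration (below the phase threshold).
#' @param problem An [slo_problem()].
#' @param config An [slo_config()].
#' @param sign,noise Optional pre-drawn sign and standard-normal vectors;
#'   drawn (signs first) from the current RNG when `NULL`.
#' @return Candidate territory clipped to the box.
#' @export
dispute_candidate_king <- function(self, king, temp, problem, config,
                                   sign = NULL, noise = NULL) {
  d <- problem$dim
  if (is.null(sign)) sign <- .rand_sign(d)
  if (is.null(noise)) noise <- stats::rnorm(d)
  cand <- king + sign * config$c1_dispute * noise * ((1 - temp) * king - self)
  .clip(cand, problem$lower, problem$upper)
}

#' Dispute move against a same-gender solitary rival
#'
#' Low-temperature move of solitary members battling a same-gender solitary
#' rival near the king:
#' `candidate = king + s * c1 * noise * ((1 - temp) * king - rival) * h`,
#' with `h = 1/(q + 1)`, `q = self_fitness / (rival_fitness + eps)` under the
#' default `ratio_mode = "divide"`.
#'
#' @param rival Territory of the same-gender solitary rival.
#' @param king Territory of the leopard king.
#' @param self_fitness,rival_fitness Objective values (shifted if negative).
#' @param temp Temperature of the iteration.
#' @param problem An [slo_problem()].
#' @param config An [slo_config()].
#' @param sign,noise Optional pre-drawn sign and standard-normal vectors;
#'   drawn (signs first) from the current RNG when `NULL`.
#' @return Candidate territory clipped to the box.
#' @export
dispute_candidate_rival <- function(rival, king, self_fitness, rival_fitness,
                                    temp, problem, config,
                                    sign = NULL, noise = NULL) {
  d <- problem$dim
  if (is.null(sign)) sign <- .rand_sign(d)
  if (is.null(noise)) noise <- stats::rnorm(d)
  h <- .dispute_factor(self_fitness, rival_fitness, config$eps,
                       config$ratio_mode)
  cand <- king + sign * config$c1_dispute * noise *
    ((1 - temp) * king - rival) * h
  .clip(cand, problem$lower, problem$upper)
}

#' Initialize the population
#'
#' Samples territories uniformly in the box and assigns the four roles:
#' the first `ceiling(pop_size/2)` members are male, the rest female; within
#' each gender every member is independently solitary or co-residing with
#' probability 1/2, then empty gender x arrangement cells are repaired by
#' flipping one randomly chosen member of that gender; co-residing males are
#' paired with co-residing females in index order, cyclically when the counts
#' differ. All fitnesses are evaluated and the king (minimum) identified.
#'
#' Draw order (from the current RNG): territories member-by-member (each
#' member's dimensions consecutively), then one uniform per member for the
#' arrangement (`u < 0.5` means solitary), then any repair draws.
#'
#' @param problem An [slo_problem()].
#' @param config An [slo_config()] with `pop_size >= 4`.
#' @param init_territories Optional numeric matrix whose rows overwrite the
#'   first rows of the sampled initial population (after sampling, so the
#'   RNG stream is unchanged); used e.g. to inject an all-features baseline
#'   in the feature-selection wrapper.
#' @return A swarm object (class `slo_swarm`): territory matrix, fitness
#'   vector, roles, partner links, king index, iteration and evaluation
#'   counters.
#' @export
initialize_population <- function(problem, config, init_territories = NULL) {
  n <- config$pop_size
  d <- problem$dim
  terr <- matrix(stats::runif(n * d, problem$lower, problem$upper),
                 nrow = n, ncol = d, byrow = TRUE)
  gender <- rep(c("male", "female"), c(ceiling(n / 2), floor(n / 2)))
  solitary <- stats::runif(n) < 0.5
  # repair: each gender needs at least one solitary and one co-residing member
  for (g in c("male", "female")) {
    idx <- which(gender == g)
    if (all(solitary[idx])) {
      flip <- idx[sample.int(length(idx), 1L)]
      solitary[flip] <- FALSE
    } else if (!any(solitary[idx])) {
      flip <- idx[sample.int(length(idx), 1L)]
      solitary[flip] <- TRUE
    }
  }
  arrangement <- ifelse(solitary, "solitary", "coresiding")
  partner <- rep(NA_integer_, n)
  cm <- which(gender == "male" & !solitary)
  cf <- which(gender == "female" & !solitary)
  partner[cm] <- cf[(seq_along(cm) - 1L) %% length(cf) + 1L]
  partner[cf] <- cm[(seq_along(cf) - 1L) %% length(cm) + 1L]

  if (!is.null(init_territories)) {
    init_territories <- matrix(as.numeric(init_territories),
                               ncol = d)
    k <- nrow(init_territories)
    if (k > n) stop("more injected territories than population members")
    terr[seq_len(k), ] <- .clip(init_territories, problem$lower, problem$upper)
  }

  fitness <- apply(terr, 1L, problem$objective)
  if (any(!is.finite(fitness)))
    stop("objective returned a non-finite value during initialization")

  structure(
    list(territories = terr, fitness = fitness,
         gender = gender, arrangement = arrangement, partner = partner,
         pools = list(
           sol_m = which(gender == "male" & solitary),
           sol_f = which(gender == "female" & solitary),
           cor_m = cm, cor_f = cf),
         king_index = which.min(fitness),
         iteration = 0L, eval_count = as.integer(n)),
    class = "slo_swarm"
  )
}

# Evaluate a candidate and accept iff strictly better; track the king.
.greedy_update <- function(swarm, i, cand, problem) {
  f <- problem$objective(cand)
  swarm$eval_count <- swarm$eval_count + 1L
  if (!is.finite(f)) {
    warning("objective returned a non-finite value; candidate rejected")
    return(swarm)
  }
  if (f < swarm$fitness[i]) {
    swarm$territories[i, ] <- cand
    swarm$fitness[i] <- f
    if (f < swarm$fitness[swarm$king_index]) swarm$king_index <- i
  }
  swarm
}

#' Greedy territory replacement
#'
#' Evaluates a candidate territory and replaces the member's territory iff
#' the candidate's objective value is strictly lower; the king index is
#' updated when the accepted value beats the incumbent. Roles never change.
#' A non-finite objective value rejects the candidate with a warning.
#'
#' @param swarm A swarm from [initialize_population()].
#' @param i Member index.
#' @param candidate Candidate territory (within bounds).
#' @param problem An [slo_problem()].
#' @return The updated swarm (evaluation counter always incremented).
#' @export
greedy_update <- function(swarm, i, candidate, problem) {
  stopifnot(inherits(swarm, "slo_swarm"), i >= 1L, i <= length(swarm$fitness))
  if (any(candidate < problem$lower - 1e-9) ||
      any(candidate > problem$upper + 1e-9))
    stop("candidate lies outside the box")
  .greedy_update(swarm, i, candidate, problem)
}

# draw one index from pool; redraw once if it picks `self`, then allow
.draw_rival <- function(pool, self) {
  r <- pool[sample.int(length(pool), 1L)]
  if (r == self && length(pool) > 1L) r <- pool[sample.int(length(pool), 1L)]
  r
}

#' Advance the swarm by one iteration
#'
#' Computes the temperature for the current iteration and runs exactly one
#' phase for every member (ascending index):
#' * `temp > temp_threshold`: delineation — each member moves near an
#'   opposite-gender member with the same living arrangement (co-residing
#'   members use their assigned partner; solitary members draw a mate
#'   uniformly from the opposite-gender solitary pool).
#' * otherwise one gate decides the whole iteration: with `bc = u1 * (1 -
#'   temp)` and a second uniform `u2`, relocation runs when `u2 * bc <
#'   gate_threshold`, else dispute. In relocation, males choose the peer or
#'   king variant with probability 1/2 and females use the peer variant, the
#'   rival drawn from same-gender co-residing members. In dispute, solitary
#'   members choose the king or rival variant with probability 1/2 and
#'   co-residing members use the king variant, the rival drawn from
#'   same-gender solitary members.
#'
#' Every candidate is clipped to the box and accepted greedily. Updates are
#' sequential within the iteration: an accepted improvement (including a new
#' king) is visible to subsequent members. Fitness values feeding the ratio
#' factors are shifted by the population minimum (fixed at the start of the
#' iteration) when that minimum is negative.
#'
#' Draw order: gate draws (`u1`, `u2`) first, then members in ascending
#' index; per member, the phase/variant uniform (if any), the rival index
#' (if any), then the per-dimension signs and magnitudes.
#'
#' @param swarm A swarm object.
#' @param problem An [slo_problem()].
#' @param config An [slo_config()].
#' @return The swarm after one iteration (`iteration` incremented).
#' @export
slo_step <- function(swarm, problem, config) {
  t <- swarm$iteration
  if (t >= config$max_iter) stop("swarm already ran for `max_iter` iterations")
  temp <- temperature(t, config$max_iter)
  n <- length(swarm$fitness)
  pools <- swarm$pools
  min_fit <- min(swarm$fitness)
  shift <- if (min_fit < 0) -min_fit else 0

  if (temp > config$temp_threshold) {
    for (i in seq_len(n)) {
      if (swarm$arrangement[i] == "coresiding") {
        m <- swarm$partner[i]
      } else {
        pool <- if (swarm$gender[i] == "male") pools$sol_f else pools$sol_m
        m <- pool[sample.int(length(pool), 1L)]
      }
      cand <- delineation_candidate(
        swarm$territories[m, ],
        swarm$fitness[i] + shift, swarm$fitness[m] + shift,
        problem, config)
      swarm <- .greedy_update(swarm, i, cand, problem)
    }
  } else {
    u1 <- stats::runif(1)
    bc <- behavioral_control(temp, u1)
    u2 <- stats::runif(1)
    if (u2 * bc < config$gate_threshold) {
      # neighborhood relocation
      for (i in seq_len(n)) {
        male <- swarm$gender[i] == "male"
        use_king <- male && stats::runif(1) >= 0.5
        if (use_king) {
          toward <- swarm$territories[swarm$king_index, ]
        } else {
          pool <- if (male) pools$cor_m else pools$cor_f
          r <- .draw_rival(pool, i)
          toward <- swarm$territories[r, ]
        }
        cand <- relocation_candidate(swarm$territories[i, ], toward, bc,
                                     problem, config)
        swarm <- .greedy_update(swarm, i, cand, problem)
      }
    } else {
      # dispute
      for (i in seq_len(n)) {
        solitary <- swarm$arrangement[i] == "solitary"
        use_rival <- solitary && stats::runif(1) >= 0.5
        king <- swarm$territories[swarm$king_index, ]
        if (use_rival) {
          pool <- if (swarm$gender[i] == "male") pools$sol_m else pools$sol_f
          r <- .draw_rival(pool, i)
          cand <- dispute_candidate_rival(
            swarm$territories[r, ], king,
            swarm$fitness[i] + shift, swarm$fitness[r] + shift,
            temp, problem, config)
        } else {
          cand <- dispute_candidate_king(swarm$territories[i, ], king,
                                         temp, problem, config)
        }
        swarm <- .greedy_update(swarm, i, cand, problem)
      }
    }
  }
  swarm$iteration <- swarm$iteration + 1L
  swarm
}

# run `fn` under set.seed(seed), restoring the caller's RNG state afterwards
.with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Run snow leopard optimization
#'
#' Seeds the RNG from `config$seed` (restoring the caller's RNG state on
#' exit), initializes the population and advances it `max_iter` iterations.
#'
#' @param problem An [slo_problem()].
#' @param config An [slo_config()].
#' @param init_territories Optional matrix of rows injected into the initial
#'   population, see [initialize_population()].
#' @return An object of class `slo_result`: `best_territory`,
#'   `best_fitness`, `history` (best-so-far per iteration, length
#'   `max_iter + 1`, non-increasing), `evals`, `seed`, and the config.
#' @examples
#' p <- slo_problem(function(x) sum(x^2), dim = 2, lower = -5, upper = 5)
#' res <- slo_optimize(p, slo_config(pop_size = 10, max_iter = 50, seed = 1))
#' res$best_fitness
#' @export
slo_optimize <- function(problem, config, init_territories = NULL) {
  stopifnot(inherits(problem, "slo_problem"), inherits(config, "slo_config"))
  .with_seed(config$seed, function() {
    swarm <- initialize_population(problem, config, init_territories)
    history <- numeric(config$max_iter + 1L)
    history[1L] <- swarm$fitness[swarm$king_index]
    for (it in seq_len(config$max_iter)) {
      swarm <- slo_step(swarm, problem, config)
      history[it + 1L] <- swarm$fitness[swarm$king_index]
    }
    structure(
      list(best_territory = swarm$territories[swarm$king_index, ],
           best_fitness = swarm$fitness[swarm$king_index],
           history = history, evals = swarm$eval_count,
           seed = config$seed, config = config),
      class = "slo_result"
    )
  })
}

#' @export
print.slo_result <- function(x, ...) {
  cat(sprintf(
    "<slo_result> best fitness %.6g after %d evaluations (seed %d)\n",
    x$best_fitness, x$evals, x$seed))
  invisible(x)
}
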