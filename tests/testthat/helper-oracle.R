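# Straight-line re-implementation of one optimizer iteration, written
# directly from the four move formulas. It shares only the documented draw
# order with the package (gate draws, then members ascending; per member:
# variant uniform, rival index, per-dimension signs, then magnitudes), so a
# component-wise comparison checks the package's candidate arithmetic
# independently.

oracle_step <- function(swarm, problem, config) {
  lo <- problem$lower; up <- problem$upper; d <- problem$dim
  obj <- problem$objective
  n <- length(swarm$fitness)
  temp <- 1 - 2 * swarm$iteration / (swarm$iteration + config$max_iter)
  min_fit <- min(swarm$fitness)
  shift <- if (min_fit < 0) -min_fit else 0

  draw_sign <- function() {
    u <- runif(d)
    ifelse(u < 0.5, 1, -1)
  }
  accept <- function(i, cand) {
    f <- obj(cand)
    if (is.finite(f) && f < swarm$fitness[i]) {
      swarm$territories[i, ] <<- cand
      swarm$fitness[i] <<- f
      if (f < swarm$fitness[swarm$king_index]) swarm$king_index <<- i
    }
  }
  pick <- function(pool, self) {
    r <- pool[sample.int(length(pool), 1L)]
    if (r == self && length(pool) > 1L) r <- pool[sample.int(length(pool), 1L)]
    r
  }
  ratio2 <- function(fs, fm) {  # delineation factor
    r <- fm / (fs + config$eps)
    if (config$ratio_mode == "divide") 1 / (r + 1)^2 else (r + 1)^2
  }
  ratio1 <- function(fs, fr) {  # dispute-rival factor
    q <- fs / (fr + config$eps)
    if (config$ratio_mode == "divide") 1 / (q + 1) else (q + 1)
  }

  if (temp > config$temp_threshold) {
    for (i in seq_len(n)) {
      if (swarm$arrangement[i] == "coresiding") {
        m <- swarm$partner[i]
      } else {
        pool <- if (swarm$gender[i] == "male") swarm$pools$sol_f
                else swarm$pools$sol_m
        m <- pool[sample.int(length(pool), 1L)]
      }
      s <- draw_sign()
      u <- runif(d)
      g <- ratio2(swarm$fitness[i] + shift, swarm$fitness[m] + shift)
      cand <- swarm$territories[m, ] + s * config$c1_explore *
        ((up - lo) * u + lo) * g
      accept(i, pmin(pmax(cand, lo), up))
    }
  } else {
    u1 <- runif(1)
    bc <- u1 * (1 - temp)
    u2 <- runif(1)
    if (u2 * bc < config$gate_threshold) {
      for (i in seq_len(n)) {
        male <- swarm$gender[i] == "male"
        use_king <- male && runif(1) >= 0.5
        if (use_king) {
          toward <- swarm$territories[swarm$king_index, ]
        } else {
          pool <- if (male) swarm$pools$cor_m else swarm$pools$cor_f
          toward <- swarm$territories[pick(pool, i), ]
        }
        s <- draw_sign()
        z <- rnorm(d)
        cand <- swarm$territories[i, ] + s * config$c1_explore * bc * z *
          (swarm$territories[i, ] - toward)
        accept(i, pmin(pmax(cand, lo), up))
      }
    } else {
      for (i in seq_len(n)) {
        solitary <- swarm$arrangement[i] == "solitary"
        use_rival <- solitary && runif(1) >= 0.5
        king <- swarm$territories[swarm$king_index, ]
        if (use_rival) {
          pool <- if (swarm$gender[i] == "male") swarm$pools$sol_m
                  else swarm$pools$sol_f
          r <- pick(pool, i)
          s <- draw_sign()
          z <- rnorm(d)
          h <- ratio1(swarm$fitness[i] + shift, swarm$fitness[r] + shift)
          cand <- king + s * config$c1_dispute * z *
            ((1 - temp) * king - swarm$territories[r, ]) * h
        } else {
          s <- draw_sign()
          z <- rnorm(d)
          cand <- king + s * config$c1_dispute * z *
            ((1 - temp) * king - swarm$territories[i, ])
        }
        accept(i, pmin(pmax(cand, lo), up))
      }
    }
  }
  swarm$iteration <- swarm$iteration + 1L
  swarm
}
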