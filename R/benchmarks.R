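#' Built-in continuous benchmark functions
#'
#' Classical test functions with known global minima, used to exercise the
#' optimizer at desk scale: sphere, Rastrigin, Rosenbrock (dim >= 2), Ackley
#' and Griewank, each with its conventional box. Additional problems (for
#' example an externally supplied CEC-style suite) can be attached with
#' [register_benchmark()] and are appended to the returned list.
#'
#' @param dim Dimensionality (>= 1; Rosenbrock is skipped for `dim = 1`).
#' @return Named list of `benchmark_problem` objects, each holding a `name`,
#'   an [slo_problem()] and the `theoretical_optimum` value.
#' @examples
#' bp <- builtin_problems(2)
#' bp$sphere$problem$objective(c(1, 1, 1)[1:2])
#' @export
builtin_problems <- function(dim) {
  dim <- as.integer(dim)
  if (dim < 1L) stop("`dim` must be >= 1")
  out <- list(
    sphere = benchmark_problem(
      "sphere", function(x) sum(x^2), dim, -100, 100, 0),
    rastrigin = benchmark_problem(
      "rastrigin",
      function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
      dim, -5.12, 5.12, 0),
    ackley = benchmark_problem(
      "ackley",
      function(x) {
        -20 * exp(-0.2 * sqrt(mean(x^2))) - exp(mean(cos(2 * pi * x))) +
          20 + exp(1)
      },
      dim, -32.768, 32.768, 0),
    griewank = benchmark_problem(
      "griewank",
      function(x) sum(x^2) / 4000 - prod(cos(x / sqrt(seq_along(x)))) + 1,
      dim, -600, 600, 0)
  )
  if (dim >= 2L) {
    out$rosenbrock <- benchmark_problem(
      "rosenbrock",
      function(x) {
        i <- seq_len(length(x) - 1L)
        sum(100 * (x[i + 1L] - x[i]^2)^2 + (1 - x[i])^2)
      },
      dim, -5, 10, 0)
  }
  for (nm in ls(.benchmark_registry)) {
    out[[nm]] <- .benchmark_registry[[nm]](dim)
  }
  out
}

#' Construct a benchmark problem
#'
#' @param name Short identifier.
#' @param objective Objective function (vector in, scalar out; minimized).
#' @param dim Dimensionality.
#' @param lower,upper Scalar box bounds.
#' @param theoretical_optimum Known global minimum value.
#' @return An object of class `benchmark_problem`.
#' @export
benchmark_problem <- function(name, objective, dim, lower, upper,
                              theoretical_optimum) {
  structure(
    list(name = name,
         problem = slo_problem(objective, dim, lower, upper),
         theoretical_optimum = as.numeric(theoretical_optimum)),
    class = "benchmark_problem"
  )
}

.benchmark_registry <- new.env(parent = emptyenv())

#' Register an external benchmark factory
#'
#' Hook for wrapping an externally supplied function suite (for example the
#' official CEC2017 implementations, which ship their own shift/rotation
#' data and are not bundled here). The factory is called as `factory(dim)`
#' and must return a `benchmark_problem`; registered problems appear in
#' every subsequent [builtin_problems()] call.
#'
#' @param name Registry key.
#' @param factory Function of `dim` returning a [benchmark_problem()].
#' @return `name`, invisibly.
#' @export
register_benchmark <- function(name, factory) {
  stopifnot(is.character(name), length(name) == 1L, is.function(factory))
  assign(name, factory, envir = .benchmark_registry)
  invisible(name)
}

#' Remove a registered benchmark factory
#' @param name Registry key previously passed to [register_benchmark()].
#' @return `TRUE` invisibly.
#' @export
unregister_benchmark <- function(name) {
  if (exists(name, envir = .benchmark_registry))
    rm(list = name, envir = .benchmark_registry)
  invisible(TRUE)
}

#' Mean error over repeated runs
#'
#' Average absolute difference between the achieved optima and the known
#' theoretical optimum: `ME = mean(|actual - theoretical|)`.
#'
#' @param actual Numeric vector of achieved objective values (one per run).
#' @param theoretical Known global minimum value.
#' @return Non-negative scalar.
#' @examples
#' mean_error(c(1, 3), 0)  # 2
#' @export
mean_error <- function(actual, theoretical) {
  if (length(actual) == 0L) stop("`actual` must be non-empty")
  if (any(!is.finite(actual)) || !is.finite(theoretical))
    stop("inputs must be finite")
  mean(abs(actual - theoretical))
}

#' Repeat an optimization run and summarize the error
#'
#' Runs the optimizer `n_runs` times with seeds `base_seed`,
#' `base_seed + 1`, ..., and summarizes the per-run best fitnesses by the
#' mean error and the sample standard deviation of the per-run absolute
#' errors (0 by convention for a single run).
#'
#' @param bp A [benchmark_problem()].
#' @param config An [slo_config()] (its `seed` field is overridden per run).
#' @param n_runs Number of independent runs (>= 1).
#' @param base_seed Seed of the first run.
#' @return A list of class `repeated_run_summary` with `name`, `n_runs`,
#'   `mean_error`, `std_error` and `per_run_best`.
#' @export
repeat_runs <- function(bp, config, n_runs, base_seed = 1L) {
  stopifnot(inherits(bp, "benchmark_problem"), n_runs >= 1L)
  best <- vapply(seq_len(n_runs), function(r) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + r - 1L)
    slo_optimize(bp$problem, cfg)$best_fitness
  }, numeric(1))
  err <- abs(best - bp$theoretical_optimum)
  structure(
    list(name = bp$name, n_runs = as.integer(n_runs),
         mean_error = mean(err),
         std_error = if (n_runs > 1L) stats::sd(err) else 0,
         per_run_best = best,
         theoretical_optimum = bp$theoretical_optimum),
    class = "repeated_run_summary"
  )
}

#' Write a benchmark summary table
#'
#' One row per function with columns `function`, `mean`, `std`, `n_runs`.
#'
#' @param summaries List of [repeat_runs()] results.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_benchmark_summary <- function(summaries, path) {
  df <- data.frame(
    `function` = vapply(summaries, `[[`, character(1), "name"),
    mean = vapply(summaries, `[[`, numeric(1), "mean_error"),
    std = vapply(summaries, `[[`, numeric(1), "std_error"),
    n_runs = vapply(summaries, `[[`, integer(1), "n_runs"),
    check.names = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
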