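#' Serialize an optimization result
#'
#' Writes the best territory, best fitness, seed and a config echo as JSON,
#' and optionally the convergence history as a two-column CSV
#' (`iteration`, `best_so_far`).
#'
#' @param res An [slo_optimize()] result.
#' @param json_path Output JSON path.
#' @param history_path Optional CSV path for the history.
#' @return `json_path`, invisibly.
#' @export
write_run_result <- function(res, json_path, history_path = NULL) {
  stopifnot(inherits(res, "slo_result"))
  payload <- list(best_territory = res$best_territory,
                  best_fitness = res$best_fitness,
                  evals = res$evals, seed = res$seed,
                  config = unclass(res$config))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(history_path)) {
    utils::write.csv(
      data.frame(iteration = seq_along(res$history) - 1L,
                 best_so_far = res$history),
      history_path, row.names = FALSE)
  }
  invisible(json_path)
}

#' Write a run manifest
#'
#' Records everything needed to re-execute a command-line run
#' bit-identically: the command and arguments, the resolved configuration
#' (including seeds), a timestamp and the output paths.
#'
#' @param command Subcommand name.
#' @param args Character vector of raw arguments.
#' @param config Named list of resolved settings (must include the seeds).
#' @param outputs Character vector of files the run wrote.
#' @param path Manifest path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(command, args, config, outputs, path) {
  payload <- list(command = command, args = as.list(args),
                  config = config,
                  created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  outputs = as.list(outputs))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
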