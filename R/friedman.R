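#' Friedman average ranks of an algorithms-by-problems score table
#'
#' Ranks each problem's row in ascending order (lower score is better) with
#' mean ranks for ties, and averages the ranks per algorithm. The
#' tie-corrected Friedman chi-square statistic on `m - 1` degrees of freedom
#' is reported alongside.
#'
#' @param scores Numeric matrix or data frame, problems in rows, algorithms
#'   in columns; all entries finite; lower is better. At least 2 columns.
#' @param algorithms,problems Optional names (default: dimnames of `scores`).
#' @return An object of class `friedman_ranks`: `ranks` (p x m matrix),
#'   `average_ranks` (named, length m), `statistic`, `df`, plus the input
#'   scores and names.
#' @examples
#' friedman_average_ranks(rbind(c(1, 2, 3), c(3, 2, 1)))$average_ranks
#' @export
friedman_average_ranks <- function(scores,
                                   algorithms = colnames(scores),
                                   problems = rownames(scores)) {
  scores <- as.matrix(scores)
  if (!is.numeric(scores)) stop("`scores` must be numeric")
  if (any(!is.finite(scores))) stop("`scores` must be finite")
  p <- nrow(scores); m <- ncol(scores)
  if (p < 1L || m < 2L) stop("need at least 1 problem row and 2 algorithms")
  if (is.null(algorithms)) algorithms <- paste0("alg", seq_len(m))
  if (is.null(problems)) problems <- paste0("problem", seq_len(p))

  ranks <- t(apply(scores, 1L, rank))  # ties.method = "average"
  if (p == 1L) ranks <- matrix(ranks, nrow = 1L)
  dimnames(ranks) <- list(problems, algorithms)
  avg <- colMeans(ranks)

  # tie-corrected chi-square: 12 * sum((R_j - p(m+1)/2)^2) /
  #   (p m (m+1) - sum(t^3 - t) / (m - 1)), t over tie-group sizes per row
  ties <- unlist(apply(ranks, 1L, function(r) {
    tab <- table(r)
    sum(tab^3 - tab)
  }))
  denom <- p * m * (m + 1) - sum(ties) / (m - 1)
  stat <- if (denom > 0)
    12 * sum((colSums(ranks) - p * (m + 1) / 2)^2) / denom
  else NA_real_  # every row fully tied: statistic undefined

  structure(
    list(scores = scores, ranks = ranks, average_ranks = avg,
         statistic = stat, df = m - 1L,
         algorithms = algorithms, problems = problems),
    class = "friedman_ranks"
  )
}

#' @export
print.friedman_ranks <- function(x, ...) {
  cat("<friedman_ranks>\n")
  print(round(x$average_ranks, 4))
  cat(sprintf("Friedman chi-square = %.4g on %d d.f.\n", x$statistic, x$df))
  invisible(x)
}

#' Read a score table from CSV
#'
#' First column holds problem names, remaining columns one algorithm each;
#' header row required.
#'
#' @param path CSV path.
#' @return Numeric matrix with problem row names and algorithm column names.
#' @export
read_scores_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 3L) stop("score CSV needs a problem column and >= 2 algorithms")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Write ranks with an appended average-rank row
#'
#' @param fr A [friedman_average_ranks()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ranks_csv <- function(fr, path) {
  stopifnot(inherits(fr, "friedman_ranks"))
  out <- rbind(fr$ranks, average_rank = fr$average_ranks)
  df <- data.frame(problem = rownames(out), out, check.names = FALSE,
                   row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
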