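# K-nearest-neighbor classifier with fully deterministic tie handling.
# Hand-implemented because the wrapper objective must be deterministic given
# the run seed: distance ties go to the lower training-row index, vote ties
# to the label with the smaller summed neighbor distance, then to the
# smaller label value.

# vote on one query given its distances to the training rows
# d: distances; y: integer training labels; idx: original training indices
.knn_vote <- function(d, y, k, idx = seq_along(d)) {
  k <- min(k, length(d))
  ord <- order(d, idx)[seq_len(k)]
  labs <- y[ord]
  counts <- table(labs)
  top <- as.integer(names(counts)[counts == max(counts)])
  if (length(top) == 1L) return(top)
  sums <- vapply(top, function(l) sum(d[ord][labs == l]), numeric(1))
  top <- top[sums == min(sums)]
  min(top)
}

#' KNN prediction with deterministic tie-breaks
#'
#' Euclidean-distance K-nearest-neighbor majority vote on raw (unscaled)
#' feature values. Distance ties are broken by the lower training-row index;
#' vote ties by the smaller summed distance within the tied labels, then by
#' the smaller label value, so predictions are deterministic.
#'
#' @param train_X Numeric training matrix (rows = samples).
#' @param train_y Training labels (integer, factor or character).
#' @param query_X Numeric query matrix with the same number of columns.
#' @param k Number of neighbors (capped at the number of training rows).
#' @return Predicted labels, one per query row, of the same type as
#'   `train_y`.
#' @examples
#' x <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
#' knn_predict(x, c("A", "A", "A", "B", "B", "B"), matrix(1.5), k = 5)
#' @export
knn_predict <- function(train_X, train_y, query_X, k = 5L) {
  train_X <- as.matrix(train_X); query_X <- as.matrix(query_X)
  if (ncol(train_X) == 0L)
    stop("at least one feature column is required")
  if (ncol(query_X) != ncol(train_X))
    stop("query and training matrices must have the same number of columns")
  if (nrow(train_X) < 1L) stop("empty training set")
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be >= 1")

  lv <- sort(unique(train_y))
  y <- match(train_y, lv)
  # squared distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2 a.b
  tn <- rowSums(train_X^2)
  qn <- rowSums(query_X^2)
  d2 <- outer(qn, tn, "+") - 2 * tcrossprod(query_X, train_X)
  d2[d2 < 0] <- 0
  pred <- vapply(seq_len(nrow(query_X)),
                 function(i) .knn_vote(sqrt(d2[i, ]), y, k),
                 integer(1))
  lv[pred]
}
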