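#' Specify a synthetic expression-like dataset
#'
#' Describes a high-dimensional, small-sample labeled dataset in which a
#' small planted subset of features carries class information (a Gaussian
#' mean shift) and every other feature is label-independent noise. This
#' emulates the few-samples / many-genes regime of microarray classification
#' benchmarks.
#'
#' For an informative feature the class means sit at equally spaced points
#' `(k - (K + 1)/2) * effect_size * noise_sd`, `k = 1..K`, symmetric about 0,
#' so adjacent classes differ by `effect_size` noise standard deviations.
#'
#' @param n_samples Number of samples (rows).
#' @param n_features Number of features (columns).
#' @param n_informative Number of planted informative features (>= 1).
#' @param n_classes Number of classes (>= 2).
#' @param effect_size Between-class mean shift in noise-SD units (> 0).
#' @param noise_sd Noise standard deviation (> 0).
#' @param class_proportions Optional vector of class proportions (sums to 1);
#'   equal by default.
#' @param seed Integer seed.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_samples, n_features, n_informative = 10L,
                       n_classes = 2L, effect_size = 2, noise_sd = 1,
                       class_proportions = NULL, seed = 1L) {
  n_samples <- as.integer(n_samples); n_features <- as.integer(n_features)
  n_informative <- as.integer(n_informative); n_classes <- as.integer(n_classes)
  if (n_samples < 2L * n_classes)
    stop("need at least 2 samples per class")
  if (n_informative < 1L || n_informative > n_features)
    stop("`n_informative` must lie in [1, n_features]")
  if (n_classes < 2L) stop("`n_classes` must be >= 2")
  if (effect_size <= 0 || noise_sd <= 0)
    stop("`effect_size` and `noise_sd` must be positive")
  if (is.null(class_proportions))
    class_proportions <- rep(1 / n_classes, n_classes)
  if (length(class_proportions) != n_classes ||
      abs(sum(class_proportions) - 1) > 1e-8 || any(class_proportions <= 0))
    stop("`class_proportions` must be positive and sum to 1")
  structure(
    list(n_samples = n_samples, n_features = n_features,
         n_informative = n_informative, n_classes = n_classes,
         effect_size = effect_size, noise_sd = noise_sd,
         class_proportions = class_proportions, seed = as.integer(seed)),
    class = "synth_spec"
  )
}

# largest-remainder apportionment of n into counts proportional to p
.apportion <- function(n, p) {
  raw <- n * p
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Generate a synthetic labeled dataset with planted informative features
#'
#' Class sizes are apportioned deterministically from the proportions
#' (largest remainder) and the label vector shuffled; all features start as
#' i.i.d. `Normal(0, noise_sd^2)` noise; the planted features (positions
#' drawn uniformly without replacement) receive the class-specific mean
#' offsets described in [synth_spec()]. The caller's RNG state is restored.
#'
#' @param spec A [synth_spec()].
#' @return A list with `dataset` (a [labeled_dataset()]), `informative`
#'   (sorted integer vector of planted feature indices) and `spec`.
#' @examples
#' g <- generate_expression_data(synth_spec(40, 100, n_informative = 5))
#' dim(g$dataset$X)
#' @export
generate_expression_data <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  .with_seed(spec$seed, function() {
    counts <- .apportion(spec$n_samples, spec$class_proportions)
    if (any(counts < 2L)) stop("every class must receive >= 2 samples")
    y <- sample(rep.int(seq_len(spec$n_classes), counts))
    X <- matrix(stats::rnorm(spec$n_samples * spec$n_features,
                             sd = spec$noise_sd),
                nrow = spec$n_samples, ncol = spec$n_features)
    informative <- sort(sample.int(spec$n_features, spec$n_informative))
    mu <- (seq_len(spec$n_classes) - (spec$n_classes + 1) / 2) *
      spec$effect_size * spec$noise_sd
    X[, informative] <- X[, informative] + mu[y]
    colnames(X) <- sprintf("feature_%05d", seq_len(spec$n_features))
    list(dataset = labeled_dataset(X, y),
         informative = informative, spec = spec)
  })
}

#' Dataset regimes mirroring common microarray benchmarks
#'
#' Eight (features, instances, classes) shapes matching widely used
#' gene-expression classification benchmarks (CL-SUB-111, Colon, GLIOMA,
#' GLl-85, Lung, Lymphoma, Prostate-GE, SMK-CAN-187), each with 10 planted
#' informative features at effect size 2 by default. Only the shapes are
#' reproduced; the generated data are synthetic.
#'
#' @param n_informative,effect_size Passed to every [synth_spec()].
#' @param seed Base seed; regime i uses `seed + i - 1`.
#' @return Named list of eight `synth_spec` objects.
#' @export
expression_regimes <- function(n_informative = 10L, effect_size = 2,
                               seed = 1L) {
  shapes <- list(
    "CL-SUB-111"  = c(11340L, 111L, 3L),
    "Colon"       = c(2000L, 62L, 2L),
    "GLIOMA"      = c(4434L, 50L, 4L),
    "GLl-85"      = c(22283L, 85L, 2L),
    "Lung"        = c(3312L, 203L, 5L),
    "Lymphoma"    = c(4026L, 96L, 9L),
    "Prostate-GE" = c(5966L, 102L, 2L),
    "SMK-CAN-187" = c(19993L, 187L, 2L)
  )
  out <- vector("list", length(shapes))
  names(out) <- names(shapes)
  for (i in seq_along(shapes)) {
    s <- shapes[[i]]
    out[[i]] <- synth_spec(n_samples = s[2L], n_features = s[1L],
                           n_informative = n_informative,
                           n_classes = s[3L], effect_size = effect_size,
                           seed = seed + i - 1L)
  }
  out
}

#' Write a generated dataset with its ground truth
#'
#' Writes the labeled table as CSV (see [write_labeled_csv()]) and a sidecar
#' JSON holding the generating spec and the planted informative indices.
#'
#' @param gen Result of [generate_expression_data()].
#' @param csv_path Output CSV path.
#' @param json_path Output sidecar path; default replaces the extension.
#' @return `csv_path`, invisibly.
#' @export
write_synth_dataset <- function(gen, csv_path,
                                json_path = sub("\\.[^.]*$", ".json",
                                                csv_path)) {
  write_labeled_csv(gen$dataset, csv_path)
  side <- list(spec = unclass(gen$spec), informative = gen$informative)
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
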