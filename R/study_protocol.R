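# Desk-verifiable arithmetic of the study design: the train/test split,
# the training-iteration schedule, and the genetic-map summary.

#' Randomly split items into training and testing sets
#'
#' Uniform random partition with a floor-sized training set:
#' `floor(n * train_fraction)` items train, the rest test. Set sizes
#' depend only on `n` and the fraction, never on the seed.
#'
#' @param item_ids vector of item identifiers (e.g., annotated image ids).
#' @param train_fraction fraction in (0, 1); default 0.8.
#' @param seed optional integer seed (local to this call).
#' @return object of class `split_plan`: list with `train_ids`,
#'   `test_ids`, `n_total`, `train_fraction`, `seed`.
#' @export
split_dataset <- function(item_ids, train_fraction = 0.8, seed = NULL) {
  if (length(item_ids) == 0L) stop("cannot split an empty item set")
  if (anyDuplicated(item_ids)) stop("item_ids must be unique")
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  n <- length(item_ids)
  n_train <- floor(n * train_fraction)
  train <- with_seed(seed, sample(item_ids, n_train))
  structure(list(train_ids = train,
                 test_ids = setdiff(item_ids, train),
                 n_total = n, train_fraction = train_fraction,
                 seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan: %d items -> %d train / %d test (fraction %.2f)>\n",
              x$n_total, length(x$train_ids), length(x$test_ids),
              x$train_fraction))
  invisible(x)
}

#' Serialise a split plan as JSON for pipeline provenance
#'
#' @param plan `split_plan` from [split_dataset()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Total optimiser iterations of an epoch-based training schedule
#'
#' `epochs * ceiling(n_train / (batch_per_device * n_devices))`: each epoch
#' visits every training item once, with the last (possibly partial) batch
#' rounded up. With 36 epochs, 44 training images and batch size 1 on 2
#' devices this gives 792 iterations.
#'
#' @param epochs,n_train,batch_per_device,n_devices positive integers.
#' @return total iteration count.
#' @export
training_iteration_count <- function(epochs, n_train, batch_per_device = 1L,
                                     n_devices = 1L) {
  stopifnot(epochs >= 1L, n_train >= 1L, batch_per_device >= 1L,
            n_devices >= 1L)
  epochs * ceiling(n_train / (batch_per_device * n_devices))
}

#' Summarise a genetic map from per-chromosome marker counts
#'
#' @param per_chromosome_marker_counts positive integer vector, one entry
#'   per chromosome.
#' @return list with `total_markers` and `n_chromosomes`.
#' @export
genetic_map_summary <- function(per_chromosome_marker_counts) {
  x <- per_chromosome_marker_counts
  if (length(x) == 0L) stop("need at least one chromosome")
  if (any(x <= 0)) stop("marker counts must be positive")
  list(total_markers = sum(x), n_chromosomes = length(x))
}
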