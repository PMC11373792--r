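# Stratified 7:2:1 train/validation/test splitting.

#' Split specification
#'
#' Ratios default to 7:2:1 with the rounding rule
#' `train = floor(0.7 n)`, `val = round-half-up(0.2 n)`,
#' `test = n - train - val`, the unique simple convention that reproduces
#' the published per-variety table from its row totals.
#'
#' @param ratios Numeric length-3 vector of train/val/test proportions
#'   (normalized internally).
#' @param rng_seed Integer seed controlling which items land in which
#'   split.
#' @param group_by_parent If `TRUE` (default) all augmented variants of
#'   one original seed are kept in the same split (leakage guard); set
#'   `FALSE` for the plain per-image split, whose per-class sizes match
#'   [split_counts()] exactly.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(ratios = c(7, 2, 1), rng_seed = 1L, group_by_parent = TRUE) {
  stopifnot(length(ratios) == 3L, all(ratios >= 0), sum(ratios) > 0)
  structure(list(ratios = ratios / sum(ratios), rng_seed = as.integer(rng_seed),
                 group_by_parent = isTRUE(group_by_parent)),
            class = "split_spec")
}

#' Per-class split sizes
#'
#' @param n Per-class total (>= 0), vectorised.
#' @param spec A [split_spec()].
#' @return For scalar `n`, a named integer vector `(train, val, test)`;
#'   for vector `n`, a data frame with one row per element. Parts are
#'   non-negative and always sum to `n`.
#' @export
split_counts <- function(n, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  n <- as.integer(n)
  if (any(n < 0)) stop("n must be >= 0")
  r <- spec$ratios
  train <- as.integer(floor(r[1] * n))
  val <- as.integer(floor(r[2] * n + 0.5))   # round half up
  test <- n - train - val
  if (any(test < 0)) { val <- val + test * (test < 0); test <- pmax(test, 0L) }
  if (length(n) == 1L) c(train = train, val = val, test = test)
  else data.frame(n = n, train = train, val = val, test = test)
}

#' Assign manifest rows to train/validation/test
#'
#' Stratified by class label; membership is decided by a seeded shuffle.
#' In grouped mode (the default leakage guard) all rows sharing a
#' `parent_id` travel together and per-class sizes approximate
#' [split_counts()] to within one group; in ungrouped mode
#' (`group_by_parent = FALSE`, the published protocol) sizes match
#' exactly.
#'
#' @param manifest Data frame with columns `label` and (for grouped
#'   mode) `parent_id`.
#' @param spec A [split_spec()].
#' @return The manifest with a `split` factor column
#'   (train/val/test).
#' @export
assign_split <- function(manifest, spec = split_spec()) {
  stopifnot(is.data.frame(manifest), "label" %in% names(manifest),
            inherits(spec, "split_spec"))
  use_groups <- spec$group_by_parent && "parent_id" %in% names(manifest)
  if (spec$group_by_parent && !use_groups && nrow(manifest) > 0L)
    warning("no parent_id column; falling back to ungrouped assignment")
  split <- rep(NA_character_, nrow(manifest))
  with_seed(spec$rng_seed, {
    for (cl in unique(manifest$label)) {
      idx <- which(manifest$label == cl)
      n <- length(idx)
      parts <- split_counts(n, spec)
      if (n < 3L && any(parts == 0L))
        warning(sprintf("class '%s' has only %d item(s); some splits are empty", cl, n))
      if (!use_groups) {
        sh <- sample(idx)
        split[sh[seq_len(parts["train"])]] <- "train"
        if (parts["val"] > 0)
          split[sh[parts["train"] + seq_len(parts["val"])]] <- "val"
        if (parts["test"] > 0)
          split[sh[parts["train"] + parts["val"] + seq_len(parts["test"])]] <- "test"
      } else {
        groups <- split(idx, manifest$parent_id[idx])
        groups <- groups[sample(length(groups))]
        filled <- c(train = 0L, val = 0L, test = 0L)
        target <- parts
        for (g in groups) {
          deficit <- target - filled
          dest <- names(which.max(deficit))
          split[g] <- dest
          filled[dest] <- filled[dest] + length(g)
        }
      }
    }
  })
  manifest$split <- factor(split, levels = c("train", "val", "test"))
  manifest
}
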