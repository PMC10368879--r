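# Seeded stratified splitting shared by training and evaluation.

# Default seed recorded in every report.
DEFAULT_SPLIT_SEED <- 1218679L

#' Stratified train/validation split indices
#'
#' @param labels Character/factor vector of class labels.
#' @param p_holdout Fraction held out (e.g. 0.3 for the internal validation
#'   split).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `holdout`; every class
#'   is represented on both sides whenever it has >= 2 members.
#' @export
stratified_holdout <- function(labels, p_holdout = 0.3,
                               seed = DEFAULT_SPLIT_SEED) {
  idx <- with_seed(seed, {
    hold <- integer()
    for (cl in unique(labels)) {
      members <- which(labels == cl)
      n_hold <- max(1L, round(p_holdout * length(members)))
      if (length(members) >= 2L) n_hold <- min(n_hold, length(members) - 1L)
      hold <- c(hold, sample(members, n_hold))
    }
    hold
  })
  list(train = setdiff(seq_along(labels), idx), holdout = sort(idx))
}

#' Stratified k-fold assignment
#'
#' @param labels Class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:k`, one per label; folds are
#'   disjoint, exhaustive, and class-balanced. Errors when a class has fewer
#'   members than folds (a fold would miss the class).
#' @export
stratified_folds <- function(labels, k = 5L, seed = DEFAULT_SPLIT_SEED) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      members <- which(labels == cl)
      if (length(members) < k) {
        stop_ade("ade_stratification_error",
                 "class '%s' has %d members, fewer than %d folds",
                 cl, length(members), k)
      }
      fold[members] <- sample(rep_len(seq_len(k), length(members)))
    }
  })
  fold
}
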