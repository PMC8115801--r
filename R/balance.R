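#' Class-balancing configuration
#'
#' @param k_neighbors number of nearest minority neighbors SMOTE
#'   interpolates towards (canonical default 5; reduced with a warning when
#'   the minority class has fewer than `k_neighbors + 1` members).
#' @param min_minority_per_subject subjects whose minority-class block
#'   count is strictly below this are excluded from analysis.
#' @param seed optional seed.
#' @return an object of class `mw_balance_config`.
#' @export
balance_config <- function(k_neighbors = 5L, min_minority_per_subject = 5L,
                           seed = NULL) {
  assert_that(k_neighbors >= 1, "balance", "k_neighbors must be >= 1")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 min_minority_per_subject = as.integer(min_minority_per_subject),
                 seed = seed),
            class = "mw_balance_config")
}

#' SMOTE minority oversampling
#'
#' Balances a two-class training set by synthesizing minority-class rows:
#' each synthetic row is `x + g * (z - x)` for a real minority row `x`, one
#' of its `k` nearest minority neighbors `z` (Euclidean distance), and `g`
#' drawn uniformly on `[0, 1]`. Parents cycle deterministically over the
#' minority rows until the deficit is met; the neighbor and `g` are redrawn
#' per synthetic row. Original rows are returned unchanged, majority rows
#' are never used as parents or neighbors.
#'
#' @param x numeric feature matrix or data.frame (rows = instances).
#' @param y binary label vector (two distinct values; the rarer one is the
#'   minority class).
#' @param config an `mw_balance_config`.
#' @param seed optional seed (defaults to `config$seed`).
#' @return list with `x` (original rows first, then synthetic), `y`,
#'   `synthetic` (logical), and for auditing `parent`, `neighbor` (row
#'   indices into `x`) and `gamma` per synthetic row.
#' @export
smote <- function(x, y, config = balance_config(), seed = config$seed) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y))
  tab <- table(y)
  assert_that(length(tab) == 2, "balance", "exactly two classes required")
  minority <- names(tab)[which.min(tab)]
  n_min <- min(tab); n_maj <- max(tab)
  deficit <- n_maj - n_min
  if (deficit == 0)
    return(list(x = x, y = y, synthetic = rep(FALSE, nrow(x)),
                parent = integer(0), neighbor = integer(0), gamma = numeric(0)))
  assert_that(n_min >= 2, "balance", "minority class needs at least 2 rows")
  k <- config$k_neighbors
  if (k > n_min - 1) {
    warning(sprintf("k_neighbors reduced from %d to %d (minority size %d)",
                    k, n_min - 1, n_min), call. = FALSE)
    k <- n_min - 1
  }
  min_idx <- which(y == minority)
  xm <- x[min_idx, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- apply(d, 1, function(r) order(r)[seq_len(k)])
  nn <- matrix(nn, nrow = k)               # k x n_min, columns = parents
  with_seed(seed, {
    parents <- rep_len(seq_along(min_idx), deficit)
    pick <- if (k == 1) rep(1L, deficit) else
      sample.int(k, deficit, replace = TRUE)
    gam <- stats::runif(deficit)
    nbrs <- nn[cbind(pick, parents)]
    synth <- xm[parents, , drop = FALSE] +
      gam * (xm[nbrs, , drop = FALSE] - xm[parents, , drop = FALSE])
    list(x = rbind(x, synth),
         y = c(y, rep(if (is.numeric(y)) as.numeric(minority) else minority,
                      deficit)),
         synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, deficit)),
         parent = min_idx[parents], neighbor = min_idx[nbrs], gamma = gam)
  })
}

#' Exclude subjects with too few minority-class blocks
#'
#' Removes every subject whose per-subject minority-class count (the rarer
#' of that subject's own two label counts) is strictly below
#' `min_minority_per_subject`; SMOTE cannot build reliable synthetic rows
#' for them.
#'
#' @param features a labeled feature table.
#' @param config an `mw_balance_config`.
#' @return list with `features` (retained rows) and `excluded` (subject ids).
#' @export
exclude_low_minority_subjects <- function(features, config = balance_config()) {
  excluded <- character(0)
  for (sid in unique(features$subject_id)) {
    lab <- features$label[features$subject_id == sid]
    n_min <- min(sum(lab == 0), sum(lab == 1))
    if (n_min < config$min_minority_per_subject) excluded <- c(excluded, sid)
  }
  if (length(excluded))
    message("excluded subject(s) with minority class < ",
            config$min_minority_per_subject, ": ",
            paste(excluded, collapse = ", "))
  list(features = features[!features$subject_id %in% excluded, , drop = FALSE],
       excluded = excluded)
}
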