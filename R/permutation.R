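#' Random-draw null for a focal gene set's topology and constraint
#'
#' Tests whether a focal gene set (for example hibernation-associated
#' genes) occupies unusual network positions or constraint levels: for each
#' requested metric, the observed statistic is the mean over the focal
#' genes, and the null distribution is built by drawing `n_draws` gene sets
#' of the same size uniformly without replacement from the sampling frame
#' (all table rows with non-missing values for the requested metrics; the
#' focal genes remain in the frame). The same draws are used for every
#' metric.
#'
#' The empirical p-value uses the add-one estimator
#' `(1 + #draws at least as extreme) / (n_draws + 1)`, which can never be
#' 0; two-sided p doubles the smaller tail, capped at 1.
#'
#' @param table data.frame with a `node` column and one column per metric
#'   (e.g. from [node_metrics()] joined with constraint values).
#' @param focal character vector of focal gene ids (must all be in
#'   `table$node`; at least 2).
#' @param metrics which columns to test. Default `aspl`, `bc`, `nc`,
#'   `mean_phylop` where present.
#' @param n_draws number of random draws (default 1000).
#' @param tail `"two-sided"` (default), `"greater"` or `"less"`.
#' @param seed integer seed.
#' @return a list of `nc_null` objects, one per metric, each with
#'   `metric`, `observed`, `null_means`, `empirical_p`, `tail`, `n_draws`,
#'   `n_frame`, `n_focal`.
#' @export
random_draw_null <- function(table, focal,
                             metrics = intersect(c("aspl", "bc", "nc",
                                                   "mean_phylop"),
                                                 names(table)),
                             n_draws = 1000L,
                             tail = c("two-sided", "greater", "less"),
                             seed = 1L) {
  tail <- match.arg(tail)
  stopifnot(is.data.frame(table), "node" %in% names(table),
            length(metrics) >= 1L, all(metrics %in% names(table)))
  focal <- as.character(focal)
  if (length(focal) < 2L) stop("focal set needs at least 2 genes")
  missing_focal <- setdiff(focal, table$node)
  if (length(missing_focal)) {
    stop("focal gene(s) not in table: ",
         paste(utils::head(missing_focal, 5), collapse = ", "))
  }
  # sampling frame: complete cases over the tested metrics
  frame <- table[stats::complete.cases(table[, metrics, drop = FALSE]), ]
  if (!all(focal %in% frame$node)) {
    stop("focal gene(s) have missing metric values: ",
         paste(setdiff(focal, frame$node), collapse = ", "))
  }
  k <- length(focal)
  n <- nrow(frame)
  if (k > n) stop("focal set larger than sampling frame")
  nc_log("random_draw_null: ", n_draws, " draws of ", k, " from frame of ",
         n, " (tail=", tail, ")")

  draw_idx <- with_seed(derive_seed(seed, "permutation"), {
    replicate(n_draws, sample.int(n, k), simplify = FALSE)
  })

  lapply(stats::setNames(metrics, metrics), function(m) {
    vals <- frame[[m]]
    observed <- mean(vals[match(focal, frame$node)])
    null_means <- vapply(draw_idx, function(ix) mean(vals[ix]), 1.0)
    p_greater <- (1 + sum(null_means >= observed)) / (n_draws + 1)
    p_less <- (1 + sum(null_means <= observed)) / (n_draws + 1)
    p <- switch(tail,
                greater = p_greater,
                less = p_less,
                `two-sided` = min(1, 2 * min(p_greater, p_less)))
    structure(list(metric = m, observed = observed, null_means = null_means,
                   empirical_p = p, tail = tail, n_draws = n_draws,
                   n_frame = n, n_focal = k),
              class = "nc_null")
  })
}

#' @export
print.nc_null <- function(x, ...) {
  cat(sprintf(
    "Random-draw null for %s: observed mean %.4g vs %d draws (frame %d)\n",
    x$metric, x$observed, x$n_draws, x$n_frame))
  cat(sprintf("  null mean %.4g (sd %.4g), empirical p = %.4g (%s)\n",
              mean(x$null_means), stats::sd(x$null_means), x$empirical_p,
              x$tail))
  invisible(x)
}
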