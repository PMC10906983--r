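#' Seed hub/intermediate/peripheral labels from metric percentiles
#'
#' Preclassifies the most extreme nodes of each metric as training seeds:
#' the top `pct_bc` fraction by betweenness centrality becomes hub (H)
#' seeds, the top `pct_nc` by neighborhood connectivity intermediate (I),
#' and the top `pct_aspl` by average shortest path length peripheral (P).
#' The hub cut is an order of magnitude smaller because hubs are the rarest
#' class in scale-free-like networks.
#'
#' A node can land in more than one top set; conflicts are resolved by the
#' priority H > I > P (BC is the most specific hub signal and hubs are the
#' rarest class). Conflict counts are logged.
#'
#' @param metrics data.frame from [node_metrics()].
#' @param pct_bc,pct_nc,pct_aspl top-quantile fractions for the H, I and P
#'   seed sets. Defaults 0.01, 0.10, 0.10.
#' @return data.frame with columns `node`, `label` (factor H/I/P), one row
#'   per seeded node; attribute `conflicts` counts multiply-seeded nodes.
#' @export
seed_labels <- function(metrics, pct_bc = 0.01, pct_nc = 0.10,
                        pct_aspl = 0.10) {
  stopifnot(is.data.frame(metrics),
            all(c("node", "aspl", "bc", "nc") %in% names(metrics)))
  n <- nrow(metrics)
  top_frac <- function(values, frac, what) {
    if (length(unique(values)) == 1L) {
      stop("degenerate quantile: all ", what, " values identical")
    }
    k <- max(1L, ceiling(frac * n))
    ord <- order(-values, metrics$node)  # node id breaks metric ties
    metrics$node[ord[seq_len(k)]]
  }
  h <- top_frac(metrics$bc, pct_bc, "BC")
  i <- top_frac(metrics$nc, pct_nc, "NC")
  p <- top_frac(metrics$aspl, pct_aspl, "ASPL")
  conflicts <- sum(i %in% h) + sum(p %in% h) + sum(p %in% i)
  i <- setdiff(i, h)
  p <- setdiff(p, union(h, i))
  sizes <- c(H = length(h), I = length(i), P = length(p))
  if (any(sizes == 0L)) {
    stop("quantile cut leaves empty seed class: ",
         paste(names(sizes)[sizes == 0L], collapse = ", "))
  }
  nc_log("seed_labels: H=", sizes["H"], " I=", sizes["I"], " P=", sizes["P"],
         " (", conflicts, " conflict(s) resolved H > I > P)")
  out <- data.frame(node = c(h, i, p),
                    label = factor(rep(c("H", "I", "P"), sizes),
                                   levels = c("H", "I", "P")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "conflicts") <- conflicts
  out
}

# standardize a feature matrix with a stored transform
apply_transform <- function(x, center, scale) {
  sweep(sweep(as.matrix(x), 2, center, "-"), 2, scale, "/")
}

#' Balance seed classes with SMOTE oversampling
#'
#' Brings every class up to the majority-class count by synthesizing
#' interpolated minority points: each synthetic row lies on the segment
#' between a real minority row and one of its `k_neighbors` nearest
#' same-class neighbors in standardized feature space, at a uniform random
#' position along the segment.
#'
#' Features (aspl, bc, nc) are standardized to zero mean and unit variance
#' computed on the seed rows only; the transform is stored in attributes
#' `center` and `scale` so that prediction-time features can be mapped
#' through the identical transform without leakage from unlabeled nodes.
#'
#' @param seeds data.frame from [seed_labels()].
#' @param metrics data.frame from [node_metrics()] covering all seed nodes.
#' @param k_neighbors number of same-class nearest neighbors to interpolate
#'   toward (default 5). Every class must have at least `k_neighbors + 1`
#'   members.
#' @param seed integer seed for reproducibility.
#' @return a training data.frame with columns `node` (NA for synthetic
#'   rows), `label`, standardized `aspl`, `bc`, `nc`, and logical
#'   `synthetic`; attributes `center` and `scale` hold the standardization.
#' @export
oversample_minority <- function(seeds, metrics, k_neighbors = 5L, seed = 1L) {
  stopifnot(is.data.frame(seeds), all(c("node", "label") %in% names(seeds)))
  feat_cols <- c("aspl", "bc", "nc")
  idx <- match(seeds$node, metrics$node)
  if (anyNA(idx)) stop("seed node(s) missing from metrics table")
  x <- as.matrix(metrics[idx, feat_cols])
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  x <- apply_transform(x, center, scale)

  label <- factor(as.character(seeds$label), levels = c("H", "I", "P"))
  counts <- table(label)
  target <- max(counts)
  need <- target - counts
  small <- names(counts)[counts < k_neighbors + 1L & need > 0L]
  if (length(small)) {
    stop("class ", paste(small, collapse = ", "), " has fewer than ",
         k_neighbors + 1L, " members; use a smaller k_neighbors")
  }

  synth <- with_seed(seed, {
    rows <- list()
    for (cls in names(counts)[need > 0L]) {
      xc <- x[label == cls, , drop = FALSE]
      dmat <- as.matrix(stats::dist(xc))
      diag(dmat) <- Inf
      n_new <- need[[cls]]
      base <- sample.int(nrow(xc), n_new, replace = TRUE)
      pts <- matrix(NA_real_, n_new, ncol(xc),
                    dimnames = list(NULL, colnames(xc)))
      for (j in seq_len(n_new)) {
        nb_pool <- order(dmat[base[j], ])[seq_len(min(k_neighbors, nrow(xc) - 1L))]
        nb <- nb_pool[sample.int(length(nb_pool), 1L)]
        gap <- stats::runif(1)
        pts[j, ] <- xc[base[j], ] + gap * (xc[nb, ] - xc[base[j], ])
      }
      rows[[cls]] <- data.frame(node = NA_character_,
                                label = factor(cls, levels = levels(label)),
                                pts, synthetic = TRUE,
                                stringsAsFactors = FALSE)
    }
    rows
  })

  real <- data.frame(node = seeds$node, label = label, x, synthetic = FALSE,
                     stringsAsFactors = FALSE)
  out <- do.call(rbind, c(list(real), unname(synth)))
  rownames(out) <- NULL
  if (nrow(out) > nrow(real)) {
    nc_log("oversample_minority: added ", nrow(out) - nrow(real),
           " synthetic row(s); classes balanced at ", target)
  }
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

svm_fit <- function(training, probability = FALSE) {
  e1071::svm(x = as.matrix(training[, c("aspl", "bc", "nc")]),
             y = training$label, kernel = "radial", cost = 1,
             scale = FALSE, probability = probability)
}

#' Replicated k-fold cross-validation of the node classifier
#'
#' Repeatedly partitions the balanced training table into `folds` random
#' folds, trains the support-vector classifier on the rest and scores the
#' held-out fold, to check that classification performance does not hinge
#' on a particular split or on residual class imbalance. Both plain and
#' stratified (per-class) fold assignment are supported; running both and
#' comparing rules out imbalance artifacts.
#'
#' @param training balanced training table from [oversample_minority()].
#' @param folds folds per replicate (default 9).
#' @param replicates number of replicated partitions (default 1000; scale
#'   down for quick checks).
#' @param stratified assign folds within each class so every fold has the
#'   class proportions of the whole table.
#' @param seed integer seed.
#' @return an object of class `nc_cv`: a list of per-replicate reports,
#'   each with `replicate`, `fold_accuracy`, `precision`, `recall`,
#'   `stratified`. Summarize with [summarize_cv()].
#' @export
cross_validate <- function(training, folds = 9L, replicates = 1000L,
                           stratified = FALSE, seed = 1L) {
  stopifnot(folds >= 2L, replicates >= 1L)
  label <- training$label
  if (stratified && any(table(label) < folds)) {
    stop("stratified CV needs every class to have at least ", folds,
         " members")
  }
  if (nrow(training) < folds) stop("fewer rows than folds")
  x <- as.matrix(training[, c("aspl", "bc", "nc")])
  classes <- levels(label)

  reports <- with_seed(derive_seed(seed, "cv"), {
    lapply(seq_len(replicates), function(r) {
      fold_of <- integer(nrow(training))
      if (stratified) {
        for (cls in classes) {
          members <- which(label == cls)
          fold_of[members] <- sample(rep_len(seq_len(folds), length(members)))
        }
      } else {
        fold_of <- sample(rep_len(seq_len(folds), nrow(training)))
      }
      conf <- matrix(0L, length(classes), length(classes),
                     dimnames = list(truth = classes, pred = classes))
      acc <- numeric(folds)
      for (f in seq_len(folds)) {
        test <- fold_of == f
        fit <- e1071::svm(x = x[!test, , drop = FALSE], y = label[!test],
                          kernel = "radial", cost = 1, scale = FALSE)
        pred <- stats::predict(fit, x[test, , drop = FALSE])
        acc[f] <- mean(pred == label[test])
        conf <- conf + table(factor(label[test], classes),
                             factor(pred, classes))
      }
      list(replicate = r, fold_accuracy = acc,
           precision = diag(conf) / pmax(colSums(conf), 1L),
           recall = diag(conf) / pmax(rowSums(conf), 1L),
           stratified = stratified)
    })
  })
  structure(reports, class = "nc_cv")
}

#' Summarize a replicated cross-validation run
#'
#' @param reports an `nc_cv` object from [cross_validate()].
#' @return list with `mean_accuracy`, `sd_accuracy`, `replicates`,
#'   `stratified`, and mean per-class `precision` and `recall`.
#' @export
summarize_cv <- function(reports) {
  acc <- vapply(reports, function(r) mean(r$fold_accuracy), 1.0)
  list(mean_accuracy = mean(acc),
       sd_accuracy = stats::sd(acc),
       replicates = length(reports),
       stratified = reports[[1]]$stratified,
       precision = rowMeans(vapply(reports, `[[`, numeric(3), "precision")),
       recall = rowMeans(vapply(reports, `[[`, numeric(3), "recall")))
}

#' Classify all network nodes as hub, intermediate, peripheral or uncertain
#'
#' Trains a radial-kernel support-vector machine (one-vs-one, cost 1,
#' kernel width `1/n_features` on unit-variance features) with Platt
#' probability calibration on the full balanced training table, then labels
#' every non-seed node with the class of maximum calibrated probability.
#' That maximum probability is the decision support; predictions with
#' support below `support_threshold` are declassified to `"uncertain"`
#' (their pre-filter label is kept in `predicted_label` for audit). Seed
#' nodes keep their seed label.
#'
#' @param training balanced training table from [oversample_minority()].
#' @param metrics data.frame from [node_metrics()] for the whole network.
#' @param support_threshold minimum calibrated class probability to retain
#'   a prediction (default 0.5).
#' @param seed integer seed (controls the probability-calibration split).
#' @return data.frame with one row per network node: `node`, `label`
#'   (H/I/P/uncertain), `support` (NA for seeds), `predicted_label`,
#'   `source` (seed/predicted).
#' @export
classify_nodes <- function(training, metrics, support_threshold = 0.5,
                           seed = 1L) {
  stopifnot(is.data.frame(training), is.data.frame(metrics))
  center <- attr(training, "center")
  scale <- attr(training, "scale")
  if (is.null(center) || is.null(scale)) {
    stop("training table lacks its standardization transform; ",
         "build it with oversample_minority()")
  }
  fit <- with_seed(derive_seed(seed, "svm"), svm_fit(training, probability = TRUE))

  seed_nodes <- training$node[!training$synthetic]
  seed_label <- as.character(training$label[!training$synthetic])
  is_seed <- metrics$node %in% seed_nodes

  out <- data.frame(node = metrics$node,
                    label = NA_character_,
                    support = NA_real_,
                    predicted_label = NA_character_,
                    source = ifelse(is_seed, "seed", "predicted"),
                    stringsAsFactors = FALSE)
  out$label[is_seed] <- seed_label[match(out$node[is_seed], seed_nodes)]

  if (any(!is_seed)) {
    xq <- apply_transform(metrics[!is_seed, c("aspl", "bc", "nc")],
                          center, scale)
    pred <- stats::predict(fit, xq, probability = TRUE)
    prob <- attr(pred, "probabilities")
    prob <- prob[, levels(training$label), drop = FALSE]
    best <- max.col(prob, ties.method = "first")
    out$predicted_label[!is_seed] <- colnames(prob)[best]
    out$support[!is_seed] <- prob[cbind(seq_len(nrow(prob)), best)]
    out$label[!is_seed] <- ifelse(out$support[!is_seed] < support_threshold,
                                  "uncertain", out$predicted_label[!is_seed])
  }
  counts <- table(factor(out$label, c("H", "I", "P", "uncertain")))
  nc_log("classify_nodes: H=", counts["H"], " I=", counts["I"],
         " P=", counts["P"], " uncertain=", counts["uncertain"],
         " (support threshold ", support_threshold, ")")
  out
}

# Default SMOTE neighborhood: the standard 5, capped at one below the
# smallest seed class so percentile seeding on small networks still yields
# a feasible oversampling problem. The value used is logged.
default_k_neighbors <- function(seeds, k = NULL) {
  if (!is.null(k)) return(as.integer(k))
  k <- max(1L, min(5L, min(base::table(seeds$label)) - 1L))
  nc_log("k_neighbors set to ", k, " (capped by smallest seed class)")
  k
}

#' Run the full node classification stage
#'
#' Convenience wrapper: percentile seeding, SMOTE balancing and SVM
#' classification in one call. `k_neighbors = NULL` (the default) uses the
#' standard 5 SMOTE neighbors capped at one below the smallest seed class.
#'
#' @inheritParams seed_labels
#' @inheritParams oversample_minority
#' @inheritParams classify_nodes
#' @return the node class table from [classify_nodes()], with the seed
#'   table in attribute `seeds` and the training table in `training`.
#' @export
classify_network <- function(metrics, pct_bc = 0.01, pct_nc = 0.10,
                             pct_aspl = 0.10, k_neighbors = NULL,
                             support_threshold = 0.5, seed = 1L) {
  seeds <- seed_labels(metrics, pct_bc = pct_bc, pct_nc = pct_nc,
                       pct_aspl = pct_aspl)
  k_neighbors <- default_k_neighbors(seeds, k_neighbors)
  training <- oversample_minority(seeds, metrics, k_neighbors = k_neighbors,
                                  seed = derive_seed(seed, "smote"))
  out <- classify_nodes(training, metrics,
                        support_threshold = support_threshold, seed = seed)
  attr(out, "seeds") <- seeds
  attr(out, "training") <- training
  out
}
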