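#' Configuration for an end-to-end pipeline run
#'
#' Collects every input path, threshold and seed for [run_pipeline()].
#' Defaults are the standard analysis settings: edge confidence cutoff 0.7,
#' seed percentiles 1% (BC) / 10% (NC) / 10% (ASPL), 9 cross-validation
#' folds with 1000 replicates, support threshold 0.5, and 1000 random
#' draws for the focal-set null.
#'
#' Inputs are given either as file paths (`network_path`,
#' `attributes_path`, `focal_path`) or as a [synthetic_spec()] in
#' `synthetic`, in which case the instance is generated at run time.
#'
#' @param network_path edge table readable by [read_edge_table()].
#' @param attributes_path TSV with columns `node`, `mean_phylop`.
#' @param focal_path TSV with columns `node`, `direction`.
#' @param synthetic optional [synthetic_spec()]; overrides the paths.
#' @param score_threshold,score_scale passed to [read_edge_table()].
#' @param pct_bc,pct_nc,pct_aspl seed percentiles for [seed_labels()].
#' @param k_neighbors SMOTE neighbors; `NULL` (default) caps the standard 5
#'   at one below the smallest seed class, so small networks remain
#'   classifiable; the value used is logged.
#' @param support_threshold declassification threshold for
#'   [classify_nodes()].
#' @param folds,cv_replicates cross-validation scheme (set
#'   `cv_replicates = 0` to skip the CV diagnostic).
#' @param n_draws random draws for [random_draw_null()].
#' @param tail tail for the null tests.
#' @param seed top-level seed; per-stage seeds derive from it via
#'   [derive_seed()].
#' @param out_dir output directory (created if missing).
#' @return an object of class `run_config`.
#' @export
run_config <- function(network_path = NULL, attributes_path = NULL,
                       focal_path = NULL, synthetic = NULL,
                       score_threshold = 0.7,
                       score_scale = c("unit", "thousand"),
                       pct_bc = 0.01, pct_nc = 0.10, pct_aspl = 0.10,
                       k_neighbors = NULL, support_threshold = 0.5,
                       folds = 9L, cv_replicates = 1000L,
                       n_draws = 1000L,
                       tail = c("two-sided", "greater", "less"),
                       seed = 1L, out_dir = tempfile("netconstraint_run")) {
  score_scale <- match.arg(score_scale)
  tail <- match.arg(tail)
  if (is.null(synthetic)) {
    for (p in c(network_path, attributes_path, focal_path)) {
      if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
    }
    if (is.null(network_path)) stop("need network_path or a synthetic spec")
  } else {
    stopifnot(inherits(synthetic, "synthetic_spec"))
  }
  structure(list(network_path = network_path,
                 attributes_path = attributes_path,
                 focal_path = focal_path, synthetic = synthetic,
                 score_threshold = score_threshold,
                 score_scale = score_scale, pct_bc = pct_bc,
                 pct_nc = pct_nc, pct_aspl = pct_aspl,
                 k_neighbors = k_neighbors,
                 support_threshold = support_threshold,
                 folds = as.integer(folds),
                 cv_replicates = as.integer(cv_replicates),
                 n_draws = as.integer(n_draws), tail = tail,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full constraint-topology pipeline
#'
#' Executes the stages network loading (or synthesis), topology metrics,
#' node classification, constraint models and focal-set permutation null,
#' writing each stage's output plus a manifest to `config$out_dir`.
#'
#' Outputs written: `network.tsv` (filtered edge list), `metrics.tsv`,
#' `classes.tsv`, `cv_summary.json` (when `cv_replicates > 0`),
#' `models.json`, `null_draws.tsv`, `null.json`, and `manifest.json`
#' (package version, configuration, per-stage row counts and the md5 of
#' every output file). Given an identical configuration and seed, every
#' output is reproduced byte-identically.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly, as a list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  counts <- list()

  net <- stage("network_io", {
    if (!is.null(config$synthetic)) {
      study <- simulate_study(config$synthetic)
      g <- study$network
      attributes <- study$attributes
      focal <- study$focal
      g
    } else {
      attributes <- if (!is.null(config$attributes_path)) {
        utils::read.delim(config$attributes_path, stringsAsFactors = FALSE)
      }
      focal <- if (!is.null(config$focal_path)) {
        utils::read.delim(config$focal_path, stringsAsFactors = FALSE)
      }
      read_edge_table(config$network_path,
                      score_threshold = config$score_threshold,
                      score_scale = config$score_scale)
    }
  })
  # stage() evaluates in this frame, so attributes/focal are bound here
  net <- largest_connected_component(net)
  write_network(net, out("network.tsv"))
  counts$nodes <- igraph::vcount(net)
  counts$edges <- igraph::ecount(net)

  metrics <- stage("topology", node_metrics(net))
  write_tsv(metrics, out("metrics.tsv"))

  classes <- stage("classify", {
    seeds <- seed_labels(metrics, pct_bc = config$pct_bc,
                         pct_nc = config$pct_nc, pct_aspl = config$pct_aspl)
    k <- default_k_neighbors(seeds, config$k_neighbors)
    training <- oversample_minority(seeds, metrics, k_neighbors = k,
                                    seed = derive_seed(config$seed, "smote"))
    if (config$cv_replicates > 0L) {
      cv <- lapply(c(plain = FALSE, stratified = TRUE), function(s) {
        summarize_cv(cross_validate(training, folds = config$folds,
                                    replicates = config$cv_replicates,
                                    stratified = s, seed = config$seed))
      })
      jsonlite::write_json(cv, out("cv_summary.json"), auto_unbox = TRUE,
                           digits = NA)
    }
    classify_nodes(training, metrics,
                   support_threshold = config$support_threshold,
                   seed = config$seed)
  })
  write_tsv(classes, out("classes.tsv"))
  counts$classified <- sum(classes$label != "uncertain")
  counts$uncertain <- sum(classes$label == "uncertain")

  models <- stage("stats", {
    if (is.null(attributes)) {
      NULL
    } else {
      tab <- join_attributes(net, attributes)
      tab <- merge(metrics, tab, by = "node")
      tab$phylop_norm <- order_quantile_normalize(tab$mean_phylop)
      tab <- merge(tab, classes[, c("node", "label")], by = "node")
      m1 <- fit_metrics_model(tab)
      m2 <- fit_category_model(tab[tab$label != "uncertain", ])
      m3 <- if (!is.null(focal)) {
        ft <- merge(tab, focal, by = "node")
        ft <- ft[ft$label != "uncertain", ]
        fit_hibernation_model(ft)
      }
      counts$model_rows <- nrow(tab)  # evaluates in run_pipeline's frame
      list(metrics_model = m1, category_model = m2, hibernation_model = m3,
           table = tab)
    }
  })
  if (!is.null(models)) {
    strip <- function(m) m[setdiff(names(m), "fit")]
    jsonlite::write_json(list(
      metrics_model = strip(models$metrics_model),
      category_model = list(model = strip(models$category_model$model),
                            contrasts = models$category_model$contrasts),
      hibernation_model = if (!is.null(models$hibernation_model)) {
        list(model = strip(models$hibernation_model$model),
             contrasts = models$hibernation_model$contrasts)
      }), out("models.json"), auto_unbox = TRUE, digits = NA, null = "null")
  }

  nulls <- stage("permutation", {
    if (is.null(focal) || is.null(models)) {
      NULL
    } else {
      random_draw_null(models$table, focal$node, n_draws = config$n_draws,
                       tail = config$tail,
                       seed = derive_seed(config$seed, "null"))
    }
  })
  if (!is.null(nulls)) {
    write_tsv(data.frame(draw = seq_len(config$n_draws),
                         lapply(nulls, `[[`, "null_means")),
              out("null_draws.tsv"))
    jsonlite::write_json(lapply(nulls, function(x) {
      x[c("metric", "observed", "empirical_p", "tail", "n_draws", "n_frame",
          "n_focal")]
    }), out("null.json"), auto_unbox = TRUE, digits = NA)
  }

  files <- setdiff(list.files(config$out_dir), "manifest.json")
  manifest <- list(
    package = "netconstraint",
    version = as.character(utils::packageVersion("netconstraint")),
    seed = config$seed,
    config = lapply(unclass(config)[setdiff(names(config), "out_dir")],
                    function(x) if (is.list(x)) unclass(x) else x),
    counts = counts,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(config$out_dir, files))), files)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  nc_log("run_pipeline: wrote ", length(files) + 1L, " file(s) to ",
         config$out_dir)
  invisible(manifest)
}
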