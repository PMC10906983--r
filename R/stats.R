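#' Rank-based inverse normal (ordered quantile) transform
#'
#' Maps values to normal quantiles through their ranks:
#' `x_i -> qnorm(rank_i / (n + 1))`, with average ranks for ties. The
#' result is monotone in the input and approximately standard normal for
#' tie-free data, which puts gene-level mean PhyloP on a scale where
#' ordinary linear models are well calibrated regardless of the raw
#' score's skew.
#'
#' Missing values stay missing; ranks are computed over the finite values
#' only (at least 3 required).
#'
#' @param values numeric vector.
#' @return numeric vector of the same length.
#' @export
#' @examples
#' round(order_quantile_normalize(c(1, 2, 3)), 4)  # -0.6745 0 0.6745
order_quantile_normalize <- function(values) {
  stopifnot(is.numeric(values))
  ok <- is.finite(values)
  if (sum(ok) < 3L) stop("need at least 3 finite values to normalize")
  if (length(unique(values[ok])) == 1L) {
    stop("all values identical; ranks are degenerate")
  }
  out <- rep(NA_real_, length(values))
  r <- rank(values[ok], ties.method = "average")
  out[ok] <- stats::qnorm(r / (sum(ok) + 1))
  out
}

#' Cohen's f from a model R-squared
#'
#' `f = sqrt(R2 / (1 - R2))`, the whole-model effect size for a linear
#' model.
#'
#' @param r_squared model R-squared in \[0, 1).
#' @return Cohen's f.
#' @export
cohens_f <- function(r_squared) {
  stopifnot(r_squared >= 0, r_squared <= 1)
  if (r_squared == 1) return(Inf)  # perfect fit
  sqrt(r_squared / (1 - r_squared))
}

#' Label the magnitude of a Cohen's d
#'
#' Uses the extended ladder: |d| >= 2.0 huge, >= 1.2 very large, >= 0.8
#' large, >= 0.5 medium, >= 0.2 small, else negligible.
#'
#' @param d Cohen's d (vectorized).
#' @return character vector of magnitude labels.
#' @export
effect_magnitude <- function(d) {
  a <- abs(d)
  cut(a, breaks = c(-Inf, 0.2, 0.5, 0.8, 1.2, 2.0, Inf), right = FALSE,
      labels = c("negligible", "small", "medium", "large", "very large",
                 "huge")) |> as.character()
}

model_result <- function(fit, formula_text) {
  s <- summary(fit)
  fs <- s$fstatistic
  res <- list(formula = formula_text,
              F = unname(fs[1]),
              df_model = as.integer(fs[2]),
              df_resid = as.integer(fs[3]),
              p = unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
              r_squared = s$r.squared,
              cohens_f = cohens_f(s$r.squared),
              coefficients = data.frame(
                term = rownames(s$coefficients),
                estimate = s$coefficients[, "Estimate"],
                se = s$coefficients[, "Std. Error"],
                p = s$coefficients[, "Pr(>|t|)"],
                row.names = NULL),
              n = length(stats::fitted(fit)),
              fit = fit)
  class(res) <- "nc_model"
  res
}

#' @export
print.nc_model <- function(x, ...) {
  cat("Linear model:", x$formula, "\n")
  cat(sprintf("  F = %.4g on %d and %d df, p = %.3g\n",
              x$F, x$df_model, x$df_resid, x$p))
  cat(sprintf("  R^2 = %.4f (%.2f%% of variance), Cohen's f = %.4f, n = %d\n",
              x$r_squared, 100 * x$r_squared, x$cohens_f, x$n))
  invisible(x)
}

# Cohen's d between two groups using the pooled standard deviation.
# Singleton groups contribute no degrees of freedom; if both groups are
# singletons the pooled SD (and hence d) is undefined and NA is returned.
pooled_cohens_d <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  df <- n1 + n2 - 2L
  if (df <= 0L) return(NA_real_)
  sp <- sqrt((sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / df)
  if (!is.finite(sp) || sp == 0) return(NA_real_)
  (mean(x1) - mean(x2)) / sp
}

# Pairwise estimated-marginal-mean contrasts with Tukey adjustment plus
# pooled-SD Cohen's d per pair, for one factor of a fitted lm.
emm_contrasts <- function(fit, data, factor_name, response) {
  emm <- emmeans::emmeans(fit, stats::as.formula(paste("~", factor_name)))
  ctr <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "tukey"))
  pairs <- strsplit(as.character(ctr$contrast), " - ")
  d <- vapply(pairs, function(pr) {
    g <- as.character(data[[factor_name]])
    pooled_cohens_d(data[[response]][g == pr[1]], data[[response]][g == pr[2]])
  }, 1.0)
  data.frame(factor = factor_name,
             pair = as.character(ctr$contrast),
             estimate = ctr$estimate,
             p_adjusted = ctr$p.value,
             cohens_d = d,
             magnitude = effect_magnitude(d),
             stringsAsFactors = FALSE)
}

#' Regress normalized constraint on the three topology metrics
#'
#' Ordinary least squares of normalized mean PhyloP on ASPL, BC and NC.
#' Incomplete rows are dropped listwise (the count is logged); nothing is
#' imputed. A negative ASPL coefficient and positive BC coefficient are
#' the signature of constraint intensifying toward the network center.
#'
#' @param table data.frame with columns `phylop_norm` (response, typically
#'   from [order_quantile_normalize()]), `aspl`, `bc`, `nc`.
#' @return an `nc_model` with whole-model F, degrees of freedom, p,
#'   R-squared and Cohen's f.
#' @export
fit_metrics_model <- function(table) {
  stopifnot(all(c("phylop_norm", "aspl", "bc", "nc") %in% names(table)))
  cc <- stats::complete.cases(table[, c("phylop_norm", "aspl", "bc", "nc")])
  dropped <- sum(!cc)
  if (dropped) nc_log("fit_metrics_model: dropped ", dropped,
                      " incomplete row(s)")
  dat <- table[cc, , drop = FALSE]
  if (nrow(dat) < 5L) stop("fewer complete rows than model parameters")
  fit <- stats::lm(phylop_norm ~ aspl + bc + nc, data = dat)
  model_result(fit, "phylop_norm ~ aspl + bc + nc")
}

#' One-way model of constraint across node categories
#'
#' One-way ANOVA of normalized mean PhyloP on the H/I/P node category,
#' followed by all pairwise contrasts of estimated marginal means with
#' Tukey adjustment and pooled-SD Cohen's d per pair. Nodes labeled
#' `"uncertain"` must be excluded upstream.
#'
#' @param table data.frame with columns `phylop_norm` and `label`
#'   (values among H, I, P; at least 2 nodes per present category).
#' @return list with `model` (an `nc_model`) and `contrasts` (data.frame of
#'   pairwise contrasts).
#' @export
fit_category_model <- function(table) {
  stopifnot(all(c("phylop_norm", "label") %in% names(table)))
  dat <- table[stats::complete.cases(table[, c("phylop_norm", "label")]), ]
  dat$label <- factor(as.character(dat$label))
  if (any(c("uncertain") %in% levels(dat$label))) {
    stop("exclude 'uncertain' nodes before fitting the category model")
  }
  counts <- base::table(dat$label)  # arg `table` shadows base::table
  if (length(counts) < 2L || any(counts < 2L)) {
    stop("need at least 2 categories with >= 2 nodes each; got: ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  fit <- stats::lm(phylop_norm ~ label, data = dat)
  list(model = model_result(fit, "phylop_norm ~ node_category"),
       contrasts = emm_contrasts(fit, dat, "label", "phylop_norm"))
}

#' Two-factor model for focal (hibernation-associated) genes
#'
#' Additive linear model of normalized mean PhyloP on node category and
#' rate direction (accelerated vs decelerated) for a focal gene set, with
#' post hoc contrasts and effect sizes for each factor. With a focal set of
#' ~18 genes an interaction term is under-determined, so the model is
#' additive by default. A factor observed at a single level is dropped with
#' a warning rather than silently.
#'
#' @param table data.frame with columns `phylop_norm`, `label` (H/I/P) and
#'   `direction` (accelerated/decelerated).
#' @return list with `model` (an `nc_model`) and `contrasts` (pairwise
#'   contrasts for every retained factor).
#' @export
fit_hibernation_model <- function(table) {
  stopifnot(all(c("phylop_norm", "label", "direction") %in% names(table)))
  dat <- table[stats::complete.cases(
    table[, c("phylop_norm", "label", "direction")]), ]
  dat$label <- factor(as.character(dat$label))
  dat$direction <- factor(as.character(dat$direction))
  factors <- c("label", "direction")
  keep <- vapply(factors, function(f) nlevels(dat[[f]]) >= 2L, TRUE)
  for (f in factors[!keep]) {
    warning("factor '", f, "' has a single level and was dropped")
  }
  factors <- factors[keep]
  if (!length(factors)) stop("no factor with >= 2 levels; nothing to fit")
  fml <- stats::as.formula(paste("phylop_norm ~",
                                 paste(factors, collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  contrasts <- do.call(rbind, lapply(factors, function(f) {
    emm_contrasts(fit, dat, f, "phylop_norm")
  }))
  list(model = model_result(fit, deparse(fml)), contrasts = contrasts)
}
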