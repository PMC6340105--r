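#' Deviance information criterion of a Gibbs fit
#'
#' Conditional-deviance DIC: the deviance conditions on the location effects
#' and residual variance, `D(theta) = -2 log N(y | Xb + Zp p + Za aD + S aS,
#' I sigma2_e)`. `pD = mean(D) - D(posterior means)`, `DIC = mean(D) + pD`.
#'
#' @param fit An `"ige_gibbs_fit"` (its per-sample deviances were recorded
#'   during sampling).
#' @param design The [build_design()] the fit was run on.
#' @return List `DIC`, `pD`, `Dbar` (posterior mean deviance) and `Dhat`
#'   (deviance at the posterior means).
#' @export
dic <- function(fit, design) {
  stopifnot(inherits(fit, "ige_gibbs_fit"), inherits(design, "ige_design"))
  if (fit$kept < 100L)
    warning("fewer than 100 retained samples; DIC will be noisy")
  Dbar <- mean(fit$deviance)
  fitted <- fitted_values(fit, design)
  s2e <- mean(fit$vc[, "sigma2_e"])
  n <- length(design$y)
  Dhat <- n * log(2 * pi * s2e) + sum((design$y - fitted)^2) / s2e
  pD <- Dbar - Dhat
  list(DIC = Dbar + pD, pD = pD, Dbar = Dbar, Dhat = Dhat)
}

# fitted values from posterior-mean location effects, for given design rows
fitted_values <- function(fit, design) {
  pm <- fit$post_mean
  out <- as.numeric(design$X %*% pm$b)
  if (fit$spec$include_pen) out <- out + pm$pen[design$pen0 + 1L]
  if (fit$spec$include_genetic) {
    out <- out + pm$aD[design$animal0 + 1L]
    if (fit$spec$social && length(design$srow_ptr)) {
      ptr <- design$srow_ptr
      for (i in seq_along(design$y)) {
        if (ptr[i + 1L] > ptr[i]) {
          k <- (ptr[i] + 1L):ptr[i + 1L]
          out[i] <- out[i] +
            sum(design$srow_val[k] * pm$aS[design$srow_col[k] + 1L])
        }
      }
    }
  }
  out
}

#' Pen-stratified cross-validation folds
#'
#' Each fold holds out one record per pen, sampled without replacement
#' within pen across folds, so with `P` pens every fold has `P` held-out
#' records and no record is ever held out twice. Pens with fewer records
#' than folds contribute each record to exactly one randomly chosen fold
#' (with a warning).
#'
#' @param pheno Phenotype table with columns `animal` and `pen` (one record
#'   per animal).
#' @param k Number of folds (default 8; must be >= 2).
#' @param seed Integer seed making the plan reproducible.
#' @return Object of class `"fold_plan"`: list of `k` character vectors of
#'   held-out animal ids.
#' @export
make_folds <- function(pheno, k = 8, seed = 1) {
  if (k < 2) stop("need at least 2 folds")
  set.seed(seed)
  folds <- rep(list(character(0)), k)
  for (p in unique(as.character(pheno$pen))) {
    ids <- as.character(pheno$animal[pheno$pen == p])
    if (length(ids) < k) {
      warning("pen ", p, " has fewer records (", length(ids),
              ") than folds (", k, "); it contributes to a subset of folds")
      at <- sample.int(k, length(ids))
      picked <- sample(ids)
    } else {
      at <- seq_len(k)
      picked <- sample(ids, k)
    }
    for (j in seq_along(at))
      folds[[at[j]]] <- c(folds[[at[j]]], picked[j])
  }
  structure(folds, class = "fold_plan", seed = seed, k = k)
}

#' Cross-validated predictive ability
#'
#' For every fold the model is refitted on the training records (variance
#' components and effects re-estimated at the supplied, typically reduced,
#' chain length) and the held-out growth records are predicted as fixed-
#' effect part + pen effect + own direct breeding value + the sum over pen
#' mates of interaction coefficient times the mate's social breeding value.
#' The held-out animal's interaction coefficients come from its behaviour
#' phenotypes, which are inputs, not responses, so they are legitimately
#' available at prediction time.
#'
#' @param design Full-data [build_design()].
#' @param ainv Sparse inverse relationship matrix.
#' @param plan A [make_folds()] plan.
#' @param config [gibbs_config()] for the per-fold refits (the per-fold seed
#'   is `config$seed + fold`).
#' @return List with `fold_r` (per-fold Pearson correlation between observed
#'   and predicted ADG), `mean`, `sd`. Folds with fewer than 3 held-out
#'   records are skipped with a warning.
#' @export
cross_validate <- function(design, ainv, plan, config = gibbs_config()) {
  stopifnot(inherits(design, "ige_design"), inherits(plan, "fold_plan"))
  rs <- numeric(0)
  for (f in seq_along(plan)) {
    held <- match(plan[[f]], design$ids)
    held <- held[!is.na(held)]
    if (length(held) < 3L) {
      warning("fold ", f, " has fewer than 3 held-out records; skipped")
      next
    }
    train <- subset_design(design, setdiff(seq_along(design$y), held))
    cfg <- config
    cfg$seed <- config$seed + f
    fit <- gibbs_sampler(train, ainv, cfg)
    test <- subset_design(design, held)
    pred <- fitted_values(fit, test)
    rs <- c(rs, stats::cor(design$y[held], pred))
  }
  list(fold_r = rs, mean = mean(rs), sd = stats::sd(rs))
}

#' Coincidence of the top fraction of two rankings
#'
#' Percentage of animals shared by the top `fraction` sets of two breeding
#' value vectors. Ties are broken by stable animal-id order; the top-set
#' size rounds to the nearest integer, minimum 1.
#'
#' @param bv_a,bv_b Named numeric vectors over the same animals.
#' @param fraction Top fraction in (0, 1); default 0.10.
#' @return Percentage in `[0, 100]`.
#' @export
top_fraction_coincidence <- function(bv_a, bv_b, fraction = 0.10) {
  if (length(bv_a) < 10L) stop("need at least 10 animals")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  ids <- names(bv_a)
  if (is.null(ids) || !setequal(ids, names(bv_b)))
    stop("breeding value vectors must be named over the same animals")
  m <- max(1L, round(fraction * length(bv_a)))
  top <- function(x) ids[order(-x[ids], seq_along(ids))][seq_len(m)]
  100 * length(intersect(top(bv_a), top(bv_b))) / m
}

#' Rank and product-moment correlation between two genetic rankings
#'
#' @param bv_a,bv_b Numeric vectors over the same animals.
#' @return List `spearman`, `pearson`.
#' @export
ranking_correlations <- function(bv_a, bv_b) {
  if (length(bv_a) != length(bv_b)) stop("rankings differ in length")
  if (stats::sd(bv_a) == 0 || stats::sd(bv_b) == 0) {
    warning("zero-variance ranking; correlations undefined")
    return(list(spearman = NA_real_, pearson = NA_real_))
  }
  list(spearman = stats::cor(bv_a, bv_b, method = "spearman"),
       pearson = stats::cor(bv_a, bv_b))
}

#' Correlations among direct, social and total breeding values
#'
#' Pearson correlations of DBV, SBV and TBV over the supplied animals
#' (conventionally those with a phenotypic observation).
#'
#' @param bvs A [total_breeding_values()] data frame from a social model.
#' @return Named vector `cor_DBV_SBV`, `cor_DBV_TBV`, `cor_SBV_TBV`.
#' @export
bv_component_correlations <- function(bvs) {
  if (all(is.na(bvs$SBV)))
    stop("no social breeding values: component correlations need a ",
         "social model")
  c(cor_DBV_SBV = stats::cor(bvs$DBV, bvs$SBV),
    cor_DBV_TBV = stats::cor(bvs$DBV, bvs$TBV),
    cor_SBV_TBV = stats::cor(bvs$SBV, bvs$TBV))
}
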