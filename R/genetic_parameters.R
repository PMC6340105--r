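as_vc <- function(vc) {
  # accept lists from em_reml, rows of a Gibbs chain, or plain named lists
  v <- as.list(vc)
  if (is.null(v$sigma2_D) && !is.null(v$sigma2_a)) v$sigma2_D <- v$sigma2_a
  if (is.null(v$sigma2_S)) v$sigma2_S <- 0
  if (is.null(v$sigma_DS)) v$sigma_DS <- 0
  if (is.null(v$sigma2_pen)) v$sigma2_pen <- 0
  v
}

#' Heritability
#'
#' Direct genetic variance as a proportion of phenotypic variance.
#'
#' @param vc Named list/vector of variance components (`sigma2_D` or
#'   `sigma2_a`, `sigma2_pen`, `sigma2_e`).
#' @param phenotypic_variance Optional denominator; defaults to
#'   `sigma2_D + sigma2_pen + sigma2_e`.
#' @return h-squared.
#' @export
heritability <- function(vc, phenotypic_variance = NULL) {
  v <- as_vc(vc)
  den <- if (is.null(phenotypic_variance))
    v$sigma2_D + v$sigma2_pen + v$sigma2_e else phenotypic_variance
  v$sigma2_D / den
}

#' Total heritable variance
#'
#' Variance of total breeding values `TBV = a_D + c (n-1) a_S` at group size
#' `n` and interaction degree `c`:
#' `sigma2_D + 2 c (n-1) sigma_DS + c^2 (n-1)^2 sigma2_S`.
#' `c = 1` gives the classical social-model expression; on the standardized
#' interaction-degree scale `c = 0` is the average degree and the expression
#' reduces to `sigma2_D`. Can be small (even near zero) when the
#' direct-social covariance is negative.
#'
#' @param vc Variance components (see [heritability()]).
#' @param n Group (pen) size.
#' @param c Interaction degree at which to evaluate.
#' @return Total heritable variance (same units as the components).
#' @export
total_heritable_variance <- function(vc, n, c = 1) {
  v <- as_vc(vc)
  v$sigma2_D + 2 * c * (n - 1) * v$sigma_DS +
    c^2 * (n - 1)^2 * v$sigma2_S
}

#' Total phenotypic variance under the social model
#'
#' `sigma2_D + c^2 (n-1) sigma2_S +
#'  r [2 c (n-1) sigma_DS + c^2 (n-1)(n-2) sigma2_S] +
#'  sigma2_pen + sigma2_e`,
#' where `r` is the mean additive relationship between pen mates.
#'
#' @inheritParams total_heritable_variance
#' @param r Mean within-pen relationship (see
#'   [mean_within_group_relationship()]).
#' @return Phenotypic variance; an error if the components render it
#'   non-positive.
#' @export
total_phenotypic_variance <- function(vc, n, r, c = 1) {
  v <- as_vc(vc)
  out <- v$sigma2_D + c^2 * (n - 1) * v$sigma2_S +
    r * (2 * c * (n - 1) * v$sigma_DS +
           c^2 * (n - 1) * (n - 2) * v$sigma2_S) +
    v$sigma2_pen + v$sigma2_e
  if (out <= 0) stop("inadmissible variance components: non-positive ",
                     "phenotypic variance")
  out
}

#' Total heritable variance as a proportion of phenotypic variance
#'
#' `T2 = sigma2_TBV / sigma2_P`; may exceed 1 under social models.
#'
#' @inheritParams total_phenotypic_variance
#' @return T-squared.
#' @export
t2 <- function(vc, n, r, c = 1) {
  total_heritable_variance(vc, n, c) / total_phenotypic_variance(vc, n, r, c)
}

#' T-squared at the quartiles of the interaction-degree distribution
#'
#' Evaluates [t2()] at the first and third empirical quartile of the
#' within-pen entries of a standardized interaction matrix, and at the mean
#' (0 on the centred scale, the average interaction degree).
#'
#' @param vc Variance components.
#' @param C A standardized-mode [interaction_matrix()] (an error for
#'   `CLASSICAL`, whose 0/1 scale has no meaningful quartiles).
#' @param n Group size.
#' @param r Mean within-pen relationship.
#' @return List `t2_q1`, `t2_mean`, `t2_q3`, plus the quartiles `q1`, `q3`.
#' @export
t2_at_quartiles <- function(vc, C, n, r) {
  stopifnot(inherits(C, "interaction_matrix"))
  if (C$mode == "CLASSICAL")
    stop("quartiles are undefined for a CLASSICAL (0/1) interaction matrix")
  deg <- interaction_degrees(C)
  q1 <- unname(stats::quantile(deg, 0.25))
  q3 <- unname(stats::quantile(deg, 0.75))
  list(t2_q1 = t2(vc, n, r, q1), t2_mean = t2(vc, n, r, 0),
       t2_q3 = t2(vc, n, r, q3), q1 = q1, q3 = q3)
}

#' Spread of T-squared across the interaction-degree quartiles
#'
#' The reporting arithmetic `T2(Q3) - T2(Q1)`: how much the heritable share
#' of phenotypic variance changes between weakly and strongly interacting
#' pairs.
#'
#' @param t2_q3,t2_q1 T-squared evaluated at the third and first quartile.
#' @return Difference `t2_q3 - t2_q1`.
#' @export
t2_quartile_spread <- function(t2_q3, t2_q1) t2_q3 - t2_q1

#' Direct, social and total breeding values
#'
#' `TBV_i = DBV_i + (sum of i's interaction coefficients to its pen mates)
#'  * SBV_i`: each animal's total expressed influence. For the classical 0/1
#' matrix this is the textbook `DBV + (n-1) SBV`; under the plain animal
#' model `TBV = DBV`.
#'
#' @param aD Named vector of direct effects (names = animal ids).
#' @param aS Optional named vector of social effects.
#' @param C Optional [interaction_matrix()]; required when `aS` is given.
#' @param ids Animals to report (default: rows of `C`, else names of `aD`).
#' @return Data frame `animal`, `DBV`, `SBV`, `TBV`. Animals not covered by
#'   `C` fall back to `TBV = DBV` with a warning.
#' @export
total_breeding_values <- function(aD, aS = NULL, C = NULL, ids = NULL) {
  if (is.null(ids)) ids <- if (!is.null(C)) rownames(C$C) else names(aD)
  dbv <- as.numeric(aD[ids])
  if (is.null(aS)) {
    return(data.frame(animal = ids, DBV = dbv, SBV = NA_real_, TBV = dbv,
                      stringsAsFactors = FALSE))
  }
  if (is.null(C)) stop("social breeding values need an interaction matrix")
  sbv <- as.numeric(aS[ids])
  at <- match(ids, rownames(C$C))
  infl <- rep(NA_real_, length(ids))
  infl[!is.na(at)] <- Matrix::rowSums(C$C)[at[!is.na(at)]]
  if (anyNA(infl)) {
    warning("animal(s) without pen coverage get TBV = DBV")
    infl[is.na(infl)] <- 0
  }
  data.frame(animal = ids, DBV = dbv, SBV = sbv, TBV = dbv + infl * sbv,
             stringsAsFactors = FALSE)
}

#' Sample-wise genetic parameter report for a Gibbs fit
#'
#' Derived parameters (h2, T2 at the mean degree and at the interaction
#' quartiles, the direct-social genetic correlation) are computed for every
#' retained sample and then summarized, rather than being evaluated at
#' posterior means.
#'
#' @param fit An `"ige_gibbs_fit"`.
#' @param n Group size for the variance partition (typically the mean pen
#'   size of the phenotyped animals).
#' @param r Mean within-pen additive relationship.
#' @param C Interaction matrix used in the fit (needed for quartile T2 under
#'   `AM_IGE_i`).
#' @return List with `summary` (a [posterior_summary()] data frame of the
#'   derived chains) and `chains` (the sample-wise values).
#' @export
genetic_parameter_report <- function(fit, n, r, C = NULL) {
  stopifnot(inherits(fit, "ige_gibbs_fit"))
  vc <- fit$vc
  social <- fit$spec$social
  c0 <- if (!social) 0 else if (fit$spec$model_class == "AM_IGE") 1 else 0
  qs <- NULL
  if (social && fit$spec$model_class == "AM_IGE_i") {
    if (is.null(C)) stop("AM_IGE_i report needs the interaction matrix")
    deg <- interaction_degrees(C)
    qs <- stats::quantile(deg, c(0.25, 0.75))
  }
  one <- function(row) {
    v <- as_vc(as.list(row))
    h2 <- heritability(v)
    out <- c(h2 = h2)
    if (social) {
      out["T2"] <- t2(v, n, r, c0)
      out["corr_DS"] <- v$sigma_DS / sqrt(v$sigma2_D * v$sigma2_S)
      if (!is.null(qs)) {
        out["T2_q1"] <- t2(v, n, r, qs[1L])
        out["T2_q3"] <- t2(v, n, r, qs[2L])
      }
    }
    out
  }
  chains <- do.call(rbind, lapply(seq_len(nrow(vc)), function(i)
    one(stats::setNames(as.list(vc[i, ]), colnames(vc)))))
  res <- list(summary = posterior_summary(chains), chains = chains,
              n = n, r = r, c0 = c0)
  if (!is.null(qs)) {
    res$q1 <- unname(qs[1L]); res$q3 <- unname(qs[2L])
    sm <- colMeans(chains)
    res$t2_spread <- t2_quartile_spread(sm[["T2_q3"]], sm[["T2_q1"]])
  }
  res
}
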