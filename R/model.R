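#' Specify a growth model with or without indirect genetic effects
#'
#' `"AM"` is the plain animal model (direct genetic effect only); `"AM_IGE"`
#' adds indirect (social) genetic effects with the classical 0/1 pen-sharing
#' incidence; `"AM_IGE_i"` uses pair-specific interaction degrees from a
#' standardized behaviour-distance [interaction_matrix()].
#'
#' @param model_class One of `"AM"`, `"AM_IGE"`, `"AM_IGE_i"`.
#' @param mode Interaction mode for `"AM_IGE_i"` (`"FR"`, `"FF"`, `"OT"`,
#'   `"FINT"`, `"ALL"`); ignored otherwise.
#' @param include_pen Include the random pen effect (default `TRUE`).
#' @param include_genetic Include genetic effects (default `TRUE`; mainly
#'   useful for degenerate checks against closed-form ANOVA/OLS results).
#' @return A list of class `"ige_model_spec"`.
#' @export
ige_model_spec <- function(model_class = c("AM", "AM_IGE", "AM_IGE_i"),
                           mode = NULL, include_pen = TRUE,
                           include_genetic = TRUE) {
  model_class <- match.arg(model_class)
  social <- model_class != "AM" && include_genetic
  if (model_class == "AM_IGE") mode <- "CLASSICAL"
  if (model_class == "AM_IGE_i") {
    if (is.null(mode) || mode == "CLASSICAL")
      stop("AM_IGE_i requires a standardized interaction mode ",
           "(FR, FF, OT, FINT or ALL)")
    mode <- match.arg(mode, c("FR", "FF", "OT", "FINT", "ALL"))
  }
  structure(list(model_class = model_class, mode = mode, social = social,
                 include_pen = include_pen,
                 include_genetic = include_genetic),
            class = "ige_model_spec")
}

#' Build design matrices for a phenotype table
#'
#' Fixed effects are batch (reference coding, first level dropped) plus the
#' covariates initial age, final age and number of pigs per pen (the last
#' centred for conditioning). The social incidence rows are the record's
#' interaction coefficients to its phenotyped pen mates.
#'
#' @param pheno Data frame with columns `animal`, `pen`, `batch`, `age_on`,
#'   `age_off`, `adg`, and optionally `n_mates` (defaults to pen size).
#' @param ped A [build_pedigree()] pedigree containing every phenotyped
#'   animal.
#' @param spec An [ige_model_spec()].
#' @param C An [interaction_matrix()] covering all phenotyped animals;
#'   required for social models. Its mode must agree with the spec
#'   (`CLASSICAL` for `AM_IGE`, standardized for `AM_IGE_i`).
#' @return A list of class `"ige_design"` with the response, dense `X`,
#'   0-based pen/animal maps, sparse social rows in CSR form, and bookkeeping
#'   (ids, pen levels, pedigree).
#' @export
build_design <- function(pheno, ped, spec, C = NULL) {
  stopifnot(inherits(spec, "ige_model_spec"), inherits(ped, "pedigree"))
  pheno <- as.data.frame(pheno)
  pheno$animal <- as.character(pheno$animal)
  miss <- setdiff(pheno$animal, ped$id)
  if (length(miss))
    stop("animal(s) missing from pedigree: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  if (anyDuplicated(pheno$animal))
    stop("multiple records per animal are not supported")
  if (is.null(pheno$n_mates))
    pheno$n_mates <- as.integer(table(pheno$pen)[as.character(pheno$pen)])

  batch <- factor(pheno$batch)
  n_mates_c <- pheno$n_mates - mean(pheno$n_mates)
  terms <- c(if (nlevels(batch) > 1L) "batch",
             "age_on", "age_off",
             if (stats::var(n_mates_c) > 0) "n_mates_c")
  form <- stats::reformulate(terms)
  X <- stats::model.matrix(form,
                           data = cbind(pheno, batch = batch,
                                        n_mates_c = n_mates_c))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("fixed-effect design is rank deficient; collinear column(s): ",
         paste(drop, collapse = ", "))
  }

  pen_levels <- sort(unique(as.character(pheno$pen)))
  pen0 <- match(as.character(pheno$pen), pen_levels) - 1L
  animal0 <- match(pheno$animal, ped$id) - 1L

  srow_ptr <- srow_col <- integer(0); srow_val <- numeric(0)
  if (spec$social) {
    if (is.null(C)) stop("social models need an interaction matrix")
    if (spec$model_class == "AM_IGE" && C$mode != "CLASSICAL")
      stop("AM_IGE expects a CLASSICAL interaction matrix")
    if (spec$model_class == "AM_IGE_i" && C$mode == "CLASSICAL")
      stop("AM_IGE_i expects a standardized interaction matrix")
    cm <- match(pheno$animal, rownames(C$C))
    if (anyNA(cm))
      stop("interaction matrix does not cover all phenotyped animals")
    n <- nrow(pheno)
    ptr <- integer(n + 1L)
    cols <- vector("list", n)
    vals <- vector("list", n)
    by_pen <- split(seq_len(n), pen0)
    for (recs in by_pen) {
      for (i in recs) {
        mates <- setdiff(recs, i)
        cc <- as.numeric(C$C[cm[i], cm[mates]])
        # standardized entries can legitimately be (near) zero; keep them all
        cols[[i]] <- animal0[mates]
        vals[[i]] <- cc
      }
    }
    lens <- vapply(cols, length, 0L)
    ptr <- c(0L, cumsum(lens))
    srow_ptr <- as.integer(ptr)
    srow_col <- as.integer(unlist(cols, use.names = FALSE))
    srow_val <- as.numeric(unlist(vals, use.names = FALSE))
  }

  structure(list(y = as.numeric(pheno$adg), X = X,
                 pen0 = pen0, pen_levels = pen_levels,
                 animal0 = animal0, ids = pheno$animal,
                 srow_ptr = srow_ptr, srow_col = srow_col,
                 srow_val = srow_val,
                 n_pens = length(pen_levels), q = nrow(ped),
                 ped = ped, spec = spec, pheno = pheno),
            class = "ige_design")
}

# restrict a design to a subset of record rows (training split); columns,
# pen levels and pedigree mapping are kept so predictions stay aligned
subset_design <- function(design, rows) {
  d <- design
  d$y <- design$y[rows]
  d$X <- design$X[rows, , drop = FALSE]
  d$pen0 <- design$pen0[rows]
  d$animal0 <- design$animal0[rows]
  d$ids <- design$ids[rows]
  d$pheno <- design$pheno[rows, , drop = FALSE]
  if (length(design$srow_ptr)) {
    ptr <- design$srow_ptr
    idx <- unlist(lapply(rows, function(i)
      if (ptr[i + 1L] > ptr[i]) (ptr[i] + 1L):ptr[i + 1L] else integer(0)))
    lens <- ptr[rows + 1L] - ptr[rows]
    d$srow_ptr <- as.integer(c(0L, cumsum(lens)))
    d$srow_col <- design$srow_col[idx]
    d$srow_val <- design$srow_val[idx]
  }
  d
}

#' Gibbs sampling configuration
#'
#' Default chain sizes are test-scale (50 000 iterations, 10 000 burn-in,
#' thinning 10); production-scale protocols (millions of samples) are
#' selectable through the same fields.
#'
#' @param n_iter Total chain length.
#' @param burn_in Discarded initial iterations (< `n_iter`).
#' @param thin Keep one sample every `thin` iterations (>= 1).
#' @param seed Integer seed; chains are reproducible given the seed.
#' @param var_upper_mult Bounded-flat prior upper bound for every variance,
#'   as a multiple of the phenotypic variance.
#' @return List of class `"gibbs_config"`.
#' @export
gibbs_config <- function(n_iter = 50000, burn_in = 10000, thin = 10,
                         seed = 1, var_upper_mult = 1e6) {
  stopifnot(burn_in < n_iter, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 var_upper_mult = var_upper_mult),
            class = "gibbs_config")
}

default_start <- function(design) {
  vy <- stats::var(design$y)
  list(b = c(mean(design$y), rep(0, ncol(design$X) - 1L)),
       pen = rep(0, design$n_pens), aD = rep(0, design$q),
       aS = rep(0, design$q), sigma2_e = vy / 2, sigma2_pen = vy / 10,
       sigma2_a = vy / 3,
       G = matrix(c(vy / 3, 0, 0, vy / 100), 2, 2))
}

#' Gibbs sampler for the (social) animal model
#'
#' Single-site Gibbs sampling of all unknowns: fixed effects and pen effects
#' from their Gaussian full conditionals; each animal's direct and social
#' effects as a joint 2x2 block with prior precision `G^-1 (x) A^-1`
#' (effect-major stacking); pen and residual variances from scaled
#' inverse-chi-square full conditionals under bounded-flat priors; the 2x2
#' genetic covariance matrix `G` from its inverse-Wishart full conditional
#' under a flat prior (degrees of freedom `q - 3`), rejecting non-positive
#' -definite draws.
#'
#' @param design An [build_design()] object.
#' @param ainv Sparse inverse relationship matrix from
#'   [inverse_relationship_matrix()], dimension = pedigree size.
#' @param config A [gibbs_config()].
#' @param start Optional named list of starting values (see
#'   `penIGE:::default_start`).
#' @return Object of class `"ige_gibbs_fit"`: retained variance-component
#'   samples (`vc`), per-sample conditional deviance, posterior-mean location
#'   effects (`post_mean`), and the config echo.
#' @export
gibbs_sampler <- function(design, ainv, config = gibbs_config(),
                          start = NULL) {
  stopifnot(inherits(design, "ige_design"), inherits(config, "gibbs_config"))
  spec <- design$spec
  if (spec$include_genetic && nrow(ainv) < design$q)
    stop("inverse relationship matrix smaller than pedigree")
  st <- default_start(design)
  if (!is.null(start)) st[names(start)] <- start
  ainv <- methods::as(methods::as(ainv, "CsparseMatrix"), "generalMatrix")
  set.seed(config$seed)
  res <- ige_gibbs_cpp(design$y, design$X, design$pen0, design$animal0,
                       design$srow_ptr, design$srow_col, design$srow_val,
                       ainv@p, ainv@i, ainv@x,
                       design$n_pens, design$q,
                       config$n_iter, config$burn_in, config$thin,
                       spec$social, spec$include_pen, spec$include_genetic,
                       st, config$var_upper_mult * stats::var(design$y))
  vc <- res$vc
  colnames(vc) <- if (spec$include_genetic && spec$social) {
    c("sigma2_D", "sigma2_S", "sigma_DS", "sigma2_pen", "sigma2_e")
  } else if (spec$include_genetic) {
    c("sigma2_a", "sigma2_pen", "sigma2_e")
  } else c("sigma2_pen", "sigma2_e")
  if (!spec$include_pen)
    vc <- vc[, setdiff(colnames(vc), "sigma2_pen"), drop = FALSE]
  structure(list(vc = vc, deviance = as.numeric(res$deviance),
                 kept = res$kept, g_rejects = res$g_rejects,
                 post_mean = list(b = as.numeric(res$b),
                                  pen = as.numeric(res$pen),
                                  aD = as.numeric(res$aD),
                                  aS = as.numeric(res$aS)),
                 spec = spec, config = config,
                 ids = design$ids, ped_ids = design$ped$id),
            class = "ige_gibbs_fit")
}

#' Summarize posterior chains
#'
#' Per-parameter posterior mean, SD and 2.5/50/97.5% quantiles. Derived
#' genetic parameters should be computed sample-wise (see
#' [genetic_parameter_report()]) and summarized here, not reconstructed from
#' summary moments.
#'
#' @param x An `"ige_gibbs_fit"` or a matrix of samples (columns =
#'   parameters).
#' @return Data frame with one row per parameter.
#' @export
posterior_summary <- function(x) {
  m <- if (inherits(x, "ige_gibbs_fit")) x$vc else as.matrix(x)
  if (nrow(m) < 100L)
    warning("fewer than 100 retained samples; summaries will be noisy")
  out <- data.frame(
    parameter = colnames(m),
    mean = colMeans(m),
    sd = apply(m, 2L, stats::sd),
    q2.5 = apply(m, 2L, stats::quantile, 0.025),
    median = apply(m, 2L, stats::median),
    q97.5 = apply(m, 2L, stats::quantile, 0.975),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' @export
print.ige_gibbs_fit <- function(x, ...) {
  cat("Gibbs fit (", x$spec$model_class,
      if (!is.null(x$spec$mode)) paste0(", ", x$spec$mode), "): ",
      x$kept, " retained samples\n", sep = "")
  print(posterior_summary(x))
  invisible(x)
}

#' EM-REML variance component estimation
#'
#' Expectation-maximization REML on Henderson's mixed-model equations,
#' iterated until the largest relative change in any variance component
#' drops below `tol` or `maxit` iterations are reached. Serves as a
#' likelihood-based cross-check of the Bayesian estimates. Dense equations:
#' intended for data sets up to a few thousand equations.
#'
#' @param design An [build_design()] object.
#' @param ainv Sparse inverse relationship matrix.
#' @param tol Relative-change convergence tolerance (default 1e-6).
#' @param maxit Maximum EM iterations (default 500).
#' @param start Optional starting values as in [gibbs_sampler()].
#' @return List of class `"ige_reml_fit"`: variance components (and `G`,
#'   `corr_DS` for social models), BLUP/BLUE solutions at convergence, a
#'   convergence flag and the iteration count (non-convergence returns the
#'   last iterate, flagged).
#' @export
em_reml <- function(design, ainv, tol = 1e-6, maxit = 500, start = NULL) {
  stopifnot(inherits(design, "ige_design"))
  spec <- design$spec
  st <- default_start(design)
  if (!is.null(start)) st[names(start)] <- start
  ainv <- methods::as(methods::as(ainv, "CsparseMatrix"), "generalMatrix")
  res <- em_reml_cpp(design$y, design$X, design$pen0, design$animal0,
                     design$srow_ptr, design$srow_col, design$srow_val,
                     ainv@p, ainv@i, ainv@x,
                     design$n_pens, design$q,
                     spec$social, spec$include_pen, spec$include_genetic,
                     st, tol, as.integer(maxit))
  if (!res$converged && (spec$include_pen || spec$include_genetic))
    warning("EM-REML did not reach tol = ", tol, " within ", maxit,
            " iterations; returning last iterate")
  out <- list(sigma2_e = res$sigma2_e, converged = res$converged,
              iterations = res$iterations, b = as.numeric(res$b))
  if (spec$include_pen) out$sigma2_pen <- res$sigma2_pen
  if (spec$include_genetic) {
    if (spec$social) {
      G <- res$G
      out$G <- G
      out$sigma2_D <- G[1, 1]; out$sigma2_S <- G[2, 2]
      out$sigma_DS <- G[1, 2]
      out$corr_DS <- G[1, 2] / sqrt(G[1, 1] * G[2, 2])
      out$aD <- as.numeric(res$aD); out$aS <- as.numeric(res$aS)
    } else {
      out$sigma2_a <- res$sigma2_a
      out$aD <- as.numeric(res$aD)
    }
  }
  structure(out, class = "ige_reml_fit")
}
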