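parse_model_name <- function(name) {
  if (name == "AM") return(ige_model_spec("AM"))
  if (name == "AM_IGE") return(ige_model_spec("AM_IGE"))
  m <- regmatches(name, regexec("^AM_IGE_(FR|FF|OT|FINT|ALL)$", name))[[1L]]
  if (length(m) == 2L) return(ige_model_spec("AM_IGE_i", mode = m[2L]))
  stop("unknown model name: ", name,
       " (expected AM, AM_IGE or AM_IGE_<FR|FF|OT|FINT|ALL>)")
}

#' Run the full model-comparison experiment
#'
#' Fits every requested model to one data set, reports genetic parameters
#' (sample-wise h2, T2 and quartile T2), DIC, optional pen-stratified
#' cross-validation, and the pairwise ranking agreement of total breeding
#' values, and writes the report files to `outdir`. Deterministic given the
#' seeds in `config`.
#'
#' @param config List with elements:
#'   \describe{
#'     \item{dataset}{an `"ige_sim"` from [simulate_dataset()], or a list
#'       with `pheno`, `ped`, `behaviour$overall`, `pens`}
#'     \item{models}{character vector of model names (`"AM"`, `"AM_IGE"`,
#'       `"AM_IGE_OT"`, ...)}
#'     \item{gibbs}{a [gibbs_config()]}
#'     \item{cv}{optional list `k`, `seed`, `config` for cross-validation;
#'       `NULL` skips it}
#'     \item{outdir}{output directory (created if missing)}
#'   }
#' @return Invisible list with the per-model fits, parameter reports, the
#'   comparison table and the ranking matrices.
#' @export
run_experiment <- function(config) {
  ds <- config$dataset
  models <- config$models
  if (!length(models)) stop("config$models must name at least one model")
  gc0 <- if (is.null(config$gibbs)) gibbs_config() else config$gibbs
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)

  pheno <- ds$pheno
  ped <- ds$ped
  pm <- stats::setNames(as.character(pheno$pen), pheno$animal)
  ainv <- inverse_relationship_matrix(ped)
  A <- relationship_matrix(ped)
  r <- mean_within_group_relationship(A, pm)$pooled
  n_bar <- mean(table(pheno$pen))

  stage <- "setup"
  fits <- list(); reports <- list(); comp <- list(); tbvs <- list()
  res <- try({
    for (mn in models) {
      stage <- paste0("fit:", mn)
      spec <- parse_model_name(mn)
      C <- if (spec$model_class == "AM") NULL
      else if (spec$model_class == "AM_IGE")
        interaction_matrix(NULL, pm, "CLASSICAL")
      else interaction_matrix(ds$behaviour$overall, pm, spec$mode)
      design <- build_design(pheno, ped, spec, C)
      fit <- gibbs_sampler(design, ainv, gc0)
      fits[[mn]] <- fit
      reports[[mn]] <- genetic_parameter_report(fit, n_bar, r, C)
      d <- dic(fit, design)
      row <- data.frame(model = mn, DIC = d$DIC, pD = d$pD,
                        stringsAsFactors = FALSE)
      if (!is.null(config$cv)) {
        stage <- paste0("cv:", mn)
        cv <- config$cv
        plan <- make_folds(pheno, k = if (is.null(cv$k)) 8 else cv$k,
                           seed = if (is.null(cv$seed)) 1 else cv$seed)
        cvc <- if (is.null(cv$config)) gc0 else cv$config
        cvr <- cross_validate(design, ainv, plan, cvc)
        row$cv_r_mean <- cvr$mean; row$cv_r_sd <- cvr$sd
      }
      comp[[mn]] <- row
      pm_fit <- fit$post_mean
      aDn <- stats::setNames(pm_fit$aD, ped$id)
      if (spec$social) {
        aSn <- stats::setNames(pm_fit$aS, ped$id)
        tbv <- total_breeding_values(aDn, aSn, C, ids = pheno$animal)
      } else {
        tbv <- total_breeding_values(aDn, ids = pheno$animal)
      }
      tbvs[[mn]] <- tbv
    }
    "ok"
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stop("experiment failed at stage [", stage, "]: ",
         attr(res, "condition")$message)

  comparison <- do.call(rbind, comp)
  nm <- names(tbvs)
  coin <- rank_cor <- matrix(NA_real_, length(nm), length(nm),
                             dimnames = list(nm, nm))
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    a <- stats::setNames(tbvs[[i]]$TBV, tbvs[[i]]$animal)
    b <- stats::setNames(tbvs[[j]]$TBV, tbvs[[j]]$animal)
    coin[i, j] <- top_fraction_coincidence(a, b[names(a)])
    rank_cor[i, j] <- ranking_correlations(as.numeric(a),
                                           as.numeric(b[names(a)]))$spearman
  }
  bv_cors <- lapply(tbvs[vapply(fits, function(f) f$spec$social, TRUE)],
                    bv_component_correlations)

  genpar <- do.call(rbind, lapply(names(reports), function(mn) {
    s <- reports[[mn]]$summary
    cbind(model = mn, s)
  }))

  out <- list(fits = fits, reports = reports, comparison = comparison,
              coincidence = coin, rank_correlation = rank_cor,
              bv_correlations = bv_cors, genetic_parameters = genpar,
              r = r, n_bar = n_bar)

  if (!is.null(outdir)) {
    utils::write.csv(genpar, file.path(outdir, "genetic_parameters.csv"),
                     row.names = FALSE)
    utils::write.csv(comparison, file.path(outdir, "model_comparison.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(coin),
                     file.path(outdir, "top10_coincidence.csv"))
    utils::write.csv(as.data.frame(rank_cor),
                     file.path(outdir, "rank_correlation.csv"))
    if (length(bv_cors))
      utils::write.csv(do.call(rbind, bv_cors),
                       file.path(outdir, "bv_correlations.csv"))
    echo <- list(models = models,
                 gibbs = unclass(gc0),
                 seed = if (!is.null(ds$seed)) ds$seed else NA,
                 version = as.character(utils::packageVersion("penIGE")))
    yaml_path <- file.path(outdir, "config.yaml")
    writeLines(simple_yaml(echo), yaml_path)
    echo$config_hash <- unname(tools::md5sum(yaml_path))
    jsonlite::write_json(
      list(version = echo$version, seed = echo$seed,
           config_hash = echo$config_hash,
           comparison = comparison,
           r_within_pen = r, mean_pen_size = n_bar),
      file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}

# minimal YAML emitter for flat config echoes
simple_yaml <- function(x, indent = 0) {
  pad <- strrep(" ", indent)
  unlist(lapply(names(x), function(k) {
    v <- x[[k]]
    if (is.list(v)) c(paste0(pad, k, ":"), simple_yaml(v, indent + 2))
    else if (length(v) > 1)
      c(paste0(pad, k, ":"), paste0(pad, "  - ", v))
    else paste0(pad, k, ": ", v)
  }))
}
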