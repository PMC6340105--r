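# shared fixtures: all data is generated in code at test time

trio_ped <- function() {
  build_pedigree(data.frame(id = c("O", "S", "D"),
                            sire = c("S", "0", "0"),
                            dam = c("D", "0", "0")))
}

# random pedigree with unknown, single-known and both-known parent cases;
# parents are always earlier animals, so the structure is acyclic
random_pedigree <- function(n, p_sire = 0.7, p_dam = 0.7) {
  sire <- dam <- rep("0", n)
  for (i in 3:n) {
    if (stats::runif(1) < p_sire) sire[i] <- paste0("a", sample(i - 1L, 1L))
    if (stats::runif(1) < p_dam)  dam[i]  <- paste0("a", sample(i - 1L, 1L))
    if (sire[i] != "0" && sire[i] == dam[i]) dam[i] <- "0"
  }
  build_pedigree(data.frame(id = paste0("a", seq_len(n)), sire = sire,
                            dam = dam))
}

tiny_params <- function(...) {
  sim_params(n_pens = 12, pen_size_range = c(8, 10), n_sires = 8,
             n_dams = 40, n_batches = 3, ...)
}

short_chain <- function(seed = 1, n_iter = 6000, burn_in = 2000, thin = 5) {
  gibbs_config(n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed)
}

design_for <- function(sim, model = "AM_IGE_i", mode = "OT", C = NULL) {
  spec <- if (model == "AM_IGE_i") ige_model_spec(model, mode = mode)
  else ige_model_spec(model)
  if (is.null(C)) {
    C <- if (model == "AM") NULL
    else if (model == "AM_IGE") {
      pm <- stats::setNames(sim$pheno$pen, sim$pheno$animal)
      interaction_matrix(NULL, pm, "CLASSICAL")
    } else sim$C
  }
  build_design(sim$pheno, sim$ped, spec, C)
}

true_vc <- function(params) {
  v <- params$vc_true
  c(sigma2_D = v$sigma2_D, sigma2_S = v$sigma2_S, sigma_DS = v$sigma_DS,
    sigma2_pen = v$sigma2_pen, sigma2_e = v$sigma2_e)
}
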