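test_that("heritability is the direct share of phenotypic variance", {
  expect_equal(heritability(list(sigma2_D = 1, sigma2_pen = 1,
                                 sigma2_e = 2)), 0.25)
  expect_equal(heritability(list(sigma2_a = 0, sigma2_pen = 0,
                                 sigma2_e = 1)), 0)
})

test_that("total heritable variance follows the degree expansion", {
  vc <- list(sigma2_D = 0.46, sigma2_S = 0.004, sigma_DS = -0.0167,
             sigma2_pen = 0.1, sigma2_e = 0.42)
  # c = 0: social terms vanish
  expect_equal(total_heritable_variance(vc, n = 12, c = 0), 0.46)
  # n = 2, c = 1, G = I
  expect_equal(total_heritable_variance(
    list(sigma2_D = 1, sigma2_S = 1, sigma_DS = 0), n = 2, c = 1), 2)
  # hand expansion at n = 12, c = 1
  hand <- 0.46 + 2 * 11 * (-0.0167) + 11^2 * 0.004
  expect_equal(total_heritable_variance(vc, n = 12, c = 1), hand)
})

test_that("total phenotypic variance reduces and errors as specified", {
  vc <- list(sigma2_D = 0.46, sigma2_S = 0.004, sigma_DS = -0.0167,
             sigma2_pen = 0.1, sigma2_e = 0.42)
  expect_equal(total_phenotypic_variance(vc, n = 12, r = 0, c = 0),
               0.46 + 0.1 + 0.42)
  # n = 2 kills the (n-2) term regardless of r
  v2 <- total_phenotypic_variance(vc, n = 2, r = 0.5, c = 1)
  expect_equal(v2, 0.46 + 0.004 + 0.5 * 2 * (-0.0167) + 0.1 + 0.42)
  bad <- list(sigma2_D = 0.01, sigma2_S = 0.1, sigma_DS = -3,
              sigma2_pen = 0.01, sigma2_e = 0.01)
  expect_error(total_phenotypic_variance(bad, n = 12, r = 1, c = 1),
               "inadmissible")
})

test_that("T2 reduces to h2 without social variance and grows with c when
           the covariance is non-negative", {
  vc0 <- list(sigma2_D = 0.46, sigma2_S = 0, sigma_DS = 0,
              sigma2_pen = 0.1, sigma2_e = 0.42)
  expect_equal(t2(vc0, n = 12, r = 0.1, c = 1), heritability(vc0))
  vc <- list(sigma2_D = 0.46, sigma2_S = 0.004, sigma_DS = 0.0167,
             sigma2_pen = 0.1, sigma2_e = 0.42)
  grid <- seq(0, 2, by = 0.1)
  vals <- vapply(grid, function(cc) t2(vc, n = 12, r = 0.1, c = cc), 0)
  expect_true(all(diff(vals) > 0))
  # c = 0 reduces to sigma2_D / sigma2_P
  expect_equal(t2(vc, n = 12, r = 0.1, c = 0),
               0.46 / total_phenotypic_variance(vc, 12, 0.1, 0))
})

test_that("quartile T2 uses the empirical within-pen degree distribution", {
  set.seed(19)
  n <- 48
  pens <- stats::setNames(rep(paste0("p", 1:6), each = 8), paste0("a", 1:n))
  tr <- data.frame(animal = paste0("a", 1:n), OT = rnorm(n))
  im <- interaction_matrix(tr, pens, "OT")
  vc <- list(sigma2_D = 0.46, sigma2_S = 0.004, sigma_DS = -0.0167,
             sigma2_pen = 0.1, sigma2_e = 0.42)
  qq <- t2_at_quartiles(vc, im, n = 8, r = 0.05)
  deg <- sort(interaction_degrees(im))
  # quantile oracle: type-7 interpolation on the sorted entry list
  qtl <- function(p) {
    h <- (length(deg) - 1) * p
    lo <- floor(h) + 1
    deg[lo] + (h - floor(h)) * (deg[min(lo + 1, length(deg))] - deg[lo])
  }
  expect_equal(qq$q1, qtl(0.25), tolerance = 1e-12)
  expect_equal(qq$q3, qtl(0.75), tolerance = 1e-12)
  expect_lt(qq$q1, 0); expect_gt(qq$q3, 0)
  # negative direct-social covariance puts T2(Q1) above T2(Q3) here because
  # the heritable variance falls faster than the phenotypic at small |c|
  expect_equal(qq$t2_mean, t2(vc, 8, 0.05, 0))

  # symmetric degrees with zero covariance: T2 is an even function of c
  pens2 <- stats::setNames(c("A", "A", "B", "B"), paste0("b", 1:4))
  tr2 <- data.frame(animal = paste0("b", 1:4), OT = c(0, 1, 0, 3))
  im2 <- interaction_matrix(tr2, pens2, "OT")  # degrees -1, +1
  vc0 <- list(sigma2_D = 0.4, sigma2_S = 0.01, sigma_DS = 0,
              sigma2_pen = 0.1, sigma2_e = 0.4)
  qq2 <- t2_at_quartiles(vc0, im2, n = 2, r = 0)
  expect_equal(qq2$t2_q1, qq2$t2_q3)

  cim <- interaction_matrix(NULL, pens2, "CLASSICAL")
  expect_error(t2_at_quartiles(vc0, cim, 2, 0), "CLASSICAL")
})

test_that("quartile spread arithmetic matches the worked examples", {
  expect_equal(t2_quartile_spread(1.29, 0.53), 0.76)
  expect_equal(t2_quartile_spread(1.24, 0.33), 0.91)
})

test_that("total breeding values sum direct and expressed social effects", {
  ids <- paste0("a", 1:12)
  pens <- stats::setNames(rep("p1", 12), ids)
  im <- interaction_matrix(NULL, pens, "CLASSICAL")
  aD <- stats::setNames(rep(10, 12), ids)
  aS <- stats::setNames(rep(1, 12), ids)
  bv <- total_breeding_values(aD, aS, im)
  expect_equal(bv$TBV, rep(21, 12))  # 10 + 11 * 1
  bv0 <- total_breeding_values(aD, stats::setNames(rep(0, 12), ids), im)
  expect_equal(bv0$TBV, bv0$DBV)

  # 4-animal worked example with hand-built pair degrees
  ids4 <- paste0("x", 1:4)
  Cm <- Matrix::sparseMatrix(
    i = c(1, 2, 1, 3, 2, 3), j = c(2, 1, 3, 1, 3, 2),
    x = c(0.5, 0.5, -1.2, -1.2, 0.3, 0.3), dims = c(4, 4),
    dimnames = list(ids4, ids4))
  im4 <- structure(list(C = Cm, mode = "OT",
                        pens = stats::setNames(c("q", "q", "q", "z"), ids4),
                        d_mean = 0, d_sd = 1),
                   class = "interaction_matrix")
  aD4 <- stats::setNames(c(1, 2, 3, 4), ids4)
  aS4 <- stats::setNames(c(0.1, -0.2, 0.3, 0.4), ids4)
  bv4 <- total_breeding_values(aD4, aS4, im4)
  # row sums: x1: 0.5 - 1.2 = -0.7; x2: 0.5 + 0.3 = 0.8;
  #           x3: -1.2 + 0.3 = -0.9; x4 has no mates
  expect_equal(bv4$TBV,
               c(1 + (-0.7) * 0.1, 2 + 0.8 * (-0.2), 3 + (-0.9) * 0.3, 4))
  # an animal outside the interaction matrix falls back to its DBV
  aD5 <- c(aD4, x5 = 7); aS5 <- c(aS4, x5 = 2)
  expect_warning(bv5 <- total_breeding_values(aD5, aS5, im4,
                                              ids = names(aD5)),
                 "TBV = DBV")
  expect_equal(bv5$TBV[5], 7)
})

test_that("the generator realizes the phenotypic-variance algebra", {
  # large unrelated population in constant-size pens, classical incidence
  set.seed(77)
  n_pens <- 830; m <- 12
  ped <- simulate_pedigree(n_pens * m, n_generations = 1)
  pens <- data.frame(animal = ped$id,
                     pen = rep(sprintf("p%03d", 1:n_pens), each = m),
                     batch = "b1", stringsAsFactors = FALSE)
  pm <- stats::setNames(pens$pen, pens$animal)
  C <- interaction_matrix(NULL, pm, "CLASSICAL")
  prm <- sim_params(batch_sd = 0)
  sim <- simulate_phenotypes(ped, pens, C, prm)
  y_rand <- sim$pheno$adg - sim$truth$fixed  # random part only
  vP <- total_phenotypic_variance(prm$vc_true, n = m, r = 0, c = 1)
  expect_lt(abs(stats::var(y_rand) - vP) / vP, 0.05)

  # heritable-variance link: var(TBV) over unrelated animals
  bv <- total_breeding_values(sim$truth$aD, sim$truth$aS, C)
  vT <- total_heritable_variance(prm$vc_true, n = m, c = 1)
  expect_lt(abs(stats::var(bv$TBV) - vT) / vT, 0.05)
})
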