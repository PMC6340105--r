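mk_visits <- function(starts, dur, intake, animal = "a1", pen = "p1") {
  data.frame(animal = animal, pen = pen,
             start = as.POSIXct(starts, tz = "UTC"),
             duration_min = dur, intake_g = intake,
             stringsAsFactors = FALSE)
}

test_that("daily traits follow from visit arithmetic", {
  d <- derive_daily_traits(mk_visits("2020-03-02 09:00:00", 10, 200))
  expect_equal(d$FF, 1)
  expect_equal(d$OT, 10)
  expect_equal(d$FR, 20)
  expect_true(is.na(d$FInt))

  d <- derive_daily_traits(mk_visits(
    c("2020-03-02 09:00:00", "2020-03-02 10:00:00"), c(10, 5), c(200, 100)))
  expect_equal(d$FF, 2)
  expect_equal(d$OT, 15)
  expect_equal(d$FR, 20)
  expect_equal(d$FInt, 50)  # 09:10 end -> 10:00 start

  # negative-duration records are rejected, not silently used
  v <- mk_visits(c("2020-03-02 09:00:00", "2020-03-02 10:00:00"),
                 c(-5, 10), c(100, 100))
  expect_message(d <- derive_daily_traits(v), "dropping")
  expect_equal(d$FF, 1)
})

test_that("sub-minute re-entries merge only within an hour block", {
  v <- mk_visits(c("2020-03-02 09:00:00", "2020-03-02 09:05:20"),
                 c(5, 5), c(100, 100))
  expect_equal(derive_daily_traits(v)$FF, 1)  # 20 s gap, same block: merged
  v <- mk_visits(c("2020-03-02 09:54:00", "2020-03-02 10:00:30"),
                 c(6, 5), c(100, 100))
  expect_equal(derive_daily_traits(v)$FF, 2)  # 30 s gap but block boundary
})

test_that("aggregation means defined daily values per window", {
  daily <- data.frame(animal = "a1", pen = "p1",
                      day = as.Date("2020-03-01") + 0:27,
                      FF = rep(c(4, 6), 14), OT = 30, FR = 10, FInt = 45)
  overall <- aggregate_traits(daily, "overall")
  expect_equal(overall$FF, 5)
  expect_equal(overall$OT, 30)
  expect_equal(overall$days, 28)
  periods <- aggregate_traits(daily, "period")
  expect_equal(nrow(periods), 2)
  expect_equal(periods$days, c(14, 14))
  # a 10-week span makes 5 two-week windows
  daily10 <- data.frame(animal = "a1", pen = "p1",
                        day = as.Date("2020-03-01") + 0:69,
                        FF = 3, OT = 30, FR = 10, FInt = 45)
  expect_equal(sort(unique(aggregate_traits(daily10, "period")$period)), 1:5)
})

test_that("phenotypic correlations recover known structure", {
  tr <- data.frame(animal = paste0("a", 1:50), x = rnorm(50))
  tr$y <- tr$x; tr$z <- -tr$x
  cc <- phenotypic_correlations(tr)
  expect_equal(cc["x", "y"], 1)
  expect_equal(cc["x", "z"], -1)

  skip_if_not_installed("MASS")
  set.seed(5)
  S <- matrix(c(1, 0.56, 0.56, 1), 2, 2)
  xy <- MASS::mvrnorm(5000, c(0, 0), S)
  tr <- data.frame(animal = paste0("a", 1:5000), FR = xy[, 1], FF = xy[, 2])
  cc <- phenotypic_correlations(tr)
  expect_lt(abs(cc["FR", "FF"] - 0.56), 0.03)

  tr$flat <- 1
  expect_warning(phenotypic_correlations(tr), "zero-variance")
})

test_that("rank stability is the Spearman correlation across periods", {
  p1 <- data.frame(animal = paste0("a", 1:20), period = 1, FR = 1:20)
  p2 <- p1; p2$period <- 2
  expect_equal(rank_stability(rbind(p1, p2), traits = "FR")$rho, 1)
  p2$FR <- 20:1
  expect_equal(rank_stability(rbind(p1, p2), traits = "FR")$rho, -1)

  set.seed(8)
  beh <- simulate_behaviour(paste0("a", 1:600),
                            sim_params(persistence = 0.78, n_periods = 3))
  rs <- rank_stability(beh$periods, traits = "OT")
  expect_true(all(rs$rho > 0.6 & rs$rho < 0.9))
})

test_that("standardization centres and scales by the population SD", {
  x <- c(4, 7, 9, 12, 30)
  z <- standardize(x)
  expect_equal(mean(z), 0)
  expect_equal(sqrt(mean((z - mean(z))^2)), 1)
  expect_equal(standardize(z), z)  # idempotent
  expect_equal(standardize(c(1, 2, 3)),
               (c(1, 2, 3) - 2) / sqrt(mean((c(1, 2, 3) - 2)^2)))
  expect_error(standardize(rep(2, 5)), "zero")
})

test_that("pair distances are Euclidean over standardized records", {
  expect_equal(pair_distance(1, -1), 2)
  expect_equal(pair_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(pair_distance(c(1, 0, 0, 0), c(0, 0, 0, 0)), 1)
  expect_equal(pair_distance(c(1, 1, 1, 1), c(0, 0, 0, 0)), 2)
  expect_error(pair_distance(c(1, NA), c(0, 0)), "missing")
})

test_that("classical interaction matrix marks pen sharing", {
  pens <- stats::setNames(c("A", "A", "A", "B", "B"), paste0("a", 1:5))
  im <- interaction_matrix(NULL, pens, "CLASSICAL")
  C <- as.matrix(im$C)
  expect_equal(C["a1", ], c(a1 = 0, a2 = 1, a3 = 1, a4 = 0, a5 = 0))
  # row sums are pen size - 1
  expect_equal(unname(Matrix::rowSums(im$C)), c(2, 2, 2, 1, 1))
})

test_that("standardized interaction degrees have mean 0 and SD 1", {
  set.seed(13)
  n <- 40
  pens <- stats::setNames(rep(paste0("p", 1:5), each = 8), paste0("a", 1:n))
  tr <- data.frame(animal = paste0("a", 1:n), FR = rnorm(n), FF = rnorm(n),
                   OT = rnorm(n), FInt = rnorm(n))
  for (mode in c("OT", "ALL")) {
    im <- interaction_matrix(tr, pens, mode)
    deg <- interaction_degrees(im)
    expect_lt(abs(mean(deg)), 1e-9)
    expect_lt(abs(sqrt(mean((deg - mean(deg))^2)) - 1), 1e-9)
    expect_true(Matrix::isSymmetric(im$C))
    # cross-pen and diagonal entries stay zero
    expect_equal(as.numeric(im$C[1, 9]), 0)
    expect_equal(as.numeric(im$C[1, 1]), 0)
  }
})

test_that("a two-pen pair example standardizes to -1 and +1", {
  pens <- stats::setNames(c("A", "A", "B", "B"), paste0("a", 1:4))
  tr <- data.frame(animal = paste0("a", 1:4), OT = c(0, 1, 0, 3))
  im <- interaction_matrix(tr, pens, "OT")
  # distances are (s, 3s) for some s > 0; population standardization of two
  # values always gives -1 and +1
  expect_equal(as.numeric(im$C["a1", "a2"]), -1)
  expect_equal(as.numeric(im$C["a3", "a4"]), 1)
})

test_that("relabelling animals permutes the interaction matrix", {
  set.seed(21)
  n <- 24
  pens <- stats::setNames(rep(paste0("p", 1:3), each = 8), paste0("a", 1:n))
  tr <- data.frame(animal = paste0("a", 1:n), OT = rnorm(n))
  im <- interaction_matrix(tr, pens, "OT")
  perm <- sample(n)
  im2 <- interaction_matrix(tr[perm, ], pens[perm], "OT")
  expect_equal(as.matrix(im2$C)[names(pens), names(pens)],
               as.matrix(im$C)[names(pens), names(pens)])
})

test_that("missing behaviour for a non-classical mode is a hard error", {
  pens <- stats::setNames(c("A", "A"), c("a1", "a2"))
  expect_error(interaction_matrix(data.frame(animal = "a1", OT = 1),
                                  pens, "OT"), "missing")
})
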