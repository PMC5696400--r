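make_calls <- function(n = 100L, b_t = 0.8, noise = 0, h = NULL,
                       pr0 = 30, pr_slope = 20, pn0 = 10, pn_slope = 8,
                       seed = 1L, locality = "loc1", species = "A") {
  set.seed(seed)
  if (is.null(h)) h <- runif(n)
  temp <- rnorm(n, 14, 3)
  data.frame(individual = sprintf("c%04d", seq_len(n)),
             locality = locality, species = species,
             region = NA_character_, sympatry = "allopatric",
             pulse_rate = pr0 + pr_slope * h + b_t * (temp - 14) +
               rnorm(n, 0, noise),
             pulse_number = pn0 + pn_slope * h +
               0.3 * b_t * (temp - 14) + rnorm(n, 0, noise),
             temperature = temp, h_true = h,
             stringsAsFactors = FALSE)
}

test_that("temperature correction removes the temperature slope", {
  calls <- make_calls(n = 200, b_t = 0.8, noise = 0.5, seed = 2)
  cc <- temperature_correct(calls)
  slope <- unname(coef(lm(cc$pulse_rate_c ~ cc$temperature))[2])
  expect_lt(abs(slope), 0.05)
  # values at the target temperature are unchanged by construction
  calls14 <- calls; calls14$temperature <- 14
  cc14 <- temperature_correct(calls14)
  expect_equal(cc14$pulse_rate_c, calls14$pulse_rate)
  # a variable with no temperature dependence estimates slope 0
  # exactly and is left unchanged
  calls0 <- make_calls(n = 50, b_t = 0, noise = 0,
                       h = rep(0.5, 50), seed = 3)
  cc0 <- temperature_correct(calls0)
  expect_equal(cc0$pulse_rate_c, calls0$pulse_rate, tolerance = 1e-10)
  expect_error(
    temperature_correct(transform(calls, temperature = NA)),
    "no temperatures")
})

test_that("correction is idempotent", {
  calls <- make_calls(n = 80, b_t = 1.2, noise = 1, seed = 4)
  cc <- temperature_correct(calls)
  cc2 <- cc
  cc2$pulse_rate <- cc$pulse_rate_c
  cc2$pulse_number <- cc$pulse_number_c
  cc2 <- temperature_correct(cc2)
  expect_equal(cc2$pulse_rate_c, cc$pulse_rate_c, tolerance = 1e-9)
  expect_equal(cc2$pulse_number_c, cc$pulse_number_c, tolerance = 1e-9)
})

test_that("noise-free linear relations give r-squared of one", {
  set.seed(5)
  n <- 60L
  h <- runif(n)
  calls <- data.frame(individual = sprintf("c%03d", 1:n),
                      locality = "x", species = "A",
                      pulse_rate = exp(0.5 + 0.8 * h),
                      pulse_number = 10 + 2 * h,
                      temperature = 14)   # at target: correction no-op
  hres <- data.frame(individual = calls$individual, h_hat = h)
  cc <- temperature_correct(calls)
  # h is exactly linear in log pulse rate ("perfect fit" notes muted)
  fit <- suppressWarnings(regress_call_on_hindex(cc, hres, "pulse_rate"))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("regression matches a hand-rolled normal-equations solver", {
  calls <- make_calls(n = 40, b_t = 0.5, noise = 2, seed = 6)
  hres <- data.frame(individual = calls$individual,
                     h_hat = calls$h_true)
  cc <- temperature_correct(calls)
  fit <- regress_call_on_hindex(cc, hres, "pulse_number")
  X <- cbind(1, log(cc$pulse_number_c))
  beta <- solve(t(X) %*% X, t(X) %*% cc$h_true)
  expect_lt(max(abs(fit$coefficients - drop(beta))), 1e-10)
})

test_that("strong coupling lands in the benchmark r-squared band", {
  # call slope 3x the noise SD at n = 75 males
  # hybrid-zone index distribution: pure and intermediate males mixed
  r2 <- vapply(1:40, function(s) {
    set.seed(100 + s)
    h <- sample(c(0, 0.5, 1), 75, TRUE, prob = c(0.4, 0.2, 0.4))
    calls <- make_calls(n = 75, b_t = 0.6, noise = 20 / 3,
                        pr_slope = 20, h = h, seed = 100 + s)
    hres <- data.frame(individual = calls$individual,
                       h_hat = calls$h_true)
    cc <- temperature_correct(calls)
    regress_call_on_hindex(cc, hres, "pulse_rate")$r_squared
  }, numeric(1))
  expect_gt(mean(r2 > 0.5 & r2 < 0.9), 0.9)
})

test_that("model choice identifies the generating variable", {
  wins <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    n <- 100L
    pn <- runif(n, 8, 20)
    pr <- runif(n, 25, 60)          # unrelated to h
    h <- pmin(pmax(0.1 * (pn - 8) + rnorm(n, 0, 0.15), 0), 1)
    calls <- data.frame(individual = sprintf("c%03d", 1:n),
                        locality = "x", species = "A",
                        pulse_rate_c = pr, pulse_number_c = pn)
    hres <- data.frame(individual = calls$individual, h_hat = h)
    st <- stepwise_select(calls, hres)
    f <- st$fits
    (f$aic[f$model == "PN"] < f$aic[f$model == "PR"]) &&
      (f$bic[f$model == "PN"] < f$bic[f$model == "PR"])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("joint model wins when both variables contribute", {
  wins <- vapply(1:50, function(s) {
    set.seed(2000 + s)
    n <- 185L
    pn <- runif(n, 8, 20); pr <- runif(n, 25, 60)
    h <- 0.05 * (pn - 8) + 0.01 * (pr - 25) + rnorm(n, 0, 0.1)
    calls <- data.frame(individual = sprintf("c%03d", 1:n),
                        locality = "x", species = "A",
                        pulse_rate_c = pr, pulse_number_c = pn)
    hres <- data.frame(individual = calls$individual, h_hat = h)
    stepwise_select(calls, hres)$best_aic == "PR+PN"
  }, logical(1))
  expect_gte(mean(wins), 0.90)
})

test_that("identical variables raise the collinearity flag", {
  n <- 30L
  calls <- data.frame(individual = sprintf("c%03d", 1:n),
                      locality = "x", species = "A",
                      pulse_rate_c = seq_len(n) + 10,
                      pulse_number_c = seq_len(n) + 10)
  hres <- data.frame(individual = calls$individual,
                     h_hat = runif(n))
  expect_warning(st <- stepwise_select(calls, hres), "collinear")
  expect_true(st$collinear)
  expect_setequal(st$fits$model, c("PR", "PN"))
})

test_that("RCD distance is Euclidean, translation-invariant", {
  sym <- data.frame(pulse_rate_c = c(13, 13), pulse_number_c = c(24, 24))
  allo <- data.frame(pulse_rate_c = c(10, 10), pulse_number_c = c(20, 20))
  expect_equal(rcd_distance(sym, allo)$d_rcd, 5)   # 3-4-5 triangle
  expect_equal(rcd_distance(allo, allo)$d_rcd, 0)
  shift <- function(d, k) transform(d, pulse_rate_c = pulse_rate_c + k,
                                    pulse_number_c = pulse_number_c + k)
  expect_equal(rcd_distance(shift(sym, 7), shift(allo, 7))$d_rcd, 5)
  # equivariant under joint scaling
  scale2 <- function(d) transform(d, pulse_rate_c = 2 * pulse_rate_c,
                                  pulse_number_c = 2 * pulse_number_c)
  expect_equal(rcd_distance(scale2(sym), scale2(allo))$d_rcd, 10)
  expect_error(rcd_distance(sym[0, ], allo), "both")
})

test_that("admixture-on-RCD regression recovers planted dependence", {
  rcd_tab <- data.frame(region = paste0("R", 1:8), species = "A",
                        d_rcd = seq(0, 7))
  adm <- data.frame(region = paste0("R", 1:8),
                    prop_F1 = 0.05 + 0.03 * seq(0, 7) +
                      rnorm(8, 0, 0.005),
                    prop_undetermined = 0.5,
                    prop_advanced = 0.3)
  set.seed(8)
  fit <- rcd_vs_admixture(rcd_tab, adm, metric = "F1")
  expect_gt(fit$r_squared, 0.8)
  # constant admixture -> no explained variance
  fit0 <- suppressWarnings(rcd_vs_admixture(rcd_tab, adm, metric = "CI"))
  expect_equal(fit0$r_squared, 0)
  expect_error(rcd_vs_admixture(rcd_tab[1:2, ], adm), ">= 3")
})

test_that("null regressions at eight regions have wide r2 spread", {
  set.seed(9)
  r2 <- vapply(1:200, function(s) {
    rcd_tab <- data.frame(region = paste0("R", 1:8), species = "A",
                          d_rcd = runif(8))
    adm <- data.frame(region = paste0("R", 1:8), prop_F1 = runif(8),
                      prop_undetermined = 0.5, prop_advanced = 0.2)
    rcd_vs_admixture(rcd_tab, adm, metric = "F1")$r_squared
  }, numeric(1))
  qs <- quantile(r2, c(0.05, 0.95))
  expect_gt(qs[2] - qs[1], 0.4)   # the documented low-power caveat
})
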