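test_that("cline curve matches its closed form at the centre and quarter width", {
  p <- cline_params(1500, 400)
  expect_equal(cline_value(1500, p), 0.5)
  expect_equal(cline_value(1500 + 100, p), 1 / (1 + exp(-1)))
  # p(c) = (pmin + pmax)/2 under scaling, tails = none
  ps <- cline_params(1500, 400, pmin = 0.2, pmax = 0.8)
  expect_equal(cline_value(1500, ps), 0.5)
  ps2 <- cline_params(1500, 400, pmin = 0.1, pmax = 0.5)
  expect_equal(cline_value(1500, ps2), 0.3)
})

test_that("tails join the sigmoid continuously, smoothly when tau = 1", {
  spec <- cline_model_spec("none", "both")
  p <- cline_params(1000, 300, deltaL = 150, deltaR = 220,
                    tauL = 1, tauR = 1)
  for (xj in c(1000 - 150, 1000 + 220)) {
    h <- 1e-5
    expect_equal(cline_value(xj - h, p, spec), cline_value(xj + h, p, spec),
                 tolerance = 1e-6)
    # finite-difference first derivative continuity
    dl <- (cline_value(xj - h, p, spec) - cline_value(xj - 3 * h, p, spec)) / (2 * h)
    dr <- (cline_value(xj + 3 * h, p, spec) - cline_value(xj + h, p, spec)) / (2 * h)
    expect_equal(dl, dr, tolerance = 1e-3)
  }
  # value continuity also for tau < 1
  p2 <- cline_params(1000, 300, deltaL = 150, deltaR = 220,
                     tauL = 0.4, tauR = 0.7)
  for (xj in c(850, 1220)) {
    h <- 1e-6
    expect_equal(cline_value(xj - h, p2, spec), cline_value(xj + h, p2, spec),
                 tolerance = 1e-6)
  }
})

test_that("cline curve is non-decreasing for any valid parameters", {
  set.seed(31)
  spec <- cline_model_spec("free", "both")
  x <- seq(-4000, 8000, by = 10)
  for (i in 1:25) {
    pmin <- runif(1, 0, 0.45); pmax <- runif(1, 0.55, 1)
    p <- cline_params(runif(1, 0, 3000), runif(1, 50, 2000),
                      pmin = pmin, pmax = pmax,
                      deltaL = runif(1, 0, 1500), deltaR = runif(1, 0, 1500),
                      tauL = runif(1), tauR = runif(1))
    v <- cline_value(x, p, spec)
    expect_true(all(diff(v) >= -1e-12))
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("log-likelihood equals the scalar-loop oracle and the C++ path", {
  set.seed(32)
  for (i in 1:10) {
    x <- sort(runif(20, 0, 3000))
    cells <- data.frame(along_km = x, qhat = runif(20), n = sample(5:200, 20))
    spec <- cline_model_spec(sample(c("none", "free"), 1),
                             sample(c("none", "both"), 1))
    p <- cline_params(runif(1, 0, 3000), runif(1, 100, 1500),
                      pmin = 0.05, pmax = 0.95,
                      deltaL = runif(1, 0, 800), deltaR = runif(1, 0, 800),
                      tauL = runif(1), tauR = runif(1))
    ll <- cline_loglik(p, spec, cells)
    expect_equal(ll, loglik_scalar_oracle(p, spec, cells), tolerance = 1e-9)
    th <- unlist(p[clinemap:::.PAR_NAMES], use.names = FALSE)
    expect_equal(ll, clinemap:::.cline_loglik_cpp(
      th, spec$tails == "both", cells$along_km, cells$qhat, 2 * cells$n),
      tolerance = 1e-9)
  }
})

test_that("log-likelihood arithmetic: single cell, additivity, entropy bound", {
  spec <- cline_model_spec()
  cells <- data.frame(along_km = 0, qhat = 0.5, n = 10)
  p <- cline_params(0, 400)  # p(0) = 0.5
  expect_equal(cline_loglik(p, spec, cells), 20 * log(0.5))
  # duplicated cell doubles its contribution
  expect_equal(cline_loglik(p, spec, rbind(cells, cells)),
               2 * cline_loglik(p, spec, cells))
  # q_i = p(x_i) maximises the per-cell contribution
  x <- seq(-500, 500, by = 100)
  perfect <- data.frame(along_km = x, qhat = cline_value(x, p), n = 50)
  ll_max <- cline_loglik(p, spec, perfect)
  worse <- cline_params(200, 400)
  expect_lt(cline_loglik(worse, spec, perfect), ll_max)
})

test_that("allele-count convention switch halves the likelihood", {
  cells <- data.frame(along_km = c(0, 100), qhat = c(0.4, 0.6), n = 25)
  p <- cline_params(50, 300)
  spec <- cline_model_spec()
  expect_equal(cline_loglik(p, spec, cells, allele_counts = "n"),
               cline_loglik(p, spec, cells, allele_counts = "2n") / 2)
})

test_that("ML fit recovers a noiseless cline to within 1 km", {
  x <- seq(0, 3000, by = 50)
  truth <- cline_params(1400, 500)
  cells <- data.frame(along_km = x, qhat = cline_value(x, truth), n = 200)
  fit <- fit_cline_ml(cline_model_spec(), cells)
  expect_lt(abs(fit$params$centre - 1400), 1)
  expect_lt(abs(fit$params$width - 500), 5)
  expect_equal(fit$orientation, "increasing")
})

test_that("decreasing clines are fitted on the complement and flagged", {
  x <- seq(0, 3000, by = 100)
  truth <- cline_params(1400, 500)
  cells <- data.frame(along_km = x, qhat = 1 - cline_value(x, truth), n = 200)
  fit <- fit_cline_ml(cline_model_spec(), cells)
  expect_equal(fit$orientation, "decreasing")
  expect_lt(abs(fit$params$centre - 1400), 1)
  expect_gt(fit$params$width, 0)
})

test_that("flat data is flagged as width at bound", {
  x <- seq(0, 3000, by = 150)
  cells <- data.frame(along_km = x, qhat = 0.5, n = 100)
  expect_warning(fit <- fit_cline_ml(cline_model_spec(), cells),
                 "flat")
  expect_true("width_at_bound" %in% fit$flags)
})

test_that("AICc matches direct arithmetic and penalty ordering", {
  expect_equal(aicc(-100, 2, 20), 204.7059, tolerance = 1e-6)
  expect_equal(aicc(-100, 6, 20), 218.4615, tolerance = 1e-6)
  expect_equal(aicc(-99, 2, 20), aicc(-100, 2, 20) - 2)
  expect_error(aicc(-100, 6, 7), "undefined")
})

test_that("model comparison returns six models; ties favour fewer parameters", {
  set.seed(33)
  x <- seq(0, 3000, by = 125)
  cells <- simulate_cline_cells(x, cline_params(1500, 400))
  tab <- compare_cline_models(cells)
  expect_equal(nrow(tab), 6)
  expect_equal(sum(tab$best), 1)
  expect_true(all(diff(tab$aicc) >= -1e-9))
  # equal-AICc ties resolve toward smaller k
  ties <- tab[abs(tab$aicc - tab$aicc[1]) < 1e-9, ]
  expect_equal(ties$k[1], min(ties$k))
})

test_that("MCMC draws are identical under a fixed seed", {
  set.seed(34)
  cells <- simulate_cline_cells(seq(0, 3000, by = 150),
                                cline_params(1500, 400))
  spec <- cline_model_spec()
  m1 <- cline_mcmc(spec, cells, chains = 2, burn_in = 500,
                   generations = 3000, thin = 3, seed = 77)
  m2 <- cline_mcmc(spec, cells, chains = 2, burn_in = 500,
                   generations = 3000, thin = 3, seed = 77)
  expect_identical(m1$draws, m2$draws)
  expect_identical(m1$acceptance, m2$acceptance)
})

test_that("posterior concentrates near the truth and shifts equivariantly", {
  set.seed(35)
  x <- seq(0, 3000, by = 100)
  cells <- simulate_cline_cells(x, cline_params(1500, 400))
  spec <- cline_model_spec()
  m <- cline_mcmc(spec, cells, chains = 3, burn_in = 2000,
                  generations = 20000, thin = 10, seed = 55)
  cr <- credible_region(m)
  expect_lt(abs(cr$centre_median - 1500), 60)
  expect_true(all(m$rhat[m$active] < 1.1))
  # translate all positions by 700 km: centre moves by 700, width stays
  cells2 <- cells
  cells2$along_km <- cells2$along_km + 700
  m2 <- cline_mcmc(spec, cells2, chains = 3, burn_in = 2000,
                   generations = 20000, thin = 10, seed = 55)
  cr2 <- credible_region(m2)
  expect_equal(cr2$centre_median - cr$centre_median, 700, tolerance = 30)
  expect_equal(cr2$width_median, cr$width_median, tolerance = 30)
})

test_that("credible region needs draws and behaves on degenerate posteriors", {
  draws <- matrix(rep(c(1500, 400, 0, 1, 0, 0, 1, 1), each = 2000),
                  nrow = 2000)
  colnames(draws) <- clinemap:::.PAR_NAMES
  fake <- structure(list(draws = draws, spec = cline_model_spec(),
                         orientation = "increasing",
                         x_range = c(0, 3000)),
                    class = "cline_mcmc")
  cr <- credible_region(fake)
  expect_equal(diff(cr$centre_ci), 0)
  expect_equal(diff(cr$width_ci), 0)
  expect_true(all(cr$envelope$p_lo == cr$envelope$p_hi))
  expect_true(all(cr$envelope$p_lo >= 0 & cr$envelope$p_hi <= 1))
  fake$draws <- draws[1:500, ]
  expect_error(credible_region(fake), "1000")
})

test_that("centre offset is the median difference with a bracketing interval", {
  mk <- function(centres) {
    draws <- cbind(centre = centres, width = 400, pmin = 0, pmax = 1,
                   deltaL = 0, deltaR = 0, tauL = 1, tauR = 1)
    structure(list(draws = draws, spec = cline_model_spec(),
                   orientation = "increasing", x_range = c(0, 3000)),
              class = "cline_mcmc")
  }
  set.seed(36)
  a <- mk(rnorm(2000, 1000, 30)); b <- mk(rnorm(2000, 2500, 30))
  off <- centre_offset(a, b)
  expect_equal(off$offset_km, 1500, tolerance = 10)
  expect_true(off$ci[1] <= -1500 + 200 && off$ci[2] >= -1500 - 200)
  # identical posteriors: zero offset
  expect_equal(centre_offset(a, a)$offset_km, 0)
  # mismatched transects error
  attr(a, "transect_name") <- "t1"; attr(b, "transect_name") <- "t2"
  expect_error(centre_offset(a, b), "different transects")
})
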