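test_that("design construction produces consistent dimensions", {
  d <- data.frame(y = rnorm(5))
  des <- build_design(d, "y", fixed = ~1)
  expect_equal(unname(des$X), matrix(1, 5, 1), ignore_attr = TRUE)

  expect_error(build_design(d, "z"), "z")
  expect_error(build_design(data.frame(y = rep(NA_real_, 4)), "y"),
               "entirely missing")

  # two traits x three units: residual bookkeeping pairs rows by unit
  long <- data.frame(unit = rep(1:3, each = 2),
                     trait = rep(c("a", "b"), 3),
                     y = rnorm(6))
  des2 <- build_design(long, "y", fixed = ~ 0 + trait,
                       residual = list(type = "us_trait", trait = "trait",
                                       unit = "unit"))
  expect_equal(des2$residual$n_units, 3L)
  expect_length(des2$residual$idx1, 3L)
  expect_equal(long$trait[des2$residual$idx1], rep("a", 3))
  expect_equal(long$unit[des2$residual$idx1],
               long$unit[des2$residual$idx2])

  bad <- long[-1, ]
  expect_error(build_design(bad, "y", fixed = ~1,
                            residual = list(type = "us_trait",
                                            trait = "trait", unit = "unit")),
               "one row per trait")
})

test_that("multiresponse stacking repeats species traits across genes", {
  cfg <- sim_config(seed = 41, n_species = 8,
                    subfamilies = default_subfamilies(
                      labels = c("OR51", "OR14"), gene_count_per_species = 3))
  ds <- simulate_dataset(cfg)
  rt <- build_rate_table(ds$gene_tree_pairs)
  long <- stack_multiresponse(rt, ds$species_table)
  expect_equal(nrow(long), 2L * nrow(rt))
  expect_equal(max(long$unit), nrow(rt))
  # trait-2 values constant within species
  sa <- long[long$trait == "sa", ]
  agg <- tapply(sa$y, sa$species, function(v) diff(range(v)))
  expect_true(all(agg < 1e-12))
  # unknown species rejected
  rt_bad <- rt; rt_bad$species[1] <- "made_up"
  expect_error(stack_multiresponse(rt_bad, ds$species_table), "made_up")
})

test_that("sampler matches the conjugate closed-form posterior", {
  set.seed(50)
  n <- 60
  X <- cbind(1, rnorm(n), rnorm(n))
  beta_true <- c(1, -0.5, 0.25)
  s2 <- 0.49
  y <- drop(X %*% beta_true) + rnorm(n, 0, sqrt(s2))
  d <- data.frame(y = y, x1 = X[, 2], x2 = X[, 3])
  des <- build_design(d, "y", fixed = ~ x1 + x2)

  for (pv in c(1e8, 100)) {
    prior <- prior_spec(fixed_var = pv, residual = list(fixed = s2))
    fit <- gibbs_fit(des, priors = prior,
                     mcmc = mcmc_config(6000, 1000, 1, seed = 60))
    # closed form: beta | y ~ N((X'X/s2 + I/pv)^-1 X'y/s2, (X'X/s2 + I/pv)^-1)
    Prec <- crossprod(X) / s2 + diag(1 / pv, 3)
    Sig <- solve(Prec)
    mu <- drop(Sig %*% crossprod(X, y) / s2)
    sam <- fit$samples[, fit$param_map$fixed]
    ess <- apply(sam, 2, ess_chain)
    mcse <- sqrt(diag(Sig)) / sqrt(ess)
    expect_true(all(abs(colMeans(sam) - mu) < 3 * mcse))
    expect_true(all(abs(apply(sam, 2, var) / diag(Sig) - 1) < 0.10))
  }
})

test_that("intercept-only diffuse fit centers on the sample mean", {
  set.seed(51)
  y <- rnorm(80, mean = 4, sd = 1.3)
  des <- build_design(data.frame(y = y), "y", fixed = ~1)
  fit <- gibbs_fit(des, mcmc = mcmc_config(3000, 500, 1, seed = 1))
  sam <- fit$samples[, "fixed.(Intercept)"]
  mcse <- sd(sam) / sqrt(ess_chain(sam))
  expect_lt(abs(mean(sam) - mean(y)), 3 * mcse)
})

test_that("identical seed and design give identical samples", {
  set.seed(52)
  d <- data.frame(y = rnorm(30), x = rnorm(30), g = rep(letters[1:5], 6))
  des <- build_design(d, "y", fixed = ~x,
                      blocks = list(ran_block(~1, "g", "us")))
  f1 <- gibbs_fit(des, mcmc = mcmc_config(500, 100, 2, seed = 77))
  f2 <- gibbs_fit(des, mcmc = mcmc_config(500, 100, 2, seed = 77))
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$dic, f2$dic)
  f3 <- gibbs_fit(des, mcmc = mcmc_config(500, 100, 2, seed = 78))
  expect_false(identical(f1$samples, f3$samples))
})

test_that("HPD intervals match known distributions", {
  expect_error(hpd_interval(rnorm(200), mass = 1.2), "mass")
  expect_equal(unname(hpd_interval(rep(2.5, 200))), c(2.5, 2.5))

  set.seed(53)
  z <- rnorm(1e5)
  h <- hpd_interval(z, 0.95)
  expect_lt(abs(h[1] + 1.96), 0.05)
  expect_lt(abs(h[2] - 1.96), 0.05)

  u <- runif(1e5)
  hu <- hpd_interval(u, 0.95)
  expect_lt(abs(unname(diff(hu)) - 0.95), 0.01)
})

test_that("DIC reduces to the deviance for a constant-deviance chain", {
  fake <- structure(list(deviance = rep(12.5, 200), d_hat = 12.5),
                    class = "mm_fit")
  expect_equal(dic(fake), 12.5)
  expect_equal(2 * mean(fake$deviance) - fake$d_hat, 12.5)

  short <- structure(list(deviance = rep(1, 5), d_hat = 1),
                     class = "mm_fit")
  expect_error(dic(short), "10")
})

test_that("stored-sample DIC recomputation is exact and penalizes noise", {
  set.seed(54)
  d <- data.frame(y = rnorm(40, 1, 1), x = rnorm(40))
  des <- build_design(d, "y", fixed = ~1)
  fit <- gibbs_fit(des, mcmc = mcmc_config(1500, 500, 1, seed = 2))
  expect_equal(dic(fit), fit$dic, tolerance = 1e-12)
  expect_equal(fit$dic, 2 * mean(fit$deviance) - fit$d_hat,
               tolerance = 1e-9)
  expect_true(is.finite(fit$dic))
  expect_gt(fit$p_d, 0)

  # a pure-noise covariate should usually cost DIC
  worse <- 0L
  for (r in 1:20) {
    set.seed(600 + r)
    dd <- data.frame(y = rnorm(50, 2, 1), x = rnorm(50))
    dz <- build_design(dd, "y", fixed = ~1)
    dx <- build_design(dd, "y", fixed = ~x)
    f0 <- gibbs_fit(dz, mcmc = mcmc_config(1200, 300, 1, seed = r))
    f1 <- gibbs_fit(dx, mcmc = mcmc_config(1200, 300, 1, seed = r))
    if (f1$dic > f0$dic) worse <- worse + 1L
  }
  expect_gte(worse, 14L)  # >= 70% of 20
})

test_that("derived covariance-ratio coefficients follow the block samples", {
  sam <- cbind("resid.a:a" = rep(4, 200), "resid.a:b" = rep(2, 200),
               "resid.b:b" = rep(8, 200))
  fake <- structure(list(samples = sam,
                         param_map = list(residual = colnames(sam))),
                    class = "mm_fit")
  expect_equal(derived_coefficient(fake, denom = 2L)$samples,
               rep(2 / 8, 200))
  expect_equal(derived_coefficient(fake, denom = 1L)$samples,
               rep(2 / 4, 200))
  sam0 <- sam; sam0[, 2] <- 0
  fake0 <- structure(list(samples = sam0,
                          param_map = list(residual = colnames(sam0))),
                     class = "mm_fit")
  expect_true(all(derived_coefficient(fake0)$samples == 0))
})

test_that("effective sample size tracks white noise and AR(1) chains", {
  set.seed(55)
  n <- 4000
  x <- rnorm(n)
  expect_lt(abs(ess_chain(x) - n) / n, 0.20)

  rho <- 0.9
  ar <- as.numeric(stats::arima.sim(list(ar = rho), n))
  target <- n * (1 - rho) / (1 + rho)
  expect_lt(abs(ess_chain(ar) - target) / target, 0.30)

  expect_true(is.na(ess_chain(rep(1, 500))))
  expect_true(is.na(geweke_z(rep(1, 500))))
  expect_lt(abs(geweke_z(rnorm(5000))), 4)

  # cross-check against an independent implementation
  if (requireNamespace("coda", quietly = TRUE)) {
    cess <- as.numeric(coda::effectiveSize(coda::mcmc(ar)))
    expect_lt(abs(ess_chain(ar) - cess) / cess, 0.5)
  }
})

test_that("missing responses are augmented rather than dropped", {
  set.seed(56)
  n <- 60
  d <- data.frame(x = rnorm(n))
  d$y <- 2 + d$x + rnorm(n, 0, 0.5)
  d_mis <- d; d_mis$y[sample.int(n, 15)] <- NA
  des <- build_design(d_mis, "y", fixed = ~x)
  fit <- gibbs_fit(des, mcmc = mcmc_config(2500, 500, 1, seed = 3))
  sm <- fit$summary
  sl <- sm[sm$parameter == "fixed.x", ]
  expect_lt(abs(sl$mean - 1), 0.4)
  expect_true(sl$lower < 1 && sl$upper > 1)

  # two-trait augmentation: missing sa rows imputed, fit still sensible
  long <- data.frame(unit = rep(1:40, each = 2),
                     trait = rep(c("a", "b"), 40))
  set.seed(57)
  mu <- c(a = 0, b = 3)
  Sig <- matrix(c(1, 0.8, 0.8, 1), 2)
  vals <- t(chol(Sig)) %*% matrix(rnorm(80), 2)
  long$y <- mu[long$trait] + as.vector(vals)
  long$y[long$trait == "b" & long$unit <= 10] <- NA
  desm <- build_design(long, "y", fixed = ~ 0 + trait,
                       residual = list(type = "us_trait", trait = "trait",
                                       unit = "unit"))
  fitm <- gibbs_fit(desm, mcmc = mcmc_config(2500, 500, 1, seed = 4))
  r12 <- fitm$summary[fitm$summary$parameter == "resid.a:b", "mean"]
  expect_gt(r12, 0.3)
})

test_that("phylogenetic signal is attributed to the right component", {
  tr <- simulate_yule_tree(25, seed = 70)
  rel <- relatedness_matrix(tr)
  depth <- max(root_to_tip(tr))
  hi <- lo <- logical(6)
  for (r in 1:6) {
    set.seed(700 + r)
    u <- simulate_bm(tr, sigma2 = 1 / depth)
    d_hi <- data.frame(species = tr$tip.label,
                       y = 0.5 + u + rnorm(25, 0, sqrt(0.05)))
    d_lo <- data.frame(species = tr$tip.label,
                       y = 0.5 + 0.2 * u + rnorm(25, 0, 1))
    mk <- function(dd) build_design(
      dd, "y", fixed = ~1,
      blocks = list(ran_block(~1, "species", "us", relatedness = rel,
                              name = "phylo")))
    f_hi <- gibbs_fit(mk(d_hi), mcmc = mcmc_config(2000, 500, 2, seed = r))
    f_lo <- gibbs_fit(mk(d_lo), mcmc = mcmc_config(2000, 500, 2, seed = r))
    frac <- function(f) {
      g <- f$samples[, f$param_map$G]
      s <- f$samples[, "resid.s2"]
      mean(g / (g + s))
    }
    hi[r] <- frac(f_hi) > 0.5
    lo[r] <- frac(f_lo) < 0.5
  }
  expect_gte(sum(hi), 5L)
  expect_gte(sum(lo), 5L)
})
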