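test_that("Yule trees are ultrametric, deterministic, and validated", {
  expect_error(simulate_yule_tree(1), ">= 2")
  expect_error(simulate_yule_tree(5, birth_rate = 0), "> 0")

  t2 <- simulate_yule_tree(2, seed = 1)
  d <- root_to_tip(t2)
  expect_equal(length(d), 2L)
  expect_equal(unname(diff(d)), 0, tolerance = 1e-12)

  for (n in c(5, 17, 40)) {
    tr <- simulate_yule_tree(n, birth_rate = 2, seed = n)
    rtt <- root_to_tip(tr)
    expect_equal(length(rtt), n)
    expect_lt(max(rtt) - min(rtt), 1e-9)
  }

  a <- write_newick(simulate_yule_tree(12, seed = 99))
  b <- write_newick(simulate_yule_tree(12, seed = 99))
  expect_identical(a, b)
  expect_false(identical(a, write_newick(simulate_yule_tree(12, seed = 100))))
})

test_that("Yule lineage accumulation tracks the exponential expectation", {
  # E[N(t)] = 2 * exp(b t) starting from 2 lineages; count lineages at t
  # from internal-node depths, capping n well above the expectation
  b <- 1; t_probe <- 1.5; n_cap <- 40
  expected <- 2 * exp(b * t_probe)
  set.seed(7)
  counts <- replicate(400, {
    tr <- simulate_yule_tree(n_cap, birth_rate = b,
                             seed = sample.int(1e6, 1))
    n <- length(tr$tip.label)
    depth <- numeric(n + tr$Nnode)
    ord <- rev(ape::postorder(tr))
    for (k in ord) {
      depth[tr$edge[k, 2]] <- depth[tr$edge[k, 1]] + tr$edge.length[k]
    }
    inner <- depth[(n + 2):(n + tr$Nnode)]  # exclude root (depth 0)
    2 + sum(inner <= t_probe)
  })
  expect_lt(abs(mean(counts) - expected) / expected, 0.10)
})

test_that("Brownian simulation has the right degenerate and iid limits", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  x <- simulate_bm(tr, sigma2 = 0, root_value = 3.5, seed = 1)
  expect_equal(unname(x), rep(3.5, 3))
  expect_error(simulate_bm(tr, sigma2 = -1), ">= 0")

  st <- star_tree(2000, depth = 1)
  y <- simulate_bm(st, sigma2 = 1, root_value = 0, seed = 42)
  ks <- stats::ks.test(y, "pnorm")
  expect_gt(ks$p.value, 0.01)
})

test_that("Brownian tip covariance matches sigma2 * vcv on three shapes", {
  for (mk in list(balanced_tree8, caterpillar_tree8,
                  function() star_tree(8))) {
    err <- bm_frobenius_error(mk(), sigma2 = 0.7, n_rep = 2000, seed = 11)
    expect_lt(err, 0.10)
  }
})

test_that("species table realizes the configured allometry and diet coding", {
  cfg0 <- sim_config(seed = 5, n_species = 20, phylo_var = 0,
                     resid_var = 1e-12,
                     species_covariance = matrix(0, 2, 2))
  tr <- simulate_yule_tree(20, seed = 2)
  st <- simulate_species_table(tr, cfg0)
  a <- cfg0$allometry
  pred <- ifelse(st$diet_class == "plant",
                 a$plant$intercept + a$plant$slope * log(st$mass_g),
                 a$animal$intercept + a$animal$slope * log(st$mass_g))
  expect_equal(log(st$surface_area), pred, tolerance = 1e-5)
  expect_equal(st$diet_class, unname(classify_diet(st$diet_index)))

  cfg1 <- sim_config(seed = 6, plant_fraction = 1)
  st1 <- simulate_species_table(simulate_yule_tree(15, seed = 3), cfg1)
  expect_true(all(st1$diet_class == "plant"))

  cfg2 <- sim_config(seed = 6, plant_fraction = 0)
  st2 <- simulate_species_table(simulate_yule_tree(15, seed = 3), cfg2)
  expect_true(all(st2$diet_class == "animal"))
})

test_that("pooled OLS recovers a shared allometric slope without bias", {
  slope_true <- 0.5
  allo <- list(plant = list(intercept = 2, slope = slope_true),
               animal = list(intercept = 2, slope = slope_true))
  ests <- ses <- numeric(50)
  for (r in 1:50) {
    cfg <- sim_config(seed = 100 + r, n_species = 40, allometry = allo,
                      phylo_var = 0, resid_var = 0.05,
                      species_covariance = matrix(0, 2, 2))
    tr <- simulate_yule_tree(40, seed = 200 + r)
    st <- simulate_species_table(tr, cfg)
    f <- stats::lm(log(surface_area) ~ log(mass_g), data = st)
    ests[r] <- stats::coef(f)[2]
    ses[r] <- summary(f)$coefficients[2, 2]
  }
  bias <- mean(ests) - slope_true
  se_mean <- sqrt(mean(ses^2) / 50)
  expect_lt(abs(bias), 2 * se_mean)
})

test_that("gene tree pairs honor detection, noise, and slope settings", {
  tr <- simulate_yule_tree(12, seed = 4)
  sf <- default_subfamilies(labels = c("OR52", "OR4"),
                            slopes = c(2, 0.5), intercepts = 0,
                            gene_count_per_species = 5,
                            rate_lognorm_sd = 0)
  cfg <- sim_config(seed = 9, n_species = 12, subfamilies = sf,
                    detection_prob = 1,
                    species_covariance = matrix(0, 2, 2))
  pairs <- simulate_gene_tree_pairs(tr, cfg)
  expect_length(pairs, 10L)
  for (p in pairs) {
    expect_setequal(p$codon_tree$tip.label, tr$tip.label)
    slope <- sf$codon_slope[match(p$subfamily, sf$label)]
    expect_equal(root_to_tip(p$codon_tree),
                 slope * root_to_tip(p$nucleotide_tree)[
                   names(root_to_tip(p$codon_tree))],
                 tolerance = 1e-10)
  }
  expect_error(
    simulate_gene_tree_pairs(tr, sim_config(detection_prob = 0)),
    "detection_prob")

  # thinning: with detection 0.55 genes lose tips but topology is shared
  cfgt <- sim_config(seed = 10, n_species = 12, subfamilies = sf)
  pt <- simulate_gene_tree_pairs(tr, cfgt)
  for (p in pt) {
    expect_identical(p$codon_tree$tip.label, p$nucleotide_tree$tip.label)
    expect_true(all(p$codon_tree$tip.label %in% tr$tip.label))
  }
})

test_that("OLS on extracted root-to-tip lengths recovers the codon slope", {
  slope_true <- 1.2
  sf <- default_subfamilies(labels = "OR6", slopes = slope_true,
                            gene_count_per_species = 50,
                            rate_lognorm_sd = 0.2)
  cfg <- sim_config(seed = 21, n_species = 15, subfamilies = sf,
                    detection_prob = 1,
                    species_covariance = matrix(0, 2, 2))
  tr <- simulate_yule_tree(15, seed = 22)
  rt <- build_rate_table(simulate_gene_tree_pairs(tr, cfg))
  f <- stats::lm(codon_rtt ~ nucl_rtt, data = rt)
  est <- stats::coef(f)[2]
  se <- summary(f)$coefficients[2, 2]
  expect_lt(abs(est - slope_true), 2 * se)
})

test_that("datasets emit, reload identically, and are seed-deterministic", {
  cfg <- sim_config(seed = 31, n_species = 8,
                    subfamilies = default_subfamilies(
                      labels = c("OR51", "OR10"), gene_count_per_species = 3))
  ds <- simulate_dataset(cfg)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  unlink(c(d1, d2), recursive = TRUE)
  emit_dataset(ds, d1)
  back <- load_dataset(d1)
  expect_equal(back$species_table, ds$species_table, tolerance = 1e-12)
  expect_equal(write_newick(back$species_tree),
               write_newick(ds$species_tree))
  expect_identical(names(back$gene_tree_pairs), names(ds$gene_tree_pairs))
  for (g in names(ds$gene_tree_pairs)) {
    expect_equal(
      root_to_tip(back$gene_tree_pairs[[g]]$codon_tree),
      root_to_tip(ds$gene_tree_pairs[[g]]$codon_tree), tolerance = 1e-12)
  }

  # byte-identical re-emission from the same config
  emit_dataset(simulate_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }

  # gene counts recorded per species match the pair tip sets
  counts <- table(unlist(lapply(ds$gene_tree_pairs,
                                function(p) p$codon_tree$tip.label)))
  for (s in ds$species_table$species) {
    cnt <- counts[s]
    if (is.na(cnt)) cnt <- 0L
    expect_equal(ds$species_table$n_or_detected[
      ds$species_table$species == s], as.integer(cnt))
  }
})
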