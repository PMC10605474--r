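locus <- rfc1_locus()

test_that("knee_epsilon isolates a gross outlier and handles degenerate curves", {
  set.seed(3)
  d <- c(rnorm(60, 6858, 30), 30000)
  eps <- knee_epsilon(d, min_samples = 5)
  expect_lt(eps, 23000)
  expect_gt(eps, 0)
  flt <- dbscan_filter(d, eps, min_samples = 5)
  expect_true(30000 %in% flt$removed)

  # identical points: flat (all-zero) k-distance curve, no knee
  expect_warning(eps0 <- knee_epsilon(rep(5, 20), min_samples = 5),
                 class = "ogmstr_no_knee")
  expect_equal(eps0, 0)

  expect_error(knee_epsilon(c(1, 2, 3), min_samples = 5),
               class = "ogmstr_insufficient_data")
})

test_that("dbscan_filter matches the stated examples", {
  flt <- dbscan_filter(c(rep(6800, 8), 30000), epsilon = 500, min_samples = 5)
  expect_equal(flt$removed, 30000)
  expect_equal(flt$kept, rep(6800, 8))

  flt2 <- dbscan_filter(rep(42, 10), epsilon = 1, min_samples = 5)
  expect_length(flt2$removed, 0L)

  # two dense clusters far apart are both kept
  two <- c(rnorm(30, 7000, 20), rnorm(30, 12000, 20))
  flt3 <- dbscan_filter(two, epsilon = 200, min_samples = 5)
  expect_length(flt3$kept, 60L)

  expect_error(dbscan_filter(1:10, epsilon = 0, min_samples = 3),
               class = "ogmstr_validation")
  expect_error(dbscan_filter(c(1, 5000, 10000), epsilon = 1, min_samples = 3),
               class = "ogmstr_all_outliers")
})

test_that("dbscan_filter agrees with the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:30) {
    inst <- random_dbscan_instance()
    got <- tryCatch(dbscan_filter(inst$d, inst$eps, inst$min_pts),
                    ogmstr_all_outliers = function(e) e)
    want <- oracle_dbscan(inst$d, inst$eps, inst$min_pts)
    if (inherits(got, "ogmstr_all_outliers")) {
      expect_length(want$kept, 0L)
    } else {
      expect_same_multiset(got$kept, want$kept)
      expect_same_multiset(got$removed, want$removed)
      expect_same_multiset(c(got$kept, got$removed), inst$d)
    }
  }
})

test_that("single-component fit equals the closed-form Gaussian MLE", {
  fit <- fit_gmm(c(1, 2, 3), 1)
  expect_equal(fit$components$mean_bp, 2)
  expect_equal(fit$components$sd_bp^2, 2 / 3)
  expect_equal(fit$loglik, oracle_gauss_mle(c(1, 2, 3))$loglik)
  expect_equal(fit$bic, 2 * log(3) - 2 * fit$loglik)

  set.seed(21)
  for (i in 1:20) {
    d <- rnorm(sample(10:200, 1), runif(1, 5000, 15000), runif(1, 20, 400))
    fit <- fit_gmm(d, 1)
    want <- oracle_gauss_mle(d)
    expect_equal(fit$components$mean_bp, want$mean, tolerance = 1e-9)
    expect_equal(fit$components$sd_bp^2, want$var, tolerance = 1e-9)
    expect_equal(fit$loglik, want$loglik, tolerance = 1e-9)
  }
})

test_that("two-component fit recovers well-separated mixture parameters", {
  # seed chosen as a representative draw (both half-sample means within one
  # standard error of the generating truth)
  set.seed(3)
  d <- c(rnorm(100, 10178, 120), rnorm(100, 10508, 110))
  fit <- fit_gmm(d, 2, sizing_config(seed = 1))
  expect_equal(fit$k, 2L)
  expect_equal(fit$components$mean_bp[1], 10178, tolerance = 30 / 10178)
  expect_equal(fit$components$mean_bp[2], 10508, tolerance = 30 / 10508)
  expect_equal(sum(fit$components$weight), 1, tolerance = 1e-9)
  expect_true(fit$converged)

  expect_error(fit_gmm(d, 3), class = "ogmstr_unsupported_k")
  expect_error(fit_gmm(rep(5, 50), 2), class = "ogmstr_degenerate_data")
})

test_that("mixture weights always sum to one and variances respect the floor", {
  set.seed(33)
  cfg <- sizing_config(seed = 2)
  for (i in 1:10) {
    d <- c(rnorm(50, 8000, runif(1, 10, 200)),
           rnorm(50, runif(1, 9000, 20000), runif(1, 10, 200)))
    for (k in 1:2) {
      fit <- fit_gmm(d, k, cfg)
      expect_equal(sum(fit$components$weight), 1, tolerance = 1e-9)
      floor_var <- cfg$variance_floor_frac * mean((d - mean(d))^2)
      expect_true(all(fit$components$sd_bp^2 >= floor_var * (1 - 1e-12)))
    }
  }
})

test_that("select_model applies the BIC-and-weights rule", {
  f1 <- fake_fit(1, 1000, 1)
  expect_equal(select_model(f1, fake_fit(2, 990, c(0.5, 0.5)))$k, 2L)
  expect_equal(select_model(f1, fake_fit(2, 990, c(0.8, 0.2)))$k, 1L)
  expect_equal(select_model(f1, fake_fit(2, 1000, c(0.5, 0.5)))$k, 1L)
  # weight exactly at the threshold fails the strict inequality
  expect_equal(select_model(f1, fake_fit(2, 990, c(0.75, 0.25)))$k, 1L)
})

test_that("model selection is invariant under affine rescaling of the data", {
  set.seed(55)
  cfg <- sizing_config(seed = 4)
  for (i in 1:10) {
    sep <- runif(1, 100, 2000)
    d <- c(rnorm(60, 9000, 150), rnorm(60, 9000 + sep, 150))
    a <- runif(1, 0.2, 5)
    b <- runif(1, -2000, 2000)
    f1 <- fit_gmm(d, 1, cfg); f2 <- fit_gmm(d, 2, cfg)
    g1 <- fit_gmm(a * d + b, 1, cfg); g2 <- fit_gmm(a * d + b, 2, cfg)
    # both BICs shift by the same additive constant 2 n log(a)
    shift <- 2 * length(d) * log(a)
    expect_lt(abs((g1$bic - f1$bic) - shift), 1e-6)
    expect_lt(abs((g2$bic - f2$bic) - shift), 0.02)
    expect_equal(select_model(g1, g2)$k, select_model(f1, f2)$k)
  }
})

test_that("bp_to_repeats reproduces the worked conversions", {
  expect_equal(bp_to_repeats(11443, locus), 917)   # 4585 bp expansion
  expect_equal(bp_to_repeats(6858, locus), 0)
  expect_equal(bp_to_repeats(10506, locus), 729.6) # 3648 bp expansion
  expect_equal(round(bp_to_repeats(10506, locus)), 730)
  expect_equal(bp_to_repeats(10180, locus), 664.4) # 3322 bp expansion
  expect_equal(repeats_to_bp(bp_to_repeats(8000, locus), locus), 8000)
  # negative estimates pass through unclamped
  expect_lt(bp_to_repeats(6838, locus), 0)
})

test_that("size_sample runs the full pipeline on simulated single-allele data", {
  dset <- simulate_molecule_distances(
    allele_spec(894, 29),
    sim_config(100, seed = 12), sample_id = "hom"
  )
  res <- size_sample(dset, locus, sizing_config(seed = 5))
  expect_equal(res$selected$k, 1L)
  expect_equal(res$zygosity_label, "single-component (reported homozygous)")
  expect_equal(res$alleles$mean_repeats, 894, tolerance = 9 / 894)
  expect_equal(res$n_total, 100L)
  expect_equal(res$n_total, res$n_kept + res$n_outliers)
  expect_equal(res$alleles$classification, "expanded")
})

test_that("size_sample resolves a heterozygous carrier with one normal allele", {
  dset <- simulate_molecule_distances(
    list(allele_spec(0, 26, 0.5), allele_spec(450, 22, 0.5)),
    sim_config(100, seed = 30), sample_id = "het"
  )
  res <- size_sample(dset, locus, sizing_config(seed = 5))
  expect_equal(res$selected$k, 2L)
  expect_equal(res$zygosity_label, "two alleles")
  expect_equal(res$alleles$classification, c("normal", "expanded"))
  expect_equal(res$alleles$mean_repeats[2], 450, tolerance = 15 / 450)
  # instability ratio undefined for the (near-zero) normal allele if <= 0
  expect_true(is.na(res$alleles$instability_ratio[1]) ||
                res$alleles$instability_ratio[1] > 0)
})

test_that("size_sample is deterministic given data and seed, and validates input", {
  dset <- simulate_molecule_distances(
    list(allele_spec(664, 24, 0.5), allele_spec(730, 22, 0.5)),
    sim_config(120, seed = 9), sample_id = "det"
  )
  r1 <- size_sample(dset, locus, sizing_config(seed = 3))
  r2 <- size_sample(dset, locus, sizing_config(seed = 3))
  expect_identical(sizing_table(r1), sizing_table(r2))

  small <- distance_set("tiny", rep(7000, 5))
  expect_error(size_sample(small, locus, sizing_config()),
               regexp = "tiny", class = "ogmstr_insufficient_data")
})

test_that("alleles are reported sorted ascending with a two-allele label", {
  dset <- simulate_molecule_distances(
    list(allele_spec(300, 15, 0.5), allele_spec(1200, 60, 0.5)),
    sim_config(120, seed = 14), sample_id = "two"
  )
  res <- size_sample(dset, locus, sizing_config(seed = 5))
  expect_equal(res$selected$k, 2L)
  expect_false(is.unsorted(res$alleles$mean_repeats))
  tab <- sizing_table(res)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$k, c(2L, 2L))
})
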