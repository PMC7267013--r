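test_that("AR(1) log-density matches closed forms and a dense oracle", {
  expect_equal(ar1_loglik(c(0, 0), 1, 0), -log(2 * pi), tolerance = 1e-12)
  expect_equal(ar1_loglik(c(1, 1), 1, 0), -log(2 * pi) - 1, tolerance = 1e-12)
  expect_equal(ar1_loglik(c(1, 1), 1, 0.5), -2.3607, tolerance = 1e-4)

  set.seed(101)
  for (k in c(2, 5, 12)) {
    e <- rnorm(k)
    for (s2 in c(0.3, 1, 2.5)) {
      for (rho in c(-0.8, -0.2, 0, 0.5, 0.9)) {
        expect_equal(ar1_loglik(e, s2, rho),
                     as.numeric(ar1_dense_loglik(e, s2, rho)),
                     tolerance = 1e-8)
      }
    }
  }
  expect_error(ar1_loglik(c(0, 0), 1, 1), "rho")
  expect_error(ar1_loglik(c(0, 0), -1, 0), "sigma2")
  expect_error(ar1_loglik(0, 1, 0), "length")
})

test_that("group model recovers planted AR(1) covariance parameters", {
  # iid noise: rho near zero
  ph0 <- simulate_shape_phenotypes(60, sigma = 0.01, rho = 0, seed = 7)
  fg0 <- fit_group_model(ph0, rep("g", 60), ef_order = 4)
  expect_lt(abs(fg0$cov$rho_x), 0.1)
  expect_lt(abs(fg0$cov$rho_y), 0.1)

  # planted rho = 0.7
  ph1 <- simulate_shape_phenotypes(100, sigma = 0.02, rho = 0.7, seed = 3)
  fg1 <- fit_group_model(ph1, rep("g", 100), ef_order = 4)
  expect_lt(abs(fg1$cov$rho_x - 0.7), 0.1)
  expect_lt(abs(fg1$cov$rho_y - 0.7), 0.1)
  expect_equal(sqrt(fg1$cov$sigma2_x), 0.02, tolerance = 0.25)
  expect_true(fg1$converged)
})

test_that("splitting identical data into two groups leaves the likelihood unchanged", {
  ph <- simulate_shape_phenotypes(30, sigma = 0.02, rho = 0.5, seed = 5)
  ph2 <- structure(list(X = rbind(ph$X, ph$X), Y = rbind(ph$Y, ph$Y),
                        z = rbind(ph$z, ph$z),
                        lines = c(paste0(ph$lines, "a"), paste0(ph$lines, "b")),
                        deme = NULL, K = ph$K), class = "shape_pheno")
  f1 <- fit_group_model(ph2, rep("one", 60), ef_order = 4)
  f2 <- fit_group_model(ph2, rep(c("A", "B"), each = 30), ef_order = 4)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("degenerate zero-residual data errors out", {
  ph <- simulate_shape_phenotypes(20, sigma = 0, rho = 0, seed = 1)
  expect_error(fit_group_model(ph, rep("g", 20), ef_order = 4), "degenerate")
})

test_that("LR test is calibrated near zero under the null and label-symmetric", {
  set.seed(31)
  med <- median(sapply(1:12, function(i) {
    ph <- simulate_shape_phenotypes(60, sigma = 0.02, rho = 0.5, seed = 300 + i)
    g <- sample(rep(c("AA", "GG"), each = 30))
    lr_test(ph, g, ef_order = 4)
  }))
  # extra mean parameters under H1 for J = 2: 4 * order + 2
  expect_lt(med, 2 * (4 * 4 + 2))

  ph <- simulate_shape_phenotypes(40, sigma = 0.02, rho = 0.5, seed = 77)
  g <- rep(c("AA", "GG"), each = 20)
  g2 <- ifelse(g == "AA", "GG", "AA")
  expect_equal(lr_test(ph, g), lr_test(ph, g2), tolerance = 1e-9)

  # single-genotype marker is not testable
  expect_true(is.na(lr_test(ph, rep("AA", 40))))
  expect_match(attr(lr_test(ph, rep("AA", 40)), "reason"), "genotype classes")
})

test_that("planted mean differences are detected with high LR", {
  ph <- simulate_shape_phenotypes(150, sigma = 0.02, rho = 0.5,
                                  group = rep(c("A", "B"), c(75, 75)),
                                  effect = 0.10, seed = 13)
  lr <- lr_test(ph, rep(c("A", "B"), c(75, 75)), ef_order = 4)
  expect_gt(lr, 100)
})

test_that("LR is exactly invariant to quarter-turn rotation of all phenotypes", {
  ph <- simulate_shape_phenotypes(50, sigma = 0.02, rho = 0.5, seed = 21)
  g <- rep(c("A", "B"), 25)
  rot <- structure(list(X = -ph$Y, Y = ph$X, z = cbind(-ph$Y, ph$X),
                        lines = ph$lines, deme = NULL, K = ph$K),
                   class = "shape_pheno")
  expect_equal(lr_test(ph, g), lr_test(rot, g), tolerance = 1e-9)
})

test_that("genome scan handles duplicates, skips and ordering", {
  ph <- simulate_shape_phenotypes(60, sigma = 0.02, rho = 0.5, seed = 41)
  set.seed(42)
  geno <- matrix(rbinom(5 * 60, 2, 0.4), 5, 60,
                 dimnames = list(paste0("M", 1:5), ph$lines))
  geno[3, ] <- geno[1, ]                       # duplicated marker
  geno[4, ] <- 0L                              # monomorphic: skipped
  sc <- genome_scan(ph, geno, ef_order = 4)
  expect_s3_class(sc, "scan_result")
  expect_equal(sc$LR[sc$marker == "M3"], sc$LR[sc$marker == "M1"])
  expect_true(sc$skipped[sc$marker == "M4"])
  expect_match(sc$reason[sc$marker == "M4"], "group-size")
  expect_true(all(sc$LR[!sc$skipped] >= 0))

  geno0 <- matrix(0L, 2, 60, dimnames = list(c("a", "b"), ph$lines))
  expect_error(genome_scan(ph, geno0), "no usable markers")
})

test_that("missing genotypes are dropped per marker", {
  ph <- simulate_shape_phenotypes(60, sigma = 0.02, rho = 0.5, seed = 43)
  g <- rep(c(0, 1), 30)
  g[1:10] <- NA
  lr_all <- lr_test(ph, g)
  sub <- structure(list(X = ph$X[11:60, ], Y = ph$Y[11:60, ],
                        z = ph$z[11:60, ], lines = ph$lines[11:60],
                        deme = NULL, K = ph$K), class = "shape_pheno")
  expect_equal(lr_all, lr_test(sub, g[11:60]), tolerance = 1e-9)
})

test_that("permutation thresholds are deterministic and quantile-monotone", {
  ph <- simulate_shape_phenotypes(50, sigma = 0.02, rho = 0.5, seed = 51)
  set.seed(52)
  geno <- matrix(rbinom(8 * 50, 2, 0.4), 8, 50,
                 dimnames = list(paste0("M", 1:8), ph$lines))
  t1 <- permutation_threshold(ph, geno, n_perm = 50, seed = 9)
  t2 <- permutation_threshold(ph, geno, n_perm = 50, seed = 9)
  expect_identical(as.numeric(t1), as.numeric(t2))

  t01 <- permutation_threshold(ph, geno, n_perm = 50, alpha = 0.01, seed = 9)
  expect_gte(as.numeric(t01), as.numeric(t1))
  tall <- permutation_threshold(ph, geno, n_perm = 50, alpha = 1, seed = 9)
  expect_equal(as.numeric(tall), min(attr(tall, "maxima")))

  expect_error(permutation_threshold(ph, geno, n_perm = 0), "n_perm")
})

test_that("null LR distribution sits below the chi-square envelope", {
  # upper bound sanity envelope: df = 4 * order * (J - 1) + 2
  set.seed(61)
  lrs <- sapply(1:30, function(i) {
    ph <- simulate_shape_phenotypes(60, sigma = 0.02, rho = 0.5, seed = 600 + i)
    lr_test(ph, sample(rep(c("A", "B"), 30)), ef_order = 4)
  })
  df <- 4 * 4 * (2 - 1) + 2
  # loose sanity envelope: covariance re-estimation inflates LR slightly
  expect_lt(quantile(lrs, 0.9), 1.2 * qchisq(0.9, df))
  expect_lt(median(lrs), 1.2 * qchisq(0.5, df))
})

test_that("per-SNP heritability matches the additive closed form", {
  expect_equal(snp_heritability(c(1, 1, 2, 2), c(0, 1, 0, 1)), 0)
  expect_equal(snp_heritability(c(1, 1, 3, 3), c(0, 0, 2, 2)), 1)
  expect_warning(h <- snp_heritability(rep(2, 10), rep(c(0, 1), 5)), "constant")
  expect_equal(h, 0)
  expect_error(snp_heritability(1:5, rep(1, 5)), "two genotype")

  set.seed(5)
  n <- 2000; p <- 0.3; a <- 0.5; sde <- 1
  g <- rbinom(n, 2, p)
  y <- a * g + rnorm(n, 0, sde)
  h2_hat <- snp_heritability(y, g)
  h2_true <- 2 * p * (1 - p) * a^2 / (2 * p * (1 - p) * a^2 + sde^2)
  expect_lt(abs(h2_hat - h2_true), 0.02)
})
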