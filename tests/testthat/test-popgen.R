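test_that("segregation typing follows the genotype-class count", {
  expect_identical(as.character(classify_segregation(c(50, 50, 0))), "testcross")
  expect_identical(as.character(classify_segregation(c(0, 50, 20))), "testcross")
  expect_identical(as.character(classify_segregation(c(30, 50, 20))), "intercross")
  expect_identical(as.character(classify_segregation(c(100, 0, 0))), "monomorphic")
  atyp <- classify_segregation(c(40, 0, 60))
  expect_identical(as.character(atyp), "intercross")
  expect_true(attr(atyp, "atypical"))
})

test_that("exact HWE test matches full enumeration", {
  expect_equal(hwe_exact_pvalue(100, 0, 0), 1)
  expect_equal(hwe_exact_pvalue(2, 0, 2), hwe_enum_oracle(2, 0, 2), tolerance = 1e-12)
  expect_lt(hwe_exact_pvalue(0, 100, 0), 1e-6)

  for (cfg in list(c(5, 3, 2), c(10, 1, 9), c(4, 8, 4), c(1, 1, 1), c(0, 4, 6))) {
    expect_equal(hwe_exact_pvalue(cfg[1], cfg[2], cfg[3]),
                 hwe_enum_oracle(cfg[1], cfg[2], cfg[3]),
                 tolerance = 1e-12)
  }
  p <- hwe_exact_pvalue(30, 45, 25)
  expect_gt(p, 0); expect_lte(p, 1)
})

make_marker_set <- function(geno, depth = NULL) {
  rownames(geno) <- paste0("M", seq_len(nrow(geno)))
  list(geno = geno, depth = depth,
       markers = data.frame(marker = rownames(geno)))
}

test_that("marker filtering applies strict inequalities in rule order", {
  n <- 100
  good <- c(rep(0L, 45), rep(1L, 42), rep(2L, 13))   # HWE-ish, maf .34
  x <- make_marker_set(rbind(good, good, good, good),
                       depth = matrix(20, 4, n))
  x$depth[2, ] <- 12                                  # mean exactly 12: rejected
  x$geno[3, ] <- c(rep(1L, 10), rep(0L, 90))          # maf exactly 0.05: rejected
  x$geno[4, 1:9] <- NA                                # missing 0.09: retained
  fl <- filter_markers(x)
  expect_identical(unname(fl$retained), c(TRUE, FALSE, FALSE, TRUE))
  expect_identical(unname(fl$tally[["depth"]]), 1L)
  expect_identical(unname(fl$tally[["maf"]]), 1L)

  # heterozygote excess over the HWE expectation is filtered, not raw het
  hetex <- c(rep(0L, 3), rep(1L, 14), rep(2L, 3))     # excess 0.2, HWE p 0.18
  ok_int <- c(rep(0L, 6), rep(1L, 10), rep(2L, 4))    # intercross, mild excess
  y <- make_marker_set(rbind(hetex, ok_int), depth = matrix(20, 2, 20))
  fl2 <- filter_markers(y)
  expect_identical(unname(fl2$retained), c(FALSE, TRUE))
  expect_identical(unname(fl2$tally[["het"]]), 1L)

  # order independence: shuffling markers only permutes the outcome
  set.seed(8)
  big <- matrix(rbinom(20 * n, 2, 0.3), 20, n)
  z <- make_marker_set(big, depth = matrix(rpois(20 * n, 20), 20, n))
  fl3 <- filter_markers(z)
  ord <- sample(20)
  z2 <- list(geno = z$geno[ord, ], depth = z$depth[ord, ],
             markers = z$markers[ord, , drop = FALSE])
  fl4 <- filter_markers(z2)
  expect_identical(unname(fl3$retained[ord]), unname(fl4$retained))
})

test_that("Weir-Cockerham theta matches its per-locus oracle and limits", {
  set.seed(17)
  n <- 40
  g <- matrix(rbinom(20 * n, 2, runif(20, 0.2, 0.8)), 20, n)
  demes <- rep(c("a", "b"), each = n / 2)

  # identical deme copies: theta about zero (slightly negative allowed)
  dup <- cbind(g, g)
  th0 <- weir_cockerham_fst(dup, rep(c("a", "b"), each = n))
  expect_lt(as.numeric(th0), 1e-12)

  # opposite fixation: theta = 1
  fx <- cbind(matrix(0L, 10, 20), matrix(2L, 10, 20))
  expect_equal(as.numeric(weir_cockerham_fst(fx, rep(c("a", "b"), each = 20))),
               1, tolerance = 1e-9)

  expect_equal(as.numeric(weir_cockerham_fst(g, demes)),
               wc_theta_oracle(g, demes), tolerance = 1e-10)

  mono <- matrix(0L, 3, n)
  expect_error(weir_cockerham_fst(mono, demes), "monomorphic")
})

test_that("Balding-Nichols divergence is recovered by theta", {
  cfg <- sim_config(n_lines = c(high = 100, low = 100), n_markers = 2000,
                    F = 0.05, seed = 17)
  g <- simulate_genotypes(cfg)
  th <- as.numeric(weir_cockerham_fst(g$geno, unname(g$deme[colnames(g$geno)])))
  expect_lt(abs(th - 0.05), 0.01)

  cfg0 <- sim_config(n_lines = c(high = 100, low = 100), n_markers = 2000,
                     F = 0, seed = 29)
  g0 <- simulate_genotypes(cfg0)
  th0 <- as.numeric(weir_cockerham_fst(g0$geno, unname(g0$deme[colnames(g0$geno)])))
  expect_lt(abs(th0), 0.01)
})

test_that("Nm follows the island-model closed form", {
  expect_equal(nm_from_fst(0.007484551), 33.152, tolerance = 5e-4)
  expect_equal(nm_from_fst(0.25), 0.75)
  expect_equal(nm_from_fst(0.2), 1.0)
  expect_error(nm_from_fst(0), "strictly inside")
  expect_error(nm_from_fst(1), "strictly inside")
})

test_that("deme variance components match method-of-moments closed forms", {
  vc <- deme_variance_components(c(0, 0, 0, 0, 1, 1, 1, 1),
                                 rep(c("lo", "hi"), each = 4))
  expect_equal(vc$sigma2_GW, 0)
  expect_gt(vc$sigma2_GB, 0)

  set.seed(19)
  same <- rnorm(400)
  vc2 <- deme_variance_components(same, rep(c("a", "b"), each = 200))
  se <- sqrt(2 / 200) * var(same)   # rough SE of a variance difference
  expect_lt(vc2$sigma2_GB, 2 * se + 1e-9)

  # balanced planted offsets +-delta with within-variance v
  set.seed(23)
  delta <- 0.5; v <- 1
  y <- c(rnorm(3000, -delta, sqrt(v)), rnorm(3000, delta, sqrt(v)))
  vc3 <- deme_variance_components(y, rep(c("a", "b"), each = 3000))
  expect_equal(vc3$sigma2_GW, v, tolerance = 0.1)
  # two demes at +-delta: the between-deme method-of-moments component
  # estimates n * sum((m_i - m)^2) / n0 / (r - 1) = 2 * delta^2
  expect_equal(vc3$sigma2_GB, 2 * delta^2, tolerance = 0.15)

  expect_error(deme_variance_components(1:3, c("a", "a", "b")), "two lines")
})

test_that("QST follows its closed form and is monotone in the between component", {
  expect_equal(qst(list(sigma2_GB = 0, sigma2_GW = 1)), 0)
  expect_equal(qst(list(sigma2_GB = 1, sigma2_GW = 1)), 1 / 3)
  expect_equal(qst(list(sigma2_GB = 2, sigma2_GW = 0)), 1)
  expect_error(qst(list(sigma2_GB = 0, sigma2_GW = 0)), "undefined")
  q <- sapply(seq(0.1, 2, by = 0.1), function(gb)
    qst(list(sigma2_GB = gb, sigma2_GW = 0.5)))
  expect_true(all(diff(q) > 0))
})

test_that("trait ANOVA uses sequential SS in the stated term order", {
  set.seed(23)
  d <- expand.grid(altitude = c("high", "low"), genotype_i = 1:10,
                   position = c("upper", "middle", "lower"), block = c("B1", "B2"))
  d$genotype <- paste(d$altitude, d$genotype_i)   # nested labels
  d$trait <- 0.5 * (d$altitude == "high") + 0.2 * (d$position == "upper") +
    rnorm(nrow(d), 0, 0.3)

  tab <- shape_anova(d)
  expect_identical(tab$term[1:4], c("altitude", "genotype", "position", "block"))

  # projection-matrix oracle for the sequential sums of squares
  terms_list <- list(~altitude, ~altitude + genotype,
                     ~altitude + genotype + position,
                     ~altitude + genotype + position + block)
  y <- d$trait
  ss_prev <- sum((y - mean(y))^2)
  ss_seq <- numeric(4)
  fitted_prev <- rep(mean(y), nrow(d))
  for (i in seq_along(terms_list)) {
    X <- model.matrix(terms_list[[i]], d)
    fitted <- qr.fitted(qr(X), y)
    ss_seq[i] <- sum((fitted - fitted_prev)^2)
    fitted_prev <- fitted
  }
  expect_equal(tab$sum_sq[1:4], ss_seq, tolerance = 1e-8)

  # pure altitude response: altitude takes all the SS
  d$trait2 <- as.numeric(d$altitude == "high")
  d2 <- d; d2$trait <- d2$trait2
  tab2 <- shape_anova(d2)
  expect_gt(tab2$sum_sq[tab2$term == "altitude"], 0)
  other <- setdiff(tab2$term, c("altitude"))
  expect_lt(sum(tab2$sum_sq[tab2$term %in% other]), 1e-20)

  expect_error(shape_anova(d[d$altitude == "high", ]), "two levels")
})

test_that("ANOVA p-values are uniform under response permutation", {
  set.seed(27)
  d <- expand.grid(altitude = c("high", "low"), genotype_i = 1:6,
                   position = c("upper", "middle", "lower"), block = c("B1", "B2"),
                   rep = 1:2)
  d$genotype <- paste(d$altitude, d$genotype_i)
  base_y <- rnorm(nrow(d))
  pvals <- sapply(1:200, function(i) {
    d$trait <- sample(base_y)
    shape_anova(d)$p[1]
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})
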