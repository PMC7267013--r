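# aligned phenotype set built from explicit landmark matrices
two_group_pheno <- function(base, transform, n_per = 6) {
  mats <- c(replicate(n_per, base, simplify = FALSE),
            replicate(n_per, transform(base), simplify = FALSE))
  pheno_from_matrices(mats)
}

test_that("genotype mean shapes are coordinate-wise means with descriptors", {
  base <- resample_contour(ovate_outline(), 70)$points
  ph <- two_group_pheno(base, identity)
  g <- rep(c("AA", "AG"), each = 6)
  gm <- genotype_mean_shapes(ph, g)
  expect_equal(gm$shapes[["AA"]]$points, gm$shapes[["AG"]]$points)

  # one genotype x-scaled: width ratio matches, lengths equal
  ph2 <- two_group_pheno(base, function(p) cbind(1.1 * p[, 1], p[, 2]))
  gm2 <- genotype_mean_shapes(ph2, g)
  tr <- gm2$traits
  expect_equal(tr$width[tr$genotype == "AG"] / tr$width[tr$genotype == "AA"],
               1.1, tolerance = 1e-6)
  expect_equal(tr$length[tr$genotype == "AG"], tr$length[tr$genotype == "AA"],
               tolerance = 1e-9)

  expect_warning(genotype_mean_shapes(ph, c(rep("AA", 11), "AG")), "omitting")
  expect_error(genotype_mean_shapes(ph, rep("AA", 3)), "call per line")
  expect_error(suppressWarnings(
    genotype_mean_shapes(ph, c(rep(NA, 10), "AA", "AG"))), "minimum size")
})

test_that("pattern rules fire on their constructed signatures", {
  base <- resample_contour(ovate_outline(), 70)$points
  s_ax <- (base[, 2] - min(base[, 2])) / diff(range(base[, 2]))

  ident <- classify_pattern(list(A = outline(base), B = outline(base)))
  expect_identical(ident$class, "NONE")

  widen <- classify_pattern(list(A = outline(base),
                                 B = outline(cbind(1.15 * base[, 1], base[, 2]))))
  expect_identical(widen$class, "WIDTH")   # uniform widening: d_base ~ d_tip

  disp <- base
  disp[s_ax < 1 / 3, 1] <- 1.08 * disp[s_ax < 1 / 3, 1]
  based <- classify_pattern(list(A = outline(base), B = outline(disp)))
  expect_identical(based$class, "BASE")

  tipd <- base
  tipd[s_ax > 2 / 3, 1] <- 1.08 * tipd[s_ax > 2 / 3, 1]
  tip <- classify_pattern(list(A = outline(base), B = outline(tipd)))
  expect_identical(tip$class, "TIP")

  lng <- classify_pattern(list(A = outline(base),
                               B = outline(cbind(0.9 * base[, 1], 1.1 * base[, 2]))))
  expect_identical(lng$class, "LENGTH")

  expect_error(classify_pattern(list(outline(base))), "two genotype")
})

test_that("classification is invariant to pose and genotype labels", {
  base <- resample_contour(ovate_outline(), 70)$points
  wide <- cbind(1.15 * base[, 1], base[, 2])
  phi <- 0.4
  rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  mv <- function(p) sweep(p %*% t(rot), 2, c(2, -1), "-")
  c1 <- classify_pattern(list(A = outline(base), B = outline(wide)))
  c2 <- classify_pattern(list(A = outline(mv(base)), B = outline(mv(wide))))
  c3 <- classify_pattern(list(B = outline(wide), A = outline(base)))
  expect_identical(c1$class, c2$class)
  expect_equal(c1$dW, c2$dW, tolerance = 1e-9)
  expect_identical(c1$class, c3$class)
})

test_that("planted QTL classes are recovered through the full pipeline", {
  run_one <- function(cls, eff, seed) {
    cfg <- sim_config(n_lines = c(high = 75, low = 75), n_markers = 6,
                      leaves_per_line = 6,
                      qtl_specs = list(list(marker = 3, class = cls,
                                            effect = eff, deme = "both",
                                            seg = "intercross")),
                      seed = seed)
    g <- simulate_genotypes(cfg)
    s <- simulate_shapes(g, cfg)
    ph <- phenotypes_from_leaves(s$leaves, 70, deme = g$deme)
    gm <- suppressWarnings(genotype_mean_shapes(ph, g$geno["M0003", ph$lines]))
    classify_pattern(gm, marker = "M0003")
  }
  expect_identical(run_one("WIDTH", 0.10, 9)$class, "WIDTH")
  expect_identical(run_one("LENGTH", 0.12, 9)$class, "LENGTH")
  base_pat <- run_one("BASE", 0.10, 9)
  expect_identical(base_pat$class, "BASE")
  tip_pat <- run_one("TIP", 0.10, 9)
  expect_identical(tip_pat$class, "TIP")
  # the planted locality dominates its region at least three-fold
  expect_gte(tip_pat$d_tip, 3 * tip_pat$d_base)
  expect_gte(base_pat$d_base, 3 * base_pat$d_tip)
})

test_that("percent difference reproduces the published effect-table rows", {
  expect_equal(percent_difference(1.823, 1.598), 14.08)
  expect_equal(percent_difference(1.610, 1.478), 8.93)
  expect_equal(percent_difference(1.633, 1.523), 7.22)
  expect_equal(percent_difference(1.682, 1.611), 4.41)
  expect_equal(percent_difference(2, 2), 0)
  expect_equal(percent_difference(1.2, 1.5), percent_difference(1.5, 1.2))
  expect_error(percent_difference(0, 1), "positive")
  expect_error(percent_difference(1, -2), "positive")
})

test_that("effect table compares genotype means across demes", {
  base <- resample_contour(ovate_outline(), 70)$points
  mats <- replicate(24, base, simplify = FALSE)
  ph <- pheno_from_matrices(mats)
  ph_a <- leafscan:::subset_pheno(ph, 1:12)
  ph_b <- leafscan:::subset_pheno(ph, 13:24)
  geno <- matrix(rep(rep(c(0L, 2L), each = 6), 2), 1, 24,
                 dimnames = list("M1", ph$lines))
  et <- effect_table(ph_a, ph_b, geno, min_group_size = 3)
  expect_true(all(et$diff_area == 0))
  expect_true(all(et$diff_width == 0))

  # genotype class absent in one deme: cells missing, not imputed
  geno2 <- geno
  geno2[1, 13:24] <- 0L
  et2 <- effect_table(ph_a, ph_b, geno2, min_group_size = 3)
  row2 <- et2[et2$genotype == "2", ]
  expect_true(is.na(row2$area_low) && is.na(row2$diff_area))
})

test_that("deme-specific QTL expression is flagged through the simulator", {
  cfg <- sim_config(n_lines = c(high = 60, low = 60), n_markers = 8,
                    leaves_per_line = 4,
                    qtl_specs = list(list(marker = 4, class = "LENGTH",
                                          effect = 0.15, deme = "high_only",
                                          seg = "intercross")),
                    seed = 13)
  g <- simulate_genotypes(cfg)
  s <- simulate_shapes(g, cfg)
  ph <- phenotypes_from_leaves(s$leaves, 70, deme = g$deme)
  ph_h <- leafscan:::subset_pheno(ph, which(ph$deme == "high"))
  ph_l <- leafscan:::subset_pheno(ph, which(ph$deme == "low"))
  lr_h <- lr_test(ph_h, g$geno["M0004", ph_h$lines])
  lr_l <- lr_test(ph_l, g$geno["M0004", ph_l$lines])
  expect_gt(lr_h, 5 * max(lr_l, 1))
  et <- effect_table(ph_h, ph_l, g$geno, markers = "M0004",
                     sig_a = c(M0004 = TRUE), sig_b = c(M0004 = FALSE))
  expect_true(all(et$deme_specific))
})
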