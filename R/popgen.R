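#' Classify the segregation type of a biallelic SNP
#'
#' In a natural outbred population the useful distinction is how many
#' genotype classes segregate, without any ratio constraint: one homozygote
#' plus the heterozygote is a testcross-type marker, two homozygotes plus
#' the heterozygote an intercross-type marker, a single class is
#' monomorphic. Two homozygote classes without heterozygotes are classified
#' intercross and flagged atypical.
#'
#' @param counts genotype counts: named/ordered vector or table
#'   (hom_ref, het, hom_alt) of non-missing calls.
#' @return `"testcross"`, `"intercross"` or `"monomorphic"`; the atypical
#'   no-heterozygote case carries attribute `atypical = TRUE`.
#' @examples
#' classify_segregation(c(50, 50, 0))       # testcross
#' classify_segregation(c(30, 50, 20))      # intercross
#' @export
classify_segregation <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L) stop("expected counts (hom_ref, het, hom_alt)")
  present <- counts > 0
  n_hom <- sum(present[c(1L, 3L)])
  has_het <- present[2L]
  if (sum(present) <= 1L) return("monomorphic")
  if (has_het && n_hom == 2L) return("intercross")
  if (has_het && n_hom == 1L) return("testcross")
  structure("intercross", atypical = TRUE)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test on the observed allele counts: the p-value is the
#' sum of probabilities of all heterozygote counts (same parity, fixed
#' allele counts) whose hypergeometric probability does not exceed that of
#' the observed configuration.
#'
#' @param n_homref,n_het,n_homalt genotype counts (non-negative, total > 0).
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_pvalue <- function(n_homref, n_het, n_homalt) {
  stopifnot(n_homref >= 0, n_het >= 0, n_homalt >= 0)
  n <- n_homref + n_het + n_homalt
  if (n == 0L) stop("no genotype calls")
  n_a <- 2L * n_homref + n_het        # allele-A count
  n_b <- 2L * n_homalt + n_het
  rare <- min(n_a, n_b)
  if (rare == 0L) return(1)           # monomorphic: single outcome
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # log P(het = h | allele counts): multinomial over genotype configurations
  logp <- vapply(hets, function(h) {
    nr <- (rare - h) / 2
    nc <- n - nr - h                  # common-homozygote count
    lgamma(n + 1) - lgamma(nr + 1) - lgamma(h + 1) - lgamma(nc + 1) +
      h * log(2) - (lgamma(2 * n + 1) - lgamma(rare + 1) -
                      lgamma(2 * n - rare + 1))
  }, 1)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[hets == n_het]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

#' SNP quality filter configuration
#'
#' Strict-inequality thresholds for marker retention: site mean sequencing
#' depth greater than `min_depth`, exact Hardy-Weinberg p-value greater
#' than `min_hwe_p`, minor allele frequency greater than `min_maf`, missing
#' fraction less than `max_missing`, and heterozygote excess less than
#' `max_het_excess`. Heterozygosity is filtered as the excess of the
#' observed heterozygote frequency over its Hardy-Weinberg expectation
#' (`het_rule = "excess"`, the default -- a literal observed-heterozygosity
#' cap would contradict retaining intercross markers); `"observed"` applies
#' the literal cap instead. `depth_rule = "per_genotype"` masks individual
#' calls at or below `min_depth` as missing before the other rules, rather
#' than averaging depth over the site.
#'
#' @param min_depth,min_hwe_p,min_maf,max_missing,max_het_excess thresholds.
#' @param het_rule `"excess"` or `"observed"`.
#' @param depth_rule `"site_mean"` or `"per_genotype"`.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_depth = 12, min_hwe_p = 0.05, min_maf = 0.05,
                          max_missing = 0.10, max_het_excess = 0.10,
                          het_rule = c("excess", "observed"),
                          depth_rule = c("site_mean", "per_genotype")) {
  structure(list(min_depth = min_depth, min_hwe_p = min_hwe_p,
                 min_maf = min_maf, max_missing = max_missing,
                 max_het_excess = max_het_excess,
                 het_rule = match.arg(het_rule),
                 depth_rule = match.arg(depth_rule)),
            class = "filter_config")
}

#' Filter SNP markers on depth, HWE, MAF, missingness and heterozygosity
#'
#' Applies the [filter_config()] rules to a marker set (strict inequalities
#' throughout) and tallies the first failing rule per rejected marker, in
#' the order depth, hwe, maf, missing, het.
#'
#' @param x a genotype data set as returned by [read_vcf()] or
#'   [simulate_genotypes()]: list with `geno` (markers x lines dose matrix,
#'   NA = missing), optional `depth` matrix, `markers` data frame.
#' @param config a [filter_config()].
#' @return List: `retained` (logical per marker), `data` (the input
#'   restricted to retained markers), `tally` (named counts of first
#'   failing rule), `stats` (per-marker depth/maf/missing/het table).
#' @export
filter_markers <- function(x, config = filter_config()) {
  geno <- x$geno
  depth <- x$depth
  m <- nrow(geno)
  if (!is.null(depth) && config$depth_rule == "per_genotype") {
    geno[!is.na(depth) & depth <= config$min_depth] <- NA
  }
  n_called <- rowSums(!is.na(geno))
  missing_frac <- 1 - n_called / ncol(geno)
  n_het <- rowSums(geno == 1L, na.rm = TRUE)
  n_alt <- rowSums(geno == 2L, na.rm = TRUE)
  n_ref <- n_called - n_het - n_alt
  p_alt <- ifelse(n_called > 0, (2 * n_alt + n_het) / (2 * n_called), NA)
  maf <- pmin(p_alt, 1 - p_alt)
  hwe_p <- vapply(seq_len(m), function(i) {
    if (n_called[i] == 0L) return(0)
    hwe_exact_pvalue(n_ref[i], n_het[i], n_alt[i])
  }, 1)
  het_obs <- ifelse(n_called > 0, n_het / n_called, NA)
  het_exp <- 2 * p_alt * (1 - p_alt)
  het_stat <- if (config$het_rule == "excess") het_obs - het_exp else het_obs
  if (is.null(depth) && config$min_depth > 0)
    warning("no depth information: the depth rule is not applied")
  mean_depth <- if (is.null(depth)) rep(Inf, m) else
    rowMeans(depth, na.rm = TRUE)
  pass_depth <- mean_depth > config$min_depth
  pass_hwe <- hwe_p > config$min_hwe_p
  pass_maf <- !is.na(maf) & maf > config$min_maf
  pass_missing <- missing_frac < config$max_missing
  pass_het <- !is.na(het_stat) & het_stat < config$max_het_excess
  first_fail <- rep(NA_character_, m)
  first_fail[!pass_het] <- "het"
  first_fail[!pass_missing] <- "missing"
  first_fail[!pass_maf] <- "maf"
  first_fail[!pass_hwe] <- "hwe"
  first_fail[!pass_depth] <- "depth"
  retained <- is.na(first_fail)
  tally <- table(factor(first_fail,
                        levels = c("depth", "hwe", "maf", "missing", "het")))
  data <- x
  data$geno <- geno[retained, , drop = FALSE]
  if (!is.null(depth)) data$depth <- depth[retained, , drop = FALSE]
  if (!is.null(x$markers)) data$markers <- x$markers[retained, , drop = FALSE]
  list(retained = retained, data = data, tally = tally,
       stats = data.frame(mean_depth = mean_depth, hwe_p = hwe_p, maf = maf,
                          missing = missing_frac, het_stat = het_stat))
}

#' Multi-locus Weir-Cockerham FST
#'
#' Weir & Cockerham (1984) theta for diploid genotype data, combining loci
#' by ratio of averages (sum of per-locus numerators over sum of per-locus
#' denominators). Monomorphic loci are skipped.
#'
#' @param geno genotype dose matrix (markers x lines, 0/1/2, NA allowed).
#' @param demes deme label per line (>= 2 demes).
#' @return Multi-locus theta (scalar); per-locus components attached as
#'   attribute `"components"` (columns a, b, c).
#' @export
weir_cockerham_fst <- function(geno, demes) {
  geno <- as.matrix(geno)
  demes <- factor(demes)
  r <- nlevels(demes)
  if (r < 2L) stop("need at least two demes")
  if (ncol(geno) != length(demes))
    stop("`demes` must label every genotype column")
  idx <- split(seq_along(demes), demes)
  # per-deme sample size, allele frequency and observed het per locus
  ni <- sapply(idx, function(j) rowSums(!is.na(geno[, j, drop = FALSE])))
  pi <- sapply(idx, function(j)
    rowSums(geno[, j, drop = FALSE], na.rm = TRUE) / (2 * rowSums(!is.na(geno[, j, drop = FALSE]))))
  hi <- sapply(idx, function(j)
    rowSums(geno[, j, drop = FALSE] == 1L, na.rm = TRUE) / rowSums(!is.na(geno[, j, drop = FALSE])))
  ni <- matrix(ni, ncol = r); pi <- matrix(pi, ncol = r); hi <- matrix(hi, ncol = r)
  nbar <- rowMeans(ni)
  nc <- (rowSums(ni) - rowSums(ni^2) / rowSums(ni)) / (r - 1)
  pbar <- rowSums(ni * pi) / rowSums(ni)
  s2 <- rowSums(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(ni * hi) / rowSums(ni)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  poly <- is.finite(a) & is.finite(b) & is.finite(cc) &
    pbar > 0 & pbar < 1
  if (!any(poly)) stop("FST undefined: all loci monomorphic")
  theta <- sum(a[poly]) / sum(a[poly] + b[poly] + cc[poly])
  structure(theta, components = cbind(a = a, b = b, c = cc)[poly, , drop = FALSE])
}

#' Effective number of migrants from FST
#'
#' Island-model relation `Nm = (1 - Fst) / (4 Fst)`.
#'
#' @param fst fixation index, strictly inside (0, 1).
#' @return Nm (scalar).
#' @examples
#' nm_from_fst(0.25)  # 0.75
#' @export
nm_from_fst <- function(fst) {
  if (!is.numeric(fst) || length(fst) != 1L || !is.finite(fst) ||
      fst <= 0 || fst >= 1)
    stop("`fst` must lie strictly inside (0, 1)")
  (1 - fst) / (4 * fst)
}

#' Between- and within-deme variance components of a line trait
#'
#' One-way ANOVA method of moments: within-deme genetic variance is the
#' within-group mean square, between-deme variance is
#' `(MS_between - MS_within) / n0` with `n0` the standard effective group
#' size for unbalanced designs; a negative between component is truncated
#' to zero with a warning.
#'
#' @param trait numeric trait value per line.
#' @param demes deme label per line (>= 2 demes, >= 2 lines each).
#' @return List with `sigma2_GB`, `sigma2_GW`, `n0` and the ANOVA mean
#'   squares.
#' @export
deme_variance_components <- function(trait, demes) {
  ok <- !is.na(trait) & !is.na(demes)
  trait <- trait[ok]; demes <- factor(demes[ok])
  r <- nlevels(demes)
  if (r < 2L) stop("need at least two demes")
  ni <- as.numeric(table(demes))
  if (any(ni < 2L)) stop("every deme needs at least two lines")
  n <- sum(ni)
  gm <- mean(trait)
  mi <- tapply(trait, demes, mean)
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum((trait - mi[demes])^2)
  msb <- ssb / (r - 1)
  msw <- ssw / (n - r)
  n0 <- (n - sum(ni^2) / n) / (r - 1)
  gb <- (msb - msw) / n0
  if (gb < 0) {
    warning("negative between-deme component truncated to 0")
    gb <- 0
  }
  list(sigma2_GB = gb, sigma2_GW = msw, n0 = n0,
       MS_between = msb, MS_within = msw)
}

#' QST from deme variance components
#'
#' `QST = sigma2_GB / (sigma2_GB + 2 sigma2_GW)` for clonally replicated
#' lines, the quantitative-trait analog of FST.
#'
#' @param components list with `sigma2_GB` and `sigma2_GW` (see
#'   [deme_variance_components()]).
#' @return QST in `[0, 1]`.
#' @export
qst <- function(components) {
  gb <- components$sigma2_GB
  gw <- components$sigma2_GW
  if (gb < 0 || gw < 0) stop("variance components must be non-negative")
  if (gb == 0 && gw == 0) stop("QST undefined: both variance components are zero")
  gb / (gb + 2 * gw)
}

#' Fixed-effects ANOVA of a scalar leaf trait
#'
#' Sequential (type-I) least-squares ANOVA of a per-leaf trait on altitude,
#' genotype nested within altitude, crown position, block, genotype-by-
#' position and altitude-by-position, in that order, with F statistics
#' against the residual mean square. Genotype (line) labels are expected to
#' be unique across altitudes, which encodes the nesting.
#'
#' @param data data frame with columns `trait`, `altitude`, `genotype`,
#'   `position`, `block`.
#' @return Data frame: term, df, sum_sq, mean_sq, F, p.
#' @export
shape_anova <- function(data) {
  need <- c("trait", "altitude", "genotype", "position", "block")
  if (!all(need %in% names(data)))
    stop("`data` needs columns: ", paste(need, collapse = ", "))
  d <- data
  for (v in need[-1L]) d[[v]] <- factor(d[[v]])
  for (v in c("altitude", "position")) {
    if (nlevels(d[[v]]) < 2L)
      stop(sprintf("factor `%s` needs at least two levels", v))
  }
  fit <- stats::aov(trait ~ altitude + genotype + position + block +
                      genotype:position + altitude:position, data = d)
  tab <- summary(fit)[[1L]]
  nm <- trimws(rownames(tab))
  if (!"Residuals" %in% nm || tab[nm == "Residuals", "Df"] <= 0)
    stop("no residual degrees of freedom")
  data.frame(term = nm, df = tab$Df, sum_sq = tab$`Sum Sq`,
             mean_sq = tab$`Mean Sq`, F = tab$`F value`,
             p = tab$`Pr(>F)`, row.names = NULL)
}
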