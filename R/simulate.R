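# Deterministic per-stage seeds derived from the single run seed, so every
# stage draws from its own named stream.
stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Default ovate leaf contour
#'
#' A smooth ovate blade with its broadest chord about 30% of the axis
#' length from the blade base (the typical broadest-region band for poplar
#' leaves), base at the bottom, first margin point at the base. The default
#' shape is an elongated ovate (axis length 3, width 1), the slender
#' ovate-lanceolate form typical of plateau poplars; absolute size is
#' removed later by Procrustes alignment, so only ratios of the landmark
#' noise sd to these dimensions matter. The half-width profile is
#' `(1 - y)^p (1 + y)^q` with exponents chosen so the maximum sits at the
#' requested axial fraction.
#'
#' @param n_points number of margin points (equal-angle about the centroid).
#' @param length blade axis length.
#' @param width maximum blade width.
#' @param broadest axial position of the widest chord, fraction from base.
#' @return An [outline].
#' @export
ovate_outline <- function(n_points = 200L, length = 3.0, width = 1.0,
                          broadest = 0.30) {
  ystar <- 2 * broadest - 1
  p <- 1 - ystar; q <- 1 + ystar
  t <- seq(0, 2 * pi, length.out = 2001L)[-2001L]
  y <- -cos(t)
  prof <- function(y) (1 - y)^p * (1 + y)^q
  sc <- (width / 2) / prof(ystar)
  x <- ifelse(t <= pi, 1, -1) * sc * prof(pmin(pmax(y, -1), 1))
  y <- y * length / 2
  # equal-angle margin points, landmark 0 on the blade-base ray
  resample_contour(outline(cbind(x, y)), n_points)
}

#' Synthetic-study configuration
#'
#' Defines a complete simulated mapping study: a two-deme clonal
#' population with Balding-Nichols SNP divergence and leaf outlines built
#' from a base elliptic Fourier shape plus planted QTL effects, deme and
#' heterophylly (crown position) effects, and AR(1)-correlated landmark
#' noise. Defaults emulate the field design this package targets: 119
#' high- and 141 low-altitude clonal lines, six leaves per line (two per
#' crown section) in two nursery blocks, 70 landmarks, order-4 elliptic
#' Fourier base shape, divergence F = 0.0075, landmark noise sd 0.02 with
#' lag-1 autocorrelation 0.5, and a 3% deme width offset (high-altitude
#' leaves slender).
#'
#' @param n_lines named vector `c(high = ..., low = ...)` of lines per deme.
#' @param leaves_per_line leaves sampled per clonal line (spread over crown
#'   positions and blocks).
#' @param n_points dense margin points per simulated leaf.
#' @param K landmark count used when phenotypes are built.
#' @param ef_order harmonic order of the base shape.
#' @param base_shape base leaf [outline] (default [ovate_outline()]).
#' @param qtl_specs list of planted QTLs, each a list with `marker`
#'   (index), `class` (`"LENGTH"`, `"WIDTH"`, `"TIP"`, `"BASE"`), `effect`
#'   (fractional descriptor change between extreme genotypes), `deme`
#'   (`"both"`, `"high_only"`, `"low_only"`), `seg` (`"testcross"` or
#'   `"intercross"`).
#' @param n_markers,maf_range,F genotype panel size, ancestral minor-allele
#'   frequency range, Balding-Nichols divergence in `[0, 1)`.
#' @param noise_sd,noise_rho AR(1) landmark noise parameters.
#' @param deme_width_offset fractional deme width divergence.
#' @param position_width_effect,block_width_effect nuisance width factors.
#' @param mean_depth mean simulated sequencing depth (Poisson).
#' @param seed single integer seed; all stage streams derive from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_lines = c(high = 119L, low = 141L),
                       leaves_per_line = 6L, n_points = 200L, K = 70L,
                       ef_order = 4L, base_shape = NULL, qtl_specs = list(),
                       n_markers = 200L, maf_range = c(0.1, 0.5),
                       F = 0.0075, noise_sd = 0.02, noise_rho = 0.7,
                       deme_width_offset = 0.03,
                       position_width_effect = 0.03,
                       block_width_effect = 0.005,
                       mean_depth = 20, seed = 1L) {
  stopifnot(F >= 0, F < 1, n_markers >= 1,
            maf_range[1L] > 0, maf_range[2L] <= 0.5,
            noise_sd >= 0, abs(noise_rho) < 1)
  for (q in qtl_specs) {
    stopifnot(is.list(q), q$marker >= 1, q$marker <= n_markers,
              q$effect >= 0)
    if (!q$class %in% c("LENGTH", "WIDTH", "TIP", "BASE"))
      stop("unknown QTL pattern class: ", q$class)
  }
  if (is.null(base_shape)) base_shape <- ovate_outline(n_points)
  structure(list(n_lines = n_lines, leaves_per_line = as.integer(leaves_per_line),
                 n_points = as.integer(n_points), K = as.integer(K),
                 ef_order = as.integer(ef_order), base_shape = base_shape,
                 qtl_specs = qtl_specs, n_markers = as.integer(n_markers),
                 maf_range = maf_range, F = F, noise_sd = noise_sd,
                 noise_rho = noise_rho, deme_width_offset = deme_width_offset,
                 position_width_effect = position_width_effect,
                 block_width_effect = block_width_effect,
                 mean_depth = mean_depth, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a two-deme SNP panel under Balding-Nichols divergence
#'
#' Ancestral allele frequencies are drawn uniformly over the configured
#' range; per-deme frequencies follow the Balding-Nichols Beta distribution
#' with divergence parameter F (F = 0 gives identical frequencies);
#' genotypes are drawn under within-deme Hardy-Weinberg. Planted QTL
#' markers are forced to the segregation class their spec requires and
#' flagged non-neutral; all other markers carry a neutrality class
#' (intergenic, intron or synonymous, in proportions typical of a
#' resequencing panel).
#'
#' @param config a [sim_config()].
#' @return List: `geno` (markers x lines dose matrix), `depth` (simulated
#'   read depths), `markers` (marker, chrom, pos, seg_type, neutrality,
#'   annotation), `lines`, `deme` (named by line), `truth` (planted QTL
#'   table, F, seed).
#' @export
simulate_genotypes <- function(config) {
  set.seed(stream_seed(config$seed, "genotypes"))
  m <- config$n_markers
  nh <- config$n_lines[[1L]]; nl <- config$n_lines[[2L]]
  n <- nh + nl
  lines <- sprintf("L%03d", seq_len(n))
  deme <- stats::setNames(rep(c("high", "low"), c(nh, nl)), lines)
  p_anc <- stats::runif(m, config$maf_range[1L], config$maf_range[2L])
  bn_draw <- function(p) {
    if (config$F == 0) return(p)
    a <- p * (1 - config$F) / config$F
    b <- (1 - p) * (1 - config$F) / config$F
    stats::rbeta(length(p), a, b)
  }
  p_h <- bn_draw(p_anc); p_l <- bn_draw(p_anc)
  geno <- matrix(NA_integer_, m, n, dimnames = list(sprintf("M%04d", seq_len(m)), lines))
  geno[, seq_len(nh)] <- stats::rbinom(m * nh, 2L, rep(p_h, nh))
  geno[, nh + seq_len(nl)] <- stats::rbinom(m * nl, 2L, rep(p_l, nl))
  qtl_idx <- vapply(config$qtl_specs, function(q) as.integer(q$marker), 1L)
  for (q in config$qtl_specs) {
    i <- as.integer(q$marker)
    seg <- q$seg %||% "intercross"
    if (seg == "testcross") {
      f <- stats::runif(1L, 0.4, 0.6)
      geno[i, ] <- stats::rbinom(n, 1L, f)          # hom-ref vs het only
    } else {
      f <- stats::runif(1L, 0.35, 0.5)
      geno[i, ] <- stats::rbinom(n, 2L, f)
      # guarantee all three classes at reasonable n
      if (length(unique(geno[i, ])) < 3L)
        geno[i, sample.int(n, 3L)] <- c(0L, 1L, 2L)
    }
  }
  depth <- matrix(stats::rpois(m * n, config$mean_depth), m, n,
                  dimnames = dimnames(geno))
  seg_type <- apply(geno, 1L, function(g)
    as.character(classify_segregation(table(factor(g, levels = 0:2)))))
  neutrality <- sample(c("intergenic", "intron", "synonymous"), m,
                       replace = TRUE, prob = c(53063, 15575, 229))
  annotation <- rep(NA_character_, m)
  if (length(qtl_idx)) {
    neutrality[qtl_idx] <- "non-neutral"
    annotation[qtl_idx] <- sprintf("GENE_%s", rownames(geno)[qtl_idx])
  }
  chrom <- rep_len(seq_len(19L), m)
  pos <- 10000L + 1000L * (seq_len(m) %/% 19L + 1L) + seq_len(m)
  markers <- data.frame(marker = rownames(geno), chrom = chrom, pos = pos,
                        ref = "A", alt = "G", seg_type = seg_type,
                        neutrality = neutrality, annotation = annotation,
                        stringsAsFactors = FALSE)
  truth <- list(
    qtls = if (length(config$qtl_specs))
      data.frame(marker = rownames(geno)[qtl_idx],
                 class = vapply(config$qtl_specs, `[[`, "", "class"),
                 effect = vapply(config$qtl_specs, `[[`, 1, "effect"),
                 deme = vapply(config$qtl_specs, function(q) q$deme %||% "both", ""))
    else data.frame(marker = character(), class = character(),
                    effect = numeric(), deme = character()),
    F = config$F, seed = config$seed)
  list(geno = geno, depth = depth, markers = markers, lines = lines,
       deme = deme, truth = truth)
}

# Stationary AR(1) noise sequence of length k.
ar1_noise <- function(k, sd, rho) {
  if (sd == 0) return(numeric(k))
  e <- numeric(k)
  e[1L] <- stats::rnorm(1L, 0, sd)
  if (k > 1L) {
    innov <- stats::rnorm(k - 1L, 0, sd * sqrt(1 - rho^2))
    for (i in 2:k) e[i] <- rho * e[i - 1L] + innov[i - 1L]
  }
  e
}

# AR(1) noise generated at `k_knots` points around the margin and linearly
# interpolated (with wrap-around) to `n` margin points, so the noise lives
# at the landmark scale while the emitted margin stays locally smooth.
ar1_margin_noise <- function(n, k_knots, sd, rho) {
  if (sd == 0) return(numeric(n))
  e <- ar1_noise(k_knots, sd, rho)
  u <- (seq_len(n) - 1L) / n * k_knots       # knot coordinate in [0, k)
  i0 <- floor(u)
  w <- u - i0
  (1 - w) * e[(i0 %% k_knots) + 1L] + w * e[((i0 + 1L) %% k_knots) + 1L]
}

# Cheap star-shape validity check: polar angle about the centroid must be
# strictly monotone along the margin, with a small safety margin so that
# downstream equal-angle ray resampling is robust at any landmark count.
is_star_shaped <- function(pts, margin_frac = 0.02) {
  ctr <- polygon_centroid(pts)
  th <- atan2(pts[, 2L] - ctr[2L], pts[, 1L] - ctr[1L])
  d <- diff(c(th, th[1L]))
  d <- (d + pi) %% (2 * pi) - pi
  eps <- margin_frac * 2 * pi / nrow(pts)
  all(d < -eps) || all(d > eps)
}

#' Simulate leaf outlines for a genotyped population
#'
#' Builds each line's mean contour from the base elliptic Fourier shape
#' plus the deme width offset and the genotype-dosed planted QTL effects
#' (LENGTH and WIDTH act on the harmonic coefficients; TIP and BASE add
#' localized displacement fields confined to the apical/basal axial third,
#' applied in landmark space so the planted locality is exact), then adds
#' per-leaf crown-position and block effects, stationary AR(1) landmark
#' noise (independent x and y streams) and a random similarity jitter
#' (removed later by Procrustes alignment). Rare leaves that violate the
#' star-shape precondition are redrawn and counted.
#'
#' @param genos result of [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return List: `leaves` (list of [outline]s with ids/positions/blocks),
#'   `line_means` (noise-free line mean outlines), `lines` (metadata frame),
#'   `truth`, `n_redrawn`.
#' @export
simulate_shapes <- function(genos, config) {
  set.seed(stream_seed(config$seed, "shapes"))
  base_desc <- efd_decompose(config$base_shape, config$ef_order)
  qtl_specs <- config$qtl_specs
  for (q in qtl_specs) {
    if (!rownames(genos$geno)[as.integer(q$marker)] %in% rownames(genos$geno))
      stop("QTL marker index outside the genotype matrix")
  }
  n_pts <- config$n_points
  positions <- rep_len(rep(c("upper", "middle", "lower"),
                           each = max(1L, config$leaves_per_line %/% 3L)),
                       config$leaves_per_line)
  pos_fac <- c(upper = -1, middle = 0, lower = 1) * config$position_width_effect
  blocks <- rep_len(c("B1", "B2"), config$leaves_per_line)
  blk_fac <- c(B1 = -1, B2 = 1) * config$block_width_effect
  leaves <- list()
  line_means <- list()
  n_redrawn <- 0L
  for (li in seq_along(genos$lines)) {
    id <- genos$lines[li]
    dm <- genos$deme[[id]]
    wf <- 1 + (if (dm == "low") config$deme_width_offset / 2 else
      -config$deme_width_offset / 2)
    lf <- 1
    local_amp <- list(TIP = 0, BASE = 0, WIDTH = 0)
    for (q in qtl_specs) {
      expr_deme <- q$deme %||% "both"
      if (expr_deme == "high_only" && dm != "high") next
      if (expr_deme == "low_only" && dm != "low") next
      dose <- genos$geno[as.integer(q$marker), id] / 2
      if (is.na(dose)) dose <- 0
      if (q$class == "LENGTH") {
        # long-narrow vs short-broad: the axis stretches while the blade
        # narrows by the same fraction
        lf <- lf * (1 + q$effect * dose)
        wf <- wf * (1 - q$effect * dose)
      } else if (q$class == "WIDTH") {
        # narrow vs broad: mid-blade widening; 1.19 calibrates the bulge
        # amplitude so the measured maximum-width change equals the effect
        local_amp$WIDTH <- local_amp$WIDTH + 1.19 * q$effect * dose
      } else local_amp[[q$class]] <- local_amp[[q$class]] + q$effect * dose
    }
    desc <- base_desc
    desc$dc <- desc$dc * c(wf, lf)
    desc$coeffs[, c("a", "b")] <- desc$coeffs[, c("a", "b")] * wf
    desc$coeffs[, c("c", "d")] <- desc$coeffs[, c("c", "d")] * lf
    mpts <- as_outline_points(efd_reconstruct(desc, n_pts))
    if (local_amp$TIP != 0 || local_amp$BASE != 0 || local_amp$WIDTH != 0) {
      s <- (mpts[, 2L] - min(mpts[, 2L])) /
        max(1e-12, diff(range(mpts[, 2L])))
      # raised-cosine margin bulges: TIP widens the middle-upper section,
      # BASE the basal section, WIDTH the blade body (all regions where
      # the blade has width, so the planted signal shows in the margin)
      bump <- function(s, centre, half) {
        w <- numeric(length(s))
        in_w <- abs(s - centre) < half
        w[in_w] <- 0.5 * (1 + cos(pi * (s[in_w] - centre) / half))
        w
      }
      mpts[, 1L] <- mpts[, 1L] *
        (1 + local_amp$TIP * bump(s, 0.78, 0.18) +
           local_amp$BASE * bump(s, 0.22, 0.18) +
           local_amp$WIDTH * bump(s, 0.40, 0.30))
    }
    line_means[[id]] <- outline(mpts, id = paste0("mean_", id), line_id = id)
    for (lf_i in seq_len(config$leaves_per_line)) {
      pos <- positions[lf_i]; blk <- blocks[lf_i]
      pts <- mpts
      pts[, 1L] <- pts[, 1L] * (1 + pos_fac[[pos]] + blk_fac[[blk]])
      for (try in seq_len(30L)) {
        # after many rejections, damp the noise rather than loop forever
        damp <- if (try <= 10L) 1 else 0.7^((try - 1L) %/% 10L)
        noisy <- pts
        noisy[, 1L] <- noisy[, 1L] +
          ar1_margin_noise(n_pts, config$K, damp * config$noise_sd,
                           config$noise_rho)
        noisy[, 2L] <- noisy[, 2L] +
          ar1_margin_noise(n_pts, config$K, damp * config$noise_sd,
                           config$noise_rho)
        if (config$noise_sd == 0 || is_star_shaped(noisy)) break
        n_redrawn <- n_redrawn + 1L
      }
      th <- stats::runif(1L, -0.2, 0.2)
      sc <- stats::runif(1L, 0.9, 1.1)
      tr <- stats::runif(2L, -0.2, 0.2)
      rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
      noisy <- sweep(sc * noisy %*% t(rot), 2L, -tr)
      leaves[[length(leaves) + 1L]] <-
        outline(noisy, id = sprintf("%s_leaf%d", id, lf_i), line_id = id,
                position = pos, block = blk)
    }
  }
  list(leaves = leaves, line_means = line_means,
       lines = data.frame(line_id = genos$lines,
                          deme = unname(genos$deme[genos$lines]),
                          n_leaves = config$leaves_per_line,
                          stringsAsFactors = FALSE),
       truth = genos$truth, n_redrawn = n_redrawn)
}

#' Simulate landmark phenotypes directly under the scan's likelihood model
#'
#' Draws per-line landmark coordinate vectors as an elliptic Fourier mean
#' curve (the projection of the base shape onto the truncated Fourier
#' basis at `K` landmarks) plus stationary AR(1) noise per coordinate
#' block. Because the mean lies exactly in the fitted model's span and the
#' noise follows the fitted covariance family, this generator is the right
#' instrument for likelihood calibration and parameter-recovery checks;
#' phenotypes derived from full outline geometry additionally carry
#' mean-model lack-of-fit, which inflates the apparent residual variance
#' and autocorrelation (see the methods vignette).
#'
#' @param n number of lines.
#' @param K landmark count.
#' @param ef_order harmonic order of the mean curve.
#' @param sigma,rho AR(1) landmark noise sd and lag-1 autocorrelation
#'   (shared by the x and y blocks; independent streams).
#' @param base_shape base [outline] providing the mean curve.
#' @param group optional group label per line; `effect` then scales the
#'   x-coordinates of groups beyond the first multiplicatively.
#' @param effect fractional x-scale difference between the first and last
#'   group (dosed linearly across ordered group levels).
#' @param seed RNG seed.
#' @return A `shape_pheno`.
#' @export
simulate_shape_phenotypes <- function(n, K = 70L, ef_order = 4L,
                                      sigma = 0.02, rho = 0.5,
                                      base_shape = NULL, group = NULL,
                                      effect = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(base_shape)) base_shape <- ovate_outline(max(200L, 3L * K))
  pts <- as_outline_points(resample_contour(base_shape, K))
  pts <- sweep(pts, 2L, colMeans(pts))
  pts <- pts / sqrt(mean(rowSums(pts^2)))
  H <- ef_hat_matrix(K, ef_order)
  mx <- as.numeric(H %*% pts[, 1L])
  my <- as.numeric(H %*% pts[, 2L])
  if (!is.null(group)) {
    g <- factor(group)
    dose <- (as.integer(g) - 1L) / max(1L, nlevels(g) - 1L)
  } else dose <- rep(0, n)
  X <- matrix(NA_real_, n, K)
  Y <- matrix(NA_real_, n, K)
  for (i in seq_len(n)) {
    X[i, ] <- mx * (1 + effect * dose[i]) + ar1_noise(K, sigma, rho)
    Y[i, ] <- my + ar1_noise(K, sigma, rho)
  }
  ids <- sprintf("L%03d", seq_len(n))
  rownames(X) <- rownames(Y) <- ids
  structure(list(X = X, Y = Y, z = cbind(X, Y), lines = ids,
                 deme = NULL, K = as.integer(K)),
            class = "shape_pheno")
}

#' Generate and write a complete synthetic study bundle
#'
#' Runs [simulate_genotypes()] and [simulate_shapes()] and writes the
#' standard input files of the analysis pipeline: `genotypes.vcf` (GT and
#' DP fields), `landmarks.csv` (the landmark CSV dialect), `lines.tsv`
#' (line metadata) and `truth.json` (planted QTLs, effect sizes, F, seed).
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with the four file `paths` plus the in-memory
#'   `genotypes` and `shapes` objects.
#' @export
generate_dataset <- function(config, dir) {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create output directory: ", dir)
  genos <- simulate_genotypes(config)
  shapes <- simulate_shapes(genos, config)
  paths <- list(vcf = file.path(dir, "genotypes.vcf"),
                landmarks = file.path(dir, "landmarks.csv"),
                lines = file.path(dir, "lines.tsv"),
                truth = file.path(dir, "truth.json"))
  write_vcf_file(genos, paths$vcf)
  write_landmark_csv(shapes$leaves, paths$landmarks,
                     deme = genos$deme)
  utils::write.table(shapes$lines, paths$lines, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(qtls = shapes$truth$qtls, F = shapes$truth$F,
         seed = shapes$truth$seed, n_redrawn = shapes$n_redrawn),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, genotypes = genos, shapes = shapes))
}
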