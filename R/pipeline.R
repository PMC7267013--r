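#' Build per-line shape phenotypes from raw leaf outlines
#'
#' The standard phenotyping path: every leaf margin is resampled at `k`
#' equal-angle landmarks, all leaves are Procrustes-aligned in one pooled
#' set (so demes share a frame), leaves are averaged per clonal line, and
#' the per-line averages are aligned again. Returns the stacked phenotype
#' container used by the scan.
#'
#' @param leaves list of [outline]s (raw margins), `line_id` fields set.
#' @param k landmark count.
#' @param deme optional named deme label per line id.
#' @return A `shape_pheno` (see [shape_phenotypes()]); the aligned per-line
#'   average outlines are attached as attribute `"avg_shapes"`.
#' @export
phenotypes_from_leaves <- function(leaves, k, deme = NULL) {
  res <- lapply(leaves, resample_contour, k = k)
  al <- procrustes_align(res)
  line_ids <- vapply(al$shapes, function(o) o$line_id, "")
  avgs <- lapply(split(al$shapes, line_ids), average_shape)
  avgs <- lapply(names(avgs), function(id) {
    o <- avgs[[id]]; o$line_id <- id; o
  })
  al2 <- procrustes_align(avgs)
  ph <- shape_phenotypes(al2$shapes, deme = deme)
  attr(ph, "avg_shapes") <- al2$shapes
  ph
}

subset_pheno <- function(ph, idx) {
  structure(list(X = ph$X[idx, , drop = FALSE], Y = ph$Y[idx, , drop = FALSE],
                 z = ph$z[idx, , drop = FALSE], lines = ph$lines[idx],
                 deme = ph$deme[idx], K = ph$K),
            class = "shape_pheno")
}

pheno_traits <- function(ph) {
  td <- apply(ph$z, 1L, function(z) {
    k <- length(z) / 2
    unlist(trait_descriptors(cbind(z[seq_len(k)], z[k + seq_len(k)]))[
      c("length", "width", "area")])
  })
  data.frame(line_id = ph$lines, t(td), stringsAsFactors = FALSE)
}

#' Pipeline run configuration
#'
#' @param vcf,landmarks,lines input paths: genotype VCF, landmark CSV and
#'   (optional) line metadata TSV with columns `line_id`, `deme`.
#' @param out_dir output directory.
#' @param ef_order harmonic order; `NULL` selects it from the explained-
#'   variance profile at `order_threshold`.
#' @param landmark_candidates candidate landmark counts for AIC selection;
#'   a single value skips selection.
#' @param max_order largest order considered during selection.
#' @param order_threshold explained-variance threshold for order selection.
#' @param n_perm,alpha permutation-threshold settings.
#' @param filter a [filter_config()].
#' @param tau_rel,tau_ratio pattern-classification thresholds.
#' @param min_group_size minimum lines per genotype class.
#' @param seed integer seed controlling every stochastic stage.
#' @return A `run_config` list.
#' @export
run_config <- function(vcf, landmarks, lines = NULL, out_dir = "leafscan_out",
                       ef_order = NULL, landmark_candidates = c(30L, 50L, 70L, 90L),
                       max_order = 6L, order_threshold = 0.95,
                       n_perm = 1000L, alpha = 0.05,
                       filter = filter_config(), tau_rel = 0.045,
                       tau_ratio = 3.0, min_group_size = 5L, seed = 1L) {
  for (p in c(vcf, landmarks, lines))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  structure(list(vcf = vcf, landmarks = landmarks, lines = lines,
                 out_dir = out_dir, ef_order = ef_order,
                 landmark_candidates = as.integer(landmark_candidates),
                 max_order = as.integer(max_order),
                 order_threshold = order_threshold,
                 n_perm = as.integer(n_perm), alpha = alpha, filter = filter,
                 tau_rel = tau_rel, tau_ratio = tau_ratio,
                 min_group_size = as.integer(min_group_size),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full shape-mapping analysis
#'
#' End-to-end orchestration: read outlines and genotypes, select the
#' landmark count (AIC) and harmonic order (explained variance) on the
#' pooled per-line averages, quality-filter the SNPs, scan each deme
#' separately with permutation thresholds per segregation type, classify
#' significant QTLs into shape-pattern classes, tabulate genotype effects
#' across demes, and compute the population-genetic summaries (FST on
#' neutral SNPs, Nm, QST per trait, trait ANOVA). Every stage, selected
#' value and skipped-marker tally is recorded in `run_log.txt`;
#' deterministic given the seed. On failure the partial outputs are
#' removed and the error names the stage.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the scan tables, pattern table, effect
#'   table, popgen summaries and selected settings.
#' @export
run_full <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out_files <- file.path(config$out_dir,
                         c("scan_high.tsv", "scan_low.tsv", "patterns.tsv",
                           "effect_table.tsv", "popgen.json", "run_log.txt"))
  log_path <- out_files[6L]
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- "setup"
  result <- tryCatch({
    say("leafscan run, seed %d", config$seed)
    for (nm in c("ef_order", "n_perm", "alpha", "min_group_size",
                 "tau_rel", "tau_ratio", "order_threshold"))
      say("config %s = %s", nm, paste(config[[nm]], collapse = ","))

    stage <- "read-landmarks"
    leaves <- read_landmark_csv(config$landmarks)
    deme <- attr(leaves, "deme")
    if (!is.null(config$lines)) {
      meta <- utils::read.delim(config$lines, stringsAsFactors = FALSE)
      deme <- stats::setNames(meta$deme, meta$line_id)
    }
    if (length(leaves) == 0L) stop("no leaves in landmark file")
    say("read %d leaves, %d lines", length(leaves),
        length(unique(vapply(leaves, function(o) o$line_id, ""))))

    stage <- "select-landmarks"
    k <- if (length(config$landmark_candidates) > 1L) {
      as.integer(select_landmark_count(leaves, config$landmark_candidates,
                                       ef_order = config$ef_order %||% 4L))
    } else config$landmark_candidates[1L]
    say("selected landmark count K = %d", k)

    stage <- "phenotypes"
    ph <- phenotypes_from_leaves(leaves, k, deme = deme)
    say("built %d per-line average shapes", length(ph$lines))

    stage <- "select-order"
    ef_order <- config$ef_order
    if (is.null(ef_order)) {
      ef_order <- as.integer(select_order(attr(ph, "avg_shapes"),
                                          max_order = config$max_order,
                                          threshold = config$order_threshold))
    }
    say("harmonic order = %d", ef_order)

    stage <- "read-vcf"
    vdat <- read_vcf(config$vcf)
    say("read %d biallelic markers (%d multi-allelic skipped)",
        nrow(vdat$geno), vdat$n_multiallelic)

    stage <- "filter"
    fl <- filter_markers(vdat, config$filter)
    say("retained %d markers; rejections: %s", sum(fl$retained),
        paste(names(fl$tally), fl$tally, sep = "=", collapse = " "))
    utils::write.table(
      data.frame(rule = names(fl$tally), rejected = as.integer(fl$tally)),
      file.path(config$out_dir, "filter_tally.tsv"), sep = "\t",
      row.names = FALSE, quote = FALSE)
    gdat <- fl$data
    if (nrow(gdat$geno) == 0L) stop("no markers passed filtering")

    stage <- "scan"
    demes_present <- unique(unname(ph$deme))
    scans <- list(); thresholds <- list()
    for (dnm in sort(demes_present)) {
      idx <- which(ph$deme == dnm)
      phd <- subset_pheno(ph, idx)
      sc <- genome_scan(phd, gdat$geno, markers = gdat$markers,
                        ef_order = ef_order,
                        min_group_size = config$min_group_size)
      thr <- rep(NA_real_, nrow(sc))
      for (st in unique(sc$seg_type[!sc$skipped])) {
        th <- permutation_threshold(
          phd, gdat$geno, seg_type = st, markers = gdat$markers,
          n_perm = config$n_perm, alpha = config$alpha,
          seed = stream_seed(config$seed, paste0("perm_", dnm, "_", st)),
          ef_order = ef_order, min_group_size = config$min_group_size)
        thr[sc$seg_type == st] <- th
        say("deme %s %s threshold (alpha %.3g, %d perms): %.3f",
            dnm, st, config$alpha, config$n_perm, th)
      }
      sc$threshold <- thr
      sc$significant <- !sc$skipped & !is.na(thr) & sc$LR > thr
      tr <- pheno_traits(phd)
      for (trt in c("width", "length", "area")) {
        sc[[paste0("h2_", trt)]] <- vapply(seq_len(nrow(sc)), function(i) {
          g <- gdat$geno[match(sc$marker[i], rownames(gdat$geno)), phd$lines]
          if (length(unique(stats::na.omit(g))) < 2L) return(NA_real_)
          snp_heritability(tr[[trt]], g)
        }, 1)
      }
      scans[[dnm]] <- sc
      say("deme %s: %d significant of %d usable markers", dnm,
          sum(sc$significant), sum(!sc$skipped))
    }

    stage <- "patterns"
    pat <- NULL
    for (dnm in names(scans)) {
      sc <- scans[[dnm]]
      phd <- subset_pheno(ph, which(ph$deme == dnm))
      for (mk in sc$marker[sc$significant]) {
        g <- gdat$geno[match(mk, rownames(gdat$geno)), phd$lines]
        cl <- tryCatch({
          ms <- suppressWarnings(
            genotype_mean_shapes(phd, g, config$min_group_size))
          classify_pattern(ms, config$tau_rel, config$tau_ratio, marker = mk)
        }, error = function(e) NULL)
        if (!is.null(cl))
          pat <- rbind(pat, data.frame(marker = mk, deme = dnm,
                                       class = cl$class, dL = cl$dL,
                                       dW = cl$dW, d_base = cl$d_base,
                                       d_mid = cl$d_mid, d_tip = cl$d_tip))
      }
    }
    say("classified %d significant QTL patterns", NROW(pat))

    stage <- "effects"
    eff <- NULL
    if (length(scans) == 2L) {
      sig_union <- unique(unlist(lapply(scans, function(s)
        s$marker[s$significant])))
      if (length(sig_union)) {
        dn <- names(scans)
        sig_flags <- lapply(scans, function(s)
          stats::setNames(s$significant, s$marker))
        eff <- effect_table(subset_pheno(ph, which(ph$deme == dn[1L])),
                            subset_pheno(ph, which(ph$deme == dn[2L])),
                            gdat$geno, markers = sig_union,
                            sig_a = sig_flags[[1L]], sig_b = sig_flags[[2L]],
                            deme_names = dn,
                            min_group_size = config$min_group_size)
      }
    }

    stage <- "popgen"
    neutral <- !is.na(gdat$markers$neutrality) &
      gdat$markers$neutrality %in% c("intergenic", "intron", "synonymous")
    demes_by_line <- unname(ph$deme[match(colnames(gdat$geno), ph$lines)])
    fst <- if (any(neutral))
      as.numeric(weir_cockerham_fst(gdat$geno[neutral, , drop = FALSE],
                                    demes_by_line)) else NA_real_
    nm <- if (is.finite(fst) && fst > 0 && fst < 1) nm_from_fst(fst) else NA_real_
    tr_all <- pheno_traits(ph)
    qst_by_trait <- sapply(c("width", "length", "area"), function(trt)
      qst(deme_variance_components(tr_all[[trt]], unname(ph$deme))))
    stage <- "anova"
    leaf_res <- lapply(leaves, resample_contour, k = k)
    leaf_al <- procrustes_align(leaf_res)$shapes
    leaf_tab <- do.call(rbind, lapply(leaf_al, function(o) {
      td <- trait_descriptors(o)
      data.frame(line_id = o$line_id, position = o$position, block = o$block,
                 width = td$width, length = td$length, area = td$area)
    }))
    leaf_tab$altitude <- unname(deme[leaf_tab$line_id])
    anova_tabs <- lapply(c("width", "length", "area"), function(trt) {
      d <- data.frame(trait = leaf_tab[[trt]], altitude = leaf_tab$altitude,
                      genotype = leaf_tab$line_id,
                      position = leaf_tab$position, block = leaf_tab$block)
      tryCatch(shape_anova(d), error = function(e) NULL)
    })
    names(anova_tabs) <- c("width", "length", "area")
    say("FST = %.6g, Nm = %.4g, QST(w/l/a) = %s", fst, nm,
        paste(signif(qst_by_trait, 4), collapse = "/"))

    stage <- "write"
    for (dnm in names(scans))
      utils::write.table(scans[[dnm]],
                         file.path(config$out_dir,
                                   sprintf("scan_%s.tsv", dnm)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(pat))
      utils::write.table(pat, out_files[3L], sep = "\t",
                         row.names = FALSE, quote = FALSE)
    if (!is.null(eff))
      utils::write.table(eff, out_files[4L], sep = "\t",
                         row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(fst = fst, nm = nm, qst = as.list(qst_by_trait),
           anova = anova_tabs, seed = config$seed,
           landmarks = k, ef_order = ef_order),
      out_files[5L], auto_unbox = TRUE, digits = NA, na = "null")
    writeLines(log_lines, log_path)
    list(scans = scans, patterns = pat, effects = eff,
         popgen = list(fst = fst, nm = nm, qst = qst_by_trait,
                       anova = anova_tabs),
         landmarks = k, ef_order = ef_order, phenotypes = ph)
  }, error = function(e) {
    unlink(out_files)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
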