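#' Read leaf outlines from a landmark CSV
#'
#' Expects the landmark CSV dialect: one row per landmark with columns
#' `leaf_id, line_id, deme, position, block, landmark_index` (0-based,
#' contiguous per leaf) and numeric `x, y`; UTF-8 with header. Rows are
#' grouped by leaf and ordered by landmark index.
#'
#' @param path CSV file path.
#' @return Named list of [outline]s (one per leaf) with attribute `"deme"`
#'   (named deme label per line). An empty file with a header yields an
#'   empty list.
#' @export
read_landmark_csv <- function(path) {
  need <- c("leaf_id", "line_id", "deme", "position", "block",
            "landmark_index", "x", "y")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("landmark CSV is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(d) == 0L) return(structure(list(), deme = character()))
  if (!is.numeric(d$x) || !is.numeric(d$y)) {
    bad <- which(is.na(suppressWarnings(as.numeric(d$x))) |
                   is.na(suppressWarnings(as.numeric(d$y))))[1L]
    stop(sprintf("non-numeric coordinate at row %d", bad + 1L))
  }
  out <- list()
  deme <- character()
  for (id in unique(d$leaf_id)) {
    rows <- d[d$leaf_id == id, ]
    rows <- rows[order(rows$landmark_index), ]
    if (!identical(as.integer(rows$landmark_index),
                   seq_len(nrow(rows)) - 1L))
      stop(sprintf("leaf '%s': landmark indices are not contiguous from 0", id))
    out[[id]] <- outline(cbind(x = rows$x, y = rows$y), id = id,
                         line_id = as.character(rows$line_id[1L]),
                         position = as.character(rows$position[1L]),
                         block = as.character(rows$block[1L]))
    deme[as.character(rows$line_id[1L])] <- as.character(rows$deme[1L])
  }
  structure(out, deme = deme)
}

#' Write leaf outlines to a landmark CSV
#'
#' Inverse of [read_landmark_csv()].
#'
#' @param leaves list of [outline]s.
#' @param path output path.
#' @param deme named deme label per line id (recycled `NA` when absent).
#' @return Invisibly, the path.
#' @export
write_landmark_csv <- function(leaves, path, deme = NULL) {
  rows <- lapply(leaves, function(o) {
    k <- nrow(o$points)
    data.frame(leaf_id = o$id, line_id = o$line_id,
               deme = if (!is.null(deme) && o$line_id %in% names(deme))
                 deme[[o$line_id]] else NA_character_,
               position = o$position, block = o$block,
               landmark_index = seq_len(k) - 1L,
               x = o$points[, 1L], y = o$points[, 2L],
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a biallelic SNP panel from a VCF file
#'
#' Parses VCF 4.x through `vcfR`, keeping biallelic records and mapping GT
#' to alt-allele doses 0/1/2 (missing and half calls to `NA`); per-sample
#' DP is read when present. Multi-allelic records are skipped and counted.
#' A neutrality class and gene annotation are taken from an INFO key
#' (default `ANN_CLASS` / `GENE`) or from a side TSV with columns
#' `chrom, pos, class, gene`.
#'
#' @param path VCF path.
#' @param info_key INFO key carrying the neutrality class.
#' @param annotation_tsv optional side TSV path.
#' @return List: `geno` (markers x samples dose matrix), `depth` (DP
#'   matrix or NULL), `markers` (marker, chrom, pos, ref, alt, seg_type,
#'   neutrality, annotation), `n_multiallelic` skipped count.
#' @export
read_vcf <- function(path, info_key = "ANN_CLASS", annotation_tsv = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  n_multi <- sum(!bi)
  v <- v[bi, ]
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dose[clean %in% c("0/0")] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean %in% c("1/1")] <- 2L
  depth <- tryCatch({
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    if (all(is.na(dp))) NULL else dp
  }, error = function(e) NULL)
  info <- vcfR::getINFO(v)
  get_info <- function(key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    val <- rep(NA_character_, length(info))
    hit <- grepl(paste0(key, "="), info)
    val[hit] <- sub(paste0(".*", key, "="), "",
                    regmatches(info, regexpr(paste0(key, "=[^;]*"), info)))
    val
  }
  neutrality <- get_info(info_key)
  annotation <- get_info("GENE")
  if (!is.null(annotation_tsv)) {
    side <- utils::read.delim(annotation_tsv, stringsAsFactors = FALSE)
    key <- paste(fix[, "CHROM"], fix[, "POS"])
    skey <- paste(side$chrom, side$pos)
    idx <- match(key, skey)
    neutrality <- ifelse(!is.na(idx), side$class[idx], neutrality)
    annotation <- ifelse(!is.na(idx), side$gene[idx], annotation)
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  rownames(dose) <- ids
  if (!is.null(depth)) rownames(depth) <- ids
  seg <- apply(dose, 1L, function(g)
    as.character(classify_segregation(table(factor(g, levels = 0:2)))))
  markers <- data.frame(marker = ids, chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]), ref = fix[, "REF"],
                        alt = fix[, "ALT"], seg_type = seg,
                        neutrality = neutrality, annotation = annotation,
                        stringsAsFactors = FALSE)
  list(geno = dose, depth = depth, markers = markers,
       n_multiallelic = n_multi)
}

#' Write a simulated SNP panel as a VCF 4.2 file
#'
#' Emits GT and DP per sample plus the neutrality class and gene
#' annotation as INFO keys, so the bundle round-trips through
#' [read_vcf()].
#'
#' @param genos result of [simulate_genotypes()] (or any list with `geno`,
#'   `depth`, `markers`).
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_vcf_file <- function(genos, path) {
  geno <- genos$geno; depth <- genos$depth; mk <- genos$markers
  gt_str <- matrix("./.", nrow(geno), ncol(geno))
  gt_str[geno == 0L] <- "0/0"
  gt_str[geno == 1L] <- "0/1"
  gt_str[geno == 2L] <- "1/1"
  cells <- matrix(paste0(gt_str, ":", as.integer(depth)),
                  nrow(geno), ncol(geno))
  info <- paste0("ANN_CLASS=", mk$neutrality,
                 ifelse(is.na(mk$annotation), "",
                        paste0(";GENE=", mk$annotation)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=leafscan-simulator",
    "##INFO=<ID=ANN_CLASS,Number=1,Type=String,Description=\"Neutrality class\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene annotation\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(geno)), collapse = "\t"))
  body <- vapply(seq_len(nrow(geno)), function(i)
    paste(c(mk$chrom[i], mk$pos[i], mk$marker[i], mk$ref[i], mk$alt[i],
            ".", "PASS", info[i], "GT:DP", cells[i, ]), collapse = "\t"), "")
  writeLines(c(header, body), path)
  invisible(path)
}
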