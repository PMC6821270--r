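# Quantification-bias diagnostics: global and per-category methylation,
# wrong-reference simulation, raw region differences, unique-shared
# disparity.

#' Per-sample global methylation
#'
#' The unweighted mean of per-site proportions M/Cov over read-covered sites
#' (Cov >= 1) on the selected chromosomes. Counting CpGs rather than reads
#' makes the value insensitive to local coverage differences.
#'
#' @param matrix a `meth_matrix`.
#' @param chroms chromosomes to include (default: all). Autosome/allosome
#'   selection is the caller's configuration, not inferred from names.
#' @return Named numeric vector, one value per sample; `NA` for a sample
#'   with no covered site.
#' @export
global_methylation <- function(matrix, chroms = NULL) {
  j <- if (is.null(chroms)) seq_len(nrow(matrix$sites)) else
    which(matrix$sites$chrom %in% chroms)
  out <- vapply(seq_len(nrow(matrix$samples)), function(i) {
    cov <- matrix$Cov[i, j]
    k <- cov >= 1L
    if (!any(k)) return(NA_real_)
    mean(matrix$M[i, j][k] / cov[k])
  }, numeric(1))
  names(out) <- matrix$samples$sample_id
  out
}

#' Per-sample, per-category mean methylation
#'
#' [global_methylation()] restricted to each CpG classification category.
#'
#' @param matrix a `meth_matrix`.
#' @param classifications [classify_cross_genome()] output in the matrix's
#'   coordinate system; joined to the matrix sites by position. Matrix sites
#'   absent from the table (e.g. CpGs unique to the other genome) are
#'   reported under category `"NOT_IN_REFERENCE"`.
#' @param chroms optional chromosome filter.
#' @return data.frame `sample_id`, `category`, `mean_meth`, `n_covered`;
#'   `mean_meth` is `NA` for a category with no covered site.
#' @export
category_methylation <- function(matrix, classifications, chroms = NULL) {
  cat_at <- as.character(
    classifications$category[match(paste(matrix$sites$chrom,
                                         matrix$sites$pos),
                                   paste(classifications$chrom,
                                         classifications$pos))])
  cat_at[is.na(cat_at)] <- "NOT_IN_REFERENCE"
  jsel <- if (is.null(chroms)) rep(TRUE, nrow(matrix$sites)) else
    matrix$sites$chrom %in% chroms
  cats <- unique(cat_at)
  out <- list()
  for (i in seq_len(nrow(matrix$samples))) {
    for (cc in cats) {
      j <- which(jsel & cat_at == cc)
      cov <- matrix$Cov[i, j]
      k <- cov >= 1L
      out[[length(out) + 1L]] <- data.frame(
        sample_id = matrix$samples$sample_id[i], category = cc,
        mean_meth = if (any(k)) mean(matrix$M[i, j][k] / cov[k]) else
          NA_real_,
        n_covered = sum(k))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate quantification under the wrong reference genome
#'
#' Transforms a correctly quantified matrix (personal-genome pipeline, in
#' `ref_genotype` coordinates) into what a pipeline aligning every sample to
#' `ref_genotype`'s genome would report. For each sample of another
#' genotype: at reference-unique CpGs whose dinucleotide is TG/CA in that
#' genotype, reads align without mismatch and are called unmethylated, so M
#' is set to 0 and coverage is kept (drawn as a Poisson with the sample's
#' mean covered-site coverage where absent); at CpGs unique to the sample's
#' own genotype, the data is removed (those positions are not CpGs in the
#' reference). Reference-genotype samples are unchanged.
#'
#' @param matrix a `meth_matrix` in `ref_genotype` coordinates.
#' @param classifications classification of the reference genome's CpGs
#'   against the other genotype's genome.
#' @param ref_genotype the genotype whose genome plays the reference.
#' @return A `meth_matrix`.
#' @export
simulate_wrong_reference <- function(matrix, classifications, ref_genotype) {
  if (!ref_genotype %in% rownames(matrix$present))
    stop("unknown reference genotype: ", ref_genotype)
  key <- paste(matrix$sites$chrom, matrix$sites$pos)
  cat_at <- as.character(
    classifications$category[match(key, paste(classifications$chrom,
                                              classifications$pos))])
  ref_unique_tgca <- which(!is.na(cat_at) & cat_at == "TG_CA")
  for (i in seq_len(nrow(matrix$samples))) {
    g <- matrix$samples$genotype[i]
    if (g == ref_genotype) next
    own_unique <- which(matrix$present[g, ] &
                          !matrix$present[ref_genotype, ])
    matrix$M[i, own_unique] <- 0L
    matrix$Cov[i, own_unique] <- 0L
    lam <- mean(matrix$Cov[i, matrix$Cov[i, ] > 0L])
    if (!is.finite(lam)) lam <- 0
    need <- ref_unique_tgca[matrix$Cov[i, ref_unique_tgca] == 0L]
    matrix$Cov[i, need] <- stats::rpois(length(need), lam)
    matrix$M[i, ref_unique_tgca] <- 0L
  }
  matrix
}

region_site_idx <- function(matrix, region) {
  which(matrix$sites$chrom == region$chrom &
          matrix$sites$pos >= region$start & matrix$sites$pos <= region$end)
}

group_rows <- function(matrix, design) {
  lapply(levels(design$group), function(g)
    match(design$sample_id[design$group == g], matrix$samples$sample_id))
}

pooled_prop <- function(matrix, rows, j) {
  # per-site pooled proportion sum(M)/sum(Cov) across the group's samples
  M <- colSums(matrix$M[rows, j, drop = FALSE])
  Cov <- colSums(matrix$Cov[rows, j, drop = FALSE])
  ifelse(Cov > 0L, M / Cov, NA_real_)
}

#' Raw (unsmoothed) methylation difference across a region
#'
#' For shared sites (`site_subset = "shared"` or `"all"`): per site, each
#' group's pooled proportion sum(M)/sum(Cov); the per-site difference is
#' group2 minus group1 and the return value is the unweighted mean over the
#' subset's eligible sites (covered in both groups). For `"unique"` sites
#' only one group carries data; the value is then the mean raw methylation
#' over group-2-unique sites within group 2 minus the mean over
#' group-1-unique sites within group 1; when only one side exists, that side
#' is compared against the other group's shared-site mean.
#'
#' @param matrix a `meth_matrix` (unsmoothed counts).
#' @param region list or one-row data.frame with `chrom`, `start`, `end`.
#' @param site_subset `"shared"`, `"unique"` or `"all"`.
#' @param design a [group_design()].
#' @return The mean difference, or `NA` (with a `"reason"` attribute) when
#'   no eligible site exists.
#' @export
raw_region_diff <- function(matrix, region,
                            site_subset = c("shared", "unique", "all"),
                            design) {
  site_subset <- match.arg(site_subset)
  j <- region_site_idx(matrix, region)
  shared <- colSums(!matrix$present) == 0L
  gr <- group_rows(matrix, design)
  if (site_subset %in% c("shared", "all")) {
    jj <- if (site_subset == "shared") j[shared[j]] else j
    if (!length(jj))
      return(structure(NA_real_, reason = "no site in subset"))
    p1 <- pooled_prop(matrix, gr[[1L]], jj)
    p2 <- pooled_prop(matrix, gr[[2L]], jj)
    ok <- !is.na(p1) & !is.na(p2)
    if (!any(ok))
      return(structure(NA_real_, reason = "no site covered in both groups"))
    return(mean(p2[ok] - p1[ok]))
  }
  # unique sites: each has data in one group only
  genos_of <- lapply(levels(design$group), function(g)
    unique(design$genotype[design$group == g]))
  only_in <- function(genos) {
    sel <- rep(TRUE, ncol(matrix$present))
    for (g in rownames(matrix$present))
      sel <- sel & (matrix$present[g, ] == (g %in% genos))
    sel
  }
  u1 <- j[only_in(genos_of[[1L]])[j]]
  u2 <- j[only_in(genos_of[[2L]])[j]]
  m1 <- if (length(u1)) mean(pooled_prop(matrix, gr[[1L]], u1),
                             na.rm = TRUE) else NA_real_
  m2 <- if (length(u2)) mean(pooled_prop(matrix, gr[[2L]], u2),
                             na.rm = TRUE) else NA_real_
  if (is.na(m1) && is.na(m2))
    return(structure(NA_real_, reason = "no covered unique site"))
  if (!is.na(m1) && !is.na(m2)) return(m2 - m1)
  # single available side vs the other group's shared-site mean
  jj <- j[shared[j]]
  if (is.na(m2)) {
    other <- mean(pooled_prop(matrix, gr[[2L]], jj), na.rm = TRUE)
    return(other - m1)
  }
  other <- mean(pooled_prop(matrix, gr[[1L]], jj), na.rm = TRUE)
  m2 - other
}

#' Unique-shared disparity of a region
#'
#' The mean raw methylation difference at the region's genotype-unique CpGs
#' minus the mean raw difference at its shared CpGs. Positive values
#' indicate differential methylation driven by unique sites.
#'
#' @inheritParams raw_region_diff
#' @return The disparity, or `NA` with a `"reason"` attribute when either
#'   subset is missing.
#' @export
unique_shared_disparity <- function(matrix, region, design) {
  du <- raw_region_diff(matrix, region, "unique", design)
  ds <- raw_region_diff(matrix, region, "shared", design)
  if (is.na(du) || is.na(ds))
    return(structure(NA_real_,
                     reason = paste(attr(du, "reason"), attr(ds, "reason"))))
  du - ds
}

#' Write a per-sample bias report
#'
#' TSV of per-sample global methylation plus, when classifications are
#' given, per-category means.
#'
#' @param matrix a `meth_matrix`.
#' @param path output file.
#' @param classifications optional classification table.
#' @param chroms optional chromosome filter.
#' @export
write_bias_report <- function(matrix, path, classifications = NULL,
                              chroms = NULL) {
  gm <- global_methylation(matrix, chroms)
  df <- data.frame(sample_id = names(gm), category = "GLOBAL",
                   mean_meth = as.numeric(gm),
                   n_covered = rowSums(matrix$Cov >= 1L))
  if (!is.null(classifications))
    df <- rbind(df, category_methylation(matrix, classifications, chroms))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
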