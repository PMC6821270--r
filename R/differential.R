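# Group-difference t-statistic tracks, DMR/block segmentation, balanced
# permutations and genome-wide family-wise error rates.

#' DMR segmentation parameters
#'
#' Defaults correspond to small-DMR finding (|t| cutoff 4.6, maxGap 300 bp);
#' large blocks use cutoff 2 and maxGap 10000 together with the `"blocks"`
#' smoothing preset.
#'
#' @param cutoff |t| threshold for member sites.
#' @param maxGap maximum bp gap between consecutive member sites.
#' @param min_cpgs minimum number of member CpGs.
#' @param min_meandiff minimum |mean methylation difference| (fraction).
#' @return A list of class `dmr_params`.
#' @export
dmr_params <- function(cutoff = 4.6, maxGap = 300, min_cpgs = 3,
                       min_meandiff = 0.10) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (min_meandiff < 0 || min_meandiff > 1)
    stop("min_meandiff must be in [0, 1]")
  structure(list(cutoff = cutoff, maxGap = maxGap,
                 min_cpgs = as.integer(min_cpgs),
                 min_meandiff = min_meandiff), class = "dmr_params")
}

running_mean <- function(x, k) {
  n <- length(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  hi <- pmin(n, seq_len(n) + half)
  lo <- pmax(0L, seq_len(n) - half - 1L)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Per-site group-difference t statistics
#'
#' At each masked site, computes the group means of the smoothed values and
#' their difference (group2 minus group1, groups ordered by the design's
#' factor levels), the pooled within-group standard deviation, floors it at
#' its `sd_floor_quantile` quantile over masked sites, smooths the floored
#' values with a running mean over `sd_smooth_sites` masked sites, and forms
#' `t = meanDiff / (sd * sqrt(1/n1 + 1/n2))`.
#'
#' @param smoothed a `smoothed_track`.
#' @param design a [group_design()]; each group needs at least 2 samples.
#' @param mask logical vector over the track's sites (from
#'   [coverage_mask()]).
#' @param sd_floor_quantile quantile of raw pooled sds used as a floor.
#' @param sd_smooth_sites width (in masked sites) of the sd running mean.
#' @return An object of class `tstat_track`: data.frame of masked sites with
#'   `chrom`, `pos`, `mean1`, `mean2`, `meanDiff`, `sd_raw`, `sd`, `t`, plus
#'   attributes `mask`, `design` and `n_per_group`.
#' @export
compute_tstat <- function(smoothed, design, mask,
                          sd_floor_quantile = 0.75, sd_smooth_sites = 101L) {
  i1 <- match(design$sample_id[design$group == levels(design$group)[1L]],
              smoothed$samples$sample_id)
  i2 <- match(design$sample_id[design$group == levels(design$group)[2L]],
              smoothed$samples$sample_id)
  if (anyNA(i1) || anyNA(i2)) stop("design samples not found in track")
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 samples (sd undefined otherwise)")
  j <- which(mask)
  f1 <- smoothed$fitted[i1, j, drop = FALSE]
  f2 <- smoothed$fitted[i2, j, drop = FALSE]
  m1 <- colMeans(f1)
  m2 <- colMeans(f2)
  v1 <- colSums((f1 - rep(m1, each = n1))^2) / (n1 - 1L)
  v2 <- colSums((f2 - rep(m2, each = n2))^2) / (n2 - 1L)
  sd_raw <- sqrt(((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L))
  floor_val <- stats::quantile(sd_raw, sd_floor_quantile, na.rm = TRUE,
                               names = FALSE)
  sd_floored <- pmax(sd_raw, floor_val)
  sd_sm <- running_mean(sd_floored, sd_smooth_sites)
  tval <- (m2 - m1) / (sd_sm * sqrt(1 / n1 + 1 / n2))
  out <- data.frame(chrom = smoothed$sites$chrom[j],
                    pos = smoothed$sites$pos[j],
                    mean1 = m1, mean2 = m2, meanDiff = m2 - m1,
                    sd_raw = sd_raw, sd = sd_sm, t = tval)
  rownames(out) <- NULL
  attr(out, "mask") <- mask
  attr(out, "design") <- design
  attr(out, "n_per_group") <- c(n1, n2)
  class(out) <- c("tstat_track", "data.frame")
  out
}

#' Segment a t-statistic track into candidate regions
#'
#' Candidate regions are maximal runs of consecutive masked sites whose
#' t statistics all exceed `cutoff` in absolute value with a constant sign,
#' split where the gap between neighbouring member sites exceeds `maxGap`
#' or at chromosome boundaries. Runs with fewer than `min_cpgs` members or
#' |mean of per-site meanDiff| below `min_meandiff` are discarded.
#'
#' @param tstat a `tstat_track`.
#' @param params a [dmr_params()].
#' @return data.frame with `chrom`, `start`, `end` (positions of the first
#'   and last member CpG, 1-based inclusive), `n_cpgs`, `meanDiff`,
#'   `areaStat` (sum of member t values), `direction` (sign of areaStat)
#'   and `gFWER` (`NA` until assigned).
#' @export
find_regions <- function(tstat, params = dmr_params()) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_cpgs = integer(0),
                      meanDiff = numeric(0), areaStat = numeric(0),
                      direction = integer(0), gFWER = numeric(0))
  n <- nrow(tstat)
  if (!n) return(empty)
  state <- integer(n)
  ok <- is.finite(tstat$t)
  state[ok & tstat$t >= params$cutoff] <- 1L
  state[ok & tstat$t <= -params$cutoff] <- -1L
  new_chrom <- c(TRUE, tstat$chrom[-1L] != tstat$chrom[-n])
  gap_break <- c(TRUE, diff(tstat$pos) > params$maxGap) | new_chrom
  run_id <- cumsum(state != c(0L, state[-n]) | gap_break |
                     (state != 0L & c(FALSE, state[-n] == 0L)))
  keep <- state != 0L
  if (!any(keep)) return(empty)
  grp <- run_id[keep]
  sp <- split(which(keep), grp)
  rows <- lapply(sp, function(ii) {
    data.frame(chrom = tstat$chrom[ii[1L]],
               start = tstat$pos[ii[1L]],
               end = tstat$pos[ii[length(ii)]],
               n_cpgs = length(ii),
               meanDiff = mean(tstat$meanDiff[ii]),
               areaStat = sum(tstat$t[ii]),
               direction = as.integer(sign(sum(tstat$t[ii]))),
               gFWER = NA_real_)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_cpgs >= params$min_cpgs &
               abs(out$meanDiff) >= params$min_meandiff, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate balanced label permutations
#'
#' For a two-genotype design, the balanced permutations are all group
#' assignments in which each group contains exactly half of each genotype,
#' de-duplicated under swapping the two group labels and excluding the
#' observed assignment. For the 4+4 genotype-vs-genotype design this yields
#' 18 permutations (the observed genotype-pure split is not itself balanced,
#' so the exclusion does not apply there).
#'
#' @param design a [group_design()] with genotype labels.
#' @return List of factor vectors (same levels as `design$group`), one per
#'   permutation, aligned to the design rows.
#' @export
balanced_permutations <- function(design) {
  genos <- unique(design$genotype)
  if (length(genos) != 2L) stop("balanced permutation needs two genotypes")
  ia <- which(design$genotype == genos[1L])
  ib <- which(design$genotype == genos[2L])
  if (length(ia) %% 2L || length(ib) %% 2L)
    stop("balanced permutation needs an even number of samples per genotype")
  g1_size <- sum(design$group == levels(design$group)[1L])
  if (g1_size != nrow(design) / 2)
    stop("balanced permutation needs equal group sizes")
  ca <- utils::combn(ia, length(ia) / 2L, simplify = FALSE)
  cb <- utils::combn(ib, length(ib) / 2L, simplify = FALSE)
  canonical <- function(set) {       # the half containing sample row 1
    if (1L %in% set) sort(set) else sort(setdiff(seq_len(nrow(design)), set))
  }
  obs <- canonical(which(design$group == levels(design$group)[1L]))
  out <- list()
  for (a in ca) for (b in cb) {
    g1 <- canonical(c(a, b))
    if (!1L %in% c(a, b)) next       # de-duplicate under group-label swap
    if (identical(g1, obs)) next     # exclude the observed assignment
    lev <- levels(design$group)
    asg <- factor(ifelse(seq_len(nrow(design)) %in% g1, lev[1L], lev[2L]),
                  levels = lev)
    out[[length(out) + 1L]] <- asg
  }
  out
}

#' Null regions under a permuted design
#'
#' Re-runs [compute_tstat()] (including the sd floor and smoothing) and
#' [find_regions()] under a permuted group assignment; smoothing itself is
#' label-free and reused.
#'
#' @param smoothed a `smoothed_track`.
#' @param perm_design a [group_design()] with permuted `group` labels.
#' @param mask analysis mask (as for [compute_tstat()]).
#' @param params a [dmr_params()].
#' @param ... passed to [compute_tstat()].
#' @return data.frame of null candidate regions.
#' @export
null_regions <- function(smoothed, perm_design, mask, params = dmr_params(),
                         ...) {
  find_regions(compute_tstat(smoothed, perm_design, mask, ...), params)
}

#' Assign genome-wide family-wise error rates to candidate regions
#'
#' For each observed region, the gFWER is the fraction of permutations
#' containing at least one null region anywhere that is "better": at least
#' as many member CpGs and at least as large an absolute areaStat.
#'
#' @param observed data.frame from [find_regions()].
#' @param nulls list (one element per permutation) of null region
#'   data.frames.
#' @return `observed` with the `gFWER` column filled in.
#' @export
assign_gfwer <- function(observed, nulls) {
  if (!length(nulls)) stop("at least one permutation is required")
  if (!nrow(observed)) return(observed)
  observed$gFWER <- vapply(seq_len(nrow(observed)), function(k) {
    nc <- observed$n_cpgs[k]; ar <- abs(observed$areaStat[k])
    mean(vapply(nulls, function(nb) {
      nrow(nb) > 0L && any(nb$n_cpgs >= nc & abs(nb$areaStat) >= ar)
    }, logical(1)))
  }, numeric(1))
  observed
}

#' Full DMR analysis with balanced-permutation gFWER
#'
#' Convenience wrapper: observed t statistics and regions, balanced
#' permutations, null regions per permutation, and gFWER assignment.
#'
#' @param smoothed a `smoothed_track`.
#' @param design a [group_design()].
#' @param mask analysis mask from [coverage_mask()].
#' @param params a [dmr_params()].
#' @param ... passed to [compute_tstat()].
#' @return List with `regions` (gFWER-annotated), `tstat`, and `nulls`.
#' @export
dmr_analysis <- function(smoothed, design, mask, params = dmr_params(),
                         ...) {
  tt <- compute_tstat(smoothed, design, mask, ...)
  obs <- find_regions(tt, params)
  perms <- balanced_permutations(design)
  nulls <- lapply(perms, function(p) {
    pd <- design
    pd$group <- p
    null_regions(smoothed, pd, mask, params, ...)
  })
  list(regions = assign_gfwer(obs, nulls), tstat = tt, nulls = nulls)
}

#' Write candidate regions as TSV or BED
#'
#' The TSV keeps 1-based inclusive `start`/`end` (first and last member CpG
#' C positions); the BED output is 0-based half-open and spans through the G
#' of the last member CpG.
#'
#' @param regions data.frame from [find_regions()] / [assign_gfwer()].
#' @param path output file.
#' @param format `"tsv"` or `"bed"`.
#' @export
write_regions <- function(regions, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(regions, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    score <- ifelse(is.na(regions$gFWER), 0,
                    as.integer(round(1000 * (1 - regions$gFWER))))
    writeLines(paste(regions$chrom, regions$start - 1L, regions$end + 1L,
                     sprintf("dmr_%d", seq_len(nrow(regions))), score,
                     ifelse(regions$direction >= 0, "+", "-"), sep = "\t"),
               path)
  }
  invisible(path)
}
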