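# Kernel-weighted local polynomial smoothing of per-sample methylation.
#
# Each sample's observed proportions M/Cov are fit, site by site, with a
# weighted local quadratic regression: the window half-width at a site is
# max(h, distance to the ns-th nearest covered site in the same cluster), and
# weights are coverage x tricube(distance / half-width). Zero-coverage sites
# (including CpGs that do not exist in the sample's genome) get weight zero
# but receive a fitted value -- the imputation that lets genotype-unique
# CpGs influence the estimate at nearby shared CpGs.

#' Smoothing parameters
#'
#' @param ns minimum number of informative (covered) sites per window.
#' @param h minimum window half-width in bp.
#' @param maxGap gap in bp splitting sites into independently smoothed
#'   clusters.
#' @param preset `"dmr"` (ns = 70, h = 1000) for small-DMR analysis or
#'   `"blocks"` (ns = 500, h = 20000) for large-block analysis; explicit
#'   `ns`/`h` arguments override the preset.
#' @return A list of class `smoothing_params`.
#' @export
smoothing_params <- function(ns = NULL, h = NULL, maxGap = 1e8,
                             preset = c("dmr", "blocks")) {
  preset <- match.arg(preset)
  def <- if (preset == "dmr") c(ns = 70, h = 1000) else c(ns = 500, h = 20000)
  if (is.null(ns)) ns <- def[["ns"]]
  if (is.null(h)) h <- def[["h"]]
  if (ns < 1 || h <= 0 || maxGap <= 0)
    stop("require ns >= 1, h > 0, maxGap > 0")
  structure(list(ns = as.integer(ns), h = as.numeric(h),
                 maxGap = as.numeric(maxGap)), class = "smoothing_params")
}

#' Split sorted positions into smoothing clusters
#'
#' Consecutive sites further apart than `maxGap` fall into different
#' clusters; clusters partition the sites.
#'
#' @param positions sorted integer vector.
#' @param maxGap maximum within-cluster gap in bp.
#' @return Integer cluster id per position (1, 2, ...).
#' @export
cluster_sites <- function(positions, maxGap) {
  if (is.unsorted(positions)) stop("positions must be sorted")
  if (!length(positions)) return(integer(0))
  cumsum(c(1L, as.integer(diff(positions) > maxGap)))
}

tricube <- function(u) {
  w <- (1 - pmin(abs(u), 1)^3)^3
  w[abs(u) >= 1] <- 0
  w
}

# distance from every position to its ns-th nearest covered position
# (covered positions sorted); handles nc < ns by using the farthest.
nsth_distance <- function(positions, cpos, ns) {
  nc <- length(cpos)
  if (nc <= ns)
    return(pmax(positions - cpos[1L], cpos[nc] - positions, 0))
  it <- findInterval(positions, cpos)
  d <- rep(Inf, length(positions))
  # the ns nearest covered sites form a contiguous run cpos[a..a+ns-1];
  # minimise over every run placement around each site (s sites at or left)
  for (s in 0:ns) {
    a <- pmin(pmax(it + 1L - s, 1L), nc - ns + 1L)
    d <- pmin(d, pmax(positions - cpos[a], cpos[a + ns - 1L] - positions))
  }
  d
}

# weighted polynomial fit evaluated at x = 0, with degree fallback 2 -> 1 -> 0
# on rank deficiency (fewer than 3 distinct covered positions in the window)
wpoly_at0 <- function(x, y, w) {
  ndist <- length(unique(x[w > 0]))
  if (ndist == 0L) return(NA_real_)
  if (ndist >= 3L) {
    x2 <- x * x
    A <- matrix(c(sum(w), sum(w * x), sum(w * x2),
                  sum(w * x), sum(w * x2), sum(w * x2 * x),
                  sum(w * x2), sum(w * x2 * x), sum(w * x2 * x2)), 3L, 3L)
    b <- try(solve(A, c(sum(w * y), sum(w * x * y), sum(w * x2 * y))),
             silent = TRUE)
    if (!inherits(b, "try-error") && all(is.finite(b))) return(b[1L])
    ndist <- 2L
  }
  if (ndist == 2L) {
    A <- matrix(c(sum(w), sum(w * x), sum(w * x), sum(w * x * x)), 2L, 2L)
    b <- try(solve(A, c(sum(w * y), sum(w * x * y))), silent = TRUE)
    if (!inherits(b, "try-error") && all(is.finite(b))) return(b[1L])
  }
  sum(w * y) / sum(w)
}

#' Smooth one sample's methylation along one chromosome
#'
#' @param M,Cov integer vectors of methylated and total counts, aligned to
#'   `positions`.
#' @param positions sorted site positions (bp).
#' @param params a [smoothing_params()].
#' @return List with `fitted` (numeric, clamped to `[0, 1]`, `NA` in clusters
#'   with no covered site) and `imputed` (logical, `TRUE` where `Cov == 0`).
#' @export
smooth_sample <- function(M, Cov, positions, params = smoothing_params()) {
  n <- length(positions)
  stopifnot(length(M) == n, length(Cov) == n)
  fitted <- rep(NA_real_, n)
  cl <- cluster_sites(positions, params$maxGap)
  for (cid in unique(cl)) {
    idx <- which(cl == cid)
    pos <- as.numeric(positions[idx])
    cov <- Cov[idx]
    ci <- which(cov > 0)
    if (!length(ci)) next
    cpos <- pos[ci]
    ccov <- as.numeric(cov[ci])
    y <- M[idx][ci] / ccov
    if (length(ci) == 1L) {          # single covered site: constant cluster
      fitted[idx] <- y
      next
    }
    w_half <- pmax(params$h, nsth_distance(pos, cpos, params$ns))
    lo <- findInterval(pos - w_half, cpos) + 1L          # first cpos > pos-w
    hi <- findInterval(pos + w_half, cpos)               # last  cpos <= pos+w
    for (j in seq_along(idx)) {
      v <- NA_real_
      if (lo[j] <= hi[j]) {
        jj <- lo[j]:hi[j]
        x <- (cpos[jj] - pos[j]) / w_half[j]
        w <- ccov[jj] * tricube(x)
        v <- wpoly_at0(x, y[jj], w)
      }
      if (is.na(v)) {                # all window weights vanished: fall back
        d <- abs(cpos - pos[j])     # to the nearest covered site(s)
        nearest <- which(d == min(d))
        v <- sum(ccov[nearest] * y[nearest]) / sum(ccov[nearest])
      }
      fitted[idx[j]] <- min(max(v, 0), 1)
    }
  }
  list(fitted = fitted, imputed = Cov == 0L)
}

#' Smooth every sample of a methylation matrix
#'
#' Applies [smooth_sample()] per sample and per chromosome over the full
#' union site list. Sites at which a sample has zero coverage -- including
#' CpGs unique to another genotype -- receive imputed values, the mechanism
#' by which genotype-unique CpGs contribute to differential analysis at
#' nearby shared sites.
#'
#' @param matrix a `meth_matrix`.
#' @param params a [smoothing_params()].
#' @return An object of class `smoothed_track`: list with `sites`, `fitted`
#'   and `imputed` (samples x sites), `samples`, `present` and `params`.
#' @export
smooth_matrix <- function(matrix, params = smoothing_params()) {
  ns <- nrow(matrix$samples); np <- nrow(matrix$sites)
  fitted <- matrix(NA_real_, ns, np,
                   dimnames = list(matrix$samples$sample_id, NULL))
  imputed <- matrix$Cov == 0L
  for (ch in unique(matrix$sites$chrom)) {
    j <- which(matrix$sites$chrom == ch)
    for (i in seq_len(ns)) {
      sm <- smooth_sample(matrix$M[i, j], matrix$Cov[i, j],
                          matrix$sites$pos[j], params)
      fitted[i, j] <- sm$fitted
    }
  }
  structure(list(sites = matrix$sites, fitted = fitted, imputed = imputed,
                 samples = matrix$samples, present = matrix$present,
                 params = params),
            class = "smoothed_track")
}

#' Write a smoothed track as long-form TSV
#'
#' Columns `chrom  pos  sample  smoothed  imputed`.
#'
#' @param track a `smoothed_track`.
#' @param path output file.
#' @export
write_smoothed_track <- function(track, path) {
  ns <- nrow(track$samples); np <- nrow(track$sites)
  df <- data.frame(chrom = rep(track$sites$chrom, each = ns),
                   pos = rep(track$sites$pos, each = ns),
                   sample = rep(track$samples$sample_id, np),
                   smoothed = as.vector(track$fitted),
                   imputed = as.vector(track$imputed))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export one sample's smoothed values as bedGraph
#'
#' @param track a `smoothed_track`.
#' @param sample_id which sample to export.
#' @param path output file.
#' @export
write_smoothed_bedgraph <- function(track, sample_id, path) {
  i <- match(sample_id, track$samples$sample_id)
  if (is.na(i)) stop("unknown sample: ", sample_id)
  keep <- is.finite(track$fitted[i, ])
  writeLines(c(sprintf("track type=bedGraph name=%s", sample_id),
               paste(track$sites$chrom[keep], track$sites$pos[keep] - 1L,
                     track$sites$pos[keep] + 1L,
                     formatC(track$fitted[i, keep], format = "fg",
                             digits = 6), sep = "\t")),
             path)
  invisible(path)
}
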