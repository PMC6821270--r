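# Independent brute-force oracles, implemented before and apart from the
# package's own code paths.

# per-site weighted local polynomial smoother, solved with lm.wfit on the
# raw (bp-scale, uncentered-slope) design; same window/weight definitions,
# different numerical path
oracle_smooth <- function(M, Cov, positions, params) {
  n <- length(positions)
  out <- rep(NA_real_, n)
  gaps <- c(Inf, diff(positions))
  cl <- cumsum(gaps > params$maxGap)
  for (cid in unique(cl)) {
    idx <- which(cl == cid)
    cov <- Cov[idx]
    ci <- which(cov > 0)
    if (!length(ci)) next
    cpos <- positions[idx][ci]
    y <- M[idx][ci] / cov[ci]
    for (j in seq_along(idx)) {
      x0 <- positions[idx][j]
      d <- sort(abs(cpos - x0))
      dns <- d[min(params$ns, length(d))]
      w_half <- max(params$h, dns)
      dd <- abs(cpos - x0)
      wt <- cov[ci] * ifelse(dd < w_half, (1 - (dd / w_half)^3)^3, 0)
      use <- wt > 0
      if (!any(use)) {
        nearest <- which(dd == min(dd))
        out[idx[j]] <- sum(cov[ci][nearest] * y[nearest]) /
          sum(cov[ci][nearest])
        next
      }
      ndist <- length(unique(cpos[use]))
      deg <- min(2L, ndist - 1L)
      x <- cpos - x0
      X <- switch(deg + 1L, cbind(rep(1, length(x))), cbind(1, x),
                  cbind(1, x, x * x))
      fit <- lm.wfit(X[use, , drop = FALSE], y[use], wt[use])
      out[idx[j]] <- fit$coefficients[1L]
    }
  }
  pmin(pmax(out, 0), 1)
}

# loop-based region segmentation
oracle_find_regions <- function(tstat, params) {
  res <- NULL
  cur <- NULL
  flush <- function(cur, res) {
    if (is.null(cur)) return(res)
    md <- mean(cur$meanDiff)
    if (length(cur$t) >= params$min_cpgs && abs(md) >= params$min_meandiff)
      res <- rbind(res, data.frame(chrom = cur$chrom, start = cur$pos[1],
                                   end = cur$pos[length(cur$pos)],
                                   n_cpgs = length(cur$t), meanDiff = md,
                                   areaStat = sum(cur$t),
                                   direction = as.integer(sign(sum(cur$t)))))
    res
  }
  for (i in seq_len(nrow(tstat))) {
    ti <- tstat$t[i]
    st <- if (is.finite(ti) && ti >= params$cutoff) 1L else
      if (is.finite(ti) && ti <= -params$cutoff) -1L else 0L
    if (st == 0L) { res <- flush(cur, res); cur <- NULL; next }
    if (!is.null(cur) &&
        (cur$state != st || cur$chrom != tstat$chrom[i] ||
         tstat$pos[i] - cur$pos[length(cur$pos)] > params$maxGap)) {
      res <- flush(cur, res); cur <- NULL
    }
    if (is.null(cur))
      cur <- list(state = st, chrom = tstat$chrom[i], pos = tstat$pos[i],
                  t = ti, meanDiff = tstat$meanDiff[i])
    else {
      cur$pos <- c(cur$pos, tstat$pos[i]); cur$t <- c(cur$t, ti)
      cur$meanDiff <- c(cur$meanDiff, tstat$meanDiff[i])
    }
  }
  res <- flush(cur, res)
  if (is.null(res))
    res <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_cpgs = integer(0),
                      meanDiff = numeric(0), areaStat = numeric(0),
                      direction = integer(0))
  rownames(res) <- NULL
  res
}

# step-by-step t-statistic computation with plain loops
oracle_tstat <- function(fitted, g1, g2, mask, q = 0.75, k = 101L) {
  j <- which(mask)
  n1 <- length(g1); n2 <- length(g2)
  m1 <- m2 <- sdr <- numeric(length(j))
  for (a in seq_along(j)) {
    x1 <- fitted[g1, j[a]]; x2 <- fitted[g2, j[a]]
    m1[a] <- mean(x1); m2[a] <- mean(x2)
    sdr[a] <- sqrt(((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) /
                     (n1 + n2 - 2))
  }
  fl <- quantile(sdr, q, names = FALSE)
  sdf <- pmax(sdr, fl)
  sm <- numeric(length(j))
  half <- (k - 1L) %/% 2L
  for (a in seq_along(j)) {
    w <- max(1L, a - half):min(length(j), a + half)
    sm[a] <- mean(sdf[w])
  }
  list(meanDiff = m2 - m1, sd = sm,
       t = (m2 - m1) / (sm * sqrt(1 / n1 + 1 / n2)))
}

# brute-force per-bin mutation-rate counting
oracle_binned <- function(cls, bin_size, chrom_lengths) {
  out <- NULL
  for (ch in names(chrom_lengths)) {
    starts <- seq(1, chrom_lengths[[ch]], by = bin_size)
    for (s in starts) {
      inbin <- cls$chrom == ch & cls$pos >= s & cls$pos < s + bin_size
      nt <- sum(inbin)
      nu <- sum(inbin & cls$category != "COMMON_CG")
      out <- rbind(out, data.frame(chrom = ch, bin_start = s, n_total = nt,
                                   n_unique = nu,
                                   rate = if (nt > 0) nu / nt else NA_real_))
    }
  }
  out
}
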