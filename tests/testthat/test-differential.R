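make_track <- function(fitted, pos = NULL, genos = NULL) {
  ns <- nrow(fitted)
  np <- ncol(fitted)
  if (is.null(pos)) pos <- seq(100L, by = 100L, length.out = np)
  ids <- sprintf("s%d", seq_len(ns))
  rownames(fitted) <- ids
  if (is.null(genos)) genos <- rep(c("A", "B"), each = ns / 2)
  structure(list(sites = data.frame(chrom = "chr1", pos = pos),
                 fitted = fitted,
                 imputed = matrix(FALSE, ns, np),
                 samples = data.frame(sample_id = ids, genotype = genos),
                 present = matrix(TRUE, 1, np, dimnames = list("A", NULL)),
                 params = smoothing_params()),
            class = "smoothed_track")
}

design_for <- function(track, groups = NULL) {
  g <- if (is.null(groups)) track$samples$genotype else groups
  group_design(track$samples$sample_id, g, track$samples$genotype)
}

test_that("identical groups give zero t everywhere", {
  set.seed(1)
  vals <- matrix(runif(40), 2, 20)
  tr <- make_track(rbind(vals, vals))     # group2 repeats group1 exactly
  d <- design_for(tr, c("g1", "g1", "g2", "g2"))
  tt <- compute_tstat(tr, d, rep(TRUE, 20))
  expect_true(all(abs(tt$t) < 1e-12))
})

test_that("the sd floor keeps t finite when within-group variance is zero", {
  set.seed(10)
  f <- matrix(runif(40), 4, 10)
  f[, 4:5] <- rep(c(0.2, 0.2, 0.7, 0.7), 2)  # raw sd 0 at sites 4 and 5
  tr <- make_track(f)
  tt <- compute_tstat(tr, design_for(tr), rep(TRUE, 10))
  expect_equal(tt$sd_raw[4:5], c(0, 0))
  expect_true(all(tt$sd > 0))                # floored at the 75% quantile
  expect_true(all(is.finite(tt$t)))
  expect_equal(tt$meanDiff[4:5], c(0.5, 0.5))
  expect_error(compute_tstat(tr, group_design(
    c("s1", "s2", "s3"), c("g1", "g1", "g2"), c("A", "A", "B")),
    rep(TRUE, 10)), "at least 2")
})

test_that("t statistics match a step-by-step oracle", {
  set.seed(42)
  f <- matrix(runif(6 * 120), 6, 120)
  tr <- make_track(f, genos = rep(c("A", "B"), each = 3))
  mask <- runif(120) < 0.8
  tt <- compute_tstat(tr, design_for(tr), mask)
  want <- oracle_tstat(tr$fitted, 1:3, 4:6, mask)
  expect_equal(tt$meanDiff, want$meanDiff, tolerance = 1e-12)
  expect_equal(tt$sd, want$sd, tolerance = 1e-12)
  expect_equal(tt$t, want$t, tolerance = 1e-12)
})

test_that("region finding obeys cutoff, sign, gaps and filters", {
  tt <- data.frame(chrom = "chr1",
                   pos = c(100L, 200L, 300L, 400L, 500L, 5000L),
                   meanDiff = c(rep(0.2, 5), 0.2),
                   t = c(5, 5, 5, 5, 5, 5))
  p <- dmr_params(cutoff = 4.6, maxGap = 300)
  r <- find_regions(tt, p)
  expect_equal(nrow(r), 1L)                 # far site split off, then dropped
  expect_equal(r$n_cpgs, 5L)
  expect_equal(r$areaStat, 25)
  expect_equal(r$direction, 1L)
  # nothing passes the cutoff
  tt$t <- rep(1, 6)
  expect_equal(nrow(find_regions(tt, p)), 0L)
  # meanDiff filter
  tt$t <- rep(5, 6)
  tt$meanDiff <- rep(0.05, 6)
  expect_equal(nrow(find_regions(tt, p)), 0L)
})

test_that("region finding matches the brute-force segmentation oracle", {
  set.seed(7)
  for (rep in 1:20) {
    n <- 150
    tt <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                     pos = sample.int(20000, n),
                     meanDiff = round(runif(n, -0.4, 0.4), 2),
                     t = round(rnorm(n, 0, 4), 2))
    tt <- tt[order(tt$chrom, tt$pos), ]
    rownames(tt) <- NULL
    p <- dmr_params(cutoff = 3, maxGap = 500, min_cpgs = 2,
                    min_meandiff = 0.05)
    got <- find_regions(tt, p)
    want <- oracle_find_regions(tt, p)
    expect_equal(got[names(want)], want, ignore_attr = TRUE)
  }
})

test_that("flipping every t sign flips regions but keeps their extent", {
  set.seed(11)
  tt <- data.frame(chrom = "chr1", pos = sort(sample.int(30000, 200)),
                   meanDiff = rnorm(200, 0, 0.2), t = rnorm(200, 0, 4))
  p <- dmr_params(cutoff = 3, maxGap = 1000, min_cpgs = 2,
                  min_meandiff = 0)
  r1 <- find_regions(tt, p)
  tt2 <- tt
  tt2$t <- -tt2$t
  tt2$meanDiff <- -tt2$meanDiff
  r2 <- find_regions(tt2, p)
  expect_equal(r1[c("chrom", "start", "end", "n_cpgs")],
               r2[c("chrom", "start", "end", "n_cpgs")])
  expect_equal(r1$direction, -r2$direction)
  expect_equal(r1$areaStat, -r2$areaStat)
})

test_that("balanced permutation counts follow the enumeration", {
  d22 <- group_design(sprintf("s%d", 1:4), rep(c("g1", "g2"), each = 2),
                      rep(c("A", "B"), each = 2))
  expect_length(balanced_permutations(d22), 2L)
  d66 <- group_design(sprintf("s%d", 1:12), rep(c("g1", "g2"), each = 6),
                      rep(c("A", "B"), each = 6))
  expect_length(balanced_permutations(d66), 200L)
  # brute-force enumeration oracle for the 6+6 case
  all_g1 <- utils::combn(12, 6, simplify = FALSE)
  balanced <- Filter(function(s) sum(s <= 6) == 3, all_g1)
  canon <- unique(lapply(balanced, function(s)
    if (1 %in% s) sort(s) else sort(setdiff(1:12, s))))
  expect_length(canon, 200L)
  expect_error(balanced_permutations(group_design(
    sprintf("s%d", 1:6), rep(c("g1", "g2"), each = 3),
    c("A", "A", "A", "B", "B", "B"))), "even|equal")
})

test_that("an observed balanced assignment is excluded from the null set", {
  # mixed design: each group holds one sample of each genotype
  d <- group_design(sprintf("s%d", 1:4), c("g1", "g2", "g1", "g2"),
                    c("A", "A", "B", "B"))
  perms <- balanced_permutations(d)
  expect_length(perms, 1L)                 # C(2,1)^2/2 - 1
  expect_false(any(vapply(perms, function(p)
    all(p == d$group), logical(1))))
})

test_that("permuting with the observed labels reproduces observed regions", {
  set.seed(3)
  f <- matrix(runif(8 * 100), 8, 100)
  f[5:8, 40:50] <- f[5:8, 40:50] + 0.5
  tr <- make_track(f)
  d <- design_for(tr)
  mask <- rep(TRUE, 100)
  p <- dmr_params(cutoff = 2, maxGap = 1000, min_cpgs = 2,
                  min_meandiff = 0.05)
  obs <- find_regions(compute_tstat(tr, d, mask), p)
  nulls <- null_regions(tr, d, mask, p)
  expect_equal(obs, nulls)
})

test_that("gFWER counts permutations with a dominating null region", {
  obs <- data.frame(chrom = "chr1", start = c(1L, 100L), end = c(50L, 150L),
                    n_cpgs = c(10L, 4L), meanDiff = c(0.3, 0.2),
                    areaStat = c(60, -18), direction = c(1L, -1L),
                    gFWER = NA_real_)
  null_strong <- data.frame(chrom = "chr1", start = 1L, end = 9L,
                            n_cpgs = 12L, meanDiff = 0.1, areaStat = -70,
                            direction = -1L)
  null_weak <- data.frame(chrom = "chr1", start = 1L, end = 9L,
                          n_cpgs = 5L, meanDiff = 0.1, areaStat = 20,
                          direction = 1L)
  empty <- null_strong[0, ]
  out <- assign_gfwer(obs, rep(list(empty), 18))
  expect_equal(out$gFWER, c(0, 0))
  out <- assign_gfwer(obs, c(list(null_strong), rep(list(empty), 17)))
  expect_equal(out$gFWER, c(1 / 18, 1 / 18))
  out <- assign_gfwer(obs, c(list(null_weak), rep(list(empty), 17)))
  expect_equal(out$gFWER, c(0, 1 / 18))    # dominates only the small DMR
  expect_error(assign_gfwer(obs, list()), "permutation")
})

test_that("gFWER is monotone in region strength against random null sets", {
  set.seed(19)
  nulls <- lapply(1:25, function(i) {
    k <- sample(0:5, 1)
    data.frame(chrom = rep("chr1", k), start = seq_len(k), end = seq_len(k),
               n_cpgs = sample(1:30, k, replace = TRUE),
               meanDiff = runif(k, -0.5, 0.5),
               areaStat = rnorm(k, 0, 40),
               direction = rep(1L, k))
  })
  obs <- data.frame(chrom = "chr1", start = 1:40, end = 1:40,
                    n_cpgs = sample(1:30, 40, replace = TRUE),
                    meanDiff = 0.2, areaStat = rnorm(40, 0, 40),
                    direction = 1L, gFWER = NA_real_)
  out <- assign_gfwer(obs, nulls)
  for (i in 1:39) for (k in (i + 1):40) {
    if (out$n_cpgs[i] >= out$n_cpgs[k] &&
        abs(out$areaStat[i]) >= abs(out$areaStat[k]))
      expect_lte(out$gFWER[i], out$gFWER[k])
  }
})
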