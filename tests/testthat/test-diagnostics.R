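two_geno_matrix <- function() {
  make_matrix(list(
    list(id = "a1", geno = "A", pos = c(10L, 20L, 30L, 40L),
         M = c(10L, 0L, 5L, 0L), Cov = c(10L, 10L, 10L, 0L)),
    list(id = "a2", geno = "A", pos = c(10L, 20L, 30L, 40L),
         M = c(8L, 2L, 5L, 0L), Cov = c(10L, 10L, 10L, 0L)),
    list(id = "b1", geno = "B", pos = c(10L, 20L, 50L),
         M = c(9L, 1L, 10L), Cov = c(10L, 10L, 10L)),
    list(id = "b2", geno = "B", pos = c(10L, 20L, 50L),
         M = c(9L, 3L, 8L), Cov = c(10L, 10L, 10L))))
}

test_that("global methylation averages proportions over covered sites", {
  mm <- make_matrix(list(
    list(id = "a1", geno = "A", pos = c(10L, 20L, 30L),
         M = c(10L, 0L, 0L), Cov = c(10L, 10L, 0L))))
  expect_equal(unname(global_methylation(mm)["a1"]), 0.5)
  # adding zero-coverage sites does not change the value
  mm2 <- make_matrix(list(
    list(id = "a1", geno = "A", pos = c(10L, 20L, 30L, 35L),
         M = c(10L, 0L, 0L, 0L), Cov = c(10L, 10L, 0L, 0L))))
  expect_equal(global_methylation(mm2), global_methylation(mm))
  # brute force on a random matrix
  set.seed(4)
  specs <- lapply(1:3, function(i)
    list(id = paste0("s", i), geno = "A", pos = seq(10L, 300L, by = 10L),
         M = integer(30), Cov = sample(0:5, 30, replace = TRUE)))
  for (i in 1:3) specs[[i]]$M <- vapply(specs[[i]]$Cov, function(cv)
    if (cv) sample(0:cv, 1L) else 0L, integer(1))
  mm3 <- make_matrix(specs)
  gm <- global_methylation(mm3)
  for (i in 1:3) {
    k <- mm3$Cov[i, ] >= 1
    expect_equal(unname(gm[i]), mean(mm3$M[i, k] / mm3$Cov[i, k]))
  }
})

test_that("category means restrict the global mean and recompose it", {
  mm <- two_geno_matrix()
  cls <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
                    category = factor(c("COMMON_CG", "COMMON_CG", "TG_CA",
                                        "OTHER_MUT"),
                                      levels = methdiverge:::CPG_CATEGORIES),
                    mapped_pos = NA_integer_)
  cm <- category_methylation(mm, cls)
  a1 <- cm[cm$sample_id == "a1", ]
  expect_equal(a1$mean_meth[a1$category == "COMMON_CG"], 0.5)
  expect_equal(a1$mean_meth[a1$category == "TG_CA"], 0.5)
  expect_equal(a1$n_covered[a1$category == "OTHER_MUT"], 0L)
  expect_true(is.na(a1$mean_meth[a1$category == "OTHER_MUT"]))
  # covered-count-weighted category means recompose the global mean
  gm <- global_methylation(mm)
  for (id in mm$samples$sample_id) {
    rows <- cm[cm$sample_id == id & cm$n_covered > 0, ]
    expect_equal(sum(rows$mean_meth * rows$n_covered) / sum(rows$n_covered),
                 unname(gm[id]))
  }
})

test_that("wrong-reference simulation zeroes reference-unique TG/CA calls", {
  mm <- two_geno_matrix()
  # site 30 is A-unique TG_CA, site 40 A-unique OTHER_MUT, site 50 B-unique
  cls <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
                    category = factor(c("COMMON_CG", "COMMON_CG", "TG_CA",
                                        "OTHER_MUT"),
                                      levels = methdiverge:::CPG_CATEGORIES),
                    mapped_pos = NA_integer_)
  set.seed(6)
  wr <- simulate_wrong_reference(mm, cls, "A")
  iA <- 1:2; iB <- 3:4
  expect_equal(wr$M[iA, ], mm$M[iA, ])     # reference samples untouched
  j30 <- which(mm$sites$pos == 30L)
  j50 <- which(mm$sites$pos == 50L)
  expect_true(all(wr$M[iB, j30] == 0L))
  expect_true(all(wr$Cov[iB, j30] > 0L))   # coverage drawn, calls all-U
  expect_true(all(wr$Cov[iB, j50] == 0L))  # own-unique data removed
  # identity when there are no unique sites
  mm2 <- make_matrix(list(
    list(id = "a1", geno = "A", pos = c(10L, 20L), M = c(1L, 2L),
         Cov = c(5L, 5L)),
    list(id = "b1", geno = "B", pos = c(10L, 20L), M = c(3L, 4L),
         Cov = c(5L, 5L))))
  cls2 <- data.frame(chrom = "chr1", pos = c(10L, 20L),
                     category = factor(rep("COMMON_CG", 2),
                                       levels = methdiverge:::CPG_CATEGORIES),
                     mapped_pos = c(10L, 20L))
  expect_equal(simulate_wrong_reference(mm2, cls2, "A"), mm2)
})

test_that("wrong-reference bias matches its analytic expectation", {
  # f = fraction of A-unique TG_CA sites among B's scored sites; the biased
  # global methylation is (1 - f) * m, with m the true mean
  n_shared <- 400; n_unique <- 100
  pos_shared <- seq(10L, by = 20L, length.out = n_shared)
  pos_unique <- seq(15L, by = 20L, length.out = n_unique)
  m_true <- 0.8
  mk <- function(id, geno, pos) {
    list(id = id, geno = geno, pos = sort(pos),
         M = as.integer(rep(10L * m_true, length(pos))),
         Cov = rep(10L, length(pos)))
  }
  mm <- make_matrix(list(mk("a1", "A", c(pos_shared, pos_unique)),
                         mk("b1", "B", pos_shared)), chrom_len = 20000L)
  cls <- data.frame(chrom = "chr1",
                    pos = sort(c(pos_shared, pos_unique)),
                    category = factor(
                      ifelse(sort(c(pos_shared, pos_unique)) %in% pos_unique,
                             "TG_CA", "COMMON_CG"),
                      levels = methdiverge:::CPG_CATEGORIES),
                    mapped_pos = NA_integer_)
  set.seed(8)
  wr <- simulate_wrong_reference(mm, cls, "A")
  f <- n_unique / (n_shared + n_unique)
  expect_equal(unname(global_methylation(wr)["b1"]), (1 - f) * m_true,
               tolerance = 0.02)
  expect_equal(unname(global_methylation(wr)["a1"]), m_true)
})

test_that("variation filtering restores global methylation exactly", {
  cfg <- sim_config(genome_length = 1e5, n_dmrs_shared = 1,
                    n_dmrs_unique = 1, seed = 13)
  sim <- simulate_dataset(cfg)
  mm <- to_common_coordinates(sim$samples, sim$maps, "A")
  set.seed(14)
  wr <- simulate_wrong_reference(mm, sim$classification, "A")
  a_unique <- sim$classification[sim$classification$category != "COMMON_CG",
                                 c("chrom", "pos")]
  b_unique <- mm$sites[mm$present["B", ] & !mm$present["A", ], ]
  filt_wr <- filter_variant_cpgs(filter_variant_cpgs(wr, a_unique), b_unique)
  filt_ok <- filter_variant_cpgs(filter_variant_cpgs(mm, a_unique), b_unique)
  expect_equal(global_methylation(filt_wr), global_methylation(filt_ok),
               tolerance = 1e-12)
})

test_that("raw region differences pool counts within groups", {
  mm <- two_geno_matrix()
  d <- group_design(mm$samples$sample_id, mm$samples$genotype,
                    mm$samples$genotype)
  region <- list(chrom = "chr1", start = 5L, end = 60L)
  # shared sites 10, 20: pooled props A (18/20, 2/20), B (18/20, 4/20)
  expect_equal(raw_region_diff(mm, region, "shared", d), mean(c(0, 0.1)))
  # identical counts in both groups give zero difference
  mm0 <- make_matrix(list(
    list(id = "a1", geno = "A", pos = 10L, M = 4L, Cov = 8L),
    list(id = "b1", geno = "B", pos = 10L, M = 4L, Cov = 8L)))
  d0 <- group_design(c("a1", "b1"), c("A", "B"), c("A", "B"))
  expect_equal(raw_region_diff(mm0, region, "all", d0), 0)
  # single site with group proportions 0.9 vs 0.4
  mm1 <- make_matrix(list(
    list(id = "a1", geno = "A", pos = 10L, M = 4L, Cov = 10L),
    list(id = "b1", geno = "B", pos = 10L, M = 9L, Cov = 10L)))
  expect_equal(raw_region_diff(mm1, region, "all", d0), 0.5)
})

test_that("unique-site differences use each group's own unique CpGs", {
  mm <- two_geno_matrix()
  d <- group_design(mm$samples$sample_id, mm$samples$genotype,
                    mm$samples$genotype)
  region <- list(chrom = "chr1", start = 5L, end = 60L)
  # A-unique covered site 30: pooled A prop 0.5; B-unique site 50: 0.9
  expect_equal(raw_region_diff(mm, region, "unique", d), 0.9 - 0.5)
  disp <- unique_shared_disparity(mm, region, d)
  expect_equal(disp, 0.4 - 0.05)
  # swapping the group labels flips the sign
  d2 <- group_design(mm$samples$sample_id,
                     factor(mm$samples$genotype, levels = c("B", "A")),
                     mm$samples$genotype)
  expect_equal(unique_shared_disparity(mm, region, d2), -disp)
})

test_that("disparity arithmetic on constructed unique and shared diffs", {
  # unique diffs {0.5, 0.3} -> mean 0.4; shared diffs {0.1, 0.1} -> 0.1
  mm <- make_matrix(list(
    list(id = "a1", geno = "A", pos = c(10L, 20L, 30L, 40L),
         M = c(4L, 4L, 0L, 2L), Cov = c(10L, 10L, 0L, 10L)),
    list(id = "b1", geno = "B", pos = c(10L, 20L, 31L, 41L),
         M = c(5L, 5L, 7L, 9L), Cov = c(10L, 10L, 10L, 10L))))
  d <- group_design(c("a1", "b1"), c("A", "B"), c("A", "B"))
  region <- list(chrom = "chr1", start = 1L, end = 100L)
  # B-unique sites 31, 41 have props 0.7, 0.9; A-unique 30, 40: 30 has no
  # coverage, 40 has 0.2 -> unique diff = mean(0.7, 0.9) - 0.2 = 0.6
  expect_equal(raw_region_diff(mm, region, "unique", d), 0.6)
  expect_equal(raw_region_diff(mm, region, "shared", d), 0.1)
  expect_equal(unique_shared_disparity(mm, region, d), 0.5)
  # missing subsets propagate NA with a reason
  region_empty <- list(chrom = "chr1", start = 900L, end = 950L)
  expect_true(is.na(unique_shared_disparity(mm, region_empty, d)))
})
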