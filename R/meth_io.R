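# Per-sample methylation counts, the union count matrix in a common
# coordinate system, and the site filters.

#' Construct a per-sample methylation record
#'
#' @param sample_id sample identifier.
#' @param genotype genotype label.
#' @param data data.frame with `chrom`, `pos` (1-based forward-strand C
#'   positions), `M` (methylated reads) and `U` (unmethylated reads), unique
#'   and sorted within chromosome.
#' @return An object of class `sample_meth`.
#' @export
sample_meth <- function(sample_id, genotype, data) {
  stopifnot(all(c("chrom", "pos", "M", "U") %in% names(data)))
  if (any(data$M < 0L) || any(data$U < 0L)) stop("counts must be >= 0")
  data <- data[order(data$chrom, data$pos), , drop = FALSE]
  if (any(duplicated(data[c("chrom", "pos")])))
    stop("duplicate positions in sample ", sample_id)
  rownames(data) <- NULL
  structure(list(sample_id = sample_id, genotype = genotype, data = data),
            class = "sample_meth")
}

#' Read Bismark methylation counts
#'
#' Supports the Bismark coverage format (`chrom start end pct_meth count_M
#' count_U`, 1-based) and the cytosine/CpG report (`chrom pos strand count_M
#' count_U context ...`). Reverse-strand records at position `p` are folded
#' into the forward-strand CpG at `p - 1` by summing counts, so the output
#' has one record per CpG. In a cytosine report the strand column identifies
#' reverse-strand rows and non-CpG contexts are skipped; in the coverage
#' format a record at `p + 1` immediately following one at `p` must be the
#' reverse-strand G (two adjacent forward-strand CpG Cs are impossible), and
#' isolated reverse-strand records can additionally be recognised by passing
#' the known C positions via `cpgs`.
#'
#' @param path counts file.
#' @param dialect `"coverage"` or `"cpg_report"`.
#' @param sample_id,genotype labels attached to the result.
#' @param cpgs optional data.frame `chrom`, `pos` of known forward-strand C
#'   positions, used to fold isolated reverse-strand coverage records.
#' @return A `sample_meth`.
#' @export
read_bismark <- function(path, dialect = c("coverage", "cpg_report"),
                         sample_id = basename(path), genotype = NA_character_,
                         cpgs = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (dialect == "coverage") {
    bad <- which(nf < 6L)
    if (length(bad))
      stop("malformed coverage line ", bad[1L], " in ", path)
    df <- data.frame(chrom = vapply(f, `[`, character(1), 1L),
                     pos = as.integer(vapply(f, `[`, character(1), 2L)),
                     M = as.integer(vapply(f, `[`, character(1), 5L)),
                     U = as.integer(vapply(f, `[`, character(1), 6L)))
    if (anyNA(df$pos) || anyNA(df$M) || anyNA(df$U))
      stop("non-numeric field in coverage file ", path)
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    # fold p+1 into p when p is present (adjacent records are the two strands)
    prev_same <- c(FALSE, df$chrom[-1L] == df$chrom[-nrow(df)] &
                     df$pos[-1L] == df$pos[-nrow(df)] + 1L)
    # an isolated record whose position-1 is a known C is reverse-strand
    if (!is.null(cpgs)) {
      iso_rev <- !prev_same &
        paste(df$chrom, df$pos - 1L) %in% paste(cpgs$chrom, cpgs$pos) &
        !paste(df$chrom, df$pos) %in% paste(cpgs$chrom, cpgs$pos)
      df$pos[iso_rev] <- df$pos[iso_rev] - 1L
      df <- df[order(df$chrom, df$pos), , drop = FALSE]
      prev_same <- c(FALSE, df$chrom[-1L] == df$chrom[-nrow(df)] &
                       df$pos[-1L] == df$pos[-nrow(df)] + 1L)
    }
    df$pos[prev_same] <- df$pos[prev_same] - 1L
  } else {
    bad <- which(nf < 5L)
    if (length(bad))
      stop("malformed cytosine-report line ", bad[1L], " in ", path)
    ctx <- ifelse(nf >= 6L, vapply(f, `[`, character(1), 6L), "CG")
    keep <- ctx %in% c("CG", "CpG")
    f <- f[keep]
    strand <- vapply(f, `[`, character(1), 3L)
    df <- data.frame(chrom = vapply(f, `[`, character(1), 1L),
                     pos = as.integer(vapply(f, `[`, character(1), 2L)),
                     M = as.integer(vapply(f, `[`, character(1), 4L)),
                     U = as.integer(vapply(f, `[`, character(1), 5L)))
    if (anyNA(df$pos) || anyNA(df$M) || anyNA(df$U))
      stop("non-numeric field in cytosine report ", path)
    df$pos[strand == "-"] <- df$pos[strand == "-"] - 1L
  }
  agg <- stats::aggregate(df[c("M", "U")], df[c("chrom", "pos")], sum)
  sample_meth(sample_id, genotype, agg)
}

#' Write a sample as a Bismark coverage file
#'
#' One folded record per CpG (forward-strand C position); the percentage
#' column is `100 * M / (M + U)` and zero-coverage sites are written with 0.
#'
#' @param sample a `sample_meth`.
#' @param path output file.
#' @export
write_bismark_cov <- function(sample, path) {
  d <- sample$data
  cov <- d$M + d$U
  pct <- ifelse(cov > 0L, 100 * d$M / cov, 0)
  writeLines(paste(d$chrom, d$pos, d$pos, formatC(pct, format = "fg"),
                   d$M, d$U, sep = "\t"), path)
  invisible(path)
}

#' Lift all samples into a common coordinate system
#'
#' Each sample's sites are lifted from its genotype's coordinates into the
#' target genotype's coordinates. All genotype coordinate systems are related
#' to a common reference through `maps`: `maps[[g]]` is the `coord_map`
#' between the reference ("A" side) and genotype `g` ("B" side); a `NULL`
#' entry means genotype `g` *is* the reference. A sample of genotype `g` is
#' lifted `g -> reference -> target`; sites unmappable at either step are
#' dropped for that sample (the discard rule). The matrix site list is the
#' union over samples; entries without data have zero coverage, and a
#' per-site annotation records which genotypes contributed data.
#'
#' @param samples list of `sample_meth`.
#' @param maps named list of `coord_map` (or `NULL`), one entry per genotype
#'   present among the samples.
#' @param target_genotype the genotype whose coordinates the matrix uses.
#' @return An object of class `meth_matrix`: list with `sites` (data.frame
#'   `chrom`, `pos`, sorted), `M` and `Cov` (samples x sites integer
#'   matrices), `samples` (data.frame `sample_id`, `genotype`) and `present`
#'   (genotypes x sites logical matrix).
#' @export
to_common_coordinates <- function(samples, maps, target_genotype) {
  genos <- vapply(samples, function(s) s$genotype, character(1))
  missing_g <- setdiff(unique(c(genos, target_genotype)), names(maps))
  if (length(missing_g))
    stop("no coordinate map for genotype(s): ",
         paste(missing_g, collapse = ", "))
  lift_one <- function(s) {
    d <- s$data
    out <- vector("list", length(unique(d$chrom)))
    chs <- unique(d$chrom)
    for (k in seq_along(chs)) {
      ch <- chs[k]
      dd <- d[d$chrom == ch, , drop = FALSE]
      pos <- dd$pos
      keep <- rep(TRUE, length(pos))
      # genotype coords -> reference coords
      if (!is.null(maps[[s$genotype]])) {
        ms <- map_sites(maps[[s$genotype]], ch, pos, "b2a")
        keep <- pos %in% ms$mapped$pos
        pos <- ms$mapped$mapped_pos
      }
      dd <- dd[keep, , drop = FALSE]
      # reference coords -> target coords
      if (!is.null(maps[[target_genotype]])) {
        o <- order(pos)
        dd <- dd[o, , drop = FALSE]; pos <- pos[o]
        ms <- map_sites(maps[[target_genotype]], ch, pos, "a2b")
        keep2 <- pos %in% ms$mapped$pos
        dd <- dd[keep2, , drop = FALSE]
        pos <- ms$mapped$mapped_pos
      }
      dd$pos <- pos
      out[[k]] <- dd
    }
    do.call(rbind, out)
  }
  lifted <- lapply(samples, lift_one)
  all_sites <- unique(do.call(rbind,
                              lapply(lifted, function(d) d[c("chrom", "pos")])))
  all_sites <- all_sites[order(all_sites$chrom, all_sites$pos), , drop = FALSE]
  rownames(all_sites) <- NULL
  key <- paste(all_sites$chrom, all_sites$pos)
  ns <- length(samples); np <- nrow(all_sites)
  M <- matrix(0L, ns, np)
  Cov <- matrix(0L, ns, np)
  glev <- unique(genos)
  present <- matrix(FALSE, length(glev), np, dimnames = list(glev, NULL))
  for (i in seq_len(ns)) {
    d <- lifted[[i]]
    j <- match(paste(d$chrom, d$pos), key)
    M[i, j] <- as.integer(d$M)
    Cov[i, j] <- as.integer(d$M + d$U)
    present[genos[i], j] <- TRUE
  }
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  rownames(M) <- rownames(Cov) <- ids
  structure(list(sites = all_sites, M = M, Cov = Cov,
                 samples = data.frame(sample_id = ids, genotype = genos),
                 present = present,
                 target_genotype = target_genotype),
            class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat("meth_matrix:", nrow(x$sites), "sites x", nrow(x$samples), "samples",
      "in", x$target_genotype, "coordinates\n")
  cat("genotypes:", paste(rownames(x$present), collapse = ", "), "\n")
  cat("shared sites:", sum(colSums(!x$present) == 0L), "\n")
  invisible(x)
}

subset_sites <- function(matrix, keep) {
  matrix$sites <- matrix$sites[keep, , drop = FALSE]
  rownames(matrix$sites) <- NULL
  matrix$M <- matrix$M[, keep, drop = FALSE]
  matrix$Cov <- matrix$Cov[, keep, drop = FALSE]
  matrix$present <- matrix$present[, keep, drop = FALSE]
  matrix
}

#' Restrict a matrix to CpGs shared by all genotypes
#'
#' The "unique-removed" analysis mode: keep only sites present in every
#' genotype. `mode = "unique-included"` is the identity.
#'
#' @param matrix a `meth_matrix`.
#' @param mode `"unique-removed"` or `"unique-included"`.
#' @return A `meth_matrix`.
#' @export
restrict_to_shared <- function(matrix,
                               mode = c("unique-removed", "unique-included")) {
  mode <- match.arg(mode)
  if (mode == "unique-included") return(matrix)
  subset_sites(matrix, colSums(!matrix$present) == 0L)
}

#' Remove per-sample heterozygous CpG sites
#'
#' For each sample, sets coverage and methylated counts to zero at its
#' heterozygous sites; the sites stay in the matrix for other samples.
#'
#' @param matrix a `meth_matrix`.
#' @param het_sites named list (by sample id) of data.frames `chrom`, `pos`
#'   in the matrix's coordinate system.
#' @return A `meth_matrix`.
#' @export
filter_heterozygous <- function(matrix, het_sites) {
  key <- paste(matrix$sites$chrom, matrix$sites$pos)
  for (id in names(het_sites)) {
    i <- match(id, matrix$samples$sample_id)
    if (is.na(i)) next
    h <- het_sites[[id]]
    if (is.null(h) || !nrow(h)) next
    j <- match(paste(h$chrom, h$pos), key)
    j <- j[!is.na(j)]
    matrix$M[i, j] <- 0L
    matrix$Cov[i, j] <- 0L
  }
  matrix
}

#' Remove variant-overlapping CpG sites from all samples
#'
#' The "variation filtering" strategy: listed sites are removed from the
#' matrix entirely. Duplicate positions in the list are harmless.
#'
#' @param matrix a `meth_matrix`.
#' @param variant_cpgs data.frame `chrom`, `pos` in the matrix's coordinate
#'   system.
#' @return A `meth_matrix`.
#' @export
filter_variant_cpgs <- function(matrix, variant_cpgs) {
  if (is.null(variant_cpgs) || !nrow(variant_cpgs)) return(matrix)
  drop <- paste(matrix$sites$chrom, matrix$sites$pos) %in%
    paste(variant_cpgs$chrom, variant_cpgs$pos)
  subset_sites(matrix, !drop)
}

#' Coverage-based analysis mask
#'
#' A site is analysable when each of the two groups has at least
#' `min_samples_per_group` samples with coverage at least `min_cov`. In a
#' genotype-vs-genotype design, genotype-unique sites are automatically
#' masked out because one group has zero coverage.
#'
#' @param matrix a `meth_matrix`.
#' @param design a [group_design()] (or data.frame `sample_id`, `group`).
#' @param min_cov minimum per-sample coverage.
#' @param min_samples_per_group minimum qualifying samples per group.
#' @return Logical vector over the matrix sites.
#' @export
coverage_mask <- function(matrix, design, min_cov = 2,
                          min_samples_per_group = 3) {
  idx <- split(match(design$sample_id, matrix$samples$sample_id),
               design$group)
  if (length(idx) != 2L) stop("design must define exactly two groups")
  if (any(lengths(idx) < min_samples_per_group))
    stop("min_samples_per_group exceeds a group size")
  ok <- lapply(idx, function(i)
    colSums(matrix$Cov[i, , drop = FALSE] >= min_cov) >=
      min_samples_per_group)
  ok[[1L]] & ok[[2L]]
}

#' Two-group sample design
#'
#' @param sample_id character vector of sample ids.
#' @param group group label per sample (coerced to factor; exactly two
#'   levels). The first level is "group1": differences are reported as
#'   group2 minus group1.
#' @param genotype genotype label per sample.
#' @return data.frame of class `group_design`.
#' @export
group_design <- function(sample_id, group, genotype) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("design must have exactly two groups")
  structure(data.frame(sample_id = sample_id, group = group,
                       genotype = genotype),
            class = c("group_design", "data.frame"))
}

#' Serialize a methylation matrix as long-form TSV
#'
#' Columns `chrom  pos  sample  M  Cov`; only entries with `Cov > 0` or
#' sites carried as zero-coverage placeholders are written (all entries, to
#' make the round trip exact). Presence annotations are rebuilt on read from
#' the genotype labels in `samples_tsv`.
#'
#' @param matrix a `meth_matrix`.
#' @param path output TSV.
#' @export
write_meth_matrix <- function(matrix, path) {
  ns <- nrow(matrix$samples); np <- nrow(matrix$sites)
  df <- data.frame(chrom = rep(matrix$sites$chrom, each = ns),
                   pos = rep(matrix$sites$pos, each = ns),
                   sample = rep(matrix$samples$sample_id, np),
                   genotype = rep(matrix$samples$genotype, np),
                   M = as.vector(matrix$M),
                   Cov = as.vector(matrix$Cov),
                   present = as.vector(
                     matrix$present[matrix$samples$genotype, , drop = FALSE]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_meth_matrix
#' @export
read_meth_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  sites <- unique(df[c("chrom", "pos")])
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  key <- paste(sites$chrom, sites$pos)
  samp <- unique(df[c("sample", "genotype")])
  ns <- nrow(samp); np <- nrow(sites)
  M <- matrix(0L, ns, np, dimnames = list(samp$sample, NULL))
  Cov <- matrix(0L, ns, np, dimnames = list(samp$sample, NULL))
  glev <- unique(samp$genotype)
  present <- matrix(FALSE, length(glev), np, dimnames = list(glev, NULL))
  i <- match(df$sample, samp$sample)
  j <- match(paste(df$chrom, df$pos), key)
  M[cbind(i, j)] <- as.integer(df$M)
  Cov[cbind(i, j)] <- as.integer(df$Cov)
  pr <- df[df$present, , drop = FALSE]
  present[cbind(match(pr$genotype, glev),
                match(paste(pr$chrom, pr$pos), key))] <- TRUE
  structure(list(sites = sites, M = M, Cov = Cov,
                 samples = data.frame(sample_id = samp$sample,
                                      genotype = samp$genotype),
                 present = present, target_genotype = NA_character_),
            class = "meth_matrix")
}
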