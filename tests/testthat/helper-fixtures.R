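# Small programmatic fixtures shared across test files.

# build a meth_matrix through the public API: each sample lists its own
# sites (zero-coverage sites included, like a CpG report), identity maps
make_matrix <- function(specs, chrom_len = 100000L, target = NULL) {
  samples <- lapply(specs, function(s)
    sample_meth(s$id, s$geno,
                data.frame(chrom = if (!is.null(s$chrom)) s$chrom else "chr1",
                           pos = s$pos, M = s$M, U = s$Cov - s$M)))
  genos <- unique(vapply(specs, function(s) s$geno, character(1)))
  maps <- stats::setNames(
    rep(list(identity_map(c(chr1 = chrom_len))), length(genos)), genos)
  if (is.null(target)) target <- genos[1L]
  to_common_coordinates(samples, maps, target)
}

# random variant table for map round-trip properties (independent of the
# package's own generator)
random_variants <- function(seq_str, n_snv = 15, n_indel = 6, seed = 1) {
  set.seed(seed)
  L <- nchar(seq_str)
  s <- strsplit(seq_str, "")[[1L]]
  pos <- sort(sample(2:(L - 10L), n_snv + n_indel))
  occupied_end <- 0L
  rows <- NULL
  for (k in seq_along(pos)) {
    p <- pos[k]
    if (p <= occupied_end + 1L) next
    if (k <= n_snv) {
      alt <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
      rows <- rbind(rows, data.frame(chrom = "chr1", pos = p, ref = s[p],
                                     alt = alt, zygosity = "homozygous"))
      occupied_end <- p
    } else {
      len <- sample(1:4, 1L)
      if (runif(1) < 0.5) {   # deletion
        ref <- paste0(s[p:(p + len)], collapse = "")
        rows <- rbind(rows, data.frame(chrom = "chr1", pos = p, ref = ref,
                                       alt = s[p], zygosity = "homozygous"))
        occupied_end <- p + len
      } else {                # insertion
        ins <- paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                      collapse = "")
        rows <- rbind(rows, data.frame(chrom = "chr1", pos = p, ref = s[p],
                                       alt = paste0(s[p], ins),
                                       zygosity = "homozygous"))
        occupied_end <- p
      }
    }
  }
  rows
}

random_sequence <- function(L, seed = 1) {
  set.seed(seed)
  paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}
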