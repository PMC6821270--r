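# Synthetic data generator: toy genome pairs, variant sets and WGBS count
# data with known truth (planted DMRs, planted genotype-unique effects).

#' Simulation configuration
#'
#' Defaults describe the package's desk-scale two-genotype study: a 2 Mb
#' single-chromosome genome pair with about 20k CpGs (CpG start frequency
#' 0.01/bp), a 10% CpG mutation rate between the genotypes, matching
#' CpG gains so each genotype carries unique sites, four samples per
#' genotype at Poisson mean coverage 15, a baseline methylation level of
#' 0.72 with ~2 kb spatially autocorrelated fluctuation, and planted DMRs
#' of +0.40 methylation in genotype B.
#'
#' @param genome_length chromosome length in bp.
#' @param chrom chromosome name.
#' @param cpg_rate target frequency of forward-strand CG dinucleotide starts
#'   per bp (toy genomes are CpG-sparse like mammalian genomes).
#' @param cpg_mut_rate probability that a CpG of genotype A carries a
#'   CG-destroying SNV in B.
#' @param tgca_fraction fraction of CG-destroying SNVs that are the
#'   deamination signature C>T / G>A (split evenly between strands, giving
#'   TG or CA in B); the remainder are other substitutions ("lost" CpGs).
#' @param cpg_gain_rate expected number of B-unique CpGs (single-base gains
#'   at TG/CA positions of A) as a fraction of A's CpG count.
#' @param snv_rate background SNV probability per bp (placed away from CpG
#'   context so CpG gain/loss is governed by the two rates above).
#' @param indel_rate indel probability per bp; lengths uniform on
#'   `1..indel_max`.
#' @param indel_max maximum indel length in bp.
#' @param het_fraction fraction of variants marked heterozygous.
#' @param n_per_genotype samples per genotype.
#' @param mean_coverage Poisson mean per-site coverage.
#' @param baseline_meth baseline methylation level (fraction).
#' @param autocorr_bp correlation length of the latent methylation field.
#' @param noise_sd sd of the latent logit-scale fluctuation.
#' @param n_dmrs_shared number of planted shared-site DMRs.
#' @param dmr_cpgs shared CpGs per planted shared DMR.
#' @param dmr_delta methylation increase in genotype B inside planted DMRs.
#' @param n_dmrs_unique number of planted unique-site DMRs.
#' @param unique_dmr_cpgs B-unique CpGs planted per unique-site DMR.
#' @param unique_dmr_spacing spacing in bp between planted unique CpGs.
#' @param genotypes labels of the two genotypes; the first is the reference.
#' @param seed integer seed driving every stage.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 2e6, chrom = "chr1", cpg_rate = 0.01,
                       cpg_mut_rate = 0.10, tgca_fraction = 0.75,
                       cpg_gain_rate = 0.10,
                       snv_rate = 0.002, indel_rate = 1e-4, indel_max = 6,
                       het_fraction = 0, n_per_genotype = 4,
                       mean_coverage = 15, baseline_meth = 0.72,
                       autocorr_bp = 2000, noise_sd = 0.7,
                       n_dmrs_shared = 10, dmr_cpgs = 20, dmr_delta = 0.4,
                       n_dmrs_unique = 5, unique_dmr_cpgs = 25,
                       unique_dmr_spacing = 60,
                       genotypes = c("A", "B"), seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cpg_rate, cpg_mut_rate, cpg_gain_rate, snv_rate, indel_rate,
             het_fraction, baseline_meth)
  if (any(probs < 0 | probs > 1)) stop("rates must be in [0, 1]")
  if (mean_coverage <= 0) stop("mean_coverage must be positive")
  if (abs(dmr_delta) > 1) stop("dmr_delta must be in [-1, 1]")
  structure(cfg, class = "sim_config")
}

#' Simulate a CpG-sparse reference chromosome
#'
#' Draws a random sequence in which CG dinucleotides are suppressed, then
#' plants CG dinucleotides at the configured per-bp frequency, so the CpG
#' start frequency is approximately `cpg_rate`. Deterministic given the
#' seed.
#'
#' @param config a [sim_config()].
#' @param seed seed (default derived from the config).
#' @return Named character vector with one chromosome.
#' @export
simulate_reference <- function(config, seed = config$seed) {
  set.seed(seed)
  L <- as.integer(config$genome_length)
  s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  # suppress CG: replace the G of every C-G pair (cannot create new CGs)
  cg <- which(s[-L] == "C" & s[-1L] == "G")
  s[cg + 1L] <- sample(c("A", "T"), length(cg), replace = TRUE)
  # plant CGs at the target frequency, at least 2 bp apart
  cand <- which(stats::runif(L - 2L) < config$cpg_rate) + 1L
  if (length(cand) > 1L)
    cand <- cand[c(TRUE, diff(cand) >= 2L)]
  s[cand] <- "C"
  s[cand + 1L] <- "G"
  stats::setNames(paste0(s, collapse = ""), config$chrom)
}

# positions where a single substitution in B creates a CG absent from A:
# either base2 is already G (mutate base1 to C) or base1 is already C
# (mutate base2 to G); avoids positions at or adjacent to existing CpGs.
gain_variant_at <- function(s_vec, p) {
  if (s_vec[p + 1L] == "G" && s_vec[p] != "C")
    return(list(pos = p, ref = s_vec[p], alt = "C"))
  if (s_vec[p] == "C" && s_vec[p + 1L] != "G")
    return(list(pos = p + 1L, ref = s_vec[p + 1L], alt = "G"))
  NULL
}

#' Simulate a variant set for genotype B relative to the reference
#'
#' Places CG-destroying SNVs at CpGs of the reference (C>T forward and G>A
#' reverse, split evenly so both TG and CA arise), CG-creating gains at
#' TG/CA-like positions, background SNVs away from CpG context, and
#' non-overlapping indels; a configured fraction of variants is marked
#' heterozygous. `forced_gains` (bp positions) lets callers plant dense
#' B-unique CpGs inside chosen regions. Deterministic given the seed.
#'
#' @param reference genome from [simulate_reference()].
#' @param config a [sim_config()].
#' @param forced_gains integer positions at which to force CpG gains.
#' @param seed seed.
#' @return A variant table (see [validate_variants()]).
#' @export
simulate_variants <- function(reference, config, forced_gains = integer(0),
                              seed = config$seed + 1L) {
  set.seed(seed)
  ch <- names(reference)[1L]
  s <- reference[[ch]]
  s_vec <- strsplit(s, "")[[1L]]
  L <- length(s_vec)
  cpgs <- find_cpgs(s)
  vs <- list()
  add <- function(pos, ref, alt, prio)
    data.frame(pos = pos, ref = ref, alt = alt, prio = prio)
  # forced CpG gains (priority 1): take the nearest position at which a
  # single substitution creates a CG, so planted unique sites land reliably
  is_cpg_near <- function(q) any(cpgs %in% (q - 1L):(q + 1L))
  for (p in forced_gains) {
    for (off in as.integer(outer(c(0L, 1L), 0:15, function(a, b)
      ifelse(a == 0L, b, -b)))) {
      q <- p + off
      if (q < 2L || q > L - 2L || is_cpg_near(q)) next
      gv <- gain_variant_at(s_vec, q)
      if (!is.null(gv)) {
        vs[[length(vs) + 1L]] <- add(gv$pos, gv$ref, gv$alt, 1L)
        break
      }
    }
  }
  # CG-destroying SNVs at CpGs (priority 2): a fraction are the deamination
  # signature (C>T / G>A, giving TG or CA), the rest other substitutions
  hit <- cpgs[stats::runif(length(cpgs)) < config$cpg_mut_rate]
  if (length(hit)) {
    fwd <- stats::runif(length(hit)) < 0.5
    deam <- stats::runif(length(hit)) < config$tgca_fraction
    alt <- character(length(hit))
    alt[fwd & deam] <- "T"
    alt[!fwd & deam] <- "A"
    alt[fwd & !deam] <- sample(c("A", "G"), sum(fwd & !deam), replace = TRUE)
    alt[!fwd & !deam] <- sample(c("C", "T"), sum(!fwd & !deam),
                                replace = TRUE)
    vs[[length(vs) + 1L]] <- add(ifelse(fwd, hit, hit + 1L),
                                 ifelse(fwd, "C", "G"), alt, 2L)
  }
  # random CpG gains (priority 3)
  n_gain <- round(config$cpg_gain_rate * length(cpgs))
  if (n_gain > 0L) {
    cand <- sort(sample.int(L - 2L, min(6L * n_gain, L - 2L)) + 1L)
    near_cpg <- cand %in% c(cpgs - 1L, cpgs, cpgs + 1L)
    cand <- cand[!near_cpg]
    b1 <- s_vec[cand + 1L] == "G" & s_vec[cand] != "C"
    b2 <- !b1 & s_vec[cand] == "C" & s_vec[cand + 1L] != "G"
    cand <- cand[b1 | b2]
    take <- utils::head(seq_along(cand), n_gain)
    if (length(take)) {
      pos <- ifelse(b1[b1 | b2][take], cand[take], cand[take] + 1L)
      vs[[length(vs) + 1L]] <- add(pos, s_vec[pos],
                                   ifelse(b1[b1 | b2][take], "C", "G"), 3L)
    }
  }
  # background SNVs away from CpG context (priority 4)
  n_snv <- stats::rbinom(1L, L, config$snv_rate)
  if (n_snv > 0L) {
    p <- sort(sample(2:(L - 1L), n_snv))
    ref <- s_vec[p]
    alt <- vapply(ref, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    ctx_old <- paste0(s_vec[p - 1L], ref, s_vec[p + 1L])
    ctx_new <- paste0(s_vec[p - 1L], alt, s_vec[p + 1L])
    keep <- !grepl("CG", ctx_old) & !grepl("CG", ctx_new)
    if (any(keep))
      vs[[length(vs) + 1L]] <- add(p[keep], ref[keep], alt[keep], 4L)
  }
  # indels (priority 5)
  n_indel <- round(config$indel_rate * L)
  if (n_indel > 0L) {
    p <- sort(sample(2:(L - config$indel_max - 2L), n_indel))
    len <- sample.int(config$indel_max, n_indel, replace = TRUE)
    ins <- stats::runif(n_indel) < 0.5
    ref <- ifelse(ins, s_vec[p],
                  substring(s, p, p + len))
    alt <- ifelse(ins,
                  paste0(s_vec[p],
                         vapply(len, function(k)
                           paste0(sample(c("A", "C", "T"), k,
                                         replace = TRUE), collapse = ""),
                           character(1))),
                  s_vec[p])
    vs[[length(vs) + 1L]] <- add(p, ref, alt, 5L)
  }
  v <- do.call(rbind, vs)
  if (is.null(v) || !nrow(v))
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      zygosity = character(0)))
  # resolve overlaps: accept in priority order, tracked via base occupancy
  v <- v[order(v$prio, v$pos), , drop = FALSE]
  starts <- v$pos
  ends <- v$pos + nchar(v$ref) - 1L
  occ <- logical(L)
  accepted <- logical(nrow(v))
  for (k in seq_len(nrow(v))) {
    span <- starts[k]:ends[k]
    if (!any(occ[span])) {
      accepted[k] <- TRUE
      occ[span] <- TRUE
    }
  }
  v <- v[accepted, , drop = FALSE]
  v <- v[order(v$pos), , drop = FALSE]
  zyg <- ifelse(stats::runif(nrow(v)) < config$het_fraction,
                "heterozygous", "homozygous")
  data.frame(chrom = names(reference)[1L], pos = v$pos, ref = v$ref,
             alt = v$alt, zygosity = zyg, row.names = NULL)
}

# smooth latent methylation field over [1, L]: moving-average Gaussian noise
# on a 100 bp grid, logistic-transformed around the baseline level
latent_field <- function(L, baseline, autocorr_bp, noise_sd, seed) {
  set.seed(seed)
  grid <- 100
  n <- ceiling(L / grid) + 1L
  z <- stats::rnorm(n + 200L)
  k <- max(1L, round(autocorr_bp / grid))
  sm <- stats::filter(z, rep(1 / k, k), sides = 2)
  sm <- sm[!is.na(sm)][seq_len(n)]
  sm <- sm / stats::sd(sm) * noise_sd
  function(pos) stats::plogis(stats::qlogis(baseline) +
                                sm[pmin(n, pos %/% grid + 1L)])
}

#' Simulate the full two-genotype WGBS study
#'
#' Orchestrates the generator: reference genome, variant set, pseudogenome
#' and coordinate map, CpG classification in both directions, planted DMR
#' placement, latent methylation fields and per-sample binomial counts at
#' Poisson coverage. Samples carry every CpG of their own genome (including
#' zero-coverage sites) in their own genome's coordinates, like a Bismark
#' CpG report, so the downstream lift and union annotate genome presence
#' correctly. All stages are deterministic given `config$seed`.
#'
#' Planted truth: `n_dmrs_shared` regions of `dmr_cpgs` consecutive shared
#' CpGs get `+dmr_delta` methylation in genotype B at shared sites;
#' `n_dmrs_unique` regions get `unique_dmr_cpgs` planted B-unique CpGs
#' (spaced `unique_dmr_spacing` bp) carrying `+dmr_delta` in genotype B
#' while shared sites are untouched -- differential signal carried entirely
#' by genotype-unique CpGs.
#'
#' @param config a [sim_config()].
#' @return A list of class `meth_simulation` with elements `config`,
#'   `reference`, `personal` (genotype B genome), `map`, `variants`,
#'   `classification` (A CpGs vs B), `classification_b` (B CpGs vs A),
#'   `samples` (list of `sample_meth`), `design`, `maps` (ready for
#'   [to_common_coordinates()]) and `truth` (planted regions, reference
#'   coordinates).
#' @export
simulate_dataset <- function(config = sim_config()) {
  gA <- config$genotypes[1L]; gB <- config$genotypes[2L]
  ch <- config$chrom
  reference <- simulate_reference(config, config$seed)
  L <- nchar(reference[[ch]])

  # place unique-site DMR anchors away from edges, evenly spread
  set.seed(config$seed + 2L)
  nu <- config$n_dmrs_unique
  u_anchor <- if (nu > 0L)
    round(seq(0.12, 0.88, length.out = max(nu, 2L))[seq_len(nu)] * L) +
      sample.int(2000L, nu) else integer(0)
  u_span <- config$unique_dmr_cpgs * config$unique_dmr_spacing
  forced <- unlist(lapply(u_anchor, function(a)
    seq(a, by = config$unique_dmr_spacing,
        length.out = config$unique_dmr_cpgs)))

  variants <- simulate_variants(reference, config, forced_gains = forced,
                                seed = config$seed + 3L)
  pg <- build_pseudogenome(reference, variants, het_policy = "reference")
  personal <- pg$genome
  names(personal) <- ch
  cpgs_a <- data.frame(chrom = ch, pos = find_cpgs(reference[[ch]]))
  cpgs_b <- data.frame(chrom = ch, pos = find_cpgs(personal[[ch]]))
  cls <- classify_cross_genome(cpgs_a, pg$map, personal, "a2b")
  cls_b <- classify_cross_genome(cpgs_b, pg$map, reference, "b2a")

  # shared-site DMRs: runs of consecutive shared CpGs, kept clear of the
  # unique-site regions and of each other
  set.seed(config$seed + 4L)
  shared_pos <- cls$pos[cls$category == "COMMON_CG"]
  nsh <- config$n_dmrs_shared
  truth <- NULL
  occupied <- if (length(u_anchor))
    cbind(u_anchor - 20000L, u_anchor + u_span + 20000L) else
      matrix(numeric(0), 0, 2)
  if (nsh > 0L) {
    anchors <- round(seq(0.06, 0.94, length.out = max(nsh, 2L))[
      seq_len(nsh)] * L)
    for (a in anchors) {
      i0 <- findInterval(a, shared_pos)
      i0 <- min(max(i0, 1L), length(shared_pos) - config$dmr_cpgs + 1L)
      st <- shared_pos[i0]; en <- shared_pos[i0 + config$dmr_cpgs - 1L]
      if (any(st <= occupied[, 2] & en >= occupied[, 1])) next
      occupied <- rbind(occupied, c(st - 20000L, en + 20000L))
      truth <- rbind(truth, data.frame(chrom = ch, start = st, end = en,
                                       delta = config$dmr_delta,
                                       target = "shared"))
    }
  }
  if (nu > 0L)
    truth <- rbind(truth, data.frame(chrom = ch, start = u_anchor,
                                     end = u_anchor + u_span,
                                     delta = config$dmr_delta,
                                     target = "unique"))
  if (is.null(truth))
    truth <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), delta = numeric(0),
                        target = character(0))
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL

  # latent methylation: one shared smooth field in reference coordinates
  base_f <- latent_field(L, config$baseline_meth, config$autocorr_bp,
                         config$noise_sd, config$seed + 5L)
  latent_a <- base_f(cpgs_a$pos)
  b_in_a <- map_position(pg$map, ch, cpgs_b$pos, "b2a")
  latent_b <- base_f(ifelse(is.na(b_in_a), cpgs_b$pos, b_in_a))

  # genotype-B effect inside planted regions; the effect direction points
  # away from the saturation boundary (hypermethylation where the local
  # baseline is low, hypomethylation where it is high) so the planted
  # contrast is realisable on the probability scale
  shared_set <- shared_pos
  b_unique_in_a <- cls_b$pos[cls_b$category != "COMMON_CG"]  # B coords
  clamp <- function(x) pmin(pmax(x, 0.02), 0.98)
  if (nrow(truth)) {
    mid_level <- base_f(as.integer((truth$start + truth$end) / 2))
    truth$delta <- abs(truth$delta) * ifelse(mid_level > 0.5, -1, 1)
  }
  for (r in seq_len(nrow(truth))) {
    st <- truth$start[r]; en <- truth$end[r]; d <- truth$delta[r]
    if (truth$target[r] == "shared") {
      sel <- !is.na(b_in_a) & b_in_a >= st & b_in_a <= en &
        b_in_a %in% shared_set
    } else if (truth$target[r] == "unique") {
      sel <- cpgs_b$pos %in% b_unique_in_a &
        ((!is.na(b_in_a) & b_in_a >= st & b_in_a <= en) |
           (is.na(b_in_a) & cpgs_b$pos >= st & cpgs_b$pos <= en + 1000L))
    } else {
      sel <- (!is.na(b_in_a) & b_in_a >= st & b_in_a <= en) |
        (is.na(b_in_a) & cpgs_b$pos >= st & cpgs_b$pos <= en)
    }
    latent_b[sel] <- clamp(latent_b[sel] + d)
  }
  latent_a <- clamp(latent_a)
  latent_b_base <- clamp(latent_b)

  # per-sample counts (all CpGs of the own genome, own coordinates)
  set.seed(config$seed + 6L)
  samples <- list()
  mk <- function(id, geno, pos, latent) {
    cov <- stats::rpois(length(pos), config$mean_coverage)
    m <- stats::rbinom(length(pos), cov, latent)
    sample_meth(id, geno, data.frame(chrom = ch, pos = pos, M = m,
                                     U = cov - m))
  }
  for (i in seq_len(config$n_per_genotype))
    samples[[length(samples) + 1L]] <-
      mk(sprintf("%s_%d", gA, i), gA, cpgs_a$pos, latent_a)
  for (i in seq_len(config$n_per_genotype))
    samples[[length(samples) + 1L]] <-
      mk(sprintf("%s_%d", gB, i), gB, cpgs_b$pos, latent_b_base)

  ids <- vapply(samples, function(s) s$sample_id, character(1))
  genos <- vapply(samples, function(s) s$genotype, character(1))
  design <- group_design(ids, factor(genos, levels = c(gA, gB)), genos)
  maps <- stats::setNames(list(NULL, pg$map), c(gA, gB))

  structure(list(config = config, reference = reference,
                 personal = personal, map = pg$map, variants = variants,
                 classification = cls, classification_b = cls_b,
                 cpgs_a = cpgs_a, cpgs_b = cpgs_b,
                 samples = samples, design = design, maps = maps,
                 truth = truth,
                 het_sites = pg$het_sites),
            class = "meth_simulation")
}

#' Write a simulated dataset as standard files
#'
#' Emits the reference and personal genomes (FASTA), the variant set (VCF),
#' the coordinate map (TSV), one Bismark coverage file per sample, a design
#' TSV (`sample_id  genotype  group  counts_file`) and the planted truth as
#' BED (0-based half-open).
#'
#' @param sim a `meth_simulation`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gA <- sim$config$genotypes[1L]; gB <- sim$config$genotypes[2L]
  write_fasta(sim$reference, file.path(dir, paste0(gA, ".fa")))
  write_fasta(sim$personal, file.path(dir, paste0(gB, ".fa")))
  write_vcf_variants(sim$variants, file.path(dir, paste0(gB, ".vcf")),
                     sample_name = gB,
                     contig_lengths = vapply(sim$reference, nchar,
                                             integer(1)))
  write_coord_map(sim$map, file.path(dir, paste0(gA, "_to_", gB,
                                                 ".map.tsv")))
  files <- character(length(sim$samples))
  for (i in seq_along(sim$samples)) {
    files[i] <- file.path(dir, paste0(sim$samples[[i]]$sample_id, ".cov"))
    write_bismark_cov(sim$samples[[i]], files[i])
  }
  utils::write.table(data.frame(sample_id = sim$design$sample_id,
                                genotype = sim$design$genotype,
                                group = sim$design$group,
                                counts_file = basename(files)),
                     file.path(dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(paste(sim$truth$chrom, sim$truth$start - 1L, sim$truth$end + 1L,
                   sim$truth$target, format(sim$truth$delta), ".",
                   sep = "\t"),
             file.path(dir, "truth.bed"))
  invisible(dir)
}
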