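# CpG enumeration, cross-genome classification and mutation-rate summaries.

CPG_CATEGORIES <- c("COMMON_CG", "TG_CA", "OTHER_MUT", "UNMAPPABLE")

#' Find all CpG sites in a sequence
#'
#' A CpG site is the 1-based position of the C of a forward-strand CG
#' dinucleotide. Dinucleotides containing N are never CpGs.
#'
#' @param sequence a single chromosome sequence (character scalar) or a named
#'   genome vector; in the latter case results for all chromosomes are bound
#'   together.
#' @return For a scalar, an integer vector of positions; for a genome, a
#'   data.frame with `chrom` and `pos`.
#' @export
find_cpgs <- function(sequence) {
  one <- function(s) {
    hits <- gregexpr("CG", s, fixed =TRUE)[[1L]]
    if (hits[1L] == -1L) integer(0) else as.integer(hits)
  }
  if (length(sequence) == 1L && is.null(names(sequence)))
    return(one(sequence))
  out <- lapply(sequence, one)
  data.frame(chrom = rep(names(sequence), lengths(out)),
             pos = unlist(out, use.names = FALSE))
}

#' Classify CpGs of genome A by their status in genome B
#'
#' Every CpG of genome A is mapped through `map` and labelled:
#' `COMMON_CG` when the mapped dinucleotide in B is CG; `TG_CA` when it is TG
#' or CA (the C-deamination signature); `UNMAPPABLE` when either strand of the
#' dinucleotide falls inside an indel, or the two images are not adjacent
#' (the dinucleotide is split by an indel); `OTHER_MUT` for everything else,
#' including dinucleotides containing N. The four categories partition the
#' CpG set of A.
#'
#' @param cpgs_a data.frame `chrom`, `pos` from [find_cpgs()] on genome A.
#' @param map `coord_map` with A on the reference side.
#' @param genome_b named character vector of genome B sequences.
#' @param direction direction through `map` that goes from A to B
#'   (`"a2b"` when A is the map's reference side).
#' @return data.frame `chrom`, `pos`, `category` (factor over the four
#'   labels), `mapped_pos` (`NA` when unmappable).
#' @export
classify_cross_genome <- function(cpgs_a, map, genome_b,
                                  direction = c("a2b", "b2a")) {
  direction <- match.arg(direction)
  src_len <- if (direction == "a2b") map$ref_lengths else map$personal_lengths
  missing_ch <- setdiff(unique(cpgs_a$chrom), names(src_len))
  if (length(missing_ch))
    stop("chromosome(s) absent from coordinate map: ",
         paste(missing_ch, collapse = ", "))
  out <- vector("list", length(unique(cpgs_a$chrom)))
  chs <- unique(cpgs_a$chrom)
  for (k in seq_along(chs)) {
    ch <- chs[k]
    pos <- cpgs_a$pos[cpgs_a$chrom == ch]
    m1 <- map_position(map, ch, pos, direction)
    gpos <- pos + 1L
    m2 <- rep(NA_integer_, length(pos))
    inb <- gpos <= src_len[[ch]]
    if (any(inb)) m2[inb] <- map_position(map, ch, gpos[inb], direction)
    cat <- rep("UNMAPPABLE", length(pos))
    ok <- !is.na(m1) & !is.na(m2) & m2 == m1 + 1L
    if (any(ok)) {
      din <- substring(genome_b[[ch]], m1[ok], m2[ok])
      cat[ok][din == "CG"] <- "COMMON_CG"
      cat[ok][din %in% c("TG", "CA")] <- "TG_CA"
      cat[ok][!din %in% c("CG", "TG", "CA")] <- "OTHER_MUT"
    }
    out[[k]] <- data.frame(chrom = ch, pos = pos,
                           category = factor(cat, levels = CPG_CATEGORIES),
                           mapped_pos = ifelse(ok, m1, NA_integer_))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' CpG mutation rate
#'
#' The fraction of CpGs unique to one genome: all non-`COMMON_CG` categories
#' (mutated to TG/CA, otherwise lost, or unmappable) over the total.
#'
#' @param classifications output of [classify_cross_genome()].
#' @return A fraction in `[0, 1]`.
#' @export
mutation_rate <- function(classifications) {
  if (!nrow(classifications)) stop("empty classification table")
  mean(classifications$category != "COMMON_CG")
}

#' CpG mutation rate in genomic bins
#'
#' Bins tile each chromosome from position 1; the last bin may be short.
#' Bins containing no CpG get `rate = NA`, not 0.
#'
#' @param classifications output of [classify_cross_genome()].
#' @param bin_size bin width in bp.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return data.frame `chrom`, `bin_start`, `n_total`, `n_unique`, `rate`.
#' @export
binned_mutation_rate <- function(classifications, bin_size, chrom_lengths) {
  if (bin_size <= 0) stop("bin_size must be positive")
  out <- lapply(names(chrom_lengths), function(ch) {
    starts <- seq.int(1L, chrom_lengths[[ch]], by = bin_size)
    cl <- classifications[classifications$chrom == ch, , drop = FALSE]
    bin <- findInterval(cl$pos, starts)
    n_total <- tabulate(bin, nbins = length(starts))
    n_unique <- tabulate(bin[cl$category != "COMMON_CG"],
                         nbins = length(starts))
    data.frame(chrom = ch, bin_start = starts, n_total = n_total,
               n_unique = n_unique,
               rate = ifelse(n_total > 0L, n_unique / n_total, NA_real_))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' CpG mutation rate across labelled genomic features
#'
#' For each feature label, the mutation rate over CpGs whose C position lies
#' in any interval carrying that label. Overlapping features are allowed and
#' a CpG may count toward several labels.
#'
#' @param classifications output of [classify_cross_genome()].
#' @param features data.frame `chrom`, `start`, `end` (1-based inclusive),
#'   `label`; see [read_bed_features()].
#' @return data.frame `label`, `n_total`, `n_unique`, `rate` (`NA` when a
#'   label covers no CpG).
#' @export
feature_mutation_rate <- function(classifications, features) {
  if (any(features$end < features$start))
    stop("malformed feature interval: end < start")
  fg <- GenomicRanges::GRanges(features$chrom,
                               IRanges::IRanges(features$start, features$end))
  cg <- GenomicRanges::GRanges(classifications$chrom,
                               IRanges::IRanges(classifications$pos,
                                                width = 1L))
  hits <- GenomicRanges::findOverlaps(cg, fg)
  lab <- features$label[S4Vectors::subjectHits(hits)]
  uniq <- classifications$category[S4Vectors::queryHits(hits)] != "COMMON_CG"
  # a CpG inside two intervals of the same label counts once for that label
  key <- paste(S4Vectors::queryHits(hits), lab)
  first <- !duplicated(key)
  lab <- lab[first]; uniq <- uniq[first]
  labels <- unique(features$label)
  n_total <- vapply(labels, function(l) sum(lab == l), integer(1))
  n_unique <- vapply(labels, function(l) sum(uniq[lab == l]), integer(1))
  data.frame(label = labels, n_total = n_total, n_unique = n_unique,
             rate = ifelse(n_total > 0L, n_unique / n_total, NA_real_),
             row.names = NULL)
}

#' Read labelled features from a BED file
#'
#' BED intervals (0-based half-open) are converted to 1-based inclusive
#' coordinates; the BED name column becomes the feature label.
#'
#' @param path BED file.
#' @return data.frame `chrom`, `start`, `end`, `label`.
#' @export
read_bed_features <- function(path) {
  g <- rtracklayer::import(path, format = "BED")
  lab <- if (!is.null(g$name)) as.character(g$name) else
    rep("feature", length(g))
  data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
             start = GenomicRanges::start(g), end = GenomicRanges::end(g),
             label = lab)
}

#' Write CpG classifications as TSV
#'
#' Columns `chrom  pos  category  mapped_pos`, with `-1` for unmappable.
#'
#' @param classifications output of [classify_cross_genome()].
#' @param path output file.
#' @export
write_classifications <- function(classifications, path) {
  m <- classifications$mapped_pos
  m[is.na(m)] <- -1L
  utils::write.table(data.frame(classifications[c("chrom", "pos")],
                                category = as.character(classifications$category),
                                mapped_pos = m),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_classifications
#' @export
read_classifications <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  x$category <- factor(x$category, levels = CPG_CATEGORIES)
  x$mapped_pos[x$mapped_pos < 0L] <- NA_integer_
  x
}

#' Published CpG counts for the C57BL/6J x CAST/EiJ strain comparison
#'
#' Forward-strand CpG dinucleotide counts for each strain's genome,
#' cross-classified against the other strain's genome, split into autosomes
#' and allosomes. These are the published genome-scale numbers for the two
#' mouse strains; the shared-CpG count is common to both columns.
#'
#' @return data.frame with `category` (`common`, `tg_ca`, `lost`,
#'   `unmappable`, `total`) and columns
#'   `bl6_autosomes`, `cast_autosomes`, `bl6_allosomes`, `cast_allosomes`.
#' @export
mouse_strain_cpg_counts <- function() {
  data.frame(
    category = c("common", "tg_ca", "lost", "unmappable", "total"),
    bl6_autosomes = c(18140628, 1601446, 522845, 99781, 20364700),
    cast_autosomes = c(18140628, 1669901, 535219, 90356, 20436104),
    bl6_allosomes = c(916392, 43330, 15394, 2676, 977792),
    cast_allosomes = c(916392, 45041, 15838, 2438, 979709)
  )
}

#' CpG mutation rate from a printed count table
#'
#' Computes (TG/CA + lost + unmappable) / total from a category count table
#' such as [mouse_strain_cpg_counts()], summing the selected columns.
#'
#' @param counts data.frame in the layout of [mouse_strain_cpg_counts()].
#' @param columns which count columns to sum, e.g.
#'   `c("bl6_autosomes", "bl6_allosomes")`.
#' @return A fraction in `[0, 1]`.
#' @export
mutation_rate_from_counts <- function(counts,
                                      columns = c("bl6_autosomes",
                                                  "bl6_allosomes")) {
  tot <- sum(vapply(columns, function(cc)
    counts[counts$category == "total", cc], numeric(1)))
  uniq <- sum(vapply(columns, function(cc)
    sum(counts[counts$category %in% c("tg_ca", "lost", "unmappable"), cc]),
    numeric(1)))
  uniq / tot
}
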