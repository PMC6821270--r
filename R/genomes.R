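# Personal genome construction and liftOver-style coordinate maps.
#
# A genome is a named character vector of uppercase chromosome sequences.
# A variant table is a data.frame with columns chrom, pos (1-based position of
# the first reference base), ref, alt (strings over A/C/G/T; alt may be empty
# for a pure deletion) and zygosity ("homozygous"/"heterozygous").
# Unmappable positions are represented by NA_integer_ in memory; the modmap
# TSV dialect written/read by the io helpers uses -1.

#' Validate a variant table against a reference genome
#'
#' Checks that variants are sorted, non-overlapping within chromosome, refer
#' to known chromosomes, and that each `ref` allele matches the reference
#' sequence at its position.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `zygosity`.
#' @param genome named character vector of chromosome sequences.
#' @return The variant table, invisibly, with `pos` as integer.
#' @export
validate_variants <- function(variants, genome) {
  need <- c("chrom", "pos", "ref", "alt", "zygosity")
  if (!all(need %in% names(variants)))
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  variants$pos <- as.integer(variants$pos)
  bad_chrom <- setdiff(unique(variants$chrom), names(genome))
  if (length(bad_chrom))
    stop("unknown chromosome(s) in variant table: ",
         paste(bad_chrom, collapse = ", "))
  if (!all(variants$zygosity %in% c("homozygous", "heterozygous")))
    stop("zygosity must be 'homozygous' or 'heterozygous'")
  if (any(!grepl("^[ACGT]+$", variants$ref)))
    stop("ref alleles must be non-empty strings over A/C/G/T")
  if (any(!grepl("^[ACGT]*$", variants$alt)))
    stop("alt alleles must be strings over A/C/G/T")
  for (ch in unique(variants$chrom)) {
    v <- variants[variants$chrom == ch, , drop = FALSE]
    if (is.unsorted(v$pos, strictly = TRUE))
      stop("variants on ", ch, " must be sorted by pos and unique")
    ends <- v$pos + nchar(v$ref) - 1L
    if (nrow(v) > 1L && any(v$pos[-1L] <= ends[-nrow(v)])) {
      i <- which(v$pos[-1L] <= ends[-nrow(v)])[1L]
      stop("overlapping variants on ", ch, " at pos ", v$pos[i], " and ",
           v$pos[i + 1L])
    }
    obs <- substring(genome[[ch]], v$pos, ends)
    mism <- which(obs != v$ref)
    if (length(mism))
      stop("variant ref allele mismatch on ", ch, " at pos ",
           v$pos[mism[1L]], ": expected '", v$ref[mism[1L]],
           "', reference has '", obs[mism[1L]], "'")
  }
  invisible(variants)
}

#' Build a personal (pseudo)genome and its coordinate map
#'
#' Applies variants to a reference genome. Homozygous variants are always
#' applied; heterozygous variants are handled per `het_policy`:
#' `"reference"` and `"exclude"` keep the reference allele (the loci are only
#' recorded for downstream filtering), `"alternate"` applies the alternate
#' allele. SNVs never shift coordinates; only applied indels create new
#' colinear blocks in the returned map.
#'
#' @param reference named character vector of chromosome sequences.
#' @param variants variant table (see [validate_variants()]).
#' @param het_policy one of `"reference"`, `"alternate"`, `"exclude"`.
#' @return A list with elements `genome` (personal sequences), `map` (a
#'   `coord_map`; reference is the "A" side, personal the "B" side) and
#'   `het_sites` (the heterozygous rows of `variants`, reference
#'   coordinates), with class `pseudogenome`.
#' @export
build_pseudogenome <- function(reference, variants,
                               het_policy = c("reference", "alternate",
                                              "exclude")) {
  het_policy <- match.arg(het_policy)
  variants <- validate_variants(variants, reference)
  het <- variants$zygosity == "heterozygous"
  apply_mask <- !het | (het_policy == "alternate")

  personal <- character(length(reference))
  names(personal) <- names(reference)
  blocks <- vector("list", length(reference))
  ref_len <- vapply(reference, nchar, integer(1))
  per_len <- ref_len

  for (ci in seq_along(reference)) {
    ch <- names(reference)[ci]
    seq_a <- reference[[ch]]
    L <- ref_len[[ci]]
    v <- variants[variants$chrom == ch & apply_mask, , drop = FALSE]
    if (!nrow(v)) {
      personal[[ch]] <- seq_a
      blocks[[ci]] <- data.frame(chrom = ch, ref_start = 1L,
                                 personal_start = 1L, length = L)
      next
    }
    rlen <- nchar(v$ref)
    alen <- nchar(v$alt)
    # sequence: reference pieces between variants interleaved with alts
    piece_start <- c(1L, v$pos + rlen)
    piece_end <- c(v$pos - 1L, L)
    pieces <- substring(seq_a, piece_start, piece_end)
    out <- character(2L * nrow(v) + 1L)
    out[seq(1L, by = 2L, length.out = nrow(v) + 1L)] <- pieces
    out[seq(2L, by = 2L, length.out = nrow(v))] <- v$alt
    personal[[ch]] <- paste0(out, collapse = "")
    # map: break a colinear block at every applied length-changing variant
    bs_ref <- integer(0); bs_per <- integer(0); bl <- integer(0)
    cur <- 1L; offset <- 0L
    for (k in which(rlen != alen)) {
      p <- v$pos[k]; r <- rlen[k]; a <- alen[k]
      kk <- min(r, a)                 # positionally aligned prefix
      len <- (p + kk - 1L) - cur + 1L
      if (len > 0L) {
        bs_ref <- c(bs_ref, cur); bs_per <- c(bs_per, cur + offset)
        bl <- c(bl, len)
      }
      offset <- offset + (a - r)
      cur <- p + r
    }
    if (cur <= L) {
      bs_ref <- c(bs_ref, cur); bs_per <- c(bs_per, cur + offset)
      bl <- c(bl, L - cur + 1L)
    }
    blocks[[ci]] <- data.frame(chrom = ch, ref_start = bs_ref,
                               personal_start = bs_per, length = bl)
    per_len[[ci]] <- L + sum(alen - rlen)
  }

  map <- coord_map(do.call(rbind, blocks), ref_len, per_len)
  structure(list(genome = personal, map = map,
                 het_sites = variants[het, c("chrom", "pos", "ref", "alt"),
                                      drop = FALSE],
                 het_policy = het_policy),
            class = "pseudogenome")
}

#' Construct a coordinate map
#'
#' A `coord_map` is a monotone piecewise mapping between two genomes induced
#' by indels: an ordered set of colinear blocks per chromosome. Positions
#' falling between blocks (inside an indel) are unmappable.
#'
#' @param blocks data.frame with columns `chrom`, `ref_start`,
#'   `personal_start`, `length` (1-based starts).
#' @param ref_lengths,personal_lengths named integer vectors of chromosome
#'   lengths on the reference ("A") and personal ("B") side.
#' @return An object of class `coord_map`.
#' @export
coord_map <- function(blocks, ref_lengths, personal_lengths) {
  stopifnot(all(c("chrom", "ref_start", "personal_start", "length") %in%
                  names(blocks)))
  blocks <- blocks[order(blocks$chrom, blocks$ref_start), , drop = FALSE]
  rownames(blocks) <- NULL
  for (ch in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == ch, , drop = FALSE]
    if (nrow(b) > 1L) {
      if (any(b$ref_start[-1L] <= b$ref_start[-nrow(b)] + b$length[-nrow(b)] - 1L) ||
          is.unsorted(b$personal_start, strictly = TRUE))
        stop("coordinate map blocks on ", ch,
             " must be strictly increasing and non-overlapping on both sides")
    }
  }
  structure(list(blocks = blocks,
                 ref_lengths = ref_lengths,
                 personal_lengths = personal_lengths),
            class = "coord_map")
}

#' Identity coordinate map
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return A `coord_map` mapping every position to itself.
#' @export
identity_map <- function(chrom_lengths) {
  coord_map(data.frame(chrom = names(chrom_lengths),
                       ref_start = 1L, personal_start = 1L,
                       length = as.integer(chrom_lengths)),
            chrom_lengths, chrom_lengths)
}

#' Map positions between the two sides of a coordinate map
#'
#' Positions inside colinear blocks map by offset; positions inside
#' indel-created gaps return `NA` (the unmappable sentinel). Out-of-bounds
#' positions are an error, distinct from unmappable.
#'
#' @param map a `coord_map`.
#' @param chrom chromosome name (scalar).
#' @param pos integer vector of 1-based positions on the source side.
#' @param direction `"a2b"` (reference to personal) or `"b2a"`.
#' @return Integer vector of mapped positions, `NA` where unmappable.
#' @export
map_position <- function(map, chrom, pos, direction = c("a2b", "b2a")) {
  direction <- match.arg(direction)
  src_len <- if (direction == "a2b") map$ref_lengths else map$personal_lengths
  if (!chrom %in% names(src_len))
    stop("chromosome not in coordinate map: ", chrom)
  pos <- as.integer(pos)
  if (any(pos < 1L | pos > src_len[[chrom]], na.rm = TRUE))
    stop("position out of bounds on ", chrom, " (length ", src_len[[chrom]],
         ")")
  b <- map$blocks[map$blocks$chrom == chrom, , drop = FALSE]
  if (direction == "a2b") {
    from <- b$ref_start; to <- b$personal_start
  } else {
    from <- b$personal_start; to <- b$ref_start
  }
  i <- findInterval(pos, from)
  out <- rep(NA_integer_, length(pos))
  ok <- !is.na(pos) & i >= 1L
  ok[ok] <- pos[ok] <= from[i[ok]] + b$length[i[ok]] - 1L
  out[ok] <- to[i[ok]] + (pos[ok] - from[i[ok]])
  out
}

#' Lift a set of CpG sites through a coordinate map
#'
#' A CpG site is identified by the 1-based position of its forward-strand C.
#' Both positions of the dinucleotide (C at `pos`, G at `pos + 1`) must map;
#' sites for which either strand falls inside an indel are discarded, the
#' rule used when reconciling strain coordinate systems.
#'
#' @param map a `coord_map`.
#' @param chrom chromosome name.
#' @param sites sorted integer vector of C positions.
#' @param direction `"a2b"` or `"b2a"`.
#' @return A list with `mapped` (data.frame `pos`, `mapped_pos`, order
#'   preserved) and `discarded` (the input positions that failed to lift).
#' @export
map_sites <- function(map, chrom, sites, direction = c("a2b", "b2a")) {
  direction <- match.arg(direction)
  sites <- as.integer(sites)
  if (is.unsorted(sites)) stop("sites must be sorted")
  if (!length(sites))
    return(list(mapped = data.frame(pos = integer(0),
                                    mapped_pos = integer(0)),
                discarded = integer(0)))
  src_len <- if (direction == "a2b") map$ref_lengths else map$personal_lengths
  m1 <- map_position(map, chrom, sites, direction)
  gpos <- sites + 1L
  m2 <- rep(NA_integer_, length(sites))
  inb <- gpos <= src_len[[chrom]]
  if (any(inb)) m2[inb] <- map_position(map, chrom, gpos[inb], direction)
  keep <- !is.na(m1) & !is.na(m2)
  list(mapped = data.frame(pos = sites[keep], mapped_pos = m1[keep]),
       discarded = sites[!keep])
}

# ---- file formats ----------------------------------------------------------

#' Read a FASTA genome
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a genome as FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read variants from a VCF file
#'
#' Reads SNVs and indels with zygosity taken from the GT field of one sample
#' column. Multi-allelic records must be pre-split and are rejected. Records
#' genotyped homozygous-reference (0/0) are dropped.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param sample sample column to read GT from; default the first. If the VCF
#'   has no genotype columns all variants are taken as homozygous.
#' @return Variant table (`chrom`, `pos`, `ref`, `alt`, `zygosity`).
#' @export
read_vcf_variants <- function(path, sample = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm)))        # single-record VCFs come back as a vector
    fixm <- matrix(fixm, nrow = 1L, dimnames = list(NULL, names(fixm)))
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  if (!nrow(fix))
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      zygosity = character(0)))
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    i <- which(grepl(",", fix$ALT, fixed = TRUE))[1L]
    stop("multi-allelic VCF record at ", fix$CHROM[i], ":", fix$POS[i],
         "; split multi-allelic records before import")
  }
  zyg <- rep("homozygous", nrow(fix))
  keep <- rep(TRUE, nrow(fix))
  gt_mat <- try(vcfR::extract.gt(v, element = "GT"), silent = TRUE)
  if (!inherits(gt_mat, "try-error") && !is.null(gt_mat) && ncol(gt_mat)) {
    col <- if (is.null(sample)) 1L else sample
    gt <- gt_mat[, col]
    alleles <- strsplit(gsub("\\|", "/", gt), "/", fixed = FALSE)
    n_alt <- vapply(alleles, function(a) sum(a == "1"), integer(1))
    n_tot <- lengths(alleles)
    keep <- !is.na(gt) & n_alt > 0L
    zyg <- ifelse(n_alt == n_tot, "homozygous", "heterozygous")
  }
  data.frame(chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
             ref = toupper(fix$REF[keep]), alt = toupper(fix$ALT[keep]),
             zygosity = zyg[keep], row.names = NULL)
}

#' Write a variant table as a minimal VCF
#'
#' @param variants variant table.
#' @param path output file.
#' @param sample_name name of the single genotype column.
#' @param contig_lengths optional named lengths for `##contig` header lines.
#' @export
write_vcf_variants <- function(variants, path, sample_name = "SAMPLE",
                               contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths),
                          as.integer(contig_lengths)))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_name, sep = "\t"))
  gt <- ifelse(variants$zygosity == "heterozygous", "0/1", "1/1")
  alt <- ifelse(nchar(variants$alt) == 0L, "<DEL>", variants$alt)
  body <- paste(variants$chrom, variants$pos, ".", variants$ref, alt, ".",
                "PASS", ".", "GT", gt, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write / read a coordinate map as TSV
#'
#' The format is one colinear block per row:
#' `chrom  ref_start  personal_start  length` (1-based starts), preceded by
#' comment lines carrying the chromosome lengths of both sides.
#'
#' @param map a `coord_map`.
#' @param path file path.
#' @export
write_coord_map <- function(map, path) {
  hdr <- c(sprintf("#ref_length\t%s\t%d", names(map$ref_lengths),
                   as.integer(map$ref_lengths)),
           sprintf("#personal_length\t%s\t%d", names(map$personal_lengths),
                   as.integer(map$personal_lengths)),
           "#chrom\tref_start\tpersonal_start\tlength")
  body <- paste(map$blocks$chrom, map$blocks$ref_start,
                map$blocks$personal_start, map$blocks$length, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_coord_map
#' @export
read_coord_map <- function(path) {
  lines <- readLines(path)
  com <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  parse_len <- function(tag) {
    x <- strsplit(com[startsWith(com, tag)], "\t")
    stats::setNames(vapply(x, function(f) as.integer(f[3L]), integer(1)),
                    vapply(x, function(f) f[2L], character(1)))
  }
  f <- strsplit(body, "\t")
  blocks <- data.frame(chrom = vapply(f, `[`, character(1), 1L),
                       ref_start = as.integer(vapply(f, `[`, character(1), 2L)),
                       personal_start = as.integer(vapply(f, `[`, character(1), 3L)),
                       length = as.integer(vapply(f, `[`, character(1), 4L)))
  coord_map(blocks, parse_len("#ref_length"), parse_len("#personal_length"))
}

#' Write per-site liftover results in the modmap TSV dialect
#'
#' Three columns `chrom  pos_A  pos_B`, with `-1` for unmappable positions.
#'
#' @param map a `coord_map`.
#' @param chrom chromosome name.
#' @param sites positions on the source side.
#' @param path output file.
#' @param direction `"a2b"` or `"b2a"`.
#' @export
write_liftover_sites <- function(map, chrom, sites, path,
                                 direction = c("a2b", "b2a")) {
  direction <- match.arg(direction)
  m <- map_position(map, chrom, sites, direction)
  m[is.na(m)] <- -1L
  writeLines(paste(chrom, sites, m, sep = "\t"), path)
  invisible(path)
}

#' Read per-site liftover results in the modmap TSV dialect
#'
#' @param path file with columns `chrom  pos_A  pos_B`; `-1` (or any negative
#'   value) in the third column is read as unmappable (`NA`).
#' @return data.frame with `chrom`, `pos`, `mapped_pos`.
#' @export
read_liftover_sites <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "pos", "mapped_pos"),
                         colClasses = c("character", "integer", "integer"))
  x$mapped_pos[x$mapped_pos < 0L] <- NA_integer_
  x
}

#' Flag CpG sites overlapping heterozygous variants
#'
#' A CpG (C at `pos`, G at `pos + 1`) is flagged when either base of the
#' dinucleotide falls within the reference span of a heterozygous variant.
#'
#' @param cpgs data.frame with `chrom`, `pos` (forward-strand C positions).
#' @param het_sites heterozygous variant rows (`chrom`, `pos`, `ref`), e.g.
#'   the `het_sites` element of [build_pseudogenome()].
#' @return Logical vector along the rows of `cpgs`.
#' @export
flag_het_cpgs <- function(cpgs, het_sites) {
  if (!nrow(het_sites)) return(rep(FALSE, nrow(cpgs)))
  hg <- GenomicRanges::GRanges(het_sites$chrom,
                               IRanges::IRanges(het_sites$pos,
                                                het_sites$pos +
                                                  nchar(het_sites$ref) - 1L))
  cg <- GenomicRanges::GRanges(cpgs$chrom,
                               IRanges::IRanges(cpgs$pos, cpgs$pos + 1L))
  IRanges::overlapsAny(cg, hg)
}
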