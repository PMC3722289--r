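# Step 1 of the pipeline: harvest the per-gene candidate read set from a
# coordinate alignment file -- pairs with either end mapped to the gene
# region, plus fully-unmapped pairs of high base quality (which the
# correction step later assigns to genes by database matching).

#' Gene region on the reference genome
#'
#' Coordinates are stored 0-based half-open; use [read_gene_regions()] for
#' the 1-based inclusive table format.
#'
#' @param gene Gene symbol.
#' @param chrom Contig name.
#' @param start,end 0-based half-open interval, `start < end`.
#' @return A `gene_region`.
#' @export
gene_region <- function(gene, chrom, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(nzchar(gene), nzchar(chrom), start < end, start >= 0L)
  structure(list(gene = gene, chrom = chrom, start = start, end = end),
            class = "gene_region")
}

#' Read a gene-region table
#'
#' Tab-separated with header columns `gene`, `chrom`, `start`, `end`;
#' coordinates 1-based inclusive (samtools convention), converted to the
#' internal 0-based half-open representation.
#'
#' @param path Path to the TSV.
#' @return A named list of `gene_region`.
#' @export
read_gene_regions <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(tab)))
  regions <- lapply(seq_len(nrow(tab)), function(i)
    gene_region(tab$gene[i], tab$chrom[i], tab$start[i] - 1L, tab$end[i]))
  stats::setNames(regions, tab$gene)
}

cigar_reference_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1L]]
    len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    type <- sub("^[0-9]+", "", ops)
    sum(len[type %in% c("M", "D", "N", "=", "X")])
  }, integer(1L), USE.NAMES = FALSE)
}

#' Harvest one gene's candidate reads from a SAM/BAM file
#'
#' Keeps every read pair with at least one end overlapping the gene region
#' (half-open semantics: a read ending exactly at the region start is
#' outside), plus fully-unmapped pairs whose mean base quality reaches
#' `quality_floor` -- those cannot be placed positionally and are resolved
#' downstream by the correction step's database matching.  Reads flagged
#' as PCR duplicates, secondary or supplementary alignments are excluded;
#' both mates of a kept pair are returned.
#'
#' @param alignments Path to a BAM file, or a SAM text file (converted on
#'   the fly).
#' @param region A [gene_region()].
#' @param quality_floor Minimum mean base Phred quality for the
#'   unmapped-rescue pool.
#' @return An object of class `gene_read_set`: `gene`, `reads` (data frame
#'   `id`, `sequence`, `quality`, `category`) and `stats` (counts per
#'   harvest category).
#' @export
extract_gene_reads <- function(alignments, region, quality_floor = 20) {
  stopifnot(inherits(region, "gene_region"))
  bam <- alignments
  if (grepl("\\.sam$", alignments, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(alignments,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  header <- Rsamtools::scanBamHeader(bam)[[1L]]
  if (!(region$chrom %in% names(header$targets))) {
    stop("contig '", region$chrom, "' absent from the alignment header")
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1L]]
  flag <- rec$flag
  keep <- bitwAnd(flag, 1024L) == 0L &  # not a PCR/optical duplicate
    bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  df <- data.frame(qname = rec$qname[keep], flag = flag[keep],
                   rname = as.character(rec$rname)[keep],
                   pos = rec$pos[keep], cigar = rec$cigar[keep],
                   sequence = as.character(rec$seq)[keep],
                   quality = as.character(rec$qual)[keep],
                   stringsAsFactors = FALSE)
  df$mapped <- bitwAnd(df$flag, 4L) == 0L
  df$mate <- ifelse(bitwAnd(df$flag, 128L) != 0L, 2L, 1L)
  width <- cigar_reference_width(df$cigar)
  p0 <- df$pos - 1L
  df$overlaps <- df$mapped & !is.na(df$pos) & df$rname == region$chrom &
    p0 < region$end & p0 + width > region$start

  groups <- split(seq_len(nrow(df)), df$qname)
  rows <- integer(0)
  category <- character(0)
  for (gi in groups) {
    if (any(df$overlaps[gi])) {
      rows <- c(rows, gi)
      category <- c(category, rep("mapped_pair", length(gi)))
    } else if (!any(df$mapped[gi])) {
      qmean <- mean(utf8ToInt(paste(df$quality[gi], collapse = ""))) - 33
      if (qmean >= quality_floor) {
        rows <- c(rows, gi)
        category <- c(category, rep("unmapped_rescue", length(gi)))
      }
    }
  }
  reads <- data.frame(
    id = paste0(df$qname[rows], "/", df$mate[rows]),
    sequence = df$sequence[rows], quality = df$quality[rows],
    category = category, stringsAsFactors = FALSE)
  dup <- duplicated(reads$id)
  reads <- reads[!dup, , drop = FALSE]
  structure(list(gene = region$gene, reads = reads,
                 stats = c(mapped_pair = sum(reads$category == "mapped_pair"),
                           unmapped_rescue = sum(reads$category == "unmapped_rescue"))),
            class = "gene_read_set")
}

#' @export
print.gene_read_set <- function(x, ...) {
  cat("<gene_read_set> ", x$gene, ": ", nrow(x$reads), " reads (",
      x$stats["mapped_pair"], " region-mapped, ",
      x$stats["unmapped_rescue"], " unmapped-rescue)\n", sep = "")
  invisible(x)
}
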