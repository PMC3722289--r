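# Step 2 of the pipeline: match each harvested read to its most similar
# allele reference, discard reads with more than `max_discordances`
# SNP/InDel events, snap retained reads to the reference, and record every
# discordance for later novel-variant judgment.

# One row per reference string handed to the matcher.  Alleles with a full
# sequence contribute it as a single reference (reads are projected onto
# exons afterwards); exon-only alleles contribute one reference per exon.
build_reference_table <- function(db, genes) {
  rows <- list()
  for (g in genes) {
    for (a in gene_alleles(db, g)) {
      if (!is.null(a$full_sequence)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, allele = a$name$raw, kind = "full", exon = NA_integer_,
          seq = a$full_sequence, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, allele = a$name$raw, kind = "exon",
          exon = seq_along(a$exons), seq = a$exons, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$ref_id <- seq_len(nrow(out))
  out
}

# exon ranges (0-based half-open on the full sequence) for every full-kind
# reference row
reference_exon_ranges <- function(db, refs) {
  full <- refs[refs$kind == "full", , drop = FALSE]
  if (nrow(full) == 0L) {
    return(data.frame(ref_id = integer(0), exon = integer(0),
                      s0 = integer(0), e0 = integer(0)))
  }
  do.call(rbind, lapply(seq_len(nrow(full)), function(i) {
    a <- db$alleles[[full$allele[i]]]
    data.frame(ref_id = full$ref_id[i], exon = seq_along(a$exons),
               s0 = a$exon_ranges[, "start"] - 1L, e0 = a$exon_ranges[, "end"])
  }))
}

parse_edits <- function(edits) {
  # "X12:A>G;D40:ACG;I55:TT" -> data.frame(type, pos, ref, alt)
  if (!nzchar(edits)) {
    return(data.frame(type = character(0), pos = integer(0),
                      ref = character(0), alt = character(0)))
  }
  items <- strsplit(edits, ";", fixed = TRUE)[[1L]]
  type <- substring(items, 1L, 1L)
  body <- substring(items, 2L)
  pos <- as.integer(sub(":.*$", "", body))
  payload <- sub("^[0-9]+:", "", body)
  ref <- ifelse(type == "X", sub(">.*$", "", payload),
                ifelse(type == "D", payload, ""))
  alt <- ifelse(type == "X", sub("^.*>", "", payload),
                ifelse(type == "I", payload, ""))
  data.frame(type = type, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' Correct harvested reads against the allele database
#'
#' Each read (and its reverse complement) is matched to the most similar
#' reference sequence of the requested genes with a seed-and-extend
#' matcher; reads whose best alignment carries more than `max_discordances`
#' SNP/InDel events, or that align over fewer than `min_span` reference
#' bases within an exon, are discarded.  Retained reads are snapped to the
#' matched reference over their aligned interval (so every corrected read
#' is an exact substring of a database exon), and every exonic discordance
#' is accumulated into a per-gene variant ledger with its supporting read
#' count.
#'
#' A discordance is one event: a mismatched base, or an insertion/deletion
#' run of any length.  Ties between equally good references are broken by
#' larger aligned span, then lexicographically smaller allele name, then
#' lower exon number.
#'
#' @param reads A data frame with columns `id` and `sequence` (a
#'   `gene_read_set` from [extract_gene_reads()] is also accepted).
#' @param db An `hla_allele_db`.
#' @param genes Genes to match against (default: all genes in `db`).
#' @param max_discordances Maximum SNP/InDel events for a read to be kept.
#' @param min_span Minimum aligned reference span within an exon (bp).
#' @param band Half-width of the indel rescue alignment window (bp).
#' @param indel_rescue Attempt a gapped alignment for reads that fail the
#'   substitution-only match.
#' @return A list of class `hla_correction` with one element per gene:
#'   `corrected` (data frame: `read_id`, `allele`, `exon`, `offset`,
#'   `sequence`, `nevent`), `ledger` (the variant records: `allele`,
#'   `exon`, `position` 0-based, `ref`, `alt`, `support`) and `stats`.
#' @export
correct_reads <- function(reads, db, genes = db$genes, max_discordances = 2L,
                          min_span = 30L, band = 8L, indel_rescue = TRUE) {
  if (inherits(reads, "gene_read_set")) reads <- reads$reads
  stopifnot(is.data.frame(reads), all(c("id", "sequence") %in% names(reads)))
  if (nrow(reads) > 0L && any(!nzchar(reads$sequence))) {
    stop("empty read sequence in input")
  }
  refs <- build_reference_table(db, genes)
  ranges <- reference_exon_ranges(db, refs)
  n_in <- nrow(reads)
  empty_gene <- function(g) list(
    corrected = data.frame(read_id = character(0), allele = character(0),
                           exon = integer(0), offset = integer(0),
                           sequence = character(0), nevent = integer(0),
                           stringsAsFactors = FALSE),
    ledger = empty_ledger(), stats = c(retained = 0L, discarded = 0L))
  out <- stats::setNames(lapply(genes, empty_gene), genes)
  if (n_in == 0L) {
    return(structure(list(genes = out,
                          stats = c(input = 0L, retained = 0L, discarded = 0L)),
                     class = "hla_correction"))
  }

  hits <- cpp_match_reads(reads$sequence, refs$seq, max_events = max_discordances,
                          band = band, seed_len = 30L,
                          indel_rescue = indel_rescue)
  if (nrow(hits) > 0L) {
    hits$gene <- refs$gene[hits$ref]
    hits$allele <- refs$allele[hits$ref]
    hits$kind <- refs$kind[hits$ref]
    hits$exon <- refs$exon[hits$ref]
    # best match per read: fewest events, widest span, allele name, exon
    ord <- order(hits$read, hits$nevent, -hits$span, hits$allele, hits$exon)
    hits <- hits[ord, , drop = FALSE]
    hits <- hits[!duplicated(hits$read), , drop = FALSE]
    chosen <- project_hits(hits, refs, ranges, min_span)
  } else {
    chosen <- NULL
  }

  retained_total <- 0L
  if (!is.null(chosen) && nrow(chosen) > 0L) {
    chosen$read_id <- reads$id[chosen$read]
    for (g in unique(chosen$gene)) {
      gi <- chosen[chosen$gene == g, , drop = FALSE]
      corrected <- data.frame(read_id = gi$read_id, allele = gi$allele,
                              exon = gi$exon, offset = gi$offset,
                              sequence = gi$sequence, nevent = gi$nevent,
                              stringsAsFactors = FALSE)
      out[[g]]$corrected <- corrected
      out[[g]]$ledger <- aggregate_ledger(gi)
      out[[g]]$stats <- c(retained = nrow(gi), discarded = 0L)
      retained_total <- retained_total + nrow(gi)
    }
  }
  discarded <- n_in - retained_total
  structure(list(genes = out,
                 stats = c(input = n_in, retained = retained_total,
                           discarded = discarded)),
            class = "hla_correction")
}

#' @export
print.hla_correction <- function(x, ...) {
  cat("<hla_correction> ", x$stats["input"], " reads in, ",
      x$stats["retained"], " retained (", x$stats["discarded"],
      " discarded)\n", sep = "")
  invisible(x)
}

empty_ledger <- function() {
  data.frame(allele = character(0), exon = integer(0), position = integer(0),
             ref = character(0), alt = character(0), support = integer(0),
             stringsAsFactors = FALSE)
}

# Project chosen hits onto exons.  Full-sequence hits are trimmed to the
# exon they overlap most (at least min_span bases); exon hits must span at
# least min_span bases.  Returns rows with exon offset, corrected sequence,
# the edit transcript and the exon's interval (s0, e0) on the matched
# reference, for later rebasing of edits.
project_hits <- function(hits, refs, ranges, min_span) {
  cols <- c("read", "gene", "allele", "exon", "offset", "sequence",
            "nevent", "edits", "s0", "e0")
  hits$end <- hits$start + hits$span
  keep <- list()

  exonic <- hits[hits$kind == "exon" & hits$span >= min_span, , drop = FALSE]
  if (nrow(exonic) > 0L) {
    exonic$offset <- exonic$start
    exonic$sequence <- substring(refs$seq[exonic$ref], exonic$start + 1L,
                                 exonic$end)
    exonic$s0 <- 0L
    exonic$e0 <- nchar(refs$seq[exonic$ref])
    keep[[length(keep) + 1L]] <- exonic[, cols, drop = FALSE]
  }

  full <- hits[hits$kind == "full", , drop = FALSE]
  if (nrow(full) > 0L) {
    full$ref_id <- full$ref
    full$exon <- NULL
    m <- merge(full, ranges, by = "ref_id")
    m$ov_start <- pmax(m$start, m$s0)
    m$ov_end <- pmin(m$end, m$e0)
    m$ov <- m$ov_end - m$ov_start
    m <- m[m$ov >= min_span, , drop = FALSE]
    if (nrow(m) > 0L) {
      # one exon per read: the largest overlap (reads cannot span two exons
      # when introns exceed the read length)
      m <- m[order(m$read, -m$ov), , drop = FALSE]
      m <- m[!duplicated(m$read), , drop = FALSE]
      m$offset <- m$ov_start - m$s0
      m$sequence <- substring(refs$seq[m$ref], m$ov_start + 1L, m$ov_end)
      keep[[length(keep) + 1L]] <- m[, cols, drop = FALSE]
    }
  }
  if (length(keep) == 0L) return(NULL)
  out <- do.call(rbind, keep)
  out[order(out$read), , drop = FALSE]
}

# rebase each hit's edit transcript onto its exon and pool support counts
# (vectorized over all retained reads of the gene)
aggregate_ledger <- function(gi) {
  has <- which(nzchar(gi$edits))
  if (length(has) == 0L) return(empty_ledger())
  items_list <- strsplit(gi$edits[has], ";", fixed = TRUE)
  row <- rep(has, lengths(items_list))
  items <- unlist(items_list, use.names = FALSE)
  type <- substring(items, 1L, 1L)
  body <- substring(items, 2L)
  pos <- as.integer(sub(":.*$", "", body))
  payload <- sub("^[0-9]+:", "", body)
  ref <- ifelse(type == "X", sub(">.*$", "", payload),
                ifelse(type == "D", payload, ""))
  alt <- ifelse(type == "X", sub("^.*>", "", payload),
                ifelse(type == "I", payload, ""))
  # keep only edits inside the exon interval; positions rebased to exon
  inside <- pos >= gi$s0[row] & pos < gi$e0[row]
  if (!any(inside)) return(empty_ledger())
  row <- row[inside]
  recs <- data.frame(allele = gi$allele[row], exon = gi$exon[row],
                     position = pos[inside] - gi$s0[row],
                     ref = ref[inside], alt = alt[inside],
                     stringsAsFactors = FALSE)
  key <- paste(recs$allele, recs$exon, recs$position, recs$ref, recs$alt,
               sep = "\r")
  counts <- table(key)
  first <- recs[!duplicated(key), , drop = FALSE]
  first$support <- as.integer(counts[key[!duplicated(key)]])
  first[order(first$allele, first$exon, first$position), , drop = FALSE]
}

#' Best reference match for a single read
#'
#' Single-read view of the matcher used by [correct_reads()].  Returns the
#' retained match with the fewest discordances over the gene's references,
#' or `NULL` when the best alignment exceeds `max_discordances` events or
#' spans fewer than `min_span` exon bases.
#'
#' @param read A read sequence (string) or a list/one-row data frame with
#'   `id` and `sequence`.
#' @param db An `hla_allele_db`.
#' @param gene Gene symbol to match against.
#' @inheritParams correct_reads
#' @return A list with `read_id`, `allele`, `exon_number`, `offset`,
#'   `discordances` (data frame), `score` (alignment identity fraction) and
#'   `corrected_sequence`, or `NULL`.
#' @export
best_reference_match <- function(read, db, gene, max_discordances = 2L,
                                 min_span = 30L, band = 8L) {
  if (is.character(read)) read <- list(id = "read1", sequence = read)
  if (!nzchar(read$sequence)) stop("empty read sequence")
  res <- correct_reads(data.frame(id = read$id, sequence = read$sequence,
                                  stringsAsFactors = FALSE),
                       db, genes = gene, max_discordances = max_discordances,
                       min_span = min_span, band = band)
  cg <- res$genes[[gene]]$corrected
  if (nrow(cg) == 0L) return(NULL)
  led <- res$genes[[gene]]$ledger
  list(read_id = cg$read_id[1L], allele = cg$allele[1L],
       exon_number = cg$exon[1L], offset = cg$offset[1L],
       discordances = led[, c("position", "ref", "alt"), drop = FALSE],
       score = 1 - cg$nevent[1L] / nchar(cg$sequence[1L]),
       corrected_sequence = cg$sequence[1L])
}

#' Snap a read to its matched reference
#'
#' @param read A read (string or list with `sequence`).
#' @param match A match as returned by [best_reference_match()].
#' @return A list with `read_id`, `sequence` (the reference-corrected
#'   sequence) and `match`.
#' @export
correct_read <- function(read, match) {
  if (is.null(match)) stop("cannot correct a read without a retained match")
  list(read_id = match$read_id, sequence = match$corrected_sequence,
       match = match)
}

#' Export a variant ledger as a VCF-like TSV
#'
#' Positions are reported 1-based.
#'
#' @param ledger A ledger data frame (see [correct_reads()]).
#' @param path Output file path.
#' @export
write_variant_ledger <- function(ledger, path) {
  out <- data.frame(allele = ledger$allele, exon = ledger$exon,
                    pos = ledger$position + 1L, ref = ledger$ref,
                    alt = ledger$alt, support = ledger$support)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
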