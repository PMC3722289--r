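# Step 3 of the pipeline: assemble corrected reads into per-exon haplotype
# sequences by perfect-overlap chaining (default minimum overlap 10 bp, no
# difference allowed in the overlap region), drop assemblies absent from
# the allele database, and score survivors.

#' Enumerate maximal perfect-overlap assemblies of a read set
#'
#' Chains reads so that consecutive reads overlap by at least `min_overlap`
#' identical bases (no mismatch allowed in the overlap region) and each
#' read extends the growing sequence.  All maximal assembled sequences are
#' returned: although reads could be chained in any order, the full set of
#' maximal consistent assemblies is enumerated deterministically, so the
#' result does not depend on read order.  Assemblies that are substrings of
#' another assembly are suppressed.
#'
#' Intended for modest read sets (the chain enumeration is exhaustive, with
#' a safety cap of `max_chains`); the pipeline itself assembles reads along
#' database exon sequences, which is equivalent after the known-haplotype
#' filter (see the methods vignette).
#'
#' @param reads Character vector of corrected read sequences (with
#'   multiplicity; each physical read is used at most once per chain).
#' @param min_overlap Minimum exact suffix/prefix overlap in bp.
#' @param max_chains Safety cap on enumerated chains.
#' @return A list of assemblies, each a list with `sequence`,
#'   `depth_profile` (per-base count of reads covering the base), and
#'   `n_reads` (reads placed on the assembly).
#' @export
assemble_exon <- function(reads, min_overlap = 10L, max_chains = 10000L) {
  reads <- as.character(reads)
  if (length(reads) == 0L) return(list())
  stopifnot(min_overlap >= 1L, all(nzchar(reads)))
  uniq <- sort(unique(reads))
  counts <- table(factor(reads, levels = uniq))

  # DFS over chain extensions; state carries the assembled sequence and the
  # number of copies of each unique read still unused
  n_chains <- 0L
  sequences <- character(0)
  seen_states <- new.env(hash = TRUE, parent = emptyenv())
  extend <- function(assembly, avail) {
    state <- paste0(assembly, "|", paste(avail, collapse = ","))
    if (!is.null(seen_states[[state]])) return(invisible(NULL))
    seen_states[[state]] <- TRUE
    if (n_chains >= max_chains) return(invisible(NULL))
    extended <- FALSE
    la <- nchar(assembly)
    for (u in seq_along(uniq)) {
      if (avail[u] == 0L) next
      v <- uniq[u]
      lv <- nchar(v)
      for (ov in seq(min_overlap, min(la, lv))) {
        if (ov == lv) next  # contained, no extension
        if (substring(assembly, la - ov + 1L, la) == substring(v, 1L, ov)) {
          avail2 <- avail
          avail2[u] <- avail2[u] - 1L
          extended <- TRUE
          extend(paste0(assembly, substring(v, ov + 1L)), avail2)
        }
      }
    }
    if (!extended) {
      n_chains <<- n_chains + 1L
      sequences <<- c(sequences, assembly)
    }
    invisible(NULL)
  }
  for (u in seq_along(uniq)) {
    avail <- as.integer(counts)
    avail[u] <- avail[u] - 1L
    extend(uniq[u], avail)
  }

  sequences <- unique(sequences)
  maximal <- !vapply(seq_along(sequences), function(i) {
    any(vapply(seq_along(sequences), function(j) {
      i != j && nchar(sequences[j]) >= nchar(sequences[i]) &&
        grepl(sequences[i], sequences[j], fixed = TRUE)
    }, logical(1L)))
  }, logical(1L))
  sequences <- sort(sequences[maximal])
  lapply(sequences, function(s) place_reads_on(s, reads))
}

# depth profile and read count of an assembly: every read occurring in the
# assembly contributes once, at its first occurrence
place_reads_on <- function(assembly, reads) {
  L <- nchar(assembly)
  depth <- integer(L)
  n <- 0L
  for (r in reads) {
    p <- regexpr(r, assembly, fixed = TRUE)[1L]
    if (p > 0L) {
      depth[p:(p + nchar(r) - 1L)] <- depth[p:(p + nchar(r) - 1L)] + 1L
      n <- n + 1L
    }
  }
  list(sequence = assembly, depth_profile = depth, n_reads = n)
}

#' Depth-reliability of an assembled sequence
#'
#' `R = 1 / (1 + D)` where `D` is the per-degree-of-freedom depth
#' dispersion index `D = [sum((Xi - Xbar)^2) / Xbar] / df` with
#' `df = length - 1`.  `R` is 1 exactly when the depth is uniform and
#' decreases as the depth profile becomes more dispersed.  Profiles of
#' length < 2 are degenerate and score 1.
#'
#' @param depth_profile Integer vector of per-base read depths.
#' @return Reliability in (0, 1].
#' @examples
#' depth_reliability(c(20, 20, 20, 20))  # 1
#' depth_reliability(c(10, 20, 30))      # 1/6
#' @export
depth_reliability <- function(depth_profile) {
  x <- as.numeric(depth_profile)
  if (length(x) < 2L) return(1)
  xbar <- mean(x)
  if (xbar <= 0) return(1)
  d <- sum((x - xbar)^2) / xbar / (length(x) - 1L)
  1 / (1 + d)
}

#' Haplotype quality score
#'
#' `S = C * R * ln(1 + N)`: coverage fraction times depth-reliability times
#' a diminishing-returns function of the supporting read count.
#'
#' @param coverage Coverage fraction `C` of the corresponding exon, in
#'   (0, 1].
#' @param reliability Depth-reliability `R` from [depth_reliability()].
#' @param n_reads Read count `N` used to construct the assembly.
#' @return The score `S >= 0`.
#' @export
hscore <- function(coverage, reliability, n_reads) {
  coverage * reliability * log1p(n_reads)
}

#' Keep only assemblies present in the allele database
#'
#' An assembly survives when its sequence is a substring of (or equal to)
#' some database exon sequence for the gene and exon number; artificial
#' (chimeric) haplotypes are filtered out.  Each survivor is annotated with
#' the compatible alleles and scored.
#'
#' @param assemblies List of assemblies from [assemble_exon()] (or rows of
#'   the guided assembler).
#' @param db An `hla_allele_db`.
#' @param gene Gene symbol.
#' @param exon_number Exon ordinal.
#' @return An object of class `exon_assembly_set`: list with `gene`,
#'   `exon_number`, `haplotypes` (data frame: `sequence`, `n_reads`,
#'   `coverage`, `reliability`, `hscore`, `bridged`, plus list columns
#'   `depth` and `compatible`), and `fragments_joined`.
#' @export
filter_known_assemblies <- function(assemblies, db, gene, exon_number) {
  variants <- exon_sequences(db, gene, exon_number)
  als <- gene_alleles(db, gene)
  keep <- list()
  for (a in assemblies) {
    hits <- vapply(variants, function(v) grepl(a$sequence, v, fixed = TRUE),
                   logical(1L))
    if (!any(hits)) next
    compat <- names(Filter(function(al) {
      length(al$exons) >= exon_number &&
        grepl(a$sequence, al$exons[[exon_number]], fixed = TRUE)
    }, als))
    ref_len <- max(nchar(variants[hits]))
    C <- nchar(a$sequence) / ref_len
    R <- depth_reliability(a$depth_profile)
    keep[[length(keep) + 1L]] <- data.frame(
      sequence = a$sequence, n_reads = a$n_reads, coverage = C,
      reliability = R, hscore = hscore(C, R, a$n_reads),
      bridged = isTRUE(a$bridged), stringsAsFactors = FALSE)
    keep[[length(keep)]]$depth <- list(a$depth_profile)
    keep[[length(keep)]]$compatible <- list(compat)
  }
  haplotypes <- if (length(keep)) do.call(rbind, keep) else
    empty_haplotype_table()
  structure(list(gene = gene, exon_number = exon_number,
                 haplotypes = haplotypes,
                 fragments_joined = any(haplotypes$bridged)),
            class = "exon_assembly_set")
}

empty_haplotype_table <- function() {
  out <- data.frame(sequence = character(0), n_reads = integer(0),
                    coverage = numeric(0), reliability = numeric(0),
                    hscore = numeric(0), bridged = logical(0),
                    stringsAsFactors = FALSE)
  out$depth <- list()
  out$compatible <- list()
  out
}

#' @export
print.exon_assembly_set <- function(x, ...) {
  cat("<exon_assembly_set> ", x$gene, " exon ", x$exon_number, ": ",
      nrow(x$haplotypes), " haplotype(s)",
      if (isTRUE(x$fragments_joined)) " (bridged)", "\n", sep = "")
  invisible(x)
}

#' Bridge assembly fragments across low-depth gaps
#'
#' When an exon is broken into fragments by low-depth regions, fragment
#' combinations are paired and the gaps filled from a database exon
#' sequence, but only when the combined sequence is consistent with that
#' exon; combinations matching no database exon are dropped.  One bridged
#' candidate is emitted per database exon variant on which two or more
#' fragments place without overlap (gap bases carry depth 0).
#'
#' @param fragments List of assemblies (each with `sequence`,
#'   `depth_profile`, `n_reads`).
#' @param db An `hla_allele_db`.
#' @param gene Gene symbol.
#' @param exon_number Exon ordinal.
#' @return List of bridged candidate assemblies (possibly empty), each
#'   flagged `bridged = TRUE`.
#' @export
bridge_fragments <- function(fragments, db, gene, exon_number) {
  if (length(fragments) < 2L) return(list())
  variants <- exon_sequences(db, gene, exon_number)
  out <- list()
  for (v in variants) {
    # place every fragment that occurs in this variant (first occurrence)
    pos <- vapply(fragments, function(f)
      regexpr(f$sequence, v, fixed = TRUE)[1L], integer(1L))
    ok <- which(pos > 0L)
    if (length(ok) < 2L) next
    ord <- ok[order(pos[ok])]
    starts <- pos[ord]
    ends <- starts + vapply(fragments[ord], function(f) nchar(f$sequence),
                            integer(1L)) - 1L
    if (any(starts[-1L] <= ends[-length(ends)])) next  # overlapping: not a break
    span_start <- starts[1L]
    span_end <- ends[length(ends)]
    depth <- integer(span_end - span_start + 1L)
    n <- 0L
    for (k in seq_along(ord)) {
      i0 <- starts[k] - span_start + 1L
      depth[i0:(i0 + nchar(fragments[[ord[k]]]$sequence) - 1L)] <-
        fragments[[ord[k]]]$depth_profile
      n <- n + fragments[[ord[k]]]$n_reads
    }
    out[[length(out) + 1L]] <- list(
      sequence = substring(v, span_start, span_end),
      depth_profile = depth, n_reads = n, bridged = TRUE)
  }
  # dedupe identical bridged sequences arising from different variants
  if (length(out) > 1L) {
    seqs <- vapply(out, `[[`, character(1L), "sequence")
    out <- out[!duplicated(seqs)]
  }
  out
}

#' Assemble one gene's corrected reads along the database (pipeline path)
#'
#' For every exon of the gene, reads are chained along each distinct
#' database exon sequence (minimum perfect overlap `min_overlap`), which
#' yields exactly the maximal perfect-overlap assemblies that survive the
#' known-haplotype filter; fragments broken by low-depth regions are then
#' bridged.  See the methods vignette for the equivalence argument with
#' [assemble_exon()] + [filter_known_assemblies()].
#'
#' @param corrected Corrected reads data frame for one gene (from
#'   [correct_reads()]).
#' @param db An `hla_allele_db`.
#' @param gene Gene symbol.
#' @param min_overlap Minimum exact overlap in bp.
#' @return Named list of `exon_assembly_set`, one per exon with any reads.
#' @export
assemble_gene <- function(corrected, db, gene, min_overlap = 10L) {
  out <- list()
  if (nrow(corrected) == 0L) return(out)
  for (e in sort(unique(corrected$exon))) {
    seqs <- corrected$sequence[corrected$exon == e]
    raw <- assemble_guided(seqs, db, gene, e, min_overlap)
    frags <- raw[!vapply(raw, function(a) isTRUE(a$bridged), logical(1L))]
    bridged <- bridge_fragments(frags, db, gene, e)
    all_asm <- c(raw, bridged)
    seqs <- vapply(all_asm, `[[`, character(1L), "sequence")
    all_asm <- all_asm[!duplicated(seqs)]  # prefer the direct assembly
    out[[as.character(e)]] <-
      filter_known_assemblies(all_asm, db, gene, e)
  }
  out
}

# chain reads along each database exon variant; returns raw assemblies
# (maximal chained segments of each variant), deduped by sequence
assemble_guided <- function(read_seqs, db, gene, exon_number, min_overlap = 10L) {
  variants <- exon_sequences(db, gene, exon_number)
  if (length(variants) == 0L || length(read_seqs) == 0L) return(list())
  uniq <- unique(read_seqs)
  mult <- as.integer(table(factor(read_seqs, levels = uniq)))
  occ <- cpp_find_occurrences(uniq, variants)
  out <- list()
  for (vi in seq_along(variants)) {
    o <- occ[occ$subject == vi, , drop = FALSE]
    if (nrow(o) == 0L) next
    # each unique read placed once, at its first occurrence in the variant
    o <- o[order(o$query, o$start), , drop = FALSE]
    o <- o[!duplicated(o$query), , drop = FALSE]
    starts <- o$start                       # 0-based
    widths <- nchar(uniq[o$query])
    ends <- starts + widths                 # half-open
    m <- mult[o$query]
    ord <- order(starts, ends)
    starts <- starts[ord]; ends <- ends[ord]; m <- m[ord]
    # sweep: a read chains into the current segment when it overlaps the
    # covered prefix by at least min_overlap
    seg_id <- integer(length(starts))
    cur <- 0L
    reach <- -Inf
    for (i in seq_along(starts)) {
      if (starts[i] <= reach - min_overlap) {
        seg_id[i] <- cur
      } else {
        cur <- cur + 1L
        seg_id[i] <- cur
      }
      reach <- max(reach, ends[i])
    }
    for (s in seq_len(cur)) {
      i <- which(seg_id == s)
      s0 <- min(starts[i]); e0 <- max(ends[i])
      depth <- integer(e0 - s0)
      for (k in i) {
        idx <- (starts[k] - s0 + 1L):(ends[k] - s0)
        depth[idx] <- depth[idx] + m[k]
      }
      out[[length(out) + 1L]] <- list(
        sequence = substring(variants[vi], s0 + 1L, e0),
        depth_profile = depth, n_reads = sum(m[i]), bridged = FALSE)
    }
  }
  if (length(out) > 1L) {
    seqs <- vapply(out, `[[`, character(1L), "sequence")
    # dedupe identical segment sequences from different variants, and drop
    # segments contained in a longer segment (maximality)
    out <- out[!duplicated(seqs)]
    seqs <- unique(seqs)
    contained <- vapply(seq_along(seqs), function(i) {
      any(vapply(seq_along(seqs), function(j) {
        i != j && nchar(seqs[j]) > nchar(seqs[i]) &&
          grepl(seqs[i], seqs[j], fixed = TRUE)
      }, logical(1L)))
    }, logical(1L))
    out <- out[!contained]
  }
  out
}

#' Export assemblies as FASTA with structured headers
#'
#' Headers carry `gene|exon|C|N|R|S` separated by `|`.
#'
#' @param exon_sets Named list of `exon_assembly_set` (see
#'   [assemble_gene()]).
#' @param path Output FASTA path.
#' @export
write_assemblies <- function(exon_sets, path) {
  seqs <- character(0); hdrs <- character(0)
  for (es in exon_sets) {
    h <- es$haplotypes
    if (nrow(h) == 0L) next
    seqs <- c(seqs, h$sequence)
    hdrs <- c(hdrs, sprintf("%s|exon%d|C=%.4f|N=%d|R=%.4f|S=%.4f",
                            es$gene, es$exon_number, h$coverage, h$n_reads,
                            h$reliability, h$hscore))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- hdrs
  Biostrings::writeXStringSet(out, path, width = 80L)
  invisible(path)
}
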