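# Shared fixtures and independent oracles for the test suite.  All
# reference data is built in code; the oracles deliberately use naive
# algorithms, independent of the package's implementation paths.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_base <- function(seq, pos, to = NULL) {
  b <- substring(seq, pos, pos)
  if (is.null(to)) to <- setdiff(c("A", "C", "G", "T"), b)[1L]
  paste0(substring(seq, 1L, pos - 1L), to, substring(seq, pos + 1L))
}

# small exon-only database from a named list: gene -> list(label -> exons)
toy_db <- function(spec) {
  alleles <- list()
  for (gene in names(spec)) {
    for (label in names(spec[[gene]])) {
      alleles[[label]] <- new_allele(label, spec[[gene]][[label]])
    }
  }
  new_allele_database(alleles)
}

# ---- correction oracle -------------------------------------------------

# event-cost fitting alignment (mismatch 1, indel run of any length 1) of
# the read against the whole reference, by dense dynamic programming; the
# read aligns end to end (interior indels only), reference flanks free
slow_event_distance <- function(read, ref) {
  n <- nchar(read); m <- nchar(ref)
  rd <- strsplit(read, "")[[1L]]
  rf <- strsplit(ref, "")[[1L]]
  INF <- 1e9
  M <- matrix(INF, n + 1L, m + 1L)
  I <- matrix(INF, n + 1L, m + 1L)
  D <- matrix(INF, n + 1L, m + 1L)
  M[1L, ] <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 1L:(m + 1L)) {
      open <- if (i == 2L) INF else M[i - 1L, j] + 1  # no leading insertion
      I[i, j] <- min(open, I[i - 1L, j])
      if (j > 1L) {
        sub <- as.integer(rd[i - 1L] != rf[j - 1L])
        M[i, j] <- min(M[i - 1L, j - 1L], I[i - 1L, j - 1L],
                       D[i - 1L, j - 1L]) + sub
        D[i, j] <- min(M[i, j - 1L] + 1, D[i, j - 1L])
      }
    }
  }
  min(M[n + 1L, ])  # no trailing indel
}

# brute-force scan: best ungapped placement of the read over every offset
# of every exon of every allele of the gene; returns the minimum mismatch
# count and all (allele, exon, offset) attaining it
slow_best_sub_match <- function(read, db, gene) {
  n <- nchar(read)
  best <- list(mm = Inf, hits = NULL)
  for (a in gene_alleles(db, gene)) {
    for (e in seq_along(a$exons)) {
      ref <- a$exons[[e]]
      m <- nchar(ref)
      if (m < n) next
      for (off in 0:(m - n)) {
        mm <- sum(strsplit(read, "")[[1L]] !=
                    strsplit(substring(ref, off + 1L, off + n), "")[[1L]])
        if (mm < best$mm) {
          best <- list(mm = mm,
                       hits = data.frame(allele = a$name$raw, exon = e,
                                         offset = off))
        } else if (mm == best$mm) {
          best$hits <- rbind(best$hits,
                             data.frame(allele = a$name$raw, exon = e,
                                        offset = off))
        }
      }
    }
  }
  best
}

# ---- assembly oracle ---------------------------------------------------

merge_with_overlap <- function(u, v, min_overlap) {
  # all merged sequences u..v for every valid exact overlap
  out <- character(0)
  for (ov in seq(min_overlap, min(nchar(u), nchar(v)))) {
    if (ov == nchar(v)) next
    if (substring(u, nchar(u) - ov + 1L, nchar(u)) == substring(v, 1L, ov)) {
      out <- c(out, paste0(u, substring(v, ov + 1L)))
    }
  }
  out
}

# brute force over all read orderings: grow chains read by read (each
# physical read used at most once), collecting every sequence reachable
# when no unused read can extend it further; then keep maximal sequences
brute_force_assemblies <- function(reads, min_overlap = 10L) {
  results <- character(0)
  grow <- function(assembly, remaining) {
    extended <- FALSE
    for (k in seq_along(remaining)) {
      for (merged in merge_with_overlap(assembly, remaining[k], min_overlap)) {
        extended <- TRUE
        grow(merged, remaining[-k])
      }
    }
    if (!extended) results <<- c(results, assembly)
    invisible(NULL)
  }
  for (k in seq_along(reads)) grow(reads[k], reads[-k])
  results <- unique(results)
  maximal <- vapply(seq_along(results), function(i) {
    !any(vapply(seq_along(results), function(j) {
      i != j && nchar(results[j]) >= nchar(results[i]) &&
        grepl(results[i], results[j], fixed = TRUE)
    }, logical(1L)))
  }, logical(1L))
  sort(results[maximal])
}

# ---- SAM fixture -------------------------------------------------------

# minimal SAM with a header and the given alignment rows (list of named
# lists); converted to BAM on the fly by extract_gene_reads
write_toy_sam <- function(records, path, contigs = c(chr6 = 5000L)) {
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  for (r in records) {
    lines <- c(lines, paste(r$qname, r$flag, r$rname, r$pos, 60L,
                            r$cigar, "*", 0L, 0L, r$seq, r$qual, sep = "\t"))
  }
  writeLines(lines, path)
  path
}

sam_pair <- function(qname, pos1, pos2, rname = "chr6", len = 40L,
                     mapped = c(TRUE, TRUE), dup = FALSE, qual_char = "I") {
  seq1 <- random_dna(len); seq2 <- random_dna(len)
  f1 <- 1L + 64L + (!mapped[1L]) * 4L + (!mapped[2L]) * 8L
  f2 <- 1L + 128L + (!mapped[2L]) * 4L + (!mapped[1L]) * 8L
  if (dup) { f1 <- f1 + 1024L; f2 <- f2 + 1024L }
  list(
    list(qname = qname, flag = f1, rname = if (mapped[1L]) rname else "*",
         pos = if (mapped[1L]) pos1 else 0L,
         cigar = if (mapped[1L]) paste0(len, "M") else "*",
         seq = seq1, qual = strrep(qual_char, len)),
    list(qname = qname, flag = f2, rname = if (mapped[2L]) rname else "*",
         pos = if (mapped[2L]) pos2 else 0L,
         cigar = if (mapped[2L]) paste0(len, "M") else "*",
         seq = seq2, qual = strrep(qual_char, len)))
}
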