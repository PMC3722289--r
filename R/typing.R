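# Step 4 of the pipeline: combine exon haplotypes into candidate full-gene
# types, rank them by TScore, call zygosity by the supporting-read ratio
# (heterozygote threshold 0.1), attach the AScore confidence, and judge
# recorded discordances as novel variants.

# per-exon read support: for each exon, which reads are consistent with
# each distinct database exon variant (a read is consistent when its
# corrected sequence is a substring of the variant)
support_sets <- function(corrected, db, gene) {
  out <- list()
  for (e in sort(unique(corrected$exon))) {
    rows <- corrected[corrected$exon == e, , drop = FALSE]
    variants <- exon_sequences(db, gene, e)
    if (length(variants) == 0L) next
    uniq <- unique(rows$sequence)
    occ <- cpp_find_occurrences(uniq, variants)
    ids_by_variant <- lapply(seq_along(variants), function(vi) {
      qs <- unique(occ$query[occ$subject == vi])
      rows$read_id[rows$sequence %in% uniq[qs]]
    })
    out[[as.character(e)]] <- list(variants = variants,
                                   ids = ids_by_variant)
  }
  out
}

#' Enumerate candidate full-gene types
#'
#' One candidate is produced per database allele compatible with at least
#' one surviving assembly in at least one exon.  For every exon the
#' best-HScore assembly consistent with the allele is recorded as that
#' exon's support, and the candidate's TScore is the sum over supported
#' exons of `N_e * S_e` (supporting reads times HScore).
#'
#' @param exon_sets Named list of `exon_assembly_set` from
#'   [assemble_gene()].
#' @param db An `hla_allele_db`.
#' @param gene Gene symbol.
#' @param corrected Corrected reads for the gene (read support is counted
#'   from them: a read supports an allele when its corrected sequence is a
#'   substring of the allele's exon).
#' @return A list of candidates, each with `allele`, `exon_support` (data
#'   frame exon/sequence/n_reads/hscore), `n_support`, `support_ids` and
#'   `tscore`, ordered by decreasing TScore (ties: higher support, then
#'   allele name).
#' @export
enumerate_candidates <- function(exon_sets, db, gene, corrected) {
  sup <- support_sets(corrected, db, gene)
  cands <- list()
  for (a in gene_alleles(db, gene)) {
    exon_rows <- list()
    ids <- character(0)
    for (e_chr in names(exon_sets)) {
      es <- exon_sets[[e_chr]]
      h <- es$haplotypes
      if (nrow(h) == 0L) next
      e <- es$exon_number
      if (length(a$exons) < e) next
      compat <- vapply(h$compatible, function(cc) a$name$raw %in% cc, logical(1L))
      if (!any(compat)) next
      hi <- h[compat, , drop = FALSE]
      hi <- hi[order(-hi$hscore, -nchar(hi$sequence), hi$sequence), , drop = FALSE]
      exon_rows[[e_chr]] <- data.frame(
        exon = e, sequence = hi$sequence[1L], n_reads = hi$n_reads[1L],
        hscore = hi$hscore[1L], stringsAsFactors = FALSE)
      ss <- sup[[e_chr]]
      if (!is.null(ss)) {
        vi <- match(a$exons[[e]], ss$variants)
        if (!is.na(vi)) ids <- c(ids, ss$ids[[vi]])
      }
    }
    if (length(exon_rows) == 0L) next
    exon_support <- do.call(rbind, exon_rows)
    cands[[length(cands) + 1L]] <- list(
      allele = a$name$raw, exon_support = exon_support,
      n_support = length(ids), support_ids = ids,
      tscore = sum(exon_support$n_reads * exon_support$hscore))
  }
  if (length(cands) == 0L) return(list())
  ord <- order(-vapply(cands, `[[`, numeric(1L), "tscore"),
               -vapply(cands, `[[`, numeric(1L), "n_support"),
               vapply(cands, `[[`, character(1L), "allele"))
  cands[ord]
}

#' TScore of a candidate type
#'
#' `TScore = sum over supported exons of N_e * S_e`, monotone
#' non-decreasing in every exon's read support and HScore.
#'
#' @param candidate A candidate from [enumerate_candidates()] (or any list
#'   with an `exon_support` data frame).
#' @return The TScore (0 for a candidate with no supported exons).
#' @export
tscore <- function(candidate) {
  es <- candidate$exon_support
  if (is.null(es) || nrow(es) == 0L) return(0)
  sum(es$n_reads * es$hscore)
}

#' Select the best and sub-optimal candidate types
#'
#' Returns the two top-TScore candidates (ties broken by higher read
#' support, then allele name) and partitions read support between them:
#' reads consistent with both count in both support totals but in neither
#' unique count.
#'
#' @param candidates Candidate list from [enumerate_candidates()].
#' @return A list with `best` and `suboptimal` (the latter `NULL` when only
#'   one candidate exists), each annotated with `n_unique_support` relative
#'   to the other.
#' @export
select_pair <- function(candidates) {
  stopifnot(length(candidates) >= 1L)
  ord <- order(-vapply(candidates, `[[`, numeric(1L), "tscore"),
               -vapply(candidates, `[[`, numeric(1L), "n_support"),
               vapply(candidates, `[[`, character(1L), "allele"))
  candidates <- candidates[ord]
  best <- candidates[[1L]]
  sub <- if (length(candidates) >= 2L) candidates[[2L]] else NULL
  if (!is.null(sub)) {
    best$n_unique_support <- length(setdiff(best$support_ids, sub$support_ids))
    sub$n_unique_support <- length(setdiff(sub$support_ids, best$support_ids))
  } else {
    best$n_unique_support <- best$n_support
  }
  list(best = best, suboptimal = sub)
}

#' Call zygosity from the supporting-read ratio
#'
#' The ratio of the sub-optimal type's unique supporting reads to the best
#' type's supporting reads decides zygosity: below the threshold (default
#' 0.1) the gene is a homozygote and only the best type is called;
#' otherwise it is a heterozygote and both types are called.  A ratio
#' exactly at the threshold calls a heterozygote (the homozygote is defined
#' strictly below it).
#'
#' @param best,suboptimal Candidates from [select_pair()] (`suboptimal` may
#'   be `NULL`, giving ratio 0).
#' @param threshold Heterozygote threshold on the ratio.
#' @return A list with `zygosity` ("homozygote"/"heterozygote"), `ratio`
#'   and `alleles` (1 or 2 allele names).
#' @export
call_zygosity <- function(best, suboptimal, threshold = 0.1) {
  if (is.null(best) || best$n_support == 0L) {
    stop("typing failure: best candidate has no supporting reads")
  }
  ratio <- if (is.null(suboptimal)) 0 else
    suboptimal$n_unique_support / best$n_support
  if (ratio < threshold) {
    list(zygosity = "homozygote", ratio = ratio, alleles = best$allele)
  } else {
    list(zygosity = "heterozygote", ratio = ratio,
         alleles = c(best$allele, suboptimal$allele))
  }
}

#' Confidence score of the final call
#'
#' `AScore = (S2 - S1) / S0` clamped to `[0, 1]`: the score separation
#' between the final type (`S2`) and its nearest competing type (`S1`),
#' normalized by the full score `S0` of all assembled haplotypes of the
#' gene.  Larger values mean a more confident separation.
#'
#' @param S0 Full score of all surviving assemblies (sum of
#'   `HScore * n_reads`).
#' @param S1 Score of the closest competing type.
#' @param S2 Score of the final type.
#' @return AScore in `[0, 1]`, or `NA` when `S0 <= 0` (undefined
#'   confidence).
#' @export
ascore <- function(S0, S1, S2) {
  if (!is.finite(S0) || S0 <= 0) return(NA_real_)
  min(1, max(0, (S2 - S1) / S0))
}

#' Judge recorded discordances as novel variants
#'
#' A discordance from the correction ledger is emitted as novel when (a)
#' its read support reaches `min_support` (default 4, the pipeline's
#' variant-calling depth floor), (b) the variant is absent from every
#' database allele of the gene at that exon -- checked by applying the edit
#' to the matched exon and looking for the edited context in all database
#' exon variants -- and (c) it can be attached to one of the called
#' alleles, whose name is recorded as the variant's closest type.
#'
#' @param ledger Variant ledger from [correct_reads()].
#' @param final A typing result (list with `gene` and `alleles`).
#' @param db An `hla_allele_db`.
#' @param min_support Minimum supporting reads.
#' @param context Bases of flanking context used for the novelty check.
#' @return The subset of ledger rows judged novel, with a `called_allele`
#'   column.
#' @export
judge_novel_variants <- function(ledger, final, db, min_support = 4L,
                                 context = 10L) {
  if (nrow(ledger) == 0L || length(final$alleles) == 0L) {
    out <- ledger[integer(0), , drop = FALSE]
    out$called_allele <- character(0)
    return(out)
  }
  gene <- final$gene
  keep <- logical(nrow(ledger))
  called_allele <- character(nrow(ledger))
  for (i in seq_len(nrow(ledger))) {
    rec <- ledger[i, ]
    if (rec$support < min_support) next
    a <- db$alleles[[rec$allele]]
    if (is.null(a) || length(a$exons) < rec$exon) next
    exon_seq <- a$exons[[rec$exon]]
    edited <- apply_variant(exon_seq, rec$position, rec$ref, rec$alt)
    w0 <- max(1L, rec$position + 1L - context)
    w1 <- min(nchar(edited), rec$position + nchar(rec$alt) + context)
    window <- substring(edited, w0, w1)
    variants <- exon_sequences(db, gene, rec$exon)
    if (any(vapply(variants, function(v) grepl(window, v, fixed = TRUE),
                   logical(1L)))) {
      next  # the alternate state exists in another extant type
    }
    keep[i] <- TRUE
    # closest called type: the called allele sharing the matched exon
    # sequence, else the first called allele
    hit <- vapply(final$alleles, function(ca) {
      cal <- db$alleles[[ca]]
      length(cal$exons) >= rec$exon && cal$exons[[rec$exon]] == exon_seq
    }, logical(1L))
    called_allele[i] <- if (any(hit)) final$alleles[which(hit)[1L]] else
      final$alleles[1L]
  }
  out <- ledger[keep, , drop = FALSE]
  out$called_allele <- called_allele[keep]
  out
}

# apply one SNP/insertion/deletion to a sequence (0-based position)
apply_variant <- function(seq, position, ref, alt) {
  p <- position + 1L
  if (nzchar(ref) && nzchar(alt)) {          # substitution
    paste0(substring(seq, 1L, p - 1L), alt, substring(seq, p + nchar(ref)))
  } else if (nzchar(ref)) {                  # deletion of ref at p
    paste0(substring(seq, 1L, p - 1L), substring(seq, p + nchar(ref)))
  } else {                                   # insertion of alt before p
    paste0(substring(seq, 1L, p - 1L), alt, substring(seq, p))
  }
}

#' Type one gene from corrected reads
#'
#' Runs assembly, candidate enumeration, pair selection, zygosity and
#' confidence scoring, and novel-variant judgment for a single gene.
#' Genes with no surviving assembly yield a structured "untypeable" result
#' rather than an error, so a multi-gene run always completes.
#'
#' @param correction An `hla_correction` from [correct_reads()].
#' @param db An `hla_allele_db`.
#' @param gene Gene symbol.
#' @param min_overlap Minimum assembly overlap (bp).
#' @param het_threshold Heterozygote ratio threshold.
#' @param novel_min_support Minimum read support for a novel variant.
#' @return A list of class `hla_typing_result`: `gene`, `status`
#'   ("ok"/"untypeable"), `zygosity`, `alleles`, `ratio`, `ascore`,
#'   `tscore` (named, per called allele), `candidates` (summary data
#'   frame) and `novel_variants`.
#' @export
type_gene <- function(correction, db, gene, min_overlap = 10L,
                      het_threshold = 0.1, novel_min_support = 4L) {
  corr <- correction$genes[[gene]]
  untypeable <- structure(
    list(gene = gene, status = "untypeable", zygosity = NA_character_,
         alleles = character(0), ratio = NA_real_, ascore = NA_real_,
         tscore = numeric(0), candidates = NULL,
         novel_variants = empty_ledger()),
    class = "hla_typing_result")
  if (is.null(corr) || nrow(corr$corrected) == 0L) return(untypeable)
  exon_sets <- assemble_gene(corr$corrected, db, gene, min_overlap = min_overlap)
  if (all(vapply(exon_sets, function(es) nrow(es$haplotypes) == 0L, logical(1L)))) {
    return(untypeable)
  }
  cands <- enumerate_candidates(exon_sets, db, gene, corr$corrected)
  if (length(cands) == 0L) return(untypeable)
  pair <- select_pair(cands)
  if (pair$best$n_support == 0L) return(untypeable)
  zyg <- call_zygosity(pair$best, pair$suboptimal, threshold = het_threshold)

  # confidence: S2 = final type's score, S1 = best candidate outside the
  # final call, S0 = full score of all surviving assemblies of the gene
  S0 <- sum(vapply(exon_sets, function(es) {
    h <- es$haplotypes
    if (nrow(h) == 0L) 0 else sum(h$hscore * h$n_reads)
  }, numeric(1L)))
  S2 <- pair$best$tscore
  outside <- Filter(function(cc) !(cc$allele %in% zyg$alleles), cands)
  S1 <- if (length(outside)) max(vapply(outside, `[[`, numeric(1L), "tscore")) else 0
  conf <- ascore(S0, S1, S2)

  cand_df <- do.call(rbind, lapply(cands, function(cc) data.frame(
    allele = cc$allele, tscore = cc$tscore, n_support = cc$n_support,
    stringsAsFactors = FALSE)))
  ts <- stats::setNames(
    vapply(zyg$alleles, function(a)
      cand_df$tscore[match(a, cand_df$allele)], numeric(1L)),
    zyg$alleles)
  result <- structure(
    list(gene = gene, status = "ok", zygosity = zyg$zygosity,
         alleles = zyg$alleles, ratio = zyg$ratio, ascore = conf,
         tscore = ts, candidates = cand_df,
         novel_variants = empty_ledger()),
    class = "hla_typing_result")
  result$novel_variants <- judge_novel_variants(
    corr$ledger, result, db, min_support = novel_min_support)
  result
}

#' @export
print.hla_typing_result <- function(x, ...) {
  if (x$status != "ok") {
    cat("<hla_typing_result> ", x$gene, ": untypeable\n", sep = "")
    return(invisible(x))
  }
  cat("<hla_typing_result> ", x$gene, ": ",
      paste(x$alleles, collapse = " / "), " (", x$zygosity,
      ", ratio ", signif(x$ratio, 3), ", AScore ", signif(x$ascore, 3), ")\n",
      sep = "")
  if (nrow(x$novel_variants)) {
    cat("  novel variants: ", nrow(x$novel_variants), "\n", sep = "")
  }
  invisible(x)
}

#' Type all genes of a sample
#'
#' Harvested (or simulated) reads are corrected against the database once;
#' each read is assigned to the gene of its closest reference, then every
#' requested gene is typed.
#'
#' @param reads Data frame with `id` and `sequence` (e.g. simulator
#'   output), a `gene_read_set`, or a list of `gene_read_set` whose reads
#'   are pooled by id.
#' @param db An `hla_allele_db`.
#' @param genes Genes to type.
#' @param ... Passed on to [correct_reads()] and [type_gene()].
#' @return A named list of `hla_typing_result`, one per gene.
#' @export
type_sample <- function(reads, db, genes = db$genes, ...) {
  dots <- list(...)
  corr_args <- dots[names(dots) %in% c("max_discordances", "min_span", "band",
                                       "indel_rescue")]
  type_args <- dots[names(dots) %in% c("min_overlap", "het_threshold",
                                       "novel_min_support")]
  if (inherits(reads, "gene_read_set")) reads <- reads$reads
  if (is.list(reads) && !is.data.frame(reads) &&
      all(vapply(reads, inherits, logical(1L), "gene_read_set"))) {
    pooled <- do.call(rbind, lapply(reads, function(rs)
      rs$reads[, c("id", "sequence"), drop = FALSE]))
    reads <- pooled[!duplicated(pooled$id), , drop = FALSE]
  }
  correction <- do.call(correct_reads,
                        c(list(reads = reads, db = db, genes = genes), corr_args))
  stats::setNames(lapply(genes, function(g)
    do.call(type_gene, c(list(correction = correction, db = db, gene = g),
                         type_args))), genes)
}

#' Tabulate typing results as a report
#'
#' @param results Named list of `hla_typing_result` (from [type_sample()]).
#' @param sample Sample identifier written into the first column.
#' @return Data frame with one row per gene: sample, gene, allele1,
#'   allele2 (`NA` for homozygotes), zygosity, ratio, tscore1, tscore2,
#'   ascore, n_novel, status.
#' @export
typing_report <- function(results, sample = "sample") {
  do.call(rbind, lapply(results, function(r) data.frame(
    sample = sample, gene = r$gene,
    allele1 = if (length(r$alleles) >= 1L) r$alleles[1L] else NA_character_,
    allele2 = if (length(r$alleles) >= 2L) r$alleles[2L] else NA_character_,
    zygosity = r$zygosity, ratio = r$ratio,
    tscore1 = if (length(r$tscore) >= 1L) unname(r$tscore[1L]) else NA_real_,
    tscore2 = if (length(r$tscore) >= 2L) unname(r$tscore[2L]) else NA_real_,
    ascore = r$ascore, n_novel = nrow(r$novel_variants), status = r$status,
    stringsAsFactors = FALSE)))
}

#' Write a typing report as TSV with a JSON evidence sidecar
#'
#' @param results Named list of `hla_typing_result`.
#' @param path Output TSV path; the JSON sidecar is written next to it with
#'   extension `.json`.
#' @param sample Sample identifier.
#' @export
write_typing_report <- function(results, path, sample = "sample") {
  report <- typing_report(results, sample = sample)
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- lapply(results, function(r) list(
    gene = r$gene, status = r$status, alleles = r$alleles,
    zygosity = r$zygosity, ratio = r$ratio, ascore = r$ascore,
    candidates = r$candidates,
    novel_variants = r$novel_variants))
  jsonlite::write_json(sidecar, sub("\\.[^.]*$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
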