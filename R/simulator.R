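# Synthetic allele panels, diploid paired-end read simulation, and the
# 2/4-digit typing-accuracy evaluator.

#' Simulation parameters for diploid read generation
#'
#' Defaults emulate the target capture sequencing design: 2 x 91 bp
#' paired-end reads with insert size 500 bp (SD 10), substitution-only
#' sequencing errors.
#'
#' @param depth Mean fold coverage over the diploid (both haplotypes
#'   together).
#' @param error_rate Per-base substitution probability, in [0, 0.05].
#' @param insert_mean,insert_sd Fragment insert size mean and SD (bp).
#' @param read_length Read length (bp).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param haplotype_pair `"random"` (two distinct alleles drawn per gene),
#'   a character vector of two allele names (applied to their gene; equal
#'   names simulate a homozygote), or a named list `gene -> c(a1, a2)`.
#' @return A `simulation_config`.
#' @export
simulation_config <- function(depth = 50, error_rate = 0, insert_mean = 500,
                              insert_sd = 10, read_length = 91L, seed = NULL,
                              haplotype_pair = "random") {
  stopifnot(depth > 0, error_rate >= 0, error_rate <= 0.05,
            insert_mean >= read_length, insert_sd >= 0, read_length >= 1L)
  structure(list(depth = depth, error_rate = error_rate,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 read_length = as.integer(read_length), seed = seed,
                 haplotype_pair = haplotype_pair),
            class = "simulation_config")
}

#' Generate a synthetic allele panel
#'
#' Builds a small IMGT/HLA-style database: per gene an ancestral sequence
#' (exons separated by introns, with flanking sequence) is mutated
#' independently per allele at the given per-base substitution rate.
#' Alleles of a gene are guaranteed pairwise distinguishable at one or more
#' exonic sites (the gene is regenerated until true); generation is
#' deterministic under `seed`.  Allele names follow two-field nomenclature
#' with two protein variants per allele group (`G1*01:01`, `G1*01:02`,
#' `G1*02:01`, ...), so truncation to one field merges allele groups.
#'
#' @param n_genes,alleles_per_gene,exons_per_gene Panel dimensions.
#' @param divergence Per-base substitution rate between an allele and the
#'   gene ancestor (pairwise divergence is about twice this).
#' @param seed Integer seed.
#' @param exon_length,intron_length,flank Segment lengths (bp); introns
#'   longer than the read length keep any read inside a single exon.
#' @param max_retries Regeneration attempts before giving up on
#'   indistinguishable alleles.
#' @return An `hla_allele_db` with full sequences and exon coordinates.
#' @export
generate_synthetic_db <- function(n_genes = 3L, alleles_per_gene = 8L,
                                  exons_per_gene = 8L, divergence = 0.01,
                                  seed = 1L, exon_length = 270L,
                                  intron_length = 140L, flank = 150L,
                                  max_retries = 100L) {
  stopifnot(alleles_per_gene >= 2L, exons_per_gene >= 1L, n_genes >= 1L,
            divergence >= 0, divergence <= 0.05)
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  alleles <- list()
  for (g in seq_len(n_genes)) {
    # layout: flank | exon1 | intron | exon2 | ... | exonK | flank
    starts <- flank + 1L + (seq_len(exons_per_gene) - 1L) *
      (exon_length + intron_length)
    ends <- starts + exon_length - 1L
    L <- ends[exons_per_gene] + flank
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      ancestor <- sample(bases, L, replace = TRUE)
      exonic <- unlist(lapply(seq_len(exons_per_gene), function(e)
        starts[e]:ends[e]))
      seqs <- lapply(seq_len(alleles_per_gene), function(i) {
        s <- ancestor
        mut <- which(stats::runif(L) < divergence)
        if (length(mut)) {
          s[mut] <- vapply(s[mut], function(b)
            sample(setdiff(bases, b), 1L), character(1L))
        }
        s
      })
      distinct <- TRUE
      for (i in seq_len(alleles_per_gene - 1L)) {
        for (j in (i + 1L):alleles_per_gene) {
          if (!any(seqs[[i]][exonic] != seqs[[j]][exonic])) {
            distinct <- FALSE
            break
          }
        }
        if (!distinct) break
      }
      if (distinct) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("could not generate pairwise-distinguishable alleles for gene G",
           g, " after ", max_retries, " attempts (divergence too low?)")
    }
    for (i in seq_len(alleles_per_gene)) {
      full <- paste(seqs[[i]], collapse = "")
      label <- sprintf("G%d*%02d:%02d", g, ceiling(i / 2), (i - 1L) %% 2L + 1L)
      alleles[[label]] <- new_allele(
        parse_allele_name(label),
        exons = substring(full, starts, ends),
        full_sequence = full,
        exon_ranges = cbind(start = starts, end = ends))
    }
  }
  new_allele_database(alleles)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate diploid paired-end reads from an allele panel
#'
#' For every gene two haplotype alleles are chosen (see
#' `haplotype_pair` in [simulation_config()]) and sequenced in silico:
#' fragments with insert length Normal(`insert_mean`, `insert_sd`)
#' (truncated at the read length) are drawn uniformly from each haplotype's
#' full sequence in equal expectation, yielding a forward read from the
#' fragment start and a reverse-complement read from its end, with
#' independent per-base substitution errors at `error_rate`.  Read names
#' carry the haplotype of origin for debugging; the typing pipeline never
#' reads them.
#'
#' @param db An `hla_allele_db` whose alleles carry full sequences.
#' @param config A [simulation_config()].
#' @param sample_id Sample name used in read names and the truth table.
#' @return A list of class `hla_simulation`: `reads` (data frame `id`,
#'   `sequence`, `quality`), `truth` (data frame `sample`, `gene`,
#'   `allele1`, `allele2`) and `config`.
#' @export
simulate_diploid <- function(db, config = simulation_config(),
                             sample_id = "sim1") {
  stopifnot(inherits(db, "hla_allele_db"), inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  rl <- config$read_length
  ids <- character(0); seqs <- character(0)
  truth <- list()
  for (g in db$genes) {
    als <- gene_alleles(db, g)
    pair <- choose_pair(config$haplotype_pair, als, g)
    truth[[g]] <- data.frame(sample = sample_id, gene = g,
                             allele1 = pair[1L], allele2 = pair[2L],
                             stringsAsFactors = FALSE)
    for (hap in 1:2) {
      a <- als[[pair[hap]]]
      template <- if (!is.null(a$full_sequence)) a$full_sequence else
        paste(a$exons, collapse = "")
      L <- nchar(template)
      if (L < rl) {
        stop("template of ", pair[hap], " shorter than the read length")
      }
      n_frag <- max(1L, as.integer(round(config$depth * L / (4 * rl))))
      ins <- pmin(L, pmax(rl, as.integer(round(
        stats::rnorm(n_frag, config$insert_mean, config$insert_sd)))))
      start <- as.integer(floor(stats::runif(n_frag) * (L - ins + 1L)))  # 0-based
      r1 <- substring(template, start + 1L, start + rl)
      r2 <- revcomp_chr(substring(template, start + ins - rl + 1L, start + ins))
      rd <- c(rbind(r1, r2))  # interleaved
      if (config$error_rate > 0) rd <- add_errors(rd, config$error_rate)
      frag_no <- rep(seq_len(n_frag), each = 2L)
      mate <- rep(1:2, n_frag)
      ids <- c(ids, sprintf("%s:%s:h%d:%d/%d", sample_id, g, hap, frag_no, mate))
      seqs <- c(seqs, rd)
    }
  }
  structure(list(
    reads = data.frame(id = ids, sequence = seqs,
                       quality = strrep("I", nchar(seqs)),
                       stringsAsFactors = FALSE),
    truth = do.call(rbind, truth), config = config),
    class = "hla_simulation")
}

choose_pair <- function(haplotype_pair, als, gene) {
  if (is.list(haplotype_pair) && !is.null(haplotype_pair[[gene]])) {
    pair <- haplotype_pair[[gene]]
  } else if (is.character(haplotype_pair) && length(haplotype_pair) == 2L) {
    pair <- haplotype_pair
  } else if (identical(haplotype_pair, "random")) {
    return(sample(names(als), 2L, replace = FALSE))
  } else {
    stop("haplotype_pair must be \"random\", two allele names, or a named list")
  }
  if (!all(pair %in% names(als))) {
    stop("haplotype alleles not in the database for gene ", gene, ": ",
         paste(setdiff(pair, names(als)), collapse = ", "))
  }
  pair
}

# independent per-base substitutions; each errored base becomes one of the
# three other bases uniformly
add_errors <- function(reads, error_rate) {
  bases <- c("A", "C", "G", "T")
  n_err <- stats::rbinom(length(reads), nchar(reads), error_rate)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(nchar(reads[i]), n_err[i])
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
    chars[pos] <- vapply(chars[pos], function(b)
      sample(setdiff(bases, b), 1L), character(1L))
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Write simulated reads as paired FASTQ
#'
#' Mates are split on the trailing `/1` / `/2` of the read names.
#'
#' @param sim An `hla_simulation` (or its `reads` data frame).
#' @param prefix Output prefix; files `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written.
#' @return Invisibly, the two paths.
#' @export
write_fastq <- function(sim, prefix) {
  reads <- if (inherits(sim, "hla_simulation")) sim$reads else sim
  paths <- character(2L)
  for (mate in 1:2) {
    sel <- endsWith(reads$id, paste0("/", mate))
    s <- Biostrings::DNAStringSet(reads$sequence[sel])
    names(s) <- reads$id[sel]
    paths[mate] <- paste0(prefix, "_", mate, ".fastq")
    Biostrings::writeXStringSet(
      s, paths[mate], format = "fastq",
      qualities = Biostrings::BStringSet(reads$quality[sel]))
  }
  invisible(paths)
}

#' Allele-level typing accuracy against truth
#'
#' Calls and truth are compared per (sample, gene) after truncating both
#' to `n_fields` name fields; each gene contributes two alleles (a
#' homozygous call or truth counts its allele twice), and the called pair
#' is matched to the truth pair in the orientation that maximizes
#' agreement.  Accuracy is correctly called alleles over total truth
#' alleles.
#'
#' @param results Data frame of calls with columns `sample`, `gene`,
#'   `allele1`, `allele2` (`NA` allele2 = homozygote; see
#'   [typing_report()]); any `depth` / `error_rate` columns are used as
#'   grouping conditions.
#' @param truth Data frame with columns `sample`, `gene`, `allele1`,
#'   `allele2`.
#' @param n_fields Resolution in name fields (1 = 2-digit, 2 = 4-digit),
#'   possibly a vector.
#' @return Long-format data frame: condition columns (if any),
#'   `resolution` (fields), `n_alleles`, `n_correct`, `accuracy`.
#' @export
evaluate_typing <- function(results, truth, n_fields = c(1L, 2L)) {
  key_r <- paste(results$sample, results$gene)
  key_t <- paste(truth$sample, truth$gene)
  orphan_r <- setdiff(key_r, key_t)
  orphan_t <- setdiff(key_t, key_r)
  if (length(orphan_r) || length(orphan_t)) {
    stop("results/truth key mismatch; only in results: [",
         paste(orphan_r, collapse = ", "), "]; only in truth: [",
         paste(orphan_t, collapse = ", "), "]")
  }
  m <- merge(results, truth, by = c("sample", "gene"),
             suffixes = c("", ".truth"))
  group_cols <- intersect(c("depth", "error_rate"), names(results))
  out <- list()
  for (nf in n_fields) {
    n_correct <- vapply(seq_len(nrow(m)), function(i) {
      called <- c(m$allele1[i],
                  if (is.na(m$allele2[i])) m$allele1[i] else m$allele2[i])
      if (anyNA(called)) return(0L)
      tr <- c(m$allele1.truth[i], m$allele2.truth[i])
      eq <- function(a, b) same_allele_at_resolution(a, b, nf)
      max(eq(called[1L], tr[1L]) + eq(called[2L], tr[2L]),
          eq(called[1L], tr[2L]) + eq(called[2L], tr[1L]))
    }, integer(1L))
    grp <- if (length(group_cols)) {
      interaction(m[group_cols], drop = TRUE, lex.order = TRUE)
    } else {
      factor(rep("all", nrow(m)))
    }
    for (lev in levels(grp)) {
      sel <- grp == lev
      row <- if (length(group_cols)) {
        unique(m[sel, group_cols, drop = FALSE])[1L, , drop = FALSE]
      } else {
        data.frame(row.names = 1L)
      }
      row$resolution <- nf
      row$n_alleles <- 2L * sum(sel)
      row$n_correct <- sum(n_correct[sel])
      row$accuracy <- row$n_correct / row$n_alleles
      out[[length(out) + 1L]] <- row
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Run a typing-accuracy simulation study
#'
#' Simulates diploid samples over a grid of sequencing depths and error
#' rates, types each with the full pipeline, and evaluates allele-level
#' accuracy at the requested resolutions.  All randomness flows from a
#' single seeded stream, so the study is reproducible.
#'
#' @param db Allele panel (default: the package's standard synthetic
#'   panel).
#' @param depths,error_rates Condition grid.
#' @param n_samples Diploid samples per condition.
#' @param n_fields Resolutions to evaluate (name fields).
#' @param seed Integer seed.
#' @param genes Genes to type (default: all).
#' @return A list with `accuracy` (long-format condition table), `calls`
#'   (per-sample typing report rows) and `truth`.
#' @export
run_simulation_study <- function(db = generate_synthetic_db(),
                                 depths = c(20, 50, 100),
                                 error_rates = c(0, 0.01, 0.02),
                                 n_samples = 36L, n_fields = c(1L, 2L),
                                 seed = 1L, genes = db$genes) {
  set.seed(seed)
  calls <- list(); truths <- list()
  for (d in depths) {
    for (e in error_rates) {
      for (s in seq_len(n_samples)) {
        cfg <- simulation_config(depth = d, error_rate = e, seed = NULL)
        sid <- sprintf("d%g_e%g_s%d", d, e, s)
        sim <- simulate_diploid(db, cfg, sample_id = sid)
        res <- type_sample(sim$reads, db, genes = genes)
        rep_df <- typing_report(res, sample = sid)
        rep_df$depth <- d
        rep_df$error_rate <- e
        calls[[length(calls) + 1L]] <- rep_df
        truths[[length(truths) + 1L]] <- sim$truth
      }
    }
  }
  calls <- do.call(rbind, calls)
  truths <- do.call(rbind, truths)
  acc <- evaluate_typing(calls, truths, n_fields = n_fields)
  list(accuracy = acc, calls = calls, truth = truths)
}
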