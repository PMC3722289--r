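#' Parse an HLA allele name
#'
#' Splits an allele label into its gene symbol and numeric name fields.
#' Modern colon-delimited nomenclature (`"A*01:01:01:01"`) and legacy
#' digit-run names (`"B*0702"`, split into 2-character fields) are both
#' accepted, so calls from either era compare correctly at two-field
#' ("4-digit") resolution.  An expression-suffix letter (N, L, S, C, A, Q)
#' on the final field is preserved in `fields` but ignored when names are
#' compared at a given resolution.
#'
#' @param label Allele label string, `GENE*FIELDS`.
#' @return An object of class `hla_allele_name` with elements `gene`
#'   (character), `fields` (character vector, 1--4 elements) and `raw`
#'   (the input label).
#' @examples
#' parse_allele_name("A*01:01:01:01")
#' parse_allele_name("DRB1*15:01")
#' parse_allele_name("B*0702")   # legacy: fields "07", "02"
#' @export
parse_allele_name <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!grepl("^[A-Za-z][A-Za-z0-9_-]*\\*", label)) {
    stop("malformed allele label (expected GENE*fields): '", label, "'")
  }
  parts <- strsplit(label, "*", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || !nzchar(parts[2L])) {
    stop("malformed allele label (expected GENE*fields): '", label, "'")
  }
  gene <- parts[1L]
  body <- parts[2L]
  suffix <- ""
  if (grepl("[A-Za-z]$", body)) {
    suffix <- substring(body, nchar(body))
    body <- substring(body, 1L, nchar(body) - 1L)
  }
  if (grepl(":", body, fixed = TRUE)) {
    fields <- strsplit(body, ":", fixed = TRUE)[[1L]]
  } else {
    # legacy nomenclature: an even run of digits, two digits per field
    if (!grepl("^[0-9]+$", body) || nchar(body) %% 2L != 0L) {
      stop("malformed legacy allele label: '", label, "'")
    }
    n <- nchar(body) / 2L
    fields <- substring(body, seq_len(n) * 2L - 1L, seq_len(n) * 2L)
  }
  if (length(fields) < 1L || length(fields) > 4L ||
      !all(grepl("^[0-9]+$", fields))) {
    stop("malformed allele label (bad fields): '", label, "'")
  }
  if (nzchar(suffix)) fields[length(fields)] <- paste0(fields[length(fields)], suffix)
  structure(list(gene = gene, fields = fields, raw = label),
            class = "hla_allele_name")
}

#' @export
print.hla_allele_name <- function(x, ...) {
  cat("<hla_allele_name> ", format_allele_name(x), "\n", sep = "")
  invisible(x)
}

#' Format an allele name in modern colon nomenclature
#'
#' @param name An `hla_allele_name`.
#' @return A string `GENE*F1:F2:...`.
#' @export
format_allele_name <- function(name) {
  stopifnot(inherits(name, "hla_allele_name"))
  paste0(name$gene, "*", paste(name$fields, collapse = ":"))
}

#' Truncate an allele name to a lower typing resolution
#'
#' Keeps the first `n_fields` name fields: one field corresponds to the
#' classical "2-digit" (allele group) resolution, two fields to "4-digit"
#' (protein-level) resolution.  Truncation is idempotent and monotone; a
#' name with fewer fields than requested is returned unchanged.
#'
#' @param name An `hla_allele_name` (or a label string, parsed on the fly).
#' @param n_fields Number of leading fields to keep (>= 1).
#' @return An `hla_allele_name` with at most `n_fields` fields.
#' @examples
#' format_allele_name(truncate_resolution("A*01:01:01:02", 2))  # "A*01:01"
#' @export
truncate_resolution <- function(name, n_fields) {
  if (is.character(name)) name <- parse_allele_name(name)
  stopifnot(inherits(name, "hla_allele_name"), n_fields >= 1L)
  k <- min(as.integer(n_fields), length(name$fields))
  fields <- name$fields[seq_len(k)]
  structure(list(gene = name$gene, fields = fields,
                 raw = paste0(name$gene, "*", paste(fields, collapse = ":"))),
            class = "hla_allele_name")
}

# strip a trailing expression-suffix letter from a name field
strip_suffix <- function(fields) sub("[A-Za-z]$", "", fields)

#' Compare two allele names at a given resolution
#'
#' Expression-suffix letters are ignored; leading zeros in a field are not
#' (fields are compared as strings, per nomenclature convention).
#'
#' @param a,b Allele labels or `hla_allele_name` objects.
#' @param n_fields Resolution in name fields (1 = 2-digit, 2 = 4-digit).
#' @return `TRUE` if gene and the first `n_fields` fields agree.
#' @export
same_allele_at_resolution <- function(a, b, n_fields) {
  a <- truncate_resolution(a, n_fields)
  b <- truncate_resolution(b, n_fields)
  identical(a$gene, b$gene) &&
    length(a$fields) == length(b$fields) &&
    all(strip_suffix(a$fields) == strip_suffix(b$fields))
}

#' Construct a single allele record
#'
#' @param name An `hla_allele_name` (or label string, parsed on the fly).
#' @param exons Character vector of exon sequences (uppercase ACGT, no
#'   gaps), in exon order.
#' @param full_sequence Optional full allele sequence containing the exons.
#' @param exon_ranges Optional two-column matrix (`start`, `end`; 1-based
#'   inclusive on `full_sequence`) locating each exon.
#' @return An `hla_allele`.
#' @export
new_allele <- function(name, exons, full_sequence = NULL, exon_ranges = NULL) {
  if (is.character(name)) name <- parse_allele_name(name)
  stopifnot(inherits(name, "hla_allele_name"), length(exons) >= 1L,
            all(nchar(exons) > 0L), !anyNA(exons))
  if (any(grepl("[^ACGT]", exons))) {
    stop("exon sequences of '", name$raw, "' contain non-ACGT characters")
  }
  structure(list(name = name, exons = exons, full_sequence = full_sequence,
                 exon_ranges = exon_ranges),
            class = "hla_allele")
}

#' Construct an allele database from components
#'
#' Low-level constructor used by [load_allele_database()] and
#' [generate_synthetic_db()].  The exon index (distinct exon sequences per
#' gene and exon number) is derived from the alleles, so it always
#' satisfies the projection invariant.
#'
#' @param alleles A named list of allele records (name, exon sequences,
#'   optional full sequence with exon coordinates); names are the raw
#'   allele labels.
#' @return An object of class `hla_allele_db` with elements `alleles`,
#'   `genes` and `exon_index`.
#' @export
new_allele_database <- function(alleles) {
  stopifnot(is.list(alleles), length(alleles) > 0L)
  raw <- vapply(alleles, function(a) a$name$raw, character(1L))
  if (anyDuplicated(raw)) {
    stop("duplicate allele names: ", paste(unique(raw[duplicated(raw)]), collapse = ", "))
  }
  names(alleles) <- raw
  db <- structure(list(alleles = alleles,
                       genes = sort(unique(vapply(alleles, function(a) a$name$gene,
                                                  character(1L)))),
                       exon_index = NULL),
                  class = "hla_allele_db")
  db$exon_index <- build_exon_index(db)
  db
}

# distinct exon sequences per (gene, exon_number): named list keyed
# "gene|exon" -> character vector of distinct sequences (sorted)
build_exon_index <- function(db) {
  idx <- list()
  for (a in db$alleles) {
    g <- a$name$gene
    for (e in seq_along(a$exons)) {
      key <- paste0(g, "|", e)
      idx[[key]] <- c(idx[[key]], a$exons[[e]])
    }
  }
  lapply(idx, function(x) sort(unique(x)))
}

#' @export
print.hla_allele_db <- function(x, ...) {
  cat("<hla_allele_db> ", length(x$alleles), " alleles over ",
      length(x$genes), " gene(s): ", paste(x$genes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Alleles of one gene
#' @param db An `hla_allele_db`.
#' @param gene Gene symbol.
#' @return Named list of allele records for `gene`.
#' @export
gene_alleles <- function(db, gene) {
  stopifnot(inherits(db, "hla_allele_db"))
  if (!gene %in% db$genes) stop("gene '", gene, "' not in database")
  Filter(function(a) a$name$gene == gene, db$alleles)
}

#' Distinct exon sequences for a gene and exon number
#' @param db An `hla_allele_db`.
#' @param gene Gene symbol.
#' @param exon_number Exon ordinal (1-based).
#' @return Character vector of distinct exon sequences (possibly empty).
#' @export
exon_sequences <- function(db, gene, exon_number) {
  seqs <- db$exon_index[[paste0(gene, "|", exon_number)]]
  if (is.null(seqs)) character(0) else seqs
}

#' Load an allele database from FASTA plus an exon map
#'
#' Two dialects are accepted.  In the *manifest* dialect `sequences` holds
#' one record per allele (the full allele sequence) and `exon_map` is a
#' tab-separated file with columns `allele_name`, `exon_number`, `start`,
#' `end` (1-based inclusive coordinates on the allele sequence).  In the
#' *exon-split* dialect each FASTA record is a single exon and its header
#' carries the allele label followed by an `exon<k>` token
#' (e.g. `>A*01:01 exon2`); no exon map is needed.
#'
#' @param sequences Path to the allele FASTA.
#' @param exon_map Path to the exon-map TSV, or `NULL` for the exon-split
#'   dialect.
#' @param quiet Suppress the loaded-counts message.
#' @return An `hla_allele_db`.
#' @export
load_allele_database <- function(sequences, exon_map = NULL, quiet = FALSE) {
  fa <- Biostrings::readDNAStringSet(sequences)
  headers <- names(fa)
  if (anyDuplicated(headers)) {
    stop("duplicate FASTA header(s): ",
         paste(unique(headers[duplicated(headers)]), collapse = ", "))
  }
  if (is.null(exon_map)) {
    db <- load_exon_split(fa)
  } else {
    db <- load_manifest(fa, exon_map)
  }
  if (!quiet) {
    message("loaded ", length(db$alleles), " alleles across ",
            length(db$genes), " genes")
  }
  db
}

load_exon_split <- function(fa) {
  labels <- sub("\\s.*$", "", names(fa))
  exon_tok <- regmatches(names(fa), regexpr("exon[0-9]+", names(fa)))
  if (length(exon_tok) != length(fa)) {
    stop("exon-split FASTA: every header needs an 'exon<k>' token")
  }
  exon_no <- as.integer(sub("exon", "", exon_tok))
  alleles <- lapply(split(seq_along(fa), labels), function(i) {
    ord <- order(exon_no[i])
    exons <- unname(as.character(fa[i][ord]))
    if (any(exon_no[i][ord] != seq_along(exons))) {
      stop("allele '", labels[i[1L]], "': exon numbers not 1..k")
    }
    new_allele(parse_allele_name(labels[i[1L]]), exons)
  })
  new_allele_database(alleles)
}

load_manifest <- function(fa, exon_map) {
  labels <- sub("\\s.*$", "", names(fa))
  names(fa) <- labels
  em <- utils::read.table(exon_map, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "integer", "integer"))
  need <- c("allele_name", "exon_number", "start", "end")
  if (!all(need %in% names(em))) {
    stop("exon map must have columns: ", paste(need, collapse = ", "))
  }
  missing_fa <- setdiff(unique(em$allele_name), labels)
  missing_em <- setdiff(labels, unique(em$allele_name))
  if (length(missing_fa) || length(missing_em)) {
    stop("allele set mismatch between FASTA and exon map; ",
         "in map only: [", paste(missing_fa, collapse = ", "), "]; ",
         "in FASTA only: [", paste(missing_em, collapse = ", "), "]")
  }
  alleles <- lapply(split(em, em$allele_name), function(rows) {
    rows <- rows[order(rows$exon_number), , drop = FALSE]
    if (any(rows$exon_number != seq_len(nrow(rows)))) {
      stop("allele '", rows$allele_name[1L], "': exon numbers not 1..k")
    }
    full <- as.character(fa[[rows$allele_name[1L]]])
    if (any(rows$start < 1L | rows$end > nchar(full) | rows$start > rows$end)) {
      stop("allele '", rows$allele_name[1L], "': exon coordinates out of range")
    }
    exons <- substring(full, rows$start, rows$end)
    new_allele(parse_allele_name(rows$allele_name[1L]), exons,
               full_sequence = full,
               exon_ranges = cbind(start = rows$start, end = rows$end))
  })
  new_allele_database(alleles)
}

#' Write an allele database as FASTA plus exon-map manifest
#'
#' Alleles carrying a full sequence are written in the manifest dialect;
#' databases without full sequences are written in the exon-split dialect
#' (and `exon_map` is then not created).  [load_allele_database()] on the
#' written files reproduces the database exactly.
#'
#' @param db An `hla_allele_db`.
#' @param sequences Output FASTA path.
#' @param exon_map Output exon-map TSV path (manifest dialect only).
#' @return Invisibly, the paths written.
#' @export
write_allele_database <- function(db, sequences, exon_map = NULL) {
  stopifnot(inherits(db, "hla_allele_db"))
  has_full <- all(vapply(db$alleles, function(a) !is.null(a$full_sequence), logical(1L)))
  if (has_full) {
    if (is.null(exon_map)) stop("manifest dialect needs an exon_map path")
    seqs <- Biostrings::DNAStringSet(vapply(db$alleles, function(a) a$full_sequence,
                                            character(1L)))
    names(seqs) <- names(db$alleles)
    Biostrings::writeXStringSet(seqs, sequences, width = 80L)
    rows <- do.call(rbind, lapply(db$alleles, function(a) {
      data.frame(allele_name = a$name$raw,
                 exon_number = seq_along(a$exons),
                 start = a$exon_ranges[, "start"],
                 end = a$exon_ranges[, "end"])
    }))
    utils::write.table(rows, exon_map, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(sequences, exon_map))
  } else {
    seqs <- character(0); hdrs <- character(0)
    for (a in db$alleles) {
      seqs <- c(seqs, a$exons)
      hdrs <- c(hdrs, paste0(a$name$raw, " exon", seq_along(a$exons)))
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- hdrs
    Biostrings::writeXStringSet(out, sequences, width = 80L)
    invisible(sequences)
  }
}
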