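test_that("modern and legacy allele labels parse into gene and fields", {
  n <- parse_allele_name("A*01:01:01:01")
  expect_equal(n$gene, "A")
  expect_equal(n$fields, c("01", "01", "01", "01"))
  expect_equal(n$raw, "A*01:01:01:01")

  n <- parse_allele_name("DRB1*15:01")
  expect_equal(n$gene, "DRB1")
  expect_equal(n$fields, c("15", "01"))

  # legacy digit-run name splits into 2-character fields
  n <- parse_allele_name("B*0702")
  expect_equal(n$gene, "B")
  expect_equal(n$fields, c("07", "02"))

  # expression suffix preserved on the last field
  n <- parse_allele_name("A*24:09N")
  expect_equal(n$fields, c("24", "09N"))

  expect_error(parse_allele_name("A01:01"), "malformed")
  expect_error(parse_allele_name("A*"), "malformed")
  expect_error(parse_allele_name("B*070"), "malformed")
  expect_error(parse_allele_name("A*xx:01"), "malformed")
})

test_that("resolution truncation keeps leading fields and is idempotent and monotone", {
  expect_equal(format_allele_name(truncate_resolution("A*01:01:01:02", 2)),
               "A*01:01")
  expect_equal(format_allele_name(truncate_resolution("A*01:01", 4)),
               "A*01:01")
  expect_equal(format_allele_name(truncate_resolution("B*57:01:03", 1)),
               "B*57")

  set.seed(42)
  for (i in 1:25) {
    k <- sample(1:4, 1)
    label <- paste0("A*", paste(sprintf("%02d", sample(1:99, k)), collapse = ":"))
    name <- parse_allele_name(label)
    n1 <- sample(1:4, 1); n2 <- sample(seq_len(n1), 1)
    t1 <- truncate_resolution(name, n1)
    expect_identical(truncate_resolution(t1, n1)$fields, t1$fields)
    expect_identical(truncate_resolution(t1, n2)$fields,
                     truncate_resolution(name, n2)$fields)
  }
})

test_that("resolution comparison ignores expression suffixes and legacy formatting", {
  expect_true(same_allele_at_resolution("A*01:01:01", "A*01:01:02", 2))
  expect_false(same_allele_at_resolution("A*01:01:01", "A*01:02:01", 2))
  expect_true(same_allele_at_resolution("B*0702", "B*07:02", 2))
  expect_true(same_allele_at_resolution("A*24:09N", "A*24:09", 2))
  expect_false(same_allele_at_resolution("A*24:09", "B*24:09", 1))
})

make_manifest_db_files <- function(dir) {
  # 2 genes x 2 alleles, 2 exons each, embedded in a longer full sequence
  set.seed(7)
  fasta <- file.path(dir, "panel.fasta")
  manifest <- file.path(dir, "panel_exons.tsv")
  alleles <- c("G1*01:01", "G1*02:01", "G2*01:01", "G2*02:01")
  full <- vapply(alleles, function(a) random_dna(200), character(1))
  writeLines(as.vector(rbind(paste0(">", alleles), full)), fasta)
  rows <- do.call(rbind, lapply(alleles, function(a)
    data.frame(allele_name = a, exon_number = 1:2,
               start = c(21L, 121L), end = c(60L, 180L))))
  utils::write.table(rows, manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fasta = fasta, manifest = manifest, full = full)
}

test_that("manifest databases load, satisfy invariants, and round-trip", {
  dir <- withr::local_tempdir()
  f <- make_manifest_db_files(dir)
  db <- load_allele_database(f$fasta, f$manifest, quiet = TRUE)
  expect_s3_class(db, "hla_allele_db")
  expect_equal(db$genes, c("G1", "G2"))
  expect_length(db$alleles, 4L)
  # exons are the declared substrings of the full sequence
  a <- db$alleles[["G1*01:01"]]
  expect_equal(a$exons[1], substring(f$full[["G1*01:01"]], 21, 60))
  expect_equal(a$exons[2], substring(f$full[["G1*01:01"]], 121, 180))
  # every allele's gene is registered
  expect_true(all(vapply(db$alleles, function(x) x$name$gene %in% db$genes,
                         logical(1))))

  # round trip: write + reload reproduces names and sequences exactly
  out_fa <- file.path(dir, "rt.fasta")
  out_map <- file.path(dir, "rt.tsv")
  write_allele_database(db, out_fa, out_map)
  db2 <- load_allele_database(out_fa, out_map, quiet = TRUE)
  expect_equal(names(db2$alleles), names(db$alleles))
  for (nm in names(db$alleles)) {
    expect_equal(db2$alleles[[nm]]$exons, db$alleles[[nm]]$exons)
    expect_equal(db2$alleles[[nm]]$full_sequence, db$alleles[[nm]]$full_sequence)
  }
  expect_equal(db2$exon_index, db$exon_index)
})

test_that("the exon-split dialect loads identically to the manifest dialect", {
  dir <- withr::local_tempdir()
  f <- make_manifest_db_files(dir)
  db <- load_allele_database(f$fasta, f$manifest, quiet = TRUE)
  # write the same content exon-per-record
  split_fa <- file.path(dir, "split.fasta")
  lines <- character(0)
  for (nm in names(db$alleles)) {
    a <- db$alleles[[nm]]
    for (e in seq_along(a$exons)) {
      lines <- c(lines, paste0(">", nm, " exon", e), a$exons[e])
    }
  }
  writeLines(lines, split_fa)
  db2 <- load_allele_database(split_fa, quiet = TRUE)
  expect_equal(names(db2$alleles), names(db$alleles))
  for (nm in names(db$alleles)) {
    expect_equal(db2$alleles[[nm]]$exons, db$alleles[[nm]]$exons)
  }
  expect_equal(db2$exon_index, db$exon_index)
})

test_that("database consistency errors are raised with offending names", {
  dir <- withr::local_tempdir()
  f <- make_manifest_db_files(dir)
  # duplicate FASTA header
  dup_fa <- file.path(dir, "dup.fasta")
  writeLines(c(">G1*01:01", random_dna(200), ">G1*01:01", random_dna(200)),
             dup_fa)
  expect_error(load_allele_database(dup_fa, f$manifest, quiet = TRUE),
               "duplicate")
  # allele present in the map but missing from the FASTA
  part_fa <- file.path(dir, "part.fasta")
  writeLines(c(">G1*01:01", random_dna(200)), part_fa)
  expect_error(load_allele_database(part_fa, f$manifest, quiet = TRUE),
               "G1\\*02:01")
})

test_that("the exon index is exactly the projection of the alleles", {
  dir <- withr::local_tempdir()
  f <- make_manifest_db_files(dir)
  db <- load_allele_database(f$fasta, f$manifest, quiet = TRUE)
  rebuilt <- hlacall:::build_exon_index(db)
  expect_identical(rebuilt, db$exon_index)
  expect_setequal(exon_sequences(db, "G1", 1),
                  unique(vapply(gene_alleles(db, "G1"),
                                function(a) a$exons[1], character(1))))
})
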