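# candidate stubs for the scoring/zygosity unit tests
stub_candidate <- function(allele, tscore, n_support, ids = character(0),
                           exon_support = NULL) {
  list(allele = allele, exon_support = exon_support, n_support = n_support,
       support_ids = ids, tscore = tscore)
}

test_that("TScore sums read-weighted exon scores and is monotone in support", {
  one <- list(exon_support = data.frame(exon = 1, n_reads = 10, hscore = 2.0))
  expect_equal(tscore(one), 20)
  two <- list(exon_support = data.frame(exon = 1:2, n_reads = c(10, 5),
                                        hscore = c(2.0, 1.0)))
  expect_equal(tscore(two), 25)
  expect_equal(tscore(list(exon_support = NULL)), 0)
  # adding a supporting read to any exon never lowers the score
  for (e in 1:2) {
    more <- two
    more$exon_support$n_reads[e] <- more$exon_support$n_reads[e] + 1L
    expect_gte(tscore(more), tscore(two))
  }
})

test_that("pair selection ranks by TScore with support and name tie-breaks", {
  cands <- list(stub_candidate("HX*03:01", 5, 3),
                stub_candidate("HX*01:01", 30, 10),
                stub_candidate("HX*02:01", 20, 8))
  pair <- select_pair(cands)
  expect_equal(pair$best$allele, "HX*01:01")
  expect_equal(pair$suboptimal$allele, "HX*02:01")

  # exact TScore tie resolved by higher support
  cands <- list(stub_candidate("HX*01:01", 30, 35),
                stub_candidate("HX*02:01", 30, 40))
  pair <- select_pair(cands)
  expect_equal(pair$best$allele, "HX*02:01")

  # full tie resolved by allele name
  cands <- list(stub_candidate("HX*02:01", 30, 40),
                stub_candidate("HX*01:01", 30, 40))
  expect_equal(select_pair(cands)$best$allele, "HX*01:01")

  # single candidate: no sub-optimal type
  pair <- select_pair(list(stub_candidate("HX*01:01", 30, 40)))
  expect_null(pair$suboptimal)
})

test_that("read partition counts shared reads for both but unique for neither", {
  b <- stub_candidate("HX*01:01", 30, 5, ids = c("a", "b", "c", "d", "e"))
  s <- stub_candidate("HX*02:01", 20, 4, ids = c("c", "d", "e", "f"))
  pair <- select_pair(list(b, s))
  expect_equal(pair$best$n_unique_support, 2L)       # a, b
  expect_equal(pair$suboptimal$n_unique_support, 1L) # f
})

test_that("zygosity follows the 0.1 supporting-read ratio rule", {
  b <- stub_candidate("HX*01:01", 30, 100)
  s <- stub_candidate("HX*02:01", 20, 50)
  s$n_unique_support <- 4L
  z <- call_zygosity(b, s)
  expect_equal(z$ratio, 0.04)
  expect_equal(z$zygosity, "homozygote")
  expect_equal(z$alleles, "HX*01:01")

  # the boundary ratio of exactly 0.1 calls a heterozygote
  s$n_unique_support <- 10L
  z <- call_zygosity(b, s)
  expect_equal(z$ratio, 0.1)
  expect_equal(z$zygosity, "heterozygote")
  expect_equal(z$alleles, c("HX*01:01", "HX*02:01"))

  # no sub-optimal candidate: homozygote at ratio 0
  z <- call_zygosity(b, NULL)
  expect_equal(z$ratio, 0)
  expect_equal(z$zygosity, "homozygote")

  b0 <- stub_candidate("HX*01:01", 0, 0)
  expect_error(call_zygosity(b0, NULL), "typing failure")
})

test_that("zygosity and ratio are mutually exclusive over randomized tables", {
  set.seed(31)
  for (i in 1:200) {
    n_best <- sample(10:200, 1)
    n_uni <- sample(0:n_best, 1)
    b <- stub_candidate("HX*01:01", 30, n_best)
    s <- stub_candidate("HX*02:01", 20, sample(1:n_best, 1))
    s$n_unique_support <- n_uni
    z <- call_zygosity(b, s)
    expect_identical(z$zygosity == "homozygote", z$ratio < 0.1)
    expect_identical(length(z$alleles) == 1L, z$zygosity == "homozygote")
  }
})

test_that("AScore measures normalized score separation and is clamped", {
  expect_equal(ascore(100, 50, 50), 0)
  expect_equal(ascore(100, 20, 60), 0.4)
  expect_equal(ascore(100, 0, 100), 1)
  expect_equal(ascore(10, 0, 50), 1)      # clamped above
  expect_true(is.na(ascore(0, 0, 10)))    # undefined confidence
  expect_true(is.na(ascore(-5, 0, 10)))
})

typing_db <- function() {
  set.seed(41)
  e1 <- random_dna(120); e2 <- random_dna(120)
  # X and Y share exon 2; Z differs everywhere
  toy_db(list(HX = list(
    "HX*01:01" = c(e1, e2),
    "HX*02:01" = c(mutate_base(mutate_base(e1, 30), 80), e2),
    "HX*03:01" = c(mutate_base(e1, 55), mutate_base(e2, 60)))))
}

reads_from <- function(db, allele, n_per_exon = 20, len = 60, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (e in seq_along(db$alleles[[allele]]$exons)) {
    ref <- db$alleles[[allele]]$exons[e]
    offs <- sample.int(nchar(ref) - len + 1L, n_per_exon, replace = TRUE)
    # force edge coverage so the full exon assembles
    offs[1:2] <- c(1L, nchar(ref) - len + 1L)
    rows[[e]] <- data.frame(id = sprintf("%s:e%d:%d", allele, e, seq_len(n_per_exon)),
                            sequence = substring(ref, offs, offs + len - 1L),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

test_that("candidates cover exactly the alleles compatible with surviving assemblies", {
  db <- typing_db()
  reads <- reads_from(db, "HX*01:01")
  corr <- correct_reads(reads, db)$genes$HX
  exon_sets <- assemble_gene(corr$corrected, db, "HX")
  cands <- enumerate_candidates(exon_sets, db, "HX", corr$corrected)
  alleles <- vapply(cands, `[[`, character(1), "allele")
  # X fully supported; Y shares exon 2 so it is listed; Z is compatible
  # only if a sub-fragment avoids its variant sites
  expect_equal(alleles[1], "HX*01:01")
  expect_true("HX*02:01" %in% alleles)
  expect_gt(cands[[1]]$tscore, 0)
  expect_equal(nrow(cands[[1]]$exon_support), 2L)
  # the exon-2 haplotype supports both X and Y equally there
  y <- cands[[which(alleles == "HX*02:01")]]
  expect_equal(y$exon_support$sequence[y$exon_support$exon == 2],
               cands[[1]]$exon_support$sequence[cands[[1]]$exon_support$exon == 2])
})

test_that("typing is invariant to read order", {
  db <- typing_db()
  reads <- rbind(reads_from(db, "HX*01:01", seed = 2),
                 reads_from(db, "HX*03:01", seed = 3))
  corr1 <- correct_reads(reads, db)
  r1 <- type_gene(corr1, db, "HX")
  set.seed(99)
  corr2 <- correct_reads(reads[sample(nrow(reads)), ], db)
  r2 <- type_gene(corr2, db, "HX")
  expect_equal(r1$alleles, r2$alleles)
  expect_equal(r1$ratio, r2$ratio)
  expect_equal(r1$ascore, r2$ascore)
  expect_equal(sort(r1$alleles), c("HX*01:01", "HX*03:01"))
  expect_equal(r1$zygosity, "heterozygote")
})

test_that("genes without surviving assemblies are reported untypeable, not errors", {
  db <- typing_db()
  corr <- correct_reads(data.frame(id = "r1", sequence = random_dna(91)), db)
  res <- type_gene(corr, db, "HX")
  expect_equal(res$status, "untypeable")
  expect_length(res$alleles, 0L)
})

test_that("novel variants require support, absence from all alleles, and a called type", {
  db <- typing_db()
  final <- list(gene = "HX", alleles = c("HX*01:01"))
  led <- data.frame(
    allele = "HX*01:01", exon = 1L, position = c(10L, 12L, 29L),
    ref = c(substring(db$alleles[["HX*01:01"]]$exons[1], 11, 11),
            substring(db$alleles[["HX*01:01"]]$exons[1], 13, 13),
            substring(db$alleles[["HX*01:01"]]$exons[1], 30, 30)),
    alt = "", support = c(10L, 2L, 10L), stringsAsFactors = FALSE)
  # give each record a plausible substitution alt
  led$alt <- vapply(seq_len(nrow(led)), function(i)
    setdiff(c("A", "C", "G", "T"), led$ref[i])[1], character(1))
  # 0-based position 29 carries the base by which HX*02:01 differs from
  # HX*01:01: that alternate exists in the database, so it is not novel
  led$alt[3] <- substring(db$alleles[["HX*02:01"]]$exons[1], 30, 30)
  out <- judge_novel_variants(led, final, db)
  expect_equal(nrow(out), 1L)
  expect_equal(out$position, 10L)     # supported and absent from the panel
  expect_equal(out$called_allele, "HX*01:01")
  # the support-2 record is suppressed, the extant-allele record rejected
  expect_false(12L %in% out$position)
  expect_false(29L %in% out$position)
})
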