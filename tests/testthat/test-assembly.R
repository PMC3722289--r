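test_that("reads merge at a 10 bp perfect overlap but not below it or across a mismatch", {
  # 14-mers sharing an exact 10-base suffix/prefix: one merged assembly
  r1 <- "ACGTTGCAATCGGA"
  r2 <- "TGCAATCGGATTTT"   # first 10 = last 10 of r1
  out <- assemble_exon(c(r1, r2), min_overlap = 10)
  expect_length(out, 1L)
  expect_equal(out[[1]]$sequence, "ACGTTGCAATCGGATTTT")
  expect_equal(nchar(out[[1]]$sequence), 18L)
  expect_equal(out[[1]]$n_reads, 2L)
  # depth 1 on the non-overlapping flanks, 2 in the overlap region
  expect_equal(out[[1]]$depth_profile, c(rep(1L, 4), rep(2L, 10), rep(1L, 4)))

  # the same pair with only 9 shared bases stays two fragments
  r2b <- "GCAATCGGATTTTC"   # first 9 = last 9 of r1
  out <- assemble_exon(c(r1, r2b), min_overlap = 10)
  expect_length(out, 2L)
  expect_setequal(vapply(out, `[[`, character(1), "sequence"), c(r1, r2b))

  # a 12-base overlap containing one mismatch does not merge
  r2c <- paste0(mutate_base(substring(r1, 3, 14), 6), "TTTT")
  out <- assemble_exon(c(r1, r2c), min_overlap = 10)
  expect_length(out, 2L)
})

test_that("assembly output is independent of read order and matches brute force", {
  set.seed(11)
  for (i in 1:40) {
    template <- random_dna(60)
    n_reads <- sample(3:8, 1)
    reads <- vapply(seq_len(n_reads), function(k) {
      len <- sample(15:25, 1)
      off <- sample.int(60 - len + 1L, 1)
      substring(template, off, off + len - 1L)
    }, character(1))
    got <- sort(vapply(assemble_exon(reads, min_overlap = 10),
                       `[[`, character(1), "sequence"))
    want <- brute_force_assemblies(reads, min_overlap = 10)
    expect_equal(got, want)
    shuffled <- sort(vapply(assemble_exon(sample(reads), min_overlap = 10),
                            `[[`, character(1), "sequence"))
    expect_equal(shuffled, want)
  }
})

test_that("depth totals are conserved when assemblies share no reads", {
  set.seed(12)
  for (i in 1:10) {
    # two well-separated islands on one template: assemblies are read-disjoint
    template <- random_dna(120)
    mk <- function(lo, hi) {
      vapply(1:3, function(k) {
        len <- sample(15:20, 1)
        off <- sample(lo:(hi - len), 1)
        substring(template, off, off + len - 1L)
      }, character(1))
    }
    reads <- c(mk(1, 45), mk(70, 120))
    out <- assemble_exon(reads, min_overlap = 10)
    placed <- sum(vapply(out, function(a) sum(a$depth_profile), numeric(1)))
    expect_equal(placed, sum(nchar(reads)))
  }
})

test_that("depth-reliability matches its dispersion formula and properties", {
  expect_equal(depth_reliability(c(20, 20, 20, 20)), 1)
  expect_equal(depth_reliability(c(10, 20, 30)), 1 / 6)
  # independently computed: mean 16.25, sum sq dev 1518.75 -> D = 31.1538...
  expect_equal(depth_reliability(c(5, 5, 5, 50)), 0.0311004784688995,
               tolerance = 1e-12)
  expect_equal(depth_reliability(c(7)), 1)  # degenerate length

  set.seed(13)
  for (i in 1:20) {
    x <- sample(5:50, sample(3:12, 1), replace = TRUE)
    expect_equal(depth_reliability(sample(x)), depth_reliability(x))
  }
  # moving one value away from the mean strictly lowers R
  x <- c(20, 20, 20, 20)
  r_prev <- depth_reliability(x)
  for (bump in c(2, 5, 10)) {
    r_new <- depth_reliability(c(20 + bump, 20, 20, 20))
    expect_lt(r_new, r_prev)
    r_prev <- r_new
  }
})

test_that("the haplotype score combines coverage, reliability and read support", {
  expect_equal(hscore(1, 1, 0), 0)
  expect_equal(hscore(1, 1, exp(1) - 1), 1)
  expect_equal(hscore(0.9, 0.5, 30), 0.9 * 0.5 * log(31))
  expect_equal(round(hscore(0.9, 0.5, 30), 3), 1.545)
  # monotone in N
  expect_true(all(diff(hscore(1, 1, 1:20)) > 0))
})

assembly_db <- function() {
  set.seed(21)
  ex <- random_dna(120)
  toy_db(list(HX = list(
    "HX*01:01" = ex,
    "HX*02:01" = mutate_base(ex, 60),
    "HX*03:01" = mutate_base(ex, 15))))
}

test_that("assemblies absent from the database are filtered; substrings keep all compatible alleles", {
  db <- assembly_db()
  ex <- db$alleles[["HX*01:01"]]$exons[1]
  full <- list(sequence = ex, depth_profile = rep(10L, 120), n_reads = 20L)
  chimera <- list(sequence = paste0(substring(ex, 1, 60), random_dna(30)),
                  depth_profile = rep(10L, 90), n_reads = 10L)
  partial <- list(sequence = substring(ex, 70, 110),
                  depth_profile = rep(5L, 41), n_reads = 6L)
  out <- filter_known_assemblies(list(full, chimera, partial), db, "HX", 1)
  h <- out$haplotypes
  expect_equal(nrow(h), 2L)
  expect_false(any(h$sequence == chimera$sequence))
  # the partial assembly is downstream of every allele's variant site
  prow <- h[h$sequence == partial$sequence, ]
  expect_setequal(prow$compatible[[1]],
                  c("HX*01:01", "HX*02:01", "HX*03:01"))
  expect_equal(prow$coverage, 41 / 120)
  # full-length assembly only matches the allele it came from
  frow <- h[h$sequence == ex, ]
  expect_setequal(frow$compatible[[1]], c("HX*01:01"))
  expect_equal(frow$coverage, 1)
  # refiltering is idempotent and output is a subset of input
  again <- filter_known_assemblies(list(full, partial), db, "HX", 1)
  expect_equal(again$haplotypes$sequence, h$sequence)
})

test_that("fragments bridge across a gap only through consistent database exons", {
  set.seed(22)
  ex <- random_dna(120)
  # the other variants differ inside the fragments, so only one exon
  # variant is consistent with both fragments
  db <- toy_db(list(HX = list(
    "HX*01:01" = ex,
    "HX*02:01" = mutate_base(ex, 100),   # differs inside fragment 2
    "HX*03:01" = mutate_base(ex, 20))))  # differs inside fragment 1
  frag1 <- list(sequence = substring(ex, 1, 40),
                depth_profile = rep(8L, 40), n_reads = 5L)
  frag2 <- list(sequence = substring(ex, 71, 120),
                depth_profile = rep(6L, 50), n_reads = 6L)
  out <- bridge_fragments(list(frag1, frag2), db, "HX", 1)
  expect_length(out, 1L)
  expect_equal(out[[1]]$sequence, ex)
  expect_true(out[[1]]$bridged)
  expect_equal(out[[1]]$n_reads, 11L)
  expect_equal(out[[1]]$depth_profile[41:70], rep(0L, 30))  # gap depth 0

  # an ambiguous gap yields one candidate per consistent variant
  db2 <- toy_db(list(HX = list(
    "HX*01:01" = ex,
    "HX*02:01" = mutate_base(ex, 55))))
  out2 <- bridge_fragments(list(frag1, frag2), db2, "HX", 1)
  expect_length(out2, 2L)
  expect_setequal(vapply(out2, `[[`, character(1), "sequence"),
                  c(ex, mutate_base(ex, 55)))

  # fragments consistent with no database exon: nothing bridged
  out3 <- bridge_fragments(list(frag1, list(sequence = random_dna(40),
                                            depth_profile = rep(3L, 40),
                                            n_reads = 2L)), db, "HX", 1)
  expect_length(out3, 0L)
})

test_that("database-guided assembly equals general assembly plus the known filter", {
  set.seed(23)
  for (i in 1:10) {
    ex <- random_dna(100)
    db <- toy_db(list(HX = list(
      "HX*01:01" = ex,
      "HX*02:01" = mutate_base(ex, sample(30:70, 1)))))
    variants <- exon_sequences(db, "HX", 1)
    reads <- unlist(lapply(variants, function(v) {
      vapply(1:5, function(k) {
        off <- sample.int(100 - 30 + 1L, 1)
        substring(v, off, off + 29L)
      }, character(1))
    }))
    guided <- hlacall:::assemble_guided(reads, db, "HX", 1, min_overlap = 10)
    guided_seqs <- sort(vapply(guided, `[[`, character(1), "sequence"))
    general <- assemble_exon(reads, min_overlap = 10)
    surviving <- filter_known_assemblies(general, db, "HX", 1)
    expect_equal(guided_seqs, sort(surviving$haplotypes$sequence))
  }
})
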