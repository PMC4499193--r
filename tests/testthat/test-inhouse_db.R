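test_that("ingestion tracks dosage, carriers and homozygotes", {
  db <- occurrence_db()
  v <- mk_variants(1, zygosity = "heterozygous")
  ingest_sample(db, v, "s1")
  expect_equal(db_n_samples(db), 1L)
  expect_equal(db_occurrences(db, v, unit = "allele"), 1L)
  expect_equal(db_occurrences(db, v, unit = "sample"), 1L)
  expect_error(ingest_sample(db, v, "s1"), "already been ingested")

  db2 <- occurrence_db()
  hom <- mk_variants(1, zygosity = "homozygous")
  for (i in 1:10) ingest_sample(db2, hom, paste0("s", i))
  expect_equal(db_occurrences(db2, hom, unit = "allele"), 20L)
  expect_equal(db_occurrences(db2, hom, unit = "sample"), 10L)
})

test_that("counts are invariant to ingestion order and conserve dosage", {
  set.seed(11)
  samples <- lapply(1:6, function(i) random_variants(8))
  build <- function(order) {
    db <- occurrence_db()
    for (i in order) ingest_sample(db, samples[[i]], paste0("s", i))
    db
  }
  a <- build(1:6)
  b <- build(sample(6))
  keys <- sort(ls(a$counts))
  expect_identical(keys, sort(ls(b$counts)))
  for (k in keys) expect_identical(a$counts[[k]], b$counts[[k]])
  # conservation: total allele count equals the summed dosages
  dosage <- sum(vapply(samples, function(vs)
    sum(ifelse(vs$zygosity == "homozygous", 2L, 1L)), integer(1)))
  total <- sum(vapply(keys, function(k) a$counts[[k]]$allele, integer(1)))
  expect_equal(total, dosage)
})

test_that("in-house MAF uses a diploid denominator and is monotone", {
  db <- occurrence_db()
  v <- mk_variants(1, zygosity = "heterozygous")
  ingest_sample(db, v, "s1")
  for (i in 2:50)
    ingest_sample(db, mk_variants(1, pos = 1000L + i), paste0("s", i))
  expect_equal(db_maf(db, v), 1 / 100)
  unseen <- mk_variants(1, pos = 99999L)
  expect_equal(db_maf(db, unseen), 0)
  expect_error(db_maf(occurrence_db(), v), "undefined")

  sat <- occurrence_db()
  hom <- mk_variants(1, zygosity = "homozygous")
  for (i in 1:50) ingest_sample(sat, hom, paste0("s", i))
  expect_equal(db_maf(sat, hom), 1)
  # more occurrences at fixed n_samples -> never a lower frequency
  expect_true(db_maf(sat, hom) >= db_maf(db, v))
})

test_that("merging requires disjoint samples and sums counts", {
  v <- mk_variants(1)
  a <- occurrence_db(); ingest_sample(a, v, "s1")
  b <- occurrence_db(); ingest_sample(b, v, "s2")
  m <- merge_occurrence_db(a, b)
  expect_equal(db_n_samples(m), 2L)
  expect_equal(db_occurrences(m, v, unit = "sample"), 2L)
  c <- occurrence_db(); ingest_sample(c, v, "s1")
  expect_error(merge_occurrence_db(a, c), "share samples")
})

test_that("common catalogued variants are tiered with strict thresholds", {
  db <- occurrence_db()
  common <- mk_variants(1, pos = 1L)              # hom in 3/25: MAF 0.12
  mid <- mk_variants(1, pos = 2L,                 # het in 1/25: MAF 0.02
                     zygosity = "heterozygous")
  low <- mk_variants(1, pos = 3L,                 # het in 1/25: MAF 0.02
                     zygosity = "heterozygous")
  rare <- mk_variants(1, pos = 4L)                # never seen: MAF 0
  for (i in 1:3)
    ingest_sample(db, rbind(common,
                            if (i == 1) mid,
                            if (i == 2) low), paste0("c", i))
  # pad to 25 samples so the denominators are fixed
  for (i in 4:25)
    ingest_sample(db, mk_variants(1, pos = 100L + i), paste0("c", i))
  pathogenic <- rbind(common, mid, low, rare)[, c("chrom", "pos",
                                                  "ref", "alt")]
  external <- data.frame(chrom = common$chrom, pos = common$pos,
                         ref = common$ref, alt = common$alt, maf = 0.001)
  rep <- flag_common_pathogenic(db, pathogenic, external)
  expect_setequal(rep$pos, c(1L, 2L, 3L))
  expect_equal(rep$tier[rep$pos == 1L], "gt5pct")
  expect_equal(rep$tier[rep$pos == 2L], "gt1pct")
  expect_true(rep$discordant_with_external[rep$pos == 1L])
  expect_false(any(rep$discordant_with_external[rep$pos != 1L]))
  # tiers are nested: every gt5pct row also satisfies the gt1pct bound
  expect_true(all(rep$inhouse_maf[rep$tier == "gt5pct"] > 0.01))
})

test_that("a variant at exactly 1 percent in-house is not flagged", {
  db <- occurrence_db()
  v <- mk_variants(1, zygosity = "heterozygous")
  ingest_sample(db, v, "s1")
  for (i in 2:50)
    ingest_sample(db, mk_variants(1, pos = 1000L + i), paste0("s", i))
  expect_equal(db_maf(db, v), 0.01)
  rep <- flag_common_pathogenic(db, v[, c("chrom", "pos", "ref", "alt")])
  expect_equal(nrow(rep), 0L)
})

test_that("frequent homozygous loss-of-function variants challenge genes", {
  db <- occurrence_db()
  lof <- mk_variants(1, gene = "CACNA1F", functional_class = "nonsense",
                     zygosity = "homozygous")
  het_lof <- mk_variants(1, pos = 2L, gene = "MYH8",
                         functional_class = "frameshift",
                         zygosity = "heterozygous")
  for (i in 1:5) ingest_sample(db, rbind(lof, het_lof), paste0("s", i))
  for (i in 6:100)
    ingest_sample(db, mk_variants(1, pos = 100L + i,
                                  functional_class = "missense",
                                  zygosity = "homozygous"), paste0("s", i))
  expect_equal(homozygous_inactivating_challenge(db), "CACNA1F")
  # only-heterozygous LoF and missense genes never appear
  expect_false("MYH8" %in% homozygous_inactivating_challenge(db))
  empty <- occurrence_db()
  ingest_sample(empty, mk_variants(1, functional_class = "missense"), "x")
  expect_equal(homozygous_inactivating_challenge(empty), character())
})

test_that("the database round-trips through its sorted TSV form", {
  db <- occurrence_db()
  set.seed(5)
  for (i in 1:4) ingest_sample(db, random_variants(6), paste0("s", i))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_occurrence_db(db, path)
  back <- read_occurrence_db(path)
  expect_equal(db_n_samples(back), db_n_samples(db))
  keys <- sort(ls(db$counts))
  expect_identical(keys, sort(ls(back$counts)))
  for (k in keys) {
    expect_equal(back$counts[[k]]$allele, db$counts[[k]]$allele)
    expect_equal(back$counts[[k]]$hom, db$counts[[k]]$hom)
  }
  # the duplicate-sample guard survives the round trip
  expect_error(ingest_sample(back, mk_variants(1), "s1"), "already")
  # rewriting is byte-identical (sorted, stable)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_occurrence_db(back, path2)
  expect_identical(readLines(path), readLines(path2))
})
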