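cfg <- cascade_config()

test_that("functional-class stage drops intronic, UTR and synonymous calls", {
  vs <- mk_variants(5, functional_class = c("intronic", "missense",
                                            "synonymous", "utr",
                                            "frameshift"))
  out <- filter_functional(vs, cfg)
  expect_equal(out$functional_class, c("missense", "frameshift"))
  kept <- mk_variants(3, functional_class = c("missense", "nonsense",
                                              "splice_site"))
  expect_equal(filter_functional(kept, cfg), kept)
  empty <- mk_variants(0, functional_class = character())
  expect_equal(nrow(filter_functional(empty, cfg)), 0L)
})

test_that("public-frequency stage removes strictly-above-threshold variants", {
  vs <- mk_variants(5, public_maf = c(0, 0.005, 0.01, 0.02, NA))
  out <- filter_public_maf(vs, cfg)
  expect_equal(out$public_maf, c(0, 0.005, 0.01, NA))
  expect_equal(nrow(filter_public_maf(vs, cascade_config(
    public_maf_threshold = 1))), 5L)
  out0 <- filter_public_maf(vs, cascade_config(public_maf_threshold = 0))
  expect_equal(out0$public_maf, c(0, NA))
  expect_error(cascade_config(public_maf_threshold = -0.1), ">= 0")
})

test_that("in-house stage removes strictly-above-cutoff occurrence counts", {
  vs <- mk_variants(3, inhouse_occurrences = c(0L, 20L, 21L))
  expect_equal(filter_inhouse(vs, cfg)$inhouse_occurrences, c(0L, 20L))
  # an empty database means every count is zero: identity
  db <- occurrence_db()
  expect_equal(nrow(filter_inhouse(vs, cfg, db)), 3L)
  out0 <- filter_inhouse(vs, cascade_config(inhouse_max_occurrences = 0))
  expect_equal(out0$inhouse_occurrences, 0L)
})

test_that("quality stage keeps scores that met or exceeded the minimum", {
  vs <- mk_variants(3, quality = c(99, 100, 101))
  expect_equal(filter_quality(vs, cfg)$quality, c(100, 101))
  expect_equal(nrow(filter_quality(vs, cascade_config(min_quality = 0))), 3L)
  expect_equal(nrow(filter_quality(mk_variants(0,
    functional_class = character()), cfg)), 0L)
})

test_that("zygosity stage follows the indicated inheritance mode", {
  vs <- mk_variants(3, zygosity = c("homozygous", "heterozygous",
                                    "heterozygous"))
  rec <- filter_zygosity(vs, cascade_config(zygosity_mode = "recessive"))
  expect_equal(rec$zygosity, "homozygous")
  expect_equal(nrow(filter_zygosity(vs, cfg)), 3L)  # default: no exclusion
  expect_equal(nrow(filter_zygosity(vs,
    cascade_config(zygosity_mode = "dominant"))), 3L)
  hemi <- mk_variants(1, zygosity = "hemizygous")
  xl <- filter_zygosity(hemi, cascade_config(zygosity_mode = "x_linked"))
  expect_equal(xl$zygosity, "hemizygous")
})

test_that("boundary values sit on the retained side of every threshold", {
  at_bounds <- mk_variants(1, public_maf = 0.01, inhouse_occurrences = 20L,
                           quality = 100, zygosity = "homozygous")
  res <- run_cascade(at_bounds, cascade_config(zygosity_mode = "recessive"))
  expect_equal(nrow(res$candidates), 1L)
  just_over <- mk_variants(1, public_maf = 0.010001,
                           inhouse_occurrences = 21L, quality = 99.999)
  expect_equal(nrow(filter_public_maf(just_over, cfg)), 0L)
  expect_equal(nrow(filter_inhouse(just_over, cfg)), 0L)
  expect_equal(nrow(filter_quality(just_over, cfg)), 0L)
})

test_that("a constructed sample loses exactly two variants per stage", {
  # 10 variants; stages trip in cascade order, two variants each
  vs <- mk_variants(
    10,
    functional_class = c("intronic", "synonymous", rep("missense", 8)),
    public_maf = c(NA, NA, 0.5, 0.9, rep(NA, 6)),
    inhouse_occurrences = c(rep(0L, 4), 21L, 30L, rep(0L, 4))[1:10],
    quality = c(rep(120, 6), 10, 50, 120, 120),
    zygosity = c(rep("homozygous", 8), "heterozygous", "heterozygous"))
  res <- run_cascade(vs, cascade_config(zygosity_mode = "recessive"),
                     sample_id = "s1")
  expect_equal(res$funnel$remaining, c(10L, 8L, 6L, 4L, 2L, 0L))
  expect_s3_class(res$funnel, "funnel_report")
})

test_that("a fully permissive configuration passes everything through", {
  open_cfg <- cascade_config(public_maf_threshold = 1,
                             inhouse_max_occurrences = .Machine$integer.max,
                             min_quality = 0, zygosity_mode = "none",
                             retained_classes = FUNCTIONAL_CLASSES)
  vs <- random_variants(50)
  res <- run_cascade(vs, open_cfg)
  expect_equal(res$candidates, vs)
  expect_true(all(res$funnel$remaining == 50L))
})

test_that("an empty sample yields an all-zero funnel", {
  res <- run_cascade(mk_variants(0, functional_class = character()), cfg)
  expect_equal(res$funnel$remaining, rep(0L, 6))
  expect_equal(nrow(res$candidates), 0L)
})

test_that("every filter is idempotent and the funnel is monotone", {
  set.seed(42)
  filters <- list(filter_functional, filter_public_maf, filter_inhouse,
                  filter_quality, filter_zygosity)
  cfg_rec <- cascade_config(zygosity_mode = "recessive")
  for (rep in 1:20) {
    vs <- random_variants(sample(0:30, 1))
    for (f in filters) {
      once <- f(vs, cfg_rec)
      expect_equal(f(once, cfg_rec), once)
    }
    res <- run_cascade(vs, cfg_rec)
    expect_true(all(diff(res$funnel$remaining) <= 0))
    # no variant is ever created
    expect_true(all(keys_of(res$candidates) %in% keys_of(vs)))
  }
})

test_that("funnel reports reject non-monotone counts", {
  expect_error(funnel_report(c(5, 6, 4, 3, 2, 1)), "non-increasing")
  expect_error(funnel_report(c(5, 4, 3)), "length")
})

test_that("ranking puts feature-matched genes first and is stable", {
  p <- mini_panelset()$vision
  cands <- mk_variants(3, pos = c(30L, 20L, 10L),
                       gene = c("OTHER", "RPGR", "OTHER"),
                       functional_class = "missense")
  ranked <- rank_candidates(cands, p, "retinal dystrophy")
  expect_equal(ranked$gene[1], "RPGR")
  # ties keep coordinate order deterministically
  expect_equal(ranked$pos[2:3], c(10L, 30L))

  one <- mk_variants(1)
  expect_equal(rank_candidates(one, p, "retinal dystrophy"), one)

  # known-pathogenic outranks tier; LoF outranks damaging missense
  mixed <- mk_variants(3, pos = c(1L, 2L, 3L),
                       functional_class = c("missense", "frameshift",
                                            "missense"),
                       sift = c(0.01, NA, 0.5),
                       known_pathogenic = c(FALSE, FALSE, TRUE))
  r <- rank_candidates(mixed)
  expect_equal(r$pos, c(3L, 2L, 1L))
})

test_that("funnel averaging is element-wise per panel with a total row", {
  f1 <- funnel_report(c(10, 8, 6, 4, 2, 0), "s1", "vision")
  f2 <- funnel_report(c(20, 16, 12, 8, 4, 0), "s2", "vision")
  avg <- average_funnels(list(f1, f2))
  vision <- avg[avg$panel_id == "vision", ]
  expect_equal(vision$mean_remaining, c(15, 12, 9, 6, 3, 0))
  total <- avg[avg$panel_id == "total", ]
  expect_equal(total$mean_remaining, vision$mean_remaining)

  expect_equal(average_funnels(list(f1))$mean_remaining[1:6],
               as.numeric(f1$remaining))
  # identical funnels average to themselves
  same <- average_funnels(list(f1, f1, f1))
  expect_equal(same[same$panel_id == "vision", "mean_remaining"],
               as.numeric(f1$remaining))

  f3 <- funnel_report(c(6, 6, 6, 6, 6, 6), "s3", "renal")
  multi <- average_funnels(list(f1, f2, f3))
  expect_setequal(unique(multi$panel_id), c("vision", "renal", "total"))
  expect_equal(nrow(average_funnels(list())), 0L)
})
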