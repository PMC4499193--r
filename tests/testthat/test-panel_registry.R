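test_that("load_panels assigns rows to panels, keeping cross-panel redundancy", {
  catalog <- data.frame(
    gene = c("A", "B", "B", "C"),
    panel = c("vision", "vision", "neurology", "renal"),
    transcript = paste0("NM_", 1:4), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ps <- load_panels(path)
  expect_s3_class(ps, "panel_set")
  expect_setequal(names(ps), c("vision", "neurology", "renal"))
  expect_setequal(panel_genes(ps$vision), c("A", "B"))
  expect_setequal(panel_genes(ps$neurology), "B")
  expect_setequal(panel_genes(ps$renal), "C")
})

test_that("load_panels handles degenerate and malformed catalogs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene\tpanel\ttranscript", path)
  expect_warning(ps <- load_panels(path), "empty")
  expect_length(ps, 0L)

  dup <- data.frame(gene = c("A", "A"), panel = c("p1", "p1"),
                    transcript = c("t", "t"))
  write.table(dup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(ps <- load_panels(path), "duplicate")
  expect_equal(panel_genes(ps$p1), "A")

  writeLines(c("gene\ttranscript", "A\tt"), path)
  expect_error(load_panels(path), "panel")
})

test_that("catalog round-trips through load_panels with identical membership", {
  catalog <- data.frame(
    gene = sprintf("G%02d", c(1:10, 9:18)),
    panel = c(rep("p1", 10), rep("p2", 10)),
    transcript = "t", stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ps1 <- load_panels(path)
  # serialize back to a catalog and reload
  back <- do.call(rbind, lapply(ps1, function(p)
    data.frame(gene = p$genes$gene_symbol, panel = p$panel_id,
               transcript = p$genes$transcript_id)))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(back, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  ps2 <- load_panels(path2)
  for (id in names(ps1))
    expect_setequal(panel_genes(ps1[[id]]), panel_genes(ps2[[id]]))
})

test_that("redundancy_fraction counts genes shared by two or more panels", {
  one <- panel_set(list(panel("p1", genes = c("A", "B"))))
  expect_equal(redundancy_fraction(one), 0)
  two <- panel_set(list(panel("p1", genes = c("A", "B")),
                        panel("p2", genes = c("B", "C"))))
  expect_equal(redundancy_fraction(two), 1 / 3)
  same <- panel_set(list(panel("p1", genes = "A"), panel("p2", genes = "A")))
  expect_equal(redundancy_fraction(same), 1)
  # 20 distinct genes, 2 shared between the two panels -> 0.10
  shared <- panel_set(list(
    panel("p1", genes = sprintf("G%02d", 1:12)),
    panel("p2", genes = sprintf("G%02d", 11:20))))
  expect_equal(redundancy_fraction(shared), 2 / 20)
  # invariant under panel reordering
  expect_equal(redundancy_fraction(panel_set(rev(unclass(two)))),
               redundancy_fraction(two))
  expect_error(redundancy_fraction(panel_set()), "empty")
})

test_that("assign_panel routes one feature to exactly one panel", {
  ps <- mini_panelset()
  expect_identical(assign_panel(ps, "retinal dystrophy")$panel_id, "vision")
  expect_identical(assign_panel(ps, "skeletal dysplasia")$panel_id,
                   "dysmorphology_dysplasia")
  # deterministic for a fixed panel set
  expect_identical(assign_panel(ps, "retinal dystrophy")$panel_id,
                   assign_panel(ps, "retinal dystrophy")$panel_id)
  expect_error(assign_panel(ps, "xyz"), "nearest")
})

test_that("assign_panel reports ambiguity when feature maps collide", {
  ps <- panel_set(list(
    panel("p1", genes = "A", feature_map = list(blur = "A")),
    panel("p2", genes = "B", feature_map = list(blur = "B"))))
  expect_error(assign_panel(ps, "blur", routing = NULL), "ambiguous")
})

test_that("spike_in grows the gene set and bumps the version", {
  p1 <- panel("vision", genes = sprintf("G%03d", 1:96))
  p2 <- spike_in(p1, sprintf("N%d", 1:4))
  expect_equal(length(panel_genes(p2)), 100L)
  expect_equal(p2$version, 2L)
  # original untouched, old genes all retained
  expect_equal(p1$version, 1L)
  expect_length(panel_genes(p1), 96L)
  expect_true(all(panel_genes(p1) %in% panel_genes(p2)))
  # identity and idempotent spike-ins
  expect_identical(spike_in(p1, character()), p1)
  expect_warning(p3 <- spike_in(p1, "G001"), "already present")
  expect_equal(p3$version, 1L)
})

test_that("panel size plausibility check is soft", {
  ps <- mini_panelset()
  msgs <- validate_panel_sizes(ps)
  expect_true(length(msgs) == length(ps))  # all mini panels are tiny
  big <- panel_set(list(panel("p", genes = sprintf("G%03d", 1:100))))
  expect_length(validate_panel_sizes(big), 0L)
})

test_that("BED export converts to 0-based half-open coordinates", {
  ps <- mini_panelset()
  path <- withr::local_tempfile(fileext = ".bed")
  export_panel_bed(ps$vision, path)
  bed <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(bed$V2, ps$vision$genes$start - 1L)
  expect_equal(bed$V3, ps$vision$genes$end)
})

test_that("the packaged routing table resolves its labels in lower case", {
  routing <- default_routing()
  expect_true(all(c("retinal dystrophy", "skeletal dysplasia") %in%
                    names(routing)))
  expect_identical(unname(routing[["retinal dystrophy"]]), "vision")
  ps <- mini_panelset()
  expect_identical(assign_panel(ps, "Retinal Dystrophy")$panel_id, "vision")
})
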