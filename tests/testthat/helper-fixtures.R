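# Shared fixture builders for the suite. Everything is generated in code;
# no files are read except the package's own extdata.

# variant table with pass-everything defaults; override per test
mk_variants <- function(n = 1L, chrom = "1", pos = seq_len(n), ref = "A",
                        alt = "G", gene = "GENE1",
                        functional_class = "missense",
                        public_maf = NA_real_, inhouse_occurrences = 0L,
                        quality = 120, zygosity = "homozygous",
                        sift = NA_real_, polyphen = NA_real_,
                        known_pathogenic = FALSE) {
  variant_table(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
                functional_class = functional_class,
                public_maf = public_maf,
                inhouse_occurrences = inhouse_occurrences, quality = quality,
                zygosity = zygosity, sift = sift, polyphen = polyphen,
                known_pathogenic = known_pathogenic)
}

keys_of <- function(vs) sort(variant_key(vs$chrom, vs$pos, vs$ref, vs$alt))

# small registry with feature maps covering the routing labels used in tests
mini_panelset <- function() {
  panel_set(list(
    panel(
      "vision", name = "Vision",
      genes = data.frame(gene_symbol = c("RPGR", "CRB1", "PAX6"),
                         chrom = "X", start = c(100L, 500L, 900L),
                         end = c(200L, 600L, 1000L),
                         stringsAsFactors = FALSE),
      feature_map = list("retinal dystrophy" = c("RPGR", "CRB1"),
                         "aniridia" = "PAX6")),
    panel("dysmorphology_dysplasia", name = "Dysmorphology-Dysplasia",
          genes = c("COL2A1", "FGFR3", "PAX6"),
          feature_map = list("skeletal dysplasia" = c("COL2A1", "FGFR3"))),
    panel("renal", name = "Renal", genes = c("PKD1", "PKD2"),
          feature_map = list("cystic kidney disease" = c("PKD1", "PKD2")))
  ))
}

# random variant table exercising every filter dimension
random_variants <- function(n) {
  variant_table(
    chrom = sample(c("1", "2", "X"), n, replace = TRUE),
    pos = sample.int(10000L, n),
    ref = "A",
    alt = sample(c("C", "G", "T"), n, replace = TRUE),
    gene = sample(c("G1", "G2", NA), n, replace = TRUE),
    functional_class = sample(FUNCTIONAL_CLASSES, n, replace = TRUE),
    public_maf = ifelse(runif(n) < 0.2, NA, runif(n)),
    inhouse_occurrences = sample(0:40, n, replace = TRUE),
    quality = runif(n, 0, 200),
    zygosity = sample(c("homozygous", "heterozygous", "hemizygous"), n,
                      replace = TRUE),
    known_pathogenic = runif(n) < 0.1
  )
}

# the five cascade predicates, written out independently of the package's
# filter implementations, for conjunction-oracle checks
brute_force_survivors <- function(vs, cfg) {
  keep <- logical(nrow(vs))
  for (i in seq_len(nrow(vs))) {
    ok <- vs$functional_class[i] %in% cfg$retained_classes
    if (!is.na(vs$public_maf[i]) &&
        vs$public_maf[i] > cfg$public_maf_threshold) ok <- FALSE
    if (vs$inhouse_occurrences[i] > cfg$inhouse_max_occurrences) ok <- FALSE
    if (vs$quality[i] < cfg$min_quality) ok <- FALSE
    if (cfg$zygosity_mode == "recessive" &&
        vs$zygosity[i] != "homozygous") ok <- FALSE
    if (cfg$zygosity_mode == "x_linked" &&
        !vs$zygosity[i] %in% c("homozygous", "hemizygous")) ok <- FALSE
    keep[i] <- ok
  }
  vs[keep, , drop = FALSE]
}

# per-base reciprocal-overlap oracle for interval matching
brute_force_reciprocal <- function(segs, track, min_reciprocal) {
  vapply(seq_len(nrow(segs)), function(i) {
    bases_i <- seq(segs$start[i], segs$end[i])
    any(vapply(seq_len(nrow(track)), function(j) {
      if (segs$chrom[i] != track$chrom[j]) return(FALSE)
      if (segs$state[i] != track$state[j]) return(FALSE)
      ov <- length(intersect(bases_i, seq(track$start[j], track$end[j])))
      ov / length(bases_i) >= min_reciprocal &&
        ov / (track$end[j] - track$start[j] + 1) >= min_reciprocal
    }, logical(1)))
  }, logical(1))
}
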