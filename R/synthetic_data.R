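# Run code under a seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

#' Parameters of a synthetic referral cohort
#'
#' Describes the statistical structure the pipeline assumes of its input: a
#' background pool of called variants per sample with a realistic
#' functional-class mix and site-frequency spectrum (a point mass of novel
#' variants plus a Beta-distributed polymorphism tail), excess homozygosity
#' from consanguinity (genotypes follow `p^2 + f*p*(1-p)` homozygote
#' frequency under inbreeding coefficient `f`), a fraction of samples
#' carrying a spiked-in causal variant that passes every cascade filter by
#' construction, per-type detection dropout (lower for indels, emulating
#' homopolymer-context losses without simulating sequence), and call
#' qualities straddling the 100 cutoff.
#'
#' @param n_samples Number of patients.
#' @param panel Optional [panel()] providing the gene pool.
#' @param variants_per_sample Mean called variants per sample (Poisson);
#'   default 1138, a typical all-panel average input.
#' @param functional_class_mix Named probability vector over
#'   [FUNCTIONAL_CLASSES]; must sum to 1.
#' @param maf_zero_prob Probability a background variant is novel (public
#'   MAF exactly 0).
#' @param maf_unknown_prob Probability the public MAF is unknown (`NA`).
#' @param maf_beta_shape1,maf_beta_shape2 Beta parameters of the
#'   polymorphism frequency tail.
#' @param consanguinity_f Inbreeding coefficient in `[0, 1]`; 0.0625 (the
#'   first-cousin-offspring expectation) by default.
#' @param causal_fraction Probability a sample receives a spiked-in causal
#'   variant; default 0.43.
#' @param detection_prob Named numeric `c(snv = , indel = )` detection
#'   probabilities; defaults 0.93 and 0.72.
#' @param quality_mean,quality_sd Normal parameters of the Phred-like
#'   quality distribution (defaults 95 and 20, straddling the 100 cutoff).
#' @param zygosity_mode Inheritance mode of the spiked causal variants:
#'   `"recessive"` (homozygous, the default for a consanguineous cohort),
#'   `"dominant"`/`"none"` (heterozygous) or `"x_linked"` (hemizygous).
#' @param seed Master RNG seed.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_samples = 100L, panel = NULL,
                          variants_per_sample = 1138,
                          functional_class_mix = c(
                            intronic = 0.55, utr = 0.08, synonymous = 0.07,
                            missense = 0.22, nonsense = 0.01,
                            frameshift = 0.01, nonframeshift_indel = 0.01,
                            splice_site = 0.01, other_exonic = 0.04),
                          maf_zero_prob = 0.20, maf_unknown_prob = 0.05,
                          maf_beta_shape1 = 0.5, maf_beta_shape2 = 1.5,
                          consanguinity_f = 0.0625, causal_fraction = 0.43,
                          detection_prob = c(snv = 0.93, indel = 0.72),
                          quality_mean = 95, quality_sd = 20,
                          zygosity_mode = c("recessive", "dominant", "none",
                                            "x_linked"),
                          seed = 1L) {
  zygosity_mode <- match.arg(zygosity_mode)
  stopifnot(n_samples >= 1L, variants_per_sample >= 0)
  if (abs(sum(functional_class_mix) - 1) > 1e-8)
    stop("functional_class_mix must sum to 1")
  bad <- setdiff(names(functional_class_mix), FUNCTIONAL_CLASSES)
  if (length(bad) > 0L) stop("unknown class in mix: ",
                             paste(bad, collapse = ", "))
  probs <- c(maf_zero_prob, maf_unknown_prob, consanguinity_f,
             causal_fraction, detection_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (maf_zero_prob + maf_unknown_prob > 1)
    stop("maf_zero_prob + maf_unknown_prob must be <= 1")
  if (!all(c("snv", "indel") %in% names(detection_prob)))
    stop("detection_prob needs 'snv' and 'indel' entries")
  structure(as.list(environment()), class = "cohort_params")
}

#' Draw genotypes at a biallelic site under inbreeding
#'
#' Genotype frequencies with inbreeding coefficient `f`: homozygous
#' alternate `p^2 + f*p*q`, heterozygous `2*p*q*(1 - f)`, homozygous
#' reference `q^2 + f*p*q` (`q = 1 - p`). At `f = 0` this is
#' Hardy-Weinberg; at `f = 1` every carrier is homozygous.
#'
#' @param p Alternate allele frequency.
#' @param f Inbreeding coefficient in `[0, 1]`.
#' @param n Number of individuals to draw.
#' @param seed Optional seed.
#' @return Character vector in `c("hom_alt", "het", "hom_ref")`.
#' @export
sample_genotypes <- function(p, f, n, seed = NULL) {
  stopifnot(p >= 0, p <= 1, f >= 0, f <= 1)
  q <- 1 - p
  probs <- c(hom_alt = p^2 + f * p * q, het = 2 * p * q * (1 - f),
             hom_ref = q^2 + f * p * q)
  with_local_seed(seed,
    sample(names(probs), n, replace = TRUE, prob = probs))
}

random_snv_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  shift <- sample.int(3L, n, replace = TRUE)
  alt <- bases[(match(ref, bases) - 1L + shift) %% 4L + 1L]
  data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE)
}

random_indel_alleles <- function(n, width) {
  bases <- c("A", "C", "G", "T")
  anchor <- sample(bases, n, replace = TRUE)
  tail <- vapply(seq_len(n), function(i)
    paste(sample(bases, width, replace = TRUE), collapse = ""), character(1))
  long <- paste0(anchor, tail)
  insertion <- stats::runif(n) < 0.5
  data.frame(ref = ifelse(insertion, anchor, long),
             alt = ifelse(insertion, long, anchor),
             stringsAsFactors = FALSE)
}

#' Generate a seeded synthetic cohort
#'
#' Draws, per sample, a Poisson number of background variants from the
#' configured class mix, frequency spectrum, occurrence, quality and
#' zygosity models, then spikes a causal variant into a
#' `causal_fraction` share of samples. A spiked variant is constructed to
#' pass every cascade filter (rare, functional, quality >= 100, zygosity
#' matching the inheritance mode) and is included in the sample's call list
#' if and only if it was drawn detectable under the per-type detection
#' probabilities. Output is byte-identical under a fixed seed.
#'
#' @param params A [cohort_params()].
#' @return A list of class `synthetic_cohort` with `variants` (one variant
#'   table with a `sample_id` column), `truth` (one row per sample:
#'   spiked-variant key, type, zygosity, detectability) and `params`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  with_local_seed(params$seed, {
    p <- params
    sample_ids <- sprintf("S%04d", seq_len(p$n_samples))
    gene_pool <- if (!is.null(p$panel)) panel_genes(p$panel)
                 else sprintf("GENE%03d", 1:60)

    n_bg <- stats::rpois(p$n_samples, p$variants_per_sample)
    N <- sum(n_bg)
    cls <- sample(names(p$functional_class_mix), N, replace = TRUE,
                  prob = p$functional_class_mix)
    u <- stats::runif(N)
    maf <- stats::rbeta(N, p$maf_beta_shape1, p$maf_beta_shape2)
    maf[u < p$maf_zero_prob] <- 0
    maf[u >= p$maf_zero_prob &
        u < p$maf_zero_prob + p$maf_unknown_prob] <- NA
    p_eff <- ifelse(is.na(maf) | maf <= 0, 1e-4, maf)
    q_eff <- 1 - p_eff
    f <- p$consanguinity_f
    hom_w <- p_eff^2 + f * p_eff * q_eff
    het_w <- 2 * p_eff * q_eff * (1 - f)
    zyg <- ifelse(stats::runif(N) < hom_w / (hom_w + het_w),
                  "homozygous", "heterozygous")
    occ <- stats::rpois(N, 1 + 200 * ifelse(is.na(maf), 0, maf))
    qual <- pmax(stats::rnorm(N, p$quality_mean, p$quality_sd), 0)
    is_indel <- cls %in% c("frameshift", "nonframeshift_indel")
    alleles <- random_snv_alleles(N)
    if (any(is_indel)) {
      alleles[is_indel & cls == "frameshift", ] <-
        random_indel_alleles(sum(is_indel & cls == "frameshift"), 1L)
      alleles[is_indel & cls == "nonframeshift_indel", ] <-
        random_indel_alleles(sum(is_indel & cls == "nonframeshift_indel"), 3L)
    }
    is_missense <- cls == "missense"
    bg <- data.frame(
      sample_id = rep(sample_ids, n_bg),
      chrom = sample(as.character(1:22), N, replace = TRUE),
      pos = sample.int(50000000L, N, replace = TRUE),
      ref = alleles$ref, alt = alleles$alt,
      gene = sample(gene_pool, N, replace = TRUE),
      functional_class = cls, public_maf = maf,
      inhouse_occurrences = occ, quality = qual, zygosity = zyg,
      sift = ifelse(is_missense, stats::runif(N), NA_real_),
      polyphen = ifelse(is_missense, stats::runif(N), NA_real_),
      known_pathogenic = stats::runif(N) < 0.01,
      variant_type = ifelse(is_indel, "indel", "snv"),
      stringsAsFactors = FALSE
    )
    # a sample must not list the same variant twice
    bg <- bg[!duplicated(paste(bg$sample_id,
                               variant_key(bg$chrom, bg$pos, bg$ref,
                                           bg$alt))), , drop = FALSE]

    spiked <- stats::runif(p$n_samples) < p$causal_fraction
    n_sp <- sum(spiked)
    causal_zyg <- switch(p$zygosity_mode,
                         recessive = "homozygous",
                         x_linked = "hemizygous",
                         "heterozygous")
    truth <- data.frame(sample_id = sample_ids, spiked = spiked,
                        chrom = NA_character_, pos = NA_integer_,
                        ref = NA_character_, alt = NA_character_,
                        gene = NA_character_, variant_type = NA_character_,
                        zygosity = NA_character_, detectable = NA,
                        stringsAsFactors = FALSE)
    if (n_sp > 0L) {
      type <- sample(c("snv", "indel"), n_sp, replace = TRUE,
                     prob = c(0.74, 0.26))
      cls_sp <- ifelse(type == "indel", "frameshift",
                       ifelse(stats::runif(n_sp) < 0.7, "missense",
                              "nonsense"))
      al <- random_snv_alleles(n_sp)
      if (any(type == "indel"))
        al[type == "indel", ] <- random_indel_alleles(sum(type == "indel"),
                                                      1L)
      sp <- data.frame(
        sample_id = sample_ids[spiked],
        chrom = sample(as.character(1:22), n_sp, replace = TRUE),
        # positions beyond the background range: spike keys never collide
        pos = 90000000L + seq_len(n_sp),
        ref = al$ref, alt = al$alt,
        gene = sample(gene_pool, n_sp, replace = TRUE),
        functional_class = cls_sp, public_maf = 0,
        inhouse_occurrences = sample(0:5, n_sp, replace = TRUE),
        quality = stats::runif(n_sp, 100, 160), zygosity = causal_zyg,
        sift = ifelse(cls_sp == "missense", 0.01, NA_real_),
        polyphen = ifelse(cls_sp == "missense", 0.99, NA_real_),
        known_pathogenic = FALSE, variant_type = type,
        stringsAsFactors = FALSE
      )
      detectable <- stats::runif(n_sp) < p$detection_prob[type]
      truth[spiked, c("chrom", "pos", "ref", "alt", "gene", "variant_type",
                      "zygosity")] <-
        sp[, c("chrom", "pos", "ref", "alt", "gene", "variant_type",
               "zygosity")]
      truth$detectable[spiked] <- detectable
      bg <- rbind(bg, sp[detectable, , drop = FALSE])
    }
    bg <- bg[order(bg$sample_id, bg$chrom, bg$pos, bg$ref, bg$alt), ,
             drop = FALSE]
    rownames(bg) <- NULL
    structure(list(variants = validate_variants(bg), truth = truth,
                   params = p),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d samples, %d variants, %d spiked causal (%d detectable)\n",
    x$params$n_samples, nrow(x$variants), sum(x$truth$spiked),
    sum(x$truth$detectable, na.rm = TRUE)))
  invisible(x)
}

#' Run the cascade over a synthetic cohort and recover the diagnostic yield
#'
#' Applies [run_cascade()] to every sample and counts a sample as solved
#' when its spiked causal variant survives to the candidate list. With full
#' detectability the estimated yield recovers the generating
#' `causal_fraction` up to binomial noise.
#'
#' @param cohort A [generate_cohort()] result.
#' @param cfg A [cascade_config()]; defaults to the cohort's inheritance
#'   mode with standard thresholds.
#' @param db Optional [occurrence_db()] for stage 3.
#' @return List with `yield` ([rate_report()]: solved samples over all
#'   samples), `solved` (logical per sample) and `funnels` (list of
#'   [funnel_report()]s).
#' @export
recover_cohort_yield <- function(cohort, cfg = NULL, db = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(cfg)) {
    mode <- cohort$params$zygosity_mode
    cfg <- cascade_config(zygosity_mode = if (mode == "none") "none" else mode)
  }
  by_sample <- split(cohort$variants,
                     factor(cohort$variants$sample_id,
                            levels = cohort$truth$sample_id))
  panel_id <- if (is.null(cohort$params$panel)) NA_character_
              else cohort$params$panel$panel_id
  solved <- logical(nrow(cohort$truth))
  funnels <- vector("list", nrow(cohort$truth))
  for (i in seq_len(nrow(cohort$truth))) {
    sid <- cohort$truth$sample_id[i]
    vs <- by_sample[[sid]]
    res <- run_cascade(vs, cfg, db = db, sample_id = sid)
    attr(res$funnel, "panel_id") <- panel_id
    funnels[[i]] <- res$funnel
    if (isTRUE(cohort$truth$spiked[i]) &&
        isTRUE(cohort$truth$detectable[i])) {
      key <- variant_key(cohort$truth$chrom[i], cohort$truth$pos[i],
                         cohort$truth$ref[i], cohort$truth$alt[i])
      cand_keys <- variant_key(res$candidates$chrom, res$candidates$pos,
                               res$candidates$ref, res$candidates$alt)
      solved[i] <- key %in% cand_keys
    }
  }
  list(yield = rate_report(sum(solved), nrow(cohort$truth)),
       solved = solved, funnels = funnels)
}

#' Generate synthetic positive-control records
#'
#' Emulates an analytical-sensitivity experiment: known mutations of each
#' type with Bernoulli detection, and a share of controls whose gene is
#' absent from the appropriate panel (design flaws, never detectable).
#'
#' @param n_snv,n_indel Control counts per type (defaults 428 and 152).
#' @param p_snv,p_indel Detection probabilities (defaults 0.93 and 0.72).
#' @param design_flaw_fraction Probability a control's gene is not covered
#'   by the panel design.
#' @param seed RNG seed.
#' @return Data.frame of `control_id`, `variant_type`, `gene_in_panel`,
#'   `detected`.
#' @export
generate_controls <- function(n_snv = 428L, n_indel = 152L, p_snv = 0.93,
                              p_indel = 0.72, design_flaw_fraction = 0,
                              seed = NULL) {
  stopifnot(p_snv >= 0, p_snv <= 1, p_indel >= 0, p_indel <= 1,
            design_flaw_fraction >= 0, design_flaw_fraction <= 1)
  with_local_seed(seed, {
    n <- n_snv + n_indel
    type <- c(rep("snv", n_snv), rep("indel", n_indel))
    p <- ifelse(type == "snv", p_snv, p_indel)
    in_panel <- stats::runif(n) >= design_flaw_fraction
    data.frame(control_id = sprintf("C%04d", seq_len(n)),
               variant_type = type, gene_in_panel = in_panel,
               detected = in_panel & stats::runif(n) < p,
               stringsAsFactors = FALSE)
  })
}

#' Generate CNV segments with known expected classifications
#'
#' Emits a boundary pack crossing the decision surfaces of the CNV rules —
#' log2 ratios in `{-1.01, -1, -0.99, 0.57, 0.58}`, probe counts `{49, 50}`
#' and lengths straddling the 200 kb / 500 kb cutoffs — plus optional
#' random segments, together with a benign track and parental segment
#' tables constructed so that selected segments are benign-matched or
#' inherited. Expected labels are computed at generation time from the
#' stated rules (simple inline comparisons, independent of the classifier
#' code) and attached as `expected_*` columns.
#'
#' @param n_random Number of additional random segments.
#' @param include_boundary Include the deterministic boundary pack.
#' @param seed RNG seed.
#' @return List with `segments` (including `expected_state`,
#'   `expected_passes`, `expected_benign`, `expected_inheritance`,
#'   `expected_classification`), `benign`, `mother`, `father`.
#' @export
generate_cnv_fixtures <- function(n_random = 20L, include_boundary = TRUE,
                                  seed = NULL) {
  with_local_seed(seed, {
    segs <- data.frame(sample_id = character(), chrom = character(),
                       start = integer(), end = integer(),
                       mean_log2 = numeric(), n_probes = integer(),
                       stringsAsFactors = FALSE)
    if (include_boundary) {
      grid <- expand.grid(
        mean_log2 = c(-1.01, -1, -0.99, 0.57, 0.58),
        n_probes = c(49L, 50L),
        length = c(199999L, 200000L, 499999L, 500000L),
        KEEP.OUT.ATTRS = FALSE)
      start <- 1000000L + (seq_len(nrow(grid)) - 1L) * 2000000L
      segs <- rbind(segs, data.frame(
        sample_id = "child", chrom = "B1", start = start,
        end = start + grid$length - 1L, mean_log2 = grid$mean_log2,
        n_probes = grid$n_probes, stringsAsFactors = FALSE))
    }
    if (n_random > 0L) {
      len <- as.integer(round(10^stats::runif(n_random, 4, 6.5)))
      start <- sample.int(100000000L, n_random)
      segs <- rbind(segs, data.frame(
        sample_id = "child",
        chrom = paste0("R", sample.int(22L, n_random, replace = TRUE)),
        start = start, end = start + len - 1L,
        mean_log2 = stats::rnorm(n_random, 0, 0.8),
        n_probes = 1L + stats::rpois(n_random, 60),
        stringsAsFactors = FALSE))
    }
    n <- nrow(segs)
    # expected labels from the stated rules, written out longhand
    state <- rep("neutral", n)
    state[segs$mean_log2 >= 0.58] <- "gain"
    state[segs$mean_log2 <= -1] <- "loss"
    len <- segs$end - segs$start + 1L
    passes <- rep(FALSE, n)
    passes[state == "gain"] <- segs$n_probes[state == "gain"] >= 50L &
      len[state == "gain"] >= 500000L
    passes[state == "loss"] <- segs$n_probes[state == "loss"] >= 50L &
      len[state == "loss"] >= 200000L

    # benign track: exact copies of every 3rd passing segment;
    # mother inherits every 5th passing segment (disjoint offsets keep the
    # two mechanisms separable)
    passing <- which(passes)
    benign_idx <- passing[seq_along(passing) %% 3L == 0L]
    mother_idx <- setdiff(passing[seq_along(passing) %% 5L == 1L],
                          benign_idx)
    copy_track <- function(idx) {
      if (length(idx) == 0L)
        return(data.frame(sample_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          mean_log2 = numeric(), n_probes = integer(),
                          stringsAsFactors = FALSE))
      data.frame(sample_id = "track", chrom = segs$chrom[idx],
                 start = segs$start[idx], end = segs$end[idx],
                 mean_log2 = segs$mean_log2[idx],
                 n_probes = segs$n_probes[idx], stringsAsFactors = FALSE)
    }
    benign <- copy_track(benign_idx)
    benign$state <- state[benign_idx]
    benign$sample_id <- NULL
    mother <- copy_track(mother_idx)
    father <- copy_track(integer())

    expected_benign <- seq_len(n) %in% benign_idx
    expected_inherit <- ifelse(seq_len(n) %in% mother_idx, "inherited",
                               "de_novo")
    expected_class <- ifelse(
      state != "neutral" & passes & !expected_benign &
        expected_inherit == "de_novo", "pathogenic", "not_classified")
    segs$expected_state <- state
    segs$expected_passes <- passes
    segs$expected_benign <- expected_benign
    segs$expected_inheritance <- expected_inherit
    segs$expected_classification <- expected_class
    list(segments = segs, benign = benign, mother = mother, father = father)
  })
}
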