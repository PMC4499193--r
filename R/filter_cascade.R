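CASCADE_STAGES <- c("input", "functional", "public_db", "inhouse_db",
                    "quality", "zygosity")

#' Configure the variant filtration cascade
#'
#' Holds the thresholds of the five-stage cascade. Boundary conventions are
#' deliberate and tested: a variant with public MAF *exactly* at the
#' threshold is retained (filtering removes strictly greater), an in-house
#' occurrence count exactly at the cutoff is retained, and a quality exactly
#' at the minimum is retained (the quality rule is inclusive: scores that
#' met or exceeded the cutoff pass).
#'
#' @param public_maf_threshold Public MAF above which (strictly) a variant
#'   is considered a common polymorphism and removed. Default 0.01 (1%).
#' @param inhouse_max_occurrences In-house occurrence count above which
#'   (strictly) a variant is considered cohort-frequent and removed.
#'   Default 20.
#' @param min_quality Minimum Phred-like quality retained (inclusive).
#'   Default 100.
#' @param zygosity_mode Inheritance mode driving the zygosity stage:
#'   `"none"` (default) and `"dominant"` exclude nothing, `"recessive"`
#'   retains homozygotes only, `"x_linked"` retains homozygotes and
#'   hemizygotes.
#' @param retained_classes Functional classes kept by the first stage;
#'   defaults to everything except intronic, UTR and synonymous. Exposed so
#'   annotation-vocabulary dialects can be remapped.
#' @param occurrence_unit Whether in-house occurrence counts are
#'   allele-dosage (`"allele"`, default) or distinct-sample (`"sample"`)
#'   counts when looked up from an [occurrence_db()].
#' @return An object of class `cascade_config`.
#' @export
cascade_config <- function(public_maf_threshold = 0.01,
                           inhouse_max_occurrences = 20L,
                           min_quality = 100,
                           zygosity_mode = c("none", "recessive", "dominant",
                                             "x_linked"),
                           retained_classes = setdiff(FUNCTIONAL_CLASSES,
                                                      NONFUNCTIONAL_CLASSES),
                           occurrence_unit = c("allele", "sample")) {
  zygosity_mode <- match.arg(zygosity_mode)
  occurrence_unit <- match.arg(occurrence_unit)
  if (public_maf_threshold < 0) stop("public_maf_threshold must be >= 0")
  if (inhouse_max_occurrences < 0) stop("inhouse_max_occurrences must be >= 0")
  if (min_quality < 0) stop("min_quality must be >= 0")
  bad <- setdiff(retained_classes, FUNCTIONAL_CLASSES)
  if (length(bad) > 0L)
    stop("unknown retained class: ", paste(bad, collapse = ", "))
  structure(
    list(public_maf_threshold = public_maf_threshold,
         inhouse_max_occurrences = as.numeric(inhouse_max_occurrences),
         min_quality = min_quality, zygosity_mode = zygosity_mode,
         retained_classes = retained_classes,
         occurrence_unit = occurrence_unit),
    class = "cascade_config"
  )
}

#' Cascade stage 1: drop classes unlikely to be functional
#'
#' Removes variants whose functional class is outside
#' `cfg$retained_classes` (by default: intronic, UTR and synonymous calls
#' are dropped). Row order is preserved.
#'
#' @param vs Variant table (see [variant_table()]).
#' @param cfg A [cascade_config()].
#' @return The filtered variant table.
#' @export
filter_functional <- function(vs, cfg = cascade_config()) {
  vs[vs$functional_class %in% cfg$retained_classes, , drop = FALSE]
}

#' Cascade stage 2: drop common public polymorphisms
#'
#' Removes variants whose public MAF is strictly greater than
#' `cfg$public_maf_threshold`. Variants absent from public databases
#' (`public_maf = NA`) are retained: absence of frequency evidence is not
#' evidence of commonness.
#'
#' @inheritParams filter_functional
#' @return The filtered variant table.
#' @export
filter_public_maf <- function(vs, cfg = cascade_config()) {
  if (cfg$public_maf_threshold < 0) stop("negative public MAF threshold")
  keep <- is.na(vs$public_maf) | vs$public_maf <= cfg$public_maf_threshold
  vs[keep, , drop = FALSE]
}

#' Cascade stage 3: drop cohort-frequent variants
#'
#' Removes variants seen strictly more than `cfg$inhouse_max_occurrences`
#' times in the in-house database. When `db` is supplied, counts are looked
#' up there (in `cfg$occurrence_unit` units); otherwise the table's own
#' `inhouse_occurrences` column is used.
#'
#' @inheritParams filter_functional
#' @param db Optional [occurrence_db()].
#' @return The filtered variant table.
#' @export
filter_inhouse <- function(vs, cfg = cascade_config(), db = NULL) {
  occ <- if (is.null(db)) vs$inhouse_occurrences
         else db_occurrences(db, vs, unit = cfg$occurrence_unit)
  vs[occ <= cfg$inhouse_max_occurrences, , drop = FALSE]
}

#' Cascade stage 4: drop low-confidence calls
#'
#' Retains variants whose Phred-like quality meets or exceeds
#' `cfg$min_quality` (inclusive boundary).
#'
#' @inheritParams filter_functional
#' @return The filtered variant table.
#' @export
filter_quality <- function(vs, cfg = cascade_config()) {
  vs[vs$quality >= cfg$min_quality, , drop = FALSE]
}

#' Cascade stage 5: zygosity filter for the indicated inheritance mode
#'
#' Applied only when an inheritance mode is indicated: `"recessive"` retains
#' homozygotes (autozygosity-driven candidates in consanguineous families),
#' `"x_linked"` retains homozygotes and hemizygotes, `"dominant"` and
#' `"none"` exclude nothing.
#'
#' @inheritParams filter_functional
#' @return The filtered variant table.
#' @export
filter_zygosity <- function(vs, cfg = cascade_config()) {
  keep <- switch(cfg$zygosity_mode,
    none = rep(TRUE, nrow(vs)),
    dominant = rep(TRUE, nrow(vs)),
    recessive = !is.na(vs$zygosity) & vs$zygosity == "homozygous",
    x_linked = !is.na(vs$zygosity) &
      vs$zygosity %in% c("homozygous", "hemizygous"),
    stop("unknown zygosity mode: ", cfg$zygosity_mode)
  )
  vs[keep, , drop = FALSE]
}

#' Per-stage survivor counts of one sample's cascade run
#'
#' @param counts Integer vector of survivors, one per entry of
#'   [CASCADE_STAGES] starting at the unfiltered input; must be
#'   non-increasing.
#' @param sample_id,panel_id Identifiers carried into funnel summaries.
#' @return An object of class `funnel_report`: a data.frame with columns
#'   `stage` and `remaining` plus `sample_id`/`panel_id` attributes.
#' @export
funnel_report <- function(counts, sample_id = NA_character_,
                          panel_id = NA_character_) {
  counts <- as.integer(counts)
  stopifnot(length(counts) == length(CASCADE_STAGES))
  if (any(diff(counts) > 0L))
    stop("funnel counts must be non-increasing across stages")
  structure(
    data.frame(stage = factor(CASCADE_STAGES, levels = CASCADE_STAGES),
               remaining = counts),
    sample_id = as.character(sample_id), panel_id = as.character(panel_id),
    class = c("funnel_report", "data.frame")
  )
}

#' Run the five-stage filtration cascade on one sample
#'
#' Applies, in order: functional-class, public-frequency, in-house
#' occurrence, quality and zygosity filters, and records the per-stage
#' survivor counts. The final candidate set is the conjunction of the five
#' predicates and is therefore independent of stage order; only the
#' intermediate funnel counts reflect the order.
#'
#' @param vs Variant table for one sample.
#' @param cfg A [cascade_config()].
#' @param db Optional [occurrence_db()] for stage 3.
#' @param panel Optional [panel()] the sample was run on (recorded in the
#'   funnel).
#' @param sample_id Sample identifier.
#' @return A list with `candidates` (surviving variant table) and `funnel`
#'   (a [funnel_report()]).
#' @examples
#' vs <- variant_table(
#'   chrom = "1", pos = 1:3, ref = "A", alt = "G",
#'   functional_class = c("missense", "intronic", "missense"),
#'   quality = c(120, 120, 60))
#' run_cascade(vs, cascade_config())$funnel
#' @export
run_cascade <- function(vs, cfg = cascade_config(), db = NULL, panel = NULL,
                        sample_id = NA_character_) {
  vs <- validate_variants(vs)
  counts <- integer(length(CASCADE_STAGES))
  counts[1] <- nrow(vs)
  vs <- filter_functional(vs, cfg);      counts[2] <- nrow(vs)
  vs <- filter_public_maf(vs, cfg);      counts[3] <- nrow(vs)
  vs <- filter_inhouse(vs, cfg, db);     counts[4] <- nrow(vs)
  vs <- filter_quality(vs, cfg);         counts[5] <- nrow(vs)
  vs <- filter_zygosity(vs, cfg);        counts[6] <- nrow(vs)
  list(candidates = vs,
       funnel = funnel_report(counts, sample_id = sample_id,
                              panel_id = if (is.null(panel)) NA_character_
                                         else panel$panel_id))
}

#' Rank surviving candidates for expert review
#'
#' Advisory ordering of the post-cascade short list: candidates in genes
#' mapped to the patient's primary clinical feature first, then variants
#' with a known-pathogenic flag, then by deleteriousness tier (2 =
#' loss-of-function class; 1 = missense predicted deleterious by SIFT <=
#' 0.05 or PolyPhen >= 0.85; 0 otherwise), with genomic coordinate as the
#' final tie-break. The sort is stable and removes nothing.
#'
#' @param candidates Variant table of cascade survivors.
#' @param panel Optional [panel()] providing the `feature_map`.
#' @param primary_feature Optional clinical-feature label to match genes
#'   against.
#' @return The reordered variant table.
#' @export
rank_candidates <- function(candidates, panel = NULL, primary_feature = NULL) {
  if (nrow(candidates) == 0L) return(candidates)
  feature_genes <- character()
  if (!is.null(panel) && !is.null(primary_feature)) {
    idx <- match(tolower(primary_feature), tolower(names(panel$feature_map)))
    if (!is.na(idx)) feature_genes <- panel$feature_map[[idx]]
  }
  matched <- !is.na(candidates$gene) & candidates$gene %in% feature_genes
  tier <- ifelse(
    candidates$functional_class %in% LOF_CLASSES, 2L,
    ifelse(candidates$functional_class == "missense" &
             ((!is.na(candidates$sift) & candidates$sift <= 0.05) |
              (!is.na(candidates$polyphen) & candidates$polyphen >= 0.85)),
           1L, 0L))
  ord <- order(-as.integer(matched), -as.integer(candidates$known_pathogenic),
               -tier, candidates$chrom, candidates$pos, method = "radix")
  candidates[ord, , drop = FALSE]
}

#' Average funnel counts per panel
#'
#' Summarizes many per-sample funnels into mean survivors per stage for
#' each panel, plus an all-panel average row (`panel_id = "total"`). Means
#' are kept exact in `mean_remaining`; `display` carries the
#' nearest-integer rounding used for tabulation.
#'
#' @param reports List of [funnel_report()]s sharing the stage order.
#' @return A data.frame with columns `panel_id`, `stage`, `mean_remaining`,
#'   `display`, `n_samples`.
#' @export
average_funnels <- function(reports) {
  if (length(reports) == 0L)
    return(data.frame(panel_id = character(), stage = character(),
                      mean_remaining = numeric(), display = integer(),
                      n_samples = integer()))
  long <- do.call(rbind, lapply(reports, function(r) {
    stopifnot(identical(as.character(r$stage), CASCADE_STAGES))
    data.frame(panel_id = attr(r, "panel_id"),
               stage = as.character(r$stage), remaining = r$remaining,
               stringsAsFactors = FALSE)
  }))
  summarize <- function(df, label) {
    m <- tapply(df$remaining, df$stage, mean)[CASCADE_STAGES]
    data.frame(panel_id = label, stage = CASCADE_STAGES,
               mean_remaining = as.numeric(m),
               display = as.integer(round(m)),
               n_samples = nrow(df) / length(CASCADE_STAGES),
               stringsAsFactors = FALSE)
  }
  groups <- split(long, long$panel_id)
  per_panel <- do.call(rbind, Map(function(df, id) summarize(df, id),
                                  groups, names(groups)))
  out <- rbind(per_panel, summarize(long, "total"))
  rownames(out) <- NULL
  out$stage <- factor(out$stage, levels = CASCADE_STAGES)
  out
}
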