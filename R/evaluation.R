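#' A numerator/denominator rate with its printed percentage
#'
#' All diagnostic-yield and sensitivity/specificity figures are reported as
#' `x % (n/m)`. Percentages are rounded to the nearest integer, half away
#' from zero, matching clinical reporting practice.
#'
#' @param numerator,denominator Non-negative integers with
#'   `numerator <= denominator` and `denominator > 0`.
#' @return A list of class `rate_report` with `numerator`, `denominator`,
#'   `fraction`, `percent`.
#' @examples
#' rate_report(507, 642)  # 79 %
#' @export
rate_report <- function(numerator, denominator) {
  numerator <- as.integer(numerator); denominator <- as.integer(denominator)
  if (denominator <= 0L) stop("rate is undefined for an empty denominator")
  if (numerator < 0L || numerator > denominator)
    stop("need 0 <= numerator <= denominator")
  fraction <- numerator / denominator
  structure(list(numerator = numerator, denominator = denominator,
                 fraction = fraction,
                 percent = round_half_up(100 * fraction)),
            class = "rate_report")
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @export
print.rate_report <- function(x, ...) {
  cat(sprintf("%d %% (%d/%d)\n", x$percent, x$numerator, x$denominator))
  invisible(x)
}

#' @export
format.rate_report <- function(x, ...) {
  sprintf("%d %% (%d/%d)", x$percent, x$numerator, x$denominator)
}

#' Expand a count summary into record-level rows
#'
#' Evaluation inputs are often tabulated as counts (`n` per combination of
#' flags); this expands such a table into one row per record so the same
#' record-level functions serve both dialects.
#'
#' @param counts Data.frame with an `n` column.
#' @return Data.frame with `sum(n)` rows and the remaining columns.
#' @export
expand_counts <- function(counts) {
  stopifnot("n" %in% names(counts))
  out <- counts[rep(seq_len(nrow(counts)), counts$n),
                setdiff(names(counts), "n"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Analytical sensitivity from positive-control records
#'
#' Fraction of known mutations detected by the assay. Controls whose gene
#' was absent from the panel matched to their presentation (design flaws,
#' `gene_in_panel = FALSE`) can be excluded from the denominator — they are
#' remediable by spike-in gene additions rather than platform limits.
#' Per-variant-type rates are computed on the design-covered subset, where
#' detection is a property of the chemistry rather than the design.
#'
#' @param controls Data.frame with `variant_type` (`"snv"`/`"indel"`),
#'   `gene_in_panel` and `detected` logical columns.
#' @param exclude_design_flaws Drop `gene_in_panel = FALSE` controls from
#'   the denominator.
#' @return List with `overall` ([rate_report()]) and `by_type` (data.frame
#'   of per-type numerators, denominators and percents).
#' @export
analytical_sensitivity <- function(controls, exclude_design_flaws = FALSE) {
  stopifnot(nrow(controls) > 0L)
  pool <- if (exclude_design_flaws)
    controls[controls$gene_in_panel, , drop = FALSE] else controls
  if (nrow(pool) == 0L) stop("no controls left after exclusion")
  overall <- rate_report(sum(pool$detected), nrow(pool))
  covered <- controls[controls$gene_in_panel, , drop = FALSE]
  by_type <- do.call(rbind, lapply(split(covered, covered$variant_type),
    function(df) {
      r <- rate_report(sum(df$detected), nrow(df))
      data.frame(variant_type = df$variant_type[1], detected = r$numerator,
                 total = r$denominator, percent = r$percent,
                 stringsAsFactors = FALSE)
    }))
  rownames(by_type) <- NULL
  list(overall = overall, by_type = by_type)
}

#' Analytical specificity from orthogonal validation records
#'
#' Fraction of assay calls (at or above the quality cutoff) confirmed by
#' orthogonal (Sanger) sequencing, per variant type.
#'
#' @param validations Data.frame with `variant_type` and logical
#'   `confirmed`.
#' @return Data.frame with one row per variant type present: `confirmed`,
#'   `total`, `percent`.
#' @export
analytical_specificity <- function(validations) {
  stopifnot(nrow(validations) > 0L)
  out <- do.call(rbind, lapply(split(validations, validations$variant_type),
    function(df) {
      r <- rate_report(sum(df$confirmed), nrow(df))
      data.frame(variant_type = df$variant_type[1], confirmed = r$numerator,
                 total = r$denominator, percent = r$percent,
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}

#' Clinical sensitivity (diagnostic yield) of a case cohort
#'
#' Fraction of referred patients in whom the panel assay identified a
#' likely causal variant (`solved_by == "panel"`), overall and per group.
#' Cases later solved by another modality (e.g. microarray CNV analysis of
#' panel-negative patients) can be excluded from the denominator via
#' `exclude_modality`, quantifying the yield on the population the assay
#' can in principle solve.
#'
#' @param cases Data.frame with `panel_id`, optional `subgroup`, and
#'   `solved_by` in `c("panel", "cnv", "wes", "unsolved")`.
#' @param group_by `"panel"` or `"subgroup"`.
#' @param exclude_modality Character vector of `solved_by` values removed
#'   from the denominator.
#' @return List with `overall` ([rate_report()]) and `by_group` (data.frame
#'   of per-group rates).
#' @export
clinical_sensitivity <- function(cases, group_by = c("panel", "subgroup"),
                                 exclude_modality = NULL) {
  stopifnot(nrow(cases) > 0L)
  group_by <- match.arg(group_by)
  if (!is.null(exclude_modality))
    cases <- cases[!cases$solved_by %in% exclude_modality, , drop = FALSE]
  solved <- cases$solved_by == "panel"
  overall <- rate_report(sum(solved), nrow(cases))
  key <- if (group_by == "panel") cases$panel_id else cases$subgroup
  groups <- split(seq_len(nrow(cases)), key)
  by_group <- do.call(rbind, lapply(names(groups), function(g) {
    idx <- groups[[g]]
    r <- rate_report(sum(solved[idx]), length(idx))
    data.frame(group = g, solved = r$numerator, total = r$denominator,
               percent = r$percent, stringsAsFactors = FALSE)
  }))
  rownames(by_group) <- NULL
  list(overall = overall, by_group = by_group)
}

#' Breakdown of missed cases by reason
#'
#' Among records the assay missed, what fraction is attributable to each
#' cause? Two record dialects are understood: positive controls (rows with
#' a logical `detected`; the missed set is `detected == FALSE`, and the
#' reason defaults to `design_flaw` when `gene_in_panel` is `FALSE`, else
#' `platform`) and case records (rows with `solved_by`; the missed set is
#' the WES-rescued cases, with an explicit `missed_reason` column).
#'
#' @param records Control or case data.frame as above.
#' @return Data.frame with `missed_reason`, `n`, `total_missed`, `percent`;
#'   empty when nothing was missed.
#' @export
missed_case_breakdown <- function(records) {
  if ("detected" %in% names(records)) {
    missed <- records[!records$detected, , drop = FALSE]
    if (!"missed_reason" %in% names(missed))
      missed$missed_reason <- ifelse(missed$gene_in_panel, "platform",
                                     "design_flaw")
  } else if ("solved_by" %in% names(records)) {
    missed <- records[records$solved_by == "wes", , drop = FALSE]
    if (!"missed_reason" %in% names(missed))
      stop("case records need a missed_reason column")
  } else {
    stop("records must carry either 'detected' or 'solved_by'")
  }
  if (nrow(missed) == 0L)
    return(data.frame(missed_reason = character(), n = integer(),
                      total_missed = integer(), percent = integer()))
  counts <- table(missed$missed_reason)
  out <- data.frame(
    missed_reason = names(counts), n = as.integer(counts),
    total_missed = nrow(missed),
    percent = vapply(as.integer(counts),
                     function(k) rate_report(k, nrow(missed))$percent,
                     numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Packaged evaluation count tables
#'
#' Returns the record-level tables bundled with the package for exercising
#' the evaluation functions at realistic scale:
#' `controls` (positive-control detection outcomes by variant type and
#' design coverage), `validations` (orthogonal confirmation outcomes by
#' type), and `cases` (a *synthetic* referral cohort: per-panel totals are
#' real-world scale, but per-panel solved counts are reconstructed from
#' rounded percentages and a fixed overall yield, and the attribution of
#' CNV-/WES-rescued cases to panels is arbitrary — see the packaged TSV
#' names ending in `_synthetic`).
#'
#' @param which One of `"controls"`, `"validations"`, `"cases"`.
#' @return A record-level data.frame (counts already expanded).
#' @export
bundled_eval_records <- function(which = c("controls", "validations",
                                           "cases")) {
  which <- match.arg(which)
  file <- switch(which,
    controls = "controls_counts.tsv",
    validations = "validation_counts.tsv",
    cases = "cases_counts_synthetic.tsv")
  path <- system.file("extdata", file, package = "paneltriage",
                      mustWork = TRUE)
  counts <- utils::read.delim(path, stringsAsFactors = FALSE)
  expand_counts(counts)
}
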