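#' Construct a gene panel
#'
#' A panel is a versioned set of genes addressing one broad clinical theme
#' (Vision, Neurology, ...). Patients are routed to exactly one panel from
#' their most prominent primary clinical feature; the optional `feature_map`
#' names the subset of panel genes most relevant to each feature and is used
#' by [rank_candidates()].
#'
#' @param panel_id Short identifier, e.g. `"vision"`.
#' @param name Human-readable clinical theme; defaults to `panel_id`.
#' @param genes A data.frame with at least a `gene_symbol` column; optional
#'   `transcript_id`, `n_exons`, `chrom`, `start`, `end` (1-based inclusive
#'   target intervals).
#' @param feature_map Named list mapping a clinical-feature label to a
#'   character vector of gene symbols; every symbol must belong to the panel.
#' @param version Monotone integer version, incremented by [spike_in()].
#' @return An object of class `panel`.
#' @seealso [panel_set()], [spike_in()], [assign_panel()]
#' @export
panel <- function(panel_id, name = panel_id, genes, feature_map = list(),
                  version = 1L) {
  if (is.character(genes)) {
    genes <- data.frame(gene_symbol = genes, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(genes), "gene_symbol" %in% names(genes))
  if (nrow(genes) == 0L) stop("a panel must contain at least one gene")
  if (any(!nzchar(genes$gene_symbol)) || anyNA(genes$gene_symbol))
    stop("gene symbols must be non-empty")
  if (all(c("start", "end") %in% names(genes))) {
    ok <- is.na(genes$start) | is.na(genes$end) | genes$start <= genes$end
    if (!all(ok)) stop("gene target intervals must satisfy start <= end")
  }
  version <- as.integer(version)
  if (version < 1L) stop("panel version must be >= 1")
  symbols <- unique(genes$gene_symbol)
  for (feat in names(feature_map)) {
    extra <- setdiff(feature_map[[feat]], symbols)
    if (length(extra) > 0L)
      stop("feature '", feat, "' maps to genes outside the panel: ",
           paste(extra, collapse = ", "))
  }
  structure(
    list(panel_id = as.character(panel_id), name = as.character(name),
         genes = genes, feature_map = feature_map, version = version),
    class = "panel"
  )
}

#' @export
print.panel <- function(x, ...) {
  cat(sprintf("<panel> %s ('%s') v%d: %d genes, %d mapped features\n",
              x$panel_id, x$name, x$version,
              length(panel_genes(x)), length(x$feature_map)))
  invisible(x)
}

#' Gene symbols of a panel
#' @param p A [panel()].
#' @return Character vector of distinct gene symbols.
#' @export
panel_genes <- function(p) unique(p$genes$gene_symbol)

#' Bundle panels into a registry
#'
#' @param panels List of [panel()] objects with distinct `panel_id`s.
#' @return An object of class `panel_set`, a named list of panels.
#' @export
panel_set <- function(panels = list()) {
  stopifnot(is.list(panels))
  ids <- vapply(panels, function(p) p$panel_id, character(1))
  if (anyDuplicated(ids)) stop("panel ids must be unique")
  names(panels) <- ids
  structure(panels, class = "panel_set")
}

#' @export
print.panel_set <- function(x, ...) {
  cat(sprintf("<panel_set> %d panels, %d distinct genes\n",
              length(x), length(unique(unlist(lapply(x, panel_genes))))))
  for (p in x) print(p)
  invisible(x)
}

# Soft sanity range for production panel sizes; synthetic mini-panels are
# legal, so this is only reported by validate_panel_sizes(), never enforced.
PANEL_SIZE_RANGE <- c(96L, 758L)

#' Report panels outside the expected production size range
#'
#' Production symptom-based panels run from roughly 96 to 758 genes; a panel
#' outside that range is often a data-entry problem. This is a soft check:
#' it returns messages rather than failing, so deliberately small test
#' panels remain usable.
#'
#' @param ps A [panel_set()].
#' @return Character vector of warnings (empty when all sizes are plausible).
#' @export
validate_panel_sizes <- function(ps) {
  msgs <- character()
  for (p in ps) {
    n <- length(panel_genes(p))
    if (n < PANEL_SIZE_RANGE[1] || n > PANEL_SIZE_RANGE[2])
      msgs <- c(msgs, sprintf(
        "panel '%s' has %d genes, outside the typical %d-%d range",
        p$panel_id, n, PANEL_SIZE_RANGE[1], PANEL_SIZE_RANGE[2]))
  }
  msgs
}

#' Load a panel catalog from TSV
#'
#' The catalog has one row per (gene, panel) assignment with columns `gene`,
#' `panel`, `transcript` and optionally `chrom`, `start`, `end` (1-based
#' inclusive). A gene listed under several panels appears in each
#' (cross-panel redundancy is an intentional design property, see
#' [redundancy_fraction()]). Duplicate (gene, panel) rows are deduplicated
#' with a warning.
#'
#' @param path Path to the TSV catalog.
#' @return A [panel_set()].
#' @export
load_panels <- function(path) {
  if (!file.exists(path)) stop("panel catalog not found: ", path)
  cat <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("gene", "panel", "transcript")
  missing <- setdiff(required, names(cat))
  if (length(missing) > 0L)
    stop("panel catalog lacks required columns: ",
         paste(missing, collapse = ", "))
  if (nrow(cat) == 0L) {
    warning("panel catalog is empty; returning an empty panel set")
    return(panel_set())
  }
  dup <- duplicated(cat[, c("gene", "panel")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (gene, panel) row(s) deduplicated")
    cat <- cat[!dup, , drop = FALSE]
  }
  panels <- lapply(split(cat, cat$panel), function(rows) {
    genes <- data.frame(gene_symbol = rows$gene,
                        transcript_id = rows$transcript,
                        stringsAsFactors = FALSE)
    if (all(c("chrom", "start", "end") %in% names(rows))) {
      genes$chrom <- rows$chrom
      genes$start <- as.integer(rows$start)
      genes$end <- as.integer(rows$end)
    }
    panel(panel_id = rows$panel[1], genes = genes)
  })
  panel_set(unname(panels))
}

#' Fraction of genes shared between panels
#'
#' Cross-panel redundancy: the number of distinct gene symbols present in at
#' least two panels divided by the number of distinct gene symbols in the
#' registry. The denominator choice (gene-weighted, over distinct genes) is
#' this package's definition; panel-pair-weighted alternatives exist and
#' would give different numbers.
#'
#' @param ps A non-empty [panel_set()].
#' @return A fraction in `[0, 1]`.
#' @export
redundancy_fraction <- function(ps) {
  if (length(ps) == 0L) stop("redundancy is undefined for an empty panel set")
  membership <- table(unlist(lapply(ps, panel_genes)))
  sum(membership >= 2L) / length(membership)
}

#' Route a primary clinical feature to its panel
#'
#' Each patient is assigned exactly one panel from the most prominent
#' primary clinical feature. Routing consults an explicit feature-to-panel
#' table (see [load_routing()] and the packaged default) and falls back to
#' the panels' own `feature_map`s. A feature resolvable to two panels is an
#' error the caller must disambiguate; an unknown feature raises an error
#' listing the closest known labels.
#'
#' @param ps A [panel_set()].
#' @param primary_feature Clinical-feature label (case-insensitive).
#' @param routing Named character vector `feature -> panel_id`; defaults to
#'   the routing table shipped with the package.
#' @return The matching [panel()].
#' @export
assign_panel <- function(ps, primary_feature, routing = default_routing()) {
  stopifnot(length(primary_feature) == 1L, is.character(primary_feature))
  feat <- tolower(trimws(primary_feature))
  hits <- character()
  if (!is.null(routing) && feat %in% tolower(names(routing))) {
    hits <- unname(routing[match(feat, tolower(names(routing)))])
  } else {
    for (p in ps) {
      if (feat %in% tolower(names(p$feature_map)))
        hits <- c(hits, p$panel_id)
    }
  }
  hits <- intersect(unique(hits), names(ps))
  if (length(hits) == 0L) {
    known <- unique(c(names(routing),
                      unlist(lapply(ps, function(p) names(p$feature_map)))))
    if (length(known) > 0L) {
      d <- utils::adist(feat, tolower(known))
      nearest <- known[order(d)][seq_len(min(3L, length(known)))]
      stop("no panel routes feature '", primary_feature,
           "'; nearest known labels: ", paste(nearest, collapse = ", "))
    }
    stop("no panel routes feature '", primary_feature,
         "' and no routing labels are defined")
  }
  if (length(hits) > 1L)
    stop("feature '", primary_feature, "' is ambiguous between panels: ",
         paste(hits, collapse = ", "))
  ps[[hits]]
}

#' Load a feature-to-panel routing table from YAML
#'
#' The YAML file maps clinical-feature labels to panel ids, e.g.
#' `retinal dystrophy: vision`.
#'
#' @param path YAML file path.
#' @return Named character vector `feature -> panel_id`.
#' @export
load_routing <- function(path) {
  if (!file.exists(path)) stop("routing table not found: ", path)
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0L) return(stats::setNames(character(), character()))
  vapply(raw, as.character, character(1))
}

#' The routing table shipped with the package
#'
#' Pre-populated with the clinical-feature subgroup labels of the 13
#' production panels (cardiovascular, deafness, dermatology,
#' dysmorphology-dysplasia, endocrinology, gastroenterology, hematology,
#' inborn errors of metabolism, neurology, primary immunodeficiency,
#' pulmonology, renal, vision).
#'
#' @return Named character vector `feature -> panel_id`.
#' @export
default_routing <- function() {
  load_routing(system.file("extdata", "routing.yaml",
                           package = "paneltriage", mustWork = TRUE))
}

#' Spike additional genes into a panel
#'
#' Newly published disease genes are added to an existing panel without a
#' redesign; the returned panel carries the union gene set and an
#' incremented version. The input panel is never modified and genes are
#' never removed. Spiking only genes already present is a warning no-op.
#'
#' @param p A [panel()].
#' @param new_genes Character vector of symbols or a data.frame like
#'   `p$genes`.
#' @return A new [panel()].
#' @export
spike_in <- function(p, new_genes) {
  stopifnot(inherits(p, "panel"))
  if (is.character(new_genes)) {
    new_genes <- data.frame(gene_symbol = new_genes, stringsAsFactors = FALSE)
  }
  if (nrow(new_genes) == 0L) return(p)
  novel <- !new_genes$gene_symbol %in% panel_genes(p)
  if (!any(novel)) {
    warning("all spike-in genes already present in panel '", p$panel_id,
            "'; version unchanged")
    return(p)
  }
  add <- new_genes[novel, , drop = FALSE]
  for (nm in setdiff(names(p$genes), names(add))) add[[nm]] <- NA
  add <- add[, names(p$genes), drop = FALSE]
  panel(panel_id = p$panel_id, name = p$name,
        genes = rbind(p$genes, add),
        feature_map = p$feature_map, version = p$version + 1L)
}

#' Export panel target regions as BED
#'
#' Converts the in-memory 1-based inclusive intervals to BED's 0-based
#' half-open convention. Genes without coordinates are skipped.
#'
#' @param p A [panel()] whose `genes` carry `chrom`, `start`, `end`.
#' @param path Output BED path.
#' @return The path, invisibly.
#' @export
export_panel_bed <- function(p, path) {
  g <- p$genes
  if (!all(c("chrom", "start", "end") %in% names(g)))
    stop("panel '", p$panel_id, "' has no target coordinates")
  g <- g[!is.na(g$start) & !is.na(g$end), , drop = FALSE]
  bed <- data.frame(chrom = g$chrom, start = g$start - 1L, end = g$end,
                    name = g$gene_symbol, stringsAsFactors = FALSE)
  bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
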