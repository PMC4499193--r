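#' Functional consequence classes recognized by the cascade
#'
#' The annotation vocabulary used throughout the package. `intronic`, `utr`
#' and `synonymous` are considered unlikely to be functional and are dropped
#' by the first cascade stage under the default configuration; all other
#' classes (including canonical splice-site changes) are retained.
#'
#' @format Character vector of class labels.
#' @export
FUNCTIONAL_CLASSES <- c(
  "intronic", "utr", "synonymous", "missense", "nonsense", "frameshift",
  "nonframeshift_indel", "splice_site", "other_exonic"
)

#' @rdname FUNCTIONAL_CLASSES
#' @export
NONFUNCTIONAL_CLASSES <- c("intronic", "utr", "synonymous")

#' @rdname FUNCTIONAL_CLASSES
#' @export
LOF_CLASSES <- c("nonsense", "frameshift", "splice_site")

ZYGOSITY_LEVELS <- c("homozygous", "heterozygous", "hemizygous")

#' Construct a table of annotated small variants
#'
#' One row per called variant, carrying the annotations the filtration
#' cascade consumes: functional class, public minor allele frequency
#' (`NA` = unknown), in-house cohort occurrence count, Phred-like call
#' quality, zygosity, deleteriousness predictions, and a known-pathogenic
#' flag. Arguments are recycled as in [data.frame()].
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions.
#' @param ref,alt Reference / alternate allele strings (`ref != alt`).
#' @param gene Gene symbol, or `NA` when intergenic.
#' @param functional_class One of [FUNCTIONAL_CLASSES].
#' @param public_maf Public-database minor allele frequency in `[0, 1]`,
#'   `NA` when the variant is absent from public databases.
#' @param inhouse_occurrences Non-negative occurrence count in the in-house
#'   database (allele-dosage units by default; see [cascade_config()]).
#' @param quality Phred-like variant quality, `>= 0`.
#' @param zygosity `"homozygous"`, `"heterozygous"` or `"hemizygous"`.
#' @param sift,polyphen Prediction scores in `[0, 1]`, `NA` when absent.
#'   Low SIFT and high PolyPhen indicate predicted deleteriousness.
#' @param known_pathogenic Logical flag from a curated disease-mutation
#'   catalogue.
#' @return A `data.frame` with one row per variant.
#' @examples
#' variant_table("1", 100, "A", "G", gene = "PAX6",
#'               functional_class = "missense", public_maf = 0.001,
#'               quality = 120, zygosity = "homozygous")
#' @export
variant_table <- function(chrom, pos, ref, alt, gene = NA_character_,
                          functional_class, public_maf = NA_real_,
                          inhouse_occurrences = 0L, quality = 0,
                          zygosity = "heterozygous", sift = NA_real_,
                          polyphen = NA_real_, known_pathogenic = FALSE) {
  if (length(pos) == 0L || length(chrom) == 0L ||
      length(functional_class) == 0L)
    return(empty_variant_table())
  vs <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    gene = as.character(gene),
    functional_class = as.character(functional_class),
    public_maf = as.numeric(public_maf),
    inhouse_occurrences = as.integer(inhouse_occurrences),
    quality = as.numeric(quality), zygosity = as.character(zygosity),
    sift = as.numeric(sift), polyphen = as.numeric(polyphen),
    known_pathogenic = as.logical(known_pathogenic),
    stringsAsFactors = FALSE
  )
  validate_variants(vs)
}

# zero-row variant table with the full column set
empty_variant_table <- function() {
  validate_variants(data.frame(chrom = character(), pos = integer(),
                               ref = character(), alt = character(),
                               stringsAsFactors = FALSE))
}

#' Validate (and complete) an annotated variant table
#'
#' Checks the invariants of the variant representation and fills optional
#' annotation columns with their unknown/default values so tables read from
#' lean sources can flow through the cascade.
#'
#' @param vs A data.frame with at least `chrom`, `pos`, `ref`, `alt`.
#' @return The validated data.frame, invisibly unchanged apart from added
#'   default columns.
#' @export
validate_variants <- function(vs) {
  stopifnot(is.data.frame(vs))
  required <- c("chrom", "pos", "ref", "alt")
  missing <- setdiff(required, names(vs))
  if (length(missing) > 0L)
    stop("variant table is missing columns: ", paste(missing, collapse = ", "))
  defaults <- list(
    gene = NA_character_, functional_class = "other_exonic",
    public_maf = NA_real_, inhouse_occurrences = 0L, quality = 0,
    zygosity = "heterozygous", sift = NA_real_, polyphen = NA_real_,
    known_pathogenic = FALSE
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(vs)) vs[[nm]] <- rep(defaults[[nm]], nrow(vs))
  }
  if (nrow(vs) == 0L) return(vs)
  if (any(vs$pos < 1L)) stop("positions must be 1-based (>= 1)")
  if (any(vs$ref == vs$alt)) stop("ref and alt alleles must differ")
  bad_class <- setdiff(unique(vs$functional_class), FUNCTIONAL_CLASSES)
  if (length(bad_class) > 0L)
    stop("unknown functional class: ", paste(bad_class, collapse = ", "))
  maf <- vs$public_maf[!is.na(vs$public_maf)]
  if (any(maf < 0 | maf > 1)) stop("public_maf must lie in [0, 1]")
  if (any(vs$quality < 0)) stop("quality must be non-negative")
  bad_zyg <- setdiff(unique(vs$zygosity[!is.na(vs$zygosity)]), ZYGOSITY_LEVELS)
  if (length(bad_zyg) > 0L)
    stop("unknown zygosity: ", paste(bad_zyg, collapse = ", "))
  if (any(vs$inhouse_occurrences < 0L)) stop("occurrence counts must be >= 0")
  vs
}

#' Canonical string key for a variant
#'
#' `chrom:pos:ref:alt` on the left-normalized representation; the unit of
#' identity for the occurrence database.
#'
#' @param chrom,pos,ref,alt Variant coordinates and alleles (vectorized).
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Left-normalize indel representations
#'
#' Trims shared trailing bases, then shared leading bases (advancing the
#' position), so that equivalent indel spellings share one canonical key.
#' SNVs pass through unchanged.
#'
#' @param pos 1-based positions.
#' @param ref,alt Allele strings.
#' @return A data.frame with normalized `pos`, `ref`, `alt`.
#' @examples
#' normalize_alleles(100, "CTT", "CT")    # -> pos 100, CT > C
#' normalize_alleles(100, "ACGT", "AGGT") # -> pos 101, C > G
#' @export
normalize_alleles <- function(pos, ref, alt) {
  pos <- as.integer(pos); ref <- as.character(ref); alt <- as.character(alt)
  n <- length(pos)
  stopifnot(length(ref) == n, length(alt) == n)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    # trim common suffix while both alleles keep at least one base
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substring(r, nchar(r)) == substring(a, nchar(a))) {
      r <- substring(r, 1L, nchar(r) - 1L)
      a <- substring(a, 1L, nchar(a) - 1L)
    }
    # trim common prefix, advancing pos
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substring(r, 1L, 1L) == substring(a, 1L, 1L)) {
      r <- substring(r, 2L); a <- substring(a, 2L); p <- p + 1L
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  data.frame(pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
}
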