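#' Create an empty in-house occurrence database
#'
#' The occurrence database accumulates, over every sample ever processed,
#' how often each variant (keyed by its left-normalized
#' `chrom:pos:ref:alt`) has been seen: allele-dosage occurrences
#' (heterozygous and hemizygous genotypes add 1, homozygous adds 2),
#' distinct carrier samples, and homozygous carrier samples. The more
#' samples ingested, the stronger the cascade's cohort-frequency filter
#' becomes. The object is environment-backed: `ingest_sample()` updates it
#' in place and also returns it invisibly.
#'
#' @return An object of class `occurrence_db`.
#' @seealso [ingest_sample()], [db_maf()], [flag_common_pathogenic()]
#' @export
occurrence_db <- function() {
  meta <- new.env(parent = emptyenv())
  meta$n_samples <- 0L
  meta$sample_ids <- character()
  structure(list(counts = new.env(parent = emptyenv()), meta = meta),
            class = "occurrence_db")
}

#' @export
print.occurrence_db <- function(x, ...) {
  cat(sprintf("<occurrence_db> %d variants over %d samples\n",
              length(ls(x$counts)), x$meta$n_samples))
  invisible(x)
}

#' Number of samples ingested into a database
#' @param db An [occurrence_db()].
#' @return Integer sample count.
#' @export
db_n_samples <- function(db) db$meta$n_samples

#' Ingest one sample's variants into the occurrence database
#'
#' Increments the total sample count and, for every variant carried by the
#' sample, its allele-dosage count (het/hemi +1, hom +2), its carrier-sample
#' count, and its homozygous-carrier count. Each sample may be ingested only
#' once; a repeated `sample_id` is rejected to prevent double counting.
#' Ingestion order never changes the resulting counts.
#'
#' @param db An [occurrence_db()] (modified in place).
#' @param vs Variant table of the sample's calls.
#' @param sample_id Unique sample identifier.
#' @return `db`, invisibly.
#' @export
ingest_sample <- function(db, vs, sample_id) {
  stopifnot(inherits(db, "occurrence_db"), length(sample_id) == 1L)
  sample_id <- as.character(sample_id)
  if (sample_id %in% db$meta$sample_ids)
    stop("sample '", sample_id, "' has already been ingested")
  vs <- validate_variants(vs)
  keys <- variant_key(vs$chrom, vs$pos, vs$ref, vs$alt)
  if (anyDuplicated(keys))
    stop("sample '", sample_id, "' lists the same variant twice")
  dosage <- ifelse(vs$zygosity == "homozygous", 2L, 1L)
  hom <- as.integer(vs$zygosity == "homozygous")
  for (i in seq_along(keys)) {
    rec <- db$counts[[keys[i]]]
    if (is.null(rec)) {
      rec <- list(allele = 0L, samples = 0L, hom = 0L,
                  gene = vs$gene[i], class = vs$functional_class[i])
    }
    rec$allele <- rec$allele + dosage[i]
    rec$samples <- rec$samples + 1L
    rec$hom <- rec$hom + hom[i]
    db$counts[[keys[i]]] <- rec
  }
  db$meta$n_samples <- db$meta$n_samples + 1L
  db$meta$sample_ids <- c(db$meta$sample_ids, sample_id)
  invisible(db)
}

#' Look up occurrence counts for a variant table
#'
#' @param db An [occurrence_db()].
#' @param vs Variant table (or data.frame with `chrom`, `pos`, `ref`, `alt`).
#' @param unit `"allele"` for allele-dosage counts (default) or `"sample"`
#'   for distinct carrier samples.
#' @return Integer vector of counts, 0 for never-seen variants.
#' @export
db_occurrences <- function(db, vs, unit = c("allele", "sample")) {
  unit <- match.arg(unit)
  keys <- variant_key(vs$chrom, vs$pos, vs$ref, vs$alt)
  vapply(keys, function(k) {
    rec <- db$counts[[k]]
    if (is.null(rec)) 0L else as.integer(rec[[if (unit == "allele") "allele"
                                              else "samples"]])
  }, integer(1), USE.NAMES = FALSE)
}

#' In-house minor allele frequency of variants
#'
#' Allele-dosage occurrences divided by `2 * n_samples` under a diploid
#' assumption (the package does not ploidy-correct X-chromosome
#' frequencies; with mostly-autosomal panels the bias is negligible and the
#' convention is documented). Unseen variants have frequency 0.
#'
#' @param db A populated [occurrence_db()].
#' @param vs Variant table or data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @return Numeric vector of frequencies in `[0, 1]`.
#' @export
db_maf <- function(db, vs) {
  n <- db_n_samples(db)
  if (n == 0L) stop("frequency is undefined on an empty occurrence database")
  db_occurrences(db, vs, unit = "allele") / (2 * n)
}

#' Merge two occurrence databases
#'
#' Sums counts key-wise. The sample sets must be disjoint, otherwise
#' variants from shared samples would be double counted.
#'
#' @param a,b [occurrence_db()] objects.
#' @return A new merged [occurrence_db()].
#' @export
merge_occurrence_db <- function(a, b) {
  shared <- intersect(a$meta$sample_ids, b$meta$sample_ids)
  if (length(shared) > 0L)
    stop("databases share samples: ", paste(shared, collapse = ", "))
  out <- occurrence_db()
  for (src in list(a, b)) {
    for (k in ls(src$counts)) {
      rec <- src$counts[[k]]
      dst <- out$counts[[k]]
      if (is.null(dst)) {
        out$counts[[k]] <- rec
      } else {
        dst$allele <- dst$allele + rec$allele
        dst$samples <- dst$samples + rec$samples
        dst$hom <- dst$hom + rec$hom
        out$counts[[k]] <- dst
      }
    }
  }
  out$meta$n_samples <- a$meta$n_samples + b$meta$n_samples
  out$meta$sample_ids <- c(a$meta$sample_ids, b$meta$sample_ids)
  out
}

#' Flag known-pathogenic variants that are common in-house
#'
#' A catalogued disease-causing variant observed at high frequency in the
#' cohort — often in homozygous form through autozygosity — argues against
#' its purported pathogenicity. This reports every supplied pathogenic
#' variant with in-house MAF strictly above 1%, tiered at strictly above
#' 5%, and flags discordance with public databases when the external MAF
#' is known and below 1% (a cohort-specific common variant).
#'
#' @param db A populated [occurrence_db()].
#' @param pathogenic Data.frame of catalogued variants with `chrom`, `pos`,
#'   `ref`, `alt`.
#' @param external Optional data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `maf` carrying public-database frequencies.
#' @param maf_threshold,high_tier_threshold Strict lower bounds for
#'   inclusion and for the high tier; defaults 0.01 and 0.05.
#' @return Data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `inhouse_maf`, `external_maf`, `tier` (`"gt1pct"`/`"gt5pct"`),
#'   `discordant_with_external`.
#' @export
flag_common_pathogenic <- function(db, pathogenic, external = NULL,
                                   maf_threshold = 0.01,
                                   high_tier_threshold = 0.05) {
  stopifnot(is.data.frame(pathogenic), nrow(pathogenic) > 0L)
  maf <- db_maf(db, pathogenic)
  ext <- rep(NA_real_, nrow(pathogenic))
  if (!is.null(external) && nrow(external) > 0L) {
    idx <- match(variant_key(pathogenic$chrom, pathogenic$pos,
                             pathogenic$ref, pathogenic$alt),
                 variant_key(external$chrom, external$pos,
                             external$ref, external$alt))
    ext <- external$maf[idx]
  }
  keep <- maf > maf_threshold
  out <- data.frame(
    chrom = pathogenic$chrom[keep], pos = pathogenic$pos[keep],
    ref = pathogenic$ref[keep], alt = pathogenic$alt[keep],
    inhouse_maf = maf[keep], external_maf = ext[keep],
    tier = ifelse(maf[keep] > high_tier_threshold, "gt5pct", "gt1pct"),
    discordant_with_external = !is.na(ext[keep]) & ext[keep] < maf_threshold,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Genes whose loss-of-function variants are frequently homozygous
#'
#' A gene harboring an apparently inactivating variant (nonsense,
#' frameshift, canonical splice) in the homozygous state in a substantial
#' fraction of the cohort — carriers lacking the purported phenotype — has
#' its disease-gene listing challenged. Returns the genes with any
#' loss-of-function variant whose homozygous-carrier fraction exceeds the
#' cutoff.
#'
#' @param db A populated [occurrence_db()].
#' @param min_hom_fraction Strict lower bound on homozygous samples /
#'   total samples; default 0.01.
#' @param lof_classes Functional classes counted as inactivating.
#' @return Sorted character vector of gene symbols.
#' @export
homozygous_inactivating_challenge <- function(db, min_hom_fraction = 0.01,
                                              lof_classes = LOF_CLASSES) {
  n <- db_n_samples(db)
  if (n == 0L) return(character())
  genes <- character()
  for (k in ls(db$counts)) {
    rec <- db$counts[[k]]
    if (!is.na(rec$gene) && rec$class %in% lof_classes &&
        rec$hom / n > min_hom_fraction)
      genes <- c(genes, rec$gene)
  }
  sort(unique(genes))
}

#' Write an occurrence database as sorted TSV
#'
#' First line is a `#` metadata header carrying the schema version, the
#' sample count and the ingested sample ids (needed to preserve the
#' duplicate-ingestion guard across round-trips); then a column header and
#' one row per variant key, sorted, so files diff stably and merges are
#' reproducible.
#'
#' @param db An [occurrence_db()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_occurrence_db <- function(db, path) {
  keys <- sort(ls(db$counts))
  rows <- lapply(keys, function(k) {
    rec <- db$counts[[k]]
    parts <- strsplit(k, ":", fixed = TRUE)[[1]]
    data.frame(chrom = parts[1], pos = as.integer(parts[2]),
               ref = parts[3], alt = parts[4],
               allele_count = rec$allele, sample_count = rec$samples,
               hom_count = rec$hom,
               gene = rec$gene, functional_class = rec$class,
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), allele_count = integer(),
               sample_count = integer(), hom_count = integer(),
               gene = character(), functional_class = character())
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#occurrence_db\tschema=1\tn_samples=%d\tsamples=%s",
                     db$meta$n_samples,
                     paste(db$meta$sample_ids, collapse = ",")), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an occurrence database written by [write_occurrence_db()]
#'
#' @param path TSV path.
#' @return An [occurrence_db()].
#' @export
read_occurrence_db <- function(path) {
  if (!file.exists(path)) stop("occurrence database not found: ", path)
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#occurrence_db"))
    stop("not an occurrence database file: ", path)
  fields <- strsplit(header, "\t", fixed = TRUE)[[1]]
  get_field <- function(name) {
    hit <- grep(paste0("^", name, "="), fields, value = TRUE)
    if (length(hit) == 0L) stop("occurrence db header lacks ", name)
    sub(paste0("^", name, "="), "", hit[1])
  }
  db <- occurrence_db()
  db$meta$n_samples <- as.integer(get_field("n_samples"))
  samples <- get_field("samples")
  db$meta$sample_ids <- if (nzchar(samples))
    strsplit(samples, ",", fixed = TRUE)[[1]] else character()
  tab <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tab))) {
    k <- variant_key(tab$chrom[i], tab$pos[i], tab$ref[i], tab$alt[i])
    db$counts[[k]] <- list(allele = tab$allele_count[i],
                           samples = tab$sample_count[i],
                           hom = tab$hom_count[i],
                           gene = tab$gene[i],
                           class = tab$functional_class[i])
  }
  db
}
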