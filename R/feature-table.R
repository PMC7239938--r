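#' Construct a feature table
#'
#' A feature table is the central container of the pipeline: an integer
#' matrix of read counts with samples in rows and taxa (OTUs, genera, ...)
#' in columns, plus a ranked taxonomy for each taxon.
#'
#' @param counts Integer matrix, samples x taxa, with unique row and column
#'   names (sample ids and taxon ids).
#' @param taxonomy Optional data.frame with one row per taxon (rownames =
#'   taxon ids) and rank columns among `phylum`, `class`, `order`, `family`,
#'   `genus`. Missing ranks may be `NA`. When omitted, every taxon gets an
#'   all-`NA` lineage.
#' @return An object of class `feature_table`: a list with elements
#'   `counts` and `taxonomy`.
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 1L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("t1", "t2")))
#' ft <- feature_table(m)
#' @export
feature_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample ids as rownames and taxon ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  storage.mode(counts) <- "integer"
  taxonomy <- .normalize_taxonomy(taxonomy, colnames(counts))
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "feature_table")
}

.tax_ranks <- c("phylum", "class", "order", "family", "genus")

.normalize_taxonomy <- function(taxonomy, taxon_ids) {
  if (is.null(taxonomy)) {
    taxonomy <- as.data.frame(matrix(NA_character_, length(taxon_ids),
                                     length(.tax_ranks),
                                     dimnames = list(taxon_ids, .tax_ranks)))
    return(taxonomy)
  }
  taxonomy <- as.data.frame(taxonomy)
  missing <- setdiff(taxon_ids, rownames(taxonomy))
  if (length(missing))
    stop("taxonomy missing for taxa: ", paste(missing, collapse = ", "))
  for (r in setdiff(.tax_ranks, names(taxonomy))) taxonomy[[r]] <- NA_character_
  taxonomy <- taxonomy[taxon_ids, .tax_ranks, drop = FALSE]
  for (r in .tax_ranks) {
    taxonomy[[r]] <- as.character(taxonomy[[r]])
    taxonomy[[r]][!is.na(taxonomy[[r]]) & taxonomy[[r]] == ""] <- NA_character_
  }
  taxonomy
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$counts), "samples x", ncol(x$counts), "taxa\n")
  cat("total reads:", sum(x$counts),
      " median depth:", stats::median(rowSums(x$counts)), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

sample_ids <- function(x) rownames(x$counts)
taxon_ids <- function(x) colnames(x$counts)

#' Read a feature table from disk
#'
#' Two plain-text layouts are supported: `tsv` (dense; first column sample
#' id, remaining columns one per taxon) and `biom_triplet` (sparse; columns
#' `sample`, `taxon`, `count`, implicit zeros restored on read).
#'
#' @param path File path.
#' @param format `"tsv"` or `"biom_triplet"`.
#' @param taxonomy Optional path to a taxonomy TSV written by
#'   [write_taxonomy()] (columns: taxon id + semicolon-free rank columns).
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, format = c("tsv", "biom_triplet"),
                               taxonomy = NULL) {
  format <- match.arg(format)
  tax <- if (!is.null(taxonomy)) read_taxonomy(taxonomy) else NULL
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
      stop("duplicate sample id in ", path, ": ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- ids
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("sample", "taxon", "count")
    if (!all(need %in% names(df)))
      stop("triplet file must have columns sample, taxon, count")
    if (anyDuplicated(df[, c("sample", "taxon")]))
      stop("duplicate (sample, taxon) entry in ", path)
    s <- unique(df$sample); t <- unique(df$taxon)
    m <- matrix(0L, length(s), length(t), dimnames = list(s, t))
    m[cbind(match(df$sample, s), match(df$taxon, t))] <- df$count
  }
  if (any(m != round(m)))
    stop("non-integer count in ", path)
  feature_table(m, taxonomy = tax)
}

#' Write a feature table to disk
#'
#' @param table A [feature_table()] or [normalized_table()].
#' @param path Output path.
#' @param format `"tsv"` (dense) or `"biom_triplet"` (sparse triplets;
#'   zeros omitted). Normalized tables are always written dense.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path,
                                format = c("tsv", "biom_triplet")) {
  format <- match.arg(format)
  m <- if (inherits(table, "normalized_table")) table$values else table$counts
  if (format == "tsv" || inherits(table, "normalized_table")) {
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    idx <- which(m != 0, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    df <- data.frame(sample = rownames(m)[idx[, 1]],
                     taxon = colnames(m)[idx[, 2]],
                     count = m[idx])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write a taxonomy table
#'
#' Taxonomy TSVs have a `taxon_id` column followed by the rank columns
#' phylum, class, order, family, genus; empty cells mean unclassified.
#'
#' @param path File path.
#' @return `read_taxonomy`: a data.frame keyed by taxon id.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  rownames(df) <- df$taxon_id
  df$taxon_id <- NULL
  df
}

#' @rdname read_taxonomy
#' @param taxonomy Taxonomy data.frame (rownames = taxon ids).
#' @export
write_taxonomy <- function(taxonomy, path) {
  df <- data.frame(taxon_id = rownames(taxonomy), taxonomy,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Construct a normalized table
#'
#' Carries real-valued abundances derived from a [feature_table()] together
#' with the normalization that produced them.
#'
#' @param values Numeric matrix, samples x taxa.
#' @param normalization One of `"relative"`, `"css_log"`, `"rarefied"`.
#' @param taxonomy Taxonomy data.frame (see [feature_table()]).
#' @return An object of class `normalized_table`.
#' @export
normalized_table <- function(values,
                             normalization = c("relative", "css_log",
                                               "rarefied"),
                             taxonomy = NULL) {
  normalization <- match.arg(normalization)
  values <- as.matrix(values)
  if (any(values < 0)) stop("normalized values must be nonnegative")
  structure(list(values = values,
                 normalization = normalization,
                 taxonomy = .normalize_taxonomy(taxonomy, colnames(values))),
            class = "normalized_table")
}

#' @export
print.normalized_table <- function(x, ...) {
  cat("normalized_table (", x$normalization, "): ", nrow(x$values),
      " samples x ", ncol(x$values), " taxa\n", sep = "")
  invisible(x)
}

# Numeric abundance matrix from either table class.
abundance_matrix <- function(x) {
  if (inherits(x, "feature_table")) return(x$counts + 0)
  if (inherits(x, "normalized_table")) return(x$values)
  as.matrix(x)
}

#' Relative-abundance normalization
#'
#' Divides each sample's counts by its library size.
#'
#' @param table A [feature_table()].
#' @return A [normalized_table()] whose nonempty rows sum to 1.
#' @export
relative_abundance <- function(table) {
  m <- abundance_matrix(table)
  tot <- rowSums(m)
  out <- m / ifelse(tot > 0, tot, 1)
  normalized_table(out, "relative", taxonomy = table$taxonomy)
}
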