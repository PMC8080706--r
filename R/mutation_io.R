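#' Read a binary mutation matrix from TSV
#'
#' Expects one header row of identifiers, one leading identifier column, and
#' 0/1 body cells. The file may store genes in rows (the common convention
#' for mutation matrices) or samples in rows; either way the result is
#' normalized to the internal samples-by-genes orientation, preserving the
#' identifier order of the file.
#'
#' @param path path to a tab-separated file.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @return a [mutation_matrix()].
#' @export
read_matrix_tsv <- function(path, orientation = c("genes_in_rows",
                                                  "samples_in_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "")
  if (ncol(df) < 2) stop("matrix TSV needs an identifier column plus data columns",
                         call. = FALSE)
  row_ids <- df[[1]]
  col_ids <- colnames(df)[-1]
  if (anyDuplicated(row_ids)) {
    stop(sprintf("duplicate row identifier: %s",
                 row_ids[duplicated(row_ids)][1]), call. = FALSE)
  }
  if (anyDuplicated(col_ids)) {
    stop(sprintf("duplicate column identifier: %s",
                 col_ids[duplicated(col_ids)][1]), call. = FALSE)
  }
  body <- as.matrix(df[, -1, drop = FALSE])
  ok <- body %in% c("0", "1")
  if (!all(ok)) {
    i <- arrayInd(which(!ok)[1], dim(body))
    stop(sprintf("non-binary cell '%s' at row '%s', column '%s'",
                 body[i], row_ids[i[1]], col_ids[i[2]]), call. = FALSE)
  }
  vals <- matrix(as.integer(body), nrow(body), ncol(body),
                 dimnames = list(row_ids, col_ids))
  if (orientation == "genes_in_rows") vals <- t(vals)
  mutation_matrix(vals)
}

#' Write a mutation matrix to TSV
#'
#' @param X a [mutation_matrix()].
#' @param path output path.
#' @param orientation row convention for the file; see [read_matrix_tsv()].
#' @export
write_matrix_tsv <- function(X, path, orientation = c("genes_in_rows",
                                                      "samples_in_rows")) {
  orientation <- match.arg(orientation)
  out <- unclass(X)
  if (orientation == "genes_in_rows") out <- t(out)
  id_name <- if (orientation == "genes_in_rows") "gene" else "sample"
  df <- data.frame(rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default qualifying variant classifications for MAF binarization
#'
#' The nonsilent coding classes in cBioPortal-dialect MAF files. Used by
#' [maf_to_matrix()] when no explicit class filter is supplied; the choice is
#' configurable because binarization rules differ between studies.
#'
#' @return character vector of Variant_Classification values.
#' @export
default_qualifying_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
    "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins", "Splice_Site",
    "Translation_Start_Site", "Nonstop_Mutation")
}

#' Binarize a MAF file into a mutation matrix
#'
#' Each record whose `Variant_Classification` is in `qualifying_classes`
#' sets entry `(Tumor_Sample_Barcode, Hugo_Symbol)` to 1; everything else is
#' 0. Samples and genes are sorted lexicographically (C locale) so the
#' result is independent of record order.
#'
#' @param maf_path path to a tab-separated MAF file; lines starting with `#`
#'   are skipped.
#' @param qualifying_classes character vector of qualifying
#'   Variant_Classification values; defaults to [default_qualifying_classes()].
#' @return a [mutation_matrix()].
#' @export
maf_to_matrix <- function(maf_path,
                          qualifying_classes = default_qualifying_classes()) {
  if (length(qualifying_classes) == 0) {
    stop("qualifying_classes must be non-empty", call. = FALSE)
  }
  maf <- utils::read.delim(maf_path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE,
                           colClasses = "character", quote = "")
  required <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  missing <- setdiff(required, colnames(maf))
  if (length(missing) > 0) {
    stop(sprintf("MAF is missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  keep <- maf$Variant_Classification %in% qualifying_classes
  hits <- unique(maf[keep, c("Tumor_Sample_Barcode", "Hugo_Symbol")])
  samples <- sort(unique(maf$Tumor_Sample_Barcode), method = "radix")
  genes <- sort(unique(maf$Hugo_Symbol), method = "radix")
  vals <- matrix(0L, length(samples), length(genes),
                 dimnames = list(samples, genes))
  if (nrow(hits) > 0) {
    vals[cbind(hits$Tumor_Sample_Barcode, hits$Hugo_Symbol)] <- 1L
  }
  mutation_matrix(vals)
}

#' Read gene sets from a GMT file
#'
#' GMT is the MSigDB interchange format: each line holds a set name, a
#' description, and one or more member gene symbols, tab-separated.
#' Duplicate genes within a line are removed.
#'
#' @param gmt_path path to a GMT file.
#' @return a `gene_set_collection`: list with `sets` (named list of character
#'   vectors) and `descriptions` (named character vector).
#' @export
read_gene_sets <- function(gmt_path) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descriptions <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has %d field(s); need name, description and >= 1 gene",
                   i, length(fields)), call. = FALSE)
    }
    name <- fields[1]
    if (name %in% names(sets)) {
      stop(sprintf("duplicate gene-set name '%s' at GMT line %d", name, i),
           call. = FALSE)
    }
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      stop(sprintf("GMT line %d ('%s') has no genes", i, name), call. = FALSE)
    }
    sets[[name]] <- genes
    descriptions[[name]] <- fields[2]
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' Write gene sets to a GMT file
#'
#' @param collection a `gene_set_collection` as returned by
#'   [read_gene_sets()], or a named list of character vectors.
#' @param path output path.
#' @export
write_gene_sets <- function(collection, path) {
  if (inherits(collection, "gene_set_collection")) {
    sets <- collection$sets
    descriptions <- collection$descriptions
  } else {
    sets <- collection
    descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, %d distinct genes\n",
              length(x$sets), length(unique(unlist(x$sets)))))
  invisible(x)
}

#' Write a gene ranking to TSV
#'
#' Columns `gene`, `score`, `rank`, `subgroup`, one row per gene, in rank
#' order (descending score, ties by ascending gene symbol).
#'
#' @param ranking a `gene_ranking` from [rank_genes()].
#' @param path output path.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "gene_ranking"), nrow(ranking) > 0)
  out <- ranking[order(ranking$rank), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene ranking written by [write_ranking()]
#'
#' @param path path to a ranking TSV.
#' @return a `gene_ranking` data frame.
#' @export
read_ranking <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, quote = "",
                          colClasses = c(gene = "character"))
  required <- c("gene", "score", "rank", "subgroup")
  missing <- setdiff(required, colnames(df))
  if (length(missing) > 0) {
    stop(sprintf("ranking TSV is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  structure(df[required], class = c("gene_ranking", "data.frame"))
}
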