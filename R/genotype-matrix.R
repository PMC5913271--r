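#' Genotype matrix of unordered diploid calls
#'
#' A `genotype_matrix` is a samples x variants character matrix whose cells
#' hold unordered diploid genotype calls in the canonical form
#' `"allele1/allele2"` with the two alleles sorted lexicographically, or `NA`
#' for a missing call. Because calls are stored in canonical order,
#' heterozygote `A/G` and `G/A` are the same value and genotype comparison is
#' plain string equality. A per-variant metadata table (variant id,
#' chromosome, position, ref/alt alleles) travels with the matrix as the
#' `"variants"` attribute.
#'
#' @param calls Character matrix (samples in rows, variants in columns) of
#'   genotype strings `"X/Y"` (order irrelevant) or `NA` for missing.
#' @param variants Optional data frame of variant metadata with at least a
#'   `variant_id` column; defaults to the column names of `calls`. Optional
#'   columns: `chrom`, `pos`, `ref`, `alt` (comma-separated for multiple
#'   alternate alleles).
#' @param sample_ids Sample identifiers; default the row names of `calls`.
#'
#' @return An object of class `genotype_matrix`.
#' @examples
#' gm <- genotype_matrix(
#'   matrix(c("A/T", "A/A", "G/G", "G/G"), nrow = 2,
#'          dimnames = list(c("s1", "s2"), c("snp1", "snp2"))))
#' gm
#' @export
genotype_matrix <- function(calls, variants = NULL, sample_ids = rownames(calls)) {
  if (!is.matrix(calls) || !is.character(calls))
    stop("`calls` must be a character matrix")
  if (is.null(sample_ids))
    sample_ids <- paste0("sample", seq_len(nrow(calls)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(calls))
    stop("length of `sample_ids` (", length(sample_ids),
         ") does not match the number of rows (", nrow(calls), ")")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (is.null(variants)) {
    ids <- colnames(calls)
    if (is.null(ids)) ids <- paste0("var", seq_len(ncol(calls)))
    variants <- data.frame(variant_id = ids, stringsAsFactors = FALSE)
  }
  variants <- as.data.frame(variants)
  if (!"variant_id" %in% names(variants))
    stop("`variants` must have a `variant_id` column")
  variants$variant_id <- as.character(variants$variant_id)
  if (nrow(variants) != ncol(calls))
    stop("number of variant records (", nrow(variants),
         ") does not match the number of columns (", ncol(calls), ")")
  if (anyDuplicated(variants$variant_id))
    stop("duplicate variant IDs: ",
         paste(unique(variants$variant_id[duplicated(variants$variant_id)]),
               collapse = ", "))
  if (!is.null(variants$pos) && any(!is.na(variants$pos) & variants$pos < 1))
    stop("variant positions must be >= 1")
  calls <- canonicalize_calls(calls)
  dimnames(calls) <- list(sample_ids, variants$variant_id)
  structure(calls, variants = variants, class = "genotype_matrix")
}

# Sort the two alleles of every "X/Y" string so unordered comparison is
# string equality. Non-missing cells must contain exactly one "/".
# Genotype matrices hold millions of cells but only a handful of distinct
# strings, so all string work happens on the unique values.
canonicalize_calls <- function(calls) {
  v <- as.vector(calls)
  u <- unique(v)
  u <- u[!is.na(u)]
  if (length(u)) {
    nslash <- nchar(u) - nchar(gsub("/", "", u, fixed = TRUE))
    if (any(nslash != 1L)) {
      badv <- u[nslash != 1L][1L]
      bad <- match(badv, v)
      stop("malformed genotype ", dQuote(badv), " at row ",
           (bad - 1L) %% nrow(calls) + 1L, ", column ",
           (bad - 1L) %/% nrow(calls) + 1L,
           " (expected exactly two '/'-separated alleles)")
    }
    a1 <- sub("/.*$", "", u)
    a2 <- sub("^[^/]*/", "", u)
    if (any(a1 == "" | a2 == ""))
      stop("empty allele in a genotype call")
    canon <- ifelse(a2 < a1, paste0(a2, "/", a1), u)
    if (!identical(canon, u)) v <- canon[match(v, u)]
  }
  matrix(v, nrow = nrow(calls), ncol = ncol(calls), dimnames = dimnames(calls))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", nrow(x), " samples x ", ncol(x), " variants; ",
      sum(is.na(x)), " missing calls\n", sep = "")
  k <- min(nrow(x), 6L); m <- min(ncol(x), 8L)
  if (k > 0 && m > 0) print(unclass(x)[seq_len(k), seq_len(m), drop = FALSE])
  if (nrow(x) > k || ncol(x) > m) cat("...\n")
  invisible(x)
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  v <- attr(x, "variants")
  calls <- unclass(x)
  if (missing(i)) i <- seq_len(nrow(calls))
  if (missing(j)) j <- seq_len(ncol(calls))
  if (is.character(j)) j <- match(j, v$variant_id)
  sub <- calls[i, j, drop = FALSE]
  genotype_matrix(sub, variants = v[j, , drop = FALSE])
}

#' Variant metadata of a genotype matrix
#' @param x A `genotype_matrix`.
#' @return The variant metadata data frame (one row per variant).
#' @export
variant_info <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  attr(x, "variants")
}

#' Sample identifiers of a genotype matrix
#' @param x A `genotype_matrix`.
#' @return Character vector of sample IDs.
#' @export
sample_ids <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  rownames(x)
}

# split canonical calls into two allele matrices (a1 <= a2 lexicographically);
# string work on unique values only
split_alleles <- function(x) {
  v <- as.vector(unclass(x))
  u <- unique(v)
  ix <- match(v, u)
  u1 <- sub("/.*$", "", u)
  u2 <- sub("^[^/]*/", "", u)
  list(a1 = matrix(u1[ix], nrow = nrow(x), dimnames = dimnames(x)),
       a2 = matrix(u2[ix], nrow = nrow(x), dimnames = dimnames(x)))
}

#' Case/control phenotype table
#'
#' @param sample_id Character vector of sample identifiers.
#' @param status Character or factor with levels `control`/`case` (entries may
#'   also be `NA` for unknown status, e.g. PLINK `-9` coding).
#' @return A data frame of class `phenotype_table` with columns `sample_id`
#'   and `status` (factor, levels `control`, `case`).
#' @export
phenotype_table <- function(sample_id, status) {
  sample_id <- as.character(sample_id)
  status <- as.character(status)
  bad <- !is.na(status) & !status %in% c("case", "control")
  if (any(bad))
    stop("unknown status token(s): ",
         paste(unique(status[bad]), collapse = ", "))
  if (length(sample_id) != length(status))
    stop("`sample_id` and `status` lengths differ")
  dup <- duplicated(sample_id)
  if (any(dup)) {
    for (s in unique(sample_id[dup])) {
      st <- unique(status[sample_id == s])
      if (length(st) > 1L)
        stop("duplicate sample ID ", dQuote(s), " with conflicting status")
    }
    keep <- !dup
    sample_id <- sample_id[keep]; status <- status[keep]
  }
  structure(
    data.frame(sample_id = sample_id,
               status = factor(status, levels = c("control", "case")),
               stringsAsFactors = FALSE),
    class = c("phenotype_table", "data.frame"))
}
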