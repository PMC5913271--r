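#' Hamming distance between two genotype vectors
#'
#' Counts the positions at which two individuals' unordered diploid genotypes
#' differ. Genotypes compare as unordered allele pairs (`A/G` equals `G/A`)
#' and the comparison is all-or-nothing: sharing one allele still counts as
#' different (allele sharing is [ibs_distance()]'s job). Positions where
#' either call is missing contribute neither to the count nor to the
#' denominator.
#'
#' @param x,y Character vectors of genotype calls (`"X/Y"` or `NA`), aligned
#'   to the same ordered variant set; rows of a [genotype_matrix()] work
#'   directly.
#' @return Named numeric vector `c(count = , compared = )`: the number of
#'   differing positions and the number of jointly called positions.
#' @examples
#' gm <- table1_fixture()
#' hamming_distance(gm["X", ], gm["Y", ])  # count 7 of 8
#' @export
hamming_distance <- function(x, y) {
  xy <- align_pair(x, y)
  both <- !is.na(xy$x) & !is.na(xy$y)
  c(count = sum(xy$x[both] != xy$y[both]), compared = sum(both))
}

#' Normalized Hamming distance between two genotype vectors
#'
#' The Hamming count divided by the number of compared (jointly called)
#' positions; equals count/n when no data are missing.
#'
#' @inheritParams hamming_distance
#' @return Fraction in `[0, 1]`.
#' @export
normalized_hamming <- function(x, y) {
  h <- hamming_distance(x, y)
  if (h[["compared"]] == 0)
    stop("undefined distance: no jointly called positions")
  unname(h[["count"]] / h[["compared"]])
}

#' Identity-by-state allele-sharing distance between two genotype vectors
#'
#' Per jointly called site, the two unordered genotypes share 0, 1 or 2
#' alleles by state (counting multiplicity); the distance is
#' `1 - shared / (2 * compared)`, i.e. `1 - (IBS2 + 0.5 IBS1) / compared`.
#'
#' @inheritParams hamming_distance
#' @return Fraction in `[0, 1]`.
#' @export
ibs_distance <- function(x, y) {
  xy <- align_pair(x, y)
  both <- which(!is.na(xy$x) & !is.na(xy$y))
  if (length(both) == 0L)
    stop("undefined distance: no jointly called positions")
  p <- sub("/.*$", "", xy$x[both]); q <- sub("^[^/]*/", "", xy$x[both])
  r <- sub("/.*$", "", xy$y[both]); s <- sub("^[^/]*/", "", xy$y[both])
  hom <- p == q
  shared <- ifelse(hom, (p == r) + (p == s),
                   (p == r | p == s) + (q == r | q == s))
  1 - sum(shared) / (2 * length(both))
}

align_pair <- function(x, y) {
  x <- as.vector(canonicalize_calls(matrix(as.character(x), nrow = 1L)))
  y <- as.vector(canonicalize_calls(matrix(as.character(y), nrow = 1L)))
  if (length(x) != length(y))
    stop("genotype vectors have different lengths (", length(x), " vs ",
         length(y), ")")
  list(x = x, y = y)
}

#' Pairwise distance matrix between all samples
#'
#' Applies a genotype distance metric to every unordered pair of samples over
#' a chosen variant set, using a vectorized cross-product formulation (one
#' indicator matrix per observed genotype value) so cohorts of hundreds of
#' samples by tens of thousands of variants are handled in seconds. Missing
#' data are treated by pairwise-complete deletion; the per-pair count of
#' jointly called sites is kept alongside the distances.
#'
#' For the `ibs` metric, sites with more than two observed alleles are
#' excluded (with a message); `hamming` and `normalized_hamming` use all
#' selected sites.
#'
#' @param x A [genotype_matrix()].
#' @param variant_ids Optional subset of variant IDs (default: all variants).
#' @param metric `"hamming"` (count of differing genotypes),
#'   `"normalized_hamming"` (count / compared sites) or `"ibs"`
#'   (allele-sharing distance).
#' @param variant_set_label Label recorded on the result (e.g. `"rare"`).
#' @return An object of class `genotype_dist`: list with `values` (symmetric
#'   n x n matrix, zero diagonal), `compared` (per-pair jointly called site
#'   counts), `metric`, `variant_set_label`, `n_variants_used`, `sample_ids`.
#' @examples
#' d <- pairwise_distances(table1_fixture(), metric = "hamming")
#' as.matrix(d)
#' @export
pairwise_distances <- function(x, variant_ids = NULL,
                               metric = c("hamming", "normalized_hamming", "ibs"),
                               variant_set_label = "all") {
  stopifnot(inherits(x, "genotype_matrix"))
  metric <- match.arg(metric)
  if (!is.null(variant_ids)) {
    if (length(variant_ids) == 0L) stop("empty variant subset")
    missing_ids <- setdiff(as.character(variant_ids),
                           variant_info(x)$variant_id)
    if (is.character(variant_ids) && length(missing_ids))
      stop("unknown variant ID(s): ", paste(utils::head(missing_ids, 5), collapse = ", "))
    x <- x[, variant_ids]
  }
  if (ncol(x) == 0L) stop("empty variant subset")
  if (nrow(x) < 2L) stop("need at least 2 samples")
  G <- unclass(x)
  n <- nrow(G)

  if (metric == "ibs") {
    counts <- allele_count_matrix(x)
    n_obs <- colSums(counts > 0)
    bi <- n_obs <= 2L
    if (!all(bi))
      message(sum(!bi), " site(s) with >2 observed alleles excluded from IBS")
    if (!any(bi)) stop("no biallelic sites available for IBS")
    G <- G[, bi, drop = FALSE]
    counts <- counts[, bi, drop = FALSE]
    al <- split_alleles(x[, which(bi)])
    # dosage of the lexicographically last observed allele (0/1/2), NA missing
    top <- vapply(seq_len(ncol(counts)), function(j) {
      obs <- rownames(counts)[counts[, j] > 0]
      if (length(obs)) obs[length(obs)] else NA_character_
    }, character(1))
    topm <- matrix(top, nrow = nrow(G), ncol = ncol(G), byrow = TRUE)
    D <- (al$a1 == topm) + (al$a2 == topm)
    ind <- lapply(0:2, function(k) (!is.na(D) & D == k) * 1)
    cross <- function(a, b) { m <- tcrossprod(ind[[a + 1L]], ind[[b + 1L]]); m + t(m) }
    L1 <- cross(0, 1) + 2 * cross(0, 2) + cross(1, 2)
    compared <- tcrossprod((!is.na(D)) * 1)
    check_compared(compared)
    values <- L1 / (2 * compared)
    values[compared == 0] <- 0
    diag(values) <- 0
    n_used <- ncol(G)
  } else {
    called <- (!is.na(G)) * 1
    compared <- tcrossprod(called)
    u <- unique(G[!is.na(G)])
    matches <- matrix(0, n, n)
    for (g in u) {
      M <- (!is.na(G) & G == g) * 1
      matches <- matches + tcrossprod(M)
    }
    count <- compared - matches
    if (metric == "hamming") {
      values <- count
    } else {
      check_compared(compared)
      values <- count / compared
      values[compared == 0] <- 0
    }
    diag(values) <- 0
    n_used <- ncol(G)
  }
  dimnames(values) <- list(rownames(G), rownames(G))
  storage.mode(compared) <- "integer"
  dimnames(compared) <- dimnames(values)
  structure(list(values = values, compared = compared, metric = metric,
                 variant_set_label = variant_set_label,
                 n_variants_used = n_used, sample_ids = rownames(G)),
            class = "genotype_dist")
}

check_compared <- function(compared) {
  off <- compared[upper.tri(compared)]
  if (any(off == 0))
    stop("undefined distance: some sample pair has no jointly called positions")
  invisible(TRUE)
}

#' @export
print.genotype_dist <- function(x, ...) {
  cat("genotype_dist (", x$metric, "): ", length(x$sample_ids), " samples, ",
      x$n_variants_used, " variants (set: ", x$variant_set_label, ")\n", sep = "")
  k <- min(length(x$sample_ids), 6L)
  print(round(x$values[seq_len(k), seq_len(k), drop = FALSE], 4))
  if (length(x$sample_ids) > k) cat("...\n")
  invisible(x)
}

#' @export
as.matrix.genotype_dist <- function(x, ...) x$values

#' @export
as.dist.genotype_dist <- function(m, diag = FALSE, upper = FALSE)
  stats::as.dist(m$values, diag = diag, upper = upper)

#' Write a distance matrix to disk
#'
#' @param d A `genotype_dist` object.
#' @param path Output path.
#' @param format `"square"` (matrix with sample-ID header row/column) or
#'   `"long"` (columns `id1`, `id2`, `distance`, `compared`, one row per
#'   unordered pair). Both carry a metadata comment line and are re-readable
#'   with [read_distance_matrix()].
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path, format = c("square", "long")) {
  stopifnot(inherits(d, "genotype_dist"))
  format <- match.arg(format)
  meta <- paste0("#snpdist format=", format, " metric=", d$metric,
                 " variant_set=", d$variant_set_label,
                 " n_variants=", d$n_variants_used)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(meta, con)
  if (format == "square") {
    writeLines(paste(c("sample_id", d$sample_ids), collapse = "\t"), con)
    utils::write.table(d$values, con, sep = "\t", quote = FALSE,
                       col.names = FALSE, row.names = TRUE)
  } else {
    ut <- which(upper.tri(d$values), arr.ind = TRUE)
    df <- data.frame(id1 = d$sample_ids[ut[, 1L]], id2 = d$sample_ids[ut[, 2L]],
                     distance = d$values[ut], compared = d$compared[ut])
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix()]
#'
#' @param path Input path.
#' @return A `genotype_dist` object (the `compared` grid is `NA` for the
#'   square format, which does not store it).
#' @export
read_distance_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#snpdist")) stop("not a snpdist distance file: ", path)
  kv <- strsplit(strsplit(sub("^#snpdist ", "", first), " ")[[1L]], "=")
  meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  if (meta[["format"]] == "square") {
    tab <- utils::read.table(path, skip = 1L, header = TRUE, sep = "\t",
                             check.names = FALSE, row.names = 1L)
    values <- as.matrix(tab)
    ids <- rownames(values)
    compared <- matrix(NA_integer_, nrow(values), ncol(values),
                       dimnames = dimnames(values))
  } else {
    df <- utils::read.table(path, skip = 1L, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    ids <- unique(c(df$id1, df$id2))
    nn <- length(ids)
    values <- matrix(0, nn, nn, dimnames = list(ids, ids))
    compared <- matrix(NA_integer_, nn, nn, dimnames = list(ids, ids))
    i <- match(df$id1, ids); j <- match(df$id2, ids)
    values[cbind(i, j)] <- df$distance; values[cbind(j, i)] <- df$distance
    compared[cbind(i, j)] <- df$compared; compared[cbind(j, i)] <- df$compared
    diag(compared) <- NA_integer_
  }
  structure(list(values = values, compared = compared, metric = meta[["metric"]],
                 variant_set_label = meta[["variant_set"]],
                 n_variants_used = as.integer(meta[["n_variants"]]),
                 sample_ids = ids),
            class = "genotype_dist")
}
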