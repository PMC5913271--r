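#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a pairwise distance matrix into `k` Euclidean dimensions via the
#' eigendecomposition of the doubly centered squared-distance matrix
#' `B = -1/2 J D^2 J`. Coordinates are the top-`k` positive eigenvectors
#' scaled by the square roots of their eigenvalues, so column `c` has squared
#' norm equal to eigenvalue `c` and a Euclidean input is reproduced exactly.
#'
#' Determinism: columns are ordered by descending eigenvalue (index breaks
#' ties) and each column's sign is flipped so its entry of largest absolute
#' value is positive (first index wins ties). Negative eigenvalues — which
#' genotype Hamming matrices may produce, since they need not be Euclidean —
#' are never embedded: they are retained in the reported spectrum, and their
#' relative mass `sum(|negative|) / sum(|all|)` is reported, with a warning
#' when it is non-negligible. If fewer than `k` positive eigenvalues exist,
#' the achievable dimension is returned with a warning.
#'
#' @param d A `genotype_dist` object, a [stats::dist] object, or a symmetric
#'   numeric matrix of distances.
#' @param k Number of dimensions to retain (default 2, `1 <= k <= n - 1`).
#' @param input How to interpret the values in `d`. `"distance"` (default):
#'   ordinary distances, squared before double centering — the textbook
#'   Torgerson recipe that reproduces a Euclidean point cloud exactly.
#'   `"squared"`: the values are already squared Euclidean distances and are
#'   Gower-centered as they stand. Genotype mismatch counts are of the second
#'   kind — a Hamming count equals the squared Euclidean distance between
#'   one-hot genotype encodings, and allele-sharing (IBS) dissimilarities are
#'   likewise of negative type — so the analysis pipeline embeds them with
#'   `input = "squared"`, the same convention PLINK's IBS-MDS uses; see
#'   [hamming_analysis()].
#' @return Object of class `mds_embedding`: `points` (n x k coordinate
#'   matrix), `eig` (full descending eigenvalue spectrum), `k`,
#'   `negative_eigenvalue_mass`, `sample_ids`, plus the source `metric` and
#'   `variant_set_label` when available.
#' @examples
#' pts <- cbind(c(0, 3, 0), c(0, 0, 4))
#' fit <- classical_mds(dist(pts), k = 2)
#' dist(fit$points)  # 3, 4, 5 recovered
#' @export
classical_mds <- function(d, k = 2, input = c("distance", "squared")) {
  input <- match.arg(input)
  metric <- NULL; label <- NULL
  if (inherits(d, "genotype_dist")) {
    metric <- d$metric; label <- d$variant_set_label
    D <- d$values
  } else if (inherits(d, "dist")) {
    D <- as.matrix(d)
  } else {
    D <- as.matrix(d)
  }
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 samples")
  if (k < 1L) stop("k must be >= 1")
  if (k > n - 1L) stop("k must be <= n - 1")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  ids <- rownames(D)
  if (is.null(ids)) ids <- paste0("sample", seq_len(n))

  D2 <- if (input == "squared") D else D * D
  rm_ <- rowMeans(D2); gm <- mean(D2)
  B <- -0.5 * (D2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  ev <- e$values
  tol <- max(abs(ev), 0) * 1e-9
  npos <- sum(ev > tol)
  kept <- min(k, npos)
  if (kept < k)
    warning("only ", kept, " positive eigenvalue(s); returning a ", kept,
            "-dimensional embedding instead of ", k)
  if (kept == 0L) {
    pts <- matrix(0, n, 0L)
  } else {
    pts <- e$vectors[, seq_len(kept), drop = FALSE] %*%
      diag(sqrt(ev[seq_len(kept)]), kept)
    # sign convention: largest-|entry| of each column made positive
    for (c in seq_len(kept)) {
      j <- which.max(abs(pts[, c]))
      if (pts[j, c] < 0) pts[, c] <- -pts[, c]
    }
  }
  dimnames(pts) <- list(ids, if (kept) paste0("dim", seq_len(kept)))
  neg_mass <- if (sum(abs(ev)) > 0) sum(abs(ev[ev < -tol])) / sum(abs(ev)) else 0
  if (neg_mass > 0.01)
    warning(sprintf("non-Euclidean input: %.1f%% of eigenvalue mass is negative",
                    100 * neg_mass))
  structure(list(points = pts, eig = ev, k = kept,
                 negative_eigenvalue_mass = neg_mass,
                 sample_ids = ids, metric = metric, variant_set_label = label),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat("mds_embedding: ", length(x$sample_ids), " samples in ", x$k,
      " dimension(s)\n", sep = "")
  cat("  leading eigenvalues:",
      paste(signif(utils::head(x$eig, 5), 4), collapse = ", "), "\n")
  cat(sprintf("  negative eigenvalue mass: %.3g\n", x$negative_eigenvalue_mass))
  invisible(x)
}

#' Euclidean distances of the embedded coordinates
#'
#' @param r An `mds_embedding`.
#' @return A `genotype_dist`-like object of class `genotype_dist` with metric
#'   `"euclidean_embedding"`.
#' @export
reconstructed_distances <- function(r) {
  stopifnot(inherits(r, "mds_embedding"))
  values <- as.matrix(stats::dist(r$points))
  if (ncol(r$points) == 0L) values[] <- 0    # empty embedding: all points coincide
  dimnames(values) <- list(r$sample_ids, r$sample_ids)
  structure(list(values = values,
                 compared = matrix(NA_integer_, nrow(values), ncol(values),
                                   dimnames = dimnames(values)),
                 metric = "euclidean_embedding",
                 variant_set_label = r$variant_set_label %||% "custom",
                 n_variants_used = NA_integer_, sample_ids = r$sample_ids),
            class = "genotype_dist")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot an MDS embedding
#'
#' Scatter of the first two embedding dimensions, optionally coloured by
#' case/control status (cases blue, controls red, the conventional palette
#' for this plot family).
#'
#' @param x An `mds_embedding`.
#' @param phenotypes Optional [phenotype_table()].
#' @param dims Which two dimensions to draw (default `c(1, 2)`).
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mds_embedding <- function(x, phenotypes = NULL, dims = c(1, 2),
                               main = NULL, ...) {
  if (x$k < max(dims)) stop("embedding has only ", x$k, " dimension(s)")
  xy <- x$points[, dims, drop = FALSE]
  col <- rep("grey30", nrow(xy)); pch <- rep(1L, nrow(xy))
  if (!is.null(phenotypes)) {
    st <- phenotypes$status[match(x$sample_ids, phenotypes$sample_id)]
    col <- ifelse(is.na(st), "grey60", ifelse(st == "case", "blue", "red"))
    pch <- ifelse(is.na(st), 1L, ifelse(st == "case", 17L, 19L))
  }
  if (is.null(main))
    main <- paste0("MDS", if (!is.null(x$metric)) paste0(" (", x$metric,
                   if (!is.null(x$variant_set_label))
                     paste0(", ", x$variant_set_label), ")"))
  graphics::plot(xy[, 1L], xy[, 2L], col = col, pch = pch,
                 xlab = colnames(x$points)[dims[1L]],
                 ylab = colnames(x$points)[dims[2L]], main = main, ...)
  if (!is.null(phenotypes))
    graphics::legend("topright", legend = c("case", "control"),
                     col = c("blue", "red"), pch = c(17L, 19L), bty = "n")
  invisible(x)
}

#' Write MDS coordinates and eigenvalue spectrum
#'
#' @param r An `mds_embedding`.
#' @param coord_path Path for the coordinate table (`sample_id`,
#'   `dim1..dimk`).
#' @param eig_path Optional path for the one-column eigenvalue table.
#' @return `coord_path`, invisibly.
#' @export
write_mds <- function(r, coord_path, eig_path = NULL) {
  stopifnot(inherits(r, "mds_embedding"))
  df <- data.frame(sample_id = r$sample_ids, r$points, check.names = FALSE)
  utils::write.table(df, coord_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(eig_path))
    utils::write.table(data.frame(eigenvalue = r$eig), eig_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(coord_path)
}
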