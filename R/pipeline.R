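#' End-to-end case-control genotype-distance analysis
#'
#' The package's main fitting function. Runs the full workflow on a genotype
#' matrix and case/control labels: sample alignment, variant QC, MAF
#' classification, then — for each requested variant class — a pairwise
#' distance matrix, a classical MDS embedding and a two-sample Hotelling's
#' T-squared test of case-control mean separation in the leading MDS
#' dimensions. Deterministic given its inputs.
#'
#' Sample handling: only the intersection of genotype samples and phenotyped
#' samples (with known status) is analysed; mismatches are reported, never
#' silently dropped. A requested class with zero QC-passing variants is
#' skipped with a warning; a class where the separation test cannot run
#' (e.g. fewer than two cases) keeps its distances and embedding, with the
#' error recorded in place of the test.
#'
#' Because up to four classes are tested per run, the summary reports raw
#' P-values together with a Bonferroni-adjusted column (factor = number of
#' classes analysed).
#'
#' @param genotypes A [genotype_matrix()].
#' @param phenotypes A [phenotype_table()], or `NULL` to skip the separation
#'   tests (QC's Hardy-Weinberg filter then uses all samples).
#' @param classes Variant classes to analyse; subset of
#'   `c("all", "common", "low_frequency", "rare")` (default all four).
#' @param metric Distance metric, as in [pairwise_distances()].
#' @param k MDS dimensions to retain (default 2).
#' @param dims Leading MDS dimensions entering the separation test
#'   (default 2, the MDS plane; must be `<= k`).
#' @param thresholds A [qc_thresholds()] object.
#' @param mds_input Passed to [classical_mds()]. The default `"squared"`
#'   Gower-centers the genotype dissimilarities as they stand — the faithful
#'   treatment, since a Hamming count is exactly the squared Euclidean
#'   distance between one-hot genotype encodings (and the convention PLINK's
#'   IBS-MDS uses); `"distance"` applies the distance-squaring textbook
#'   recipe instead.
#' @return Object of class `hamming_analysis` with elements `qc` (the
#'   [apply_qc()] result), `classes` (per-class list: `n_variants`,
#'   `distances`, `mds`, `hotelling` — a `hotelling_test` or an error
#'   condition), `metric`, `k`, `dims`, `phenotypes`, `n_cases`,
#'   `n_controls`. Methods: `print`, `summary`, `plot`.
#' @examples
#' sim <- simulate_cohort(n_cases = 30, n_controls = 30, n_common = 80,
#'                        n_low_freq = 80, n_rare = 200,
#'                        affected_fraction = c(rare = 0.3), seed = 7)
#' fit <- hamming_analysis(sim$genotypes, sim$phenotypes,
#'                         classes = c("common", "rare"))
#' summary(fit)
#' @export
hamming_analysis <- function(genotypes, phenotypes = NULL,
                             classes = c("all", "common", "low_frequency", "rare"),
                             metric = c("hamming", "normalized_hamming", "ibs"),
                             k = 2, dims = 2,
                             thresholds = qc_thresholds(),
                             mds_input = c("squared", "distance")) {
  mds_input <- match.arg(mds_input)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  metric <- match.arg(metric)
  bad <- setdiff(classes, c("all", "common", "low_frequency", "rare"))
  if (length(bad)) stop("unknown variant class(es): ", paste(bad, collapse = ", "))
  if (dims > k) stop("`dims` cannot exceed the retained MDS dimension `k`")

  n_cases <- n_controls <- 0L
  if (!is.null(phenotypes)) {
    known <- phenotypes[!is.na(phenotypes$status), , drop = FALSE]
    keep <- intersect(rownames(genotypes), known$sample_id)
    if (length(keep) == 0L)
      stop("no overlap between genotype samples and phenotype table")
    n_geno_only <- nrow(genotypes) - length(keep)
    n_pheno_only <- nrow(known) - length(keep)
    if (n_geno_only || n_pheno_only)
      message("sample alignment: ", length(keep), " analysed; ", n_geno_only,
              " genotyped-only and ", n_pheno_only,
              " phenotyped-only sample(s) dropped")
    genotypes <- genotypes[keep, ]
    st <- known$status[match(keep, known$sample_id)]
    n_cases <- sum(st == "case"); n_controls <- sum(st == "control")
  }
  if (nrow(genotypes) < 2L) stop("need at least 2 analysable samples")

  qc <- apply_qc(genotypes, phenotypes, thresholds)
  sets <- variant_classes(qc)
  results <- list()
  for (cl in classes) {
    ids <- sets[[cl]]
    if (length(ids) == 0L) {
      warning("class ", dQuote(cl), " has no QC-passing variants; skipped")
      next
    }
    d <- pairwise_distances(qc$genotypes, ids, metric = metric,
                            variant_set_label = cl)
    mds <- classical_mds(d, k = min(k, length(d$sample_ids) - 1L),
                         input = mds_input)
    ht <- if (is.null(phenotypes)) NULL else
      tryCatch(separation_report(mds, phenotypes, dims = min(dims, mds$k)),
               error = function(e) e)
    results[[cl]] <- list(n_variants = length(ids), distances = d,
                          mds = mds, hotelling = ht)
  }
  structure(list(qc = qc, classes = results, metric = metric, k = k,
                 dims = dims, phenotypes = phenotypes,
                 n_cases = n_cases, n_controls = n_controls),
            class = "hamming_analysis")
}

#' @export
summary.hamming_analysis <- function(object, ...) {
  cls <- names(object$classes)
  m <- length(cls)
  rows <- lapply(cls, function(cl) {
    r <- object$classes[[cl]]
    ht <- r$hotelling
    ok <- inherits(ht, "hotelling_test")
    data.frame(class = cl, n_variants = r$n_variants,
               n_cases = if (ok) ht$n1 else NA_integer_,
               n_controls = if (ok) ht$n2 else NA_integer_,
               t2 = if (ok) ht$t2 else NA_real_,
               f_stat = if (ok) ht$f_stat else NA_real_,
               df1 = if (ok) ht$df1 else NA_integer_,
               df2 = if (ok) ht$df2 else NA_integer_,
               p_value = if (ok) ht$p_value else NA_real_,
               note = if (ok) "" else if (is.null(ht)) "no phenotypes" else
                 conditionMessage(ht),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_value * m)
  structure(out, class = c("summary.hamming_analysis", "data.frame"),
            metric = object$metric)
}

#' @export
print.summary.hamming_analysis <- function(x, ...) {
  cat("Case-control separation by variant class (metric: ",
      attr(x, "metric"), ")\n", sep = "")
  df <- as.data.frame(x)
  df$t2 <- signif(df$t2, 5); df$f_stat <- signif(df$f_stat, 5)
  df$p_print <- ifelse(is.na(df$p_value), NA,
                       ifelse(df$p_value < 2.2e-16, "< 2.2e-16",
                              signif(df$p_value, 4)))
  print(df[, c("class", "n_variants", "t2", "p_print", "p_bonferroni", "note")],
        row.names = FALSE)
  invisible(x)
}

#' @export
print.hamming_analysis <- function(x, ...) {
  cat("hamming_analysis: ", x$n_cases, " cases + ", x$n_controls,
      " controls; ", sum(x$qc$classification$qc_pass), " QC-passing variants\n",
      sep = "")
  print(summary(x))
  invisible(x)
}

#' @export
plot.hamming_analysis <- function(x, classes = names(x$classes), ...) {
  m <- length(classes)
  if (m == 0L) stop("nothing to plot")
  op <- graphics::par(mfrow = grDevices::n2mfrow(m))
  on.exit(graphics::par(op))
  for (cl in classes)
    plot(x$classes[[cl]]$mds, phenotypes = x$phenotypes,
         main = paste0(cl, " (", x$classes[[cl]]$n_variants, " variants)"), ...)
  invisible(x)
}

#' IBS-based population-stratification check
#'
#' Runs the same load -> QC -> per-class distance -> MDS flow with the
#' identity-by-state metric, the conventional screen for ancestry structure
#' before a case-control distance analysis, and flags outlying samples in
#' each class's MDS plane: a sample is flagged when, in either of the first
#' two dimensions, it lies more than `mad_multiplier` scaled median absolute
#' deviations from the coordinate-wise median. Flagging is reporting-only;
#' exclusion (if wanted) is the caller's decision via `exclude`.
#'
#' @inheritParams hamming_analysis
#' @param mad_multiplier Outlier threshold in MAD units (default 6).
#' @param exclude If `TRUE`, re-run the flow once with the flagged samples
#'   (union over classes) removed and return that second fit in `$refit`.
#' @return Object of class `stratification_check`: the underlying
#'   `hamming_analysis` (IBS metric) plus `outliers` (named list of flagged
#'   sample IDs per class) and optionally `refit`.
#' @export
stratification_check <- function(genotypes, phenotypes = NULL,
                                 classes = c("all", "common", "low_frequency", "rare"),
                                 k = 2, dims = 2, thresholds = qc_thresholds(),
                                 mad_multiplier = 6, exclude = FALSE) {
  fit <- hamming_analysis(genotypes, phenotypes, classes = classes,
                          metric = "ibs", k = k, dims = dims,
                          thresholds = thresholds)
  outliers <- lapply(fit$classes, function(r) {
    pts <- r$mds$points[, seq_len(min(2L, r$mds$k)), drop = FALSE]
    flagged <- rep(FALSE, nrow(pts))
    for (c in seq_len(ncol(pts))) {
      med <- stats::median(pts[, c]); md <- stats::mad(pts[, c])
      if (md > 0) flagged <- flagged | abs(pts[, c] - med) > mad_multiplier * md
    }
    r$mds$sample_ids[flagged]
  })
  out <- list(fit = fit, outliers = outliers, mad_multiplier = mad_multiplier)
  if (exclude) {
    drop <- unique(unlist(outliers))
    if (length(drop)) {
      keep <- setdiff(rownames(genotypes), drop)
      out$refit <- hamming_analysis(genotypes[keep, ], phenotypes,
                                    classes = classes, metric = "ibs", k = k,
                                    dims = dims, thresholds = thresholds)
    }
  }
  structure(out, class = "stratification_check")
}

#' @export
print.stratification_check <- function(x, ...) {
  cat("IBS stratification check (outlier threshold: ", x$mad_multiplier,
      " MADs)\n", sep = "")
  for (cl in names(x$outliers)) {
    o <- x$outliers[[cl]]
    cat("  ", cl, ": ", if (length(o)) paste(o, collapse = ", ") else
      "no outliers", "\n", sep = "")
  }
  print(summary(x$fit))
  invisible(x)
}

#' Write the per-class artifacts and consolidated report of a fit
#'
#' Writes, per analysed class, the distance matrix (long format), MDS
#' coordinates and eigenvalue spectrum, plus a consolidated tab-delimited
#' summary (`report.tsv`) and a human-readable `report.txt`.
#'
#' @param x A `hamming_analysis` (or `stratification_check`) object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  if (inherits(x, "stratification_check")) x <- x$fit
  stopifnot(inherits(x, "hamming_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cl in names(x$classes)) {
    r <- x$classes[[cl]]
    write_distance_matrix(r$distances,
                          file.path(dir, paste0("distance_", cl, ".tsv")),
                          format = "long")
    write_mds(r$mds, file.path(dir, paste0("mds_", cl, ".tsv")),
              file.path(dir, paste0("eigenvalues_", cl, ".tsv")))
  }
  s <- summary(x)
  utils::write.table(as.data.frame(s), file.path(dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  con <- file(file.path(dir, "report.txt"), "w")
  sink(con); on.exit({ sink(); close(con) })
  print(x)
  invisible(dir)
}
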