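#' Quality-control thresholds and MAF class boundaries
#'
#' Container of the tunable cutoffs used by [apply_qc()] and
#' [classify_by_maf()]. The MAF class boundaries follow the standard
#' definitions: common means MAF >= 5%, low-frequency means
#' 0.5% <= MAF < 5%, rare means MAF < 0.5%.
#'
#' @param min_call_rate Minimum per-variant call rate (default 0.95).
#' @param hwe_alpha Significance level below which the Hardy-Weinberg exact
#'   P-value fails a variant (default 1e-6).
#' @param hwe_sample_set Compute HWE on `"controls_only"` (default, requires
#'   a phenotype table; avoids discarding true association signal) or on
#'   `"all"` samples.
#' @param low_freq_bound Rare/low-frequency MAF boundary (default 0.005).
#' @param common_bound Low-frequency/common MAF boundary (default 0.05).
#' @param drop_monomorphic Remove monomorphic variants? Default `FALSE`:
#'   they are retained and classified rare (they contribute zero to every
#'   Hamming distance, so inclusion is harmless and keeps counts
#'   reconcilable).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.95, hwe_alpha = 1e-6,
                          hwe_sample_set = c("controls_only", "all"),
                          low_freq_bound = 0.005, common_bound = 0.05,
                          drop_monomorphic = FALSE) {
  hwe_sample_set <- match.arg(hwe_sample_set)
  stopifnot(min_call_rate >= 0, min_call_rate <= 1, hwe_alpha > 0, hwe_alpha <= 1)
  if (!(low_freq_bound > 0 && low_freq_bound < common_bound && common_bound < 0.5))
    stop("need 0 < low_freq_bound < common_bound < 0.5")
  structure(list(min_call_rate = min_call_rate, hwe_alpha = hwe_alpha,
                 hwe_sample_set = hwe_sample_set,
                 low_freq_bound = low_freq_bound, common_bound = common_bound,
                 drop_monomorphic = drop_monomorphic),
            class = "qc_thresholds")
}

# allele counts per variant: levels x variants integer matrix
allele_count_matrix <- function(x) {
  al <- split_alleles(x)
  av <- c(as.vector(al$a1), as.vector(al$a2))
  f <- factor(av)
  L <- nlevels(f)
  nv <- ncol(x); n <- nrow(x)
  if (L == 0L) return(matrix(0L, 0L, nv, dimnames = list(NULL, colnames(x))))
  cidx <- rep(rep.int(seq_len(nv), rep.int(n, nv)), times = 2L)
  li <- as.integer(f)
  keep <- !is.na(li)
  cnt <- tabulate((cidx[keep] - 1L) * L + li[keep], nbins = nv * L)
  matrix(cnt, nrow = L, dimnames = list(levels(f), colnames(x)))
}

col_max <- function(m) if (nrow(m)) do.call(pmax, lapply(seq_len(nrow(m)), function(i) m[i, ])) else numeric(ncol(m))

# minor allele count: smallest positive count, 0 if <=1 allele observed
minor_count <- function(counts) {
  n_obs <- colSums(counts > 0)
  tmp <- counts
  tmp[tmp == 0] <- Inf
  mc <- if (nrow(tmp)) do.call(pmin, lapply(seq_len(nrow(tmp)), function(i) tmp[i, ])) else rep(Inf, ncol(tmp))
  ifelse(n_obs <= 1L, 0, mc)
}

maf_from_counts <- function(counts) {
  called <- colSums(counts)
  ifelse(called == 0, NA_real_, minor_count(counts) / pmax(called, 1))
}

#' Minor allele frequency per variant
#'
#' Counts each non-missing sample's two alleles (cases and controls pooled)
#' and returns, per variant, the smallest observed allele frequency — the MAF
#' for a biallelic site, 0 for a monomorphic one. Invariant under ref/alt
#' relabeling.
#'
#' @param x A [genotype_matrix()].
#' @param variants Optional variant IDs (or indices) to restrict to.
#' @return Named numeric vector of MAFs in `[0, 0.5]`.
#' @export
compute_maf <- function(x, variants = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (!is.null(variants)) x <- x[, variants]
  counts <- allele_count_matrix(x)
  maf <- maf_from_counts(counts)
  if (anyNA(maf))
    stop("MAF undefined (all calls missing) for variant(s): ",
         paste(colnames(x)[is.na(maf)], collapse = ", "))
  names(maf) <- colnames(x)
  maf
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact HWE test: conditional on the observed allele counts, all
#' heterozygote counts of matching parity are enumerated and the
#' probabilities of every outcome no more probable than the observed table
#' are summed. Probabilities are accumulated in log space, so large genotype
#' counts are handled stably.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (vectors recycle to common length).
#' @return P-value(s) in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  n <- max(length(n_AA), length(n_Aa), length(n_aa))
  n_AA <- rep_len(n_AA, n); n_Aa <- rep_len(n_Aa, n); n_aa <- rep_len(n_aa, n)
  if (any(n_AA < 0 | n_Aa < 0 | n_aa < 0)) stop("genotype counts must be nonnegative")
  if (any(n_AA + n_Aa + n_aa < 1)) stop("need at least one genotyped sample")
  vapply(seq_len(n), function(i) hwe_exact_one(n_AA[i], n_Aa[i], n_aa[i]), numeric(1))
}

hwe_exact_one <- function(nAA, nAa, naa) {
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  n1 <- min(nA, na)
  hs <- seq.int(n1 %% 2L, n1, by = 2L)
  if (length(hs) == 1L) return(1)
  # log P(h+2) - log P(h) = log(4 * nAA(h) * naa(h)) - log((h+2)(h+1))
  h <- hs[-length(hs)]
  steps <- log(4) + log((nA - h) / 2) + log((na - h) / 2) - log(h + 2) - log(h + 1)
  logp <- c(0, cumsum(steps))
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  p_obs <- p[match(nAa, hs)]
  min(1, sum(p[p <= p_obs * (1 + 1e-10)]))
}

#' Classify variants by minor allele frequency
#'
#' Applies the three-band classification: rare (MAF < `low_freq_bound`),
#' low-frequency (`low_freq_bound` <= MAF < `common_bound`) and common
#' (MAF >= `common_bound`). Boundaries follow the inclusive-common convention
#' (MAF exactly 5% is common; exactly 0.5% is low-frequency).
#'
#' @param maf Numeric vector of MAFs in `[0, 0.5]` (`NA` allowed, returns `NA`).
#' @param thresholds A [qc_thresholds()] object supplying the two boundaries.
#' @return Factor with levels `rare`, `low_frequency`, `common`.
#' @export
classify_by_maf <- function(maf, thresholds = qc_thresholds()) {
  if (any(maf < 0 | maf > 0.5, na.rm = TRUE)) stop("MAF must lie in [0, 0.5]")
  cls <- ifelse(is.na(maf), NA_character_,
                ifelse(maf >= thresholds$common_bound, "common",
                       ifelse(maf >= thresholds$low_freq_bound, "low_frequency", "rare")))
  factor(cls, levels = c("rare", "low_frequency", "common"))
}

#' Apply the variant quality-control pipeline
#'
#' Filters a genotype matrix on variant call rate, allele number (biallelic
#' only) and Hardy-Weinberg exact-test deviation, and classifies every
#' variant into the rare / low-frequency / common MAF bands. Every removal is
#' recorded with its reason; surviving variant order is preserved, and the
#' operation is idempotent.
#'
#' @param x A [genotype_matrix()].
#' @param phenotypes Optional [phenotype_table()]; needed when
#'   `thresholds$hwe_sample_set == "controls_only"` (falls back to all
#'   samples, with a message, when no controls are available).
#' @param thresholds A [qc_thresholds()] object.
#' @return A list of class `variant_qc` with elements `genotypes` (the
#'   filtered matrix), `classification` (data frame: `variant_id`, `maf`,
#'   `n_called_alleles`, `class`, `hwe_p`, `qc_pass`, `fail_reasons`) and
#'   `thresholds`.
#' @export
apply_qc <- function(x, phenotypes = NULL, thresholds = qc_thresholds()) {
  stopifnot(inherits(x, "genotype_matrix"), inherits(thresholds, "qc_thresholds"))
  if (ncol(x) == 0L || nrow(x) == 0L) stop("empty genotype matrix")
  n <- nrow(x)
  counts <- allele_count_matrix(x)
  called_alleles <- colSums(counts)
  call_rate <- (called_alleles / 2) / n
  n_obs_alleles <- colSums(counts > 0)
  maf <- maf_from_counts(counts)

  # HWE sample set
  hx <- x
  if (thresholds$hwe_sample_set == "controls_only") {
    if (is.null(phenotypes)) {
      message("no phenotype table supplied; computing HWE on all samples")
    } else {
      ctrl <- phenotypes$sample_id[!is.na(phenotypes$status) &
                                     phenotypes$status == "control"]
      ctrl <- intersect(rownames(x), ctrl)
      if (length(ctrl) >= 1L) hx <- x[ctrl, ] else
        message("no control samples found; computing HWE on all samples")
    }
  }
  hwe_p <- rep(NA_real_, ncol(x))
  eligible <- which(n_obs_alleles >= 1L & n_obs_alleles <= 2L)
  if (length(eligible)) {
    hcounts <- allele_count_matrix(hx[, eligible])
    hal <- split_alleles(hx[, eligible])
    het <- colSums(hal$a1 != hal$a2, na.rm = TRUE)
    hcalled <- colSums(hcounts) / 2          # genotyped samples
    mc <- minor_count(hcounts)
    hom_minor <- (mc - het) / 2
    hom_major <- hcalled - het - hom_minor
    ok <- hcalled >= 1
    hwe_p[eligible[ok]] <- hwe_exact_test(hom_major[ok], het[ok], hom_minor[ok])
  }

  reasons <- lapply(seq_len(ncol(x)), function(j) {
    r <- character(0)
    if (call_rate[j] < thresholds$min_call_rate) r <- c(r, "call_rate")
    if (n_obs_alleles[j] > 2L) r <- c(r, "multiallelic")
    if (!is.na(hwe_p[j]) && hwe_p[j] < thresholds$hwe_alpha) r <- c(r, "hwe")
    if (thresholds$drop_monomorphic && n_obs_alleles[j] <= 1L)
      r <- c(r, "monomorphic")
    r
  })
  qc_pass <- lengths(reasons) == 0L
  classification <- data.frame(
    variant_id = colnames(x),
    maf = maf,
    n_called_alleles = as.integer(called_alleles),
    class = classify_by_maf(maf, thresholds),
    hwe_p = hwe_p,
    qc_pass = qc_pass,
    fail_reasons = vapply(reasons, paste, "", collapse = ","),
    row.names = NULL, stringsAsFactors = FALSE)
  n_mono <- sum(n_obs_alleles <= 1L & qc_pass)
  if (n_mono > 0L)
    message(n_mono, " monomorphic variant(s) retained and classified rare")
  structure(list(genotypes = x[, qc_pass],
                 classification = classification,
                 thresholds = thresholds),
            class = "variant_qc")
}

#' @export
print.variant_qc <- function(x, ...) {
  cl <- x$classification
  cat("variant_qc: ", sum(cl$qc_pass), " of ", nrow(cl), " variants pass QC\n",
      sep = "")
  if (any(!cl$qc_pass)) {
    tab <- table(unlist(strsplit(cl$fail_reasons[!cl$qc_pass], ",", fixed = TRUE)))
    cat("  removals:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  tab <- table(cl$class[cl$qc_pass])
  cat("  MAF classes (passing): ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Variant-ID sets per MAF class
#'
#' @param qc A `variant_qc` object from [apply_qc()].
#' @return Named list of QC-passing variant-ID vectors: `all`, `common`,
#'   `low_frequency`, `rare`. The last three partition `all`.
#' @export
variant_classes <- function(qc) {
  stopifnot(inherits(qc, "variant_qc"))
  cl <- qc$classification[qc$classification$qc_pass, ]
  list(all = cl$variant_id,
       common = cl$variant_id[cl$class == "common"],
       low_frequency = cl$variant_id[cl$class == "low_frequency"],
       rare = cl$variant_id[cl$class == "rare"])
}

#' Write the per-variant QC/classification report
#'
#' @param qc A `variant_qc` object.
#' @param path Output path for the tab-delimited report.
#' @return `path`, invisibly.
#' @export
write_classification <- function(qc, path) {
  stopifnot(inherits(qc, "variant_qc"))
  utils::write.table(qc$classification, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
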