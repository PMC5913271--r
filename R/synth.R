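#' Simulate a case-control genotype cohort
#'
#' Generates a diploid cohort with three MAF-defined variant classes and an
#' optional planted case-control allele-frequency divergence concentrated in
#' chosen classes — the qualitative signature of a disorder driven by rare
#' variation. For every variant a control allele frequency is drawn uniformly
#' from its class's range; with probability `affected_fraction[class]` the
#' case frequency is the control frequency multiplied by `effect_size`
#' (capped at 1), otherwise the two are equal. Each individual's genotype is
#' two independent allele draws at their group's frequency (Hardy-Weinberg
#' within group, no linkage disequilibrium), and each call is independently
#' set missing with probability `missing_rate`. Fully reproducible from
#' `seed`.
#'
#' Defaults describe the reference validation cohort used throughout the
#' package: 200 cases and 200 controls over 2,000 common, 2,000 low-frequency
#' and 5,000 rare variants, with the frequency shift planted only in rare
#' variants.
#'
#' @param n_cases,n_controls Group sizes.
#' @param n_common,n_low_freq,n_rare Variant counts per MAF class.
#' @param common_range,low_freq_range,rare_range Control allele-frequency
#'   ranges per class (each inside its classification band).
#' @param affected_fraction Named fractions (names `common`, `low_frequency`,
#'   `rare`) of each class's variants carrying a case-control shift; a scalar
#'   recycles to all three classes.
#' @param effect_size Multiplicative risk-allele frequency factor in cases.
#' @param missing_rate Per-call missing probability.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `synthetic_cohort`: `genotypes` (a
#'   [genotype_matrix()]), `phenotypes` (a [phenotype_table()]) and `truth`
#'   (data frame of planted per-variant frequencies and effect flags).
#' @examples
#' sim <- simulate_cohort(n_cases = 20, n_controls = 20, n_common = 50,
#'                        n_low_freq = 50, n_rare = 100, seed = 1)
#' sim$genotypes
#' @export
simulate_cohort <- function(n_cases = 200, n_controls = 200,
                            n_common = 2000, n_low_freq = 2000, n_rare = 5000,
                            common_range = c(0.05, 0.5),
                            low_freq_range = c(0.005, 0.05),
                            rare_range = c(0.0005, 0.005),
                            affected_fraction = c(common = 0, low_frequency = 0,
                                                  rare = 0.2),
                            effect_size = 3, missing_rate = 0, seed = NULL) {
  stopifnot(n_cases >= 0, n_controls >= 0, n_common >= 0, n_low_freq >= 0,
            n_rare >= 0, effect_size > 0, missing_rate >= 0, missing_rate <= 1)
  n <- n_cases + n_controls
  if (n == 0L) stop("zero samples requested")
  if (length(affected_fraction) == 1L && is.null(names(affected_fraction)))
    affected_fraction <- c(common = affected_fraction,
                           low_frequency = affected_fraction,
                           rare = affected_fraction)
  af <- c(common = 0, low_frequency = 0, rare = 0)
  af[names(affected_fraction)] <- affected_fraction
  if (any(af < 0 | af > 1)) stop("affected_fraction must lie in [0, 1]")
  check_range <- function(r, lo, hi, what) {
    if (r[1L] < lo || r[2L] > hi || r[1L] > r[2L])
      stop(what, " frequency range must lie inside [", lo, ", ", hi, "]")
  }
  check_range(common_range, 0.05, 0.5, "common")
  check_range(low_freq_range, 0.005, 0.05, "low-frequency")
  check_range(rare_range, 0, 0.005, "rare")
  if (!is.null(seed)) set.seed(seed)

  cls <- rep(c("common", "low_frequency", "rare"),
             times = c(n_common, n_low_freq, n_rare))
  nv <- length(cls)
  if (nv == 0L) stop("zero variants requested")
  vid <- paste0(c(common = "cv", low_frequency = "lf", rare = "rv")[cls],
                stats::ave(seq_len(nv), cls, FUN = seq_along))
  ranges <- list(common = common_range, low_frequency = low_freq_range,
                 rare = rare_range)
  p_ctrl <- numeric(nv)
  for (cl in names(ranges)) {
    idx <- cls == cl
    p_ctrl[idx] <- stats::runif(sum(idx), ranges[[cl]][1L], ranges[[cl]][2L])
  }
  affected <- stats::runif(nv) < af[cls]
  p_case <- ifelse(affected, pmin(p_ctrl * effect_size, 1), p_ctrl)

  # random ref/alt letters; alt carries the simulated (risk) allele frequency
  pairs <- t(vapply(seq_len(nv), function(i) sample(c("A", "C", "G", "T"), 2L),
                    character(2)))
  ref <- pairs[, 1L]; alt <- pairs[, 2L]
  geno_str <- rbind(paste0(ref, "/", ref),
                    paste0(pmin(ref, alt), "/", pmax(ref, alt)),
                    paste0(alt, "/", alt))

  draw <- function(ng, p) {
    if (ng == 0L) return(matrix(0L, 0L, nv))
    matrix(stats::rbinom(ng * nv, 2L, rep(p, each = ng)), nrow = ng)
  }
  D <- rbind(draw(n_cases, p_case), draw(n_controls, p_ctrl))
  calls <- matrix(geno_str[cbind(as.vector(D) + 1L, rep(seq_len(nv), each = n))],
                  nrow = n)
  if (missing_rate > 0)
    calls[stats::runif(length(calls)) < missing_rate] <- NA_character_
  ids <- c(sprintf("case_%03d", seq_len(n_cases)),
           sprintf("control_%03d", seq_len(n_controls)))
  status <- rep(c("case", "control"), c(n_cases, n_controls))
  variants <- data.frame(variant_id = vid, chrom = "1", pos = seq_len(nv),
                         ref = ref, alt = alt, stringsAsFactors = FALSE)
  truth <- data.frame(variant_id = vid, class = cls, ref = ref, alt = alt,
                      control_freq = p_ctrl, case_freq = p_case,
                      affected = affected, stringsAsFactors = FALSE)
  structure(list(genotypes = genotype_matrix(calls, variants = variants,
                                             sample_ids = ids),
                 phenotypes = phenotype_table(ids, status),
                 truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort: ", sum(x$phenotypes$status == "case"), " cases + ",
      sum(x$phenotypes$status == "control"), " controls, ",
      nrow(x$truth), " variants (", sum(x$truth$affected),
      " with planted effects)\n", sep = "")
  invisible(x)
}

#' The three-subject, eight-SNP worked-example genotype matrix
#'
#' Returns the small reference matrix used throughout the documentation:
#' subjects X, Y and Z genotyped at eight SNPs, where the Hamming distances
#' are H(X,Y) = 7, H(Y,Z) = 3 and H(X,Z) = 5.
#'
#' @return A 3 x 8 [genotype_matrix()] with no missing calls.
#' @examples
#' pairwise_distances(table1_fixture(), metric = "hamming")
#' @export
table1_fixture <- function() {
  calls <- rbind(
    X = c("A/T", "G/G", "C/G", "C/C", "C/C", "A/G", "A/C", "T/T"),
    Y = c("A/A", "G/G", "C/C", "T/T", "C/T", "G/G", "C/C", "C/T"),
    Z = c("A/A", "G/G", "C/C", "C/C", "C/T", "A/A", "C/C", "T/T"))
  variants <- data.frame(
    variant_id = paste0("SNP", 1:8),
    ref = c("A", "G", "C", "C", "C", "A", "A", "C"),
    alt = c("T", "T", "G", "T", "T", "G", "C", "T"),
    stringsAsFactors = FALSE)
  genotype_matrix(calls, variants = variants)
}
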