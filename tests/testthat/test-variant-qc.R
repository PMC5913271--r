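test_that("MAF counts pooled alleles and is relabeling-invariant", {
  gm <- table1_fixture()
  maf <- compute_maf(gm)
  # SNP1: X={A,T}, Y={A,A}, Z={A,A} -> A x5, T x1
  expect_equal(unname(maf["SNP1"]), 1 / 6)
  # SNP2 is monomorphic G
  expect_equal(unname(maf["SNP2"]), 0)
  expect_true(all(maf >= 0 & maf <= 0.5))

  # 50 samples with known allele counts 37 alt / 63 ref
  calls <- matrix(c(rep("A/A", 26), rep("A/G", 11), rep("G/G", 13)), ncol = 1)
  rownames(calls) <- sprintf("s%02d", 1:50); colnames(calls) <- "v1"
  expect_equal(unname(compute_maf(genotype_matrix(calls))), 0.37)

  # swapping allele labels leaves the MAF unchanged (min over frequencies)
  swapped <- chartr("AG", "GA", calls)
  expect_equal(compute_maf(genotype_matrix(swapped)),
               compute_maf(genotype_matrix(calls)))

  # all-missing variant is an error
  calls2 <- cbind(calls, v2 = NA_character_)
  expect_error(compute_maf(genotype_matrix(calls2)), "all calls missing")
})

test_that("HWE exact test matches full enumeration on small tables", {
  # the observed table is the most probable of the two attainable ones
  expect_equal(hwe_exact_test(0, 2, 0), 1)
  # a single attainable outcome
  expect_equal(hwe_exact_test(1, 0, 0), 1)
  # classic mid-size table against the independent enumeration oracle
  expect_equal(hwe_exact_test(25, 50, 25), hwe_enum_oracle(25, 50, 25),
               tolerance = 1e-12)
  # extreme het deficit is essentially impossible under HWE
  expect_lt(hwe_exact_test(100, 0, 100), 1e-6)
  expect_error(hwe_exact_test(-1, 2, 0), "nonnegative")
})

test_that("HWE exact test agrees with enumeration across a table grid", {
  for (n in c(2, 5, 17, 30)) {
    for (nA in 0:n) {
      hs <- seq.int(min(nA, 2 * n - nA) %% 2L, min(nA, 2 * n - nA), by = 2L)
      for (h in hs) {
        nAA <- (nA - h) / 2
        naa <- n - nAA - h
        expect_equal(hwe_exact_test(nAA, h, naa), hwe_enum_oracle(nAA, h, naa),
                     tolerance = 1e-12,
                     label = sprintf("table (%d,%d,%d)", nAA, h, naa))
      }
    }
  }
})

test_that("MAF class boundaries follow the inclusive-common convention", {
  th <- qc_thresholds()
  expect_equal(as.character(classify_by_maf(0.05, th)), "common")
  expect_equal(as.character(classify_by_maf(0.005, th)), "low_frequency")
  expect_equal(as.character(classify_by_maf(0.004999, th)), "rare")
  expect_equal(as.character(classify_by_maf(0, th)), "rare")
  expect_equal(as.character(classify_by_maf(0.5, th)), "common")
  # the three classes partition any MAF vector
  set.seed(1)
  m <- runif(1000, 0, 0.5)
  expect_equal(sum(table(classify_by_maf(m, th))), 1000L)
  expect_error(classify_by_maf(0.7, th), "0, 0.5")
})

test_that("QC removes variants by call rate, allele count and HWE", {
  gm <- rand_genotype_matrix(10, 5, seed = 21)
  calls <- unclass(gm)
  calls[1:4, 2] <- NA                               # call rate 0.6
  calls[1:3, 3] <- c("A/A", "A/C", "A/T")           # 3 observed alleles
  gm <- genotype_matrix(calls, variants = variant_info(gm))
  qc <- suppressMessages(apply_qc(gm, thresholds = qc_thresholds()))
  cl <- qc$classification
  expect_false(cl$qc_pass[2])
  expect_match(cl$fail_reasons[2], "call_rate")
  expect_false(cl$qc_pass[3])
  expect_match(cl$fail_reasons[3], "multiallelic")
  expect_equal(variant_info(qc$genotypes)$variant_id,
               cl$variant_id[cl$qc_pass])

  # (100, 0, 100) genotype counts fail HWE far below 1e-6
  hwe_calls <- matrix(c(rep("A/A", 100), rep("G/G", 100)), ncol = 1,
                      dimnames = list(sprintf("s%03d", 1:200), "vh"))
  qc2 <- suppressMessages(apply_qc(genotype_matrix(hwe_calls)))
  expect_match(qc2$classification$fail_reasons, "hwe")
  expect_lt(qc2$classification$hwe_p, 1e-6)
  expect_equal(ncol(qc2$genotypes), 0L)
})

test_that("controls-only HWE uses only control samples", {
  # het-deficit concentrated in cases: controls are in perfect HWE
  calls <- matrix(c(rep("A/A", 50), rep("G/G", 50),         # cases
                    rep("A/A", 25), rep("A/G", 50), rep("G/G", 25)), ncol = 1,
                  dimnames = list(sprintf("s%03d", 1:200), "v1"))
  gm <- genotype_matrix(calls)
  ph <- phenotype_table(rownames(calls),
                        rep(c("case", "control"), each = 100))
  qc_ctrl <- suppressMessages(apply_qc(gm, ph, qc_thresholds()))
  expect_true(qc_ctrl$classification$qc_pass)
  qc_all <- suppressMessages(
    apply_qc(gm, ph, qc_thresholds(hwe_sample_set = "all")))
  expect_false(qc_all$classification$qc_pass)
})

test_that("QC is idempotent and monomorphic variants classify rare", {
  gm <- rand_genotype_matrix(30, 40, maf = c(0.01, 0.5), missing_rate = 0.03,
                             seed = 5)
  calls <- unclass(gm)
  calls[, 1] <- "C/C"
  gm <- genotype_matrix(calls, variants = variant_info(gm))
  qc1 <- suppressMessages(apply_qc(gm))
  qc2 <- suppressMessages(apply_qc(qc1$genotypes))
  expect_identical(unclass(qc2$genotypes), unclass(qc1$genotypes))
  expect_true(all(qc2$classification$qc_pass))
  cl1 <- qc1$classification
  expect_true(cl1$qc_pass[1])
  expect_equal(as.character(cl1$class[1]), "rare")
  # partition invariant
  expect_equal(sum(lengths(variant_classes(qc1)[c("common", "low_frequency",
                                                  "rare")])),
               sum(cl1$qc_pass))
})
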