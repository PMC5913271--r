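test_that("the worked-example genotype table reads into a 3 x 8 matrix", {
  path <- write_table1_file(tempfile(fileext = ".tsv"))
  gm <- read_genotype_table(path)
  expect_s3_class(gm, "genotype_matrix")
  expect_equal(dim(gm), c(3L, 8L))
  expect_equal(sample_ids(gm), c("X", "Y", "Z"))
  expect_equal(variant_info(gm)$variant_id, paste0("SNP", 1:8))
  expect_equal(unclass(gm)["X", "SNP1"], "A/T")
  expect_equal(sum(is.na(gm)), 0L)
  # allele annotations from the header land in the variant metadata
  expect_equal(variant_info(gm)$ref[1], "A")
  expect_equal(variant_info(gm)$alt[1], "T")
})

test_that("an empty data section yields 0 samples under a valid header", {
  path <- tempfile(fileext = ".tsv")
  writeLines(paste(c("id", paste0("SNP", 1:8)), collapse = "\t"), path)
  gm <- read_genotype_table(path)
  expect_equal(dim(gm), c(0L, 8L))
})

test_that("malformed genotypes are rejected with the offending cell named", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("id\tSNP1\tSNP2", "X\tAZ\tGG"), path)
  expect_error(read_genotype_table(path), "AZ.*X.*SNP1|invalid allele")
  writeLines(c("id\tSNP1\tSNP2", "X\tATT\tGG"), path)
  expect_error(read_genotype_table(path), "two allele characters")
  writeLines(c("id\tSNP1", "X\tAA", "X\tAT"), path)
  expect_error(read_genotype_table(path), "duplicate sample")
  writeLines(c("id\tSNP1\tSNP1", "X\tAA\tAT"), path)
  expect_error(read_genotype_table(path), "duplicate variant")
})

test_that("genotype comparison is order-insensitive and missing tokens work", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("id\tSNP1\tSNP2", "X\tTA\tNN", "Y\tAT\t./."), path)
  gm <- read_genotype_table(path)
  expect_equal(unclass(gm)["X", "SNP1"], unclass(gm)["Y", "SNP1"])
  expect_true(all(is.na(unclass(gm)[, "SNP2"])))
  # configurable missing token
  writeLines(c("id\tSNP1", "X\t00"), path)
  gm2 <- read_genotype_table(path, missing = "00")
  expect_true(is.na(unclass(gm2)[1, 1]))
})

test_that("genotype tables round-trip through write/read", {
  gm <- rand_genotype_matrix(12, 30, missing_rate = 0.1, seed = 11)
  path <- tempfile(fileext = ".tsv")
  write_genotype_table(gm, path)
  back <- read_genotype_table(path)
  expect_identical(unclass(back), unclass(gm))
  expect_identical(variant_info(back)$ref, variant_info(gm)$ref)
})

test_that("VCF genotypes resolve GT indices, phase and half-calls", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1\t1|0",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t./.\t0/.",
    "1\t300\trs3\tG\tA,T\t.\tPASS\t.\tGT\t1/2\t0/0",
    "1\t400\t.\tT\tTA\t.\tPASS\t.\tGT\t0/1\t1/1"), path)
  gm <- read_vcf(path)
  expect_equal(dim(gm), c(2L, 4L))
  # phased and unphased heterozygotes are the same unordered call
  expect_equal(unclass(gm)["s1", "rs1"], "A/G")
  expect_equal(unclass(gm)["s2", "rs1"], "A/G")
  # ./. and half-calls are missing
  expect_true(all(is.na(unclass(gm)[, "rs2"])))
  # multiallelic sites are retained at this stage
  expect_equal(unclass(gm)["s1", "rs3"], "A/T")
  # indel alleles and chrom:pos fallback IDs
  expect_equal(unclass(gm)["s1", "1:400"], "T/TA")
})

test_that("a VCF without GT errors", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tDP\t10"), path)
  expect_error(read_vcf(path), "GT")
})

test_that("VCF write/read round-trips a genotype matrix", {
  gm <- rand_genotype_matrix(3, 5, missing_rate = 0.15, seed = 3)
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  back <- read_vcf(path)
  expect_identical(call_grid(back), call_grid(gm))
  expect_equal(variant_info(back)$ref, variant_info(gm)$ref)
})

test_that("PLINK .bed 2-bit codes decode against a hand-built fixture", {
  prefix <- tempfile()
  # 4 samples x 3 variants, variant-major. Codes per variant (s1..s4):
  #   v1: 00 10 11 01  -> homA1, het, homA2, missing -> byte 0b01111000
  #   v2: 11 11 00 00  -> byte 0b00001111
  #   v3: 10 10 10 10  -> byte 0b10101010
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x78, 0x0f, 0xaa)),
           paste0(prefix, ".bed"))
  writeLines(c("1\tv1\t0\t100\tA\tG",
               "1\tv2\t0\t200\tT\tC",
               "1\tv3\t0\t300\tG\tC"), paste0(prefix, ".bim"))
  writeLines(c("f1\ti1\t0\t0\t1\t2", "f2\ti2\t0\t0\t1\t1",
               "f3\ti3\t0\t0\t2\t2", "f4\ti4\t0\t0\t2\t1"),
             paste0(prefix, ".fam"))
  res <- read_plink(prefix)
  gm <- res$genotypes
  expect_equal(dim(gm), c(4L, 3L))
  expect_equal(unname(unclass(gm)[, "v1"]), c("A/A", "A/G", "G/G", NA))
  expect_equal(unname(unclass(gm)[, "v2"]), c("C/C", "C/C", "T/T", "T/T"))
  expect_equal(unname(unclass(gm)[, "v3"]), rep("C/G", 4))
  # .fam 2/1 coding maps to case/control
  expect_equal(as.character(res$phenotypes$status),
               c("case", "control", "case", "control"))
})

test_that("PLINK reader flags bad magic, bad sizes and all-missing payloads", {
  prefix <- tempfile()
  writeLines("1\tv1\t0\t100\tA\tG", paste0(prefix, ".bim"))
  writeLines(c("f1\ti1\t0\t0\t1\t-9", "f2\ti2\t0\t0\t1\t0"),
             paste0(prefix, ".fam"))
  writeBin(as.raw(c(0x00, 0x1b, 0x01, 0x55)), paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "magic")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x55, 0x55)), paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "payload")
  # all-missing payload (code 01 everywhere) and unknown phenotypes
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x05)), paste0(prefix, ".bed"))
  res <- suppressMessages(read_plink(prefix))
  expect_true(all(is.na(unclass(res$genotypes))))
  expect_true(all(is.na(res$phenotypes$status)))
})

test_that("phenotype files accept word and numeric codings", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("X,case", "Y,control", "Z,control"), path)
  ph <- read_phenotypes(path)
  expect_equal(sum(ph$status == "case"), 1L)
  expect_equal(sum(ph$status == "control"), 2L)
  writeLines(c("sample,status", "X,2", "Y,1", "Z,1"), path)
  ph2 <- read_phenotypes(path)
  expect_equal(as.character(ph2$status), as.character(ph$status))
  writeLines(c("X,case", "X,control"), path)
  expect_error(read_phenotypes(path), "conflicting")
  writeLines(c("X,affected"), path)
  expect_error(read_phenotypes(path), "affected")
})
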