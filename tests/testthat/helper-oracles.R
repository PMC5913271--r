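# Independent reference implementations used as oracles. These deliberately
# use the slow/direct formulation so they share no code path with the package.

# per-pair double loop over the pair functions (themselves trivially simple)
naive_pairwise <- function(x, metric = "hamming") {
  n <- nrow(x)
  v <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v[i, j] <- v[j, i] <- switch(metric,
        hamming = unname(hamming_distance(unclass(x)[i, ], unclass(x)[j, ])["count"]),
        normalized_hamming = normalized_hamming(unclass(x)[i, ], unclass(x)[j, ]),
        ibs = ibs_distance(unclass(x)[i, ], unclass(x)[j, ]))
    }
  }
  v
}

# direct full-enumeration HWE exact test from the conditional distribution
# P(nAa | n, nA) = n! / (nAA! nAa! naa!) * 2^nAa * nA! na! / (2n)!
hwe_enum_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * n - nA
  hs <- seq.int(min(nA, na) %% 2L, min(nA, na), by = 2L)
  logp <- vapply(hs, function(h) {
    aa <- (nA - h) / 2
    bb <- (na - h) / 2
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(nAa, hs)]
  min(1, sum(p[p <= p_obs * (1 + 1e-10)]))
}

# small random genotype matrix over biallelic A/B sites
rand_genotype_matrix <- function(n, nv, maf = c(0.05, 0.5), missing_rate = 0,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- runif(nv, maf[1], maf[2])
  pairs <- t(vapply(seq_len(nv), function(i) sample(c("A", "C", "G", "T"), 2L),
                    character(2)))
  d <- matrix(rbinom(n * nv, 2L, rep(p, each = n)), nrow = n)
  strs <- rbind(paste0(pairs[, 1], "/", pairs[, 1]),
                paste0(pmin(pairs[, 1], pairs[, 2]), "/",
                       pmax(pairs[, 1], pairs[, 2])),
                paste0(pairs[, 2], "/", pairs[, 2]))
  calls <- matrix(strs[cbind(as.vector(d) + 1L, rep(seq_len(nv), each = n))],
                  nrow = n)
  if (missing_rate > 0) calls[runif(length(calls)) < missing_rate] <- NA
  rownames(calls) <- sprintf("s%02d", seq_len(n))
  colnames(calls) <- sprintf("v%03d", seq_len(nv))
  genotype_matrix(calls,
                  variants = data.frame(variant_id = colnames(calls),
                                        ref = pairs[, 1], alt = pairs[, 2]))
}

# bare call grid (drops the variant-metadata attribute for comparisons)
call_grid <- function(g) {
  m <- unclass(g)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}

# the worked-example genotype table in its on-disk form
write_table1_file <- function(path) {
  writeLines(c(
    "sample_id\tSNP1(A/T)\tSNP2(G/T)\tSNP3(C/G)\tSNP4(C/T)\tSNP5(C/T)\tSNP6(A/G)\tSNP7(A/C)\tSNP8(C/T)",
    "X\tAT\tGG\tCG\tCC\tCC\tAG\tAC\tTT",
    "Y\tAA\tGG\tCC\tTT\tCT\tGG\tCC\tCT",
    "Z\tAA\tGG\tCC\tCC\tCT\tAA\tCC\tTT"), path)
  path
}
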