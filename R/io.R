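#' Read a plain-text genotype table
#'
#' Reads the simple wide genotype layout: a header row naming the variants
#' (optionally annotated with their alleles, e.g. `SNP1(A/T)`), then one row
#' per subject whose first field is the sample ID followed by one
#' two-character genotype per variant (`AT`, `GG`, ...). Genotypes are
#' unordered; `AT` and `TA` read as the same call.
#'
#' @param path Path to a tab- or comma-delimited text file.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma.
#' @param missing Token encoding a missing genotype (default `"NN"`; `"./."`
#'   is also always accepted).
#' @param alphabet Allowed allele symbols (default `A`, `C`, `G`, `T`).
#' @return A [genotype_matrix()]. Allele annotations from the header, when
#'   present, are stored as `ref`/`alt` in the variant metadata.
#' @export
read_genotype_table <- function(path, sep = NULL, missing = "NN",
                                alphabet = c("A", "C", "G", "T")) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty genotype table: ", path)
  if (is.null(sep))
    sep <- if (grepl("\t", lines[1L])) "\t" else ","
  rows <- strsplit(lines, sep, fixed = TRUE)
  rows <- lapply(rows, trimws)
  header <- rows[[1L]]
  if (length(header) < 2L) stop("header must name at least one variant")
  vcells <- header[-1L]
  ann <- regmatches(vcells, regexec("^(.*?)\\(([^/()]+)/([^/()]+)\\)$", vcells))
  has_ann <- lengths(ann) == 4L
  vid <- vcells
  vid[has_ann] <- vapply(ann[has_ann], `[`, "", 2L)
  variants <- data.frame(variant_id = vid, stringsAsFactors = FALSE)
  if (any(has_ann)) {
    variants$ref <- ifelse(has_ann, NA_character_, NA_character_)
    variants$alt <- NA_character_
    variants$ref[has_ann] <- vapply(ann[has_ann], `[`, "", 3L)
    variants$alt[has_ann] <- vapply(ann[has_ann], `[`, "", 4L)
  }
  body <- rows[-1L]
  nvar <- length(vid)
  if (length(body) == 0L) {
    calls <- matrix(NA_character_, 0L, nvar)
    return(genotype_matrix(calls, variants = variants, sample_ids = character(0)))
  }
  nf <- lengths(body)
  if (any(nf != nvar + 1L))
    stop("row ", which(nf != nvar + 1L)[1L] + 1L, " has ", nf[nf != nvar + 1L][1L],
         " fields; expected ", nvar + 1L)
  ids <- vapply(body, `[`, "", 1L)
  geno <- t(vapply(body, function(r) r[-1L], character(nvar)))
  if (nvar == 1L) geno <- matrix(geno, ncol = 1L)
  calls <- matrix(NA_character_, nrow = length(ids), ncol = nvar)
  g <- as.vector(geno)
  is_miss <- g %in% c(missing, "./.", "")
  slashed <- grepl("/", g, fixed = TRUE)
  twochar <- !is_miss & !slashed
  if (any(nchar(g[twochar]) != 2L)) {
    bad <- which(twochar)[which(nchar(g[twochar]) != 2L)[1L]]
    stop("malformed genotype ", dQuote(g[bad]), " for sample ",
         dQuote(ids[(bad - 1L) %% length(ids) + 1L]), ", variant ",
         dQuote(vid[(bad - 1L) %/% length(ids) + 1L]),
         " (expected two allele characters)")
  }
  al1 <- ifelse(slashed, sub("/.*$", "", g), substr(g, 1L, 1L))
  al2 <- ifelse(slashed, sub("^[^/]*/", "", g), substr(g, 2L, 2L))
  ok <- !is_miss
  bad_sym <- ok & (!al1 %in% alphabet | !al2 %in% alphabet)
  if (any(bad_sym)) {
    bad <- which(bad_sym)[1L]
    stop("invalid allele symbol in genotype ", dQuote(g[bad]), " for sample ",
         dQuote(ids[(bad - 1L) %% length(ids) + 1L]), ", variant ",
         dQuote(vid[(bad - 1L) %/% length(ids) + 1L]))
  }
  calls[ok] <- paste0(al1[ok], "/", al2[ok])
  genotype_matrix(calls, variants = variants, sample_ids = ids)
}

#' Write a genotype matrix as a plain-text genotype table
#'
#' Inverse of [read_genotype_table()]: one header row (variant IDs, annotated
#' with `(ref/alt)` when the metadata carries alleles), then one row per
#' sample with two-character genotypes. Only single-character alleles can be
#' written in this format.
#'
#' @param x A [genotype_matrix()].
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @param missing Token to write for missing calls (default `"NN"`).
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(x, path, sep = "\t", missing = "NN") {
  stopifnot(inherits(x, "genotype_matrix"))
  al <- split_alleles(x)
  if (any(nchar(al$a1) > 1L | nchar(al$a2) > 1L, na.rm = TRUE))
    stop("plain-text genotype tables support single-character alleles only")
  v <- variant_info(x)
  hdr <- v$variant_id
  if (!is.null(v$ref) && !is.null(v$alt)) {
    has <- !is.na(v$ref) & !is.na(v$alt)
    hdr[has] <- paste0(v$variant_id[has], "(", v$ref[has], "/", v$alt[has], ")")
  }
  geno <- matrix(paste0(al$a1, al$a2), nrow = nrow(x))
  geno[is.na(unclass(x))] <- missing
  out <- c(paste(c("sample_id", hdr), collapse = sep),
           vapply(seq_len(nrow(x)),
                  function(i) paste(c(rownames(x)[i], geno[i, ]), collapse = sep),
                  character(1)))
  writeLines(out, path)
  invisible(path)
}

#' Read genotypes from a multi-sample VCF
#'
#' Resolves GT allele indices to allele strings. Phase separators `|` and `/`
#' are treated identically (phase is discarded); half-calls and `./.` become
#' missing calls. Sites with more than two alleles are retained here —
#' filtering is quality control's job.
#'
#' @param path Path to a VCF 4.x file (plain or bgzipped).
#' @return A [genotype_matrix()] with `chrom`, `pos`, `ref`, `alt` variant
#'   metadata.
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(vcf@gt) < 2L) stop("VCF has no sample columns: ", path)
  fmt <- strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)
  if (!all(vapply(fmt, function(f) "GT" %in% f, logical(1))))
    stop("GT field absent from FORMAT at one or more sites")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ref <- vcfR::getREF(vcf)
  alt <- vcfR::getALT(vcf)
  chrom <- vcfR::getCHROM(vcf)
  pos <- vcfR::getPOS(vcf)
  id <- vcfR::getID(vcf)
  if (is.null(id)) id <- rep(NA_character_, length(ref))
  id <- ifelse(is.na(id) | id == ".", paste0(chrom, ":", pos), id)
  nvar <- length(ref); nsamp <- ncol(gt)
  alt_list <- strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE)
  calls <- matrix(NA_character_, nrow = nsamp, ncol = nvar)
  g <- gsub("|", "/", as.vector(t(gt)), fixed = TRUE)  # sample-major vector
  parts <- strsplit(g, "/", fixed = TRUE)
  vix <- rep(seq_len(nvar), each = nsamp)
  ok <- !is.na(g) & lengths(parts) == 2L
  i1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  i2 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  ok <- ok & !is.na(i1) & !is.na(i2)
  idx <- which(ok)
  if (length(idx)) {
    allele_of <- function(ai, vi) {
      out <- rep(NA_character_, length(ai))
      r <- ai == 0L
      out[r] <- ref[vi[r]]
      a <- !r
      out[a] <- mapply(function(k, v) {
        al <- alt_list[[v]]
        if (k <= length(al)) al[k] else NA_character_
      }, ai[a], vi[a])
      out
    }
    s1 <- allele_of(i1[idx], vix[idx])
    s2 <- allele_of(i2[idx], vix[idx])
    val <- ifelse(is.na(s1) | is.na(s2), NA_character_, paste0(s1, "/", s2))
    calls[cbind((idx - 1L) %% nsamp + 1L, vix[idx])] <- val
  }
  variants <- data.frame(variant_id = id, chrom = chrom, pos = pos,
                         ref = ref, alt = alt, stringsAsFactors = FALSE)
  genotype_matrix(calls, variants = variants, sample_ids = colnames(gt))
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits an unphased VCF 4.2 with a GT-only FORMAT column. Every variant must
#' carry `ref` and `alt` metadata and every observed allele must be one of
#' them; missing calls are written `./.`.
#'
#' @param x A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  v <- variant_info(x)
  if (is.null(v$ref) || is.null(v$alt) || anyNA(v$ref) || anyNA(v$alt))
    stop("writing VCF requires ref/alt alleles for every variant")
  chrom <- if (!is.null(v$chrom)) v$chrom else rep("1", nrow(v))
  pos <- if (!is.null(v$pos)) v$pos else seq_len(nrow(v))
  al <- split_alleles(x)
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(x)), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(j) {
    alleles <- c(v$ref[j], strsplit(v$alt[j], ",", fixed = TRUE)[[1L]])
    k1 <- match(al$a1[, j], alleles) - 1L
    k2 <- match(al$a2[, j], alleles) - 1L
    miss <- is.na(unclass(x)[, j])
    if (any(!miss & (is.na(k1) | is.na(k2))))
      stop("variant ", v$variant_id[j],
           ": observed allele not among ref/alt alleles")
    gt <- ifelse(miss, "./.", paste0(k1, "/", k2))
    paste(c(chrom[j], pos[j], v$variant_id[j], v$ref[j], v$alt[j], ".",
            "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read PLINK 1 binary genotypes (.bed/.bim/.fam)
#'
#' Decodes the 2-bit genotype codes of a PLINK 1 `.bed` file (variant-major
#' or sample-major per the mode byte) using the `.bim` allele columns; code
#' `01` becomes a missing call. The `.fam` phenotype column, when 1/2 coded,
#' is returned as a phenotype table (1 = control, 2 = case; `-9`/`0` map to
#' unknown status `NA`).
#'
#' @param prefix Path prefix; `<prefix>.bed`, `<prefix>.bim` and
#'   `<prefix>.fam` must all exist.
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `phenotypes` (a [phenotype_table()], status `NA` where unknown).
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  miss <- !file.exists(paths)
  if (any(miss)) stop("missing PLINK file(s): ", paste(paths[miss], collapse = ", "))
  bim <- utils::read.table(paths[2L], stringsAsFactors = FALSE,
                           col.names = c("chrom", "variant_id", "cm", "pos", "a1", "a2"))
  fam <- utils::read.table(paths[3L], stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"))
  nvar <- nrow(bim); nsamp <- nrow(fam)
  raw <- readBin(paths[1L], "raw", n = file.info(paths[1L])$size)
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b))
    stop("not a PLINK 1 .bed file (magic-byte mismatch): ", paths[1L])
  mode <- as.integer(raw[3L])
  if (!mode %in% c(0L, 1L)) stop("unknown .bed mode byte: ", mode)
  payload <- as.integer(raw[-(1:3)])
  per <- if (mode == 1L) ceiling(nsamp / 4) else ceiling(nvar / 4)
  nblk <- if (mode == 1L) nvar else nsamp
  if (length(payload) != per * nblk)
    stop(".bed payload has ", length(payload), " bytes; expected ", per * nblk,
         " for ", nsamp, " samples x ", nvar, " variants")
  codes <- rbind(payload %% 4L, (payload %/% 4L) %% 4L,
                 (payload %/% 16L) %% 4L, payload %/% 64L)
  codes <- matrix(as.vector(codes), nrow = 4L * per)  # entries x block
  if (mode == 1L) {
    codes <- codes[seq_len(nsamp), , drop = FALSE]          # samples x variants
  } else {
    codes <- t(codes[seq_len(nvar), , drop = FALSE])        # samples x variants
  }
  # 00 = hom a1, 10 = het, 11 = hom a2, 01 = missing
  a1 <- bim$a1[col(codes)]; a2 <- bim$a2[col(codes)]
  calls <- matrix(NA_character_, nsamp, nvar)
  calls[codes == 0L] <- paste0(a1, "/", a1)[codes == 0L]
  calls[codes == 2L] <- paste0(a1, "/", a2)[codes == 2L]
  calls[codes == 3L] <- paste0(a2, "/", a2)[codes == 3L]
  ids <- fam$iid
  if (anyDuplicated(ids)) ids <- paste(fam$fid, fam$iid, sep = "_")
  status <- rep(NA_character_, nsamp)
  status[fam$pheno == 1] <- "control"
  status[fam$pheno == 2] <- "case"
  n_unknown <- sum(is.na(status))
  if (n_unknown > 0L)
    message(n_unknown, " sample(s) with unknown (-9/0) phenotype in ", paths[3L])
  variants <- data.frame(variant_id = bim$variant_id, chrom = as.character(bim$chrom),
                         pos = bim$pos, ref = bim$a2, alt = bim$a1,
                         stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(calls, variants = variants, sample_ids = ids),
       phenotypes = phenotype_table(ids, status))
}

#' Read a case/control phenotype file
#'
#' Two delimited columns, `sample_id` then status. Both word coding
#' (`case`/`control`) and PLINK-style numeric coding (`2` = case,
#' `1` = control) are accepted by default; the token sets are configurable.
#' A header line is skipped automatically when its second field is not a
#' recognised status token.
#'
#' @param path Path to the phenotype file.
#' @param sep Field separator; `NULL` auto-detects tab vs comma.
#' @param case_tokens,control_tokens Tokens mapped to case / control status.
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path, sep = NULL,
                            case_tokens = c("case", "2"),
                            control_tokens = c("control", "1")) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty phenotype file: ", path)
  if (is.null(sep)) sep <- if (grepl("\t", lines[1L])) "\t" else ","
  rows <- lapply(strsplit(lines, sep, fixed = TRUE), trimws)
  if (any(lengths(rows) < 2L))
    stop("phenotype file must have two columns (sample_id, status)")
  known <- c(case_tokens, control_tokens)
  # a leading header line is skipped only when data rows follow it
  if (length(rows) > 1L && !rows[[1L]][2L] %in% known) rows <- rows[-1L]
  ids <- vapply(rows, `[`, "", 1L)
  tok <- vapply(rows, `[`, "", 2L)
  bad <- !tok %in% known
  if (any(bad))
    stop("unknown status token(s): ", paste(unique(tok[bad]), collapse = ", "))
  status <- ifelse(tok %in% case_tokens, "case", "control")
  phenotype_table(ids, status)
}
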