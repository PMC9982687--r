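#' Read and write genotype panels in standard formats
#'
#' `write_plink()`/`read_plink()` handle PLINK1 binary filesets (SNP-major
#' BED with magic bytes 0x6C 0x1B 0x01, plus BIM and FAM). The BIM A1
#' allele is the panel's alternate (counted) allele. Only hard-called
#' integer genotypes can be stored in BED; fractional dosages require VCF.
#' `write_vcf()`/`read_vcf()` handle VCF 4.2 with GT and DS FORMAT fields;
#' when a DS field is present it takes precedence over the GT hard call.
#'
#' @param panel a `genotype_panel`.
#' @param prefix path prefix for `.bed`/`.bim`/`.fam` files.
#' @param pop_labels optional data.frame (FID, IID, POP) attaching
#'   population labels on read; `write_population_labels()` produces the
#'   matching TSV.
#' @return `read_*` return a `genotype_panel`; `write_*` return the path(s)
#'   invisibly.
#' @name genotype_io
NULL

#' @rdname genotype_io
#' @export
write_plink <- function(panel, prefix) {
  D <- panel$dosages
  if (any(D != round(D), na.rm = TRUE))
    stop("BED stores hard calls only; use write_vcf() for dosages")
  n <- nrow(D); m <- ncol(D)
  # PLINK 2-bit codes, counted (A1 = alt) allele: 2->00, NA->01, 1->10, 0->11
  code <- matrix(3L, nrow = n, ncol = m)
  code[D == 2] <- 0L
  code[D == 1] <- 2L
  code[is.na(D)] <- 1L
  n_pad <- 4L * ceiling(n / 4L)
  if (n_pad > n) code <- rbind(code, matrix(0L, n_pad - n, m))
  i1 <- seq(1L, n_pad, by = 4L)
  bytes <- code[i1, , drop = FALSE] + 4L * code[i1 + 1L, , drop = FALSE] +
    16L * code[i1 + 2L, , drop = FALSE] + 64L * code[i1 + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)  # column-major = variant-major
  v <- panel$variants
  bim <- data.frame(v$chrom, v$id, 0L, v$pos, v$alt, v$ref)
  data.table::fwrite(bim, paste0(prefix, ".bim"), sep = "\t",
                     col.names = FALSE)
  s <- panel$samples
  sex <- if ("sex" %in% names(s)) s$sex else 0L
  fam <- data.frame(s$fid, s$iid, 0L, 0L, sex, -9L)
  data.table::fwrite(fam, paste0(prefix, ".fam"), sep = "\t",
                     col.names = FALSE)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

#' @rdname genotype_io
#' @export
read_plink <- function(prefix, pop_labels = NULL) {
  bim <- data.table::fread(paste0(prefix, ".bim"), header = FALSE,
                           col.names = c("chrom", "id", "cm", "pos",
                                         "a1", "a2"))
  fam <- data.table::fread(paste0(prefix, ".fam"), header = FALSE,
                           col.names = c("fid", "iid", "pat", "mat",
                                         "sex", "pheno"))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = file.size(paste0(prefix, ".bed")))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b) ||
      raw[3] != as.raw(0x01))
    stop("not a SNP-major PLINK1 BED file (magic byte mismatch)")
  bpv <- ceiling(n / 4)
  body <- as.integer(raw[-(1:3)])
  if (length(body) != bpv * m)
    stop(sprintf(
      "BED size inconsistent with BIM/FAM: %d data bytes, expected %d",
      length(body), bpv * m))
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, (body %/% 64L) %% 4L)
  dim(codes) <- c(4L * bpv, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  D <- matrix(NA_real_, n, m)
  D[codes == 0L] <- 2
  D[codes == 2L] <- 1
  D[codes == 3L] <- 0
  samples <- data.frame(fid = as.character(fam$fid),
                        iid = as.character(fam$iid),
                        pop = NA_character_, sex = fam$sex,
                        stringsAsFactors = FALSE)
  if (!is.null(pop_labels))
    samples$pop <- pop_labels$POP[match(samples$iid, pop_labels$IID)]
  variants <- data.frame(chrom = bim$chrom, pos = bim$pos, id = bim$id,
                         ref = bim$a2, alt = bim$a1,
                         stringsAsFactors = FALSE)
  genotype_panel(D, variants, samples)
}

#' @rdname genotype_io
#' @param path VCF file path (uncompressed or bgzipped on read).
#' @export
write_vcf <- function(panel, path) {
  D <- panel$dosages
  v <- panel$variants
  gt_of <- function(d) {
    out <- rep("./.", length(d))
    r <- round(d)
    out[!is.na(d) & r == 0] <- "0/0"
    out[!is.na(d) & r == 1] <- "0/1"
    out[!is.na(d) & r == 2] <- "1/1"
    out
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=DS,Number=1,Type=Float,Description=",
           "\"Alternate allele dosage\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples$iid), collapse = "\t"))
  body <- vapply(seq_len(ncol(D)), function(j) {
    d <- D[, j]
    cell <- paste0(gt_of(d), ":",
                   ifelse(is.na(d), ".", formatC(d, format = "g",
                                                 digits = 6)))
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".", ".",
            ".", "GT:DS", cell), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname genotype_io
#' @export
read_vcf <- function(path, pop_labels = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  fmt <- vcf@gt[, 1]
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    D <- t(ds)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    g <- as.vector(gt)
    cnt <- rep(NA_real_, length(g))
    ok <- !is.na(g) & !(g %in% c("./.", ".|.", "."))
    cnt[ok] <- vapply(strsplit(g[ok], "[/|]"),
                      function(a) sum(a == "1"), numeric(1))
    D <- t(matrix(cnt, nrow = nrow(gt), dimnames = dimnames(gt)))
  }
  samples <- data.frame(fid = rownames(D), iid = rownames(D),
                        pop = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(pop_labels))
    samples$pop <- pop_labels$POP[match(samples$iid, pop_labels$IID)]
  variants <- data.frame(chrom = as.integer(fix[, "CHROM"]),
                         pos = as.integer(fix[, "POS"]), id = ids,
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  genotype_panel(D, variants, samples)
}

#' @rdname genotype_io
#' @export
write_population_labels <- function(panel, path) {
  data.table::fwrite(data.frame(FID = panel$samples$fid,
                                IID = panel$samples$iid,
                                POP = panel$samples$pop),
                     path, sep = "\t")
  invisible(path)
}

#' @rdname genotype_io
#' @export
read_population_labels <- function(path) {
  as.data.frame(data.table::fread(path, header = TRUE))
}
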