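#' Read a multi-sample SNP VCF
#'
#' Parses a VCF 4.x file (via vcfR) into a [geno_set]. Only biallelic SNPs
#' are kept; multiallelic or indel records are dropped and counted. Genotypes
#' are read from GT (phased or unphased), allele depths from AD when present.
#' SNP identifiers in the ID column of the form `tag:col` (the usual RADseq
#' convention) populate `tag_id` with the part before the colon.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param popmap optional path to a two-column TSV (sample, population); when
#'   absent all samples get population "unknown".
#' @return a `geno_set`; attribute `n_dropped_multiallelic` records how many
#'   non-biallelic-SNP records were discarded.
#' @export
read_vcf <- function(path, popmap = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e)))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  is_snp <- !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_dropped <- sum(!is_snp)
  if (!any(is_snp)) stop("no biallelic SNPs in ", path)
  v <- v[is_snp, ]
  fix <- fix[is_snp, , drop = FALSE]

  gt_chr <- vcfR::extract.gt(v, element = "GT")  # snps x samples
  code <- function(s) {
    s <- gsub("|", "/", s, fixed = TRUE)
    out <- rep(NA_integer_, length(s))
    out[s %in% c("0/0")] <- 0L
    out[s %in% c("0/1", "1/0")] <- 1L
    out[s %in% c("1/1")] <- 2L
    out
  }
  geno <- t(matrix(code(gt_chr), nrow(gt_chr), ncol(gt_chr)))  # ind x snps
  rownames(geno) <- colnames(gt_chr)

  ad <- NULL
  fmt <- v@gt[, 1]
  if (all(grepl("AD", fmt))) {
    ad_chr <- vcfR::extract.gt(v, element = "AD")
    split2 <- function(s, i) suppressWarnings(as.integer(vapply(
      strsplit(as.vector(s), ",", fixed = TRUE),
      function(z) if (length(z) >= i) z[i] else NA_character_, character(1))))
    refm <- t(matrix(split2(ad_chr, 1L), nrow(ad_chr), ncol(ad_chr)))
    altm <- t(matrix(split2(ad_chr, 2L), nrow(ad_chr), ncol(ad_chr)))
    refm[is.na(geno)] <- NA_integer_
    altm[is.na(geno)] <- NA_integer_
    ad <- list(ref = refm, alt = altm)
  }

  id <- fix$ID
  tag_id <- ifelse(!is.na(id) & id != "." & grepl(":", id),
                   sub(":.*$", "", id), NA_character_)
  snps <- data.frame(
    id = ifelse(is.na(id) | id == ".", paste0(fix$CHROM, ":", fix$POS), id),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, tag_id = tag_id,
    stringsAsFactors = FALSE)

  samples <- data.frame(sample_id = rownames(geno),
                        population = "unknown", stringsAsFactors = FALSE)

  ord <- order(snps$chrom, snps$pos)
  geno <- geno[, ord, drop = FALSE]
  snps <- snps[ord, , drop = FALSE]
  if (!is.null(ad)) ad <- list(ref = ad$ref[, ord, drop = FALSE],
                               alt = ad$alt[, ord, drop = FALSE])
  if (!is.null(popmap)) {
    pm <- read_popmap(popmap)
    samples$population <- pm$population[match(samples$sample_id, pm$sample_id)]
    if (anyNA(samples$population))
      stop("samples missing from population map: ",
           paste(samples$sample_id[is.na(samples$population)], collapse = ", "))
  }
  out <- geno_set(geno, snps, samples, ad = ad)
  attr(out, "n_dropped_multiallelic") <- n_dropped
  out
}

#' Read a sample-to-population map
#'
#' @param path two-column delimited text (sample id, population code), no
#'   header required; a header line `sample_id<TAB>population` is tolerated.
#' @return data.frame with columns `sample_id`, `population`.
#' @export
read_popmap <- function(path) {
  pm <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("sample_id", "population"))
  if (identical(tolower(pm$sample_id[1]), "sample_id")) pm <- pm[-1, , drop = FALSE]
  if (any(!nzchar(pm$population))) stop("empty population code in ", path)
  pm
}

#' Write a geno_set as a plain-text VCF 4.2
#'
#' Emits GT (and AD when depths are present) with deterministic record order
#' (the `geno_set` order: chrom, then position). Round-trips through
#' [read_vcf] exactly.
#'
#' @param x a `geno_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  snps <- x$snps
  has_ad <- !is.null(x$ad)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=radpopgen",
    paste0("##contig=<ID=", unique(snps$chrom), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_ad) '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples$sample_id), collapse = "\t")), con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[x$geno + 1L], nrow = nrow(x$geno))
  gt_str[is.na(gt_str)] <- "./."
  if (has_ad) {
    ad_str <- matrix(paste0(x$ad$ref, ",", x$ad$alt), nrow = nrow(x$geno))
    ad_str[is.na(x$ad$ref)] <- ".,."
    gt_str <- matrix(paste0(gt_str, ":", ad_str), nrow = nrow(x$geno))
  }
  recs <- paste(snps$chrom, snps$pos, snps$id, snps$ref, snps$alt, ".", "PASS",
                ".", if (has_ad) "GT:AD" else "GT",
                apply(gt_str, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(recs, con)
  invisible(path)
}

#' Write the sample-to-population map
#' @param x a `geno_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(x, path) {
  utils::write.table(x$samples[, c("sample_id", "population")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
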