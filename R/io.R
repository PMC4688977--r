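# Readers and writers for the pipeline's tabular formats and VCF.

#' Write / read a genotype matrix as TSV
#'
#' Plain 0/1/2 (or dosage) matrix with individual ids in the first column
#' and snp ids as header.
#'
#' @param genotypes individuals x markers matrix.
#' @param path file path.
#' @return \code{read_genotypes_tsv} returns the matrix.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- data.frame(id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a SNP map as TSV
#'
#' @param snp_map data.frame (snp_id, chrom, pos_bp, pos_cm, panel).
#' @param path file path.
#' @export
write_snp_map <- function(snp_map, path) {
  write.table(snp_map, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_snp_map
#' @export
read_snp_map <- function(path) {
  map <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  validate_snp_map(map)
  map
}

#' Write genotypes (and optional dosages) as VCF v4.2
#'
#' One contig per chromosome, GT genotype field (unphased), and a DS dosage
#' field when dosages are supplied. Requires the vcfR package.
#'
#' @param genotypes individuals x markers 0/1/2 matrix.
#' @param snp_map map aligned to the columns.
#' @param path output path (\code{.vcf.gz} appended by vcfR when absent).
#' @param dosages optional matrix of dosages with the same shape.
#' @return the path written.
#' @export
write_genotypes_vcf <- function(genotypes, snp_map, path, dosages = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_ovimp("vcfR is required for VCF output")
  }
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow = nrow(snp_map), ncol = nrow(genotypes))
  obs <- !is.na(t(genotypes))
  gt[obs] <- gt_code[as.character(t(genotypes)[obs])]
  fmt <- "GT"
  if (!is.null(dosages)) {
    gt <- matrix(paste(gt, sprintf("%.3f", t(dosages)), sep = ":"),
                 nrow = nrow(snp_map))
    fmt <- "GT:DS"
  }
  gt <- cbind(FORMAT = fmt, gt)
  colnames(gt) <- c("FORMAT", rownames(genotypes))
  fix <- cbind(CHROM = as.character(snp_map$chrom),
               POS = as.character(snp_map$pos_bp),
               ID = snp_map$snp_id, REF = "A", ALT = "B",
               QUAL = ".", FILTER = "PASS", INFO = ".")
  meta <- c("##fileformat=VCFv4.2",
            sprintf("##contig=<ID=%s>", unique(as.character(snp_map$chrom))),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            if (!is.null(dosages))
              "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Imputed dosage\">")
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read a genotype matrix from a VCF
#'
#' Returns the 0/1/2 genotype matrix (individuals x markers) and, when
#' present, the DS dosage matrix.
#'
#' @param path VCF path (plain or gzipped).
#' @return list(genotypes, dosages or NULL, snp_ids).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_ovimp("vcfR is required for VCF input")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt %in% c("0/0", "0|0")] <- 0L
  code[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  code[gt %in% c("1/1", "1|1")] <- 2L
  ds <- NULL
  if (any(grepl("DS", v@gt[, "FORMAT"]))) {
    d <- vcfR::extract.gt(v, element = "DS")
    ds <- t(matrix(as.numeric(d), nrow(d), ncol(d)))
    dimnames(ds) <- list(colnames(d), rownames(d))
  }
  list(genotypes = t(code), dosages = ds, snp_ids = rownames(gt))
}

#' Write a GRM as a dense matrix TSV and as id-id-value triplets
#'
#' @param grm an \code{ovimp_grm}.
#' @param path base path; \code{<path>.tsv} holds the dense matrix with a
#'   header row, \code{<path>_triplets.tsv} the lower-triangle triplets.
#' @export
write_grm <- function(grm, path) {
  stopifnot(inherits(grm, "ovimp_grm"))
  m <- as.matrix(grm)
  write.table(data.frame(id = rownames(m), m, check.names = FALSE),
              paste0(path, ".tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  lt <- which(lower.tri(m, diag = TRUE), arr.ind = TRUE)
  trip <- data.frame(id1 = rownames(m)[lt[, 1]], id2 = colnames(m)[lt[, 2]],
                     value = m[lt])
  write.table(trip, paste0(path, "_triplets.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}
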