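# Plain-text readers and writers for the pipeline's interchange formats:
# TSV trait tables, minimal VCFv4.2 genotypes, annotation/metadata TSVs,
# GCTA-style GRM lower triangle, and BED exclusion regions.

#' Write / read a trait table as TSV
#'
#' @param x data.frame (single-cell, well-level or donor-level table).
#' @param path file path.
#' @return `read_trait_tsv` returns a data.frame.
#' @export
write_trait_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trait_tsv
#' @export
read_trait_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write a genotype set as minimal VCFv4.2
#'
#' Emits CHROM, POS, ID, REF, ALT, QUAL, FILTER, INFO, FORMAT and one GT
#' column per donor; dosages map to 0/0, 0/1, 1/1 and missing to ./.
#'
#' @param g a [genotype_set()].
#' @param path output path (plain text).
#' @export
write_genotypes_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=morphoqtl",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", g$donors), collapse = "\t")
  ), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  v <- g$variants
  for (j in seq_len(nrow(v))) {
    d <- g$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
                       ".", v$filter[j], ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Parses a VCF (via vcfR) into a [genotype_set()]; the GT field is
#' converted to alternate-allele dosage, with missing genotypes NA.
#' Multi-allelic ALT strings are preserved so QC can drop them.
#'
#' @param path VCF path.
#' @param annotation optional annotation data.frame (variant_id, gene,
#'   impact) to attach.
#' @return a [genotype_set()].
#' @export
read_genotypes_vcf <- function(path, annotation = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  count_alt <- function(x) {
    ifelse(is.na(x) | x %in% c("./.", ".|.", "."), NA_integer_,
           vapply(strsplit(x, "[/|]"), function(a) {
             sum(a != "0" & a != ".")
           }, integer(1)))
  }
  dosage <- apply(gt, 2, count_alt)
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = 1)
  dosage <- t(dosage)  # donors x variants
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[
    is.na(ids) | ids == "."]
  colnames(dosage) <- ids
  rownames(dosage) <- colnames(gt)
  variants <- data.frame(
    id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    filter = ifelse(is.na(fix$FILTER) | fix$FILTER == ".",
                    "PASS", fix$FILTER),
    stringsAsFactors = FALSE
  )
  if (is.null(annotation)) {
    genotype_set(dosage, variants)
  } else {
    genotype_set(dosage, variants, annotation)
  }
}

#' Write / read the variant annotation table
#'
#' Two/three-column TSV: variant_id, gene, impact.
#' @param annotation data.frame; @param path file path.
#' @export
write_annotation_tsv <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write the GRM as GCTA-style lower triangle
#'
#' One row per donor pair (i >= j): index i, index j, number of variants,
#' relatedness; plus an `.id` file listing donor ids.
#'
#' @param grm matrix from [compute_grm()].
#' @param prefix output prefix (writes `<prefix>.grm.txt` and
#'   `<prefix>.grm.id`).
#' @export
write_grm <- function(grm, prefix) {
  n <- nrow(grm)
  idx <- which(lower.tri(grm, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- data.frame(i = idx[, 1], j = idx[, 2],
                    n_variants = attr(grm, "n_variants") %||% NA,
                    value = grm[idx])
  write.table(out, paste0(prefix, ".grm.txt"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(rownames(grm), paste0(prefix, ".grm.id"))
  invisible(prefix)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a BED file of exclusion regions
#'
#' 0-based half-open intervals (chrom, start, end), e.g. long-range LD
#' regions to drop before pruning.
#'
#' @param path BED path.
#' @return data.frame with columns chrom, start, end.
#' @export
read_bed <- function(path) {
  bed <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)[, 1:3]
  names(bed) <- c("chrom", "start", "end")
  bed
}
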