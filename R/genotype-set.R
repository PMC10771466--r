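#' Construct a genotype set
#'
#' A light container for donor-by-variant dosages plus variant metadata and
#' functional annotation, the unit all genotype QC and association
#' operations act on.
#'
#' @param dosage integer matrix, donors x variants, entries in {0,1,2} or
#'   NA for missing; dimnames required.
#' @param variants data.frame with columns id, chrom, pos, ref, alt,
#'   filter (and optionally type), one row per dosage column, positions
#'   1-based as in VCF.
#' @param annotation data.frame with columns variant_id, gene, impact
#'   (HIGH/MODERATE/LOW/MODIFIER); may cover a subset of variants.
#' @return object of class `genotype_set`.
#' @export
genotype_set <- function(dosage, variants,
                         annotation = data.frame(variant_id = character(0),
                                                 gene = character(0),
                                                 impact = character(0))) {
  stopifnot(is.matrix(dosage), !is.null(rownames(dosage)),
            !is.null(colnames(dosage)),
            all(c("id", "chrom", "pos", "ref", "alt", "filter") %in%
                  names(variants)),
            nrow(variants) == ncol(dosage),
            identical(variants$id, colnames(dosage)),
            all(c("variant_id", "gene", "impact") %in% names(annotation)))
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  structure(list(dosage = dosage, variants = variants,
                 annotation = annotation,
                 donors = rownames(dosage)),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("genotype_set:", length(x$donors), "donors x",
      nrow(x$variants), "variants\n")
  if (nrow(x$annotation)) {
    cat("  annotated rare variants:", nrow(x$annotation), "in",
        length(unique(x$annotation$gene)), "genes\n")
  }
  invisible(x)
}

#' Subset a genotype set by variant ids (and optionally donors)
#'
#' @param g a [genotype_set()].
#' @param ids variant ids to keep (original order preserved).
#' @param donors optional donor ids to keep.
#' @return the subset `genotype_set`.
#' @export
subset_variants <- function(g, ids, donors = NULL) {
  if (is.null(donors)) donors <- g$donors
  keep <- g$variants$id %in% ids
  genotype_set(g$dosage[donors, g$variants$id[keep], drop = FALSE],
               g$variants[keep, , drop = FALSE],
               g$annotation[g$annotation$variant_id %in% ids, ,
                            drop = FALSE])
}

#' Per-variant summary statistics
#'
#' Computes call rate, minor allele frequency on observed genotypes, and
#' the exact Hardy-Weinberg test p-value for every variant.
#'
#' @param g a [genotype_set()].
#' @return data.frame with columns id, n_obs, call_rate, p_alt, maf, hwe_p.
#' @export
variant_stats <- function(g) {
  stopifnot(inherits(g, "genotype_set"))
  d <- g$dosage
  n <- nrow(d)
  n_obs <- colSums(!is.na(d))
  n0 <- colSums(d == 0L, na.rm = TRUE)
  n1 <- colSums(d == 1L, na.rm = TRUE)
  n2 <- colSums(d == 2L, na.rm = TRUE)
  p_alt <- ifelse(n_obs > 0, (n1 + 2 * n2) / (2 * n_obs), NA_real_)
  hwe <- mapply(hwe_exact_test, n0, n1, n2)
  data.frame(id = g$variants$id,
             n_obs = n_obs,
             call_rate = n_obs / n,
             p_alt = p_alt,
             maf = pmin(p_alt, 1 - p_alt),
             hwe_p = hwe,
             row.names = NULL)
}
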