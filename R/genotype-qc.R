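.autosomes <- as.character(1:22)

is_autosomal <- function(chrom) {
  sub("^chr", "", chrom) %in% .autosomes
}

#' Quality control for common-variant association
#'
#' Applies, in order: structural pre-filters (autosomal, biallelic, unique
#' position, indel size at most 5 bp, FILTER = PASS); removal of donors
#' with genotype missingness above `donor_miss_max`; then the statistical
#' filters — minor allele frequency at least `maf_min`, variant
#' missingness at most `miss_max`, and exact Hardy-Weinberg p-value at
#' least `hwe_p_min`.
#'
#' @param g a [genotype_set()].
#' @param maf_min,miss_max,hwe_p_min statistical filter thresholds
#'   (defaults 0.05, 0.05, 1e-5).
#' @param donor_miss_max maximum tolerated donor-level missingness (0.10).
#' @return the filtered `genotype_set`; attribute `qc_log` holds the
#'   variant funnel counts per filter and dropped donors.
#' @export
qc_common_variants <- function(g, maf_min = 0.05, miss_max = 0.05,
                               hwe_p_min = 1e-5, donor_miss_max = 0.10) {
  stopifnot(inherits(g, "genotype_set"))
  v <- g$variants
  log <- list(n_in = nrow(v))

  autosomal <- is_autosomal(v$chrom)
  biallelic <- !grepl(",", v$alt, fixed = TRUE)
  posk <- paste(v$chrom, v$pos)
  unique_pos <- !(posk %in% posk[duplicated(posk)])
  indel_ok <- abs(nchar(v$ref) - nchar(v$alt)) <= 5
  pass <- v$filter == "PASS"
  structural <- autosomal & biallelic & unique_pos & indel_ok & pass
  log$n_non_autosomal <- sum(!autosomal)
  log$n_multiallelic <- sum(!biallelic)
  log$n_dup_position <- sum(!unique_pos)
  log$n_long_indel <- sum(!indel_ok)
  log$n_filter_fail <- sum(!pass)
  log$n_structural_pass <- sum(structural)

  g <- subset_variants(g, v$id[structural])

  donor_miss <- rowMeans(is.na(g$dosage))
  keep_donors <- donor_miss <= donor_miss_max
  log$donors_dropped <- g$donors[!keep_donors]
  if (!all(keep_donors)) {
    g <- subset_variants(g, g$variants$id, donors = g$donors[keep_donors])
  }

  st <- variant_stats(g)
  ok <- st$maf >= maf_min & (1 - st$call_rate) <= miss_max &
    st$hwe_p >= hwe_p_min
  ok[is.na(ok)] <- FALSE
  log$n_low_maf <- sum(st$maf < maf_min, na.rm = TRUE)
  log$n_high_missing <- sum(1 - st$call_rate > miss_max)
  log$n_hwe_fail <- sum(st$hwe_p < hwe_p_min, na.rm = TRUE)
  log$n_out <- sum(ok)
  out <- subset_variants(g, st$id[ok])
  attr(out, "qc_log") <- log
  out
}

# squared Pearson correlation between dosage columns, mean-imputed
.dosage_r2 <- function(d) {
  for (j in seq_len(ncol(d))) {
    x <- d[, j]
    if (anyNA(x)) d[is.na(x), j] <- mean(x, na.rm = TRUE)
  }
  suppressWarnings(cor(d)^2)
}

#' Greedy LD pruning
#'
#' Removes variants in high linkage disequilibrium within sliding windows.
#' Two modes mirror the two standard parameterizations: `"bp"` (r² > 0.1
#' within 50 kb windows sliding by 10 kb, the pre-GRM/PCA setting) and
#' `"count"` (r² > 0.2 within 50-variant windows shifting by 5 variants,
#' the indep-pairwise setting used before effect-size-mixture fitting).
#' Within each window, while any retained pair exceeds the threshold the
#' member with the smaller MAF is removed (tie: the later position).
#' Long-range LD exclusion regions, if given, are removed first.
#'
#' @param g a [genotype_set()], variants position-sorted per chromosome.
#' @param mode "bp" or "count".
#' @param r2_max,window,step override the mode's defaults (window/step in
#'   bp for "bp" mode, in variant counts for "count" mode).
#' @param exclude_regions optional data.frame (chrom, start, end), 0-based
#'   half-open intervals to drop before pruning (e.g. from a BED file).
#' @return character vector of retained variant ids, in position order.
#' @export
ld_prune <- function(g, mode = c("bp", "count"), r2_max = NULL,
                     window = NULL, step = NULL, exclude_regions = NULL) {
  stopifnot(inherits(g, "genotype_set"))
  mode <- match.arg(mode)
  if (is.null(r2_max)) r2_max <- if (mode == "bp") 0.1 else 0.2
  if (is.null(window)) window <- if (mode == "bp") 50000 else 50
  if (is.null(step)) step <- if (mode == "bp") 10000 else 5

  v <- g$variants
  for (ch in unique(v$chrom)) {
    p <- v$pos[v$chrom == ch]
    if (is.unsorted(p)) stop("ld_prune: variants not position-sorted on ",
                             ch)
  }
  if (!is.null(exclude_regions)) {
    drop <- rep(FALSE, nrow(v))
    for (i in seq_len(nrow(exclude_regions))) {
      hit <- sub("^chr", "", v$chrom) ==
        sub("^chr", "", exclude_regions$chrom[i]) &
        v$pos - 1 >= exclude_regions$start[i] &
        v$pos - 1 < exclude_regions$end[i]
      drop <- drop | hit
    }
    v <- v[!drop, , drop = FALSE]
  }
  st <- variant_stats(g)
  maf <- setNames(st$maf, st$id)

  retained <- character(0)
  for (ch in unique(v$chrom)) {
    vc <- v[v$chrom == ch, , drop = FALSE]
    keep <- setNames(rep(TRUE, nrow(vc)), vc$id)
    starts <- if (mode == "bp") {
      seq(min(vc$pos), max(vc$pos), by = step)
    } else {
      seq(1, nrow(vc), by = step)
    }
    for (s in starts) {
      widx <- if (mode == "bp") {
        which(vc$pos >= s & vc$pos < s + window)
      } else {
        seq(s, min(s + window - 1, nrow(vc)))
      }
      widx <- widx[keep[widx]]
      if (length(widx) < 2) next
      repeat {
        ids <- vc$id[widx]
        r2 <- .dosage_r2(g$dosage[, ids, drop = FALSE])
        offending <- which(upper.tri(r2) & r2 > r2_max, arr.ind = TRUE)
        if (!nrow(offending)) break
        # resolve the strongest pair first (deterministic)
        o <- offending[order(-r2[offending], offending[, 1],
                             offending[, 2])[1], ]
        i1 <- widx[o[1]]; i2 <- widx[o[2]]
        drop_i <- if (maf[vc$id[i1]] < maf[vc$id[i2]]) i1
                  else if (maf[vc$id[i2]] < maf[vc$id[i1]]) i2
                  else max(i1, i2)  # tie: later position
        keep[drop_i] <- FALSE
        widx <- widx[widx != drop_i]
        if (length(widx) < 2) break
      }
    }
    retained <- c(retained, vc$id[keep])
  }
  retained
}

#' Genetic relatedness matrix (GRM)
#'
#' Standard normalized-genotype cross-product: with dosage x and allele
#' frequency p per variant, entries are averages over variants of
#' (x_j - 2p)(x_k - 2p) / (2p(1-p)). Missing dosages are mean-imputed per
#' variant; monomorphic variants are skipped with a warning.
#'
#' @param g a [genotype_set()] (typically LD-pruned common variants).
#' @return symmetric donor-by-donor matrix with attribute `n_variants`.
#' @export
compute_grm <- function(g) {
  stopifnot(inherits(g, "genotype_set"))
  d <- g$dosage
  p <- colMeans(d, na.rm = TRUE) / 2
  mono <- is.na(p) | p <= 0 | p >= 1
  if (any(mono)) {
    warning("compute_grm: skipping ", sum(mono), " monomorphic variant(s)")
    d <- d[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  if (!ncol(d)) stop("compute_grm: no polymorphic variants")
  w <- sweep(d, 2, 2 * p)
  for (j in seq_len(ncol(w))) {
    x <- w[, j]
    if (anyNA(x)) w[is.na(x), j] <- 0  # mean-impute => centered value 0
  }
  w <- sweep(w, 2, sqrt(2 * p * (1 - p)), "/")
  grm <- tcrossprod(w) / ncol(w)
  attr(grm, "n_variants") <- ncol(w)
  grm
}

#' Ancestry principal components from a GRM
#'
#' Top-k eigenvectors of the GRM scaled by the square root of their
#' eigenvalues, in descending eigenvalue order. Sign convention: the
#' largest-magnitude loading of each PC is positive.
#'
#' @param grm symmetric donor-by-donor matrix.
#' @param k number of components (default 20).
#' @return list with `pcs` (donor x k matrix, columns PC1..PCk) and
#'   `eigenvalues`.
#' @export
pca_from_grm <- function(grm, k = 20) {
  stopifnot(is.matrix(grm), nrow(grm) == ncol(grm))
  n <- nrow(grm)
  if (k > n) stop("pca_from_grm: k exceeds the number of donors")
  e <- eigen(grm, symmetric = TRUE)
  vals <- e$values[seq_len(k)]
  vecs <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  pcs <- sweep(vecs, 2, sqrt(pmax(vals, 0)), "*")
  dimnames(pcs) <- list(rownames(grm), paste0("PC", seq_len(k)))
  list(pcs = pcs, eigenvalues = vals)
}

#' Collapse qualifying rare variants to gene-level burden
#'
#' Selects rare variants that are autosomal, FILTER = PASS, called in more
#' than `call_rate_min` of donors, with MAF below `maf_max`, and annotated
#' with a qualifying (protein-altering) impact; codes each donor as
#' carrier (1) or non-carrier (0) of any qualifying alternate allele per
#' gene; and drops genes whose carrier count is below
#' `ceiling(min_carrier_fraction * n_donors)` (2% of 297 donors gives the
#' minimum carrier count of 6 used at full scale).
#'
#' @param g a [genotype_set()] with rare-variant annotation.
#' @param maf_max MAF upper bound (exclusive), default 0.01.
#' @param call_rate_min call-rate lower bound (exclusive), default 0.95.
#' @param impacts qualifying impact classes, default HIGH and MODERATE.
#' @param min_carrier_fraction minimum carrier fraction per gene, 0.02.
#' @return list with `burden` (binary donor x gene matrix),
#'   `carrier_counts`, and `variants_per_gene` (qualifying variant ids).
#' @export
collapse_rare_burden <- function(g, maf_max = 0.01, call_rate_min = 0.95,
                                 impacts = c("HIGH", "MODERATE"),
                                 min_carrier_fraction = 0.02) {
  stopifnot(inherits(g, "genotype_set"))
  if (!nrow(g$annotation)) stop("collapse_rare_burden: no annotation")
  st <- variant_stats(g)
  v <- g$variants
  qual_ids <- st$id[
    is_autosomal(v$chrom) & v$filter == "PASS" &
      st$call_rate > call_rate_min &
      !is.na(st$maf) & st$maf < maf_max
  ]
  ann <- g$annotation[g$annotation$variant_id %in% qual_ids &
                        g$annotation$impact %in% impacts, , drop = FALSE]
  if (!nrow(ann)) stop("collapse_rare_burden: no qualifying variants")
  per_gene <- split(ann$variant_id, ann$gene)
  n <- length(g$donors)
  burden <- vapply(per_gene, function(vs) {
    d <- g$dosage[, vs, drop = FALSE]
    as.integer(rowSums(d >= 1, na.rm = TRUE) > 0)
  }, integer(n))
  rownames(burden) <- g$donors
  counts <- colSums(burden)
  min_carriers <- ceiling(min_carrier_fraction * n)
  keep <- counts >= min_carriers
  list(burden = burden[, keep, drop = FALSE],
       carrier_counts = counts[keep],
       variants_per_gene = per_gene[keep],
       min_carriers = min_carriers)
}
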