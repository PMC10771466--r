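#' Remove cells with excessive missing trait measurements
#'
#' Drops every cell whose fraction of missing trait values exceeds
#' `max_missing_fraction` (default: more than 5% missing removed).
#'
#' @param table single-cell trait table.
#' @param max_missing_fraction maximum tolerated missing-trait fraction,
#'   in (0, 1).
#' @return the filtered table, with an attribute `qc_log` recording counts.
#' @export
qc_cells <- function(table, max_missing_fraction = 0.05) {
  stopifnot(max_missing_fraction > 0, max_missing_fraction < 1)
  traits <- trait_names(table)
  frac <- rowMeans(is.na(as.matrix(table[traits])))
  keep <- frac <= max_missing_fraction
  if (!any(keep)) stop("qc_cells: all cells removed")
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc_log") <- list(n_in = nrow(table), n_kept = sum(keep),
                              n_removed = sum(!keep))
  out
}

#' Remove problematic traits
#'
#' Drops blocklisted traits, traits never measured (all-missing columns),
#' and traits with (near-)zero variance across cells.
#'
#' @param table single-cell trait table.
#' @param blocklist character vector of trait names known a priori to be
#'   problematic.
#' @param var_tol variance below which a trait counts as non-variable.
#' @return table without the dropped trait columns; attribute `qc_log`
#'   records which traits were dropped and why.
#' @export
qc_traits <- function(table, blocklist = character(0), var_tol = 1e-12) {
  traits <- trait_names(table)
  m <- as.matrix(table[traits])
  all_missing <- colSums(!is.na(m)) == 0
  v <- apply(m, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) 0 else var(x)
  })
  drop <- traits %in% blocklist | all_missing | v <= var_tol
  out <- table[c(intersect(.cell_meta_cols, names(table)),
                 traits[!drop])]
  attr(out, "qc_log") <- list(
    blocklisted = intersect(traits, blocklist),
    all_missing = traits[all_missing],
    zero_variance = traits[!(traits %in% blocklist) & !all_missing &
                             v <= var_tol]
  )
  out
}

#' Split cells into colony and isolate contexts
#'
#' Cells with no touching neighbors are "isolate" cells; cells with one or
#' more neighbors are "colony" cells. The two contexts are analyzed
#' separately throughout the pipeline.
#'
#' @param table single-cell trait table with a `neighbor_count` column.
#' @return list with elements `colony` and `isolate`; their union is the
#'   input.
#' @export
split_context <- function(table) {
  stopifnot("neighbor_count" %in% names(table),
            all(table$neighbor_count >= 0))
  iso <- table$neighbor_count == 0
  list(colony = table[!iso, , drop = FALSE],
       isolate = table[iso, , drop = FALSE])
}

#' Aggregate single cells to well-level trait means
#'
#' Averages each trait across all retained cells of a well (missing values
#' ignored), yielding one row per well with the retained-cell count and the
#' mean neighbor count carried along. Wells with zero cells simply do not
#' appear.
#'
#' @param table single-cell trait table (typically one context).
#' @return well-by-trait data.frame with metadata columns plate_id,
#'   well_id, donor_id, on_edge, n_cells, mean_neighbors.
#' @export
aggregate_wells <- function(table) {
  if (nrow(table) == 0) stop("aggregate_wells: empty input")
  traits <- trait_names(table)
  key <- interaction(table$plate_id, table$well_id, table$donor_id,
                     drop = TRUE)
  idx <- split(seq_len(nrow(table)), key)
  m <- as.matrix(table[traits])
  rows <- lapply(idx, function(i) {
    data.frame(
      plate_id = table$plate_id[i[1]],
      well_id = table$well_id[i[1]],
      donor_id = table$donor_id[i[1]],
      on_edge = table$on_edge[i[1]],
      n_cells = length(i),
      mean_neighbors = mean(table$neighbor_count[i]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  vals <- do.call(rbind, lapply(idx, function(i) {
    colMeans(m[i, , drop = FALSE], na.rm = TRUE)
  }))
  vals[is.nan(vals)] <- NA_real_
  out <- cbind(out, as.data.frame(vals))
  names(out)[-seq_along(.well_meta_cols)] <- traits
  out <- out[order(out$plate_id, out$well_id, out$donor_id), ]
  rownames(out) <- NULL
  out
}

#' Rank-based inverse normal transformation
#'
#' Gaussianizes each trait across all rows jointly (i.e. across plates):
#' values are replaced by normal quantiles of their fractional ranks,
#' \eqn{\Phi^{-1}((r - c)/(n - 2c + 1))} with the Blom offset c = 3/8 by
#' default; ties receive average ranks. Missing values stay missing and do
#' not consume ranks.
#'
#' @param matrix well-by-trait data.frame (or donor-by-trait).
#' @param offset rank offset c; 3/8 is the Blom convention usual in QTL
#'   studies.
#' @return the data.frame with every trait column transformed.
#' @export
inverse_normal_transform <- function(matrix, offset = 3 / 8) {
  traits <- trait_names(matrix)
  for (tr in traits) {
    x <- matrix[[tr]]
    obs <- !is.na(x)
    xo <- x[obs]
    if (length(unique(xo)) < 2) {
      stop("inverse_normal_transform: trait '", tr,
           "' is constant; run qc_traits first")
    }
    r <- rank(xo, ties.method = "average")
    n <- length(xo)
    x[obs] <- qnorm((r - offset) / (n - 2 * offset + 1))
    matrix[[tr]] <- x
  }
  matrix
}

#' Donor-level trait correlation matrix
#'
#' Pearson correlations between traits over donor-level values, with
#' pairwise-complete observations; the input for composite-trait
#' selection.
#'
#' @param donor_matrix donor-by-trait data.frame.
#' @return trait-by-trait correlation matrix.
#' @export
donor_correlation <- function(donor_matrix) {
  traits <- trait_names(donor_matrix)
  cor(as.matrix(donor_matrix[traits]), use = "pairwise.complete.obs")
}

#' Greedy selection of composite (non-redundant) traits
#'
#' Iteratively selects representative traits so that no retained pair is
#' correlated above the threshold in any input correlation matrix:
#' at each step the trait with |r| >= threshold to the largest number of
#' other traits (neighbor counts summed across matrices) is retained as a
#' hub, and the hub together with all its above-threshold neighbors (in any
#' matrix) leaves the pool; traits with no above-threshold neighbor are
#' retained. Ties on the neighbor count go to the lexicographically
#' smallest trait name, making the procedure deterministic.
#'
#' @param matrices list of trait correlation matrices sharing one trait
#'   set (e.g. colony and isolate contexts).
#' @param threshold correlation threshold in (0, 1); default 0.9.
#' @param signed if FALSE (default) the threshold applies to |r|, treating
#'   anti-correlated pairs as redundant; if TRUE only r >= threshold
#'   counts.
#' @return list with `traits` (retained trait names, selection order) and
#'   `log` (data.frame: iteration, selected hub, number removed).
#' @export
select_composite_traits <- function(matrices, threshold = 0.9,
                                    signed = FALSE) {
  stopifnot(length(matrices) >= 1, threshold > 0, threshold < 1)
  traits <- colnames(matrices[[1]])
  for (m in matrices) {
    if (!identical(sort(colnames(m)), sort(traits)) ||
        !identical(colnames(m), rownames(m))) {
      stop("select_composite_traits: matrices must share one trait set")
    }
  }
  adj <- lapply(matrices, function(m) {
    m <- m[traits, traits]
    a <- if (signed) m >= threshold else abs(m) >= threshold
    a[is.na(a)] <- FALSE
    diag(a) <- FALSE
    a
  })
  remaining <- traits
  kept <- character(0)
  log <- list()
  it <- 0L
  while (length(remaining)) {
    counts <- Reduce(`+`, lapply(adj, function(a) {
      rowSums(a[remaining, remaining, drop = FALSE])
    }))
    if (all(counts == 0)) {
      kept <- c(kept, sort(remaining))
      log[[length(log) + 1]] <- data.frame(
        iteration = it + seq_along(remaining), selected = sort(remaining),
        n_removed = 0L, stringsAsFactors = FALSE)
      break
    }
    it <- it + 1L
    cand <- remaining[counts == max(counts)]
    hub <- sort(cand)[1]
    nbrs <- unique(unlist(lapply(adj, function(a) {
      remaining[a[hub, remaining]]
    })))
    kept <- c(kept, hub)
    log[[length(log) + 1]] <- data.frame(
      iteration = it, selected = hub, n_removed = length(nbrs),
      stringsAsFactors = FALSE)
    remaining <- setdiff(remaining, c(hub, nbrs))
  }
  # post-condition: no retained pair above threshold in any matrix
  for (a in adj) {
    sub <- a[kept, kept, drop = FALSE]
    stopifnot(!any(sub))
  }
  list(traits = kept, log = do.call(rbind, log))
}

#' Pseudo-bulk wells to donor-level trait values
#'
#' Averages each composite trait across all wells of a donor, yielding one
#' measurement per trait per donor. The donor's mean neighbor count is the
#' cell-weighted average across wells.
#'
#' @param matrix well-by-trait data.frame (post-INT).
#' @param traits character vector of composite traits to keep, or a
#'   selection from [select_composite_traits()]; NULL keeps all.
#' @return donor-by-trait data.frame with metadata donor_id, n_wells,
#'   mean_neighbors.
#' @export
pseudo_bulk <- function(matrix, traits = NULL) {
  if (is.list(traits) && !is.null(traits$traits)) traits <- traits$traits
  all_traits <- trait_names(matrix)
  if (is.null(traits)) traits <- all_traits
  missing_tr <- setdiff(traits, all_traits)
  if (length(missing_tr)) {
    stop("pseudo_bulk: unknown traits: ", paste(missing_tr, collapse = ", "))
  }
  idx <- split(seq_len(nrow(matrix)), matrix$donor_id)
  m <- as.matrix(matrix[traits])
  out <- data.frame(
    donor_id = names(idx),
    n_wells = vapply(idx, length, 1L),
    mean_neighbors = vapply(idx, function(i) {
      sum(matrix$mean_neighbors[i] * matrix$n_cells[i]) /
        sum(matrix$n_cells[i])
    }, 1.0),
    stringsAsFactors = FALSE
  )
  vals <- do.call(rbind, lapply(idx, function(i) {
    colMeans(m[i, , drop = FALSE], na.rm = TRUE)
  }))
  vals[is.nan(vals)] <- NA_real_
  out <- cbind(out, as.data.frame(vals))
  names(out)[-seq_along(.donor_meta_cols)] <- traits
  rownames(out) <- NULL
  out
}
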