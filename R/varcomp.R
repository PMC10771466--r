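# Variance decomposition of well-level traits via linear mixed models.
#
# The full model mirrors the study design: fixed terms for donor age,
# ancestry PCs 1-4 and (colony context) the well's mean neighbor count;
# random intercepts for disease status, source tissue, sex, imaging plate,
# well position, plate-edge status and donor (cell line) identity.

.vc_formula <- function(response, fixed_vars, random_terms) {
  rhs <- c(fixed_vars, sprintf("(1 | %s)", random_terms))
  if (!length(rhs)) rhs <- "1"
  as.formula(paste0("`", response, "` ~ ", paste(rhs, collapse = " + ")))
}

.fit_mixed <- function(data, response, fixed_vars, random_terms,
                       reml = TRUE) {
  f <- .vc_formula(response, fixed_vars, random_terms)
  if (length(random_terms)) {
    ctrl <- lme4::lmerControl(
      check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4),
      calc.derivs = FALSE)
    lme4::lmer(f, data = data, REML = reml, control = ctrl)
  } else {
    stats::lm(f, data = data)
  }
}

#' Fit a variance decomposition for one response
#'
#' REML estimation of the variance attributable to each random-intercept
#' factor, each fixed-term group, and the residual, as fractions of the
#' total. Random-component variances come straight from the REML fit; the
#' fixed-term contribution is the variance of the fitted fixed-effect
#' linear predictor over the observed design, apportioned to the fixed
#' groups in proportion to their individual predictor variances so that
#' all fractions sum to exactly 1.
#'
#' @param data data.frame with the response and all model terms.
#' @param response response column name.
#' @param random_terms character vector of random-intercept grouping
#'   factors (each needs >= 2 levels).
#' @param fixed_groups named list of fixed-term groups, e.g.
#'   `list(age = "age", ancestry = c("PC1","PC2"))`; may be empty.
#' @return object of class `vc_fit`: fractions, the fitted model, the
#'   model inputs (for component tests), and a convergence flag.
#' @export
fit_lmm_components <- function(data, response, random_terms,
                               fixed_groups = list()) {
  stopifnot(response %in% names(data))
  fixed_vars <- unlist(fixed_groups, use.names = FALSE)
  for (rt in random_terms) {
    if (length(unique(data[[rt]])) < 2) {
      stop("random factor '", rt, "' has fewer than 2 levels")
    }
  }
  if (anyNA(data[[response]])) stop("missing responses not allowed")
  msgs <- character(0)
  fit <- withCallingHandlers(
    .fit_mixed(data, response, fixed_vars, random_terms, reml = TRUE),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  converged <- !any(grepl("converge", msgs, ignore.case = TRUE))

  if (inherits(fit, "merMod")) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    rand_var <- setNames(vc$vcov[match(random_terms, vc$grp)], random_terms)
    resid_var <- vc$vcov[vc$grp == "Residual"]
    X <- model.matrix(fit)
    b <- lme4::fixef(fit)
  } else {
    rand_var <- setNames(numeric(0), character(0))
    resid_var <- sum(fit$residuals^2) / fit$df.residual
    X <- model.matrix(fit)
    b <- coef(fit)
  }

  fixed_raw <- vapply(fixed_groups, function(vars) {
    cols <- unlist(lapply(vars, function(v) {
      grep(paste0("^`?", v), colnames(X), value = TRUE)
    }))
    cols <- setdiff(unique(cols), "(Intercept)")
    if (!length(cols)) return(0)
    as.numeric(var(X[, cols, drop = FALSE] %*% b[cols]))
  }, 1.0)
  nonint <- setdiff(colnames(X), "(Intercept)")
  fixed_total <- if (length(nonint)) {
    as.numeric(var(X[, nonint, drop = FALSE] %*% b[nonint]))
  } else 0
  fixed_var <- if (length(fixed_raw) && sum(fixed_raw) > 0) {
    fixed_raw * fixed_total / sum(fixed_raw)
  } else fixed_raw

  total <- sum(rand_var) + resid_var + fixed_total
  fractions <- c(rand_var, fixed_var, residual = resid_var) / total
  structure(list(
    fractions = fractions,
    total_variance = total,
    model = fit,
    data = data, response = response,
    random_terms = random_terms, fixed_groups = fixed_groups,
    converged = converged, warnings = msgs
  ), class = "vc_fit")
}

#' Likelihood-ratio test for one variance component
#'
#' Tests a random-intercept component by comparing maximum-likelihood fits
#' with and without it. Because the null value (variance zero) lies on the
#' boundary of the parameter space, the reference distribution is the
#' equal mixture of a point mass at zero and chi-square with 1 df:
#' p = 0.5 P(chi2_1 >= LRT), and p = 1 when the statistic is zero.
#'
#' @param fit a `vc_fit` from [fit_lmm_components()].
#' @param component one of the fit's random terms.
#' @return list with `statistic` and `p`.
#' @export
test_component_significance <- function(fit, component) {
  stopifnot(inherits(fit, "vc_fit"))
  if (!component %in% fit$random_terms) {
    stop("component '", component, "' is not a random term of the model")
  }
  fixed_vars <- unlist(fit$fixed_groups, use.names = FALSE)
  full <- suppressWarnings(suppressMessages(
    .fit_mixed(fit$data, fit$response, fixed_vars, fit$random_terms,
               reml = FALSE)))
  reduced <- suppressWarnings(suppressMessages(
    .fit_mixed(fit$data, fit$response, fixed_vars,
               setdiff(fit$random_terms, component), reml = FALSE)))
  stat <- max(0, 2 * (as.numeric(logLik(full)) -
                        as.numeric(logLik(reduced))))
  p <- if (stat <= 0) 1 else 0.5 * pchisq(stat, 1, lower.tail = FALSE)
  list(statistic = stat, p = p)
}

# ML likelihood-ratio test for a fixed-term group (chi-square, df = number
# of removed columns).
.test_fixed_group <- function(fit, group) {
  fixed_vars <- unlist(fit$fixed_groups, use.names = FALSE)
  reduced_vars <- unlist(fit$fixed_groups[
    setdiff(names(fit$fixed_groups), group)], use.names = FALSE)
  full <- suppressWarnings(suppressMessages(
    .fit_mixed(fit$data, fit$response, fixed_vars, fit$random_terms,
               reml = FALSE)))
  reduced <- suppressWarnings(suppressMessages(
    .fit_mixed(fit$data, fit$response, reduced_vars, fit$random_terms,
               reml = FALSE)))
  df <- attr(logLik(full), "df") - attr(logLik(reduced), "df")
  stat <- max(0, 2 * (as.numeric(logLik(full)) -
                        as.numeric(logLik(reduced))))
  list(statistic = stat, p = pchisq(stat, max(df, 1), lower.tail = FALSE))
}

#' Variance decomposition of one well-level trait
#'
#' Fits the full study design model for a gaussianized trait at well
#' level: fixed terms age, ancestry PCs 1-4 and (colony) mean neighbor
#' count; random intercepts for disease, source tissue, sex, plate, well
#' position, edge status and donor identity. Component significance is
#' assessed by likelihood-ratio tests (boundary mixture for random terms)
#' and Bonferroni-adjusted for the number of traits tested.
#'
#' @param well_matrix well-by-trait data.frame (post-INT), one context.
#' @param trait trait column to decompose.
#' @param metadata donor metadata (donor_id, sex, age, disease,
#'   source_tissue).
#' @param pcs donor x PC matrix (>= 4 columns).
#' @param context "colony" or "isolate"; colony adds the neighbor-count
#'   fixed term.
#' @param n_traits_for_correction Bonferroni denominator (number of traits
#'   analyzed; 3418 at full study scale).
#' @param test_components if FALSE skip the per-component LRTs (fractions
#'   only; much faster).
#' @return object of class `variance_decomposition` with a `table`
#'   (component, fraction, p, p_bonferroni), the underlying `vc_fit` and
#'   a convergence flag.
#' @export
fit_variance_components <- function(well_matrix, trait, metadata, pcs,
                                    context = c("colony", "isolate"),
                                    n_traits_for_correction = 1,
                                    test_components = TRUE) {
  context <- match.arg(context)
  stopifnot(trait %in% trait_names(well_matrix))
  md <- metadata[match(well_matrix$donor_id, metadata$donor_id), ,
                 drop = FALSE]
  data <- data.frame(
    y = well_matrix[[trait]],
    plate_id = factor(well_matrix$plate_id),
    well_id = factor(well_matrix$well_id),
    on_edge = factor(well_matrix$on_edge),
    donor_id = factor(well_matrix$donor_id),
    mean_neighbors = well_matrix$mean_neighbors,
    sex = factor(md$sex),
    age = as.numeric(md$age),
    disease = factor(md$disease),
    source_tissue = factor(md$source_tissue)
  )
  names(data)[1] <- trait
  pc_use <- pcs[well_matrix$donor_id, seq_len(min(4, ncol(pcs))),
                drop = FALSE]
  colnames(pc_use) <- paste0("PC", seq_len(ncol(pc_use)))
  data <- cbind(data, as.data.frame(pc_use))

  random_terms <- c("disease", "source_tissue", "sex", "plate_id",
                    "well_id", "on_edge", "donor_id")
  random_terms <- random_terms[vapply(random_terms, function(rt) {
    length(unique(data[[rt]])) >= 2
  }, TRUE)]
  fixed_groups <- list(age = "age", ancestry = colnames(pc_use))
  if (context == "colony") fixed_groups$neighbors <- "mean_neighbors"

  fit <- fit_lmm_components(data, trait, random_terms, fixed_groups)

  comp <- names(fit$fractions)
  pvals <- rep(NA_real_, length(comp))
  if (test_components) {
    for (i in seq_along(comp)) {
      if (comp[i] %in% random_terms) {
        pvals[i] <- test_component_significance(fit, comp[i])$p
      } else if (comp[i] %in% names(fixed_groups)) {
        pvals[i] <- .test_fixed_group(fit, comp[i])$p
      }
    }
  }
  table <- data.frame(
    trait = trait, context = context, component = comp,
    fraction = as.numeric(fit$fractions),
    p = pvals,
    p_bonferroni = pmin(1, pvals * n_traits_for_correction),
    stringsAsFactors = FALSE
  )
  structure(list(table = table, fit = fit, converged = fit$converged),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("variance decomposition of", x$table$trait[1],
      "(", x$table$context[1], "context )\n")
  print(x$table[c("component", "fraction", "p", "p_bonferroni")],
        row.names = FALSE, digits = 3)
  if (!x$converged) cat("NOTE: fit flagged as non-converged\n")
  invisible(x)
}
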