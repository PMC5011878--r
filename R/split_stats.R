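#' Square-root transformation policy for root traits
#'
#' Root traits (elongation rate and intercept of the crown-root model,
#' medium and maximal lateral-root lengths, lateral counts, root dry weight)
#' are square-root transformed before mixed-model analysis to approach
#' normality; shoot traits are analysed untransformed. No outliers are
#' removed. Transformed analyses stay on the transformed scale (heritability
#' and BLUPs are not back-transformed).
#'
#' @param values numeric trait values (>= 0 for transformed traits).
#' @param trait trait name; names starting with `ER_Cr`, `IC_Cr`, `Med_Lat`,
#'   `Max_Lat`, `No_Lat` or `DW_R` are transformed.
#' @return Transformed (or untouched) values.
#' @export
#' @examples
#' transform_trait(c(0, 1, 4, 9), "No_Lat_1st")  # 0 1 2 3
transform_trait <- function(values, trait) {
  if (!is_sqrt_trait(trait)) return(values)
  neg <- which(values < 0)
  if (length(neg))
    stop("value error: trait '", trait, "' has negative value(s) at record(s) ",
         paste(neg, collapse = ", "), "; square-root transform undefined",
         call. = FALSE)
  sqrt(values)
}

#' @rdname transform_trait
#' @export
is_sqrt_trait <- function(trait) {
  prefixes <- c("ER_Cr", "IC_Cr", "Med_Lat", "Max_Lat", "No_Lat", "DW_R")
  any(vapply(prefixes, function(p) startsWith(trait, p), logical(1)))
}

# traits computed and exported but excluded from the default mixed-model run
# (not normally distributed even after transformation)
non_normal_traits <- function()
  c("LBrZ", "density_1st", "density_2nd", "start_branching_zone")

#' Model specification for the split-nitrogen mixed model
#'
#' The full model for split-root observations is
#' `y = mu + G + N + G:N + R + S + GR + e`, with genotype (G), nitrogen level
#' (N), their interaction, replicate (R) and slide side (S) fixed, the
#' genotype-replication interaction GR (identifying the individual slide)
#' random, and a separate residual variance per nitrogen level. Traits with
#' one value per slide (shoot traits, SPAD) use the reduced model
#' `y = mu + G + R + e`. For heritability, genotype is treated as random.
#'
#' @param response trait name to analyse.
#' @param type `"split_root"` (full model) or `"per_slide"` (reduced model).
#' @param transform `"auto"` (square-root for the root-trait list),
#'   `"sqrt"`, or `"none"`.
#' @param genotype_random treat genotype as a random factor (heritability
#'   mode); only meaningful with per-stratum fitting via [heritability_by_n].
#' @return A `model_spec` list.
#' @export
model_spec <- function(response, type = c("split_root", "per_slide"),
                       transform = c("auto", "sqrt", "none"),
                       genotype_random = FALSE) {
  structure(list(response = response, type = match.arg(type),
                 transform = match.arg(transform),
                 genotype_random = genotype_random),
            class = "model_spec")
}

apply_transform <- function(values, spec) {
  switch(spec$transform,
         auto = transform_trait(values, spec$response),
         sqrt = transform_trait(values, paste0("No_Lat_", spec$response)),
         none = values)
}

#' Fit the split-nitrogen linear mixed model to one trait
#'
#' REML estimation of the model defined by [model_spec] on a long-format
#' [trait_table]. Fixed effects use sum-to-zero coding; each fixed term gets
#' a marginal Wald F test with containment denominator degrees of freedom
#' (terms constant within slides are tested against the slide stratum, terms
#' varying within slides against the residual stratum). Missing cells are
#' handled by the likelihood; nothing is imputed.
#'
#' @param table a [trait_table].
#' @param spec a [model_spec].
#' @return A `mixed_fit`: list with `beta`, `vcov_beta`, `anova` (term, df,
#'   ddf, F, p), `varcomp` (`sigma2_GR`, `sigma2_e` per nitrogen level),
#'   `blup_slide` (GR BLUPs), `genotype_means` (predicted means with
#'   `avsed`), `spec`, `data`, `converged`.
#' @export
fit_mixed <- function(table, spec) {
  df <- as.data.frame(table)
  df <- df[df$trait == spec$response, , drop = FALSE]
  if (nrow(df) == 0L) stop("no records for trait '", spec$response, "'",
                           call. = FALSE)
  df$value <- apply_transform(df$value, spec)
  df$G <- factor(df$genotype)
  df$R <- factor(df$replicate)
  if (nlevels(df$G) < 2L) stop("need at least 2 genotypes", call. = FALSE)

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)

  if (spec$type == "split_root") {
    df$N <- factor(df$n_level, levels = c("high", "low"))
    df$S <- factor(df$side)
    form <- if (nlevels(df$S) > 1L) ~ G + N + G:N + R + S else ~ G + N + G:N + R
    X <- stats::model.matrix(form, df)
    group <- interaction(df$G, df$R, drop = TRUE)
    fit <- reml_fit(df$value, X, group = group, stratum = df$N)
    varcomp <- list(sigma2_GR = fit$sigma2_u, sigma2_e = fit$sigma2_e)
  } else {
    form <- ~ G + R
    X <- stats::model.matrix(form, df)
    group <- NULL
    fit <- reml_fit(df$value, X, group = NULL, stratum = NULL)
    varcomp <- list(sigma2_GR = NULL, sigma2_e = fit$sigma2_e)
  }

  anova_tab <- wald_anova(fit, X, group, attr(stats::terms(form), "term.labels"))
  gm <- predicted_genotype_means(fit, X, df, spec)

  structure(list(beta = fit$beta, vcov_beta = fit$vcov_beta,
                 anova = anova_tab, varcomp = varcomp,
                 blup_slide = fit$blup, genotype_means = gm,
                 spec = spec, data = df, reml = fit,
                 converged = fit$converged),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("Linear mixed model for trait", x$spec$response, "\n")
  print(x$anova, row.names = FALSE)
  if (!is.null(x$varcomp$sigma2_GR))
    cat(sprintf("sigma2_GR = %.4g; residual: %s\n", x$varcomp$sigma2_GR,
                paste(sprintf("%s = %.4g", names(x$varcomp$sigma2_e),
                              x$varcomp$sigma2_e), collapse = ", ")))
  invisible(x)
}

# marginal (Type III, sum-to-zero) Wald F per fixed term with containment ddf
wald_anova <- function(fit, X, group, term_labels) {
  asgn <- attr(X, "assign")
  kept <- colnames(fit$vcov_beta)
  keep_idx <- match(kept, colnames(X))
  asgn_kept <- asgn[keep_idx]

  n <- fit$n
  if (!is.null(group)) {
    n_groups <- nlevels(droplevels(as.factor(group)))
    # classify columns: constant within groups -> between (slide) stratum
    const_within <- vapply(seq_along(keep_idx), function(j) {
      v <- X[, keep_idx[j]]
      all(abs(stats::ave(v, group, FUN = function(z) max(z) - min(z))) < 1e-12)
    }, logical(1))
    n_between_cols <- sum(const_within)   # includes intercept
    n_within_cols <- sum(!const_within)
    ddf_between <- n_groups - n_between_cols
    ddf_within <- n - n_groups - n_within_cols
  }

  terms_idx <- sort(unique(asgn_kept[asgn_kept > 0]))
  rows <- lapply(terms_idx, function(ti) {
    cols <- which(asgn_kept == ti)
    b <- fit$beta[cols]
    Cb <- fit$vcov_beta[cols, cols, drop = FALSE]
    q <- length(cols)
    Fval <- tryCatch(drop(crossprod(b, solve(Cb, b))) / q,
                     error = function(e) if (sum(b^2) > 0) Inf else NaN)
    if (!is.null(group)) {
      v <- X[, keep_idx[cols[1]]]
      is_between <- all(abs(stats::ave(v, group, FUN = function(z) max(z) - min(z))) < 1e-12)
      ddf <- if (is_between) ddf_between else ddf_within
    } else {
      ddf <- n - fit$p
    }
    data.frame(term = term_labels[ti], df = q, ddf = ddf, F = Fval,
               p = stats::pf(Fval, q, ddf, lower.tail = FALSE))
  })
  do.call(rbind, rows)
}

# predicted genotype (x nitrogen) means and the average SE of a difference
predicted_genotype_means <- function(fit, X, df, spec) {
  kept <- colnames(fit$vcov_beta)
  keep_idx <- match(kept, colnames(X))
  if (spec$type == "split_root") {
    cell <- interaction(df$G, df$N, sep = " x ", drop = TRUE)
  } else {
    cell <- df$G
  }
  L <- rowsum(X[, keep_idx, drop = FALSE], cell) /
    as.vector(table(cell)[levels(cell)])
  mu <- drop(L %*% fit$beta)
  Vm <- L %*% fit$vcov_beta %*% t(L)
  k <- nrow(L)
  sed <- outer(diag(Vm), diag(Vm), "+") - 2 * Vm
  sed <- sqrt(pmax(sed, 0))
  avsed <- mean(sed[lower.tri(sed)])
  data.frame(level = rownames(L), mean = mu, se = sqrt(pmax(diag(Vm), 0)),
             avsed = avsed, row.names = NULL)
}

#' Mean-based heritability
#'
#' `H2 = sigma2_g / (sigma2_g + sigma2_e / r)`: the fraction of variance
#' among genotype means that is genetic, with `r` replications. Negative
#' component estimates are clamped to 0 before forming the ratio, so a zero
#' genotypic variance gives `H2 = 0`.
#'
#' @param sigma2_g genotypic variance (scalar or vector).
#' @param sigma2_e residual variance.
#' @param r number of replications (>= 1).
#' @return Heritability in `[0, 1]`.
#' @export
#' @examples
#' heritability(3, 4, 4)  # 0.75
heritability <- function(sigma2_g, sigma2_e, r) {
  if (any(r <= 0)) stop("value error: r must be positive", call. = FALSE)
  sigma2_g <- pmax(sigma2_g, 0)
  sigma2_e <- pmax(sigma2_e, 0)
  ifelse(sigma2_g == 0, 0, sigma2_g / (sigma2_g + sigma2_e / r))
}

#' Per-nitrogen-level heritability of a root trait
#'
#' For each nitrogen level, fits the random-genotype model
#' `y = mu + R + S + g + e` (genotype random) by REML on the records of that
#' level and forms the mean-based heritability with `r` replications. This
#' realizes the heterogeneous-variance heritability analysis: genotypic and
#' residual variances are free to differ between the nitrogen levels.
#'
#' @param table a [trait_table].
#' @param trait trait name.
#' @param r number of replications; default the number of distinct
#'   replicates present.
#' @param transform `"auto"`, `"sqrt"` or `"none"` (see [model_spec]).
#' @return Data frame: `n_level`, `sigma2_g`, `sigma2_e`, `r`, `h2`.
#' @export
heritability_by_n <- function(table, trait, r = NULL,
                              transform = c("auto", "sqrt", "none")) {
  transform <- match.arg(transform)
  df <- as.data.frame(table)
  df <- df[df$trait == trait, , drop = FALSE]
  if (nrow(df) == 0L) stop("no records for trait '", trait, "'", call. = FALSE)
  spec <- model_spec(trait, transform = transform)
  df$value <- apply_transform(df$value, spec)
  levels_n <- intersect(c("high", "low", "none"), unique(df$n_level))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  rows <- lapply(levels_n, function(nl) {
    d <- df[df$n_level == nl, , drop = FALSE]
    d$R <- factor(d$replicate)
    d$S <- factor(d$side)
    form <- if (nlevels(d$S) > 1L) ~ R + S else if (nlevels(d$R) > 1L) ~ R else ~ 1
    X <- stats::model.matrix(form, d)
    fit <- reml_fit(d$value, X, group = factor(d$genotype), stratum = NULL)
    rr <- if (is.null(r)) length(unique(d$replicate)) else r
    data.frame(n_level = nl, sigma2_g = fit$sigma2_u,
               sigma2_e = unname(fit$sigma2_e[1]), r = rr,
               h2 = heritability(fit$sigma2_u, unname(fit$sigma2_e[1]), rr))
  })
  do.call(rbind, rows)
}

#' Tukey's honestly significant difference
#'
#' `HSD = q * sqrt(MSE / n)`, with `q` the studentized-range critical value
#' for the chosen significance level and degrees of freedom (supplied by the
#' caller, not computed), `MSE` the mean square error and `n` the number of
#' treatment levels. When only the average standard error of a difference
#' between predicted means (avsed) is available, `MSE = n * avsed^2 / 2`
#' recovers it (from `sed = sqrt(2 MSE / n)`).
#'
#' @param q studentized-range critical value (> 0).
#' @param mse mean square error (>= 0).
#' @param n number of treatment levels (>= 1).
#' @return The honestly significant difference.
#' @export
#' @examples
#' tukey_hsd(4, 1, 4)  # 2
tukey_hsd <- function(q, mse, n) {
  if (n < 1) stop("value error: n must be >= 1", call. = FALSE)
  if (q <= 0) stop("value error: q must be positive", call. = FALSE)
  if (mse < 0) stop("value error: mse must be non-negative", call. = FALSE)
  q * sqrt(mse / n)
}

#' @rdname tukey_hsd
#' @param avsed average standard error of a difference between predicted means.
#' @export
mse_from_avsed <- function(avsed, n) {
  if (n < 1) stop("value error: n must be >= 1", call. = FALSE)
  n * avsed^2 / 2
}

#' Genotype BLUPs per trait
#'
#' Fits, per trait, the random-genotype model (`y = mu + N + R + S + g + e`
#' for split-root traits, `y = mu + R + g + e` for per-slide traits, with
#' per-nitrogen residual variance where applicable) and extracts the genotype
#' BLUPs, the basis for diversity summaries. BLUPs are on the transformed
#' scale for square-root-transformed traits.
#'
#' @param table a [trait_table].
#' @param traits trait names; default all traits present except the
#'   non-normal exclusion list.
#' @return A genotype x trait matrix of BLUPs.
#' @export
genotype_blups <- function(table, traits = NULL) {
  df <- as.data.frame(table)
  if (is.null(traits))
    traits <- setdiff(sort(unique(df$trait)), non_normal_traits())
  genos <- sort(unique(df$genotype))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  out <- matrix(NA_real_, length(genos), length(traits),
                dimnames = list(genos, traits))
  for (tr in traits) {
    d <- df[df$trait == tr, , drop = FALSE]
    if (nrow(d) == 0L) next
    d$value <- transform_trait(d$value, tr)
    d$R <- factor(d$replicate)
    split_root <- all(d$n_level %in% c("high", "low"))
    if (split_root) {
      d$N <- factor(d$n_level, levels = c("high", "low"))
      d$S <- factor(d$side)
      form <- if (nlevels(d$S) > 1L) ~ N + R + S else ~ N + R
      X <- stats::model.matrix(form, d)
      fit <- reml_fit(d$value, X, group = factor(d$genotype), stratum = d$N)
    } else {
      form <- if (nlevels(d$R) > 1L) ~ R else ~ 1
      X <- stats::model.matrix(form, d)
      fit <- reml_fit(d$value, X, group = factor(d$genotype), stratum = NULL)
    }
    out[names(fit$blup), tr] <- fit$blup
  }
  out
}

#' Correlation and PCA summaries of genotype BLUPs
#'
#' Pearson correlations (pairwise-complete genotypes) between traits, and a
#' principal component analysis of the genotype x trait BLUP matrix: traits
#' are centred and unit-scaled, components come from the eigendecomposition
#' of the correlation matrix, and each component's sign is fixed by making
#' its largest-magnitude loading positive. Zero-variance traits are dropped
#' with a warning.
#'
#' @param blups genotype x trait matrix (e.g. from [genotype_blups]).
#' @return List with `correlations`, `loadings`, `scores`,
#'   `var_explained` (proportion per component), and `dropped`.
#' @export
blup_summaries <- function(blups) {
  stopifnot(is.matrix(blups), nrow(blups) >= 3L)
  sds <- apply(blups, 2, stats::sd, na.rm = TRUE)
  dropped <- colnames(blups)[!is.finite(sds) | sds == 0]
  if (length(dropped)) {
    warning("dropping zero-variance trait(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
    blups <- blups[, setdiff(colnames(blups), dropped), drop = FALSE]
  }
  if (ncol(blups) < 2L) stop("need at least 2 traits with variance", call. = FALSE)
  cors <- stats::cor(blups, use = "pairwise.complete.obs")
  eig <- eigen(cors, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  load <- eig$vectors
  dimnames(load) <- list(colnames(blups), paste0("PC", seq_len(ncol(load))))
  for (j in seq_len(ncol(load))) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) load[, j] <- -load[, j]
  }
  Z <- scale(blups)
  Z[is.na(Z)] <- 0  # pairwise-complete compromise for score computation
  scores <- Z %*% load
  list(correlations = cors, loadings = load, scores = scores,
       var_explained = vals / sum(vals), dropped = dropped)
}
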