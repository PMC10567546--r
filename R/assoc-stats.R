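# Statistical kernels: covariate design, genotype encodings, OLS
# association, Fisher's exact test, exact binomial, genomic inflation.

#' Build a covariate design matrix
#'
#' Constructs the fixed covariate design for one association flavour:
#'
#' * `exwas`: intercept, age, sex, age x sex, age^2, age^2 x sex, PC1-PC4,
#'   batch indicators (relative to the first batch) and the panel-specific
#'   measurement-to-sampling time offset (`panel` must name a panel with a
#'   `sample_time_<panel>` column).
#' * `collapsing`: the same age/sex/PC/batch terms without the panel time
#'   offset.
#' * `pan_ancestry`: `collapsing` plus broad-ancestry indicator columns.
#' * `ch`: `collapsing` plus `bmi` and `pack_years`.
#'
#' Constant columns and columns that are collinear with earlier ones are
#' dropped (recorded in the `"dropped"` attribute) so the returned design
#' always has full column rank.
#'
#' @param covariates Data frame with columns `sample_id`, `age`, `sex`
#'   (`"female"`/`"male"`), `pc1`..`pc4`, `batch`, and as required
#'   `ancestry`, `bmi`, `pack_years`, `sample_time_<panel>`.
#' @param flavor One of `"exwas"`, `"collapsing"`, `"pan_ancestry"`, `"ch"`.
#' @param panel Panel identifier; required for `flavor = "exwas"`.
#' @return Numeric design matrix (rows = samples, named by `sample_id`)
#'   including an intercept column, with attribute `"dropped"`.
#' @export
build_covariates <- function(covariates,
                             flavor = c("exwas", "collapsing",
                                        "pan_ancestry", "ch"),
                             panel = NULL) {
  flavor <- match.arg(flavor)
  need <- c("sample_id", "age", "sex", "pc1", "pc2", "pc3", "pc4", "batch")
  if (flavor == "pan_ancestry") need <- c(need, "ancestry")
  if (flavor == "ch") need <- c(need, "bmi", "pack_years")
  if (flavor == "exwas") {
    if (is.null(panel)) stop("flavor 'exwas' requires a panel id")
    need <- c(need, paste0("sample_time_", panel))
  }
  missing_cols <- setdiff(need, names(covariates))
  if (length(missing_cols)) {
    stop("covariate table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }

  age <- covariates$age
  sex <- as.numeric(covariates$sex == "female")
  X <- cbind(
    intercept = 1,
    age = age,
    sex = sex,
    age_sex = age * sex,
    age2 = age^2,
    age2_sex = age^2 * sex,
    pc1 = covariates$pc1, pc2 = covariates$pc2,
    pc3 = covariates$pc3, pc4 = covariates$pc4
  )
  batch <- factor(covariates$batch)
  if (nlevels(droplevels(batch)) > 1) {
    batch <- droplevels(batch)
    bm <- stats::model.matrix(~batch)[, -1, drop = FALSE]
    colnames(bm) <- sub("^batch", "batch_", colnames(bm))
    X <- cbind(X, bm)
  }
  if (flavor == "pan_ancestry") {
    anc <- factor(covariates$ancestry)
    if (nlevels(droplevels(anc)) > 1) {
      anc <- droplevels(anc)
      am <- stats::model.matrix(~anc)[, -1, drop = FALSE]
      colnames(am) <- sub("^anc", "ancestry_", colnames(am))
      X <- cbind(X, am)
    }
  }
  if (flavor == "ch") {
    X <- cbind(X, bmi = covariates$bmi, pack_years = covariates$pack_years)
  }
  if (flavor == "exwas") {
    st <- covariates[[paste0("sample_time_", panel)]]
    X <- cbind(X, sample_time = st)
  }
  rownames(X) <- covariates$sample_id

  # drop constant (beyond the intercept) then rank-deficient columns
  dropped <- character(0)
  const <- apply(X[, -1, drop = FALSE], 2, function(z) {
    all(is.na(z)) || stats::var(z, na.rm = TRUE) == 0
  })
  if (any(const)) {
    dropped <- colnames(X)[-1][const]
    X <- X[, c(TRUE, !const), drop = FALSE]
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    dropped <- c(dropped, colnames(X)[-keep])
    X <- X[, sort(keep), drop = FALSE]
  }
  attr(X, "dropped") <- dropped
  attr(X, "flavor") <- flavor
  X
}

#' Encode genotypes under a genetic model
#'
#' @param genotypes Vector of alt-allele dosages in `{0, 1, 2, NA}`.
#' @param model `"genotypic"` (additive 0/1/2 dosage), `"dominant"`
#'   (any alt allele) or `"recessive"` (homozygous alt). Missing values
#'   stay missing.
#' @return Numeric vector.
#' @export
encode_genotype <- function(genotypes,
                            model = c("genotypic", "dominant", "recessive")) {
  model <- match.arg(model)
  g <- as.numeric(genotypes)
  if (!all(g[!is.na(g)] %in% c(0, 1, 2))) {
    stop("genotype values must be 0, 1, 2 or NA")
  }
  switch(model,
         genotypic = g,
         dominant = as.numeric(g >= 1),
         recessive = as.numeric(g == 2))
}

assoc_result <- function(beta = NA_real_, se = NA_real_, ci_low = NA_real_,
                         ci_high = NA_real_, p = NA_real_, n_used = 0L,
                         n_carriers = NA_integer_, untestable = FALSE,
                         reason = "") {
  structure(list(beta = beta, se = se, ci_low = ci_low, ci_high = ci_high,
                 p = p, n_used = n_used, n_carriers = n_carriers,
                 untestable = untestable, reason = reason),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  if (x$untestable) {
    cat("<assoc_result> untestable (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf(
      "<assoc_result> beta = %.4g (95%% CI %.4g to %.4g), P = %.3g, n = %d, carriers = %d\n",
      x$beta, x$ci_low, x$ci_high, x$p, x$n_used,
      ifelse(is.na(x$n_carriers), -1L, x$n_carriers)))
  }
  invisible(x)
}

#' Linear association of a phenotype with an encoded genotype
#'
#' Ordinary least squares of `y` on `x` adjusting for a covariate design,
#' with a two-sided t-test on the genotype coefficient. Missingness is
#' handled complete-case per test. A degenerate predictor (constant after
#' complete-case filtering, or collinear with the covariates) yields an
#' `untestable` result rather than an error.
#'
#' @param y Numeric phenotype vector.
#' @param x Numeric encoded genotype / carrier vector.
#' @param covariates Optional design matrix from [build_covariates()] (or
#'   any numeric matrix; an intercept column is added if absent).
#' @return An `assoc_result` with `beta`, `se`, 95% `ci_low`/`ci_high`,
#'   two-sided `p`, `n_used` and `n_carriers` (`sum(x > 0)` among used
#'   samples).
#' @export
linear_assoc <- function(y, x, covariates = NULL) {
  stopifnot(length(y) == length(x))
  if (is.null(covariates)) {
    covariates <- matrix(1, length(y), 1, dimnames = list(NULL, "intercept"))
  }
  covariates <- as.matrix(covariates)
  if (!any(apply(covariates, 2, function(z) all(z == 1)))) {
    covariates <- cbind(intercept = 1, covariates)
  }
  stopifnot(nrow(covariates) == length(y))

  keep <- stats::complete.cases(y, x, covariates)
  y <- y[keep]; x <- x[keep]; C <- covariates[keep, , drop = FALSE]
  n <- length(y)
  n_car <- sum(x > 0)
  if (length(unique(x)) < 2) {
    return(assoc_result(n_used = n, n_carriers = as.integer(n_car),
                        untestable = TRUE, reason = "constant-genotype"))
  }
  X <- cbind(C, g = x)
  if (n <= ncol(X) + 2) {
    return(assoc_result(n_used = n, n_carriers = as.integer(n_car),
                        untestable = TRUE, reason = "insufficient-n"))
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    # x collinear with covariates (or design still deficient)
    return(assoc_result(n_used = n, n_carriers = as.integer(n_car),
                        untestable = TRUE, reason = "collinear-design"))
  }
  coefs <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  df <- n - qx$rank
  sigma2 <- sum(res^2) / df
  Ri <- chol2inv(qr.R(qx))
  xtx_inv_diag <- numeric(ncol(X))
  xtx_inv_diag[qx$pivot] <- diag(Ri)
  k <- ncol(X)
  se <- sqrt(sigma2 * xtx_inv_diag[k])
  beta <- unname(coefs[k])
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  p <- max(p, .Machine$double.xmin)  # keep p in (0, 1]
  ci <- beta + c(-1, 1) * stats::qt(0.975, df) * se
  assoc_result(beta = beta, se = se, ci_low = ci[1], ci_high = ci[2], p = p,
               n_used = n, n_carriers = as.integer(n_car))
}

# Vectorised OLS over a variant block: Y (n x P), X (n x V), C covariates.
# Requires complete data (callers route variants with missing genotypes
# through linear_assoc). Identical to per-test OLS because residualising
# both sides against C and regressing is the Frisch-Waugh-Lovell partition.
assoc_matrix <- function(Y, X, C) {
  Y <- as.matrix(Y); X <- as.matrix(X); C <- as.matrix(C)
  n <- nrow(Y)
  stopifnot(nrow(X) == n, nrow(C) == n)
  qC <- qr(C)
  Yr <- qr.resid(qC, Y)
  Xr <- qr.resid(qC, X)
  df <- n - qC$rank - 1L
  Sxx <- colSums(Xr^2)
  Syy <- colSums(Yr^2)
  Sxy <- crossprod(Xr, Yr)                    # V x P
  ok <- Sxx > n * .Machine$double.eps * 100
  beta <- sweep(Sxy, 1, ifelse(ok, Sxx, NA_real_), "/")
  rss <- pmax(outer(rep(1, length(Sxx)), Syy) - beta * Sxy, 0)
  se <- sqrt(sweep(rss / df, 1, ifelse(ok, Sxx, NA_real_), "/"))
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  p[p < .Machine$double.xmin] <- .Machine$double.xmin
  list(beta = beta, se = se, p = p, df = df, testable = ok, n = n)
}

#' Fisher's exact test for a carrier-by-case table
#'
#' Two-sided exact Fisher P-value for a 2x2 carrier/case table, with the
#' sample odds ratio computed after a Haldane-Anscombe 0.5 correction when
#' any cell is zero, and a Woolf (log-OR normal) 95% CI on the corrected
#' counts.
#'
#' @param carriers Logical (or 0/1) carrier indicator, or a 2x2 matrix of
#'   counts (rows: carrier yes/no; columns: case yes/no).
#' @param cases Logical (or 0/1) case indicator; ignored when `carriers`
#'   is a matrix.
#' @return Object of class `contingency_result` with `odds_ratio`,
#'   `ci_low`, `ci_high`, two-sided `p` and the `table` of counts. An
#'   empty margin yields an `untestable` result.
#' @export
fisher_binary_assoc <- function(carriers, cases = NULL) {
  if (is.matrix(carriers)) {
    stopifnot(all(dim(carriers) == 2), all(carriers >= 0))
    tab <- carriers
  } else {
    stopifnot(!is.null(cases), length(carriers) == length(cases))
    carrier <- as.logical(carriers); case <- as.logical(cases)
    keep <- !is.na(carrier) & !is.na(case)
    carrier <- carrier[keep]; case <- case[keep]
    tab <- matrix(c(sum(carrier & case), sum(carrier & !case),
                    sum(!carrier & case), sum(!carrier & !case)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(carrier = c("yes", "no"),
                                  case = c("yes", "no")))
  }
  res <- structure(list(odds_ratio = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_, table = tab,
                        untestable = FALSE, reason = ""),
                   class = "contingency_result")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    res$untestable <- TRUE
    res$reason <- "empty-margin"
    return(res)
  }
  res$p <- stats::fisher.test(tab)$p.value
  ct <- tab
  if (any(ct == 0)) ct <- ct + 0.5
  or <- (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])
  se_log <- sqrt(sum(1 / ct))
  res$odds_ratio <- or
  res$ci_low <- exp(log(or) - 1.96 * se_log)
  res$ci_high <- exp(log(or) + 1.96 * se_log)
  res
}

#' @export
print.contingency_result <- function(x, ...) {
  if (x$untestable) {
    cat("<contingency_result> untestable (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("<contingency_result> OR = %.3g (95%% CI %.3g to %.3g), P = %.3g\n",
                x$odds_ratio, x$ci_low, x$ci_high, x$p))
  }
  invisible(x)
}

#' Two-sided exact binomial test
#'
#' Minimum-likelihood two-sided exact binomial P-value: the sum of
#' `P(X = i)` over all outcomes `i` whose point probability does not
#' exceed that of the observed `k`, with `X ~ Binomial(n, p0)`. This is
#' the convention of [stats::binom.test()] and of most exact-test
#' software.
#'
#' @param k Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param p0 Null success probability in (0, 1).
#' @return Two-sided P-value.
#' @examples
#' binomial_two_sided(5, 5, 0.5)   # 0.0625
#' binomial_two_sided(1, 2, 0.5)   # 1
#' @export
binomial_two_sided <- function(k, n, p0) {
  stopifnot(length(k) == 1L, length(n) == 1L, length(p0) == 1L)
  if (!is.finite(n) || n < 1) stop("n must be >= 1")
  if (!is.finite(k) || k < 0 || k > n) stop("k must lie in [0, n]")
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  stats::binom.test(round(k), round(n), p = p0)$p.value
}

#' Genomic inflation factor
#'
#' Median-based genomic-control lambda: the median of the chi-square(1)
#' quantile transform of the P-values divided by the chi-square(1) median
#' (0.4549...). Lambda near 1 indicates a well-calibrated scan.
#'
#' @param pvalues Numeric vector of at least 100 P-values in (0, 1].
#' @return The inflation factor (scalar).
#' @export
lambda_gc <- function(pvalues) {
  p <- pvalues[!is.na(pvalues)]
  if (length(p) < 100) stop("lambda_gc needs at least 100 P-values")
  if (any(p <= 0 | p > 1)) stop("P-values must lie in (0, 1]")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}
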