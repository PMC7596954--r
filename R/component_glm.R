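#' Build a covariate-adjusted group design matrix
#'
#' Assembles the regression design for loading-wise group inference:
#' intercept, diagnostic group (TD = 0, autism = 1), and the requested
#' covariates. Sites are dummy-coded with the first level as reference.
#' Rows with missing values in any used column are dropped (listwise
#' deletion), which reproduces the shifting per-analysis sample sizes that
#' arise when instruments are incompletely administered.
#'
#' Supported terms: `"group"`, `"age"`, `"sex"`, `"fsiq"`, `"site"`,
#' `"adhd"`, `"age2"` (age squared), `"age_x_group"`, `"age2_x_group"`,
#' `"sex_x_group"`.
#'
#' @param table phenotype data.frame with columns `subject_id`, `group`
#'   (values `"autism"`/`"TD"`), `age`, `sex`, `fsiq`, `site`, and `adhd`
#'   (0/1, may contain NA) as needed.
#' @param terms character vector of term names; `"group"` is required.
#' @return List with `X` (numeric design matrix), `rows` (indices of
#'   retained table rows), `group_col` (column name of the group code),
#'   `terms`, and group sizes `n1` (autism), `n0` (TD).
#' @export
build_design <- function(table,
                         terms = c("group", "age", "sex", "fsiq", "site")) {
  if (!"group" %in% terms) stop("the design must include the group term")
  need <- unique(unlist(lapply(terms, function(t) switch(
    t,
    group = "group", age = "age", sex = "sex", fsiq = "fsiq", site = "site",
    adhd = "adhd", age2 = "age", age_x_group = c("age", "group"),
    age2_x_group = c("age", "group"), sex_x_group = c("sex", "group"),
    stop("unknown design term: ", t)))))
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("phenotype table lacks columns: ", paste(missing_cols, collapse = ", "))
  keep <- complete.cases(table[need])
  rows <- which(keep)
  tab <- table[rows, , drop = FALSE]

  g <- as.numeric(tab$group == "autism")
  cols <- list("(intercept)" = rep(1, nrow(tab)))
  for (t in terms) {
    cols <- c(cols, switch(
      t,
      group = list(group = g),
      age = list(age = tab$age),
      sex = list(sex = as.numeric(tab$sex == "male")),
      fsiq = list(fsiq = tab$fsiq),
      adhd = list(adhd = as.numeric(tab$adhd)),
      age2 = list(age2 = tab$age^2),
      age_x_group = list(age_x_group = tab$age * g),
      age2_x_group = list(age2_x_group = tab$age^2 * g),
      sex_x_group = list(sex_x_group = as.numeric(tab$sex == "male") * g),
      site = {
        f <- factor(tab$site)
        if (nlevels(f) > 1) {
          dm <- model.matrix(~f)[, -1, drop = FALSE]
          colnames(dm) <- paste0("site_", levels(f)[-1])
          as.list(as.data.frame(dm))
        } else list()
      }))
  }
  x <- do.call(cbind, cols)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  list(X = x, rows = rows, group_col = "group", terms = terms,
       n1 = sum(g == 1), n0 = sum(g == 0))
}

#' Per-component GLM of participant loadings on diagnosis
#'
#' Fits one ordinary-least-squares model per component, with the loading as
#' the dependent variable and the full design as regressors, and reports the
#' group coefficient with its t statistic, two-sided p value and Cohen's d
#' (`d = t * sqrt(1/n1 + 1/n2)`, the covariate-adjusted form). Loadings are
#' standardized to unit variance per column first so betas are comparable
#' across components. Multiple comparisons over components are corrected by
#' Benjamini-Hochberg FDR at level `q`.
#'
#' @param loadings N x d numeric matrix (rows in phenotype-table order; the
#'   design's retained rows are selected internally).
#' @param design output of [build_design].
#' @param q FDR level (default 0.05).
#' @param standardize z-score loading columns before fitting.
#' @return Object of class `glm_fit`: data.frame `table` with `component`,
#'   `beta`, `t`, `p`, `d`, `fdr_significant`; plus `fdr_threshold` (largest
#'   rejected p, NA when none), `df`, `n1`, `n2`, `q`.
#' @export
fit_loading_glm <- function(loadings, design, q = 0.05, standardize = TRUE) {
  y <- as.matrix(loadings)[design$rows, , drop = FALSE]
  if (standardize) y <- zscore_cols(y)
  x <- design$X
  n <- nrow(x)
  rk <- qr(x)$rank
  df <- n - rk
  if (df < 1) stop("no residual degrees of freedom (N - rank(design) < 1)")
  xtx_inv <- chol2inv(chol(crossprod(x)))
  beta_all <- xtx_inv %*% crossprod(x, y)
  resid <- y - x %*% beta_all
  sigma2 <- colSums(resid^2) / df
  gi <- match(design$group_col, colnames(x))
  se <- sqrt(sigma2 * xtx_inv[gi, gi])
  beta <- beta_all[gi, ]
  tt <- beta / se
  p <- 2 * pt(-abs(tt), df)
  d <- tt * sqrt(1 / design$n1 + 1 / design$n0)
  fdr <- fdr_bh(p, q)
  comp <- colnames(loadings) %||% sprintf("IC%02d", seq_along(p))
  structure(
    list(table = data.frame(component = comp, beta = beta, t = tt, p = p,
                            d = d,
                            fdr_significant = seq_along(p) %in% fdr$rejected,
                            row.names = NULL, stringsAsFactors = FALSE),
         fdr_threshold = fdr$threshold, df = df,
         n1 = design$n1, n2 = design$n0, q = q, terms = design$terms,
         n_used = n),
    class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("glm_fit:", nrow(x$table), "components, N =", x$n_used,
      "(", x$n1, "autism /", x$n2, "TD ), df =", x$df, "\n")
  sig <- x$table[x$table$fdr_significant, , drop = FALSE]
  cat(" ", nrow(sig), "FDR-significant at q =", x$q,
      if (!is.na(x$fdr_threshold))
        paste0("(threshold p <= ", signif(x$fdr_threshold, 4), ")") else "",
      "\n")
  invisible(x)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Returns the indices rejected at level `q` and the largest rejected raw
#' p value (the realized threshold).
#'
#' @param pvals numeric vector of p values in `[0, 1]`.
#' @param q FDR level.
#' @return List with `rejected` (integer indices) and `threshold` (largest
#'   rejected p, `NA` if none).
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) return(list(rejected = integer(0), threshold = NA_real_))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  adj <- p.adjust(pvals, method = "BH")
  rej <- which(adj <= q)
  list(rejected = rej,
       threshold = if (length(rej)) max(pvals[rej]) else NA_real_)
}

#' Write GLM results as TSV plus a JSON provenance sidecar
#'
#' @param fit a `glm_fit`.
#' @param path output TSV path; the sidecar is written alongside with
#'   extension `.json`.
#' @return Invisibly, the two paths.
#' @export
write_glm <- function(fit, path) {
  write.table(fit$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(
    list(terms = fit$terms, n_used = fit$n_used, n_autism = fit$n1,
         n_td = fit$n2, df = fit$df, q = fit$q,
         fdr_threshold = fit$fdr_threshold),
    side, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(path, side))
}
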