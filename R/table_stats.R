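#' Two-sample t test from printed group summaries
#'
#' Recomputes a two-sample t test from group sizes, means and standard
#' deviations, as needed to check published demographic tables. `pooled`
#' uses Student's t with `df = n1 + n2 - 2`; `welch` uses the Satterthwaite
#' approximation. With both sds zero and equal means the statistic is
#' undefined and returned as `NA` with `p = NA`.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2,
                         variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(n1 > 1, n2 > 1, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2)
      return(list(t = NA_real_, df = NA_real_, p = NA_real_))
    return(list(t = sign(mean1 - mean2) * Inf,
                df = if (variant == "pooled") n1 + n2 - 2 else NA_real_,
                p = 0))
  }
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tt <- (mean1 - mean2) / se
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

#' Chi-square test of independence on a 2x2 table
#'
#' Computes `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` without continuity
#' correction by default (the form that reproduces published sex and
#' comorbidity contrasts exactly); the Yates-corrected variant subtracts
#' `N/2` from `|ad - bc|` first. p from the chi-square distribution with 1
#' degree of freedom.
#'
#' @param counts 2x2 matrix of non-negative integer counts.
#' @param yates apply the continuity correction.
#' @return List with `chisq` and `p`.
#' @export
chi_square_2x2 <- function(counts, yates = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("counts must be a 2x2 table")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  a <- counts[1, 1]; b <- counts[1, 2]; c <- counts[2, 1]; d <- counts[2, 2]
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("zero margin in 2x2 table")
  num <- abs(a * d - b * c)
  if (yates) num <- max(num - n / 2, 0)
  chisq <- n * num^2 / prod(margins)
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Group comparison table from a phenotype data.frame
#'
#' Emits a demographic-table-style summary: for each numeric variable the
#' per-group mean and sd with the two-sample t test, and for each
#' categorical variable the counts with the chi-square test.
#'
#' @param table phenotype data.frame with a `group` column
#'   (`"autism"`/`"TD"`).
#' @param numeric_vars numeric columns to compare (default `age`, `fsiq`).
#' @param categorical_vars binary columns to compare (default `sex`,
#'   `adhd`).
#' @param variant t-test variant, `"pooled"` or `"welch"`.
#' @return data.frame with one row per variable: `variable`, `statistic`
#'   (`t` or `chisq`), `value`, `p`, and per-group summaries.
#' @export
table1_stats <- function(table, numeric_vars = c("age", "fsiq"),
                         categorical_vars = c("sex", "adhd"),
                         variant = "pooled") {
  g1 <- table$group == "autism"
  rows <- list()
  for (v in intersect(numeric_vars, names(table))) {
    x1 <- table[[v]][g1]
    x2 <- table[[v]][!g1]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    tt <- two_sample_t(mean(x1), sd(x1), length(x1),
                       mean(x2), sd(x2), length(x2), variant = variant)
    rows[[v]] <- data.frame(variable = v, statistic = "t", value = tt$t,
                            p = tt$p, mean1 = mean(x1), sd1 = sd(x1),
                            n1 = length(x1), mean2 = mean(x2), sd2 = sd(x2),
                            n2 = length(x2))
  }
  for (v in intersect(categorical_vars, names(table))) {
    f <- factor(table[[v]])
    ok <- !is.na(table[[v]])
    tab <- table(factor(g1[ok], levels = c(TRUE, FALSE)), f[ok])
    if (ncol(tab) == 2) {
      cs <- chi_square_2x2(as.matrix(tab))
      rows[[v]] <- data.frame(variable = v, statistic = "chisq",
                              value = cs$chisq, p = cs$p,
                              mean1 = NA, sd1 = NA, n1 = sum(tab[1, ]),
                              mean2 = NA, sd2 = NA, n2 = sum(tab[2, ]))
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
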