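# Population-level trait statistics: descriptive summaries with the
# SPSS-style bias-corrected G1 skewness and G2 excess kurtosis, a combined
# Shapiro-Wilk + moment-rule normality assessment, and Pearson correlations.

g1_skewness <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  m3 <- mean((x - mean(x))^3)
  if (m2 == 0) return(0)
  g1 <- m3 / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

g2_kurtosis <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  m4 <- mean((x - mean(x))^4)
  if (m2 == 0) return(0)
  g2 <- m4 / m2^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

#' Descriptive summary of one trait
#'
#' Sample mean and SD (n-1 denominator), CV as `100 * sd / mean`, the
#' bias-corrected Fisher-Pearson G1 skewness and G2 excess kurtosis, the
#' Shapiro-Wilk p-value, and a moment-rule normality flag
#' (`|G1| < 3` and `|G2| < 10`).
#'
#' @param values numeric vector, n >= 3 finite values; missing values are
#'   dropped. The mean must be positive for the CV.
#' @param name trait name carried in the output.
#' @return One-row data.frame of class `trait_summary` with columns
#'   trait_name, n, minimum, maximum, mean, sd, cv_percent, skewness,
#'   kurtosis, shapiro_p, normal_flag.
#' @export
summarize_trait <- function(values, name = "trait") {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) stop("insufficient-data error: need at least 3 finite values")
  mu <- mean(values)
  s <- stats::sd(values)
  if (mu <= 0) stop("undefined-CV error: mean must be positive")
  sw <- if (s > 0) stats::shapiro.test(values)$p.value else NA_real_
  sk <- g1_skewness(values)
  ku <- if (n > 3) g2_kurtosis(values) else NA_real_
  out <- data.frame(
    trait_name = name, n = n,
    minimum = min(values), maximum = max(values),
    mean = mu, sd = s, cv_percent = 100 * s / mu,
    skewness = sk, kurtosis = ku,
    shapiro_p = sw,
    normal_flag = abs(sk) < 3 && (is.na(ku) || abs(ku) < 10),
    stringsAsFactors = FALSE
  )
  class(out) <- c("trait_summary", class(out))
  out
}

#' Summaries for every trait column of a trait table
#'
#' @param trait_table data.frame; all columns except `line_id`/`grain_id`
#'   are summarized.
#' @return data.frame with one row per trait.
#' @export
summarize_traits <- function(trait_table) {
  traits <- setdiff(names(trait_table), c("line_id", "grain_id"))
  do.call(rbind, lapply(traits, function(nm)
    summarize_trait(trait_table[[nm]], nm)))
}

#' Normality assessment combining Shapiro-Wilk and the moment rule
#'
#' Reports both verdicts separately: the Shapiro-Wilk test at `alpha`, and
#' the skewness/kurtosis rule (`|skewness| < 3` and `|kurtosis| < 10`).
#'
#' @param summary a one-row [summarize_trait()] result (or a data.frame with
#'   `skewness`, `kurtosis`, `shapiro_p`).
#' @param alpha significance level for Shapiro-Wilk.
#' @return data.frame with trait_name, shapiro_reject, rule_normal.
#' @export
normality_assessment <- function(summary, alpha = 0.05) {
  stopifnot(all(c("skewness", "kurtosis", "shapiro_p") %in% names(summary)))
  data.frame(
    trait_name = if ("trait_name" %in% names(summary)) summary$trait_name else NA,
    shapiro_reject = !is.na(summary$shapiro_p) & summary$shapiro_p < alpha,
    rule_normal = abs(summary$skewness) < 3 &
      (is.na(summary$kurtosis) | abs(summary$kurtosis) < 10),
    stringsAsFactors = FALSE
  )
}

#' Pearson correlation matrix with pairwise test p-values
#'
#' Complete cases only (rows with any missing value are dropped; the count
#' is reported as an attribute). Zero-variance columns are flagged and
#' their correlations reported as `NA`.
#'
#' @param trait_table data.frame of numeric trait columns (id columns are
#'   ignored); n >= 3 complete rows required.
#' @return list with `r` (symmetric correlation matrix, unit diagonal),
#'   `p` (two-sided t-test p-values, `NA` diagonal), `n_used`, and
#'   `zero_variance` (character vector of flagged columns).
#' @export
correlation_matrix <- function(trait_table) {
  num <- trait_table[, setdiff(names(trait_table), c("line_id", "grain_id")),
                     drop = FALSE]
  num <- num[, vapply(num, is.numeric, logical(1)), drop = FALSE]
  cc <- stats::complete.cases(num)
  dropped <- sum(!cc)
  num <- num[cc, , drop = FALSE]
  n <- nrow(num)
  if (n < 3) stop("insufficient-data error: need at least 3 complete rows")
  p <- ncol(num)
  sds <- vapply(num, stats::sd, numeric(1))
  zerovar <- names(num)[sds == 0]
  r <- suppressWarnings(stats::cor(num))
  diag(r) <- 1
  r[sds == 0, ] <- NA; r[, sds == 0] <- NA
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pmat <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  pmat[r == 1 | r == -1] <- 0
  diag(pmat) <- NA
  structure(list(r = r, p = pmat, n_used = n, zero_variance = zerovar),
            class = "trait_correlations", dropped_rows = dropped)
}

#' @export
print.trait_correlations <- function(x, ...) {
  cat(sprintf("<trait_correlations> %d traits, n = %d complete rows\n",
              ncol(x$r), x$n_used))
  if (length(x$zero_variance))
    cat("  zero-variance columns:", paste(x$zero_variance, collapse = ", "), "\n")
  print(round(x$r, 3))
  invisible(x)
}
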