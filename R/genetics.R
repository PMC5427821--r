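#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Pearson chi-square test (1 degree of freedom, no continuity
#' correction) of observed genotype counts against the expectations
#' \eqn{n p^2, 2np(1-p), n(1-p)^2} under the allele frequency estimated
#' from the same counts. An exact test (summing the conditional
#' probabilities of all heterozygote counts no more probable than the
#' observed one, given the allele counts) is available as an option.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (reference
#'   homozygote, heterozygote, alternate homozygote).
#' @param method `"chisq"` (default) or `"exact"`.
#' @return A list with `chisq`, `df`, `p`, the estimated risk-allele
#'   frequency `maf`, and the expected counts. For the exact test
#'   `chisq` is `NA`.
#' @examples
#' hwe_test(25, 50, 25)   # exact HWE proportions: chisq 0, p 1
#' hwe_test(30, 40, 30)   # chisq 4, p 0.0455
#' @export
hwe_test <- function(n_hom_ref, n_het, n_hom_alt,
                     method = c("chisq", "exact")) {
  method <- match.arg(method)
  obs <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(obs < 0) || any(obs != round(obs)))
    stop("genotype counts must be nonnegative integers")
  n <- sum(obs)
  if (n == 0) stop("all genotype counts are zero")
  p <- (2 * n_hom_alt + n_het) / (2 * n)   # alternate-allele frequency
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)

  if (method == "chisq") {
    if (p == 0 || p == 1) {
      # monomorphic: observed equals expected by construction
      return(list(chisq = 0, df = 1L, p = 1, maf = p, expected = expd))
    }
    chisq <- sum((obs - expd)^2 / expd)
    return(list(chisq = chisq, df = 1L,
                p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
                maf = p, expected = expd))
  }

  # exact test: condition on the number of alternate alleles
  na <- 2 * n_hom_alt + n_het
  nb <- 2 * n - na
  hets <- seq(na %% 2, min(na, nb), by = 2)
  logprob <- lgamma(n + 1) - lgamma((na - hets) / 2 + 1) -
    lgamma(hets + 1) - lgamma((nb - hets) / 2 + 1) +
    hets * log(2) + lgamma(na + 1) + lgamma(nb + 1) - lgamma(2 * n + 1)
  prob <- exp(logprob - max(logprob))
  prob <- prob / sum(prob)
  pval <- sum(prob[prob <= prob[match(n_het, hets)] * (1 + 1e-12)])
  list(chisq = NA_real_, df = NA_integer_, p = min(pval, 1), maf = p,
       expected = expd)
}

#' Count genotypes of an allele-count vector
#'
#' @param g vector of risk-allele counts in \{0, 1, 2\} (NA allowed).
#' @return Counts `(n_hom_ref, n_het, n_hom_alt)` over non-missing
#'   entries.
#' @export
genotype_counts <- function(g) {
  g <- g[!is.na(g)]
  if (!all(g %in% 0:2)) stop("allele counts must be 0, 1, 2 or missing")
  c(n_hom_ref = sum(g == 0), n_het = sum(g == 1), n_hom_alt = sum(g == 2))
}

#' Build the genotype risk score
#'
#' The score is the per-subject sum of resistin-increasing alleles across
#' the two SNPs (0-4). Subjects with any missing genotype get a missing
#' score and are excluded from score-based analyses (complete-case
#' policy). Scores at or above the pooling threshold (default 3) are
#' pooled into a single top category, giving categories 0, 1, 2, "3+".
#'
#' @param table a cohort data.frame with integer columns `g1`, `g2`.
#' @param pool_at scores `>= pool_at` are pooled (default 3).
#' @return An object of class `grs_profile`: list with `score`
#'   (integer, NA for incomplete genotypes), `category` (factor with the
#'   pooled top level), `category_counts`, `n_genotyped`, `n_excluded`,
#'   and `pool_at`.
#' @examples
#' d <- data.frame(g1 = c(2, 1, 0), g2 = c(2, NA, 1))
#' build_grs(d)$category
#' @export
build_grs <- function(table, pool_at = 3) {
  for (col in c("g1", "g2")) {
    if (!col %in% names(table)) stop("table lacks genotype column ", col)
    bad <- !is.na(table[[col]]) & !table[[col]] %in% 0:2
    if (any(bad))
      stop("allele counts outside {0,1,2} in column ", col, ", rows: ",
           paste(utils::head(which(bad), 5), collapse = ", "))
  }
  score <- table$g1 + table$g2
  max_score <- 4L
  labels <- c(as.character(0:(pool_at - 1)), paste0(pool_at, "+"))
  category <- cut(score, breaks = c(seq(0, pool_at) - 0.5, max_score + 0.5),
                  labels = labels)
  counts <- table(category)
  structure(list(
    score = as.integer(score),
    category = category,
    category_counts = counts,
    n_genotyped = sum(!is.na(score)),
    n_excluded = sum(is.na(score)),
    pool_at = pool_at
  ), class = "grs_profile")
}

#' @export
print.grs_profile <- function(x, ...) {
  cat("Genotype risk score profile\n")
  cat(sprintf("  genotyped: %d; excluded (incomplete genotypes): %d\n",
              x$n_genotyped, x$n_excluded))
  print(x$category_counts)
  invisible(x)
}

#' Test balance of confounders across the genotype risk score
#'
#' A valid instrument must be independent of the confounders of the
#' exposure-outcome relationship. For each covariate this computes the
#' p-value of its association with the risk score: a linear-model slope
#' test for continuous covariates and a chi-square trend test
#' ([stats::prop.trend.test()]) for binary ones. Constant covariates are
#' flagged with an `NA` p-value rather than an error.
#'
#' @param table cohort data.frame.
#' @param grs a [build_grs()] profile on the same rows.
#' @param covariates character vector of covariate column names.
#' @return data.frame with columns `covariate`, `type`, `p`, `note`.
#' @export
confounder_balance <- function(table, grs, covariates) {
  if (length(covariates) == 0) stop("empty covariate list")
  score <- grs$score
  rows <- lapply(covariates, function(cv) {
    if (!cv %in% names(table)) stop("covariate column missing: ", cv)
    x <- table[[cv]]
    keep <- !is.na(score) & !is.na(x)
    xs <- x[keep]; ss <- score[keep]
    if (is.character(xs)) xs <- factor(xs)
    if (is.factor(xs)) xs <- as.numeric(xs) - 1
    if (is.logical(xs)) xs <- as.numeric(xs)
    binary <- all(xs %in% c(0, 1))
    if (length(unique(xs)) < 2)
      return(data.frame(covariate = cv, type = if (binary) "binary" else "continuous",
                        p = NA_real_, note = "constant covariate",
                        stringsAsFactors = FALSE))
    if (binary) {
      tab <- table(factor(ss, levels = sort(unique(ss))), xs)
      tt <- stats::prop.trend.test(tab[, "1"], rowSums(tab),
                                   score = as.numeric(rownames(tab)))
      data.frame(covariate = cv, type = "binary", p = tt$p.value,
                 note = "", stringsAsFactors = FALSE)
    } else {
      fit <- stats::lm(xs ~ ss)
      p <- summary(fit)$coefficients["ss", "Pr(>|t|)"]
      data.frame(covariate = cv, type = "continuous", p = p,
                 note = "", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
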