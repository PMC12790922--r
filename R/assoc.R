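#' Exact Hardy-Weinberg equilibrium test
#'
#' Standard exact conditional test on the heterozygote count given the
#' allele counts: the p-value sums the probabilities of all heterozygote
#' counts (same parity as the minor-allele count) whose conditional
#' probability does not exceed that of the observed configuration. No mid-p
#' correction. Monomorphic sites have p = 1.
#'
#' @param n_AA,n_Aa,n_aa Non-negative genotype counts.
#' @return Exact p-value in (0, 1].
#' @export
#' @examples
#' hwe_exact_p(25, 50, 25)
#' hwe_exact_p(50, 0, 50) # extreme heterozygote deficit
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) abort("genotype counts must be >= 0.")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) abort("at least one genotyped individual is required.")
  n_a <- 2 * n_aa + n_Aa
  n_A <- 2 * n_AA + n_Aa
  n_r <- min(n_a, n_A)
  n_c <- max(n_a, n_A)
  if (n_r == 0) return(1)
  h_vals <- seq(n_r %% 2, n_r, by = 2)
  ## log P(h | n, n_r) up to the shared constant n_r! n_c! n! / (2n)!.
  logp <- h_vals * log(2) -
    lfactorial((n_c - h_vals) / 2) -
    lfactorial(h_vals) -
    lfactorial((n_r - h_vals) / 2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, h_vals)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Chi-square Hardy-Weinberg test
#'
#' One-degree-of-freedom goodness-of-fit alternative to [hwe_exact_p()],
#' without continuity correction.
#'
#' @inheritParams hwe_exact_p
#' @return P-value.
#' @export
hwe_chisq_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p %in% c(0, 1)) return(1)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

## Genotype counts (AA, Aa, aa) from a dosage vector (alt-allele counts),
## ignoring missing entries.
dosage_counts <- function(g) {
  g <- g[!is.na(g)]
  c(n_AA = sum(g == 0), n_Aa = sum(g == 1), n_aa = sum(g == 2))
}

#' Filter a genotype dosage matrix for association analysis
#'
#' Applies the standard genotype-quality chain, sample filter first:
#' samples with call rate at or below `min_sample_call_rate` are dropped,
#' then variants with call rate at or below `min_variant_call_rate`, minor
#' allele frequency (computed on non-missing dosages) not above `min_maf`,
#' or exact Hardy-Weinberg p-value below `min_hwe_p` are dropped. Every drop
#' carries a reason code.
#'
#' @param gmat Numeric matrix, samples in rows, variants in columns, entries
#'   in \{0, 1, 2, NA\}.
#' @param min_variant_call_rate,min_sample_call_rate Call-rate bounds
#'   (default 0.9, strict >).
#' @param min_maf Minor-allele-frequency bound (default 0.05, strict >).
#' @param min_hwe_p Variants with HWE p below this are dropped
#'   (default 1e-6; p equal to the bound is kept).
#' @param hwe_test `"exact"` (default) or `"chisq"`.
#' @return List with `gmat` (filtered matrix), `dropped_samples` and
#'   `dropped_variants` (tibbles of id + reason).
#' @export
filter_genotypes <- function(gmat, min_variant_call_rate = 0.9,
                             min_sample_call_rate = 0.9, min_maf = 0.05,
                             min_hwe_p = 1e-6,
                             hwe_test = c("exact", "chisq")) {
  hwe_test <- match.arg(hwe_test)
  hwe_fun <- if (hwe_test == "exact") hwe_exact_p else hwe_chisq_p
  sample_cr <- rowMeans(!is.na(gmat))
  drop_s <- sample_cr <= min_sample_call_rate
  if (all(drop_s)) abort("all samples dropped by the sample call-rate filter.")
  g <- gmat[!drop_s, , drop = FALSE]

  var_cr <- colMeans(!is.na(g))
  af <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hwe_p <- apply(g, 2, function(col) {
    cnt <- dosage_counts(col)
    if (sum(cnt) == 0) return(1)
    hwe_fun(cnt[1], cnt[2], cnt[3])
  })
  reason <- dplyr::case_when(
    var_cr <= min_variant_call_rate ~ "call_rate",
    maf <= min_maf ~ "maf",
    hwe_p < min_hwe_p ~ "hwe",
    TRUE ~ NA_character_
  )
  keep <- is.na(reason)
  list(
    gmat = g[, keep, drop = FALSE],
    dropped_samples = tibble::tibble(
      sample_id = rownames(gmat)[drop_s] %||% which(drop_s),
      reason = "sample_call_rate"),
    dropped_variants = tibble::tibble(
      variant_id = (colnames(gmat) %||% seq_len(ncol(gmat)))[!keep],
      reason = reason[!keep])
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select common mtDNA variants as heteroplasmy phenotypes
#'
#' Chooses mtDNA variants whose carrier frequency among the supplied
#' (unrelated) samples is at least `min_freq` (5%) and builds one continuous
#' phenotype per variant: each sample's heteroplasmic level (VAF), with 0
#' for non-carriers.
#'
#' @param calls Filtered call tibble from [filter_variant_calls()].
#' @param samples Character vector of unrelated sample ids (supplied
#'   externally; relatedness inference is out of scope).
#' @param min_freq Minimum carrier frequency (default 0.05, inclusive).
#' @return Wide tibble: `sample_id` plus one column per selected variant
#'   (named like `m.4769A>G`), values in `[0, 1]`.
#' @export
select_mt_phenotypes <- function(calls, samples, min_freq = 0.05) {
  calls <- dplyr::filter(calls, .data$sample_id %in% samples)
  keep <- calls |>
    dplyr::count(.data$pos, .data$ref, .data$alt) |>
    dplyr::filter(.data$n / length(samples) >= min_freq)
  base <- tibble::tibble(sample_id = samples)
  if (nrow(keep) == 0L) return(base)
  calls |>
    dplyr::semi_join(keep, by = c("pos", "ref", "alt")) |>
    dplyr::mutate(variant_id = sprintf("m.%d%s>%s", .data$pos, .data$ref,
                                       .data$alt)) |>
    dplyr::select("sample_id", "variant_id", "vaf") |>
    tidyr::pivot_wider(names_from = "variant_id", values_from = "vaf",
                       values_fill = 0, values_fn = max) |>
    dplyr::right_join(base, by = "sample_id") |>
    dplyr::mutate(dplyr::across(-"sample_id", function(x) tidyr::replace_na(x, 0))) |>
    dplyr::relocate("sample_id") |>
    dplyr::arrange(match(.data$sample_id, samples))
}

#' Principal components of the genotype matrix
#'
#' Column-standardised PCA of the dosage matrix for population-structure
#' covariates. Missing dosages are mean-imputed for the PCA only;
#' zero-variance columns are dropped before standardisation. The sign of
#' each component is fixed by making its largest-magnitude loading
#' positive.
#'
#' @param gmat Numeric dosage matrix (samples x variants).
#' @param k Number of components (default 12).
#' @return Numeric matrix of PC scores (samples x k), columns `PC1..PCk`.
#' @export
genotype_pca <- function(gmat, k = 12) {
  imputed <- apply(gmat, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  v <- apply(imputed, 2, stats::var)
  imputed <- imputed[, v > 0, drop = FALSE]
  if (ncol(imputed) == 0L) abort("no variant has nonzero variance; PCA undefined.")
  pc <- prcomp(imputed, center = TRUE, scale. = TRUE)
  rank <- sum(pc$sdev > 1e-8)
  if (k > rank) {
    abort(sprintf("requested k = %d components but the matrix has rank %d.",
                  k, rank))
  }
  if (k == 0L) {
    return(matrix(numeric(0), nrow = nrow(gmat), ncol = 0))
  }
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Association scan of a heteroplasmy phenotype against nuclear dosages
#'
#' For every nuclear variant, fits ordinary least squares of the continuous
#' phenotype on the dosage plus an intercept and the covariate block
#' (typically the top genotype PCs and sex), and tests the dosage
#' coefficient with a two-sided Wald t-test. Benjamini-Hochberg q-values are
#' computed across the scan. Variants whose dosage is constant or collinear
#' with the covariates are reported with `NA` statistics rather than
#' dropped. Samples with a missing dosage at a variant are excluded from
#' that variant's fit only.
#'
#' @param phenotype Numeric vector (one value per row of `gmat`).
#' @param gmat Numeric dosage matrix, samples x variants.
#' @param covariates Numeric matrix or data frame of covariates (may have
#'   zero columns).
#' @param mt_variant Label of the mtDNA phenotype carried into the results.
#' @return An object of class `mt_assoc_scan`: list with `results` (tibble
#'   of `mt_variant`, `ndna_variant`, `n`, `beta`, `se`, `t_stat`,
#'   `p_value`, `q_value`) and `meta`. Use [generics::tidy()],
#'   [generics::glance()] or `autoplot()` on it.
#' @export
glm_scan <- function(phenotype, gmat, covariates = NULL,
                     mt_variant = "phenotype") {
  n <- length(phenotype)
  if (nrow(gmat) != n) abort("phenotype length must match nrow(gmat).")
  X0 <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates) && NCOL(covariates) > 0L) {
    X0 <- cbind(X0, as.matrix(covariates))
  }
  if (qr(X0)$rank < ncol(X0)) abort("covariates are rank deficient.")
  p0 <- ncol(X0)

  ids <- colnames(gmat) %||% paste0("var", seq_len(ncol(gmat)))
  complete_base <- !is.na(phenotype) & stats::complete.cases(X0)

  ## Fast path (no missing dosages): residualise phenotype and dosages
  ## against the covariate block once (Frisch-Waugh-Lovell); the slope on
  ## residualised variables equals the full-model dosage coefficient, with
  ## df = n - p0 - 1.
  q_full <- qr(X0[complete_base, , drop = FALSE])
  ry_full <- qr.resid(q_full, phenotype[complete_base])
  fit_one <- function(g) {
    ok <- complete_base & !is.na(g)
    m <- sum(ok)
    if (m <= p0 + 1L) return(c(m, NA, NA, NA, NA))
    gv <- g[ok]
    if (stats::var(gv) == 0) return(c(m, NA, NA, NA, NA))
    if (m == sum(complete_base)) {
      q <- q_full
      ry <- ry_full
    } else {
      q <- qr(X0[ok, , drop = FALSE])
      ry <- qr.resid(q, phenotype[ok])
    }
    rg <- qr.resid(q, gv)
    sgg <- sum(rg^2)
    if (sgg < 1e-12) return(c(m, NA, NA, NA, NA)) # collinear with covariates
    beta <- sum(rg * ry) / sgg
    rss <- sum((ry - beta * rg)^2)
    df <- m - p0 - 1L
    se <- sqrt(rss / df / sgg)
    tval <- beta / se
    c(m, beta, se, tval, 2 * pt(-abs(tval), df))
  }
  stats_mat <- unname(apply(gmat, 2, fit_one))
  res <- tibble::tibble(
    mt_variant = mt_variant,
    ndna_variant = ids,
    n = as.integer(stats_mat[1, ]),
    beta = as.numeric(stats_mat[2, ]),
    se = as.numeric(stats_mat[3, ]),
    t_stat = as.numeric(stats_mat[4, ]),
    p_value = as.numeric(stats_mat[5, ]),
    q_value = p.adjust(as.numeric(stats_mat[5, ]), method = "BH")
  )
  structure(
    list(results = res,
         meta = list(mt_variant = mt_variant, n_samples = n,
                     n_variants = ncol(gmat), n_covariates = p0 - 1L)),
    class = "mt_assoc_scan")
}

#' Multiple-testing thresholds for the mtDNA-nDNA scan
#'
#' The scan tests `n_mt` mtDNA phenotypes, so the per-scan significance
#' levels are divided by `n_mt`: the primary threshold is `alpha / n_mt`
#' applied to BH q-values, and the stringent threshold is the genome-wide
#' level `gw / n_mt` applied to raw p-values. With the defaults and
#' `n_mt = 93` these are 5.4e-4 and 5.4e-10 at two significant figures.
#'
#' @param alpha FDR level (default 0.05).
#' @param gw Genome-wide significance level (default 5e-8).
#' @param n_mt Number of mtDNA phenotypes tested (default 93).
#' @return Named list `primary`, `stringent`.
#' @export
#' @examples
#' significance_thresholds(n_mt = 93)
significance_thresholds <- function(alpha = 0.05, gw = 5e-8, n_mt = 93) {
  if (n_mt < 1) abort("n_mt must be at least 1.")
  list(primary = alpha / n_mt, stringent = gw / n_mt)
}

#' Flag significant associations
#'
#' Adds `significant_primary` (BH q-value below the primary threshold — the
#' published rule applies the FDR-adjusted value against `alpha / n_mt`; set
#' `bonferroni = TRUE` for the conventional alternative of raw p against the
#' same divisor) and `significant_stringent` (raw p below `gw / n_mt`).
#'
#' @param scan An `mt_assoc_scan` object or its results tibble.
#' @param thresholds From [significance_thresholds()].
#' @param bonferroni Apply the primary threshold to raw p-values instead of
#'   q-values.
#' @return Results tibble with the two flag columns.
#' @export
flag_significant <- function(scan, thresholds = significance_thresholds(),
                             bonferroni = FALSE) {
  res <- if (inherits(scan, "mt_assoc_scan")) scan$results else scan
  primary_stat <- if (bonferroni) res$p_value else res$q_value
  dplyr::mutate(res,
                significant_primary = primary_stat < thresholds$primary,
                significant_stringent = .data$p_value < thresholds$stringent)
}

#' @export
print.mt_assoc_scan <- function(x, ...) {
  cat(sprintf(
    "<mt_assoc_scan> %s: %d nuclear variants, %d samples, %d covariates\n",
    x$meta$mt_variant, x$meta$n_variants, x$meta$n_samples,
    x$meta$n_covariates))
  print(utils::head(dplyr::arrange(x$results, .data$p_value), 5))
  invisible(x)
}

#' Tidy an association scan
#'
#' @param x An `mt_assoc_scan` object.
#' @param ... Unused.
#' @return The per-variant results tibble.
#' @method tidy mt_assoc_scan
#' @export
tidy.mt_assoc_scan <- function(x, ...) x$results

#' One-row summary of an association scan
#'
#' Includes the genomic-control inflation factor lambda (median chi-square
#' of the scan over the null median).
#'
#' @param x An `mt_assoc_scan` object.
#' @param ... Unused.
#' @return One-row tibble: `mt_variant`, `n_samples`, `n_variants`,
#'   `n_tested`, `lambda_gc`, `min_p`.
#' @method glance mt_assoc_scan
#' @export
glance.mt_assoc_scan <- function(x, ...) {
  p <- x$results$p_value
  chisq <- stats::qchisq(1 - p[!is.na(p)], df = 1)
  tibble::tibble(
    mt_variant = x$meta$mt_variant,
    n_samples = x$meta$n_samples,
    n_variants = x$meta$n_variants,
    n_tested = sum(!is.na(p)),
    lambda_gc = stats::median(chisq) / stats::qchisq(0.5, df = 1),
    min_p = suppressWarnings(min(p, na.rm = TRUE))
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
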