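# Per-site summaries, sample outlier exclusion, dosage PCA and the
# allele-frequency / size spectrum report.

#' Per-site genotype summaries
#'
#' Computes, per variant column: alternate allele count `ac` and called
#' allele number `an` over non-missing genotypes, `af = ac/an`,
#' `mac = min(ac, an - ac)`, missing rate, homozygous-alternate count, a
#' Hardy-Weinberg equilibrium p-value (1-df chi-square of the observed
#' hom-ref/het/hom-alt counts against `p^2, 2pq, q^2` at the estimated
#' allele frequency), and the `singleton` (`ac == 1`) and `rare`
#' (`af < 0.01`) classifications.
#'
#' @param gm a [genotype_matrix()].
#' @return data.frame with one row per variant.
#' @export
summarize_sites <- function(gm) {
  dos <- dosages(gm)
  m <- ncol(dos)
  n_called <- colSums(!is.na(dos))
  ac <- colSums(dos, na.rm = TRUE)
  an <- 2L * n_called
  af <- ifelse(an > 0, ac / an, NA_real_)
  n2 <- colSums(dos == 2L, na.rm = TRUE)
  n1 <- colSums(dos == 1L, na.rm = TRUE)
  n0 <- n_called - n1 - n2
  hwe_p <- .hwe_chisq_p(n0, n1, n2)
  data.frame(
    variant_id = colnames(dos) %||% character(),
    ac = as.integer(ac), an = as.integer(an), af = af,
    mac = as.integer(pmin(ac, an - ac)),
    missing_rate = if (nrow(dos) > 0) colMeans(is.na(dos)) else rep(NA_real_, m),
    n_hom_alt = as.integer(n2),
    hwe_p = hwe_p,
    singleton = ac == 1L,
    rare = !is.na(af) & af < 0.01,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# 1-df chi-square HWE test from genotype class counts (vectorised).
# Monomorphic sites have statistic 0 by convention (all mass in one class).
.hwe_chisq_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- ifelse(n > 0, (n1 + 2 * n2) / (2 * n), NA_real_)
  e0 <- n * (1 - p)^2
  e1 <- n * 2 * p * (1 - p)
  e2 <- n * p^2
  term <- function(o, e) ifelse(e > 0, (o - e)^2 / e, 0)
  stat <- term(n0, e0) + term(n1, e1) + term(n2, e2)
  ifelse(is.na(p), NA_real_, pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Detect call-count outlier samples
#'
#' Excludes samples with too many total SV calls
#' (`n_sv_all > median + 4 * MAD`) or too few high-quality calls
#' (`n_sv_hq < median - 4 * MAD`).  The MAD is the unscaled median absolute
#' deviation (no 1.4826 consistency factor), and the inequalities are
#' strict, so a cohort of identical counts excludes nobody.
#'
#' @param sample_counts data.frame with `sample_id`, `n_sv_all`, `n_sv_hq`
#'   (as produced by [count_svs_per_sample()]).
#' @param n_mad multiplier on the MAD (default 4).
#' @param scaled use the 1.4826-scaled MAD instead (default `FALSE`).
#' @return Character vector of excluded sample ids.
#' @export
detect_outlier_samples <- function(sample_counts, n_mad = 4, scaled = FALSE) {
  req <- c("sample_id", "n_sv_all", "n_sv_hq")
  if (!is.data.frame(sample_counts) || !all(req %in% names(sample_counts)))
    .stopf("'sample_counts' needs columns %s", paste(req, collapse = ", "))
  if (nrow(sample_counts) < 3)
    .stopf("need at least 3 samples for outlier detection")
  k <- if (scaled) 1.4826 else 1
  all_ct <- sample_counts$n_sv_all
  hq_ct <- sample_counts$n_sv_hq
  mad_all <- k * median(abs(all_ct - median(all_ct)))
  mad_hq <- k * median(abs(hq_ct - median(hq_ct)))
  bad <- all_ct > median(all_ct) + n_mad * mad_all |
    hq_ct < median(hq_ct) - n_mad * mad_hq
  sample_counts$sample_id[bad]
}

#' Principal components of common SV dosages
#'
#' Restricts to sites with `MAF > maf_min` and HWE p-value `> hwe_min`,
#' mean-imputes missing dosages, standardises each site by
#' `sqrt(2 p (1 - p))`, and returns the top-`k` left singular vectors of the
#' standardised matrix (orthonormal sample coordinates).
#'
#' @param gm a [genotype_matrix()].
#' @param maf_min minor-allele-frequency threshold (strict).
#' @param hwe_min HWE p-value threshold (strict).
#' @param k number of components.
#' @param summaries optional precomputed [summarize_sites()] table.
#' @return data.frame `sample_id`, `PC1`..`PCk`, with attributes `sdev`
#'   (singular values / sqrt(n-1)) and `n_sites_used`.  If `k` exceeds the
#'   matrix rank, the available components are returned with a warning.
#' @export
sv_pca <- function(gm, maf_min = 0.01, hwe_min = 1e-5, k = 10,
                   summaries = NULL) {
  dos <- dosages(gm)
  if (is.null(summaries)) summaries <- summarize_sites(gm)
  maf <- pmin(summaries$af, 1 - summaries$af)
  keep <- !is.na(maf) & maf > maf_min & !is.na(summaries$hwe_p) &
    summaries$hwe_p > hwe_min
  if (!any(keep))
    .stopf("no sites pass MAF > %g and HWE p > %g", maf_min, hwe_min)
  X <- dos[, summaries$variant_id[keep], drop = FALSE]
  p <- summaries$af[keep]
  X <- apply(X, 2L, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  X <- sweep(X, 2L, 2 * p, "-")
  X <- sweep(X, 2L, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(X)
  tol <- max(dim(X)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (k > rank) {
    .warnf("requested %d PCs but rank is %d; returning %d", k, rank, rank)
    k <- rank
  }
  out <- data.frame(sample_id = rownames(dos), sv$u[, seq_len(k), drop = FALSE],
                    stringsAsFactors = FALSE)
  names(out) <- c("sample_id", paste0("PC", seq_len(k)))
  attr(out, "sdev") <- sv$d[seq_len(k)] / sqrt(max(nrow(X) - 1, 1))
  attr(out, "n_sites_used") <- ncol(X)
  out
}

#' Allele-frequency and size spectrum report
#'
#' Summarises a callset: singleton and rare (AF < 1\%) counts and
#' fractions, the cumulative fraction of variants at or below a fixed
#' allele-frequency grid, and a log-scale size histogram with detected
#' local modes (kernel-density peaks on log10 size, strongest first).
#'
#' @param summaries a [summarize_sites()] table (or any data.frame with
#'   `af` and logical `singleton`, `rare` columns).
#' @param sizes optional vector of SV lengths in bp.
#' @return list with `n_sites`, `n_singleton`, `singleton_fraction`,
#'   `singleton_pct` (rounded), `n_rare`, `rare_fraction`, `rare_pct`,
#'   `af_grid`, `af_cumulative`, and (when sizes are given) `size_modes`
#'   and `size_hist`.
#' @export
spectrum_report <- function(summaries, sizes = NULL) {
  if (!is.data.frame(summaries) ||
      !all(c("af", "singleton", "rare") %in% names(summaries)))
    .stopf("'summaries' needs columns af, singleton, rare")
  n <- nrow(summaries)
  n_single <- sum(summaries$singleton, na.rm = TRUE)
  n_rare <- sum(summaries$rare, na.rm = TRUE)
  grid <- 10^seq(-4, 0, by = 0.25)
  cum <- if (n > 0) {
    vapply(grid, function(g) mean(summaries$af <= g, na.rm = TRUE), numeric(1))
  } else {
    rep(NA_real_, length(grid))
  }
  out <- list(
    n_sites = n,
    n_singleton = n_single,
    singleton_fraction = if (n > 0) n_single / n else NA_real_,
    singleton_pct = if (n > 0) as.integer(round(100 * n_single / n)) else NA_integer_,
    n_rare = n_rare,
    rare_fraction = if (n > 0) n_rare / n else NA_real_,
    rare_pct = if (n > 0) as.integer(round(100 * n_rare / n)) else NA_integer_,
    af_grid = grid,
    af_cumulative = cum
  )
  if (!is.null(sizes)) {
    sizes <- sizes[!is.na(sizes) & sizes > 0]
    if (length(sizes) >= 10) {
      d <- density(log10(sizes))
      peak <- which(diff(sign(diff(d$y))) == -2) + 1L
      peak <- peak[order(d$y[peak], decreasing = TRUE)]
      out$size_modes <- 10^d$x[peak]
      h <- hist(log10(sizes), breaks = 50, plot = FALSE)
      out$size_hist <- data.frame(log10_size_mid = h$mids, count = h$counts)
    } else {
      out$size_modes <- numeric()
      out$size_hist <- NULL
    }
  }
  class(out) <- "spectrum_report"
  out
}

#' @export
print.spectrum_report <- function(x, ...) {
  cat(sprintf(
    "spectrum_report: %d sites; %d singletons (%d%%), %d rare AF<1%% (%d%%)\n",
    x$n_sites, x$n_singleton, x$singleton_pct, x$n_rare, x$rare_pct
  ))
  if (!is.null(x$size_modes) && length(x$size_modes))
    cat(sprintf("  size modes (bp): %s\n",
                paste(round(x$size_modes), collapse = ", ")))
  invisible(x)
}
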