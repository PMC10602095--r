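# Single-variant association (additive and recessive), eligibility
# filtering, Benjamini-Hochberg FDR, and SV-to-SNV LD tagging.

#' Association-eligible sites
#'
#' Keeps variants with missing rate strictly below `missing_max` and minor
#' allele count strictly above `mac_min` (so `mac == 5` is excluded at the
#' default).
#'
#' @param summaries a [summarize_sites()] table computed on the analysis
#'   samples.
#' @param missing_max exclusive upper bound on missing rate.
#' @param mac_min exclusive lower bound on minor allele count.
#' @return Character vector of eligible variant ids.
#' @export
eligible_sites <- function(summaries, missing_max = 0.5, mac_min = 5) {
  if (!is.data.frame(summaries) ||
      !all(c("variant_id", "missing_rate", "mac") %in% names(summaries)))
    .stopf("'summaries' needs variant_id, missing_rate, mac")
  keep <- !is.na(summaries$missing_rate) & summaries$missing_rate < missing_max &
    !is.na(summaries$mac) & summaries$mac > mac_min
  summaries$variant_id[keep]
}

#' Recessive genotype recoding
#'
#' Under a recessive model two copies of the alternate allele are required
#' to alter risk: dosage 2 recodes to 1, dosages 0 and 1 to 0, missing
#' stays missing.  The homozygous allele frequency (homozygous-alternate
#' carriers over non-missing calls) is reported alongside.
#'
#' @param dosage vector over `{0, 1, 2, NA}`.
#' @return list with `dosage` (recoded vector) and `hom_af`.
#' @export
recessive_recode <- function(dosage) {
  if (!all(dosage %in% c(0:2, NA)))
    .stopf("dosages must be 0, 1, 2 or NA")
  rec <- ifelse(is.na(dosage), NA_integer_, as.integer(dosage == 2L))
  n_called <- sum(!is.na(dosage))
  list(dosage = rec,
       hom_af = if (n_called > 0) sum(dosage == 2L, na.rm = TRUE) / n_called
                else NA_real_)
}

#' Single-variant association test
#'
#' Regresses a phenotype on a genotype dosage plus covariates and reports
#' the Wald test for the genotype term.  Binary phenotypes use logistic
#' regression (IRLS via `glm`), quantitative ones ordinary least squares.
#' Under the recessive model the dosage is first passed through
#' [recessive_recode()].  Samples missing the genotype, phenotype or any
#' covariate are dropped.  Non-convergence, separation or a constant
#' genotype column yield a flagged result (`p = NA`, `note` set), never a
#' silent number.
#'
#' @param dosage dosage vector over `{0, 1, 2, NA}`.
#' @param phenotype 0/1 vector (binary family) or numeric (quantitative).
#' @param covariates optional data.frame of covariates.
#' @param model `"additive"` or `"recessive"`.
#' @param family `"binary"` or `"quantitative"`.
#' @param variant_id label carried into the result.
#' @return One-row data.frame: `variant_id`, `model`, `family`, `beta`,
#'   `se`, `p`, `n_used`, `af`, `mac`, `note`.
#' @export
single_variant_test <- function(dosage, phenotype, covariates = NULL,
                                model = c("additive", "recessive"),
                                family = c("binary", "quantitative"),
                                variant_id = NA_character_) {
  model <- match.arg(model)
  family <- match.arg(family)
  if (length(dosage) != length(phenotype))
    .stopf("dosage and phenotype lengths differ")
  if (!is.null(covariates) && nrow(covariates) != length(phenotype))
    .stopf("covariate rows must match phenotype length")

  g <- dosage
  if (model == "recessive") g <- recessive_recode(dosage)$dosage
  df <- data.frame(.y = phenotype, .g = g)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  ok <- complete.cases(df)
  df <- df[ok, , drop = FALSE]
  n_used <- nrow(df)

  d_ok <- dosage[ok]
  af <- if (n_used > 0) mean(d_ok) / 2 else NA_real_
  ac <- sum(d_ok)
  mac <- min(ac, 2L * n_used - ac)

  res <- data.frame(variant_id = variant_id, model = model, family = family,
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    n_used = n_used, af = af, mac = as.integer(mac),
                    note = NA_character_, stringsAsFactors = FALSE)
  if (n_used < 2 || var(df$.g) == 0) {
    res$note <- "no_genotype_variance"
    return(res)
  }
  if (family == "binary") {
    if (length(unique(df$.y)) < 2) {
      res$note <- "single_phenotype_class"
      return(res)
    }
    warned <- FALSE
    fit <- withCallingHandlers(
      glm(.y ~ ., data = df, family = binomial()),
      warning = function(w) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    )
    cf <- summary(fit)$coefficients
    if (!".g" %in% rownames(cf) || !fit$converged || warned &&
        abs(cf[".g", "Estimate"]) > 15) {
      res$note <- "separation_or_nonconvergence"
      return(res)
    }
    res$beta <- cf[".g", "Estimate"]
    res$se <- cf[".g", "Std. Error"]
    res$p <- 2 * pnorm(-abs(cf[".g", "Estimate"] / cf[".g", "Std. Error"]))
    if (warned) res$note <- "glm_warning"
  } else {
    fit <- lm(.y ~ ., data = df)
    cf <- summary(fit)$coefficients
    if (!".g" %in% rownames(cf)) {
      res$note <- "rank_deficient"
      return(res)
    }
    res$beta <- cf[".g", "Estimate"]
    res$se <- cf[".g", "Std. Error"]
    res$p <- cf[".g", "Pr(>|t|)"]
  }
  res
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q(i) = min over j >= i of m * p(j) / j` in sorted order, clipped at 1.
#'
#' @param p p-values in `(0, 1]`.
#' @return q-values in the original order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    .stopf("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' LD scan between SV and SNV dosages
#'
#' For every SV/SNV pair, computes the squared Pearson correlation of the
#' dosage vectors over the samples non-missing in both, and reports pairs
#' with `r2 > r2_min`.  Pairs with fewer than `min_overlap` shared calls
#' are skipped with a warning.
#'
#' @param sv_dosages,snv_dosages samples-by-variants matrices (a vector is
#'   taken as one column) with aligned sample ordering.
#' @param r2_min reporting threshold (exclusive).
#' @param min_overlap minimum pairwise non-missing sample count.
#' @return data.frame `sv_id`, `snv_id`, `r2`, `n_overlap` for reported
#'   pairs.
#' @export
ld_scan <- function(sv_dosages, snv_dosages, r2_min = 0.2, min_overlap = 30) {
  as_mat <- function(x, prefix) {
    if (is.null(dim(x)))
      x <- matrix(as.vector(x), ncol = 1,
                  dimnames = list(NULL, paste0(prefix, "1")))
    if (is.null(colnames(x))) colnames(x) <- paste0(prefix, seq_len(ncol(x)))
    x
  }
  sv <- as_mat(sv_dosages, "sv")
  snv <- as_mat(snv_dosages, "snv")
  if (nrow(sv) != nrow(snv))
    .stopf("SV and SNV matrices must have the same samples")
  out <- list()
  for (i in seq_len(ncol(sv))) {
    for (j in seq_len(ncol(snv))) {
      a <- sv[, i]; b <- snv[, j]
      ok <- !is.na(a) & !is.na(b)
      n_ov <- sum(ok)
      if (n_ov < min_overlap) {
        .warnf("pair %s/%s skipped: only %d shared non-missing samples",
               colnames(sv)[i], colnames(snv)[j], n_ov)
        next
      }
      r <- suppressWarnings(cor(a[ok], b[ok]))
      r2 <- if (is.na(r)) NA_real_ else r^2
      if (!is.na(r2) && r2 > r2_min) {
        out[[length(out) + 1L]] <- data.frame(
          sv_id = colnames(sv)[i], snv_id = colnames(snv)[j],
          r2 = r2, n_overlap = n_ov, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sv_id = character(), snv_id = character(),
                      r2 = numeric(), n_overlap = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
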