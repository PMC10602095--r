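# Synthetic multi-sample SV cohorts with the statistical structure the
# downstream analyses assume: a bimodal size spectrum, a rare-skewed allele
# frequency spectrum with an explicit singleton mass, Hardy-Weinberg
# genotypes, multi-model duplicate records, a controllable fraction of sites
# passing the per-type high-quality clauses, and phenotypes from a logistic
# (or Gaussian) model with covariate, per-genome burden and per-site effects.

#' Cohort simulation configuration
#'
#' Bundles the knobs of the synthetic-cohort generator.  Defaults emulate a
#' large short-read WGS SV callset: the type mix follows the per-type share
#' of a 400,234-site discovery callset (57.8\% deletions, 11.5\%
#' duplications, 29.9\% insertions, 0.8\% inversions), sizes come from a
#' two-component log-normal mixture with modes at 300 bp (Alu scale) and
#' 6,000 bp (L1 scale), 24\% of sites are singletons and 58\% are rare
#' (AF < 1\%, singletons included), and 42\% of sites satisfy the per-type
#' high-quality metric clauses.
#'
#' @param n_samples number of samples (diploid genomes).
#' @param n_sv_sites number of distinct SV loci to simulate.
#' @param type_mix named proportions over `DEL`, `DUP`, `INS`, `INV`, `BND`;
#'   must sum to 1 within 1e-9.  Breakends default to 0 because they are
#'   removed by [prefilter_sites()]; give them positive weight to exercise
#'   that path.
#' @param size_mixture data.frame with columns `mode_bp`, `sd_log`, `weight`:
#'   a log-normal mixture for SV length, parameterised by the modal length
#'   of each component.  Weights must sum to 1 within 1e-9.
#' @param af_spectrum list with `singleton_frac` (point mass of sites whose
#'   cohort allele count is exactly 1), `rare_frac` (total fraction of sites
#'   with AF < 1\%, singletons included) and `af_max` (upper bound of the
#'   common-site log-uniform band).
#' @param hq_pass_fraction target fraction of non-BND sites whose simulated
#'   metrics satisfy the high-quality clauses of [is_high_quality()].
#' @param dup_model_fraction fraction of sites emitted twice under different
#'   caller-model tags (exactly `round(dup_model_fraction * n_sv_sites)`
#'   sites are duplicated).
#' @param outlier_fraction fraction of samples given inflated call counts,
#'   emulating problem samples caught by [detect_outlier_samples()].
#' @param missing_rate per-call probability of a missing genotype.
#' @param seed integer seed; a fixed seed makes every generated artifact
#'   byte-identical across runs.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_samples,
                          n_sv_sites,
                          type_mix = c(DEL = 231385, DUP = 45839,
                                       INS = 119648, INV = 3362,
                                       BND = 0) / 400234,
                          size_mixture = data.frame(
                            mode_bp = c(300, 6000),
                            sd_log = c(0.35, 0.35),
                            weight = c(0.7, 0.3)
                          ),
                          af_spectrum = list(singleton_frac = 0.24,
                                             rare_frac = 0.58,
                                             af_max = 0.5),
                          hq_pass_fraction = 0.42,
                          dup_model_fraction = 0.15,
                          outlier_fraction = 0.035,
                          missing_rate = 0.02,
                          seed = 1L) {
  if (!.is_count(n_samples, positive = TRUE))
    .stopf("'n_samples' must be a positive integer")
  if (!.is_count(n_sv_sites))
    .stopf("'n_sv_sites' must be a non-negative integer")
  if (is.null(names(type_mix)) || !all(names(type_mix) %in% .SV_TYPES))
    .stopf("'type_mix' must be named with types among %s",
           paste(.SV_TYPES, collapse = ", "))
  if (any(type_mix < 0) || abs(sum(type_mix) - 1) > 1e-9)
    .stopf("'type_mix' proportions must be non-negative and sum to 1 (got %.12f)",
           sum(type_mix))
  if (!is.data.frame(size_mixture) ||
      !all(c("mode_bp", "sd_log", "weight") %in% names(size_mixture)))
    .stopf("'size_mixture' needs columns mode_bp, sd_log, weight")
  if (any(size_mixture$weight < 0) || abs(sum(size_mixture$weight) - 1) > 1e-9)
    .stopf("'size_mixture' weights must be non-negative and sum to 1")
  if (any(size_mixture$mode_bp < 50))
    .stopf("'size_mixture' modes must be >= 50 bp (SV definition)")
  af <- af_spectrum
  if (!is.list(af) ||
      !all(c("singleton_frac", "rare_frac", "af_max") %in% names(af)))
    .stopf("'af_spectrum' needs singleton_frac, rare_frac, af_max")
  if (af$singleton_frac < 0 || af$rare_frac < af$singleton_frac ||
      af$rare_frac > 1 || af$af_max <= 0.01 || af$af_max > 1)
    .stopf("inconsistent 'af_spectrum' (need 0 <= singleton <= rare <= 1, 0.01 < af_max <= 1)")
  for (nm in c("hq_pass_fraction", "dup_model_fraction", "outlier_fraction",
               "missing_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      .stopf("'%s' must be a single value in [0, 1]", nm)
  }
  if (!.is_count(abs(seed))) .stopf("'seed' must be an integer")
  structure(
    list(n_samples = as.integer(n_samples),
         n_sv_sites = as.integer(n_sv_sites),
         type_mix = type_mix, size_mixture = size_mixture,
         af_spectrum = af, hq_pass_fraction = hq_pass_fraction,
         dup_model_fraction = dup_model_fraction,
         outlier_fraction = outlier_fraction,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "cohort_config: %d samples, %d SV sites (seed %d)\n  type mix: %s\n  hq target %.2f, dup-model %.2f, outliers %.3f, missing %.3f\n",
    x$n_samples, x$n_sv_sites, x$seed,
    paste(sprintf("%s %.3f", names(x$type_mix), x$type_mix), collapse = ", "),
    x$hq_pass_fraction, x$dup_model_fraction, x$outlier_fraction,
    x$missing_rate
  ))
  invisible(x)
}

# Site metrics drawn so a designated site passes (or decisively fails) its
# type's high-quality clause set.  Failing sites break exactly one clause,
# sampled among the clauses controllable independently of the realized
# cohort AC; NUM_MERGED_SVS is scaled so AC/NUM_MERGED_SVS stays well under
# the threshold of 25 for passing sites even after genotype sampling noise.
.simulate_site_metrics <- function(svtype, pass, exp_ac) {
  n <- length(svtype)
  qd <- ifelse(svtype == "DUP", 5, 12) + rexp(n, 1 / 8)
  hetless <- runif(n) < 0.3
  abhet <- ifelse(hetless, -1, runif(n, 0.31, 0.65))
  pass_ratio <- runif(n, 0.15, 0.95)
  maxaas <- 5L + rpois(n, 5)
  num_merged <- pmax(1, ceiling(exp_ac / 8))
  pass_ac <- pmax(1L, as.integer(round(pass_ratio * exp_ac)))
  fail <- which(!is.na(pass) & !pass)
  for (i in fail) {
    cl <- switch(svtype[i],
      DEL = sample(c("qd", "abhet", "ratio", "pass_ac"), 1L),
      DUP = sample(c("qd", "pass_ac"), 1L),
      sample(c("ratio", "abhet", "maxaas", "pass_ac"), 1L)
    )
    if (cl == "qd") {
      qd[i] <- runif(1, 0, if (svtype[i] == "DUP") 5 else 12)
    } else if (cl == "abhet") {
      abhet[i] <- runif(1, 0.01, if (svtype[i] == "DEL") 0.295 else 0.245)
    } else if (cl == "ratio") {
      pass_ratio[i] <- runif(1, 0, 0.0999)
    } else if (cl == "maxaas") {
      maxaas[i] <- sample(0:4, 1L)
    } else {
      pass_ac[i] <- 0L
    }
  }
  bnd <- svtype == "BND"
  qd[bnd] <- NA_real_; abhet[bnd] <- NA_real_; pass_ratio[bnd] <- NA_real_
  maxaas[bnd] <- NA_integer_; pass_ac[bnd] <- NA_integer_
  num_merged[bnd] <- 1
  data.frame(qd = qd, abhet = abhet,
             num_merged_svs = as.integer(num_merged),
             pass_ac = pass_ac, pass_ratio = pass_ratio,
             maxaas = as.integer(maxaas))
}

#' Simulate SV sites
#'
#' Draws SV loci per the configuration: types from `type_mix`, lengths from
#' the log-normal size mixture, allele frequencies from the
#' singleton/rare/common spectrum, and site metrics such that the realized
#' fraction of non-BND sites passing [is_high_quality()] matches
#' `hq_pass_fraction` (binomially, so within about +/-0.05 for 2,000 or more
#' sites).  A fraction `dup_model_fraction` of sites is emitted twice under
#' distinct caller-model tags to exercise [select_model_records()]; BND
#' records carry no length.  The returned table also keeps the simulation
#' truth columns `af`, `singleton` and `hq_designed`.
#'
#' @param config a [cohort_config()].
#' @return data.frame of SV records sorted by chromosome and position, one
#'   row per VCF record (duplicated loci share an `id`).
#' @export
simulate_sites <- function(config) {
  if (!inherits(config, "cohort_config"))
    .stopf("'config' must be a cohort_config")
  set.seed(config$seed)
  n <- config$n_sv_sites
  if (n == 0L) {
    out <- .empty_sites()
    out$af <- numeric(); out$singleton <- logical(); out$hq_designed <- logical()
    return(out)
  }
  tm <- config$type_mix[config$type_mix > 0]
  svtype <- sample(names(tm), n, replace = TRUE, prob = tm)
  sm <- config$size_mixture
  comp <- sample.int(nrow(sm), n, replace = TRUE, prob = sm$weight)
  # log-normal parameterised by its mode: mu = log(mode) + sdlog^2
  mu <- log(sm$mode_bp) + sm$sd_log^2
  svlen <- pmax(50L, as.integer(round(rlnorm(n, mu[comp], sm$sd_log[comp]))))
  chrom <- sample(names(.CHROM_LEN), n, replace = TRUE, prob = .CHROM_LEN)
  spanned <- svtype %in% c("DEL", "DUP", "INV")
  pos <- as.integer(floor(runif(n, 1, .CHROM_LEN[chrom] - ifelse(spanned, svlen, 0) - 1)))
  end <- as.integer(ifelse(spanned, pos + svlen, pos))
  svlen[svtype == "BND"] <- NA_integer_

  afs <- config$af_spectrum
  af_min <- 1 / (2 * config$n_samples)
  u <- runif(n)
  singleton <- u < afs$singleton_frac
  rare <- !singleton & u < afs$rare_frac
  common <- !singleton & !rare
  af <- numeric(n)
  af[singleton] <- af_min
  rare_lo <- min(2 * af_min, 0.009)
  af[rare] <- 10^runif(sum(rare), log10(rare_lo), log10(0.01))
  af[common] <- 10^runif(sum(common), log10(0.01), log10(afs$af_max))
  exp_ac <- ifelse(singleton, 1, pmax(1, round(2 * config$n_samples * af)))

  hq_designed <- rep(NA, n)
  nb <- svtype != "BND"
  hq_designed[nb] <- runif(sum(nb)) < config$hq_pass_fraction
  met <- .simulate_site_metrics(svtype, hq_designed, exp_ac)

  sites <- data.frame(
    id = sprintf("sv%06d", seq_len(n)),
    chrom = chrom, pos = pos, end = end, svtype = svtype, svlen = svlen,
    model = "aggregated",
    qd = met$qd, abhet = met$abhet,
    ac = as.integer(exp_ac), an = 2L * config$n_samples,
    num_merged_svs = met$num_merged_svs, pass_ac = met$pass_ac,
    pass_ratio = met$pass_ratio, maxaas = met$maxaas,
    af = af, singleton = singleton, hq_designed = hq_designed,
    stringsAsFactors = FALSE
  )
  n_dup <- round(config$dup_model_fraction * n)
  if (n_dup > 0) {
    idx <- sample.int(n, n_dup)
    dup <- sites[idx, , drop = FALSE]
    dup$model <- sample(c("breakpoint", "coverage"), n_dup, replace = TRUE)
    sites <- rbind(sites, dup)
  }
  sites <- sites[.site_order(sites), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Simulate genotypes under Hardy-Weinberg sampling
#'
#' Per unique site, dosages are drawn `Binomial(2, AF)` independently across
#' samples; singleton-designated sites instead receive exactly one
#' heterozygote.  Optionally, a fraction of samples is given inflated call
#' counts (extra carriers at common sites) and per-call missingness is
#' applied (never to a singleton's sole carrier).  Per-call FT pass flags are
#' drawn with the site's `pass_ratio` as the pass probability.
#'
#' @param sites site table from [simulate_sites()] (needs `af`, `singleton`;
#'   duplicate model records collapse to one genotype column).
#' @param n_samples number of samples.
#' @param seed integer seed.
#' @param missing_rate per-call missing probability.
#' @param outlier_fraction fraction of samples with inflated counts; their
#'   ids are attached as attribute `outlier_samples`.
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(sites, n_samples, seed,
                               missing_rate = 0, outlier_fraction = 0) {
  .check_sites(sites, c("id", "svtype", "af", "singleton"))
  if (any(sites$af < 0 | sites$af > 1, na.rm = TRUE))
    .stopf("site AF outside [0, 1]")
  set.seed(seed)
  us <- sites[!duplicated(sites$id), , drop = FALSE]
  m <- nrow(us)
  sids <- sprintf("S%05d", seq_len(n_samples))
  dos <- matrix(0L, n_samples, m, dimnames = list(sids, us$id))
  if (m > 0 && n_samples > 0) {
    ns <- which(!us$singleton)
    if (length(ns))
      dos[, ns] <- matrix(
        rbinom(n_samples * length(ns), 2L, rep(us$af[ns], each = n_samples)),
        nrow = n_samples
      )
    # AC = 1 is reserved for designated singletons: a rare non-singleton
    # site that realizes a single alternate allele gets a second carrier,
    # so the realized singleton fraction tracks the configured mass
    if (n_samples >= 2) {
      for (j in ns) {
        if (sum(dos[, j]) == 1L) {
          free <- which(dos[, j] == 0L)
          dos[free[sample.int(length(free), 1L)], j] <- 1L
        }
      }
    }
    for (j in which(us$singleton))
      dos[sample.int(n_samples, 1L), j] <- 1L
  }
  outlier_ids <- character()
  k <- round(outlier_fraction * n_samples)
  if (k > 0 && m > 0) {
    out_idx <- sample.int(n_samples, k)
    outlier_ids <- sids[out_idx]
    cm <- which(us$af >= 0.01 & !us$singleton)
    for (i in out_idx) {
      extra <- cm[runif(length(cm)) < 0.3]
      if (length(extra)) dos[i, extra] <- pmax(dos[i, extra], 1L)
    }
  }
  if (missing_rate > 0 && m > 0 && n_samples > 0) {
    miss <- matrix(runif(n_samples * m) < missing_rate, n_samples, m)
    # a singleton's single carrier is never set missing (AC=1 by design)
    for (j in which(us$singleton)) {
      carrier <- which(dos[, j] > 0L)
      miss[carrier, j] <- FALSE
    }
    dos[miss] <- NA_integer_
  }
  ftp <- NULL
  if (m > 0 && n_samples > 0) {
    pr <- us$pass_ratio
    pr[is.na(pr)] <- 1
    ftp <- matrix(runif(n_samples * m) < rep(pr, each = n_samples),
                  n_samples, m, dimnames = dimnames(dos))
  }
  gm <- genotype_matrix(dos, ftp)
  attr(gm, "outlier_samples") <- outlier_ids
  gm
}

#' Specification of an SV/SNV linkage-disequilibrium pair
#'
#' @param sv_id,snv_id variant identifiers.
#' @param target_r2 target squared dosage correlation, in `[0, 1]`.
#' @return An object of class `ld_pair_spec`.
#' @export
ld_pair_spec <- function(sv_id, snv_id, target_r2) {
  if (!is.numeric(target_r2) || length(target_r2) != 1L || is.na(target_r2) ||
      target_r2 < 0 || target_r2 > 1)
    .stopf("'target_r2' must be in [0, 1]")
  structure(list(sv_id = sv_id, snv_id = snv_id, target_r2 = target_r2),
            class = "ld_pair_spec")
}

#' Couple an SNV dosage vector to an SV at a target r-squared
#'
#' Decomposes the SV dosages into two haplotypes per sample, copies each
#' haplotype allele to the SNV with probability `sqrt(target_r2)` (and
#' otherwise redraws it from the SV allele frequency), then collapses back to
#' dosages.  Haplotype-level correlation `sqrt(r2)` yields genotypic
#' r-squared close to `target_r2` (within about +/-0.05 for n >= 2,000);
#' `target_r2 = 1` reproduces the SV dosage vector exactly.
#'
#' @param spec an [ld_pair_spec()].
#' @param base_dosages complete SV dosage vector (0/1/2).
#' @param seed integer seed.
#' @return Integer SNV dosage vector with attribute `realized_r2`.  If the
#'   target is unreachable (monomorphic base), a warning is raised and the
#'   best-effort vector is returned with its realized value.
#' @export
couple_ld_pair <- function(spec, base_dosages, seed) {
  if (!inherits(spec, "ld_pair_spec")) .stopf("'spec' must be an ld_pair_spec")
  d <- base_dosages
  if (anyNA(d)) .stopf("'base_dosages' must be complete (couple before masking)")
  if (!all(d %in% 0:2)) .stopf("'base_dosages' must be 0/1/2")
  d <- as.integer(d)
  if (spec$target_r2 == 1) {
    return(structure(d, realized_r2 = 1))
  }
  set.seed(seed)
  n <- length(d)
  p <- mean(d) / 2
  if (p == 0 || p == 1) {
    .warnf("base dosages are monomorphic; target r2 %.2f unreachable (realized NA)",
           spec$target_r2)
    return(structure(d, realized_r2 = NA_real_))
  }
  cc <- sqrt(spec$target_r2)
  h1 <- as.integer(d == 2L)
  het <- d == 1L
  h1[het] <- rbinom(sum(het), 1L, 0.5)
  h2 <- d - h1
  s1 <- ifelse(runif(n) < cc, h1, rbinom(n, 1L, p))
  s2 <- ifelse(runif(n) < cc, h2, rbinom(n, 1L, p))
  snv <- as.integer(s1 + s2)
  r2 <- suppressWarnings(cor(d, snv))^2
  if (is.na(r2)) {
    .warnf("coupled SNV is monomorphic; realized r2 undefined")
  } else if (abs(r2 - spec$target_r2) > 0.1) {
    .warnf("realized r2 %.3f is far from target %.3f (best effort)",
           r2, spec$target_r2)
  }
  structure(snv, realized_r2 = unname(r2))
}

#' Planted phenotype effects
#'
#' Describes the data-generating model for [simulate_phenotypes()]:
#' `eta = intercept + covariates %*% covariate_betas +
#' burden_beta * (per-sample CNV carrier count) + sum(site_betas * dosage)`.
#' Binary traits are Bernoulli(plogis(eta)); quantitative traits are
#' Gaussian around eta.
#'
#' @param intercept log-odds (binary) or mean (quantitative) intercept.
#' @param covariate_betas named vector of effects on the columns of the
#'   expanded covariate design (see [simulate_phenotypes()]); `NULL` for none.
#' @param burden_beta log-odds per additional CNV (DEL/DUP) carried.
#' @param site_betas named vector, variant id to per-alternate-allele
#'   log-odds.
#' @param trait_model `"binary"` or `"quantitative"`.
#' @param sd_quantitative residual standard deviation for quantitative traits.
#' @return An object of class `effect_plan`.
#' @export
effect_plan <- function(intercept = 0, covariate_betas = NULL,
                        burden_beta = 0, site_betas = NULL,
                        trait_model = c("binary", "quantitative"),
                        sd_quantitative = 1) {
  trait_model <- match.arg(trait_model)
  if (!is.null(site_betas) &&
      (is.null(names(site_betas)) || any(!nzchar(names(site_betas)))))
    .stopf("'site_betas' must be named by variant id")
  structure(
    list(intercept = intercept, covariate_betas = covariate_betas,
         burden_beta = burden_beta, site_betas = site_betas,
         trait_model = trait_model, sd_quantitative = sd_quantitative),
    class = "effect_plan"
  )
}

#' Simulate per-sample covariates
#'
#' Generates the kind of technical and ancestry covariates an SV association
#' adjusts for: sex, a sequencing-center factor, a platform factor, PCR
#' status, and five genotype principal components (standard normal).  The
#' platform/center factors stand in for batch structure; no specific batch
#' composition is asserted.
#'
#' @param n_samples number of samples.
#' @param seed integer seed.
#' @return data.frame with columns `sex`, `center`, `platform`, `pcr`,
#'   `PC1`..`PC5`.
#' @export
make_covariates <- function(n_samples, seed) {
  set.seed(seed)
  data.frame(
    sex = rbinom(n_samples, 1L, 0.55),
    center = factor(sample(c("C1", "C2", "C3"), n_samples, replace = TRUE)),
    platform = factor(sample(c("P1", "P2"), n_samples, replace = TRUE,
                             prob = c(0.7, 0.3))),
    pcr = rbinom(n_samples, 1L, 0.4),
    PC1 = rnorm(n_samples), PC2 = rnorm(n_samples), PC3 = rnorm(n_samples),
    PC4 = rnorm(n_samples), PC5 = rnorm(n_samples)
  )
}

#' Per-sample SV call counts
#'
#' Counts, per sample, carried SVs (dosage >= 1 over non-missing calls) over
#' all non-BND sites, over high-quality sites, and per type.  High-quality
#' status is taken from a `hq` column when present, else computed with
#' [is_high_quality()].
#'
#' @param gm a [genotype_matrix()].
#' @param sites site table (duplicate model records are collapsed).
#' @return data.frame with `sample_id`, `n_sv_all`, `n_sv_hq`, `n_del`,
#'   `n_dup`, `n_ins`, `n_inv`.
#' @export
count_svs_per_sample <- function(gm, sites) {
  .check_sites(sites, c("id", "svtype"))
  us <- sites[!duplicated(sites$id) & sites$svtype != "BND", , drop = FALSE]
  us <- us[us$id %in% variant_ids(gm), , drop = FALSE]
  hq <- if ("hq" %in% names(us)) us$hq else is_high_quality(us)
  carried <- dosages(gm)[, us$id, drop = FALSE] >= 1L
  cnt <- function(sel) {
    if (!any(sel)) return(integer(nrow(carried)))
    as.integer(rowSums(carried[, sel, drop = FALSE], na.rm = TRUE))
  }
  data.frame(
    sample_id = sample_ids(gm),
    n_sv_all = cnt(rep(TRUE, nrow(us))),
    n_sv_hq = cnt(!is.na(hq) & hq),
    n_del = cnt(us$svtype == "DEL"),
    n_dup = cnt(us$svtype == "DUP"),
    n_ins = cnt(us$svtype == "INS"),
    n_inv = cnt(us$svtype == "INV"),
    stringsAsFactors = FALSE
  )
}

#' Simulate phenotypes from planted effects
#'
#' Builds the linear predictor of the [effect_plan()] and draws binary traits
#' `Bernoulli(plogis(eta))` or quantitative traits `Normal(eta, sd)`.  For
#' binary traits, case ages are "age at onset" and control ages "age at last
#' exam" (cases drawn slightly younger, mirroring the convention that onset
#' precedes the last exam of surviving controls).
#'
#' @param gm a [genotype_matrix()].
#' @param covariates data.frame of per-sample covariates (or `NULL`).  Factor
#'   columns are expanded via `model.matrix`; `covariate_betas` in the plan
#'   are matched to the expanded column names (unnamed vectors must match the
#'   expanded width).
#' @param plan an [effect_plan()].
#' @param seed integer seed.
#' @param sites site table; required when `burden_beta != 0` or to attach
#'   per-sample call counts.
#' @return A sample table: `sample_id`, `status`, `trait`, `age`, `age_type`,
#'   covariates, and call-count columns when `sites` is given.
#' @export
simulate_phenotypes <- function(gm, covariates, plan, seed, sites = NULL) {
  if (!inherits(plan, "effect_plan")) .stopf("'plan' must be an effect_plan")
  dos <- dosages(gm)
  n <- nrow(dos)
  if (!is.null(covariates) && nrow(covariates) != n)
    .stopf("covariate rows (%d) must match samples (%d)", nrow(covariates), n)
  set.seed(seed)
  eta <- rep(plan$intercept, n)
  if (!is.null(covariates) && ncol(covariates) > 0) {
    X <- model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
    b <- plan$covariate_betas
    if (is.null(b)) b <- setNames(numeric(ncol(X)), colnames(X))
    if (is.null(names(b))) {
      if (length(b) != ncol(X))
        .stopf("unnamed 'covariate_betas' must have length %d (expanded design)",
               ncol(X))
      names(b) <- colnames(X)
    }
    unknown <- setdiff(names(b), colnames(X))
    if (length(unknown))
      .stopf("covariate_betas name(s) not in design: %s",
             paste(unknown, collapse = ", "))
    eta <- eta + as.vector(X[, names(b), drop = FALSE] %*% b)
  }
  counts <- NULL
  if (!is.null(sites)) counts <- count_svs_per_sample(gm, sites)
  if (plan$burden_beta != 0) {
    if (is.null(counts))
      .stopf("'sites' is required when burden_beta != 0 (CNV counts)")
    eta <- eta + plan$burden_beta * (counts$n_del + counts$n_dup)
  }
  if (length(plan$site_betas)) {
    missing_ids <- setdiff(names(plan$site_betas), colnames(dos))
    if (length(missing_ids))
      .stopf("site_betas id(s) not in genotype matrix: %s",
             paste(missing_ids, collapse = ", "))
    D <- dos[, names(plan$site_betas), drop = FALSE]
    D[is.na(D)] <- 0L
    eta <- eta + as.vector(D %*% plan$site_betas)
  }
  if (plan$trait_model == "binary") {
    y <- rbinom(n, 1L, plogis(eta))
    status <- ifelse(y == 1L, "case", "control")
    age <- ifelse(y == 1L, rnorm(n, 74.6, 10.4), rnorm(n, 77.4, 8.0))
    age <- round(pmin(pmax(age, 50), 105), 1)
    age_type <- ifelse(y == 1L, "onset", "last_exam")
  } else {
    y <- eta + rnorm(n, 0, plan$sd_quantitative)
    status <- "unknown"
    age <- round(pmin(pmax(rnorm(n, 76, 9), 50), 105), 1)
    age_type <- "last_exam"
  }
  out <- data.frame(sample_id = rownames(dos), status = status, trait = y,
                    age = age, age_type = age_type, stringsAsFactors = FALSE)
  if (!is.null(covariates)) out <- cbind(out, covariates)
  if (!is.null(counts)) out <- cbind(out, counts[, -1, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Simulate a complete cohort
#'
#' Convenience wrapper chaining [simulate_sites()], [simulate_genotypes()],
#' [make_covariates()] and [simulate_phenotypes()] with seeds derived from
#' `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param plan an [effect_plan()]; defaults to a null model (no effects).
#' @return list with elements `sites`, `genotypes`, `samples`, `config`,
#'   of class `sv_cohort`.
#' @export
simulate_cohort <- function(config, plan = effect_plan()) {
  sites <- simulate_sites(config)
  gm <- simulate_genotypes(sites, config$n_samples, seed = config$seed + 1L,
                           missing_rate = config$missing_rate,
                           outlier_fraction = config$outlier_fraction)
  covars <- make_covariates(config$n_samples, seed = config$seed + 2L)
  samples <- simulate_phenotypes(gm, covars, plan, seed = config$seed + 3L,
                                 sites = sites)
  structure(list(sites = sites, genotypes = gm, samples = samples,
                 config = config),
            class = "sv_cohort")
}

#' @export
print.sv_cohort <- function(x, ...) {
  cat(sprintf("sv_cohort: %d samples, %d SV records (%d unique sites)\n",
              nrow(x$samples), nrow(x$sites),
              length(unique(x$sites$id))))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Emits a VCF 4.2 multi-sample SV file (via [write_sv_vcf()]), a phenotype
#' TSV, optionally a TSV of SNV dosages and a JSON file of planted truth.
#' Output is deterministic: the same inputs produce byte-identical files.
#'
#' @param sites,gm,samples site table, [genotype_matrix()] and sample table.
#' @param dir output directory (created if absent).
#' @param snv optional samples-by-SNVs dosage matrix written as
#'   `snv.tsv`.
#' @param truth optional list serialised to `truth.json` (planted effects,
#'   LD specs).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_cohort <- function(sites, gm, samples, dir, snv = NULL, truth = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(sv_vcf = file.path(dir, "sv.vcf"),
             phenotypes = file.path(dir, "phenotypes.tsv"))
  write_sv_vcf(sites, gm, paths[["sv_vcf"]])
  write.table(samples, paths[["phenotypes"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(snv)) {
    paths[["snv"]] <- file.path(dir, "snv.tsv")
    snv_df <- data.frame(sample_id = rownames(snv), snv, check.names = FALSE)
    write.table(snv_df, paths[["snv"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(truth)) {
    paths[["truth"]] <- file.path(dir, "truth.json")
    jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(paths)
}
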