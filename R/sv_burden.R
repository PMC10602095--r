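# Stratified per-sample SV burden, covariate-adjusted permutation burden
# testing, ultra-rare gene-set construction, and SKAT-O-style aggregation
# with a permutation-calibrated minimum-p statistic.

#' Per-sample burden counts
#'
#' Counts, per sample, high-quality sites of an SV class at which the
#' sample carries at least one alternate allele.  Classes: `CNV`
#' (deletions and duplications), `INS`, `INV`, or `ALL` (every non-BND
#' type).  Strata: `all` (every qualifying site), `singleton` (sites with
#' cohort allele count exactly 1 -- note a homozygous private variant has
#' AC = 2 and is excluded), `homozygous` (sites where the sample itself is
#' homozygous alternate).
#'
#' @param gm a [genotype_matrix()].
#' @param sites site table with an `hq` column (see [add_quality_flags()]).
#' @param sv_class `"CNV"`, `"INS"`, `"INV"` or `"ALL"`.
#' @param stratum `"all"`, `"singleton"` or `"homozygous"`.
#' @return Named integer vector of per-sample counts.
#' @export
per_sample_burden <- function(gm, sites,
                              sv_class = c("CNV", "INS", "INV", "ALL"),
                              stratum = c("all", "singleton", "homozygous")) {
  sv_class <- match.arg(sv_class)
  stratum <- match.arg(stratum)
  .check_sites(sites, c("id", "svtype", "hq"))
  types <- switch(sv_class,
                  CNV = c("DEL", "DUP"), INS = "INS", INV = "INV",
                  ALL = c("DEL", "DUP", "INS", "INV"))
  us <- sites[!duplicated(sites$id), , drop = FALSE]
  us <- us[us$svtype %in% types & !is.na(us$hq) & us$hq &
             us$id %in% variant_ids(gm), , drop = FALSE]
  dos <- dosages(gm)
  zero <- setNames(integer(nrow(dos)), rownames(dos))
  if (nrow(us) == 0) return(zero)
  sub <- dos[, us$id, drop = FALSE]
  if (stratum == "singleton") {
    ac <- colSums(sub, na.rm = TRUE)
    sub <- sub[, ac == 1L, drop = FALSE]
    if (ncol(sub) == 0) return(zero)
  }
  hit <- if (stratum == "homozygous") sub == 2L else sub >= 1L
  setNames(as.integer(rowSums(hit, na.rm = TRUE)), rownames(dos))
}

# Wald z for the named column of the design in a fitted glm.fit object
# (reproduces summary.glm's unscaled covariance from the IRLS QR).
.glmfit_z <- function(fit, col) {
  p1 <- seq_len(fit$rank)
  cov <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  piv <- fit$qr$pivot[p1]
  jcol <- match(col, names(fit$coefficients))
  j <- match(jcol, piv)
  if (is.na(j)) return(c(beta = NA_real_, se = NA_real_, z = NA_real_))
  beta <- fit$coefficients[jcol]
  se <- sqrt(cov[j, j])
  c(beta = unname(beta), se = se, z = unname(beta) / se)
}

#' Covariate-adjusted permutation burden test
#'
#' Fits logistic regression of case/control status on a per-sample burden
#' count plus covariates and reports the Wald statistic for the burden
#' term.  The empirical p-value is one-sided for an \emph{increased} burden
#' in cases: phenotype labels are permuted `B` times (covariates stay with
#' their samples), and `p_empirical = (1 + #\{z_perm >= z_obs\}) / (1 + B)`
#' -- the add-one estimator, so it is never 0 and never below
#' `1 / (B + 1)`.
#'
#' @param burden per-sample count vector ([per_sample_burden()]).
#' @param phenotype 0/1 (or two-level) case/control vector.
#' @param covariates optional data.frame.
#' @param B number of permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @param sv_class,stratum labels carried into the result.
#' @return An object of class `burden_result`: `odds_ratio`, `beta`, `se`,
#'   `z`, `p_asymptotic` (two-sided Wald), `p_empirical`, `n_permutations`,
#'   `n_used`, `sv_class`, `stratum`.
#' @export
burden_test <- function(burden, phenotype, covariates = NULL, B = 10000,
                        seed = 1, sv_class = NA_character_,
                        stratum = NA_character_) {
  if (!.is_count(B, positive = TRUE)) .stopf("'B' must be a positive integer")
  y <- phenotype
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (!all(y %in% c(0, 1), na.rm = TRUE))
    .stopf("phenotype must be binary 0/1")
  if (length(burden) != length(y)) .stopf("burden/phenotype length mismatch")
  df <- data.frame(.b = burden, .y = y)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df <- df[complete.cases(df), , drop = FALSE]
  y <- df$.y
  if (length(unique(y)) < 2)
    .stopf("phenotype must contain both cases and controls")
  X <- model.matrix(~ ., data = df[, setdiff(names(df), ".y"), drop = FALSE])
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  obs <- .glmfit_z(fit, ".b")
  set.seed(seed)
  n <- length(y)
  z_perm <- numeric(B)
  for (b in seq_len(B)) {
    yp <- y[sample.int(n)]
    fp <- suppressWarnings(glm.fit(X, yp, family = binomial()))
    z_perm[b] <- .glmfit_z(fp, ".b")[["z"]]
  }
  z_perm[is.na(z_perm)] <- -Inf
  p_emp <- (1 + sum(z_perm >= obs[["z"]])) / (1 + B)
  structure(
    list(sv_class = sv_class, stratum = stratum,
         odds_ratio = exp(obs[["beta"]]), beta = obs[["beta"]],
         se = obs[["se"]], z = obs[["z"]],
         p_asymptotic = 2 * pnorm(-abs(obs[["z"]])),
         p_empirical = p_emp, n_permutations = as.integer(B),
         n_used = n),
    class = "burden_result"
  )
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf(
    "burden_result [%s/%s]: OR %.3f (beta %.4f, se %.4f), asymptotic p %.3g, one-sided empirical p %.3g (B = %d, n = %d)\n",
    x$sv_class, x$stratum, x$odds_ratio, x$beta, x$se,
    x$p_asymptotic, x$p_empirical, x$n_permutations, x$n_used
  ))
  invisible(x)
}

#' Ultra-rare CNVs on a gene list
#'
#' Selects deletion and duplication sites overlapping any listed gene
#' interval (1 bp suffices) with cohort minor allele count strictly below
#' `mac_max`, and groups them by gene.  Counts by type, singleton status
#' and (when annotation is present) protein-altering status are reported.
#'
#' @param sites site table; an optional logical `protein_altering` column
#'   feeds the annotation counts.
#' @param summaries [summarize_sites()] table supplying `mac` and
#'   `singleton` per variant id.
#' @param gene_regions data.frame `chrom`, `start` (0-based), `end`
#'   (exclusive), `gene`.
#' @param mac_max exclusive MAC bound (default 5: "MAC < 5").
#' @return list with `variants` (one row per variant/gene overlap),
#'   `by_gene` (variant ids split by gene) and `counts`
#'   (`n_del`, `n_dup`, `n_singleton`, `n_protein_altering_del`,
#'   `n_protein_altering_dup`).
#' @export
ultra_rare_set <- function(sites, summaries, gene_regions, mac_max = 5) {
  .check_sites(sites)
  req <- c("chrom", "start", "end", "gene")
  if (!is.data.frame(gene_regions) || !all(req %in% names(gene_regions)))
    .stopf("'gene_regions' needs columns %s", paste(req, collapse = ", "))
  us <- sites[!duplicated(sites$id) & sites$svtype %in% c("DEL", "DUP"), ,
              drop = FALSE]
  us$mac <- summaries$mac[match(us$id, summaries$variant_id)]
  us$singleton <- summaries$singleton[match(us$id, summaries$variant_id)]
  us <- us[!is.na(us$mac) & us$mac < mac_max, , drop = FALSE]
  empty_counts <- list(n_del = 0L, n_dup = 0L, n_singleton = 0L,
                       n_protein_altering_del = 0L,
                       n_protein_altering_dup = 0L)
  if (nrow(us) == 0 || nrow(gene_regions) == 0) {
    return(list(variants = data.frame(variant_id = character(),
                                      gene = character(),
                                      svtype = character(),
                                      mac = integer(),
                                      singleton = logical()),
                by_gene = list(), counts = empty_counts))
  }
  sgr <- GenomicRanges::GRanges(us$chrom,
                                IRanges::IRanges(us$pos, pmax(us$end, us$pos)))
  ggr <- GenomicRanges::GRanges(gene_regions$chrom,
                                IRanges::IRanges(gene_regions$start + 1L,
                                                 gene_regions$end))
  h <- GenomicRanges::findOverlaps(sgr, ggr)
  if (!length(h)) {
    return(list(variants = data.frame(variant_id = character(),
                                      gene = character(),
                                      svtype = character(),
                                      mac = integer(),
                                      singleton = logical()),
                by_gene = list(), counts = empty_counts))
  }
  qi <- S4Vectors::queryHits(h)
  pa <- if ("protein_altering" %in% names(us)) us$protein_altering else
    rep(NA, nrow(us))
  variants <- data.frame(
    variant_id = us$id[qi],
    gene = gene_regions$gene[S4Vectors::subjectHits(h)],
    svtype = us$svtype[qi],
    mac = us$mac[qi],
    singleton = us$singleton[qi],
    protein_altering = pa[qi],
    stringsAsFactors = FALSE
  )
  uv <- variants[!duplicated(variants$variant_id), , drop = FALSE]
  counts <- list(
    n_del = sum(uv$svtype == "DEL"),
    n_dup = sum(uv$svtype == "DUP"),
    n_singleton = sum(uv$singleton, na.rm = TRUE),
    n_protein_altering_del = sum(uv$svtype == "DEL" & uv$protein_altering,
                                 na.rm = TRUE),
    n_protein_altering_dup = sum(uv$svtype == "DUP" & uv$protein_altering,
                                 na.rm = TRUE)
  )
  list(variants = variants,
       by_gene = split(variants$variant_id, variants$gene),
       counts = counts)
}

#' SKAT-O-style rare-variant aggregation test
#'
#' Score-based test combining a variance-component (SKAT) and a collapsing
#' (burden) statistic over a mixing grid `rho`.  From the null model
#' (covariates only), per-variant scores `S_j = sum_i G_ij (y_i - mu_i)`
#' give `Q_rho = (1 - rho) * sum(w_j^2 S_j^2) + rho * (sum(w_j S_j))^2`.
#' Calibration is by phenotype-label permutation: each `Q_rho` is converted
#' to a permutation p-value, the observed statistic is the minimum p over
#' the grid, and the overall p-value compares that minimum against the same
#' quantity computed for every permutation (min-p method), with the
#' add-one estimator throughout.
#'
#' @param gm a [genotype_matrix()] restricted to the variant set (use
#'   `[.gm_subset]`-style subsetting or pass a dosage matrix).
#' @param phenotype 0/1 vector (binary) or numeric (quantitative).
#' @param covariates optional data.frame.
#' @param family `"binary"` or `"quantitative"`.
#' @param rho_grid mixing grid in `[0, 1]`.
#' @param weights per-variant weights; default is the Beta(1, 25) density
#'   evaluated at each variant's MAF (a common rare-variant up-weighting;
#'   not derived from any published SV analysis).
#' @param B number of permutations.
#' @param seed integer seed.
#' @return An object of class `aggregate_result`: `q_stats` (observed
#'   `Q_rho`), `p_rho` (per-rho permutation p-values), `p_empirical`,
#'   `rho_grid`, `weights`, `n_permutations`, `n_variants`, `n_used`.
#' @export
aggregate_test <- function(gm, phenotype, covariates = NULL,
                           family = c("binary", "quantitative"),
                           rho_grid = c(0, 0.01, 0.04, 0.09, 0.25, 0.5, 1),
                           weights = NULL, B = 2000, seed = 1) {
  family <- match.arg(family)
  if (!.is_count(B, positive = TRUE)) .stopf("'B' must be a positive integer")
  if (any(rho_grid < 0 | rho_grid > 1)) .stopf("'rho_grid' must lie in [0, 1]")
  G <- if (inherits(gm, "genotype_matrix")) dosages(gm) else as.matrix(gm)
  if (ncol(G) == 0) .stopf("empty variant set")
  if (nrow(G) != length(phenotype))
    .stopf("genotype rows must match phenotype length")
  y <- phenotype
  if (is.factor(y)) y <- as.integer(y) - 1L
  df <- data.frame(.y = y)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  ok <- complete.cases(df)
  df <- df[ok, , drop = FALSE]
  G <- G[ok, , drop = FALSE]
  y <- df$.y
  if (family == "binary" && !all(y %in% c(0, 1)))
    .stopf("binary family needs a 0/1 phenotype")
  # mean-impute residual missingness in the genotype block
  G <- apply(G, 2L, function(col) {
    if (anyNA(col)) col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  G <- matrix(G, nrow = length(y))
  if (is.null(weights)) {
    maf <- pmin(colMeans(G) / 2, 1 - colMeans(G) / 2)
    weights <- dbeta(pmin(pmax(maf, 1e-6), 1 - 1e-6), 1, 25)
  }
  if (length(weights) != ncol(G))
    .stopf("'weights' must have one entry per variant")

  X <- if (ncol(df) > 1) {
    model.matrix(~ ., data = df[, -1, drop = FALSE])
  } else {
    matrix(1, length(y), 1)
  }
  resid_of <- if (family == "binary") {
    function(yy) {
      f <- suppressWarnings(glm.fit(X, yy, family = binomial()))
      yy - f$fitted.values
    }
  } else {
    qr0 <- qr(X)
    function(yy) qr.resid(qr0, yy)
  }
  q_of <- function(S) {
    (1 - rho_grid) * sum((weights * S)^2) + rho_grid * sum(weights * S)^2
  }

  S_obs <- as.vector(crossprod(G, resid_of(y)))
  q_obs <- q_of(S_obs)

  set.seed(seed)
  n <- length(y)
  Qp <- matrix(NA_real_, B, length(rho_grid))
  for (b in seq_len(B)) {
    Qp[b, ] <- q_of(as.vector(crossprod(G, resid_of(y[sample.int(n)]))))
  }
  # per-rho permutation p for the observed data and for every permutation
  p_rho_obs <- vapply(seq_along(rho_grid), function(r) {
    (1 + sum(Qp[, r] >= q_obs[r])) / (1 + B)
  }, numeric(1))
  p_rho_perm <- vapply(seq_along(rho_grid), function(r) {
    # #{b' != b: Q_b' >= Q_b} = B - min-rank(Q_b); add-one as for the obs
    (1 + B - rank(Qp[, r], ties.method = "min")) / (1 + B)
  }, numeric(B))
  t_obs <- min(p_rho_obs)
  t_perm <- apply(p_rho_perm, 1L, min)
  p_emp <- (1 + sum(t_perm <= t_obs)) / (1 + B)
  structure(
    list(q_stats = setNames(q_obs, paste0("rho_", rho_grid)),
         p_rho = setNames(p_rho_obs, paste0("rho_", rho_grid)),
         p_empirical = p_emp, statistic_min_p = t_obs,
         rho_grid = rho_grid, weights = weights,
         n_permutations = as.integer(B), n_variants = ncol(G),
         n_used = n),
    class = "aggregate_result"
  )
}

#' @export
print.aggregate_result <- function(x, ...) {
  cat(sprintf(
    "aggregate_result: %d variants, n = %d; min-p statistic %.4g, empirical p %.4g (B = %d)\n",
    x$n_variants, x$n_used, x$statistic_min_p, x$p_empirical,
    x$n_permutations
  ))
  invisible(x)
}
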