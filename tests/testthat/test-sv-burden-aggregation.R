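# Stratified burden counting, permutation burden test, ultra-rare gene-set
# construction, and the SKAT-O-style aggregation statistic.

test_that("per-sample burden counts carriers by class and stratum", {
  sites <- rbind(
    make_site(id = "d1", svtype = "DEL"),
    make_site(id = "d2", svtype = "DEL", pos = 3000L, end = 3500L),
    make_site(id = "d3", svtype = "DEL", pos = 6000L, end = 6200L),
    make_site(id = "i1", svtype = "INS", qd = 0, maxaas = 9L)
  )
  sites$hq <- TRUE
  dos <- matrix(c(1L, 2L, 0L, 0L,   # sample 1 at d1..d3, i1
                  0L, 0L, 1L, 1L),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("d1", "d2", "d3", "i1")))
  gm <- genotype_matrix(dos)
  expect_equal(per_sample_burden(gm, sites, "CNV", "all"),
               c(s1 = 2L, s2 = 1L))
  expect_equal(per_sample_burden(gm, sites, "CNV", "homozygous"),
               c(s1 = 1L, s2 = 0L))
  expect_equal(per_sample_burden(gm, sites, "INS", "all"),
               c(s1 = 0L, s2 = 1L))
  expect_equal(per_sample_burden(gm, sites, "ALL", "all"),
               c(s1 = 2L, s2 = 2L))
  # singleton stratum: d1 and d3 have AC=1; d2 (a lone homozygote, AC=2)
  # is excluded even though one sample carries both alleles
  expect_equal(per_sample_burden(gm, sites, "CNV", "singleton"),
               c(s1 = 1L, s2 = 1L))
  # non-HQ sites never count
  sites$hq <- FALSE
  expect_equal(per_sample_burden(gm, sites, "CNV", "all"),
               c(s1 = 0L, s2 = 0L))
})

test_that("strata counts never exceed the all-stratum count", {
  cfg <- cohort_config(120, 800, seed = 121)
  coh <- simulate_cohort(cfg)
  sites <- add_quality_flags(prefilter_sites(select_model_records(coh$sites)))
  all_ct <- per_sample_burden(coh$genotypes, sites, "CNV", "all")
  expect_true(all(per_sample_burden(coh$genotypes, sites, "CNV",
                                    "singleton") <= all_ct))
  expect_true(all(per_sample_burden(coh$genotypes, sites, "CNV",
                                    "homozygous") <= all_ct))
})

test_that("burden test validates inputs and never returns p = 0", {
  set.seed(131)
  n <- 200
  bur <- rpois(n, 10)
  y <- rbinom(n, 1L, 0.5)
  expect_error(burden_test(bur, y, B = 0), "positive")
  expect_error(burden_test(bur, rep(1L, n), B = 10), "both cases")
  expect_error(burden_test(bur, y + 2L, B = 10), "binary")
  bt <- burden_test(bur, y, B = 99, seed = 5)
  expect_gte(bt$p_empirical, 1 / 100)
  expect_lte(bt$p_empirical, 1)
  expect_equal(bt$odds_ratio, exp(bt$beta))
  # deterministic under a fixed seed
  bt2 <- burden_test(bur, y, B = 99, seed = 5)
  expect_identical(bt$p_empirical, bt2$p_empirical)
})

test_that("burden statistic is invariant to affine covariate rescaling", {
  set.seed(132)
  n <- 300
  bur <- rpois(n, 15)
  cov1 <- data.frame(age = rnorm(n, 75, 8), pc = rnorm(n))
  cov2 <- data.frame(age = (cov1$age - 70) / 10, pc = 3 * cov1$pc + 1)
  y <- rbinom(n, 1L, plogis(0.02 * bur - 0.2))
  b1 <- burden_test(bur, y, cov1, B = 49, seed = 7)
  b2 <- burden_test(bur, y, cov2, B = 49, seed = 7)
  expect_equal(b1$z, b2$z, tolerance = 1e-8)
  expect_identical(b1$p_empirical, b2$p_empirical)
})

test_that("a planted burden effect is detected with high power", {
  set.seed(133)
  n <- 1200
  hits <- replicate(25, {
    bur <- rpois(n, 20)
    y <- rbinom(n, 1L, plogis(-1 + 0.05 * bur))
    burden_test(bur, y, B = 199, seed = sample.int(1e6, 1))$p_empirical <= 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("ultra-rare set reconstruction matches the published gene table", {
  tab <- load_gene_cnv_table(fixture_path("ad_gene_ultra_rare_cnv.tsv"),
                             n_samples = 12908)
  urs <- ultra_rare_set(tab$sites, tab$summaries, tab$gene_regions)
  expect_equal(urs$counts$n_del, 35L)
  expect_equal(urs$counts$n_dup, 10L)
  expect_equal(urs$counts$n_singleton, 34L)
  expect_equal(urs$counts$n_protein_altering_del, 14L)
  expect_equal(urs$counts$n_protein_altering_dup, 8L)
  expect_true(all(c("ABCA7", "PLCG2", "SORL1") %in% names(urs$by_gene)))
})

test_that("the MAC bound is strict and empty gene lists give empty sets", {
  sites <- rbind(make_site(id = "a"), make_site(id = "b", pos = 5000L,
                                                end = 5100L))
  sm <- data.frame(variant_id = c("a", "b"), mac = c(5L, 4L),
                   singleton = c(FALSE, FALSE))
  genes <- data.frame(chrom = "chr1", start = 0L, end = 10000L, gene = "G1")
  urs <- ultra_rare_set(sites, sm, genes, mac_max = 5)
  expect_equal(urs$variants$variant_id, "b")  # mac 5 excluded, 4 kept
  empty <- ultra_rare_set(sites, sm, genes[0, ])
  expect_equal(length(empty$by_gene), 0L)
  expect_equal(empty$counts$n_del, 0L)
})

test_that("aggregate test reduces to the single-variant score test", {
  set.seed(141)
  n <- 600
  cov <- data.frame(sex = rbinom(n, 1L, 0.5), PC1 = rnorm(n))
  g <- matrix(rbinom(n, 2L, 0.03), ncol = 1,
              dimnames = list(sprintf("s%d", 1:n), "v1"))
  y <- rbinom(n, 1L, 0.5)
  ag <- aggregate_test(g, y, cov, B = 5000, seed = 9)
  # oracle: direct permutation of the squared score from the null model
  X <- model.matrix(~ ., cov)
  res_of <- function(yy) {
    f <- suppressWarnings(glm.fit(X, yy, family = binomial()))
    yy - f$fitted.values
  }
  s_obs <- sum(g * res_of(y))^2
  set.seed(9)
  sp <- replicate(5000, sum(g * res_of(y[sample.int(n)]))^2)
  p_direct <- (1 + sum(sp >= s_obs)) / 5001
  expect_lt(abs(ag$p_empirical - p_direct), 0.02)
  # every rho gives the same ranking for a single variant
  expect_equal(unname(ag$p_rho), rep(ag$p_rho[[1]], length(ag$rho_grid)))
})

test_that("rho = 1 equals the collapsed-burden permutation oracle", {
  set.seed(142)
  n <- 600
  cov <- data.frame(PC1 = rnorm(n))
  G <- matrix(rbinom(n * 8, 2L, rep(runif(8, 0.005, 0.05), each = n)), n, 8,
              dimnames = list(sprintf("s%d", 1:n), sprintf("v%d", 1:8)))
  y <- rbinom(n, 1L, 0.5)
  w <- rep(1, 8)
  ag <- aggregate_test(G, y, cov, rho_grid = 1, weights = w, B = 5000,
                       seed = 10)
  X <- model.matrix(~ ., cov)
  res_of <- function(yy) {
    f <- suppressWarnings(glm.fit(X, yy, family = binomial()))
    yy - f$fitted.values
  }
  collapsed <- as.vector(G %*% w)
  q_obs <- sum(collapsed * res_of(y))^2
  set.seed(10)
  qp <- replicate(5000, sum(collapsed * res_of(y[sample.int(n)]))^2)
  p_coll <- (1 + sum(qp >= q_obs)) / 5001
  expect_lt(abs(ag$p_empirical - p_coll), 0.02)
})

test_that("aggregate test is calibrated under the null", {
  set.seed(143)
  n <- 500
  cov <- data.frame(sex = rbinom(n, 1L, 0.5))
  rej <- replicate(300, {
    G <- matrix(rbinom(n * 6, 2L, rep(runif(6, 0.005, 0.05), each = n)), n, 6)
    y <- rbinom(n, 1L, 0.5)
    aggregate_test(G, y, cov, B = 199,
                   seed = sample.int(1e6, 1))$p_empirical <= 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("aggregate test rejects empty sets and supports quantitative traits", {
  n <- 100
  empty <- matrix(integer(), n, 0)
  y <- rnorm(n)
  expect_error(aggregate_test(empty, y, family = "quantitative"), "empty")
  set.seed(144)
  G <- matrix(rbinom(n * 4, 2L, 0.05), n, 4)
  ag <- aggregate_test(G, y, family = "quantitative", B = 99, seed = 3)
  expect_gte(ag$p_empirical, 1 / 100)
  expect_lte(ag$p_empirical, 1)
})
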