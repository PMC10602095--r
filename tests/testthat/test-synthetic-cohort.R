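# Synthetic cohort generator: configuration validation, size/AF spectra,
# Hardy-Weinberg genotypes, LD coupling, phenotype model, determinism.

test_that("cohort_config validates proportions and counts", {
  expect_error(cohort_config(0, 10), "n_samples")
  expect_error(cohort_config(10, -1), "n_sv_sites")
  expect_error(cohort_config(10, 10, type_mix = c(DEL = 0.6, DUP = 0.5)),
               "sum to 1")
  expect_error(cohort_config(10, 10, type_mix = c(XXX = 1)), "named")
  bad_mix <- data.frame(mode_bp = 300, sd_log = 0.35, weight = 0.5)
  expect_error(cohort_config(10, 10, size_mixture = bad_mix), "sum to 1")
  expect_s3_class(cohort_config(10, 10), "cohort_config")
})

test_that("simulate_sites draws lengths from the mode-parameterised mixture", {
  cfg <- cohort_config(
    n_samples = 200, n_sv_sites = 3000,
    size_mixture = data.frame(mode_bp = 300, sd_log = 0.35, weight = 1),
    dup_model_fraction = 0, seed = 11
  )
  sites <- simulate_sites(cfg)
  spanned <- sites$svtype %in% c("DEL", "DUP", "INV")
  expect_gt(median(sites$svlen[spanned]), 200)
  expect_lt(median(sites$svlen[spanned]), 450)
  expect_true(all(sites$svlen[!is.na(sites$svlen)] >= 50))
  expect_equal(sites$end[spanned] - sites$pos[spanned], sites$svlen[spanned])
  ins <- sites$svtype == "INS"
  expect_true(all(sites$end[ins] == sites$pos[ins]))
})

test_that("simulate_sites honours edge configurations exactly", {
  expect_equal(nrow(simulate_sites(cohort_config(10, 0))), 0L)
  cfg <- cohort_config(100, 1000, dup_model_fraction = 0.5, seed = 3)
  sites <- simulate_sites(cfg)
  expect_equal(nrow(sites), 1500L)
  expect_equal(sum(table(sites$id) == 2L), 500L)
  dup_ids <- names(which(table(sites$id) == 2L))
  two_models <- vapply(dup_ids, function(i) {
    length(unique(sites$model[sites$id == i])) == 2L
  }, logical(1))
  expect_true(all(two_models))
})

test_that("BND records carry no length and exercise the prefilter", {
  cfg <- cohort_config(
    50, 400, type_mix = c(DEL = 0.5, BND = 0.5),
    dup_model_fraction = 0, seed = 5
  )
  sites <- simulate_sites(cfg)
  bnd <- sites$svtype == "BND"
  expect_gt(sum(bnd), 0)
  expect_true(all(is.na(sites$svlen[bnd])))
  expect_false(any(prefilter_sites(sites)$svtype == "BND"))
})

test_that("genotypes follow the site allele frequencies", {
  sites <- make_site(id = "v1", ac = 1L)
  sites$af <- 0.5; sites$singleton <- FALSE
  gm <- simulate_genotypes(sites, 10000, seed = 21)
  af_hat <- mean(dosages(gm)) / 2
  expect_lt(abs(af_hat - 0.5), 3 * sqrt(0.25 / (2 * 10000)))

  sites$af <- 0
  gm0 <- simulate_genotypes(sites, 500, seed = 22)
  expect_true(all(dosages(gm0) == 0L))

  sites$af <- 2
  expect_error(simulate_genotypes(sites, 10, seed = 1), "AF")
})

test_that("singleton sites get exactly one heterozygote, kept under missingness", {
  sites <- do.call(rbind, lapply(1:50, function(i) {
    s <- make_site(id = sprintf("v%02d", i))
    s$af <- 1 / 200; s$singleton <- TRUE
    s
  }))
  gm <- simulate_genotypes(sites, 100, seed = 31, missing_rate = 0.3)
  cs <- colSums(dosages(gm), na.rm = TRUE)
  expect_true(all(cs == 1L))
  expect_gt(mean(is.na(dosages(gm))), 0.2)
})

test_that("realized singleton fraction tracks the configured mass", {
  cfg <- cohort_config(300, 6000, dup_model_fraction = 0,
                       outlier_fraction = 0, seed = 41)
  coh <- simulate_cohort(cfg)
  sm <- summarize_sites(coh$genotypes)
  expect_lt(abs(mean(sm$singleton) - 0.24), 0.03)
})

test_that("couple_ld_pair hits the target r2", {
  set.seed(51)
  d <- rbinom(5000, 2, 0.2)
  s1 <- couple_ld_pair(ld_pair_spec("sv", "snv", 1), d, seed = 52)
  expect_identical(as.integer(s1), as.integer(d))
  expect_equal(attr(s1, "realized_r2"), 1)

  s0 <- couple_ld_pair(ld_pair_spec("sv", "snv", 0), d, seed = 53)
  expect_lt(attr(s0, "realized_r2"), 0.01)

  s9 <- couple_ld_pair(ld_pair_spec("sv", "snv", 0.9), d, seed = 54)
  expect_gt(attr(s9, "realized_r2"), 0.85)
  expect_lt(attr(s9, "realized_r2"), 0.95)

  expect_warning(
    couple_ld_pair(ld_pair_spec("sv", "snv", 0.5), rep(0L, 100), seed = 55),
    "monomorphic"
  )
  expect_error(ld_pair_spec("a", "b", 1.2), "target_r2")
})

test_that("null phenotype model gives a balanced cohort", {
  gm <- dose_mat(matrix(0L, 10000, 1))
  ph <- simulate_phenotypes(gm, NULL, effect_plan(intercept = 0), seed = 61)
  expect_lt(abs(mean(ph$status == "case") - 0.5), 0.02)
  expect_true(all(ph$age_type[ph$status == "case"] == "onset"))
  expect_true(all(ph$age_type[ph$status == "control"] == "last_exam"))
})

test_that("planted burden effect is recovered as an odds ratio", {
  # two burden groups, 0 vs 10 CNVs, log-odds 0.1 per CNV => group OR = e
  n <- 10000
  sites <- do.call(rbind, lapply(1:10, function(i) {
    s <- make_site(id = sprintf("b%02d", i), svtype = "DEL")
    s$af <- 0.5; s$singleton <- FALSE
    s
  }))
  set.seed(71)
  grp <- rep(c(0L, 1L), each = n / 2)
  dos <- matrix(rep(grp, 10), n, 10,
                dimnames = list(sprintf("s%05d", 1:n), sites$id))
  gm <- genotype_matrix(dos)
  plan <- effect_plan(intercept = -0.5, burden_beta = 0.1)
  ph <- simulate_phenotypes(gm, NULL, plan, seed = 72, sites = sites)
  fit <- glm((ph$status == "case") ~ grp, family = binomial())
  or_grp <- exp(coef(fit)[["grp"]])
  expect_lt(abs(or_grp - exp(1)) / exp(1), 0.15)
})

test_that("quantitative traits centre on the intercept", {
  gm <- dose_mat(matrix(0L, 2000, 1))
  plan <- effect_plan(intercept = 3, trait_model = "quantitative")
  ph <- simulate_phenotypes(gm, NULL, plan, seed = 81)
  expect_lt(abs(mean(ph$trait) - 3), 3 / sqrt(2000))
  expect_true(all(ph$status == "unknown"))
})

test_that("site_betas must reference generated variants", {
  gm <- dose_mat(matrix(0L, 10, 2))
  plan <- effect_plan(site_betas = c(nope = 1))
  expect_error(simulate_phenotypes(gm, NULL, plan, seed = 1), "nope")
})

test_that("a fixed seed reproduces the cohort byte for byte", {
  cfg <- cohort_config(60, 150, seed = 91)
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  c1 <- simulate_cohort(cfg)
  write_cohort(c1$sites, c1$genotypes, c1$samples, d1,
               truth = list(seed = 91))
  c2 <- simulate_cohort(cfg)
  write_cohort(c2$sites, c2$genotypes, c2$samples, d2,
               truth = list(seed = 91))
  for (f in c("sv.vcf", "phenotypes.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("writing zero samples yields a header-only VCF", {
  sites <- make_site()
  sites$af <- 0.1; sites$singleton <- FALSE
  gm <- genotype_matrix(matrix(integer(), 0, 1, dimnames = list(NULL, "s1")))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(sites[0, ], gm, path)
  lines <- readLines(path)
  expect_true(all(startsWith(lines, "#")))
})
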