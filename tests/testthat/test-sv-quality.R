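# High-quality clause truth tables (with strict boundaries), region masks,
# problematic flagging against a brute-force oracle, and high-confident
# insertion classification.

test_that("deletion clauses follow the truth table including boundaries", {
  base <- site_maker(svtype = "DEL", qd = 12.5, abhet = -1, ac = 3L,
                     num_merged_svs = 1L, pass_ac = 1L, pass_ratio = 0.2)
  expect_true(is_high_quality(base()))
  expect_true(is_high_quality(base(abhet = 0.31)))
  expect_false(is_high_quality(base(qd = 12)))          # QD > 12 strict
  expect_false(is_high_quality(base(abhet = 0.30)))     # ABHet > 0.30 strict
  expect_false(is_high_quality(base(ac = 25L)))         # AC/NUM < 25 strict
  expect_true(is_high_quality(base(ac = 25L, num_merged_svs = 2L)))
  expect_false(is_high_quality(base(pass_ac = 0L)))     # PASS_AC > 0 strict
  expect_false(is_high_quality(base(pass_ratio = 0.1))) # ratio > 0.1 strict
  expect_false(is_high_quality(base(qd = NA)))          # missing metric fails
})

test_that("duplication clauses use only QD, PASS_AC and the merge ratio", {
  base <- site_maker(svtype = "DUP", qd = 5.5, abhet = 0.1, ac = 3L,
                     num_merged_svs = 1L, pass_ac = 1L, pass_ratio = 0.01,
                     maxaas = 0L)
  expect_true(is_high_quality(base()))   # ABHet/ratio/MaxAAS irrelevant
  expect_false(is_high_quality(base(qd = 5)))
  expect_false(is_high_quality(base(pass_ac = 0L)))
  expect_false(is_high_quality(base(ac = 50L)))
})

test_that("insertion and inversion clauses share their table", {
  for (tp in c("INS", "INV")) {
    base <- site_maker(svtype = tp, qd = 0, abhet = 0.5, ac = 2L,
                       num_merged_svs = 1L, pass_ac = 1L, pass_ratio = 0.2,
                       maxaas = 5L)
    expect_true(is_high_quality(base()), label = tp)
    expect_false(is_high_quality(base(maxaas = 4L)))    # MaxAAS > 4 strict
    expect_false(is_high_quality(base(abhet = 0.25)))   # ABHet > 0.25 strict
    expect_true(is_high_quality(base(abhet = -1)))      # sentinel passes
    expect_false(is_high_quality(base(pass_ratio = 0.1)))
    expect_false(is_high_quality(base(pass_ac = 0L)))
  }
})

test_that("is_high_quality is pure and rejects breakends", {
  s <- make_site()
  expect_identical(is_high_quality(s), is_high_quality(s))
  expect_error(is_high_quality(make_site(svtype = "BND")), "BND")
})

test_that("simulated cohorts realise the configured high-quality fraction", {
  for (f in c(0.2, 0.42, 0.8)) {
    cfg <- cohort_config(150, 2000, hq_pass_fraction = f,
                         dup_model_fraction = 0, seed = 100 + round(100 * f))
    sites <- simulate_sites(cfg)
    expect_lt(abs(mean(is_high_quality(sites)) - f), 0.05, label = f)
  }
})

test_that("region masks are merged unions in BED coordinates", {
  bed1 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t150\t300"), bed1)
  rs <- load_region_mask(bed1)
  expect_equal(rs$intervals,
               data.frame(chrom = "chr1", start = 100L, end = 300L,
                          stringsAsFactors = FALSE))

  bed2 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr2\t10\t50", "chr2\t60\t90"), bed2)
  rs2 <- load_region_mask(c(bed1, bed2))
  expect_equal(nrow(rs2$intervals), 3L)
  expect_equal(rs2$intervals$chrom, c("chr1", "chr2", "chr2"))

  expect_equal(nrow(load_region_mask(character())$intervals), 0L)
  expect_error(load_region_mask("/nonexistent.bed"), "no such")
})

test_that("random masks merge identically to a brute-force union", {
  set.seed(210)
  for (rep in 1:5) {
    n <- 60
    start <- sample.int(5000, n)
    len <- sample.int(300, n, replace = TRUE)
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    rs <- region_set(chrom, start, start + len)
    # oracle: positions covered per chromosome
    for (cc in unique(chrom)) {
      covered <- rep(FALSE, 6000)
      for (i in which(chrom == cc)) {
        covered[(start[i] + 1):(start[i] + len[i])] <- TRUE
      }
      iv <- rs$intervals[rs$intervals$chrom == cc, ]
      merged <- rep(FALSE, 6000)
      for (j in seq_len(nrow(iv))) merged[(iv$start[j] + 1):iv$end[j]] <- TRUE
      expect_identical(merged, covered)
      expect_true(all(diff(iv$start) > 0))
      expect_true(all(iv$start[-1] > iv$end[-nrow(iv)]))  # disjoint
    }
  }
})

test_that("problematic flagging matches containment examples", {
  mask <- region_set("chr1", 100L, 200L)
  del_in <- make_site(id = "a", pos = 101L, end = 150L)
  expect_true(flag_problematic(del_in, mask)$problematic)
  ins_out <- make_site(id = "b", svtype = "INS", pos = 500L, end = 500L)
  mask2 <- region_set("chr1", 600L, 700L)
  expect_false(flag_problematic(ins_out, mask2)$problematic)
  ins_in <- make_site(id = "c", svtype = "INS", pos = 650L, end = 650L)
  expect_true(flag_problematic(ins_in, mask2)$problematic)
  # 1 bp of boundary overlap is enough
  del_edge <- make_site(id = "d", pos = 50L, end = 101L)
  expect_true(flag_problematic(del_edge, mask)$problematic)
  # mask (100,200) 0-based is 1-based [101,200]; a span ending at 100 misses it
  del_miss <- make_site(id = "e", pos = 50L, end = 100L)
  expect_false(flag_problematic(del_miss, mask)$problematic)
})

test_that("problematic flagging agrees with a brute-force overlap oracle", {
  set.seed(220)
  n_mask <- 40
  ms <- sample.int(100000, n_mask)
  mask_df <- data.frame(chrom = sample(c("chr1", "chr2"), n_mask, TRUE),
                        start = ms, end = ms + sample.int(500, n_mask, TRUE))
  mask <- region_set(mask_df$chrom, mask_df$start, mask_df$end)
  pos <- sample.int(100000, 1000)
  tp <- sample(c("DEL", "DUP", "INV", "INS"), 1000, replace = TRUE)
  len <- sample.int(400, 1000, replace = TRUE)
  sites <- data.frame(
    id = sprintf("s%04d", 1:1000),
    chrom = sample(c("chr1", "chr2"), 1000, replace = TRUE),
    pos = pos, end = ifelse(tp == "INS", pos, pos + len), svtype = tp,
    stringsAsFactors = FALSE
  )
  got <- flag_problematic(sites, mask)$problematic
  expect_identical(got, brute_problematic(sites, mask_df))
})

test_that("high-confident classification is insertion-only and flag-driven", {
  ins_good <- make_site(id = "i1", svtype = "INS", qd = 0, abhet = 0.5,
                        maxaas = 9L)
  ins_bad <- make_site(id = "i2", svtype = "INS", pos = 150L, end = 150L,
                       qd = 0, abhet = 0.5, maxaas = 9L)
  del <- make_site(id = "d1")
  sites <- add_quality_flags(rbind(ins_good, ins_bad, del),
                             mask = region_set("chr1", 100L, 200L))
  hc <- classify_high_confident_insertions(sites)
  expect_equal(hc$id, "i1")
  expect_true(all(sites$hq))
  expect_false("d1" %in% hc$id)
})
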