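# Shared fixtures and independent brute-force oracles.

# Site constructor over a default argument list, overridable per call
# (make_site defaults + `base` overrides + per-call overrides).
site_maker <- function(...) {
  base <- list(...)
  function(...) do.call(make_site, utils::modifyList(base, list(...)))
}

# Quick site-row constructor with passing DEL metrics by default.
make_site <- function(id = "s1", chrom = "chr1", pos = 1000L, end = 2000L,
                      svtype = "DEL", svlen = NULL, model = "aggregated",
                      qd = 20, abhet = 0.5, ac = 2L, an = 100L,
                      num_merged_svs = 1L, pass_ac = 1L, pass_ratio = 0.5,
                      maxaas = 10L) {
  if (is.null(svlen)) {
    svlen <- if (svtype %in% c("DEL", "DUP", "INV")) end - pos else 0L
  }
  data.frame(id = id, chrom = chrom, pos = as.integer(pos),
             end = as.integer(end), svtype = svtype,
             svlen = as.integer(svlen), model = model, qd = qd,
             abhet = abhet, ac = as.integer(ac), an = as.integer(an),
             num_merged_svs = as.integer(num_merged_svs),
             pass_ac = as.integer(pass_ac), pass_ratio = pass_ratio,
             maxaas = as.integer(maxaas), stringsAsFactors = FALSE)
}

make_sites <- function(...) do.call(rbind, list(...))

# O(n*m) overlap oracle: does site i overlap any 0-based half-open interval?
brute_problematic <- function(sites, mask_df) {
  vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    lo <- s$pos
    hi <- if (s$svtype %in% c("DEL", "DUP", "INV")) max(s$end, s$pos) else s$pos
    any(mask_df$chrom == s$chrom &
          (mask_df$start + 1L) <= hi & mask_df$end >= lo)
  }, logical(1))
}

# O(n^2) matcher oracle: same candidate rule and greedy policy as
# match_callsets, written as plain double loops.
brute_match <- function(query, ref, ro = 0.5, win = 500) {
  cand <- NULL
  for (i in seq_len(nrow(query))) {
    for (j in seq_len(nrow(ref))) {
      if (query$svtype[i] != ref$svtype[j]) next
      if (query$chrom[i] != ref$chrom[j]) next
      tp <- query$svtype[i]
      if (tp %in% c("DEL", "DUP", "INV")) {
        la <- query$end[i] - query$pos[i]
        lb <- ref$end[j] - ref$pos[j]
        if (la <= 0 || lb <= 0) next
        ov <- min(query$end[i], ref$end[j]) - max(query$pos[i], ref$pos[j])
        if (ov <= 0) next
        if (ov / la >= ro && ov / lb >= ro) {
          cand <- rbind(cand, data.frame(q = i, r = j,
                                         score = min(ov / la, ov / lb),
                                         rs = ref$pos[j]))
        }
      } else if (tp == "INS") {
        d <- abs(query$pos[i] - ref$pos[j])
        if (d <= win) {
          cand <- rbind(cand, data.frame(q = i, r = j, score = -d,
                                         rs = ref$pos[j]))
        }
      }
    }
  }
  if (is.null(cand)) {
    return(data.frame(query_id = character(), ref_id = character()))
  }
  cand <- cand[order(-cand$score, cand$rs, cand$q), , drop = FALSE]
  uq <- logical(nrow(query)); ur <- logical(nrow(ref))
  out <- NULL
  for (k in seq_len(nrow(cand))) {
    if (!uq[cand$q[k]] && !ur[cand$r[k]]) {
      uq[cand$q[k]] <- TRUE; ur[cand$r[k]] <- TRUE
      out <- rbind(out, cand[k, ])
    }
  }
  data.frame(query_id = query$id[out$q], ref_id = ref$id[out$r],
             stringsAsFactors = FALSE)
}

# Random callset for matcher stress tests.
random_callset <- function(n, seed, prefix = "q") {
  set.seed(seed)
  tp <- sample(c("DEL", "DUP", "INV", "INS"), n, replace = TRUE,
               prob = c(0.4, 0.2, 0.1, 0.3))
  pos <- sample.int(2e6, n, replace = TRUE)
  len <- pmax(50L, as.integer(round(rlnorm(n, log(500), 1))))
  end <- ifelse(tp == "INS", pos, pos + len)
  data.frame(id = sprintf("%s%04d", prefix, seq_len(n)),
             chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
             pos = pos, end = as.integer(end), svtype = tp,
             stringsAsFactors = FALSE)
}

# Dosage matrix wrapper with default names.
dose_mat <- function(dos, samples = NULL, variants = NULL) {
  if (is.null(samples)) samples <- sprintf("smp%03d", seq_len(nrow(dos)))
  if (is.null(variants)) variants <- sprintf("var%03d", seq_len(ncol(dos)))
  dimnames(dos) <- list(samples, variants)
  genotype_matrix(dos)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "svcohort", mustWork = TRUE)
}
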