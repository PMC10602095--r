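# Loader for published-style tables of CNVs on candidate genes with
# per-group allele counts, turning them into the site/summary/gene-region
# shapes the aggregation module consumes.

#' Load a gene CNV count table
#'
#' Reads a TSV with columns `chrom`, `pos`, `end`, `svtype`, `ac_case`,
#' `ac_control`, `gene` and optionally `protein_altering`, and builds the
#' three inputs of [ultra_rare_set()]: a site table (with
#' `svlen = end - pos` and the annotation column), a per-variant summary
#' table whose `ac` is the summed case and control allele counts over
#' `n_samples` diploid genomes, and per-gene regions spanning each gene's
#' variants.  A packaged example (ultra-rare deletions and duplications on
#' curated candidate genes for Alzheimer's disease, transcribed from a
#' published cohort table) ships as
#' `system.file("extdata", "ad_gene_ultra_rare_cnv.tsv", package = "svcohort")`.
#'
#' @param path TSV path.
#' @param n_samples number of analysis samples behind the allele counts
#'   (`an = 2 * n_samples`, assuming full call rate).
#' @return list with `sites`, `summaries`, `gene_regions`, `n_samples`.
#' @export
load_gene_cnv_table <- function(path, n_samples) {
  if (!.is_count(n_samples, positive = TRUE))
    .stopf("'n_samples' must be a positive count")
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "end", "svtype", "ac_case", "ac_control", "gene")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    .stopf("table is missing column(s): %s", paste(miss, collapse = ", "))
  an <- 2L * as.integer(n_samples)
  ac <- tab$ac_case + tab$ac_control
  sites <- data.frame(
    id = sprintf("%s:%d-%d:%s", tab$chrom, tab$pos, tab$end, tab$svtype),
    chrom = tab$chrom, pos = as.integer(tab$pos), end = as.integer(tab$end),
    svtype = tab$svtype, svlen = as.integer(tab$end - tab$pos),
    model = "aggregated",
    gene = tab$gene,
    protein_altering = if ("protein_altering" %in% names(tab))
      as.logical(tab$protein_altering) else NA,
    stringsAsFactors = FALSE
  )
  summaries <- data.frame(
    variant_id = sites$id,
    ac = as.integer(ac), an = an, af = ac / an,
    mac = as.integer(pmin(ac, an - ac)),
    ac_case = as.integer(tab$ac_case),
    ac_control = as.integer(tab$ac_control),
    missing_rate = 0,
    singleton = ac == 1L,
    rare = ac / an < 0.01,
    stringsAsFactors = FALSE
  )
  gene_regions <- do.call(rbind, lapply(split(sites, sites$gene), function(s) {
    data.frame(chrom = s$chrom[1], start = min(s$pos) - 1L, end = max(s$end),
               gene = s$gene[1], stringsAsFactors = FALSE)
  }))
  rownames(gene_regions) <- NULL
  list(sites = sites, summaries = summaries, gene_regions = gene_regions,
       n_samples = as.integer(n_samples))
}
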