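# Multi-sample SV VCF reading/writing, multi-model duplicate resolution and
# the callset prefilters (breakend removal, 10 Mb size cap).

.VCF_INFO_HEADER <- c(
  '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
  '##INFO=<ID=END,Number=1,Type=Integer,Description="End position of the variant">',
  '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Length of the variant (negative for deletions)">',
  '##INFO=<ID=AC,Number=1,Type=Integer,Description="Alternate allele count over called genotypes">',
  '##INFO=<ID=AN,Number=1,Type=Integer,Description="Number of called alleles">',
  '##INFO=<ID=NUM_MERGED_SVS,Number=1,Type=Integer,Description="Number of SVs merged into this record">',
  '##INFO=<ID=QD,Number=1,Type=Float,Description="QUAL divided by non-reference sequence depth">',
  '##INFO=<ID=ABHet,Number=1,Type=Float,Description="Allele balance of heterozygous calls; -1 if no heterozygous calls">',
  '##INFO=<ID=PASS_AC,Number=1,Type=Integer,Description="Alternate alleles in genotypes with FT PASS">',
  '##INFO=<ID=PASS_ratio,Number=1,Type=Float,Description="Fraction of genotype calls with FT PASS">',
  '##INFO=<ID=MaxAAS,Number=1,Type=Integer,Description="Maximum alternate allele support">',
  '##INFO=<ID=MODEL,Number=1,Type=String,Description="Genotyping model: aggregated, breakpoint or coverage">',
  '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
  '##FORMAT=<ID=FT,Number=1,Type=String,Description="Per-call filter">'
)

.fmt_num <- function(x, digits = 4) {
  ifelse(is.na(x), NA_character_, formatC(x, digits = digits, format = "f"))
}

#' Write a multi-sample SV VCF
#'
#' Emits VCF 4.2 with INFO keys `SVTYPE`, `END`, `SVLEN`, `AC`, `AN`,
#' `NUM_MERGED_SVS`, `QD`, `ABHet`, `PASS_AC`, `PASS_ratio`, `MaxAAS`,
#' `MODEL` and FORMAT `GT:FT`.  `AC`/`AN` are recomputed from the genotype
#' matrix so the file round-trips exactly.  BND records carry no `END` or
#' `SVLEN`; deletions are written with negative `SVLEN` per VCF convention.
#' Output is deterministic (fixed number formatting, no timestamps).
#'
#' @param sites site table, one row per record; duplicate model records of
#'   one locus share an `id` and one genotype column.
#' @param gm a [genotype_matrix()] whose variant ids cover `sites$id`; pass
#'   `NULL` for a site-only VCF without sample columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(sites, gm, path) {
  .check_sites(sites, c("id", "chrom", "pos", "end", "svtype"))
  n_rec <- nrow(sites)
  have_gt <- !is.null(gm) && length(sample_ids(gm)) > 0
  if (have_gt) {
    missing_ids <- setdiff(sites$id, variant_ids(gm))
    if (length(missing_ids))
      .stopf("genotype matrix lacks %d site id(s), e.g. %s",
             length(missing_ids), missing_ids[1])
  }
  chroms <- unique(sites$chrom)
  chroms <- chroms[order(match(chroms, names(.CHROM_LEN)), chroms)]
  contig <- sprintf(
    "##contig=<ID=%s%s>", chroms,
    ifelse(chroms %in% names(.CHROM_LEN),
           sprintf(",length=%d", .CHROM_LEN[chroms]), "")
  )
  header <- c("##fileformat=VCFv4.2", "##source=svcohort",
              .VCF_INFO_HEADER, contig,
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", if (have_gt) c("FORMAT", sample_ids(gm))),
                    collapse = "\t"))
  lines <- header
  if (n_rec > 0) {
    g <- function(col) if (col %in% names(sites)) sites[[col]] else rep(NA, n_rec)
    ac <- g("ac"); an <- g("an")
    if (have_gt) {
      dos <- dosages(gm)[, sites$id, drop = FALSE]
      ac <- as.integer(colSums(dos, na.rm = TRUE))
      an <- as.integer(2L * colSums(!is.na(dos)))
    }
    kv <- function(key, val) ifelse(is.na(val), NA, paste0(key, "=", val))
    spanned <- sites$svtype %in% c("DEL", "DUP", "INV", "INS")
    svlen_signed <- ifelse(sites$svtype == "DEL", -1L, 1L) * g("svlen")
    info_parts <- cbind(
      kv("SVTYPE", sites$svtype),
      ifelse(spanned, kv("END", sites$end), NA),
      ifelse(sites$svtype == "BND", NA, kv("SVLEN", svlen_signed)),
      kv("AC", ac), kv("AN", an),
      kv("NUM_MERGED_SVS", g("num_merged_svs")),
      kv("QD", .fmt_num(g("qd"))),
      kv("ABHet", .fmt_num(g("abhet"))),
      kv("PASS_AC", g("pass_ac")),
      kv("PASS_ratio", .fmt_num(g("pass_ratio"))),
      kv("MaxAAS", g("maxaas")),
      kv("MODEL", g("model"))
    )
    info <- apply(info_parts, 1L, function(p) paste(p[!is.na(p)], collapse = ";"))
    rec <- paste(sites$chrom, sites$pos, sites$id, "N",
                 paste0("<", sites$svtype, ">"), ".", ".", info, sep = "\t")
    if (have_gt) {
      gt_str <- c("0/0", "0/1", "1/1")[dos + 1L]
      gt_str[is.na(gt_str)] <- "./."
      ft <- gm$ft_pass
      if (is.null(ft)) {
        ft_str <- matrix(".", nrow(dos), ncol(dos))
      } else {
        ft <- ft[, sites$id, drop = FALSE]
        ft_str <- ifelse(is.na(ft), ".", ifelse(ft, "PASS", "FAIL"))
      }
      cells <- matrix(paste0(gt_str, ":", ft_str), nrow = nrow(dos))
      gt_cols <- apply(cells, 2L, paste, collapse = "\t")
      rec <- paste(rec, "GT:FT", gt_cols, sep = "\t")
    }
    lines <- c(lines, rec)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

.gt_to_dosage <- function(g) {
  out <- rep(NA_integer_, length(g))
  out[g %in% c("0/0", "0|0", "0")] <- 0L
  out[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  out[g %in% c("1/1", "1|1", "1")] <- 2L
  out
}

#' Read a multi-sample SV VCF
#'
#' Parses a VCF 4.2 SV file into a site table (one row per record, duplicate
#' model records preserved) and a [genotype_matrix()] built from `GT`
#' (missing for `./.`) and `FT`.  Missing INFO keys yield sentinel values:
#' `ABHet` becomes -1 (the "no heterozygous calls" sentinel), `AC`/`AN` are
#' recomputed from genotypes, other metrics become `NA`.  Multi-allelic
#' records are rejected.
#'
#' @param path VCF path (plain or bgzipped).
#' @return list with `sites` (data.frame) and `genotypes`
#'   ([genotype_matrix()]; zero columns share the first record's genotypes
#'   across duplicate model records of one id).
#' @export
read_sv_vcf <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  v <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
    error = function(e) .stopf("failed to parse VCF '%s': %s",
                               path, conditionMessage(e))
  )
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) {
    empty <- genotype_matrix(matrix(integer(), 0, 0))
    return(list(sites = .empty_sites(), genotypes = empty))
  }
  alt <- fix[, "ALT"]
  bad <- grepl(",", alt, fixed = TRUE)
  if (any(bad))
    .stopf("multi-allelic record not supported (record %d: ALT '%s')",
           which(bad)[1], alt[which(bad)[1]])

  info_chr <- function(key) {
    x <- suppressWarnings(vcfR::extract.info(v, element = key))
    if (is.null(x)) rep(NA_character_, nrow(fix)) else as.character(x)
  }
  info_num <- function(key) suppressWarnings(as.numeric(info_chr(key)))

  svtype <- info_chr("SVTYPE")
  from_alt <- gsub("[<>]", "", alt)
  svtype[is.na(svtype) & from_alt %in% .SV_TYPES] <- from_alt[is.na(svtype) & from_alt %in% .SV_TYPES]
  if (any(is.na(svtype) | !svtype %in% .SV_TYPES))
    .stopf("record %d has unknown SVTYPE", which(is.na(svtype) | !svtype %in% .SV_TYPES)[1])

  pos <- as.integer(fix[, "POS"])
  end <- as.integer(info_num("END"))
  svlen <- abs(as.integer(info_num("SVLEN")))
  spanned <- svtype %in% c("DEL", "DUP", "INV")
  end[svtype %in% c("INS", "BND")] <- pos[svtype %in% c("INS", "BND")]
  end[spanned & is.na(end)] <- pos[spanned & is.na(end)] + svlen[spanned & is.na(end)]
  if (any(spanned & is.na(end)))
    .stopf("record %d (%s) lacks both END and SVLEN",
           which(spanned & is.na(end))[1], svtype[which(spanned & is.na(end))[1]])
  # length convention: breakpoint distance end - pos for spanned types;
  # insertions use |SVLEN| when present, else 0; breakends have none
  svlen[spanned] <- end[spanned] - pos[spanned]
  svlen[svtype == "INS" & is.na(svlen)] <- 0L
  svlen[svtype == "BND"] <- NA_integer_

  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- sprintf("site%06d", which(is.na(ids) | ids == "."))

  model <- info_chr("MODEL")
  abhet <- info_num("ABHet")
  abhet[is.na(abhet)] <- -1

  n_samp <- if (ncol(v@gt) > 1) ncol(v@gt) - 1L else 0L
  uniq <- !duplicated(ids)
  if (n_samp > 0) {
    gt <- vcfR::extract.gt(v, element = "GT", IDtoRowNames = FALSE)
    dos <- matrix(.gt_to_dosage(gt), nrow = nrow(gt),
                  dimnames = list(NULL, colnames(gt)))
    ft <- suppressWarnings(vcfR::extract.gt(v, element = "FT",
                                            IDtoRowNames = FALSE))
    ftp <- if (is.null(ft)) NULL else {
      m <- matrix(NA, nrow(gt), ncol(gt))
      m[ft == "PASS"] <- TRUE
      m[!is.na(ft) & ft != "PASS" & ft != "."] <- FALSE
      m
    }
    dos_u <- t(dos[uniq, , drop = FALSE])
    colnames(dos_u) <- ids[uniq]
    ftp_u <- if (is.null(ftp)) NULL else {
      x <- t(ftp[uniq, , drop = FALSE]); colnames(x) <- ids[uniq]; x
    }
    gmx <- genotype_matrix(dos_u, ftp_u)
    ac_rec <- as.integer(colSums(dos_u, na.rm = TRUE))[match(ids, ids[uniq])]
    an_rec <- as.integer(2L * colSums(!is.na(dos_u)))[match(ids, ids[uniq])]
  } else {
    gmx <- genotype_matrix(matrix(integer(), 0, sum(uniq),
                                  dimnames = list(NULL, ids[uniq])))
    ac_rec <- as.integer(info_num("AC"))
    an_rec <- as.integer(info_num("AN"))
  }
  ac_info <- as.integer(info_num("AC"))
  an_info <- as.integer(info_num("AN"))
  if (n_samp == 0) {
    ac_rec <- ac_info
    an_rec <- an_info
  }

  sites <- data.frame(
    id = ids, chrom = fix[, "CHROM"], pos = pos, end = end, svtype = svtype,
    svlen = svlen, model = model,
    qd = info_num("QD"), abhet = abhet, ac = ac_rec, an = an_rec,
    num_merged_svs = as.integer(info_num("NUM_MERGED_SVS")),
    pass_ac = as.integer(info_num("PASS_AC")),
    pass_ratio = info_num("PASS_ratio"),
    maxaas = as.integer(info_num("MaxAAS")),
    stringsAsFactors = FALSE
  )
  rownames(sites) <- NULL
  list(sites = sites, genotypes = gmx)
}

#' Resolve multi-model duplicate records
#'
#' A joint genotyper can emit one SV under several algorithmic models
#' (aggregated, breakpoint, coverage), producing duplicate VCF records of a
#' single locus.  This keeps exactly one record per identity key
#' `(chrom, pos, end, svtype)`: the first model present in the priority
#' order aggregated > breakpoint > coverage.  Record order is otherwise
#' preserved, and the operation is idempotent.
#'
#' @param sites site table with a `model` column (records with `NA` model
#'   rank last).
#' @return Deduplicated site table.
#' @export
select_model_records <- function(sites) {
  .check_sites(sites, c("chrom", "pos", "end", "svtype"))
  if (nrow(sites) == 0) return(sites)
  key <- paste(sites$chrom, sites$pos, sites$end, sites$svtype, sep = "\r")
  rank <- match(sites$model %||% rep(NA, nrow(sites)), .MODELS)
  rank[is.na(rank)] <- length(.MODELS) + 1L
  idx <- seq_len(nrow(sites))
  o <- order(rank, idx)  # stable: best model first, earlier record wins ties
  keep <- o[!duplicated(key[o])]
  out <- sites[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prefilter a callset: drop breakends and giant SVs
#'
#' Removes all BND records (unresolved breakends have no resolved type or
#' span) and every site longer than 10 Mb (strictly greater; a 10,000,000 bp
#' deletion is kept).  Insertions without a known length are never removed
#' by the size cap.  Order is preserved.
#'
#' @param sites site table.
#' @param max_svlen size cap in bp (default 10 Mb).
#' @return Filtered site table.
#' @export
prefilter_sites <- function(sites, max_svlen = 1e7) {
  .check_sites(sites, c("svtype"))
  if (nrow(sites) == 0) return(sites)
  svlen <- if ("svlen" %in% names(sites)) sites$svlen else rep(NA, nrow(sites))
  keep <- sites$svtype != "BND" & (is.na(svlen) | svlen <= max_svlen)
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
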