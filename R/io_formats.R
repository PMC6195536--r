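default_column_map <- function() {
  c(snp_id = "snp", chrom = "chr", pos = "pos", allele_effect = "a1",
    allele_other = "a2", betahat = "betahat", se = "se", n = "n")
}

# natural chromosome ordering: 1..22, X, Y, then anything else
chrom_order <- function(chrom) {
  ch <- sub("^chr", "", as.character(chrom))
  num <- suppressWarnings(as.integer(ch))
  num[ch %in% c("X", "x")] <- 23L
  num[ch %in% c("Y", "y")] <- 24L
  num[is.na(num)] <- 25L
  num
}

is_sex_chrom <- function(chrom) chrom_order(chrom) %in% c(23L, 24L)

#' Read GWAS summary statistics from delimited text
#'
#' Parses a delimited file with a header into the standard summary-statistic
#' table: one row per SNP with identifier, coordinates, effect and other
#' allele, the single-SNP effect estimate `betahat`, its standard error `se`
#' and the sample size `n`.  Rows whose `betahat` or `se` does not parse to
#' a finite number (or with `se <= 0`) are dropped with a reported count;
#' output is sorted by chromosome and position.
#'
#' @param path Path to the delimited file (separator sniffed by
#'   [data.table::fread()]).
#' @param column_map Named character vector mapping the required internal
#'   names (`snp_id`, `chrom`, `pos`, `allele_effect`, `allele_other`,
#'   `betahat`, `se`, `n`) to the file's column names.  Defaults to
#'   `snp, chr, pos, a1, a2, betahat, se, n`.
#' @return data.frame with the standard columns; the number of dropped rows
#'   is attached as attribute `n_dropped`.
#' @export
read_summary_stats <- function(path, column_map = default_column_map()) {
  req <- default_column_map()
  miss_map <- setdiff(names(req), names(column_map))
  if (length(miss_map)) column_map <- c(column_map, req[miss_map])
  dt <- as.data.frame(data.table::fread(path, na.strings = c("NA", "", ".")))
  missing_cols <- setdiff(unname(column_map), names(dt))
  if (length(missing_cols))
    stop("summary-statistic file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(
    snp_id = as.character(dt[[column_map["snp_id"]]]),
    chrom = as.character(dt[[column_map["chrom"]]]),
    pos = as.integer(dt[[column_map["pos"]]]),
    allele_effect = toupper(as.character(dt[[column_map["allele_effect"]]])),
    allele_other = toupper(as.character(dt[[column_map["allele_other"]]])),
    betahat = as.numeric(dt[[column_map["betahat"]]]),
    se = as.numeric(dt[[column_map["se"]]]),
    n = as.numeric(dt[[column_map["n"]]]),
    stringsAsFactors = FALSE)
  bad <- !is.finite(out$betahat) | !is.finite(out$se) | out$se <= 0 |
    !is.finite(out$n) | out$n < 1
  if (any(bad)) {
    message("read_summary_stats: dropped ", sum(bad),
            " row(s) with non-finite or invalid betahat/se/n")
    out <- out[!bad, , drop = FALSE]
  }
  dup <- duplicated(out$snp_id)
  if (any(dup))
    stop("duplicate snp_id in summary statistics: ",
         paste(head(unique(out$snp_id[dup]), 5), collapse = ", "))
  out <- out[order(chrom_order(out$chrom), out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(bad)
  out
}

#' Default major-histocompatibility-complex exclusion window
#'
#' chr6:25,000,000-35,000,000 (GRCh37); a deliberately generous window
#' around the MHC, whose exceptionally long-range LD violates the banded
#' model.
#'
#' @return One-row data.frame with `chrom`, `start`, `end`.
#' @export
mhc_region <- function() data.frame(chrom = "6", start = 25e6, end = 35e6)

#' Apply the standard SNP filters
#'
#' Removes SNPs on sex chromosomes, SNPs whose minor allele frequency in the
#' reference panel falls below `maf_min` (default 1%), SNPs inside any
#' excluded region (default: the MHC), and SNPs absent from the panel
#' (their MAF cannot be assessed).
#'
#' @param stats Summary-statistic table.
#' @param panel Reference panel (see [load_reference_panel()]).
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param exclude_regions data.frame of `chrom`/`start`/`end` windows
#'   (1-based, inclusive); default [mhc_region()].
#' @return The retained table; per-rule removal counts are attached as
#'   attribute `removal_counts` and reported via `message()`.
#' @export
filter_snps <- function(stats, panel, maf_min = 0.01,
                        exclude_regions = mhc_region()) {
  key_s <- paste(sub("^chr", "", stats$chrom), stats$pos)
  key_p <- paste(sub("^chr", "", panel$snp$chrom), panel$snp$pos)
  idx <- match(key_s, key_p)
  maf <- rep(NA_real_, nrow(stats))
  hit <- !is.na(idx)
  af <- colMeans(panel$geno) / if (identical(panel$type, "genotype")) 2 else 1
  maf[hit] <- pmin(af[idx[hit]], 1 - af[idx[hit]])
  rm_sex <- is_sex_chrom(stats$chrom)
  rm_nopanel <- !hit & !rm_sex
  rm_maf <- hit & maf < maf_min & !rm_sex
  rm_region <- rep(FALSE, nrow(stats))
  if (!is.null(exclude_regions) && nrow(exclude_regions)) {
    for (i in seq_len(nrow(exclude_regions))) {
      rm_region <- rm_region |
        (sub("^chr", "", stats$chrom) ==
           sub("^chr", "", exclude_regions$chrom[i]) &
         stats$pos >= exclude_regions$start[i] &
         stats$pos <= exclude_regions$end[i])
    }
  }
  rm_region <- rm_region & !rm_sex & !rm_maf & !rm_nopanel
  counts <- c(sex_chrom = sum(rm_sex), not_in_panel = sum(rm_nopanel),
              low_maf = sum(rm_maf), excluded_region = sum(rm_region))
  keep <- !(rm_sex | rm_nopanel | rm_maf | rm_region)
  if (!any(keep)) stop("no SNPs retained after filtering")
  if (sum(counts) > 0)
    message("filter_snps: removed ",
            paste(names(counts), counts, sep = "=", collapse = ", "))
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removal_counts") <- counts
  out
}

#' Harmonize summary-statistic effect alleles to the reference panel
#'
#' Matches SNPs to the panel by chromosome and position and orients every
#' effect estimate to the panel's alternate allele: when the effect allele
#' equals the panel reference allele the sign of `betahat` is flipped (and
#' the allele columns swapped).  Strand-ambiguous SNPs (A/T and C/G pairs)
#' are dropped, as are SNPs whose allele pair is incompatible with the panel
#' or absent from it; counts of each are reported.  The operation is
#' idempotent: a harmonized table passes through unchanged.
#'
#' @inheritParams filter_snps
#' @param drop_ambiguous Drop A/T and C/G SNPs (default `TRUE`).
#' @return The harmonized table with attribute `harmonize_counts`.
#' @export
harmonize_alleles <- function(stats, panel, drop_ambiguous = TRUE) {
  key_s <- paste(sub("^chr", "", stats$chrom), stats$pos)
  key_p <- paste(sub("^chr", "", panel$snp$chrom), panel$snp$pos)
  idx <- match(key_s, key_p)
  matched <- !is.na(idx)
  ref <- toupper(panel$snp$ref[idx])
  alt <- toupper(panel$snp$alt[idx])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  na_false <- function(x) { x[is.na(x)] <- FALSE; x }
  ambiguous <- na_false(matched & (stats$allele_effect ==
                                     unname(comp[stats$allele_other])))
  same <- na_false(matched & stats$allele_effect == alt &
                     stats$allele_other == ref)
  flipped <- na_false(matched & stats$allele_effect == ref &
                        stats$allele_other == alt)
  if (!drop_ambiguous) ambiguous[] <- FALSE
  incompatible <- matched & !same & !flipped
  keep <- matched & !ambiguous & !incompatible
  counts <- c(unmatched = sum(!matched), ambiguous = sum(ambiguous & !incompatible),
              incompatible_alleles = sum(incompatible & !ambiguous),
              sign_flipped = sum(flipped & keep))
  out <- stats[keep, , drop = FALSE]
  fl <- flipped[keep]
  out$betahat[fl] <- -out$betahat[fl]
  tmp <- out$allele_effect[fl]
  out$allele_effect[fl] <- out$allele_other[fl]
  out$allele_other[fl] <- tmp
  if (!nrow(out)) stop("no SNPs retained after allele harmonization")
  if (sum(counts[1:3]) > 0)
    message("harmonize_alleles: ",
            paste(names(counts), counts, sep = "=", collapse = ", "))
  rownames(out) <- NULL
  attr(out, "harmonize_counts") <- counts
  out
}

#' Read gene sets in GMT format
#'
#' One tab-separated line per set: name, description, then member gene
#' symbols.  Duplicate genes within a set are collapsed; duplicate set
#' names or empty member lists are errors.
#'
#' @param path Path to the `.gmt` file.
#' @return Object of class `gene_set_collection`: a named list of character
#'   vectors with a `source` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": expected name, description, >=1 gene")
    nm <- f[1]
    if (nm %in% names(sets)) stop("duplicate gene-set name at line ", i, ": ", nm)
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("malformed GMT line ", i, ": empty member list")
    sets[[nm]] <- genes
  }
  structure(sets, source = basename(path), class = "gene_set_collection")
}

#' Read gene coordinates from a BED file
#'
#' BED4+ (chrom, start, end, name, ...): 0-based half-open intervals,
#' converted on read to the package's 1-based inclusive convention.
#' Multiple records for the same gene symbol are merged to the union span
#' (overlapping transcripts collapse to one region per gene).
#'
#' @param path Path to the BED file (no header; `track`/`browser` lines
#'   skipped).
#' @return data.frame with `gene`, `chrom`, `start`, `end`, `strand`
#'   (1-based inclusive coordinates).
#' @export
read_gene_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(track|browser|#)", lines)]
  recs <- strsplit(lines, "[ \t]+")
  bad <- which(vapply(recs, length, 0L) < 4L)
  if (length(bad))
    stop("malformed BED line ", bad[1], ": need at least 4 fields")
  df <- data.frame(
    gene = vapply(recs, `[`, "", 4L),
    chrom = vapply(recs, `[`, "", 1L),
    start = as.numeric(vapply(recs, `[`, "", 2L)) + 1,  # BED 0-based -> 1-based
    end = as.numeric(vapply(recs, `[`, "", 3L)),
    strand = vapply(recs, function(r) if (length(r) >= 6L) r[6L] else "*", ""),
    stringsAsFactors = FALSE)
  if (any(df$start > df$end))
    stop("malformed BED interval (start >= end) at line ",
         which(df$start > df$end)[1])
  merged <- do.call(rbind, lapply(split(df, df$gene), function(d) {
    if (length(unique(d$chrom)) > 1L) {
      warning("gene ", d$gene[1], " on multiple chromosomes; keeping ",
              d$chrom[1])
      d <- d[d$chrom == d$chrom[1], , drop = FALSE]
    }
    data.frame(gene = d$gene[1], chrom = d$chrom[1], start = min(d$start),
               end = max(d$end), strand = d$strand[1],
               stringsAsFactors = FALSE)
  }))
  merged <- merged[order(chrom_order(merged$chrom), merged$start), ]
  rownames(merged) <- NULL
  merged
}

#' Load a reference genotype/haplotype panel from VCF
#'
#' Keeps biallelic SNVs only; multi-allelic records and SNPs with any
#' missing call are dropped (with counts).  Fully phased panels yield a
#' haplotype matrix (two rows per individual, values 0/1); otherwise a
#' genotype dosage matrix (0/1/2).
#'
#' @param path_vcf Path to a VCF 4.x file (plain or bgzipped).
#' @param region Optional `"chrom:start-end"` string restricting the SNPs
#'   retained (applied after reading; panels here are small).
#' @param ancestry Free-text ancestry label stored with the panel.
#' @return Object of class `ref_panel`: list with `geno` (matrix), `snp`
#'   (data.frame `snp_id`, `chrom`, `pos`, `ref`, `alt`), `type`
#'   (`"haplotype"` or `"genotype"`), `ancestry`.
#' @export
load_reference_panel <- function(path_vcf, region = NULL, ancestry = NA_character_) {
  v <- vcfR::read.vcfR(path_vcf, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & !grepl(",", fix$ALT) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_multi <- sum(!snv)
  if (n_multi) message("load_reference_panel: dropped ", n_multi,
                       " non-biallelic-SNV record(s)")
  fix <- fix[snv, , drop = FALSE]
  gt <- gt[snv, , drop = FALSE]
  if (!is.null(region)) {
    mr <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(mr) != 4L) stop("region must be 'chrom:start-end'")
    sel <- sub("^chr", "", fix$CHROM) == sub("^chr", "", mr[2]) &
      as.numeric(fix$POS) >= as.numeric(mr[3]) &
      as.numeric(fix$POS) <= as.numeric(mr[4])
    fix <- fix[sel, , drop = FALSE]
    gt <- gt[sel, , drop = FALSE]
  }
  if (!nrow(fix)) stop("no biallelic SNVs retained from ", path_vcf)
  miss <- apply(gt, 1L, function(g) any(is.na(g) | grepl("\\.", g)))
  if (any(miss)) message("load_reference_panel: dropped ", sum(miss),
                         " SNP(s) with missing genotype calls")
  fix <- fix[!miss, , drop = FALSE]
  gt <- gt[!miss, , drop = FALSE]
  phased <- all(grepl("\\|", gt))
  if (phased) {
    a1 <- t(apply(gt, 1L, function(g) as.integer(substr(g, 1L, 1L))))
    a2 <- t(apply(gt, 1L, function(g) as.integer(substr(g, 3L, 3L))))
    geno <- rbind(t(a1), t(a2))   # haplotypes x SNPs
    type <- "haplotype"
  } else {
    geno <- t(apply(gt, 1L, function(g) {
      as.integer(substr(g, 1L, 1L)) + as.integer(substr(g, 3L, 3L))
    }))
    geno <- t(geno)               # individuals x SNPs
    type <- "genotype"
  }
  ord <- order(chrom_order(fix$CHROM), as.numeric(fix$POS))
  snp <- data.frame(snp_id = ifelse(fix$ID == "." | is.na(fix$ID),
                                    paste0(fix$CHROM, ":", fix$POS), fix$ID),
                    chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT,
                    stringsAsFactors = FALSE)[ord, ]
  rownames(snp) <- NULL
  structure(list(geno = geno[, ord, drop = FALSE], snp = snp, type = type,
                 ancestry = ancestry),
            class = "ref_panel")
}

#' Write (and re-read) analysis results
#'
#' TSV output preserves full double precision so that a written table
#' re-read with [read_report()] is bit-identical; JSON output serializes
#' the full structure via `jsonlite`.
#'
#' @param results A data.frame (e.g. a gene report), an
#'   `enrichment_result`/list of them, or a `sharing_estimate`.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass_deep(results), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    return(invisible(path))
  }
  df <- as_report_df(results)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, unclass_deep)
    attributes(x) <- list(names = names(x))
  }
  x
}

as_report_df <- function(results) {
  if (is.data.frame(results)) return(results)
  if (inherits(results, "enrichment_result")) results <- list(results)
  if (is.list(results) && all(vapply(results, inherits, TRUE, "enrichment_result"))) {
    return(do.call(rbind, lapply(results, function(r) {
      data.frame(name = r$name, n_inside_snps = r$n_inside_snps,
                 log10_bf = r$log10_bf, theta_mean = r$theta_mean,
                 theta_lo = r$theta_ci[1], theta_hi = r$theta_ci[2],
                 stringsAsFactors = FALSE)
    })))
  }
  if (inherits(results, "sharing_estimate")) {
    return(data.frame(pi00 = results$pi[1], pi01 = results$pi[2],
                      pi10 = results$pi[3], pi11 = results$pi[4],
                      conditional_sharing = conditional_sharing(results),
                      loglik = results$loglik, n_pathways = results$n_pathways))
  }
  stop("write_report: unsupported result type ", paste(class(results), collapse = "/"))
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") return(jsonlite::read_json(path, simplifyVector = TRUE))
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Write a JSON run manifest
#'
#' Records the inputs, parameters, seed and package version of a run; every
#' command-line subcommand writes one next to its outputs.
#'
#' @param path Output path.
#' @param command Subcommand or function name.
#' @param inputs,params Named lists.
#' @param seed Integer seed used.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, command, inputs = list(),
                               params = list(), seed = NA_integer_) {
  jsonlite::write_json(
    list(command = command, inputs = inputs, params = params, seed = seed,
         package = "gsenrich",
         version = as.character(utils::packageVersion("gsenrich")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
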