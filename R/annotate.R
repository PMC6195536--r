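#' SNP-level annotation of a gene set via the 100 kb proximity rule
#'
#' Marks SNP j as inside the set (`a_j = 1`) when its position lies within
#' `window` base pairs of the transcribed region of at least one member
#' gene on the same chromosome, i.e. `pos_j` in
#' `[start - window, end + window]`, boundaries inclusive.  The broad
#' default window (100 kb) is intended to capture nearby regulatory
#' variants, since most GWAS associations are noncoding.  Strand is ignored
#' (the rule is symmetric) and gene spans are transcript unions (see
#' [read_gene_annotations()]).
#'
#' @param gene_set Character vector of member gene symbols (one element of a
#'   `gene_set_collection`), or a single set selected by name from one.
#' @param genes Gene annotation table from [read_gene_annotations()].
#' @param stats Summary-statistic table defining the analyzed SNPs.
#' @param window Window size in bp (default 100,000).
#' @param set_name Optional label stored with the annotation.
#' @return Object of class `snp_annotation`: list with binary vector `a`
#'   (length `nrow(stats)`), `set_name`, `window`, `n_inside`, the vector
#'   of `unresolved` symbols, and an `empty` flag.
#' @export
build_snp_annotation <- function(gene_set, genes, stats, window = 100000,
                                 set_name = NULL) {
  if (inherits(gene_set, "gene_set_collection")) {
    stopifnot(length(gene_set) == 1L)
    set_name <- set_name %||% names(gene_set)[1]
    gene_set <- gene_set[[1]]
  }
  gene_set <- unique(as.character(gene_set))
  hit <- genes$gene %in% gene_set
  unresolved <- setdiff(gene_set, genes$gene)
  if (length(unresolved) == length(gene_set))
    stop("empty annotation: no gene symbol of the set resolves in the gene table")
  if (length(unresolved))
    message("build_snp_annotation: ", length(unresolved),
            " unresolved gene symbol(s) skipped")
  a <- snps_near_genes(genes[hit, , drop = FALSE], stats, window)
  ann <- structure(list(a = as.integer(a), set_name = set_name %||% "gene_set",
                        window = window, n_inside = sum(a),
                        unresolved = unresolved, empty = sum(a) == 0L),
                   class = "snp_annotation")
  if (ann$empty) warning("annotation '", ann$set_name,
                         "' covers no analyzed SNP")
  ann
}

snps_near_genes <- function(genes, stats, window) {
  a <- logical(nrow(stats))
  if (!nrow(genes)) return(a)
  schrom <- sub("^chr", "", stats$chrom)
  for (ch in unique(sub("^chr", "", genes$chrom))) {
    sel <- which(schrom == ch)
    if (!length(sel)) next
    pos <- stats$pos[sel]
    g <- genes[sub("^chr", "", genes$chrom) == ch, , drop = FALSE]
    for (i in seq_len(nrow(g)))
      a[sel[pos >= g$start[i] - window & pos <= g$end[i] + window]] <- TRUE
  }
  a
}

#' Gene loci: the SNPs within the window of each member gene
#'
#' One locus per resolvable member gene; a SNP lying within the window of
#' several genes appears in each of their loci (no unique assignment).  The
#' union of all locus SNPs equals the inside-SNPs of
#' [build_snp_annotation()] run with the same arguments.
#'
#' @inheritParams build_snp_annotation
#' @return Named list (one element per gene) of sorted SNP index vectors;
#'   genes with no nearby SNP get an empty vector (with a message).
#' @export
build_gene_loci <- function(gene_set, genes, stats, window = 100000) {
  if (inherits(gene_set, "gene_set_collection")) gene_set <- gene_set[[1]]
  gene_set <- unique(as.character(gene_set))
  g <- genes[genes$gene %in% gene_set, , drop = FALSE]
  if (!nrow(g)) stop("empty annotation: no gene symbol of the set resolves")
  schrom <- sub("^chr", "", stats$chrom)
  loci <- lapply(seq_len(nrow(g)), function(i) {
    sel <- which(schrom == sub("^chr", "", g$chrom[i]) &
                 stats$pos >= g$start[i] - window &
                 stats$pos <= g$end[i] + window)
    sort(unique(sel))
  })
  names(loci) <- g$gene
  n_empty <- sum(!lengths(loci))
  if (n_empty) message("build_gene_loci: ", n_empty,
                       " gene(s) with no SNP within the window")
  loci
}

#' Annotation of SNPs near any gene
#'
#' The union annotation over every gene in the table; used both as the
#' "generic genic enrichment" comparator in the sanity suite and as the
#' universe from which matched null sets are drawn.
#'
#' @inheritParams build_snp_annotation
#' @return A `snp_annotation` named `"all_genes"`.
#' @export
all_genes_annotation <- function(genes, stats, window = 100000) {
  a <- snps_near_genes(genes, stats, window)
  structure(list(a = as.integer(a), set_name = "all_genes", window = window,
                 n_inside = sum(a), unresolved = character(0),
                 empty = sum(a) == 0L),
            class = "snp_annotation")
}

#' Random size-matched near-gene null SNP set
#'
#' Draws exactly `n_inside` SNPs uniformly without replacement from the
#' near-gene universe (an all-genes annotation).  Such sets carry no
#' set-specific signal by construction and calibrate the null distribution
#' of the enrichment Bayes factor.
#'
#' @param annotation_universe `snp_annotation` marking all near-gene SNPs.
#' @param n_inside Number of SNPs to draw.
#' @param seed Integer seed; the draw is reproducible.
#' @return A `snp_annotation` named `"null_set"`.
#' @export
random_matched_null_set <- function(annotation_universe, n_inside, seed) {
  stopifnot(inherits(annotation_universe, "snp_annotation"))
  pool <- which(annotation_universe$a == 1L)
  if (n_inside > length(pool))
    stop("n_inside (", n_inside, ") exceeds the near-gene universe size (",
         length(pool), ")")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  a <- integer(length(annotation_universe$a))
  a[sample(pool, n_inside)] <- 1L
  ann <- structure(list(a = a, set_name = "null_set",
                        window = annotation_universe$window,
                        n_inside = n_inside, unresolved = character(0),
                        empty = n_inside == 0L),
                   class = "snp_annotation")
  if (ann$empty) warning("null annotation with 0 inside SNPs")
  ann
}

#' Export an annotation as BED intervals (one per inside SNP)
#'
#' @param annotation A `snp_annotation`.
#' @param stats The summary-statistic table it was built against.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
annotation_to_bed <- function(annotation, stats, path) {
  idx <- which(annotation$a == 1L)
  df <- data.frame(chrom = stats$chrom[idx], start = stats$pos[idx] - 1L,
                   end = stats$pos[idx], name = stats$snp_id[idx])
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.snp_annotation <- function(x, ...) {
  cat("SNP annotation '", x$set_name, "': ", x$n_inside, "/", length(x$a),
      " SNPs inside (window ", x$window, " bp)\n", sep = "")
  invisible(x)
}
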