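#' Column dialect for summary-statistic files
#'
#' Maps the logical fields of a summary-statistics table to the column names
#' of a particular export format. The default matches eQTL Catalogue style
#' headers, where \code{an} is the allele number (2n for diploids). Either an
#' \code{an} or an \code{n} column must be mappable.
#'
#' @param variant,chromosome,position,ref,alt,beta,se,maf column names.
#' @param an allele-number column (2n); used when \code{n} is absent.
#' @param n sample-size column; takes precedence over \code{an} if present.
#' @param trait trait-identifier column; when absent the file is treated as
#'   a single trait.
#' @return named character vector usable as the \code{dialect} argument of
#'   \code{\link{readSumstats}}.
#' @export
sumstatDialect <- function(variant = "variant", chromosome = "chromosome",
                           position = "position", ref = "ref", alt = "alt",
                           beta = "beta", se = "se", maf = "maf",
                           an = "an", n = "n",
                           trait = "molecular_trait_id") {
  c(variant = variant, chromosome = chromosome, position = position,
    ref = ref, alt = alt, beta = beta, se = se, maf = maf, an = an,
    n = n, trait = trait)
}

#' Read per-variant association summary statistics
#'
#' Parses a tab-delimited summary-statistics file (gzip-transparent) into
#' one \linkS4class{RegionStats} per distinct trait. Rows with missing beta
#' or standard error are dropped and counted; rows with non-positive
#' standard errors are rejected with a warning. Allele frequencies are
#' folded to the minor allele.
#'
#' @param path file path.
#' @param dialect named character vector from \code{\link{sumstatDialect}}.
#' @param traitId trait id to use when the file has no trait column.
#' @param datasetId dataset label attached to every trait.
#' @return named list of \linkS4class{RegionStats}, one per trait, with an
#'   attribute \code{nDropped} counting rejected rows.
#' @export
readSumstats <- function(path, dialect = sumstatDialect(),
                         traitId = "trait1", datasetId = "dataset1") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("variant", "chromosome", "position", "ref", "alt", "beta",
            "se", "maf")
  for (f in need) {
    if (!dialect[[f]] %in% names(df)) {
      stop("summary-statistics file is missing required column '",
           dialect[[f]], "' (field: ", f, ")")
    }
  }
  if (dialect[["n"]] %in% names(df)) {
    nCol <- df[[dialect[["n"]]]]
  } else if (dialect[["an"]] %in% names(df)) {
    nCol <- df[[dialect[["an"]]]] / 2
  } else {
    stop("summary-statistics file is missing required column '",
         dialect[["an"]], "' (field: an) or '", dialect[["n"]],
         "' (field: n)")
  }
  trait <- if (dialect[["trait"]] %in% names(df)) {
    as.character(df[[dialect[["trait"]]]])
  } else {
    rep(traitId, nrow(df))
  }

  beta <- as.numeric(df[[dialect[["beta"]]]])
  se <- as.numeric(df[[dialect[["se"]]]])
  dropMissing <- is.na(beta) | is.na(se)
  badSe <- !dropMissing & se <= 0
  if (any(badSe)) {
    warning(sum(badSe), " row(s) with non-positive standard error rejected")
  }
  keep <- !dropMissing & !badSe
  nDropped <- sum(!keep)

  out <- list()
  for (tid in unique(trait[keep])) {
    idx <- which(keep & trait == tid)
    v <- data.frame(
      id = as.character(df[[dialect[["variant"]]]][idx]),
      chrom = as.character(df[[dialect[["chromosome"]]]][idx]),
      pos = as.integer(df[[dialect[["position"]]]][idx]),
      ref = as.character(df[[dialect[["ref"]]]][idx]),
      alt = as.character(df[[dialect[["alt"]]]][idx]),
      stringsAsFactors = FALSE
    )
    out[[tid]] <- regionStats(
      traitId = tid, variants = v, beta = beta[idx], se = se[idx],
      maf = as.numeric(df[[dialect[["maf"]]]][idx]),
      n = round(stats::median(nCol[idx])), datasetId = datasetId
    )
  }
  attr(out, "nDropped") <- nDropped
  out
}

#' Write summary statistics in the default dialect
#'
#' Emits the tab-separated layout with columns
#' \code{variant chromosome position ref alt beta se maf an} (an = 2n), plus
#' a \code{molecular_trait_id} column, so that
#' \code{readSumstats(writeSumstats(x))} round-trips numeric columns to
#' 1e-12 and string columns exactly.
#'
#' @param x a RegionStats or list of RegionStats.
#' @param path output path (".gz" suffix writes gzip).
#' @return \code{path}, invisibly.
#' @export
writeSumstats <- function(x, path) {
  if (is(x, "RegionStats")) x <- list(x)
  rows <- lapply(x, function(s) {
    v <- variants(s)
    data.frame(
      molecular_trait_id = traitId(s), variant = v$id,
      chromosome = v$chrom, position = v$pos, ref = v$ref, alt = v$alt,
      beta = s@beta, se = s@se, maf = s@maf, an = 2L * s@n,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(format(df, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene annotation GRanges
#'
#' @param gene_id character vector.
#' @param chrom chromosome names.
#' @param start,end 1-based inclusive gene-body coordinates.
#' @param strand "+" or "-".
#' @param gene_type biotype string; \code{protein_coding} flags are derived
#'   from it.
#' @return GRanges with mcols \code{gene_id}, \code{gene_type},
#'   \code{protein_coding}.
#' @export
geneAnnotation <- function(gene_id, chrom, start, end,
                           strand = "+", gene_type = "protein_coding") {
  stopifnot(all(start <= end))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand
  )
  S4Vectors::mcols(gr)$gene_id <- as.character(gene_id)
  S4Vectors::mcols(gr)$gene_type <- rep_len(gene_type, length(gr))
  S4Vectors::mcols(gr)$protein_coding <-
    S4Vectors::mcols(gr)$gene_type == "protein_coding"
  gr
}

#' Read gene annotations from TSV or GFF3
#'
#' TSV files must carry the columns \code{gene_id chromosome start end
#' strand gene_type}; files ending in \code{.gff}/\code{.gff3} are parsed
#' with rtracklayer, keeping \code{type == "gene"} records.
#'
#' @param path annotation file.
#' @return GRanges as from \code{\link{geneAnnotation}}.
#' @export
readGeneAnnotation <- function(path) {
  if (grepl("\\.gff3?(\\.gz)?$", path)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("rtracklayer is required to read GFF3 annotations")
    }
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    biotype <- if (!is.null(gr$gene_type)) gr$gene_type else gr$biotype
    return(geneAnnotation(gr$gene_id,
                          as.character(GenomicRanges::seqnames(gr)),
                          GenomicRanges::start(gr), GenomicRanges::end(gr),
                          as.character(GenomicRanges::strand(gr)), biotype))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chromosome", "start", "end", "strand", "gene_type")
  if (!all(need %in% names(df))) {
    stop("gene annotation must have columns: ", paste(need, collapse = ", "))
  }
  geneAnnotation(df$gene_id, df$chromosome, df$start, df$end, df$strand,
                 df$gene_type)
}

#' Strand-aware transcription start sites
#'
#' @param genes GRanges from \code{\link{geneAnnotation}}.
#' @return integer vector of TSS positions (start on "+", end on "-").
#' @export
tssPositions <- function(genes) {
  ifelse(as.character(GenomicRanges::strand(genes)) == "-",
         GenomicRanges::end(genes), GenomicRanges::start(genes))
}

#' Read a per-signal log-Bayes-factor matrix
#'
#' Rows are fine-mapped signals, columns are variant ids, values are
#' natural-log Bayes factors (the layout written by
#' \code{\link{writeLbfMatrix}}).
#'
#' @param path TSV file.
#' @return numeric matrix with variant ids as column names.
#' @export
readLbfMatrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' @rdname readLbfMatrix
#' @param x L x M matrix with variant-id column names.
#' @export
writeLbfMatrix <- function(x, path) {
  df <- data.frame(signal = seq_len(nrow(x)), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Harmonize two sets of summary statistics to shared effect alleles
#'
#' Inner-joins two traits' variants on (chromosome, position). Variants
#' whose ref/alt labels are swapped in the second trait have their effect
#' sign flipped; variants with incompatible allele pairs are dropped.
#' Strand-ambiguous (A/T, C/G) variants are kept as-is and counted. The
#' output row order follows the first trait.
#'
#' @param a,b \linkS4class{RegionStats} on the same chromosome.
#' @return data.frame with columns \code{id, chrom, pos, ref, alt, beta_a,
#'   se_a, maf_a, beta_b, se_b, maf_b, flipped}; attributes
#'   \code{nIncompatible} and \code{nStrandAmbiguous}.
#' @export
harmonizePair <- function(a, b) {
  va <- variants(a)
  vb <- variants(b)
  if (length(intersect(unique(va$chrom), unique(vb$chrom))) == 0) {
    stop("harmonizePair: traits share no chromosome")
  }
  keyA <- paste(va$chrom, va$pos)
  keyB <- paste(vb$chrom, vb$pos)
  j <- match(keyA, keyB)
  ia <- which(!is.na(j))
  if (length(ia) == 0L) {
    stop("harmonizePair: no overlapping variants between the two regions")
  }
  ib <- j[ia]

  same <- va$ref[ia] == vb$ref[ib] & va$alt[ia] == vb$alt[ib]
  swap <- va$ref[ia] == vb$alt[ib] & va$alt[ia] == vb$ref[ib]
  ok <- same | swap
  nIncompatible <- sum(!ok)
  ia <- ia[ok]; ib <- ib[ok]; swap <- swap[ok]

  if (length(ia) == 0L) {
    stop("harmonizePair: no allele-compatible overlapping variants")
  }
  ambig <- paste0(va$ref[ia], va$alt[ia]) %in% c("AT", "TA", "CG", "GC")

  out <- data.frame(
    id = va$id[ia], chrom = va$chrom[ia], pos = va$pos[ia],
    ref = va$ref[ia], alt = va$alt[ia],
    beta_a = a@beta[ia], se_a = a@se[ia], maf_a = a@maf[ia],
    beta_b = ifelse(swap, -b@beta[ib], b@beta[ib]),
    se_b = b@se[ib], maf_b = b@maf[ib],
    flipped = swap, stringsAsFactors = FALSE
  )
  attr(out, "nIncompatible") <- nIncompatible
  attr(out, "nStrandAmbiguous") <- sum(ambig)
  out
}

#' Cis-window around a gene's TSS
#'
#' The window is the closed interval \code{[tss - 1e6 + 1, tss + 1e6]} —
#' exactly 2,000,000 bp wide, centered at the strand-aware TSS — clipped at
#' the chromosome start.
#'
#' @param gene a length-1 GRanges (from \code{\link{geneAnnotation}}).
#' @return list with \code{center}, \code{lo}, \code{hi}.
#' @export
cisWindowBounds <- function(gene, halfWidth = 1e6) {
  stopifnot(length(gene) == 1L)
  tss <- tssPositions(gene)
  list(center = tss, lo = max(1, tss - halfWidth + 1), hi = tss + halfWidth)
}

#' @rdname cisWindowBounds
#' @param stats a \linkS4class{RegionStats} to restrict to the window.
#' @param halfWidth half the window width in bp (default 1e6 gives the
#'   standard 2 Mb cis-window).
#' @return for \code{cisWindow}: the RegionStats restricted (order
#'   preserved) to variants inside the window. An error of class
#'   \code{emptyRegion} is signalled when no variant falls inside.
#' @export
cisWindow <- function(gene, stats, halfWidth = 1e6) {
  w <- cisWindowBounds(gene, halfWidth)
  v <- variants(stats)
  keep <- which(v$chrom == as.character(GenomicRanges::seqnames(gene)) &
                v$pos >= w$lo & v$pos <= w$hi)
  if (length(keep) == 0L) {
    stop(structure(
      class = c("emptyRegion", "error", "condition"),
      list(message = paste0("no variants in the cis-window of ",
                            gene$gene_id),
           call = sys.call())
    ))
  }
  stats[keep]
}
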