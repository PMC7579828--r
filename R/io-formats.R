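#' Read and validate a pedigree CSV
#'
#' Expects a header `animal,sire,dam` (extra columns are carried along).
#' Missing parents may be coded as empty strings or `"0"`. Parents that
#' appear only as sire/dam are added as founders (pedigree closure). The
#' result is topologically sorted so parents precede offspring; cycles
#' (an animal among its own ancestors) and duplicate ids are errors.
#'
#' @param path CSV file path.
#' @return A validated, sorted pedigree `data.frame`.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(ped)))
    stop("pedigree file must have columns animal, sire, dam")
  if (anyDuplicated(ped$animal))
    stop("duplicate animal id(s): ",
         paste(unique(ped$animal[duplicated(ped$animal)]), collapse = ", "))
  ped$sire <- normalize_parent(ped$sire)
  ped$dam <- normalize_parent(ped$dam)
  extra <- setdiff(na.omit(c(ped$sire, ped$dam)), ped$animal)
  if (length(extra)) {
    add <- ped[rep(1L, length(extra)), , drop = FALSE]
    add[] <- NA
    add$animal <- extra
    ped <- rbind(add, ped)
  }
  sort_pedigree(ped)
}

#' Topologically sort a pedigree
#'
#' Kahn's algorithm over the parent-offspring graph; raises an error
#' naming an animal on a cycle if the pedigree is not acyclic.
#'
#' @param ped pedigree `data.frame` (`animal`, `sire`, `dam`).
#' @return The same rows, sorted so every parent precedes its offspring.
#' @export
sort_pedigree <- function(ped) {
  n <- nrow(ped)
  si <- match(normalize_parent(ped$sire), ped$animal)
  di <- match(normalize_parent(ped$dam), ped$animal)
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) if (!is.na(p))
      children[[p]] <- c(children[[p]], i)
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    bad <- setdiff(seq_len(n), order)
    stop("pedigree contains a cycle involving: ",
         paste(ped$animal[bad], collapse = ", "))
  }
  out <- ped[order, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a pedigree CSV
#'
#' @param ped pedigree `data.frame`.
#' @param path output path; missing parents are written as empty fields.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped
  out$sire[is.na(out$sire)] <- ""
  out$dam[is.na(out$dam)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read genotypes from PLINK .raw or VCF
#'
#' PLINK `.raw` (additive coding from `plink --recode A`) is parsed into
#' an allele-count matrix; SNP columns are recognized by their
#' `_<allele>` suffix. VCF is read through the `vcfR` package: `GT`
#' fields are tallied per genotype string, so `0/1`, `1/0` and `0|1` all
#' count 1, `1/1` counts 2 and missing genotypes become `NA`.
#'
#' @param path input file.
#' @param format `"plink_raw"` or `"vcf"`.
#' @return A list with `geno` (animals x SNPs allele counts) and `map`
#'   (`snp`, `chr`, `pos` where available).
#' @export
read_genotypes <- function(path, format = c("plink_raw", "vcf")) {
  format <- match.arg(format)
  if (format == "plink_raw") read_plink_raw(path) else read_vcf_counts(path)
}

read_plink_raw <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "[ \t]+")[[1]]
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta %in% header))
    stop("malformed PLINK .raw header (line 1): expected FID..PHENOTYPE")
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = c("NA", "-9"))
  snp_cols <- setdiff(names(raw), meta)
  geno <- as.matrix(raw[, snp_cols, drop = FALSE])
  if (!all(geno %in% c(0, 1, 2, NA)))
    stop("PLINK .raw allele counts must be 0, 1, 2 or NA")
  storage.mode(geno) <- "double"
  rownames(geno) <- as.character(raw$IID)
  snp <- sub("_[^_]*$", "", snp_cols)
  colnames(geno) <- snp
  list(geno = geno, map = data.frame(snp = snp, chr = NA_integer_,
                                     pos = NA_integer_,
                                     stringsAsFactors = FALSE))
}

read_vcf_counts <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  counts <- apply(gt, c(1, 2), count_alt_alleles)
  geno <- t(counts)
  map <- data.frame(snp = rownames(gt),
                    chr = vcfR::getCHROM(v),
                    pos = vcfR::getPOS(v), stringsAsFactors = FALSE)
  list(geno = geno, map = map)
}

# tally ALT alleles in one GT string; any missing allele -> NA
count_alt_alleles <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_real_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_real_)
  sum(alleles != "0")
}

#' Write genotypes as PLINK .raw text
#'
#' @param geno allele-count matrix (animals x SNPs).
#' @param path output path.
#' @param a1 counted-allele label appended to SNP column names.
#' @export
write_plink_raw <- function(geno, path, a1 = "A") {
  df <- data.frame(FID = rownames(geno), IID = rownames(geno),
                   PAT = 0, MAT = 0, SEX = 0, PHENOTYPE = -9,
                   check.names = FALSE)
  snp <- as.data.frame(geno, check.names = FALSE)
  names(snp) <- paste0(colnames(geno), "_", a1)
  utils::write.table(cbind(df, snp), path, row.names = FALSE,
                     quote = FALSE, sep = " ", na = "NA")
  invisible(path)
}

#' Read gene annotations from BED or GFF3
#'
#' Files are parsed with `rtracklayer`, whose import already normalizes
#' BED (0-based half-open) and GFF3 (1-based closed) onto the 1-based
#' closed convention used throughout this package. Strand is read but
#' plays no role in distance-based gene lookups.
#'
#' @param path annotation file.
#' @param format `"bed"` or `"gff3"`.
#' @param feature for GFF3, which feature type to keep (default "gene").
#' @return `data.frame` with `gene_id`, `chr`, `start`, `end`, `strand`.
#' @export
read_annotations <- function(path, format = c("bed", "gff3"),
                             feature = "gene") {
  format <- match.arg(format)
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading annotations requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED"
                                           else "GFF3")
  if (format == "gff3") {
    keep <- as.character(gr$type) == feature
    if (any(keep)) gr <- gr[keep]
    ids <- as.character(gr$ID)
  } else {
    ids <- as.character(gr$name)
  }
  if (length(ids) == 0L || all(is.na(ids)))
    ids <- sprintf("feature%04d", seq_along(gr))
  ids[is.na(ids)] <- sprintf("feature%04d", which(is.na(ids)))
  out <- data.frame(gene_id = ids,
                    chr = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  if (any(out$start < 1L | out$end < 1L, na.rm = TRUE))
    stop("annotation coordinates must be positive")
  if (any(out$start > out$end))
    stop("annotation has start > end after normalization")
  out
}

#' Write the simulation truth table
#'
#' @param truth `data.frame` with columns `animal`, `trait`, `true_bv`.
#' @param path output TSV path.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
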