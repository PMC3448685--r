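#' Construct a genotype matrix
#'
#' Dosages count copies of the minor allele (0/1/2, `NA` = missing),
#' following the additive coding used throughout the scans. Rows are
#' samples, columns are SNPs.
#'
#' @param dosage numeric matrix, samples x SNPs, values in `{0,1,2,NA}`;
#'   must carry sample rownames and SNP-id colnames.
#' @param snps data frame with one row per SNP: `snp_id`, `chrom`,
#'   `pos` (1-based), `major`, `minor` allele labels.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosage, snps) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage)) || is.null(colnames(dosage))) {
    stop("dosage matrix needs sample rownames and SNP colnames")
  }
  if (anyDuplicated(rownames(dosage))) stop("duplicated sample id")
  if (anyDuplicated(colnames(dosage))) stop("duplicated SNP id")
  if (!identical(colnames(dosage), as.character(snps$snp_id))) {
    stop("SNP metadata rows must match dosage columns in order")
  }
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  if (any(snps$pos < 0, na.rm = TRUE)) stop("SNP position must be >= 0")
  structure(list(dosage = dosage, snps = as.data.frame(snps)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Per-SNP minor allele frequency and call rate
#'
#' @param G a `genotype_matrix`.
#' @return `snp_maf()`: numeric vector of observed minor-allele
#'   frequencies; `snp_call_rate()`: fraction of non-missing genotypes.
#' @export
snp_maf <- function(G) {
  colMeans(G$dosage, na.rm = TRUE) / 2
}

#' @rdname snp_maf
#' @export
snp_call_rate <- function(G) {
  colMeans(!is.na(G$dosage))
}

# Orient a counted-allele dosage vector so it counts the minor allele.
# Ties at frequency 0.5 resolve to the alphabetically first allele.
orient_to_minor <- function(counted_dosage, counted_allele, other_allele) {
  f <- mean(counted_dosage, na.rm = TRUE) / 2
  flip <- if (is.nan(f) || f == 0.5) {
    # tie (or fully missing): minor = alphabetically first allele
    counted_allele != min(counted_allele, other_allele)
  } else {
    f > 0.5
  }
  if (flip) {
    list(dosage = 2 - counted_dosage, major = counted_allele,
         minor = other_allele)
  } else {
    list(dosage = counted_dosage, major = other_allele,
         minor = counted_allele)
  }
}

#' Read genotypes from VCF or a dosage TSV
#'
#' For VCF input the GT field is parsed and recoded so dosage counts the
#' dataset's minor allele (observed frequency; ties broken by taking the
#' alphabetically first allele as minor). Multiallelic records are
#' rejected. The dosage TSV format is the one written by
#' [write_dosage_tsv()]: columns `snp_id`, `chrom`, `pos`, `major`,
#' `minor`, then one column per sample.
#'
#' @param path file path.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF has no variant records: ", path)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    stop("multiallelic VCF record at ", fix$CHROM[multi][1], ":",
         fix$POS[multi][1], " (only biallelic sites are supported)")
  }
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  if (anyDuplicated(ids)) stop("duplicated SNP id in VCF: ", ids[duplicated(ids)][1])
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  if (anyDuplicated(samples)) stop("duplicated sample id in VCF")
  # count ALT alleles; "." anywhere in the call -> missing
  alt_count <- function(g) {
    a <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
    vapply(a, function(al) {
      if (length(al) != 2 || any(al == ".") || anyNA(al)) return(NA_real_)
      if (!all(al %in% c("0", "1"))) {
        stop("malformed GT call '", paste(al, collapse = "/"), "'")
      }
      sum(al == "1")
    }, numeric(1))
  }
  dos <- t(apply(gt, 1, alt_count))
  n_snp <- nrow(fix)
  dosage <- matrix(NA_real_, nrow = length(samples), ncol = n_snp,
                   dimnames = list(samples, ids))
  major <- minor <- character(n_snp)
  for (j in seq_len(n_snp)) {
    o <- orient_to_minor(dos[j, ], fix$ALT[j], fix$REF[j])
    dosage[, j] <- o$dosage
    major[j] <- o$major
    minor[j] <- o$minor
  }
  snps <- data.frame(snp_id = ids, chrom = fix$CHROM,
                     pos = as.numeric(fix$POS),
                     major = major, minor = minor,
                     stringsAsFactors = FALSE)
  genotype_matrix(dosage, snps)
}

read_genotypes_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("snp_id", "chrom", "pos", "major", "minor")
  if (!all(meta_cols %in% names(d))) {
    stop("dosage TSV must start with columns ", paste(meta_cols, collapse = ", "))
  }
  sample_cols <- setdiff(names(d), meta_cols)
  if (length(sample_cols) == 0) stop("dosage TSV has no sample columns")
  dosage <- t(as.matrix(d[, sample_cols, drop = FALSE]))
  bad <- which(!(dosage %in% c(0, 1, 2) | is.na(dosage)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("malformed dosage value at line %d of %s",
                 bad[1, 2] + 1, path))
  }
  colnames(dosage) <- d$snp_id
  rownames(dosage) <- sample_cols
  storage.mode(dosage) <- "double"
  meta <- d[, meta_cols]
  meta$pos <- as.numeric(meta$pos)
  genotype_matrix(dosage, meta)
}

#' @param G a `genotype_matrix` to write.
#' @rdname read_genotypes
#' @export
write_dosage_tsv <- function(G, path) {
  out <- cbind(G$snps[, c("snp_id", "chrom", "pos", "major", "minor")],
               as.data.frame(t(G$dosage)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a normalized expression matrix
#'
#' TSV with a `sample_id` first column and one column per probe;
#' values are normalized log-scale intensities.
#'
#' @param path file path.
#' @return numeric matrix, samples x probes.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "sample_id") stop("expression TSV must start with sample_id")
  if (anyDuplicated(d$sample_id)) stop("duplicated sample id in expression file")
  E <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(E) || any(!is.finite(E))) {
    stop("expression values must be finite numerics")
  }
  rownames(E) <- d$sample_id
  E
}

#' @param E expression matrix (samples x probes) to write.
#' @rdname read_expression
#' @export
write_expression_tsv <- function(E, path) {
  out <- data.frame(sample_id = rownames(E), E, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the covariate table
#'
#' @param path TSV with columns `sample_id`, `age`, `sex` and optionally
#'   `status` (replication-cohort disease indicator).
#' @return data frame of per-sample covariates.
#' @export
read_covariates <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "age", "sex")
  if (!all(need %in% names(d))) {
    stop("covariate TSV needs columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(d$sample_id)) stop("duplicated sample id in covariates")
  d
}

probe_quality_levels <- c("perfect", "good", "average", "bad")

read_bed_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0) {
    return(genomic_intervals(character(0), numeric(0), numeric(0),
                             name = character(0)))
  }
  nm <- if (!is.null(gr$name)) as.character(gr$name) else NA_character_
  # GRanges is 1-based closed; BED start = start - 1, BED end = end
  genomic_intervals(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr) - 1, GenomicRanges::end(gr),
                    name = nm)
}

#' Read annotation inputs into an annotation set
#'
#' pri-miRNA and 3'UTR intervals come from BED files (0-based half-open,
#' names in column 4); probe annotations from a TSV with columns
#' `probe_id`, `gene`, `chrom`, `start1`, `end1` (1-based inclusive span),
#' `quality` (ReMOAT-style flag, e.g. `"perfect"`), `contains_snp`
#' (TRUE/FALSE). Unknown quality flags are kept with a warning.
#'
#' @param mirna_bed,utr3_bed BED file paths for pri-miRNA and 3'UTR
#'   intervals.
#' @param probe_tsv probe annotation TSV path.
#' @return An `annotation_set`: list with `mirna`, `utr3`
#'   (`genomic_intervals`) and `probes` (data frame with internal
#'   0-based half-open `start`/`end`).
#' @export
read_annotations <- function(mirna_bed, utr3_bed, probe_tsv) {
  mirna <- read_bed_intervals(mirna_bed)
  utr3 <- read_bed_intervals(utr3_bed)
  pr <- utils::read.delim(probe_tsv, stringsAsFactors = FALSE)
  need <- c("probe_id", "gene", "chrom", "start1", "end1", "quality",
            "contains_snp")
  if (!all(need %in% names(pr))) {
    stop("probe TSV needs columns ", paste(need, collapse = ", "))
  }
  if (any(pr$start1 > pr$end1)) {
    stop("probe interval with start > end in ", probe_tsv)
  }
  unk <- !(pr$quality %in% probe_quality_levels) & !is.na(pr$quality)
  if (any(unk)) {
    warning("unknown probe quality flag(s): ",
            paste(unique(pr$quality[unk]), collapse = ", "),
            " (records kept)")
  }
  probes <- data.frame(
    probe_id = pr$probe_id, gene = pr$gene, chrom = pr$chrom,
    start = pr$start1 - 1, end = pr$end1,
    quality = pr$quality, contains_snp = as.logical(pr$contains_snp),
    stringsAsFactors = FALSE
  )
  annotation_set(mirna, utr3, probes)
}

#' @param mirna,utr3 `genomic_intervals` keyed by miRNA / gene name.
#' @param probes probe annotation data frame (internal coordinates).
#' @rdname read_annotations
#' @export
annotation_set <- function(mirna, utr3, probes) {
  stopifnot(inherits(mirna, "genomic_intervals"),
            inherits(utr3, "genomic_intervals"))
  if (anyDuplicated(stats::na.omit(mirna$name))) {
    stop("duplicate pri-miRNA interval keys")
  }
  if (anyDuplicated(probes$probe_id)) stop("duplicate probe ids")
  structure(list(mirna = mirna, utr3 = utr3, probes = probes),
            class = "annotation_set")
}

#' Write / read tab-separated result tables
#'
#' Tables are written with a header row and full double precision so a
#' write-then-read round trip reproduces every field value exactly.
#'
#' @param records a data frame of results.
#' @param path output path.
#' @return `write_results()` the path, invisibly; `read_results()` the
#'   data frame.
#' @export
write_results <- function(records, path) {
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
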