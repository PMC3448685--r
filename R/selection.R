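#' Assign SNPs to genomic regions
#'
#' A SNP is assigned to every region whose (half-open) interval contains
#' its position; multi-assignment is allowed and an empty assignment is
#' valid. Membership is strand-agnostic.
#'
#' @param G a [genotype_matrix()].
#' @param regions a [genomic_intervals()] collection (e.g. pri-miRNA or
#'   3'UTR intervals).
#' @return data frame with columns `snp_id`, `region` (interval name),
#'   `chrom`, `pos`; zero rows if nothing overlaps.
#' @export
map_snps_to_regions <- function(G, regions) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(regions, "genomic_intervals"))
  out <- vector("list", nrow(G$snps))
  for (i in seq_len(nrow(G$snps))) {
    hit <- interval_contains(regions, G$snps$chrom[i], G$snps$pos[i])
    if (any(hit)) {
      out[[i]] <- data.frame(snp_id = G$snps$snp_id[i],
                             region = regions$name[hit],
                             chrom = G$snps$chrom[i], pos = G$snps$pos[i],
                             stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(snp_id = character(0), region = character(0),
                      chrom = character(0), pos = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Filter probes to the eligible analysis set
#'
#' Keeps probes annotated with `"perfect"` quality whose genomic sequence
#' does not harbor a SNP; probes with missing flags are excluded and
#' reported in the attached log.
#'
#' @param probes probe annotation data frame (from [read_annotations()]).
#' @return the eligible subset, with attribute `"excluded"` giving the
#'   reason per dropped probe.
#' @export
filter_probes <- function(probes) {
  reason <- rep(NA_character_, nrow(probes))
  miss <- is.na(probes$quality) | is.na(probes$contains_snp)
  reason[miss] <- "missing_flag"
  reason[!miss & probes$quality != "perfect"] <- "quality"
  reason[!miss & probes$quality == "perfect" & probes$contains_snp] <- "contains_snp"
  keep <- is.na(reason)
  out <- probes[keep, , drop = FALSE]
  attr(out, "excluded") <- data.frame(probe_id = probes$probe_id[!keep],
                                      reason = reason[!keep],
                                      stringsAsFactors = FALSE)
  out
}

#' Selection accounting for the interaction scan
#'
#' Summarizes the analysis units: how many miSNPs / distinct miRNAs enter
#' the marginal scan, how many probes and genes are eligible, and — for
#' genes with at least one 3'UTR SNP proxy — the per-gene histogram of
#' distinct 3utrSNPs. One genotyped proxy may tag several 3utrSNPs, so
#' the histogram-derived total (sum over genes of their 3utrSNP count)
#' can exceed the number of distinct proxies actually scanned; both are
#' reported.
#'
#' @param misnp_assignments SNP-to-pri-miRNA assignment data frame (from
#'   [map_snps_to_regions()]).
#' @param utr_assignments SNP-to-3'UTR assignment data frame; region
#'   names are gene symbols.
#' @param eligible_probes probe data frame from [filter_probes()].
#' @param utr_proxies optional data frame `target`, `proxy`, `r2` mapping
#'   each 3utrSNP to its genotyped proxy (defaults to identity).
#' @return a `selection_report` list: counts, the per-gene histogram, and
#'   the interaction test units (`units`: one row per (gene, probe,
#'   3utrSNP proxy)).
#' @export
build_selection_report <- function(misnp_assignments, utr_assignments,
                                   eligible_probes, utr_proxies = NULL) {
  if (is.null(utr_proxies)) {
    utr_proxies <- data.frame(target = utr_assignments$snp_id,
                              proxy = utr_assignments$snp_id, r2 = 1,
                              stringsAsFactors = FALSE)
  }
  utr <- utr_assignments
  utr$proxy <- utr_proxies$proxy[match(utr$snp_id, utr_proxies$target)]
  utr <- utr[!is.na(utr$proxy), , drop = FALSE]
  # distinct 3utrSNPs (with a surviving proxy) per gene
  per_gene <- tapply(utr$snp_id, utr$region,
                     function(x) length(unique(x)))
  per_gene <- per_gene[per_gene > 0]
  # restrict to genes with at least one eligible probe
  genes_with_probe <- unique(eligible_probes$gene)
  per_gene <- per_gene[names(per_gene) %in% genes_with_probe]
  hist_tab <- table(factor(per_gene))
  histogram <- data.frame(n_utrsnp = as.integer(names(hist_tab)),
                          n_genes = as.integer(hist_tab))
  # interaction test units: every eligible probe of a gene x each distinct proxy
  utr_g <- unique(utr[utr$region %in% names(per_gene),
                      c("region", "proxy")])
  units <- merge(utr_g,
                 eligible_probes[, c("gene", "probe_id")],
                 by.x = "region", by.y = "gene")
  names(units) <- c("gene", "utr_proxy", "probe_id")
  units <- units[order(units$gene, units$probe_id, units$utr_proxy), ,
                 drop = FALSE]
  rownames(units) <- NULL
  structure(list(
    n_misnp = length(unique(misnp_assignments$snp_id)),
    n_mirna_distinct = length(unique(misnp_assignments$region)),
    n_probes_marginal = nrow(eligible_probes),
    n_genes_marginal = length(genes_with_probe),
    n_genes_interaction = length(per_gene),
    n_probes_interaction = length(unique(units$probe_id)),
    n_3utrsnp = length(unique(utr$snp_id)),
    n_3utrsnp_proxies = length(unique(utr$proxy)),
    histogram = histogram,
    units = units
  ), class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf(paste0(
    "selection_report: %d miSNPs (%d miRNAs); %d eligible probes / %d genes;\n",
    "  interaction scan: %d genes, %d probes, %d 3utrSNPs (%d proxies)\n"),
    x$n_misnp, x$n_mirna_distinct, x$n_probes_marginal, x$n_genes_marginal,
    x$n_genes_interaction, x$n_probes_interaction, x$n_3utrsnp,
    x$n_3utrsnp_proxies))
  invisible(x)
}

#' Histogram totals for a selection report
#'
#' Returns the two accounting identities of the per-gene histogram: the
#' number of genes (sum of counts) and the proxy-derivable 3utrSNP total
#' (sum of k times the count at k).
#'
#' @param histogram data frame with columns `n_utrsnp`, `n_genes`.
#' @return list with `n_genes` and `n_utrsnp_total`.
#' @export
histogram_totals <- function(histogram) {
  list(n_genes = sum(histogram$n_genes),
       n_utrsnp_total = sum(histogram$n_utrsnp * histogram$n_genes))
}
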