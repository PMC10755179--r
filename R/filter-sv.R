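#' Filter a structural-variant call set
#'
#' Germline SV filtering rules for a Delly-style call set: keep only calls
#' flagged `PASS`, with `QUAL >= 20`, paired-end support `PE > 3`
#' (`PE > 5` would apply to translocations, but translocations are excluded
#' outright as interchromosomal), of a simple intrachromosomal type
#' (DEL, DUP, INV or INS on a single chromosome), and genotyped in at most
#' `max_samples` samples (a line-specific event can appear in at most the
#' line's population plus its sequenced clones).
#'
#' @param svs data frame with columns `chrom`, `start`, `end`, `sv_type`
#'   (`DEL`, `DUP`, `INV`, `INS`, `TRA`), `pe`, `qual`, `filter`, and a list
#'   column `samples` of genotyped sample ids.
#' @param min_qual,min_pe,min_pe_tra,max_samples thresholds; defaults are
#'   the published rules.
#' @return `list(kept, decisions)`; `decisions` lists every violated rule
#'   per record.
#' @export
filter_svs <- function(svs, min_qual = 20, min_pe = 3L, min_pe_tra = 5L,
                       max_samples = 3L) {
  stopifnot(all(c("chrom", "start", "end", "sv_type", "pe", "qual",
                  "filter", "samples") %in% names(svs)))
  simple <- c("DEL", "DUP", "INV", "INS")
  intra <- svs$sv_type %in% simple
  stopifnot(all(svs$pe >= 0), all(svs$start[intra] <= svs$end[intra]))

  n <- nrow(svs)
  reasons <- replicate(n, character(0), simplify = FALSE)
  n_samp <- lengths(svs$samples)
  for (i in seq_len(n)) {
    r <- character(0)
    if (svs$filter[i] != "PASS") r <- c(r, "not_pass")
    if (svs$qual[i] < min_qual) r <- c(r, "low_qual")
    pe_min <- if (svs$sv_type[i] == "TRA") min_pe_tra else min_pe
    if (svs$pe[i] <= pe_min) r <- c(r, "low_pe")
    if (!intra[i]) r <- c(r, "not_intrachromosomal")
    if (n_samp[i] > max_samples) r <- c(r, "multi_sample")
    reasons[[i]] <- r
  }
  rs <- join_reasons(reasons)
  dec <- data.frame(chrom = svs$chrom, pos = svs$start, alt = svs$sv_type,
                    stage = "filter_svs",
                    verdict = ifelse(rs == "", "pass", "fail"),
                    reasons = rs)
  list(kept = svs[rs == "", , drop = FALSE], decisions = dec)
}

#' Overlap SVs with gene models
#'
#' Reports, for each SV, the genes whose CDS intervals it overlaps
#' (1-based closed-interval convention, so an SV abutting a CDS end
#' coordinate overlaps it) and in which transcript half (5' or 3') the SV
#' begins. An SV starting upstream of the coding sequence is assigned to the
#' 5' region, matching how upstream-starting deletions of a two-domain
#' receptor are counted with the signal-peptide half.
#'
#' @param svs SV data frame (see [filter_svs()]).
#' @param genome a `toy_genome` providing gene models.
#' @return Data frame with one row per (SV, gene) overlap: `sv_idx`,
#'   `chrom`, `start`, `end`, `sv_type`, `gene_id`, `region`.
#' @export
sv_gene_overlap <- function(svs, genome) {
  genes <- genome$genes
  out <- list()
  if (nrow(svs) == 0 || nrow(genes) == 0) {
    return(data.frame(sv_idx = integer(), chrom = character(),
                      start = integer(), end = integer(),
                      sv_type = character(), gene_id = character(),
                      region = character()))
  }
  for (i in seq_len(nrow(svs))) {
    on_chrom <- genes[genes$chrom == svs$chrom[i], , drop = FALSE]
    if (nrow(on_chrom) == 0) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(svs$start[i], svs$end[i]),
      IRanges::IRanges(on_chrom$start, on_chrom$end))
    gids <- unique(on_chrom$gene_id[S4Vectors::subjectHits(hits)])
    for (g in gids) {
      out[[length(out) + 1L]] <- data.frame(
        sv_idx = i, chrom = svs$chrom[i], start = svs$start[i],
        end = svs$end[i], sv_type = svs$sv_type[i], gene_id = g,
        region = sv_region(genome, g, svs$start[i], svs$end[i]))
    }
  }
  if (length(out) == 0) {
    return(data.frame(sv_idx = integer(), chrom = character(),
                      start = integer(), end = integer(),
                      sv_type = character(), gene_id = character(),
                      region = character()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Which transcript half does an SV begin in? The SV "start" in transcript
# orientation is the genomic start for "+" genes and the genomic end for
# "-" genes; a start upstream of the CDS maps to the 5' region.
sv_region <- function(genome, gene_id, start, end) {
  ex <- gene_exons(genome, gene_id)
  tx_start_pos <- if (ex$strand[1] == "+") start else end
  off <- cds_offset(genome, gene_id, tx_start_pos)
  if (is.na(off)) {
    upstream <- if (ex$strand[1] == "+") tx_start_pos < min(ex$start)
                else tx_start_pos > max(ex$end)
    if (upstream) return("5prime")
    # intronic or downstream start: locate the first overlapped CDS base
    cds_pos <- sort(unlist(lapply(seq_len(nrow(ex)),
                                  function(i) ex$start[i]:ex$end[i])))
    inside <- cds_pos[cds_pos >= start & cds_pos <= end]
    if (length(inside) == 0) return("3prime")
    tx_pos <- if (ex$strand[1] == "+") min(inside) else max(inside)
    off <- cds_offset(genome, gene_id, tx_pos)
  }
  if (off <= ex$region_boundary[1]) "5prime" else "3prime"
}
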