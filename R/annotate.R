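#' Consequence-to-impact mapping
#'
#' Fixed, total mapping from consequence term to predicted impact:
#' `stop_gained` is High, `missense_variant` Moderate, `synonymous_variant`
#' Low, and the flanking/intergenic terms Modifier.
#'
#' @param term consequence term(s).
#' @return Character vector of impact ratings.
#' @export
consequence_impact <- function(term) {
  map <- c(stop_gained = "High", missense_variant = "Moderate",
           synonymous_variant = "Low", upstream_gene_variant = "Modifier",
           downstream_gene_variant = "Modifier", intergenic = "Modifier")
  out <- map[term]
  if (anyNA(out)) stop("unknown consequence term(s): ",
                       paste(unique(term[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Classify the consequence of a biallelic SNV against toy gene models
#'
#' A coding variant is classified by translating its codon before and after
#' the substitution (standard nuclear code, strand aware):
#' `stop_gained` when the alternate codon is a stop, `synonymous_variant`
#' when the amino acid is unchanged, `missense_variant` otherwise. A variant
#' within `flank` bp upstream (downstream) of a gene in transcript
#' orientation is an `upstream_gene_variant` (`downstream_gene_variant`);
#' anything else is `intergenic`.
#'
#' @param genome a `toy_genome`.
#' @param chrom,pos,ref,alt the variant (single-base ref and alt).
#' @param flank flank size in bp for the up/downstream classes.
#' @return A list with `term`, `impact`, `gene_id` (NA when intergenic),
#'   `aa_change` ("ref/alt" amino acids, "*" for stop; NA for noncoding).
#' @export
classify_variant <- function(genome, chrom, pos, ref, alt, flank = 1000L) {
  stopifnot(nchar(ref) == 1L, nchar(alt) == 1L, ref != alt)
  if (genome_base(genome, chrom, pos) != ref) {
    stop("reference_mismatch: genome has ",
         genome_base(genome, chrom, pos), " at ", site_key(chrom, pos),
         ", record says ", ref)
  }
  genes <- unique(genome$genes$gene_id[genome$genes$chrom == chrom])
  for (g in genes) {
    off <- cds_offset(genome, g, pos)
    if (!is.na(off)) {
      ex <- gene_exons(genome, g)
      cds <- gene_cds(genome, g)
      # variant base in transcript orientation
      tx_ref <- ref; tx_alt <- alt
      if (ex$strand[1] == "-") {
        comp <- c(A = "T", C = "G", G = "C", T = "A")
        tx_ref <- comp[ref]; tx_alt <- comp[alt]
      }
      codon_i <- (off - 1L) %/% 3L
      in_codon <- off - codon_i * 3L
      codon <- as.character(
        Biostrings::subseq(cds, codon_i * 3L + 1L, codon_i * 3L + 3L))
      stopifnot(substr(codon, in_codon, in_codon) == tx_ref)
      codon_alt <- codon
      substr(codon_alt, in_codon, in_codon) <- unname(tx_alt)
      aa_ref <- Biostrings::GENETIC_CODE[[codon]]
      aa_alt <- Biostrings::GENETIC_CODE[[codon_alt]]
      term <- if (aa_alt == "*" && aa_ref != "*") "stop_gained"
              else if (aa_alt == aa_ref) "synonymous_variant"
              else "missense_variant"
      return(list(term = term, impact = consequence_impact(term),
                  gene_id = g,
                  aa_change = if (term == "synonymous_variant") NA_character_
                              else paste0(aa_ref, "/", aa_alt)))
    }
  }
  # flanking classes, transcript orientation
  for (g in genes) {
    ex <- gene_exons(genome, g)
    left <- min(ex$start); right <- max(ex$end)
    if (pos >= left && pos <= right) next  # intronic: treat as intergenic
    before <- pos < left
    dist <- if (before) left - pos else pos - right
    if (dist > flank) next
    upstream <- (ex$strand[1] == "+") == before
    term <- if (upstream) "upstream_gene_variant" else "downstream_gene_variant"
    return(list(term = term, impact = consequence_impact(term), gene_id = g,
                aa_change = NA_character_))
  }
  list(term = "intergenic", impact = consequence_impact("intergenic"),
       gene_id = NA_character_, aa_change = NA_character_)
}

#' Assign a variant to a gene's 5' or 3' region
#'
#' The two halves of a gene's coding sequence (split at `region_boundary`,
#' by default the transcript-coordinate end of exon 1) define its 5' and 3'
#' regions. A coding variant is assigned by its CDS offset; a flanking
#' variant is assigned to the region of the gene end it abuts in transcript
#' orientation (upstream flank is 5', downstream flank is 3').
#'
#' @param genome a `toy_genome`.
#' @param gene_id the gene.
#' @param pos genomic position of the variant.
#' @param flank maximum flank distance for association.
#' @return `"5prime"` or `"3prime"`.
#' @export
assign_region <- function(genome, gene_id, pos, flank = 1000L) {
  ex <- gene_exons(genome, gene_id)
  off <- cds_offset(genome, gene_id, pos)
  if (!is.na(off)) {
    return(if (off <= ex$region_boundary[1]) "5prime" else "3prime")
  }
  left <- min(ex$start); right <- max(ex$end)
  if (pos >= left && pos <= right) {
    # intronic: fall on the side of the nearest transcript half
    mid_tx <- ex$region_boundary[1]
    cds_len <- sum(ex$end - ex$start + 1L)
    nearest <- if (pos - left < right - pos) left else right
    off_near <- cds_offset(genome, gene_id, nearest)
    return(if (off_near <= mid_tx) "5prime" else "3prime")
  }
  before <- pos < left
  dist <- if (before) left - pos else pos - right
  if (dist > flank) stop("position ", pos, " not associated with gene ",
                         gene_id, " (beyond ", flank, " bp flank)")
  upstream <- (ex$strand[1] == "+") == before
  if (upstream) "5prime" else "3prime"
}
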