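#' Generate a toy reference genome with non-overlapping gene models
#'
#' Builds a random haploid genome that stands in for a real amoebozoan
#' reference during simulation and testing. Base composition is controlled by
#' `at_fraction` because the genomes this emulates are strongly AT rich
#' (>77% AT in *D. discoideum*). Each gene is a two-exon protein-coding model
#' on a random strand; the boundary between the two exons (in transcript
#' coordinates) doubles as the default split between the gene's 5' and 3'
#' regions, mirroring how two-domain receptor genes are partitioned when
#' testing region-specific phenotype associations.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_len length of every chromosome in bp (>= 1000).
#' @param n_genes total number of genes to place (0 allowed).
#' @param at_fraction target A+T fraction in (0, 1).
#' @param seed integer seed; the same seed reproduces the genome byte for byte.
#' @param exon_codons integer length-2 vector, codons in exon 1 and exon 2.
#'   The default 128/130 keeps toy genes small; pass `c(383, 390)` for a
#'   full-size two-domain receptor stand-in.
#' @param intron_len intron length separating the two exons.
#' @return An object of class `toy_genome`: a list with elements
#'   `seq` (a [Biostrings::DNAStringSet] of chromosomes) and `genes`
#'   (a data frame with one row per exon: `gene_id`, `chrom`, `strand`,
#'   `exon`, `start`, `end`, `region_boundary` in CDS coordinates).
#' @export
make_reference <- function(n_chroms, chrom_len, n_genes, at_fraction = 0.77,
                           seed = 1L, exon_codons = c(128L, 130L),
                           intron_len = 60L) {
  stopifnot(n_chroms >= 1, chrom_len >= 1000, n_genes >= 0,
            at_fraction > 0, at_fraction < 1, length(exon_codons) == 2L)
  set.seed(derive_seed(seed, "reference"))
  p <- c(A = at_fraction / 2, C = (1 - at_fraction) / 2,
         G = (1 - at_fraction) / 2, T = at_fraction / 2)
  chroms <- vapply(seq_len(n_chroms), function(i) {
    paste(sample(names(p), chrom_len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  names(chroms) <- paste0("chr", seq_len(n_chroms))
  seqs <- Biostrings::DNAStringSet(chroms)

  gene_span <- sum(exon_codons) * 3L + intron_len
  flank <- 1200L # keep genes clear of each other's promoter flanks
  per_chrom_cap <- max(0L, (chrom_len - flank) %/% (gene_span + flank))
  if (n_genes > per_chrom_cap * n_chroms) {
    stop("cannot place ", n_genes, " genes of span ", gene_span,
         " bp on ", n_chroms, " chromosome(s) of ", chrom_len, " bp")
  }

  genes <- NULL
  if (n_genes > 0) {
    slots <- data.frame(
      chrom = rep(names(chroms), each = per_chrom_cap),
      slot = rep(seq_len(per_chrom_cap), times = n_chroms)
    )
    pick <- slots[sample.int(nrow(slots), n_genes), , drop = FALSE]
    rows <- lapply(seq_len(n_genes), function(i) {
      start1 <- flank + (pick$slot[i] - 1L) * (gene_span + flank) + 1L
      strand <- sample(c("+", "-"), 1L)
      # transcript exon 1 always has exon_codons[1] codons; on "-" it is the
      # genomic right-hand exon
      e_left <- 3L * if (strand == "+") exon_codons[1] else exon_codons[2]
      e_right <- 3L * sum(exon_codons) - e_left
      ex <- data.frame(
        gene_id = sprintf("gene%03d", i),
        chrom = pick$chrom[i],
        strand = strand,
        exon = if (strand == "+") 1:2 else 2:1,
        start = c(start1, start1 + e_left + intron_len),
        end = c(start1 + e_left - 1L,
                start1 + e_left + intron_len + e_right - 1L)
      )
      ex$region_boundary <- exon_codons[1] * 3L
      ex
    })
    genes <- do.call(rbind, rows)
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
    rownames(genes) <- NULL
  } else {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        strand = character(), exon = integer(),
                        start = integer(), end = integer(),
                        region_boundary = integer())
  }
  structure(list(seq = seqs, genes = genes), class = "toy_genome")
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("toy_genome:", length(x$seq), "chromosome(s),",
      length(unique(x$genes$gene_id)), "gene(s)\n")
  invisible(x)
}

#' Fetch one reference base
#'
#' @param genome a `toy_genome`.
#' @param chrom chromosome name.
#' @param pos 1-based position.
#' @return Single-character base.
#' @export
genome_base <- function(genome, chrom, pos) {
  as.character(Biostrings::subseq(genome$seq[[chrom]], pos, pos))
}

# Exon rows of one gene, in transcript order.
gene_exons <- function(genome, gene_id) {
  ex <- genome$genes[genome$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(ex) == 0) stop("unknown gene_id: ", gene_id)
  ex[order(ex$exon), , drop = FALSE]
}

#' Concatenated coding sequence of a gene (introns excluded)
#'
#' @inheritParams genome_base
#' @param gene_id gene identifier in `genome$genes`.
#' @return A [Biostrings::DNAString] in transcript orientation.
#' @export
gene_cds <- function(genome, gene_id) {
  ex <- gene_exons(genome, gene_id)
  ex <- ex[order(ex$start), , drop = FALSE]
  pieces <- lapply(seq_len(nrow(ex)), function(i) {
    Biostrings::subseq(genome$seq[[ex$chrom[i]]], ex$start[i], ex$end[i])
  })
  cds <- do.call(Biostrings::xscat, pieces)
  if (ex$strand[1] == "-") cds <- Biostrings::reverseComplement(cds)
  cds
}

#' GC content of a gene's coding sequence
#'
#' Fraction of G+C bases over the concatenated CDS, introns excluded.
#'
#' @inheritParams gene_cds
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(genome, gene_id) {
  cds <- gene_cds(genome, gene_id)
  unname(Biostrings::letterFrequency(cds, "GC", as.prob = TRUE)[1])
}

# 1-based CDS offset of a genomic position within a gene, or NA if the
# position is intronic / outside the CDS. Strand aware.
cds_offset <- function(genome, gene_id, pos) {
  ex <- gene_exons(genome, gene_id)
  off <- 0L
  for (i in seq_len(nrow(ex))) {
    len <- ex$end[i] - ex$start[i] + 1L
    if (pos >= ex$start[i] && pos <= ex$end[i]) {
      within <- if (ex$strand[i] == "+") pos - ex$start[i] + 1L
                else ex$end[i] - pos + 1L
      return(off + within)
    }
    off <- off + len
  }
  NA_integer_
}
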