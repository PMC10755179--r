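#' Per-gene tallies of called SNPs
#'
#' For each gene: the number of distinct SNP sites, the number of distinct
#' evolved lines in which any of those SNPs was called (a clone and its own
#' population count once), and the consequence terms observed. Parallel
#' evolution at the gene level shows up as a gene collecting many unique
#' SNPs across lines.
#'
#' @param rows data frame with columns `chrom`, `pos`, `gene_id` and list
#'   column `samples` (e.g. from [load_snp_fixture()] or an annotated final
#'   call set via [callset_to_rows()]). Rows with NA `gene_id` (intergenic)
#'   are ignored.
#' @return Data frame `gene_id`, `n_snps`, `n_lines`, `consequences`.
#' @export
tally_per_gene <- function(rows) {
  rows <- rows[!is.na(rows$gene_id), , drop = FALSE]
  if (nrow(rows) == 0) {
    return(data.frame(gene_id = character(), n_snps = integer(),
                      n_lines = integer(), consequences = character()))
  }
  out <- lapply(split(seq_len(nrow(rows)), rows$gene_id), function(idx) {
    sub <- rows[idx, , drop = FALSE]
    lines <- unique(stats::na.omit(line_of_sample(unlist(sub$samples))))
    data.frame(gene_id = sub$gene_id[1],
               n_snps = length(unique(site_key(sub$chrom, sub$pos))),
               n_lines = length(lines),
               consequences = paste(sort(unique(sub$consequence)),
                                    collapse = ";"))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(-res$n_snps, res$gene_id), , drop = FALSE]
}

#' Sites called in more than one evolved line
#'
#' A site is cross-line shared when its called samples span two or more
#' distinct lines; a clone and its own population count as one line. True
#' new mutations are expected to be private to one line, so shared sites
#' are the exception worth reporting.
#'
#' @inheritParams tally_per_gene
#' @return The subset of `rows` whose samples span > 1 line, with an added
#'   `lines` column.
#' @export
cross_line_sharing <- function(rows) {
  if (nrow(rows) == 0) {
    rows$lines <- character(0)
    return(rows)
  }
  line_sets <- lapply(rows$samples, function(s) {
    ln <- line_of_sample(s)
    if (anyNA(ln)) stop("unresolvable sample id(s): ",
                        paste(s[is.na(ln)], collapse = ", "))
    sort(unique(ln))
  })
  shared <- lengths(line_sets) > 1
  out <- rows[shared, , drop = FALSE]
  out$lines <- vapply(line_sets[shared], paste, character(1), collapse = ",")
  out
}

#' Number of called SNPs per sample
#'
#' @inheritParams tally_per_gene
#' @param all_samples optional character vector of the full sample universe;
#'   samples with no SNPs are reported with count 0.
#' @return Data frame `sample`, `n_snps`.
#' @export
per_sample_counts <- function(rows, all_samples = NULL) {
  called <- unlist(rows$samples)
  tab <- table(called)
  samples <- all_samples %||% sort(names(tab))
  data.frame(sample = samples,
             n_snps = as.integer(ifelse(samples %in% names(tab),
                                        tab[samples], 0L)))
}

#' Mean origin-population allele frequency over a site subset
#'
#' For each SNP, the alternate-allele read fraction in the population of the
#' line in which it was called; the summary is the arithmetic mean over the
#' subset. Used to compare read support between gene groups (strongly
#' selected mutations ride to higher population frequency).
#'
#' @param cs an AF-annotated consensus [callset()] (see [annotate_af()]).
#' @param meta sample metadata.
#' @param sites optional logical/integer index selecting the subset.
#' @return A list with `mean_af` (NA when no site has data), `n_sites`, and
#'   the per-site values `af`.
#' @export
mean_population_af <- function(cs, meta, sites = NULL) {
  idx <- sites %||% seq_len(n_sites(cs))
  if (is.logical(idx)) idx <- which(idx)
  pops <- meta$sample_id[meta$role == "population"]
  af <- vapply(idx, function(i) {
    called <- colnames(cs$gt)[cs$gt[i, ] == "1"]
    lines <- unique(stats::na.omit(line_of_sample(called)))
    vals <- cs$af[i, intersect(as.character(lines), pops)]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) NA_real_ else mean(vals)
  }, numeric(1))
  usable <- !is.na(af)
  if (any(!usable)) {
    warning(sum(!usable), " site(s) lack population AF; excluded")
  }
  list(mean_af = if (any(usable)) mean(af[usable]) else NA_real_,
       n_sites = sum(usable), af = af)
}

#' Convert an annotated call set to summary rows
#'
#' Builds the row format consumed by the parallelism summaries from a final
#' call set: one row per site with its called samples and, when a genome is
#' supplied, its consequence classification.
#'
#' @param cs a [callset()].
#' @param genome optional `toy_genome` for consequence annotation.
#' @return Data frame with `chrom`, `pos`, `gene_id`, `consequence`,
#'   `impact`, `aa_change` and list column `samples`.
#' @export
callset_to_rows <- function(cs, genome = NULL) {
  v <- cs$variants
  samples <- lapply(seq_len(n_sites(cs)),
                    function(i) colnames(cs$gt)[cs$gt[i, ] == "1"])
  out <- data.frame(chrom = v$chrom, pos = v$pos)
  out$samples <- I(samples)
  if (!is.null(genome)) {
    ann <- lapply(seq_len(n_sites(cs)), function(i) {
      classify_variant(genome, v$chrom[i], v$pos[i], v$ref[i], v$alt[i])
    })
    out$gene_id <- vapply(ann, `[[`, character(1), "gene_id")
    out$consequence <- vapply(ann, `[[`, character(1), "term")
    out$impact <- vapply(ann, `[[`, character(1), "impact")
    out$aa_change <- vapply(ann, `[[`, character(1), "aa_change")
  } else {
    out$gene_id <- NA_character_
    out$consequence <- NA_character_
    out$impact <- NA_character_
    out$aa_change <- NA_character_
  }
  out
}
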