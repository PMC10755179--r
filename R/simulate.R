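#' Simulate serial-passage evolution of selected mutations
#'
#' Runs the passaging design of the low-relatedness evolution experiment on a
#' toy genome. Each line accumulates new mutations (Poisson per passage);
#' every mutation's population frequency follows a deterministic logistic
#' selection step \eqn{f' = f(1+s) / (1 + f s)} followed by binomial
#' resampling of the founder spores, once per passage. Loci evolve
#' independently (no linkage or clonal interference), so per-line frequencies
#' are marginals and may sum above one.
#'
#' Mutation classes: `5prime` and `3prime` fall in the corresponding region
#' of a random gene's CDS, `other` falls in a gene's upstream flank, and
#' `neutral` (the only class with `s = 0`) is intergenic. A sequenced clone
#' carries each of its line's mutations independently with probability equal
#' to the mutation's final frequency, and is non-fruiting with probability
#' `penetrance_nonfruiting` when it carries at least one `5prime`-class
#' mutation.
#'
#' @param genome a [make_reference()] toy genome with at least one gene when
#'   any non-neutral mutations are to be planted.
#' @param cfg a [sim_config()].
#' @param n_clones_per_line sequenced clones per line.
#' @param planted optional data frame with columns `line`, `class`,
#'   `arise_passage`, and optionally `init_freq` and `s`, overriding the
#'   random mutation process (used to plant mutations under controlled
#'   conditions).
#' @return An object of class `truth_set`: list with `mutations` (data frame
#'   with `mut_id`, `line`, `chrom`, `pos`, `ref`, `alt`, `class`, `s`,
#'   `arise_passage`, `final_freq`, and list column `trajectory`),
#'   `genotypes` (0/1 matrix, mutations x clone samples), `sample_meta`
#'   (one row per sample: `sample_id`, `line`, `role`, `phenotype`), and the
#'   `cfg` used.
#' @export
simulate_evolution <- function(genome, cfg, n_clones_per_line = 1L,
                               planted = NULL) {
  validate_sim_config(cfg)
  stopifnot(n_clones_per_line >= 1)
  set.seed(derive_seed(cfg$seed, "evolution"))

  if (is.null(planted)) {
    rows <- list()
    for (line in seq_len(cfg$n_lines)) {
      for (p in seq_len(cfg$n_passages)) {
        k <- stats::rpois(1, cfg$mutation_rate)
        if (k > 0) {
          cls <- sample(names(cfg$class_probs), k, replace = TRUE,
                        prob = cfg$class_probs)
          rows[[length(rows) + 1L]] <- data.frame(
            line = line, class = cls, arise_passage = p)
        }
      }
    }
    planted <- if (length(rows)) do.call(rbind, rows) else
      data.frame(line = integer(), class = character(),
                 arise_passage = integer())
  }
  if (nrow(planted) > 0) {
    stopifnot(all(planted$class %in% c("5prime", "3prime", "other", "neutral")),
              all(planted$arise_passage >= 1),
              all(planted$arise_passage <= cfg$n_passages))
  }
  if (is.null(planted$init_freq)) planted$init_freq <- rep(cfg$init_freq, nrow(planted))
  if (is.null(planted$s)) {
    planted$s <- ifelse(planted$class == "neutral", 0, cfg$selection_coeff)
  }

  n_mut <- nrow(planted)
  mut <- planted
  mut$mut_id <- if (n_mut) sprintf("mut%03d", seq_len(n_mut)) else character()
  pos_info <- place_mutations(genome, mut$class)
  mut$chrom <- pos_info$chrom
  mut$pos <- pos_info$pos
  mut$gene_id <- pos_info$gene_id
  mut$ref <- pos_info$ref
  mut$alt <- pos_info$alt

  # frequency trajectories: logistic selection then founder resampling
  traj <- lapply(seq_len(n_mut), function(i) {
    f <- numeric(cfg$n_passages)
    t0 <- mut$arise_passage[i]
    f[t0] <- mut$init_freq[i]
    s <- mut$s[i]
    if (t0 < cfg$n_passages) {
      for (p in (t0 + 1L):cfg$n_passages) {
        fsel <- f[p - 1L] * (1 + s) / (1 + f[p - 1L] * s)
        f[p] <- stats::rbinom(1L, cfg$founder_count, fsel) / cfg$founder_count
        if (f[p] == 0) break
      }
    }
    f
  })
  mut$trajectory <- traj
  mut$final_freq <- vapply(traj, function(f) f[cfg$n_passages], numeric(1))

  # samples: one ancestor, one population per line, clones per line
  clone_ids <- as.vector(t(outer(seq_len(cfg$n_lines),
                                 seq_len(n_clones_per_line),
                                 function(l, k) paste0(l, "-NF", k))))
  sample_meta <- rbind(
    data.frame(sample_id = "ancestor", line = NA_integer_, role = "ancestor",
               phenotype = "unknown"),
    data.frame(sample_id = as.character(seq_len(cfg$n_lines)),
               line = seq_len(cfg$n_lines), role = "population",
               phenotype = "unknown"),
    data.frame(sample_id = clone_ids,
               line = line_of_sample(clone_ids), role = "clone",
               phenotype = NA_character_)
  )

  genotypes <- matrix(0L, nrow = n_mut, ncol = length(clone_ids),
                      dimnames = list(mut$mut_id, clone_ids))
  for (cid in clone_ids) {
    l <- line_of_sample(cid)
    idx <- which(mut$line == l)
    if (length(idx)) {
      genotypes[idx, cid] <- stats::rbinom(length(idx), 1L, mut$final_freq[idx])
    }
    carries_5p <- any(genotypes[idx, cid] == 1L & mut$class[idx] == "5prime")
    nonfruiting <- carries_5p &&
      stats::runif(1) < cfg$penetrance_nonfruiting
    sample_meta$phenotype[sample_meta$sample_id == cid] <-
      if (nonfruiting) "nonfruiting" else "fruiting"
  }

  mut <- mut[, c("mut_id", "line", "chrom", "pos", "ref", "alt", "gene_id",
                 "class", "s", "arise_passage", "init_freq", "final_freq",
                 "trajectory")]
  structure(list(mutations = mut, genotypes = genotypes,
                 sample_meta = sample_meta, cfg = cfg),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("truth_set:", nrow(x$mutations), "mutation(s),",
      nrow(x$sample_meta), "sample(s)\n")
  invisible(x)
}

# Draw genomic positions for mutations by class; positions are unique.
place_mutations <- function(genome, classes) {
  n <- length(classes)
  out <- data.frame(chrom = character(n), pos = integer(n),
                    gene_id = NA_character_, ref = character(n),
                    alt = character(n), stringsAsFactors = FALSE)
  if (n == 0) return(out)
  genes <- unique(genome$genes$gene_id)
  if (length(genes) == 0 && any(classes != "neutral")) {
    stop("genome has no genes; only neutral mutations can be placed")
  }
  used <- character(0)
  for (i in seq_len(n)) {
    repeat {
      cls <- classes[i]
      if (cls %in% c("5prime", "3prime")) {
        g <- sample(genes, 1)
        ex <- gene_exons(genome, g)
        cds_len <- sum(ex$end - ex$start + 1L)
        b <- ex$region_boundary[1]
        off <- if (cls == "5prime") sample.int(b, 1)
               else b + sample.int(cds_len - b, 1)
        pos <- genomic_position(genome, g, off)
        chrom <- ex$chrom[1]
      } else if (cls == "other") {
        g <- sample(genes, 1)
        ex <- gene_exons(genome, g)
        chrom <- ex$chrom[1]
        if (ex$strand[1] == "+") {
          pos <- min(ex$start) - sample.int(1000L, 1)
        } else {
          pos <- max(ex$end) + sample.int(1000L, 1)
        }
      } else {
        chrom <- sample(names(genome$seq), 1)
        pos <- sample.int(length(genome$seq[[chrom]]), 1)
        if (nrow(genome$genes) > 0) {
          near <- genome$genes$chrom == chrom &
            pos >= genome$genes$start - 1100L & pos <= genome$genes$end + 1100L
          if (any(near)) next
        }
        g <- NA_character_
      }
      if (pos < 1 || pos > length(genome$seq[[chrom]])) next
      key <- site_key(chrom, pos)
      if (key %in% used) next
      used <- c(used, key)
      ref <- genome_base(genome, chrom, pos)
      out$chrom[i] <- chrom
      out$pos[i] <- pos
      out$gene_id[i] <- if (classes[i] == "neutral") NA_character_ else g
      out$ref[i] <- ref
      out$alt[i] <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      break
    }
  }
  out
}

# Genomic coordinate of a 1-based CDS offset (inverse of cds_offset()).
genomic_position <- function(genome, gene_id, offset) {
  ex <- gene_exons(genome, gene_id)
  for (i in seq_len(nrow(ex))) {
    len <- ex$end[i] - ex$start[i] + 1L
    if (offset <= len) {
      return(if (ex$strand[i] == "+") ex$start[i] + offset - 1L
             else ex$end[i] - offset + 1L)
    }
    offset <- offset - len
  }
  stop("CDS offset beyond gene ", gene_id)
}

#' Simulate per-site per-sample read counts at mapped-depth level
#'
#' Depth at each site/sample is Poisson with the role's mean depth; true
#' alternate reads are binomial at the sample's allele frequency (trajectory
#' endpoint for populations, 0/1 for clones and the ancestor); each read then
#' reports a wrong base with probability `error_rate` (uniform over the other
#' three bases). In addition to the truth sites, `ancestral_poly_sites`
#' intergenic sites carry standing variation or ancestor-level artifacts in
#' three equal classes: sites where the ancestor is fixed for a non-reference
#' allele (`ancestor_variant`), sites with no ancestor coverage
#' (`ancestor_uncalled`), and genuinely polymorphic sites whose ancestor
#' major allele frequency is drawn from `ancestor_maf_range`
#' (`ancestor_maf`). All of these must be removed by ancestral masking
#' downstream.
#'
#' @param truth a [simulate_evolution()] truth set.
#' @param genome the toy genome the truth set was simulated on.
#' @param cfg the same [sim_config()].
#' @return A data frame of class `read_counts` with columns `chrom`, `pos`,
#'   `sample`, `ref`, `alt`, `n_a`, `n_c`, `n_g`, `n_t`, `depth`
#'   (depth = sum of the four base counts), carrying a `site_info` attribute
#'   that records each site's origin class.
#' @export
simulate_readcounts <- function(truth, genome, cfg) {
  validate_sim_config(cfg)
  set.seed(derive_seed(cfg$seed, "readcounts"))
  meta <- truth$sample_meta

  sites <- truth$mutations[, c("chrom", "pos", "ref", "alt")]
  sites$origin <- rep("mutation", nrow(sites))
  sites$mut_id <- truth$mutations$mut_id
  sites$anc_freq <- 0

  if (cfg$ancestral_poly_sites > 0) {
    kinds <- rep(c("ancestor_variant", "ancestor_uncalled", "ancestor_maf"),
                 length.out = cfg$ancestral_poly_sites)
    poly_pos <- place_mutations(genome, rep("neutral", cfg$ancestral_poly_sites))
    anc_freq <- ifelse(kinds == "ancestor_variant", 1,
                ifelse(kinds == "ancestor_uncalled", 0.5,
                       1 - stats::runif(cfg$ancestral_poly_sites,
                                        cfg$ancestor_maf_range[1],
                                        cfg$ancestor_maf_range[2])))
    poly <- data.frame(chrom = poly_pos$chrom, pos = poly_pos$pos,
                       ref = poly_pos$ref, alt = poly_pos$alt,
                       origin = kinds, mut_id = NA_character_,
                       anc_freq = anc_freq)
    sites <- rbind(sites, poly)
  }

  freq_for <- function(site_idx, sample_row) {
    s <- sites[site_idx, ]
    if (s$origin == "mutation") {
      m <- match(s$mut_id, truth$mutations$mut_id)
      switch(sample_row$role,
        ancestor = 0,
        population = if (truth$mutations$line[m] == sample_row$line)
          truth$mutations$final_freq[m] else 0,
        clone = if (truth$mutations$line[m] == sample_row$line)
          truth$genotypes[s$mut_id, sample_row$sample_id] else 0)
    } else {
      # standing variation: same frequency in every derived sample
      s$anc_freq
    }
  }

  rows <- vector("list", nrow(sites) * nrow(meta))
  k <- 0L
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(meta))) {
      mrow <- meta[j, ]
      mean_depth <- if (mrow$role == "clone") cfg$depth_clone else
        cfg$depth_population
      depth <- stats::rpois(1, mean_depth)
      if (sites$origin[i] == "ancestor_uncalled" && mrow$role == "ancestor") {
        depth <- 0L
      }
      f <- freq_for(i, mrow)
      cnt <- sim_base_counts(depth, sites$ref[i], sites$alt[i], f,
                             cfg$error_rate)
      k <- k + 1L
      rows[[k]] <- data.frame(chrom = sites$chrom[i], pos = sites$pos[i],
                              sample = mrow$sample_id, ref = sites$ref[i],
                              alt = sites$alt[i], n_a = cnt["A"],
                              n_c = cnt["C"], n_g = cnt["G"], n_t = cnt["T"],
                              depth = sum(cnt))
    }
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- NULL
  attr(counts, "site_info") <- sites
  class(counts) <- c("read_counts", "data.frame")
  counts
}

# Observed base counts for one site/sample: true allele draw + uniform
# sequencing error over the other three bases.
sim_base_counts <- function(depth, ref, alt, f, error_rate) {
  bases <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  if (depth == 0) return(bases)
  n_alt_true <- stats::rbinom(1L, depth, f)
  n_ref_true <- depth - n_alt_true
  for (b in list(c(ref, n_ref_true), c(alt, n_alt_true))) {
    n_true <- as.integer(b[2])
    if (n_true == 0) next
    others <- setdiff(names(bases), b[1])
    probs <- stats::setNames(rep(error_rate / 3, 4), names(bases))
    probs[b[1]] <- 1 - error_rate
    draw <- stats::rmultinom(1, n_true, probs)[, 1]
    bases <- bases + draw
  }
  bases
}

#' Extract one sample's alternate-allele count at given sites
#'
#' @param counts a `read_counts` table.
#' @param chrom,pos,sample vectors identifying (site, sample) entries.
#' @return Integer vector of alternate-allele read counts (NA where the
#'   entry is absent from `counts`).
#' @export
alt_count <- function(counts, chrom, pos, sample) {
  key <- paste(chrom, pos, sample)
  idx <- match(key, paste(counts$chrom, counts$pos, counts$sample))
  out <- rep(NA_integer_, length(key))
  ok <- !is.na(idx)
  col <- c(A = "n_a", C = "n_c", G = "n_g", T = "n_t")
  if (any(ok)) {
    m <- counts[idx[ok], , drop = FALSE]
    out[ok] <- as.integer(
      m[cbind(seq_len(nrow(m)), match(col[m$alt], names(m)))])
  }
  out
}

#' Simulate a clone genotyping screen
#'
#' Draws additional clones from each evolved line at the line's final
#' mutation frequencies, and records for every (clone, variant) pair whether
#' the clone carries the variant and whether it forms fruiting bodies in
#' isolation (penetrance model: non-fruiting with probability
#' `penetrance_nonfruiting` when carrying any `5prime`-class mutation).
#'
#' @param truth a [simulate_evolution()] truth set.
#' @param n_clones_per_line clones to screen per line (>= 1).
#' @param seed integer seed for the screen's substream.
#' @return A data frame with columns `line`, `clone_id`, `variant_id`,
#'   `fruits` (0/1), `carries` (0/1).
#' @export
simulate_clone_screen <- function(truth, n_clones_per_line, seed = 1L) {
  if (n_clones_per_line < 1) stop("n_clones_per_line must be >= 1")
  set.seed(derive_seed(seed, "clone_screen"))
  cfg <- truth$cfg
  mut <- truth$mutations
  out <- list()
  for (line in sort(unique(mut$line))) {
    idx <- which(mut$line == line)
    for (k in seq_len(n_clones_per_line)) {
      carries <- stats::rbinom(length(idx), 1L, mut$final_freq[idx])
      carries_5p <- any(carries == 1L & mut$class[idx] == "5prime")
      fruits <- !(carries_5p && stats::runif(1) < cfg$penetrance_nonfruiting)
      out[[length(out) + 1L]] <- data.frame(
        line = line, clone_id = paste0("screen", k),
        variant_id = mut$mut_id[idx], fruits = as.integer(fruits),
        carries = carries)
    }
  }
  if (length(out) == 0) {
    return(data.frame(line = integer(), clone_id = character(),
                      variant_id = character(), fruits = integer(),
                      carries = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
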