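#' Filtration thresholds for the SNV cascade
#'
#' Every threshold of the published filtration cascade, with the published
#' value as default. Thresholds written as strict inequalities in the source
#' pipeline are strict here too; "minimum QUAL of 200" keeps QUAL >= 200,
#' "at least 5 reads" keeps >= 5, "more than 10 samples" drops > 10, and
#' "more than 1.5 times the average DP" drops > 1.5 x mean.
#'
#' @param ancestor_maf_min sites with ancestor major allele frequency below
#'   this are removed as ancestral polymorphism.
#' @param max_missing_samples drop sites uncalled in more than this many
#'   samples.
#' @param max_alt_ac drop sites with more than this many samples called
#'   alternate (haploid AC; at most one population plus its clones should
#'   carry a line-specific mutation).
#' @param min_qual minimum Phred-scaled site quality.
#' @param dp_mean_factor drop sites whose DP exceeds this multiple of the
#'   mean DP over the sites surviving the preceding custom rules.
#' @param min_origin_support_reads a clone call must be backed by at least
#'   this many alternate reads in its origin population.
#' @param shared_support_min_reads,shared_support_min_lines drop a SNP whose
#'   alternate allele has at least `shared_support_min_reads` supporting
#'   reads in the populations of at least `shared_support_min_lines` lines
#'   other than those in which it was called.
#' @param missing_metric_fails when `TRUE` a missing caller metric fails its
#'   rule; by default it does not (rank-sum metrics are legitimately absent
#'   at sites without both alleles) and is only flagged.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(ancestor_maf_min = 0.90,
                          max_missing_samples = 10L,
                          max_alt_ac = 3L,
                          min_qual = 200,
                          dp_mean_factor = 1.5,
                          min_origin_support_reads = 5L,
                          shared_support_min_reads = 2L,
                          shared_support_min_lines = 2L,
                          missing_metric_fails = FALSE) {
  cfg <- list(ancestor_maf_min = ancestor_maf_min,
              max_missing_samples = as.integer(max_missing_samples),
              max_alt_ac = as.integer(max_alt_ac),
              min_qual = min_qual, dp_mean_factor = dp_mean_factor,
              min_origin_support_reads = as.integer(min_origin_support_reads),
              shared_support_min_reads = as.integer(shared_support_min_reads),
              shared_support_min_lines = as.integer(shared_support_min_lines),
              missing_metric_fails = isTRUE(missing_metric_fails))
  stopifnot(cfg$ancestor_maf_min > 0, cfg$ancestor_maf_min <= 1,
            cfg$max_missing_samples >= 0, cfg$max_alt_ac >= 0,
            cfg$min_qual >= 0, cfg$dp_mean_factor >= 0,
            cfg$min_origin_support_reads >= 0)
  structure(cfg, class = "filter_config")
}

decision_frame <- function(cs, reasons, stage) {
  n <- n_sites(cs)
  data.frame(chrom = cs$variants$chrom, pos = cs$variants$pos,
             alt = cs$variants$alt, stage = rep_len(stage, n),
             verdict = ifelse(nchar(reasons) > 0, "fail", "pass"),
             reasons = reasons)
}

join_reasons <- function(lst) {
  vapply(lst, function(r) paste(r, collapse = ";"), character(1))
}

#' Major allele frequency per site/sample from read counts
#'
#' MAF is the fraction of reads supporting the most common base.
#'
#' @param counts a `read_counts` table.
#' @return `counts` with an added `maf` column (NA at zero depth).
#' @export
maf_from_counts <- function(counts) {
  m <- as.matrix(counts[, c("n_a", "n_c", "n_g", "n_t")])
  counts$maf <- ifelse(counts$depth > 0,
                       apply(m, 1, max) / counts$depth, NA_real_)
  counts
}

#' Mask ancestral variation
#'
#' Removes, from all samples, every site at which the ancestor (i) was
#' called as a variant, (ii) was left uncalled, or (iii) has a major allele
#' frequency below `ancestor_maf_min` in its read counts — i.e. sites that
#' reflect standing variation or reference error rather than evolution
#' during the experiment. A site absent from the ancestor's read counts is
#' treated as uncalled in the ancestor and flagged distinctly.
#'
#' @param cs a [callset()] whose genotype matrix includes the ancestor.
#' @param ancestor_counts `read_counts` rows for the ancestor sample (a full
#'   table may be passed; rows for other samples are ignored).
#' @param cfg a [filter_config()].
#' @param ancestor_id ancestor sample id in the genotype matrix.
#' @return `list(kept, decisions)`.
#' @export
mask_ancestral <- function(cs, ancestor_counts, cfg = filter_config(),
                           ancestor_id = "ancestor") {
  if (!ancestor_id %in% colnames(cs$gt)) {
    stop("ancestor sample '", ancestor_id, "' absent from call set")
  }
  anc <- ancestor_counts[ancestor_counts$sample == ancestor_id, , drop = FALSE]
  anc <- maf_from_counts(anc)
  idx <- match(callset_keys(cs), site_key(anc$chrom, anc$pos))
  anc_gt <- cs$gt[, ancestor_id]

  reasons <- vector("list", n_sites(cs))
  for (i in seq_len(n_sites(cs))) {
    r <- character(0)
    if (anc_gt[i] == "1") r <- c(r, "ancestor_variant")
    if (anc_gt[i] == ".") r <- c(r, "ancestor_uncalled")
    if (is.na(idx[i])) {
      r <- c(r, "ancestor_missing_counts")
    } else if (!is.na(anc$maf[idx[i]]) &&
               anc$maf[idx[i]] < cfg$ancestor_maf_min) {
      r <- c(r, "ancestor_maf")
    }
    reasons[[i]] <- r
  }
  rs <- join_reasons(reasons)
  list(kept = subset_callset(cs, rs == ""),
       decisions = decision_frame(cs, rs, "mask_ancestral"))
}

# shared machinery for the two hard filters: each rule is (metric, test).
apply_metric_rules <- function(variants, rules, missing_metric_fails) {
  n <- nrow(variants)
  reasons <- replicate(n, character(0), simplify = FALSE)
  for (name in names(rules)) {
    vals <- variants[[name]]
    if (is.null(vals)) vals <- rep(NA_real_, n)
    ok <- rules[[name]](vals)
    absent <- is.na(vals)
    for (i in which(absent)) {
      reasons[[i]] <- c(reasons[[i]], paste0("metric_absent:", name))
    }
    fail <- if (missing_metric_fails) (absent | !ok) else (!absent & !ok)
    for (i in which(fail)) reasons[[i]] <- c(reasons[[i]], name)
  }
  reasons
}

#' GATK-style hard filter
#'
#' Pass iff `QD > 2`, `FS < 60`, `SOR < 3`, `MQ > 40`, `MQRankSum > -12.5`
#' and `ReadPosRankSum > -8` (the GATK Best Practices germline
#' recommendations); all violated rules are listed. A missing metric is
#' flagged `metric_absent:<name>` and, by default, does not fail its rule.
#'
#' @param cs a caller-A [callset()] (or its `variants` data frame).
#' @param missing_metric_fails see [filter_config()].
#' @return `list(kept, decisions)` when given a callset; a decisions data
#'   frame when given a bare data frame.
#' @export
hard_filter_a <- function(cs, missing_metric_fails = FALSE) {
  rules <- list(QD = function(x) x > 2, FS = function(x) x < 60,
                SOR = function(x) x < 3, MQ = function(x) x > 40,
                MQRankSum = function(x) x > -12.5,
                ReadPosRankSum = function(x) x > -8)
  hard_filter_impl(cs, rules, missing_metric_fails, "hard_filter_a")
}

#' Freebayes-style hard filter
#'
#' Pass iff `MQM > 40`, `SAF > 0`, `SAR > 0`, `SAP > 0.5`, `SRP > 0.5`,
#' `RPR > 1` and `RPL > 1` (mapping-quality, strand-balance and
#' read-placement rules). Missing-metric policy as in [hard_filter_a()].
#'
#' @inheritParams hard_filter_a
#' @return As [hard_filter_a()].
#' @export
hard_filter_b <- function(cs, missing_metric_fails = FALSE) {
  rules <- list(MQM = function(x) x > 40, SAF = function(x) x > 0,
                SAR = function(x) x > 0, SAP = function(x) x > 0.5,
                SRP = function(x) x > 0.5, RPR = function(x) x > 1,
                RPL = function(x) x > 1)
  hard_filter_impl(cs, rules, missing_metric_fails, "hard_filter_b")
}

hard_filter_impl <- function(cs, rules, missing_metric_fails, stage) {
  variants <- if (inherits(cs, "callset")) cs$variants else cs
  reasons <- apply_metric_rules(variants, rules, missing_metric_fails)
  # metric_absent entries are flags, not failures, unless the policy says so
  failing <- vapply(reasons, function(r) {
    any(!startsWith(r, "metric_absent:")) ||
      (missing_metric_fails && length(r) > 0)
  }, logical(1))
  rs <- join_reasons(reasons)
  dec <- data.frame(chrom = variants$chrom, pos = variants$pos,
                    alt = variants$alt,
                    stage = rep_len(stage, nrow(variants)),
                    verdict = ifelse(failing, "fail", "pass"),
                    reasons = rs)
  if (inherits(cs, "callset")) {
    list(kept = subset_callset(cs, !failing), decisions = dec)
  } else {
    dec
  }
}

#' Custom site-level filters
#'
#' Applies, in order: removal of indels and multi-allelic sites (only
#' biallelic SNVs are considered); removal of sites uncalled in more than
#' `max_missing_samples` samples; removal of sites with haploid alternate
#' allele count above `max_alt_ac`; removal of sites with QUAL below
#' `min_qual`; and removal of sites whose approximate read depth exceeds
#' `dp_mean_factor` times the mean DP of the sites surviving the preceding
#' rules of this cascade (so the DP threshold is computed on the cleaned
#' set, making this rule order dependent by design).
#'
#' @param cs a [callset()].
#' @param cfg a [filter_config()].
#' @return `list(kept, decisions)`.
#' @export
custom_filter <- function(cs, cfg = filter_config()) {
  v <- cs$variants
  n <- n_sites(cs)
  reasons <- replicate(n, character(0), simplify = FALSE)

  not_snv <- v$is_indel | v$multiallelic |
    nchar(v$ref) != 1L | nchar(v$alt) != 1L
  n_missing <- rowSums(cs$gt == ".")
  ac <- rowSums(cs$gt == "1")
  for (i in seq_len(n)) {
    r <- character(0)
    if (not_snv[i]) r <- c(r, "not_biallelic_snv")
    if (n_missing[i] > cfg$max_missing_samples) r <- c(r, "missingness")
    if (ac[i] > cfg$max_alt_ac) r <- c(r, "max_ac")
    if (v$qual[i] < cfg$min_qual) r <- c(r, "min_qual")
    reasons[[i]] <- r
  }
  surviving <- lengths(reasons) == 0
  if (any(surviving)) {
    dp_mean <- mean(v$dp[surviving])
    excess <- surviving & v$dp > cfg$dp_mean_factor * dp_mean
    for (i in which(excess)) reasons[[i]] <- c(reasons[[i]], "excess_dp")
  }
  rs <- join_reasons(reasons)
  list(kept = subset_callset(cs, rs == ""),
       decisions = decision_frame(cs, rs, "custom_filter"))
}

#' Intersect two independently filtered call sets
#'
#' A site survives only when present, with the same alternate allele, in
#' both fully filtered call sets; the consensus record carries caller A's
#' annotations. Sites present in only one set are dropped
#' (`single_caller`); a shared position with different alternate alleles is
#' dropped and flagged `alt_mismatch`.
#'
#' @param cs_a,cs_b filtered caller A / caller B [callset()]s.
#' @return `list(kept, decisions)`; decisions cover the union of sites.
#' @export
intersect_callsets <- function(cs_a, cs_b) {
  ka <- callset_keys(cs_a)
  kb <- callset_keys(cs_b)
  m <- match(ka, kb)
  in_both <- !is.na(m)
  alt_same <- in_both & cs_a$variants$alt == cs_b$variants$alt[ifelse(is.na(m), 1L, m)]

  reasons_a <- ifelse(!in_both, "single_caller",
                      ifelse(alt_same, "", "alt_mismatch"))
  dec_a <- data.frame(chrom = cs_a$variants$chrom, pos = cs_a$variants$pos,
                      alt = cs_a$variants$alt,
                      stage = rep_len("intersect", length(ka)),
                      verdict = ifelse(reasons_a == "", "pass", "fail"),
                      reasons = reasons_a)
  only_b <- !(kb %in% ka)
  dec_b <- data.frame(chrom = cs_b$variants$chrom[only_b],
                      pos = cs_b$variants$pos[only_b],
                      alt = cs_b$variants$alt[only_b],
                      stage = rep_len("intersect", sum(only_b)),
                      verdict = rep_len("fail", sum(only_b)),
                      reasons = rep_len("single_caller", sum(only_b)))
  kept <- subset_callset(cs_a, alt_same)
  attr(kept, "caller") <- "consensus"
  list(kept = kept, decisions = rbind(dec_a, dec_b))
}

#' Validate variant read support across samples
#'
#' Two rules close the cascade. First, every call made in a clone must be
#' backed by at least `min_origin_support_reads` reads supporting the same
#' alternate allele in the clone's origin population; a clone call without
#' that support is rejected (flagged `clone_call_rejected`), and the SNP is
#' dropped entirely when no supported call remains. Second, a SNP whose
#' alternate allele has low-level read support (at least
#' `shared_support_min_reads` reads) in the populations of at least
#' `shared_support_min_lines` lines other than those in which it was called
#' is dropped as a shared artifact (`cross_line_support`) — a true new
#' mutation should be private to one line.
#'
#' @param cs the consensus [callset()].
#' @param counts a `read_counts` table covering all sites and samples.
#' @param meta sample metadata (`sample_id`, `line`, `role`).
#' @param cfg a [filter_config()].
#' @return `list(kept, decisions, flags)`; `flags` records per-sample
#'   rejections.
#' @export
validate_read_support <- function(cs, counts, meta, cfg = filter_config()) {
  v <- cs$variants
  n <- n_sites(cs)
  reasons <- replicate(n, character(0), simplify = FALSE)
  flags <- data.frame(chrom = character(), pos = integer(),
                      sample = character(), flag = character())
  gt <- cs$gt

  # precompute alt-read support per site for every sample in the metadata
  count_keys <- paste(counts$chrom, counts$pos, counts$sample)
  altm <- matrix(NA_integer_, n, nrow(meta),
                 dimnames = list(NULL, meta$sample_id))
  for (s in meta$sample_id) {
    idx <- match(paste(v$chrom, v$pos, s), count_keys)
    ok <- !is.na(idx)
    altm[ok, s] <- alt_count(counts, v$chrom[ok], v$pos[ok],
                             rep(s, sum(ok)))
  }

  clone_ids <- meta$sample_id[meta$role == "clone"]
  for (i in seq_len(n)) {
    called <- colnames(gt)[gt[i, ] == "1"]
    for (cl in intersect(called, clone_ids)) {
      origin <- as.character(meta$line[meta$sample_id == cl])
      if (!origin %in% colnames(altm) || is.na(altm[i, origin])) {
        stop("origin population '", origin, "' for clone '", cl,
             "' absent from read counts at ", site_key(v$chrom[i], v$pos[i]))
      }
      if (altm[i, origin] < cfg$min_origin_support_reads) {
        gt[i, cl] <- "."
        flags <- rbind(flags, data.frame(
          chrom = v$chrom[i], pos = v$pos[i], sample = cl,
          flag = "clone_call_rejected"))
      }
    }
    called_after <- colnames(gt)[gt[i, ] == "1"]
    if (length(called_after) == 0 && length(called) > 0) {
      reasons[[i]] <- c(reasons[[i]], "origin_support")
    }
    called_lines <- unique(stats::na.omit(line_of_sample(called_after)))
    other_pops <- meta$sample_id[meta$role == "population" &
                                   !(meta$line %in% called_lines)]
    if (length(other_pops) > 0) {
      sup <- altm[i, other_pops]
      n_shared <- sum(!is.na(sup) & sup >= cfg$shared_support_min_reads)
      if (n_shared >= cfg$shared_support_min_lines) {
        reasons[[i]] <- c(reasons[[i]], "cross_line_support")
      }
    }
  }
  rs <- join_reasons(reasons)
  kept <- callset(cs$variants, gt, dpm = cs$dpm, af = cs$af,
                  caller = attr(cs, "caller"))
  list(kept = subset_callset(kept, rs == ""),
       decisions = decision_frame(cs, rs, "read_support"),
       flags = flags)
}

#' Annotate per-sample allele frequencies from read counts
#'
#' AF is the alternate-allele read fraction from the read-count table; it is
#' undefined (NA) where the sample has zero depth. Genotypes are unchanged.
#'
#' @param cs a [callset()].
#' @param counts a `read_counts` table covering all sites.
#' @return The callset with its `af` matrix (re)computed.
#' @export
annotate_af <- function(cs, counts) {
  v <- cs$variants
  samples <- colnames(cs$gt)
  af <- matrix(NA_real_, n_sites(cs), length(samples),
               dimnames = list(NULL, samples))
  count_keys <- paste(counts$chrom, counts$pos, counts$sample)
  for (j in seq_along(samples)) {
    idx <- match(paste(v$chrom, v$pos, samples[j]), count_keys)
    depth <- counts$depth[idx]
    ac <- alt_count(counts, v$chrom, v$pos, rep(samples[j], n_sites(cs)))
    af[, j] <- ifelse(!is.na(depth) & depth > 0, ac / depth, NA_real_)
  }
  callset(v, cs$gt, dpm = cs$dpm, af = af, caller = attr(cs, "caller"))
}

#' Run the full SNV filtration cascade
#'
#' Ancestral masking, per-caller hard filters and custom filters are applied
#' independently to the two call sets; the surviving sets are intersected;
#' the consensus set is then validated against origin-population read
#' support and cross-line low-level support, and annotated with per-sample
#' allele frequencies.
#'
#' @param cs_a,cs_b raw caller A and caller B [callset()]s.
#' @param counts a `read_counts` table (must include the ancestor).
#' @param meta sample metadata.
#' @param cfg a [filter_config()].
#' @param ancestor_id ancestor sample id.
#' @return A list with `final` (annotated consensus callset), `decisions`
#'   (all stages, with a `callset` column), `flags`, and `stage_counts`
#'   (sites surviving each stage per branch).
#' @export
filter_snv_cascade <- function(cs_a, cs_b, counts, meta,
                               cfg = filter_config(),
                               ancestor_id = "ancestor") {
  run_branch <- function(cs, hard, label) {
    decs <- list()
    m <- mask_ancestral(cs, counts, cfg, ancestor_id)
    decs$mask <- m$decisions
    h <- hard(m$kept, cfg$missing_metric_fails)
    decs$hard <- h$decisions
    cu <- custom_filter(h$kept, cfg)
    decs$custom <- cu$decisions
    d <- do.call(rbind, decs)
    d$callset <- rep_len(label, nrow(d))
    list(kept = cu$kept, decisions = d,
         counts = c(input = n_sites(cs), mask = n_sites(m$kept),
                    hard = n_sites(h$kept), custom = n_sites(cu$kept)))
  }
  a <- run_branch(cs_a, hard_filter_a, "A")
  b <- run_branch(cs_b, hard_filter_b, "B")
  ix <- intersect_callsets(a$kept, b$kept)
  ix$decisions$callset <- rep_len("consensus", nrow(ix$decisions))
  rv <- validate_read_support(ix$kept, counts, meta, cfg)
  rv$decisions$callset <- rep_len("consensus", nrow(rv$decisions))
  final <- annotate_af(rv$kept, counts)

  decisions <- rbind(a$decisions, b$decisions, ix$decisions, rv$decisions)
  stage_counts <- data.frame(
    stage = c(names(a$counts), "intersect", "read_support"),
    A = c(unname(a$counts), NA, NA),
    B = c(unname(b$counts), NA, NA),
    consensus = c(rep(NA, 4), n_sites(ix$kept), n_sites(final)))
  list(final = final, decisions = decisions, flags = rv$flags,
       stage_counts = stage_counts)
}
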