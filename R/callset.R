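#' Construct a call set
#'
#' A call set bundles the site-level records of one variant caller with the
#' per-sample haploid genotype matrix. Caller "A" carries GATK-style site
#' metrics (QD, FS, SOR, MQ, MQRankSum, ReadPosRankSum); caller "B" carries
#' Freebayes-style metrics (MQM, SAF, SAR, SAP, SRP, RPR, RPL). Metric
#' columns that a caller does not emit are simply absent.
#'
#' @param variants data frame with at least `chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `dp`, `is_indel`, `multiallelic`, plus caller metric columns.
#' @param gt character matrix (sites x samples) with entries `"0"` (ref),
#'   `"1"` (alt) or `"."` (uncalled); column names are sample ids.
#' @param dpm,af optional numeric matrices (sites x samples) of per-sample
#'   depth and alternate-allele read fraction.
#' @param caller `"A"` or `"B"` (or `"consensus"` after intersection).
#' @return An object of class `callset`.
#' @export
callset <- function(variants, gt, dpm = NULL, af = NULL, caller = "A") {
  stopifnot(is.data.frame(variants), is.matrix(gt),
            nrow(variants) == nrow(gt))
  stopifnot(all(c("chrom", "pos", "ref", "alt", "qual", "dp",
                  "is_indel", "multiallelic") %in% names(variants)))
  stopifnot(all(gt %in% c("0", "1", ".")))
  stopifnot(all(variants$pos >= 1), all(variants$qual >= 0))
  rownames(variants) <- NULL
  structure(list(variants = variants, gt = gt, dpm = dpm, af = af),
            caller = caller, class = "callset")
}

#' @export
print.callset <- function(x, ...) {
  cat("callset (caller ", attr(x, "caller"), "): ", nrow(x$variants),
      " site(s) x ", ncol(x$gt), " sample(s)\n", sep = "")
  invisible(x)
}

#' Number of sites in a call set
#' @param cs a `callset`.
#' @return Integer site count.
#' @export
n_sites <- function(cs) nrow(cs$variants)

# Subset a callset to a logical/integer site index, keeping matrices aligned.
subset_callset <- function(cs, idx) {
  callset(cs$variants[idx, , drop = FALSE],
          cs$gt[idx, , drop = FALSE],
          dpm = if (!is.null(cs$dpm)) cs$dpm[idx, , drop = FALSE],
          af = if (!is.null(cs$af)) cs$af[idx, , drop = FALSE],
          caller = attr(cs, "caller"))
}

callset_keys <- function(cs) site_key(cs$variants$chrom, cs$variants$pos)

#' Emulate the output of two SNV callers and one SV caller
#'
#' Converts a read-count table into the call sets the filtration cascade
#' consumes. A sample is called alternate at a site when it has at least
#' `callable_min_reads` alternate reads making up at least
#' `callable_min_frac` of its depth; samples with zero depth are uncalled.
#' True calls receive passing metric values drawn from comfortable ranges and
#' a site QUAL that scales with the total alternate read support. On top of
#' the truth-derived sites, `fp_sites` false positives are injected, cycling
#' through `fp_classes`; each carries exactly one designed defect
#' (a failing caller metric, low QUAL, excess depth, excess missingness,
#' alternate allele count above the per-line maximum, presence in a single
#' caller, insufficient origin-population read support, or low-level shared
#' support across lines) so that removal can be attributed to a single
#' downstream rule. The SV call set contains planted true structural
#' variants plus one failure of each SV filtering rule.
#'
#' @param counts a [simulate_readcounts()] table covering all truth sites.
#' @param truth the matching truth set.
#' @param cfg the same [sim_config()].
#' @param genome optional toy genome; when supplied, true SVs are placed
#'   inside gene bodies so that SV/gene overlap can be exercised.
#' @return A list with elements `a` and `b` (caller A/B [callset()]s), `sv`
#'   (SV data frame as consumed by [filter_svs()]), `counts` (the input
#'   table augmented with rows for injected sites), `injected` (data frame
#'   mapping injected SNV sites to their failure class) and `injected_sv`
#'   (idem for SVs).
#' @export
emulate_callers <- function(counts, truth, cfg, genome = NULL) {
  validate_sim_config(cfg)
  set.seed(derive_seed(cfg$seed, "callers"))
  meta <- truth$sample_meta
  samples <- meta$sample_id

  inj <- inject_false_positives(counts, truth, cfg)
  counts <- inj$counts
  injected <- inj$injected

  sites <- unique(counts[, c("chrom", "pos", "ref", "alt")])
  rownames(sites) <- NULL
  n <- nrow(sites)

  depth_m <- matrix(0L, n, length(samples), dimnames = list(NULL, samples))
  altc_m <- depth_m
  key_counts <- paste(counts$chrom, counts$pos, counts$sample)
  for (j in seq_along(samples)) {
    idx <- match(paste(sites$chrom, sites$pos, samples[j]), key_counts)
    depth_m[, j] <- counts$depth[idx]
    altc_m[, j] <- alt_count(counts, sites$chrom, sites$pos,
                             rep(samples[j], n))
  }
  frac <- ifelse(depth_m > 0, altc_m / depth_m, 0)
  gt <- matrix("0", n, length(samples), dimnames = list(NULL, samples))
  gt[altc_m >= cfg$callable_min_reads & frac >= cfg$callable_min_frac] <- "1"
  gt[depth_m == 0] <- "."

  alt_total <- rowSums(altc_m * (gt == "1"))
  base <- data.frame(sites,
                     qual = 30 + 10 * alt_total,
                     dp = rowSums(depth_m),
                     is_indel = FALSE, multiallelic = FALSE)

  metrics_a <- data.frame(
    QD = stats::runif(n, 10, 35), FS = stats::runif(n, 0, 10),
    SOR = stats::runif(n, 0.3, 2), MQ = stats::runif(n, 55, 60),
    MQRankSum = stats::runif(n, -2, 2),
    ReadPosRankSum = stats::runif(n, -2, 2))
  saf <- stats::rbinom(n, pmax(alt_total, 0), 0.5)
  metrics_b <- data.frame(
    MQM = stats::runif(n, 50, 60), SAF = saf, SAR = pmax(alt_total, 0) - saf,
    SAP = stats::runif(n, 1, 10), SRP = stats::runif(n, 1, 10),
    RPR = sample(2:10, n, replace = TRUE),
    RPL = sample(2:10, n, replace = TRUE))

  # apply the designed per-class defects
  keys <- site_key(sites$chrom, sites$pos)
  in_a <- rep(TRUE, n)
  in_b <- rep(TRUE, n)
  qual_a <- base$qual
  qual_b <- base$qual
  if (nrow(injected) > 0) {
    for (r in seq_len(nrow(injected))) {
      i <- match(site_key(injected$chrom[r], injected$pos[r]), keys)
      switch(injected$class[r],
        low_qd = { metrics_a$QD[i] <- 1.0 },
        low_mqm = { metrics_b$MQM[i] <- 30 },
        strand_bias = {
          metrics_a$FS[i] <- 80; metrics_a$SOR[i] <- 4
          metrics_b$SAF[i] <- max(1, alt_total[i]); metrics_b$SAR[i] <- 0
        },
        low_qual = { qual_a[i] <- 100; qual_b[i] <- 100 },
        caller_a_only = { in_b[i] <- FALSE },
        caller_b_only = { in_a[i] <- FALSE },
        # excess_dp, missingness, high_ac, low_origin_support and
        # cross_line_support are expressed through the counts themselves
        NULL)
    }
  }

  va <- cbind(base, metrics_a); va$qual <- qual_a
  vb <- cbind(base, metrics_b); vb$qual <- qual_b
  cs_a <- callset(va[in_a, , drop = FALSE], gt[in_a, , drop = FALSE],
                  dpm = depth_m[in_a, , drop = FALSE],
                  af = frac[in_a, , drop = FALSE], caller = "A")
  cs_b <- callset(vb[in_b, , drop = FALSE], gt[in_b, , drop = FALSE],
                  dpm = depth_m[in_b, , drop = FALSE],
                  af = frac[in_b, , drop = FALSE], caller = "B")

  sv <- emulate_svs(truth, cfg, genome)

  list(a = cs_a, b = cs_b, sv = sv$svs, counts = counts,
       injected = injected, injected_sv = sv$injected)
}

# Build counts rows for injected false-positive sites and return the
# augmented table plus the site/class map.
inject_false_positives <- function(counts, truth, cfg) {
  injected <- data.frame(chrom = character(), pos = integer(),
                         class = character())
  if (cfg$fp_sites == 0) {
    return(list(counts = counts, injected = injected))
  }
  meta <- truth$sample_meta
  chroms <- unique(counts$chrom)
  used <- unique(site_key(counts$chrom, counts$pos))
  lines <- meta$line[meta$role == "population"]
  classes <- rep(cfg$fp_classes, length.out = cfg$fp_sites)
  pos_base <- max(counts$pos) + 101L

  new_rows <- list()
  for (k in seq_along(classes)) {
    cls <- classes[k]
    chrom <- chroms[1 + (k - 1) %% length(chroms)]
    pos <- pos_base + 37L * k
    while (site_key(chrom, pos) %in% used) pos <- pos + 1L
    used <- c(used, site_key(chrom, pos))
    ref <- "A"; alt <- "G"
    line <- lines[1 + (k - 1) %% length(lines)]
    clone_id <- meta$sample_id[meta$role == "clone" & meta$line == line][1]

    # per-sample (depth, alt fraction) defaults: covered, reference
    plan <- data.frame(sample = meta$sample_id, role = meta$role,
                       depth = NA_real_, f = 0, fixed_alt = NA_integer_)
    plan$depth <- ifelse(plan$role == "clone", cfg$depth_clone,
                         cfg$depth_population)
    called_pop <- as.character(line)
    if (cls %in% c("low_qd", "low_mqm", "strand_bias", "low_qual",
                   "excess_dp", "caller_a_only", "caller_b_only")) {
      plan$f[plan$sample == called_pop] <- 0.5
      if (!is.na(clone_id)) plan$f[plan$sample == clone_id] <- 1
      if (cls == "excess_dp") plan$depth <- plan$depth * 3
    } else if (cls == "missingness") {
      plan$f[plan$sample == called_pop] <- 0.5
      keep <- plan$sample %in% c("ancestor", called_pop)
      plan$depth[!keep] <- 0
    } else if (cls == "high_ac") {
      over <- lines[seq_len(min(length(lines), 4L))]
      plan$f[plan$role == "population" & line_of_sample(plan$sample) %in% over] <- 0.6
    } else if (cls == "low_origin_support") {
      if (!is.na(clone_id)) plan$f[plan$sample == clone_id] <- 1
      plan$fixed_alt[plan$sample == called_pop] <- 4L
    } else if (cls == "cross_line_support") {
      if (!is.na(clone_id)) plan$f[plan$sample == clone_id] <- 1
      plan$f[plan$sample == called_pop] <- 0.3
      others <- setdiff(lines, line)
      share <- as.character(others[seq_len(min(2L, length(others)))])
      plan$fixed_alt[plan$sample %in% share] <- 3L
    }

    for (j in seq_len(nrow(plan))) {
      depth <- if (plan$depth[j] == 0) 0L else stats::rpois(1, plan$depth[j])
      cnt <- sim_base_counts(depth, ref, alt, plan$f[j], cfg$error_rate)
      if (!is.na(plan$fixed_alt[j]) && depth > 0) {
        cnt[] <- 0L
        cnt[alt] <- plan$fixed_alt[j]
        cnt[ref] <- depth - plan$fixed_alt[j]
      }
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        chrom = chrom, pos = pos, sample = plan$sample[j], ref = ref,
        alt = alt, n_a = cnt["A"], n_c = cnt["C"], n_g = cnt["G"],
        n_t = cnt["T"], depth = sum(cnt))
    }
    injected <- rbind(injected,
                      data.frame(chrom = chrom, pos = pos, class = cls))
  }
  aug <- rbind(as.data.frame(counts), do.call(rbind, new_rows))
  rownames(aug) <- NULL
  site_info <- attr(counts, "site_info")
  attr(aug, "site_info") <- site_info
  class(aug) <- c("read_counts", "data.frame")
  list(counts = aug, injected = injected)
}

# Planted true SVs plus one failure per SV rule class.
emulate_svs <- function(truth, cfg, genome = NULL) {
  meta <- truth$sample_meta
  lines <- meta$line[meta$role == "population"]
  pick_samples <- function(line) {
    ids <- meta$sample_id[!is.na(meta$line) & meta$line == line]
    list(ids)
  }
  gene_span <- function(k) {
    if (!is.null(genome) && nrow(genome$genes) > 0) {
      gids <- unique(genome$genes$gene_id)
      g <- genome$genes[genome$genes$gene_id ==
                          gids[1 + (k - 1) %% length(gids)], ]
      c(chrom = g$chrom[1], start = min(g$start) + 10L,
        end = min(g$start) + 300L)
    } else {
      c(chrom = "chr1", start = 1000L + 500L * k, end = 1300L + 500L * k)
    }
  }
  mk <- function(k, type, pe, qual, filter, line, n_samples = NULL) {
    sp <- gene_span(k)
    smp <- if (is.null(n_samples)) pick_samples(line) else
      list(meta$sample_id[meta$role == "population"][seq_len(n_samples)])
    data.frame(chrom = sp["chrom"], start = as.integer(sp["start"]),
               end = as.integer(sp["end"]), sv_type = type, pe = pe,
               qual = qual, filter = filter,
               samples = I(smp))
  }
  rows <- list(
    mk(1, "DEL", 12, 60, "PASS", lines[1]),
    mk(2, "DUP", 10, 55, "PASS", lines[min(2, length(lines))]),
    mk(3, "INV", 11, 70, "PASS", lines[min(3, length(lines))]),
    mk(4, "DEL", 12, 60, "LowQual", lines[1]),
    mk(5, "DEL", 12, 10, "PASS", lines[1]),
    mk(6, "DEL", 3, 60, "PASS", lines[1]),
    mk(7, "TRA", 10, 60, "PASS", lines[1]),
    mk(8, "DEL", 12, 60, "PASS", lines[1],
       n_samples = min(4L, sum(meta$role == "population")))
  )
  svs <- do.call(rbind, rows)
  rownames(svs) <- NULL
  injected <- data.frame(
    idx = seq_len(nrow(svs)),
    class = c("true_sv", "true_sv", "true_sv", "not_pass", "low_qual",
              "low_pe", "tra", "multi_sample"))
  list(svs = svs, injected = injected)
}
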