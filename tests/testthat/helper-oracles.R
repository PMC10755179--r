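# Keys of a callset's sites, safe for zero-row sets.
cs_keys <- function(cs) {
  paste0(cs$variants$chrom, ":", cs$variants$pos)[seq_len(nrow(cs$variants))]
}

# Independent oracles. These deliberately re-derive each quantity with the
# most literal method available (direct enumeration, per-site rule checks,
# closed forms) and share no code with the implementation they check.

# --- Fisher's exact test: direct enumeration over the hypergeometric support
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- Clopper-Pearson endpoints via the beta-quantile closed form
cp_beta_oracle <- function(k, n, conf = 0.95) {
  alpha <- 1 - conf
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

# --- Brute-force SNV cascade: per-site rule-by-rule reimplementation.
# Returns the set of surviving "chrom:pos" keys.
brute_force_cascade <- function(cs_a, cs_b, counts, meta,
                                cfg = filter_config()) {
  counts_key <- paste(counts$chrom, counts$pos, counts$sample)
  altc <- function(chrom, pos, sample) {
    row <- counts[match(paste(chrom, pos, sample), counts_key), ]
    if (nrow(row) == 0 || is.na(row$chrom)) return(NA_integer_)
    as.integer(row[[c(A = "n_a", C = "n_c", G = "n_g", T = "n_t")[row$alt]]])
  }
  anc_maf <- function(chrom, pos) {
    # distinguish "no ancestor counts row" (absent) from "zero depth" (NA maf)
    row <- counts[match(paste(chrom, pos, "ancestor"), counts_key), ]
    if (nrow(row) == 0 || is.na(row$chrom)) return(list(present = FALSE))
    if (row$depth == 0) return(list(present = TRUE, maf = NA_real_))
    list(present = TRUE,
         maf = max(row$n_a, row$n_c, row$n_g, row$n_t) / row$depth)
  }

  survives_branch <- function(cs, caller) {
    v <- cs$variants
    keep <- logical(nrow(v))
    for (i in seq_len(nrow(v))) {
      anc_gt <- cs$gt[i, "ancestor"]
      if (anc_gt == "1" || anc_gt == ".") next
      am <- anc_maf(v$chrom[i], v$pos[i])
      if (!am$present) next           # absent from ancestor counts
      if (!is.na(am$maf) && am$maf < cfg$ancestor_maf_min) next
      if (caller == "A") {
        bad <- (!is.na(v$QD[i]) && !(v$QD[i] > 2)) ||
          (!is.na(v$FS[i]) && !(v$FS[i] < 60)) ||
          (!is.na(v$SOR[i]) && !(v$SOR[i] < 3)) ||
          (!is.na(v$MQ[i]) && !(v$MQ[i] > 40)) ||
          (!is.na(v$MQRankSum[i]) && !(v$MQRankSum[i] > -12.5)) ||
          (!is.na(v$ReadPosRankSum[i]) && !(v$ReadPosRankSum[i] > -8))
      } else {
        bad <- (!is.na(v$MQM[i]) && !(v$MQM[i] > 40)) ||
          (!is.na(v$SAF[i]) && !(v$SAF[i] > 0)) ||
          (!is.na(v$SAR[i]) && !(v$SAR[i] > 0)) ||
          (!is.na(v$SAP[i]) && !(v$SAP[i] > 0.5)) ||
          (!is.na(v$SRP[i]) && !(v$SRP[i] > 0.5)) ||
          (!is.na(v$RPR[i]) && !(v$RPR[i] > 1)) ||
          (!is.na(v$RPL[i]) && !(v$RPL[i] > 1))
      }
      if (bad) next
      if (v$is_indel[i] || v$multiallelic[i]) next
      if (sum(cs$gt[i, ] == ".") > cfg$max_missing_samples) next
      if (sum(cs$gt[i, ] == "1") > cfg$max_alt_ac) next
      if (v$qual[i] < cfg$min_qual) next
      keep[i] <- TRUE
    }
    # DP rule: mean over the sites surviving everything above
    if (any(keep)) {
      dp_mean <- mean(v$dp[keep])
      keep <- keep & !(v$dp > cfg$dp_mean_factor * dp_mean)
    }
    keep
  }

  ka <- paste0(cs_a$variants$chrom, ":", cs_a$variants$pos)
  kb <- paste0(cs_b$variants$chrom, ":", cs_b$variants$pos)
  keep_a <- survives_branch(cs_a, "A")
  keep_b <- survives_branch(cs_b, "B")
  consensus <- character(0)
  for (i in which(keep_a)) {
    j <- which(kb == ka[i] & keep_b)
    if (length(j) != 1) next
    if (cs_b$variants$alt[j] != cs_a$variants$alt[i]) next
    # read-support validation
    v <- cs_a$variants
    gt_row <- cs_a$gt[i, ]
    called <- names(gt_row)[gt_row == "1"]
    for (cl in called) {
      role <- meta$role[meta$sample_id == cl]
      if (length(role) == 1 && role == "clone") {
        origin <- as.character(meta$line[meta$sample_id == cl])
        sup <- altc(v$chrom[i], v$pos[i], origin)
        if (!is.na(sup) && sup < cfg$min_origin_support_reads) {
          gt_row[cl] <- "."
        }
      }
    }
    called_after <- names(gt_row)[gt_row == "1"]
    if (length(called) > 0 && length(called_after) == 0) next
    called_lines <- unique(stats::na.omit(line_of_sample(called_after)))
    pops <- meta$sample_id[meta$role == "population" &
                             !(meta$line %in% called_lines)]
    n_shared <- 0
    for (p in pops) {
      sup <- altc(v$chrom[i], v$pos[i], p)
      if (!is.na(sup) && sup >= cfg$shared_support_min_reads) {
        n_shared <- n_shared + 1
      }
    }
    if (n_shared >= cfg$shared_support_min_lines) next
    consensus <- c(consensus, ka[i])
  }
  sort(consensus)
}

# --- Brute-force SV filter: returns indices of surviving records.
brute_force_sv <- function(svs, min_qual = 20, min_pe = 3, min_pe_tra = 5,
                           max_samples = 3) {
  keep <- integer(0)
  for (i in seq_len(nrow(svs))) {
    if (svs$filter[i] != "PASS") next
    if (svs$qual[i] < min_qual) next
    thr <- if (svs$sv_type[i] == "TRA") min_pe_tra else min_pe
    if (svs$pe[i] <= thr) next
    if (!svs$sv_type[i] %in% c("DEL", "DUP", "INV", "INS")) next
    if (length(svs$samples[[i]]) > max_samples) next
    keep <- c(keep, i)
  }
  keep
}
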