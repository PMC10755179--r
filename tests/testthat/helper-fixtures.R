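# Programmatic fixtures shared across test files.

# A minimal callset with controllable fields; one chromosome, one sample set.
mini_callset <- function(n, samples = c("ancestor", "1", "2", "1-NF1"),
                         qual = 300, dp = 100, caller = "A") {
  v <- data.frame(chrom = rep_len("chr1", n), pos = seq_len(n) * 10L,
                  ref = rep_len("A", n), alt = rep_len("G", n),
                  qual = rep_len(qual, n), dp = rep_len(dp, n),
                  is_indel = rep_len(FALSE, n),
                  multiallelic = rep_len(FALSE, n))
  if (caller == "A") {
    v <- cbind(v, data.frame(QD = rep_len(25, n), FS = rep_len(1, n),
                             SOR = rep_len(1, n), MQ = rep_len(60, n),
                             MQRankSum = rep_len(0, n),
                             ReadPosRankSum = rep_len(0, n)))
  } else {
    v <- cbind(v, data.frame(MQM = rep_len(60, n), SAF = rep_len(5, n),
                             SAR = rep_len(5, n), SAP = rep_len(3, n),
                             SRP = rep_len(3, n), RPR = rep_len(4, n),
                             RPL = rep_len(4, n)))
  }
  gt <- matrix("0", n, length(samples), dimnames = list(NULL, samples))
  callset(v, gt, caller = caller)
}

mini_meta <- function(n_lines = 2, n_clones = 1) {
  clones <- as.vector(outer(seq_len(n_lines), seq_len(n_clones),
                            function(l, k) paste0(l, "-NF", k)))
  rbind(
    data.frame(sample_id = "ancestor", line = NA_integer_,
               role = "ancestor", phenotype = "unknown"),
    data.frame(sample_id = as.character(seq_len(n_lines)),
               line = seq_len(n_lines), role = "population",
               phenotype = "unknown"),
    data.frame(sample_id = clones, line = line_of_sample(clones),
               role = "clone", phenotype = "fruiting"))
}

# Uniform read-count rows for a set of sites x samples, all-reference
# except where overridden afterwards.
mini_counts <- function(cs, samples, depth = 100, alt_frac = 0) {
  v <- cs$variants
  grid <- expand.grid(i = seq_len(nrow(v)), s = samples,
                      stringsAsFactors = FALSE)
  n_alt <- round(depth * alt_frac)
  out <- data.frame(chrom = v$chrom[grid$i], pos = v$pos[grid$i],
                    sample = grid$s, ref = v$ref[grid$i],
                    alt = v$alt[grid$i], n_a = 0L, n_c = 0L, n_g = 0L,
                    n_t = 0L, depth = depth)
  base_col <- c(A = "n_a", C = "n_c", G = "n_g", T = "n_t")
  for (r in seq_len(nrow(out))) {
    out[r, base_col[out$ref[r]]] <- depth - n_alt
    out[r, base_col[out$alt[r]]] <- n_alt
  }
  class(out) <- c("read_counts", "data.frame")
  out
}

set_count <- function(counts, chrom, pos, sample, ref_n, alt_n) {
  i <- which(counts$chrom == chrom & counts$pos == pos &
               counts$sample == sample)
  stopifnot(length(i) == 1)
  base_col <- c(A = "n_a", C = "n_c", G = "n_g", T = "n_t")
  counts[i, c("n_a", "n_c", "n_g", "n_t")] <- 0L
  counts[i, base_col[counts$ref[i]]] <- ref_n
  counts[i, base_col[counts$alt[i]]] <- alt_n
  counts$depth[i] <- ref_n + alt_n
  counts
}

# Random paired call sets + counts + metadata for cascade property tests.
# Metrics, QUAL, DP, genotypes and ancestor composition are drawn so that
# every rule of the cascade fires on some sites.
random_callset_pair <- function(seed, n = 100, n_lines = 6) {
  set.seed(seed)
  meta <- mini_meta(n_lines = n_lines, n_clones = 1)
  samples <- meta$sample_id
  pos <- sort(sample.int(n * 50, n))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))

  depth <- matrix(sample(c(0L, 40:250), n * length(samples), replace = TRUE,
                         prob = c(0.03, rep(0.97 / 211, 211))),
                  n, length(samples), dimnames = list(NULL, samples))
  # alternate fraction: mostly 0, some low-level, some real calls
  f <- matrix(sample(c(0, 0.02, 0.3, 0.6, 1), n * length(samples),
                     replace = TRUE, prob = c(0.55, 0.15, 0.1, 0.1, 0.1)),
              n, length(samples), dimnames = list(NULL, samples))
  # ancestor occasionally polymorphic (maf straddles 0.90)
  f[, "ancestor"] <- sample(c(0, 0.05, 0.08, 0.12, 0.3, 1), n,
                            replace = TRUE,
                            prob = c(0.6, 0.1, 0.1, 0.1, 0.05, 0.05))
  altc <- matrix(stats::rbinom(n * length(samples), as.vector(depth),
                               as.vector(f)),
                 n, length(samples), dimnames = list(NULL, samples))

  base_col <- c(A = "n_a", C = "n_c", G = "n_g", T = "n_t")
  rows <- expand.grid(i = seq_len(n), s = samples, stringsAsFactors = FALSE)
  counts <- data.frame(chrom = "chr1", pos = pos[rows$i], sample = rows$s,
                       ref = ref[rows$i], alt = alt[rows$i],
                       n_a = 0L, n_c = 0L, n_g = 0L, n_t = 0L,
                       depth = depth[cbind(rows$i, match(rows$s, samples))])
  ac_vec <- altc[cbind(rows$i, match(rows$s, samples))]
  for (b in bases) {
    counts[[base_col[b]]] <- ifelse(counts$ref == b, counts$depth - ac_vec,
                                    ifelse(counts$alt == b, ac_vec, 0L))
  }
  class(counts) <- c("read_counts", "data.frame")

  gt <- matrix("0", n, length(samples), dimnames = list(NULL, samples))
  frac <- ifelse(depth > 0, altc / depth, 0)
  gt[altc >= 3 & frac >= 0.05] <- "1"
  gt[depth == 0] <- "."
  # sprinkle extra missingness and unsupported clone calls
  gt[stats::runif(length(gt)) < 0.04] <- "."
  clone_cols <- meta$sample_id[meta$role == "clone"]
  flip <- matrix(stats::runif(n * length(clone_cols)) < 0.08, n,
                 length(clone_cols))
  gt[, clone_cols][flip] <- "1"

  metric <- function(pass, fail, p_fail = 0.12) {
    ifelse(stats::runif(n) < p_fail, fail(n), pass(n))
  }
  va <- data.frame(
    chrom = "chr1", pos = pos, ref = ref, alt = alt,
    qual = ifelse(stats::runif(n) < 0.12, stats::runif(n, 0, 199.9),
                  stats::runif(n, 210, 2000)),
    dp = rowSums(depth) * ifelse(stats::runif(n) < 0.08,
                                 stats::runif(n, 2, 4), 1),
    is_indel = stats::runif(n) < 0.05,
    multiallelic = stats::runif(n) < 0.05,
    QD = metric(function(k) stats::runif(k, 3, 35),
                function(k) stats::runif(k, 0, 2)),
    FS = metric(function(k) stats::runif(k, 0, 50),
                function(k) stats::runif(k, 60, 200)),
    SOR = metric(function(k) stats::runif(k, 0, 2.9),
                 function(k) stats::runif(k, 3, 9)),
    MQ = metric(function(k) stats::runif(k, 41, 60),
                function(k) stats::runif(k, 0, 40)),
    MQRankSum = metric(function(k) stats::runif(k, -12, 12),
                       function(k) stats::runif(k, -20, -12.5)),
    ReadPosRankSum = metric(function(k) stats::runif(k, -7.9, 8),
                            function(k) stats::runif(k, -20, -8)))
  va$QD[stats::runif(n) < 0.05] <- NA  # missing-metric policy exercised
  vb <- data.frame(
    chrom = "chr1", pos = pos, ref = ref, alt = alt,
    qual = va$qual, dp = va$dp, is_indel = va$is_indel,
    multiallelic = va$multiallelic,
    MQM = metric(function(k) stats::runif(k, 41, 60),
                 function(k) stats::runif(k, 0, 40)),
    SAF = metric(function(k) sample(1:30, k, replace = TRUE),
                 function(k) rep(0L, k)),
    SAR = metric(function(k) sample(1:30, k, replace = TRUE),
                 function(k) rep(0L, k)),
    SAP = stats::runif(n, 0.6, 20),
    SRP = stats::runif(n, 0.6, 20),
    RPR = metric(function(k) sample(2:20, k, replace = TRUE),
                 function(k) sample(0:1, k, replace = TRUE)),
    RPL = sample(2:20, n, replace = TRUE))

  keep_a <- stats::runif(n) > 0.08
  keep_b <- stats::runif(n) > 0.08
  # alt mismatches between callers
  mismatch <- which(stats::runif(n) < 0.05)
  vb$alt[mismatch] <- vapply(mismatch, function(i) {
    sample(setdiff(bases, c(ref[i], alt[i])), 1)
  }, character(1))

  list(a = callset(va[keep_a, , drop = FALSE], gt[keep_a, , drop = FALSE],
                   caller = "A"),
       b = callset(vb[keep_b, , drop = FALSE], gt[keep_b, , drop = FALSE],
                   caller = "B"),
       counts = counts, meta = meta)
}

# Random SV set exercising every SV rule.
random_svs <- function(seed, n = 200, n_samples = 8) {
  set.seed(seed)
  ids <- c(as.character(1:4), paste0(1:4, "-NF1"))[seq_len(n_samples)]
  svs <- data.frame(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = sample.int(1e5, n),
    sv_type = sample(c("DEL", "DUP", "INV", "INS", "TRA"), n,
                     replace = TRUE, prob = c(0.3, 0.2, 0.2, 0.1, 0.2)),
    pe = sample(0:15, n, replace = TRUE),
    qual = stats::runif(n, 0, 100),
    filter = sample(c("PASS", "LowQual"), n, replace = TRUE,
                    prob = c(0.8, 0.2)))
  svs$end <- svs$start + sample.int(5e3, n)
  svs$samples <- I(lapply(seq_len(n), function(i) {
    sample(ids, sample.int(min(6, n_samples), 1))
  }))
  svs
}
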