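test_that("reference genomes are deterministic, AT-calibrated and validly packed", {
  g1 <- make_reference(1, 10000, 2, at_fraction = 0.77, seed = 1)
  g2 <- make_reference(1, 10000, 2, at_fraction = 0.77, seed = 1)
  expect_identical(as.character(g1$seq), as.character(g2$seq))
  expect_identical(g1$genes, g2$genes)

  at <- 1 - Biostrings::letterFrequency(g1$seq[[1]], "GC", as.prob = TRUE)[1]
  expect_lt(abs(at - 0.77), 0.02)

  g0 <- make_reference(1, 10000, 0, at_fraction = 0.5, seed = 1)
  expect_equal(nrow(g0$genes), 0)

  expect_error(make_reference(1, 1000, 50, seed = 1), "cannot place")

  # gene-model invariants
  g <- make_reference(2, 30000, 8, seed = 5)
  for (gid in unique(g$genes$gene_id)) {
    ex <- g$genes[g$genes$gene_id == gid, ]
    expect_true(all(ex$start >= 1))
    expect_true(all(ex$end <= length(g$seq[[ex$chrom[1]]])))
    cds_len <- sum(ex$end - ex$start + 1)
    expect_equal(cds_len %% 3, 0)
    expect_gt(ex$region_boundary[1], 0)
    expect_lt(ex$region_boundary[1], cds_len)
  }
  # genes do not overlap
  for (chr in unique(g$genes$chrom)) {
    ex <- g$genes[g$genes$chrom == chr, ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) > 1) expect_true(all(diff(ex$start) > 0) &&
                                    all(ex$start[-1] > ex$end[-nrow(ex)]))
  }
})

test_that("selection trajectories match the deterministic recursion; neutral alleles drift within binomial bounds", {
  g <- make_reference(1, 20000, 4, seed = 2)

  # neutral: planted at 0.3 with one million founders stays put
  cfg <- sim_config(n_lines = 1, seed = 11)
  planted <- data.frame(line = 1, class = "neutral", arise_passage = 1,
                        init_freq = 0.3)
  tr <- simulate_evolution(g, cfg, planted = planted)
  se <- sqrt(31 * 0.3 * 0.7 / cfg$founder_count)
  expect_lt(abs(tr$mutations$final_freq[1] - 0.3), 5 * se)

  # selected: final frequency close to iterating f' = f(1+s)/(1+fs)
  det <- 1e-4
  for (p in 2:31) det <- det * 1.5 / (1 + det * 0.5)
  finals <- vapply(1:5, function(s) {
    cfgi <- sim_config(n_lines = 1, selection_coeff = 0.5, seed = 100 + s)
    tri <- simulate_evolution(g, cfgi, planted = data.frame(
      line = 1, class = "5prime", arise_passage = 1, init_freq = 1e-4,
      s = 0.5))
    tri$mutations$final_freq[1]
  }, numeric(1))
  expect_lt(abs(mean(finals) - det), 0.1)
  expect_true(all(abs(finals - det) < 0.35))

  # full penetrance: every 5prime carrier clone is non-fruiting
  cfg2 <- sim_config(n_lines = 3, penetrance_nonfruiting = 1, seed = 12)
  tr2 <- simulate_evolution(g, cfg2, planted = data.frame(
    line = 1:3, class = "5prime", arise_passage = 1, init_freq = 0.999))
  meta <- tr2$sample_meta
  for (cid in meta$sample_id[meta$role == "clone"]) {
    idx <- which(tr2$mutations$line == line_of_sample(cid) &
                   tr2$mutations$class == "5prime")
    if (any(tr2$genotypes[idx, cid] == 1)) {
      expect_equal(meta$phenotype[meta$sample_id == cid], "nonfruiting")
    }
  }
})

test_that("read counts hit depth targets, conserve reads, and track allele frequency", {
  g <- make_reference(1, 20000, 3, seed = 3)
  cfg <- sim_config(n_lines = 4, seed = 21)
  # hold frequencies at 0.6 (neutral, huge founder pool)
  tr <- simulate_evolution(g, cfg, planted = data.frame(
    line = 1:4, class = "neutral", arise_passage = 1, init_freq = 0.6))
  cnt <- simulate_readcounts(tr, g, cfg)

  expect_true(all(cnt$n_a + cnt$n_c + cnt$n_g + cnt$n_t == cnt$depth))

  pops <- as.character(1:4)
  pop_rows <- cnt[cnt$sample %in% pops, ]
  expect_lt(abs(mean(pop_rows$depth) - 195) / 195, 0.05)
  clone_rows <- cnt[grepl("NF", cnt$sample), ]
  expect_lt(abs(mean(clone_rows$depth) - 54) / 54, 0.10)

  # observed alt fraction near the planted 0.6 in origin populations
  mut <- tr$mutations
  for (i in seq_len(nrow(mut))) {
    ac <- alt_count(cnt, mut$chrom[i], mut$pos[i], as.character(mut$line[i]))
    dp <- cnt$depth[cnt$chrom == mut$chrom[i] & cnt$pos == mut$pos[i] &
                      cnt$sample == as.character(mut$line[i])]
    f_true <- mut$final_freq[i]
    expect_lt(abs(ac / dp - f_true), 4 * sqrt(f_true * (1 - f_true) / dp) + 0.02)
  }

  # error-free clone carrying a mutation shows alt fraction exactly 1
  cfg0 <- sim_config(n_lines = 1, error_rate = 0, seed = 22)
  tr0 <- simulate_evolution(g, cfg0, planted = data.frame(
    line = 1, class = "5prime", arise_passage = 1, init_freq = 0.9999))
  cnt0 <- simulate_readcounts(tr0, g, cfg0)
  cid <- tr0$sample_meta$sample_id[tr0$sample_meta$role == "clone"][1]
  if (tr0$genotypes[1, cid] == 1) {
    m <- tr0$mutations
    ac <- alt_count(cnt0, m$chrom[1], m$pos[1], cid)
    dp <- cnt0$depth[cnt0$chrom == m$chrom[1] & cnt0$pos == m$pos[1] &
                       cnt0$sample == cid]
    expect_equal(ac, dp)
  }
})

test_that("caller emulation calls well-supported sites in both callers and injects single-caller artifacts correctly", {
  g <- make_reference(2, 40000, 6, seed = 4)
  cfg <- sim_config(n_lines = 6, seed = 31)
  tr <- simulate_evolution(g, cfg, planted = data.frame(
    line = 1:6, class = "3prime", arise_passage = 1, init_freq = 0.6))
  cnt <- simulate_readcounts(tr, g, cfg)
  em <- emulate_callers(cnt, tr, cfg, g)

  mut_keys <- paste0(tr$mutations$chrom, ":", tr$mutations$pos)
  ka <- paste0(em$a$variants$chrom, ":", em$a$variants$pos)
  kb <- paste0(em$b$variants$chrom, ":", em$b$variants$pos)
  expect_true(all(mut_keys %in% ka))
  expect_true(all(mut_keys %in% kb))

  a_only <- em$injected[em$injected$class == "caller_a_only", ]
  expect_false(paste0(a_only$chrom, ":", a_only$pos) %in% kb)
  b_only <- em$injected[em$injected$class == "caller_b_only", ]
  expect_false(paste0(b_only$chrom, ":", b_only$pos) %in% ka)

  # callable threshold: called samples have >= 3 alt reads and >= 5% fraction
  i <- match(mut_keys[1], ka)
  called <- colnames(em$a$gt)[em$a$gt[i, ] == "1"]
  for (s in called) {
    ac <- alt_count(em$counts, tr$mutations$chrom[1], tr$mutations$pos[1], s)
    dp <- em$counts$depth[em$counts$chrom == tr$mutations$chrom[1] &
                            em$counts$pos == tr$mutations$pos[1] &
                            em$counts$sample == s]
    expect_gte(ac, 3)
    expect_gte(ac / dp, 0.05)
  }
})

test_that("clone screens follow the penetrance model and binomial carriage", {
  g <- make_reference(1, 20000, 3, seed = 5)
  cfg <- sim_config(n_lines = 1, penetrance_nonfruiting = 1, seed = 41)
  tr <- simulate_evolution(g, cfg, planted = data.frame(
    line = 1, class = "5prime", arise_passage = 1, init_freq = 0.5))
  scr <- simulate_clone_screen(tr, 100, seed = 42)

  # carrier & fruiting cell empty at full penetrance (only 5prime planted)
  tab <- build_contingency(scr, "variant")[[1]]
  expect_equal(tab$c, 0)

  # carriage is binomial at the final frequency
  f <- tr$mutations$final_freq[1]
  expect_lt(abs(sum(scr$carries) - 100 * f), 4 * sqrt(100 * f * (1 - f)) + 1)

  expect_error(simulate_clone_screen(tr, 0, seed = 1), "n_clones_per_line")
})

test_that("identical configurations reproduce identical truth sets, counts and call sets", {
  g <- make_reference(1, 20000, 4, seed = 6)
  cfg <- sim_config(n_lines = 3, seed = 51)
  run <- function() {
    tr <- simulate_evolution(g, cfg)
    cnt <- simulate_readcounts(tr, g, cfg)
    em <- emulate_callers(cnt, tr, cfg, g)
    list(tr = tr, cnt = cnt, em = em)
  }
  r1 <- run()
  r2 <- run()
  expect_identical(r1$tr$mutations, r2$tr$mutations)
  expect_identical(r1$tr$genotypes, r2$tr$genotypes)
  expect_identical(as.data.frame(r1$cnt), as.data.frame(r2$cnt))
  expect_identical(r1$em$a$variants, r2$em$a$variants)
  expect_identical(r1$em$b$gt, r2$em$b$gt)
})
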