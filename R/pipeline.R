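#' Run the full analysis pipeline end-to-end
#'
#' Orchestrates simulate -> filter-snv -> filter-sv -> annotate -> summarize
#' -> associate on synthetic data, writing per-stage outputs and a run
#' manifest (seed, stage record counts, md5 of every emitted file) to
#' `out_dir`. Reruns with an identical configuration and seed produce an
#' identical manifest.
#'
#' @param cfg a [sim_config()] or the path to a YAML config file.
#' @param out_dir output directory (created if needed).
#' @param fcfg a [filter_config()].
#' @param n_chroms,chrom_len,n_genes toy-genome dimensions.
#' @param n_screen_clones clones per line in the association screen.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(cfg = sim_config(), out_dir,
                         fcfg = filter_config(),
                         n_chroms = 3L, chrom_len = 60000L, n_genes = 12L,
                         n_screen_clones = 20L) {
  if (is.character(cfg)) cfg <- read_sim_config(cfg)
  validate_sim_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  emitted <- character(0)
  emit <- function(writer, obj, name) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    emitted <<- c(emitted, path)
    path
  }
  write_tsv <- function(obj, path) {
    utils::write.table(obj, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("failed at stage: ", name, "\n", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # simulate
  sim <- run_stage("simulate", {
    genome <- make_reference(n_chroms, chrom_len, n_genes,
                             seed = cfg$seed)
    truth <- simulate_evolution(genome, cfg)
    counts <- simulate_readcounts(truth, genome, cfg)
    emul <- emulate_callers(counts, truth, cfg, genome)
    list(genome = genome, truth = truth, emul = emul)
  })
  stages$simulate <- c(n_in = nrow(sim$truth$mutations),
                       n_out = n_sites(sim$emul$a))
  emit(write_vcf, sim$emul$a, "caller_a.vcf")
  emit(write_vcf, sim$emul$b, "caller_b.vcf")
  emit(write_readcounts, sim$emul$counts, "readcounts.tsv")
  emit(write_sample_meta, sim$truth$sample_meta, "samples.tsv")
  truth_tab <- sim$truth$mutations
  truth_tab$trajectory <- NULL
  emit(write_tsv, truth_tab, "truth.tsv")

  # filter-snv
  snv <- run_stage("filter-snv", {
    filter_snv_cascade(sim$emul$a, sim$emul$b, sim$emul$counts,
                       sim$truth$sample_meta, fcfg)
  })
  stages$filter_snv <- c(n_in = n_sites(sim$emul$a),
                         n_out = n_sites(snv$final))
  emit(write_vcf, snv$final, "final_snvs.vcf")
  emit(write_tsv, snv$decisions, "snv_decisions.tsv")

  # filter-sv
  sv <- run_stage("filter-sv", filter_svs(sim$emul$sv))
  stages$filter_sv <- c(n_in = nrow(sim$emul$sv), n_out = nrow(sv$kept))
  sv_out <- sv$kept
  sv_out$samples <- vapply(sv_out$samples, paste, character(1), collapse = ",")
  emit(write_tsv, sv_out, "final_svs.tsv")
  emit(write_tsv, sv$decisions, "sv_decisions.tsv")

  # annotate
  rows <- run_stage("annotate", callset_to_rows(snv$final, sim$genome))
  stages$annotate <- c(n_in = n_sites(snv$final), n_out = nrow(rows))
  rows_out <- rows
  rows_out$samples <- vapply(rows_out$samples, paste, character(1),
                             collapse = " & ")
  emit(write_tsv, rows_out, "annotated_snvs.tsv")

  # summarize
  summ <- run_stage("summarize", {
    list(gene = tally_per_gene(rows),
         sample = per_sample_counts(rows, sim$truth$sample_meta$sample_id),
         shared = cross_line_sharing(rows))
  })
  stages$summarize <- c(n_in = nrow(rows), n_out = nrow(summ$gene))
  emit(write_tsv, summ$gene, "gene_summary.tsv")
  emit(write_tsv, summ$sample, "sample_summary.tsv")

  # associate
  assoc <- run_stage("associate", {
    screen <- simulate_clone_screen(sim$truth, n_screen_clones,
                                    seed = derive_seed(cfg$seed, "screen"))
    mut <- sim$truth$mutations
    regional <- mut$mut_id[mut$class %in% c("5prime", "3prime")]
    screen <- screen[screen$variant_id %in% regional, , drop = FALSE]
    if (nrow(screen) == 0) {
      NULL
    } else {
      rm_ <- stats::setNames(mut$class[match(unique(screen$variant_id),
                                             mut$mut_id)],
                             unique(screen$variant_id))
      screen_report(screen, rm_)
    }
  })
  stages$associate <- c(
    n_in = n_screen_clones * length(unique(sim$truth$mutations$line)),
    n_out = if (is.null(assoc)) 0L else nrow(assoc$per_region))
  if (!is.null(assoc)) {
    emit(write_tsv, assoc$per_line, "association_per_line.tsv")
    emit(write_tsv, assoc$per_region, "association_per_region.tsv")
  }

  manifest <- list(
    seed = cfg$seed,
    config = unclass(cfg),
    stages = data.frame(stage = names(stages),
                        n_in = vapply(stages, `[[`, numeric(1), "n_in"),
                        n_out = vapply(stages, `[[`, numeric(1), "n_out")),
    files = data.frame(file = basename(emitted),
                       md5 = unname(tools::md5sum(emitted))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

#' Write the packaged fixture tables to a directory
#'
#' Copies the packaged transcriptions of the study's printed result tables
#' (per-sample SNP counts and depths; the 38-SNP final call list; pooled
#' clone-screen counts by gene region) into `out_dir`. Overwrites existing
#' copies, so the call is idempotent.
#'
#' @param out_dir destination directory.
#' @return Character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c("sample_snp_counts.tsv", "called_snps.tsv",
             "clone_screen_counts.tsv")
  out <- vapply(files, function(f) {
    src <- system.file("extdata", f, package = "dictyvar", mustWork = TRUE)
    dst <- file.path(out_dir, f)
    file.copy(src, dst, overwrite = TRUE)
    dst
  }, character(1))
  invisible(unname(out))
}

#' Path to a packaged fixture
#'
#' @param name fixture file name.
#' @return Absolute path inside the installed package.
#' @export
fixture_path <- function(name) {
  system.file("extdata", name, package = "dictyvar", mustWork = TRUE)
}
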