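#' Write a call set as VCF 4.2
#'
#' Emits the dialect the package works in: haploid GT, per-sample AF and DP
#' FORMAT fields, site DP and caller metrics as INFO keys (each declared in
#' the header). QUAL is printed as a number (0 prints as "0", not ".").
#'
#' @param cs a [callset()].
#' @param path output file.
#' @param source_tag value for the `##source=` header line.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cs, path, source_tag = "dictyvar") {
  v <- cs$variants
  samples <- colnames(cs$gt)
  metric_cols <- setdiff(names(v), c("chrom", "pos", "ref", "alt", "qual",
                                     "dp", "is_indel", "multiallelic"))
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=", source_tag),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Approximate read depth across samples\">",
    vapply(metric_cols, function(m) paste0(
      "##INFO=<ID=", m,
      ",Number=1,Type=Float,Description=\"Caller site metric ", m, "\">"),
      character(1)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele read fraction\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Sample read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  fmt_num <- function(x) {
    ifelse(is.na(x), ".",
           ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
                  format(round(x, 4), scientific = FALSE, trim = TRUE)))
  }
  body <- vapply(seq_len(nrow(v)), function(i) {
    info <- paste0("DP=", fmt_num(v$dp[i]))
    for (m in metric_cols) {
      if (!is.na(v[[m]][i])) info <- paste0(info, ";", m, "=", fmt_num(v[[m]][i]))
    }
    cells <- vapply(samples, function(s) {
      af <- if (!is.null(cs$af)) cs$af[i, s] else NA_real_
      dp <- if (!is.null(cs$dpm)) cs$dpm[i, s] else NA_real_
      paste(cs$gt[i, s], fmt_num(af), fmt_num(dp), sep = ":")
    }, character(1))
    paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], fmt_num(v$qual[i]),
            "PASS", info, "GT:AF:DP", cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a call set
#'
#' Parses a VCF 4.x file (plain or bgzip) and interprets the package's
#' dialect: haploid GT ("." means uncalled), per-sample AF/DP, INFO DP and
#' caller metrics. Unknown INFO keys are preserved as numeric columns when
#' they parse as numbers. Multi-allelic ALT fields are flagged
#' (`multiallelic = TRUE`), not silently decomposed; indel alleles set
#' `is_indel`.
#'
#' @param path VCF file.
#' @param caller caller tag to attach (`"A"` or `"B"`).
#' @return A [callset()].
#' @export
read_vcf <- function(path, caller = "A") {
  if (!file.exists(path)) stop("no such file: ", path)
  check_vcf_structure(path)
  raw <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(raw, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  first_alt <- sub(",.*$", "", alt)
  v <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = first_alt,
    qual = ifelse(is.na(fix[, "QUAL"]), 0, as.numeric(fix[, "QUAL"])),
    dp = NA_real_,
    is_indel = nchar(fix[, "REF"]) != 1L | (nchar(first_alt) != 1L & !multi),
    multiallelic = multi)

  # INFO keys -> numeric columns where possible
  info <- fix[, "INFO"]
  pairs <- strsplit(info, ";", fixed = TRUE)
  keys <- unique(sub("=.*$", "", unlist(pairs)))
  for (k in keys) {
    vals <- vapply(pairs, function(p) {
      hit <- p[startsWith(p, paste0(k, "="))]
      if (length(hit) == 0) NA_character_ else sub("^[^=]*=", "", hit[1])
    }, character(1))
    num <- suppressWarnings(as.numeric(vals))
    col <- if (k == "DP") "dp" else k
    v[[col]] <- if (all(is.na(num) == is.na(vals))) num else vals
  }

  gt_raw <- raw@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2) {
    gt <- matrix(character(0), nrow = n, ncol = 0)
    af <- dpm <- NULL
  } else {
    samples <- colnames(gt_raw)[-1]
    pick <- function(field) {
      m <- vcfR::extract.gt(raw, element = field, as.numeric = field != "GT")
      if (is.null(dim(m))) m <- matrix(m, nrow = n, dimnames = list(NULL, samples))
      m
    }
    gtm <- pick("GT")
    gtm[is.na(gtm)] <- "."
    af <- suppressWarnings(pick("AF"))
    dpm <- suppressWarnings(pick("DP"))
    gt <- gtm
    colnames(gt) <- samples
  }
  callset(v, gt, dpm = dpm, af = af, caller = caller)
}

# Light structural validation with line numbers (uncompressed files only);
# vcfR is tolerant of ragged bodies, so ragged records are caught here.
check_vcf_structure <- function(path) {
  if (grepl("\\.gz$", path)) return(invisible(TRUE))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !startsWith(lines[1], "##fileformat=VCF")) {
    stop("malformed VCF header at line 1 of ", path)
  }
  hdr <- which(startsWith(lines, "#CHROM"))
  if (length(hdr) != 1) stop("missing #CHROM header line in ", path)
  want <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1]])
  body <- seq_along(lines) > hdr
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(nf != want)
  if (length(bad) > 0) {
    stop("malformed VCF record at line ", hdr + bad[1], " of ", path,
         " (", nf[bad[1]], " fields, expected ", want, ")")
  }
  invisible(TRUE)
}

#' Write / read a read-count table as TSV
#'
#' @param counts a `read_counts` table.
#' @param path TSV path.
#' @return `path` / the table.
#' @export
write_readcounts <- function(counts, path) {
  utils::write.table(as.data.frame(counts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_readcounts
#' @export
read_readcounts <- function(path) {
  counts <- utils::read.delim(path, colClasses = c(
    chrom = "character", sample = "character", ref = "character",
    alt = "character"))
  stopifnot(all(c("chrom", "pos", "sample", "ref", "alt", "n_a", "n_c",
                  "n_g", "n_t", "depth") %in% names(counts)))
  bad <- with(counts, n_a + n_c + n_g + n_t != depth)
  if (any(bad)) stop("allele counts do not sum to depth at row ", which(bad)[1])
  class(counts) <- c("read_counts", "data.frame")
  counts
}

#' Write / read sample metadata as TSV
#'
#' Columns `sample_id`, `line`, `role`, `phenotype`; exactly one ancestor.
#'
#' @param meta sample metadata data frame.
#' @param path TSV path.
#' @return `path` / the table.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_meta
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, colClasses = c(sample_id = "character"))
  stopifnot(all(c("sample_id", "line", "role", "phenotype") %in% names(meta)),
            sum(meta$role == "ancestor") == 1,
            all(meta$role %in% c("ancestor", "population", "clone")))
  meta
}

#' Load the called-SNP fixture table
#'
#' Reads the TSV transcription of the study's final SNP list (site, gene,
#' called samples, consequence, impact, amino-acid change). Sample cells
#' like `"7 & 7-NF2"` are split into individual sample ids; the consequence
#' vocabulary is validated and normalised to full sequence-ontology terms.
#'
#' @param path TSV with columns `chrom_site`, `gene_id`, `gene_name`,
#'   `samples`, `consequence`, `impact`, `aa_change`.
#' @return Data frame with one row per SNP, `samples` as a list column, and
#'   added `chrom` / `pos` columns split from `chrom_site`.
#' @export
load_snp_fixture <- function(path) {
  allowed <- c(missense_var. = "missense_variant",
               stop_gained = "stop_gained",
               synonymous_var. = "synonymous_variant",
               upstream_gene_var. = "upstream_gene_variant",
               downstream_gene_var. = "downstream_gene_variant")
  df <- utils::read.delim(path, colClasses = "character")
  if (nrow(df) == 0) {
    return(data.frame(chrom_site = character(), gene_id = character(),
                      gene_name = character(), samples = I(list()),
                      consequence = character(), impact = character(),
                      aa_change = character(), chrom = character(),
                      pos = integer()))
  }
  stopifnot(all(c("chrom_site", "gene_id", "samples", "consequence",
                  "impact") %in% names(df)))
  bad <- !(df$consequence %in% names(allowed) | df$consequence %in% allowed)
  if (any(bad)) {
    stop("unknown consequence '", df$consequence[which(bad)[1]],
         "'; allowed: ", paste(names(allowed), collapse = ", "))
  }
  df$consequence <- ifelse(df$consequence %in% names(allowed),
                           allowed[df$consequence], df$consequence)
  df$samples <- I(strsplit(df$samples, " & ", fixed = TRUE))
  stopifnot(all(lengths(df$samples) > 0))
  df$chrom <- sub(":.*$", "", df$chrom_site)
  df$pos <- as.integer(sub("^.*:", "", df$chrom_site))
  df
}

#' Load a clone-screen table
#'
#' TSV with columns `line`, `clone_id`, `variant_id`, `fruits`, `carries`
#' (both 0/1). Duplicate (line, clone_id, variant_id) triples are an error,
#' as are non-binary phenotype/genotype codes. When sample metadata is
#' given, screened lines must exist in it.
#'
#' @param path TSV path.
#' @param meta optional sample metadata for validation.
#' @return Data frame of clone-screen records.
#' @export
load_clone_screen <- function(path, meta = NULL) {
  df <- utils::read.delim(path, colClasses = c(clone_id = "character",
                                               variant_id = "character"))
  stopifnot(all(c("line", "clone_id", "variant_id", "fruits", "carries")
                %in% names(df)))
  if (!all(df$fruits %in% c(0L, 1L)) || !all(df$carries %in% c(0L, 1L))) {
    stop("fruits and carries must be 0/1")
  }
  key <- paste(df$line, df$clone_id, df$variant_id)
  if (anyDuplicated(key)) {
    stop("duplicated (line, clone_id, variant_id): ", key[duplicated(key)][1])
  }
  if (!is.null(meta) && !all(df$line %in% meta$line)) {
    stop("screened line(s) absent from sample metadata: ",
         paste(setdiff(df$line, meta$line), collapse = ", "))
  }
  df
}

#' Load the per-sample SNP count / depth fixture
#'
#' @param path TSV with columns `sample`, `snp_count`, `mean_depth`.
#' @return Data frame.
#' @export
load_sample_counts_fixture <- function(path) {
  df <- utils::read.delim(path, colClasses = c(sample = "character"))
  stopifnot(all(c("sample", "snp_count", "mean_depth") %in% names(df)))
  df
}
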