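# On-disk formats: VCF 4.2 for genotypes, TSV for expression and summary
# statistics, JSON for the truth ledger, GMT for gene sets.  All files are
# plain text and round-trip exactly.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a dosage matrix as an unphased VCF 4.2 file
#'
#' Dosages 0/1/2 become GT fields `0/0`, `0/1`, `1/1`.
#'
#' @param geno Samples x SNPs integer dosage matrix with dimnames.
#' @param snp_info Data frame with columns `snp`, `chr`, `pos` matching the
#'   columns of `geno`.
#' @param path Output path.
#' @export
write_vcf <- function(geno, snp_info, path) {
  if (is.null(dimnames(geno))) stop("genotype matrix needs dimnames")
  ord <- match(colnames(geno), snp_info$snp)
  if (anyNA(ord)) stop("snp_info does not cover all genotyped SNPs")
  gt <- c("0/0", "0/1", "1/1")[t(geno) + 1L]
  body <- matrix(gt, nrow = ncol(geno))
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=cortnet",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t"),
    paste(snp_info$chr[ord], snp_info$pos[ord], snp_info$snp[ord],
          "A", "G", ".", "PASS", ".", "GT",
          apply(body, 1L, paste, collapse = "\t"), sep = "\t")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a VCF file into a samples x SNPs dosage matrix
#'
#' Parses GT fields with vcfR and counts alternate alleles.
#'
#' @param path VCF path.
#' @return List with `geno` (samples x SNPs dosage matrix) and `snp_info`
#'   (snp, chr, pos).
#' @export
read_vcf_dosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  d <- (substr(gt, 1, 1) == "1") + (substr(gt, 3, 3) == "1")
  mode(d) <- "integer"
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  list(geno = t(d),
       snp_info = data.frame(snp = fix$ID, chr = fix$CHROM,
                             pos = as.integer(fix$POS),
                             stringsAsFactors = FALSE))
}

#' Write an expression matrix as TSV (genes x samples)
#'
#' First column `gene_id`, then one column per sample.
#'
#' @param m Genes x samples matrix with dimnames.
#' @param path Output path.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Read an expression TSV written by [write_expression_tsv()]
#'
#' @param path TSV path.
#' @return Genes x samples numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "cortnet", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Thin wrapper over `fgsea::gmtPathways()`.
#'
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a simulated cohort to a directory
#'
#' Emits `genotypes.vcf`, `expr_<tissue>.tsv` (and `repl_<tissue>.tsv` when
#' a replication set is supplied), `summary_stats.tsv`, `gene_info.tsv`,
#' `truth.json` and `config.yaml`.  Reading the directory back with
#' [read_cohort()] reproduces the matrices exactly.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param out_dir Writable directory (created if absent).
#' @param replication Optional per-tissue replication expression list from
#'   [simulate_replication()].
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, out_dir, replication = NULL) {
  stopifnot(inherits(cohort, "cortnet_cohort"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir)
  }
  paths <- c(
    genotypes = file.path(out_dir, "genotypes.vcf"),
    summary_stats = file.path(out_dir, "summary_stats.tsv"),
    gene_info = file.path(out_dir, "gene_info.tsv"),
    truth = file.path(out_dir, "truth.json"),
    config = file.path(out_dir, "config.yaml")
  )
  write_vcf(cohort$genotypes, cohort$snp_info, paths["genotypes"])
  .write_tsv(cohort$gwama, paths["summary_stats"])
  .write_tsv(cohort$gene_info, paths["gene_info"])

  for (t in names(cohort$expression)) {
    p <- file.path(out_dir, sprintf("expr_%s.tsv", t))
    write_expression_tsv(cohort$expression[[t]], p)
    paths[sprintf("expr_%s", t)] <- p
  }
  if (!is.null(replication)) {
    for (t in names(replication)) {
      p <- file.path(out_dir, sprintf("repl_%s.tsv", t))
      write_expression_tsv(replication[[t]], p)
      paths[sprintf("repl_%s", t)] <- p
    }
  }

  tr <- cohort$truth
  jsonlite::write_json(
    list(snp_block_map = as.list(tr$snp_block_map),
         true_trans_pairs = tr$true_trans_pairs,
         true_edges = tr$true_edges,
         instrument_map = as.list(tr$instrument_map),
         gwama_pvalues = as.list(tr$gwama_pvalues),
         genes = tr$genes, tissues = tr$tissues),
    paths["truth"], auto_unbox = TRUE, digits = NA, null = "null")

  cfg <- cohort$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, paths["config"])
  invisible(paths)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory path.
#' @return A list shaped like a [simulate_cohort()] result (class
#'   `cortnet_cohort`), plus `replication` when replication matrices were
#'   written.
#' @export
read_cohort <- function(dir) {
  need <- file.path(dir, c("genotypes.vcf", "summary_stats.tsv",
                           "gene_info.tsv", "truth.json"))
  missing <- need[!file.exists(need)]
  if (length(missing)) stop("missing cohort artifact: ", missing[1])
  vd <- read_vcf_dosage(need[1])
  gwama <- .read_tsv(need[2])
  gene_info <- .read_tsv(need[3])
  tj <- jsonlite::read_json(need[4], simplifyVector = TRUE)
  snp_info <- merge(vd$snp_info,
                    gwama[, c("snp", "block")], by = "snp", sort = FALSE)
  snp_info <- snp_info[match(colnames(vd$geno), snp_info$snp), ]
  rownames(snp_info) <- NULL

  read_set <- function(prefix) {
    fs <- list.files(dir, pattern = sprintf("^%s_.*\\.tsv$", prefix),
                     full.names = TRUE)
    if (!length(fs)) return(NULL)
    nms <- sub(sprintf("^%s_(.*)\\.tsv$", prefix), "\\1", basename(fs))
    stats::setNames(lapply(fs, read_expression_tsv), nms)
  }
  expression <- read_set("expr")
  replication <- read_set("repl")

  truth <- list(
    snp_block_map = unlist(tj$snp_block_map),
    true_trans_pairs = as.data.frame(tj$true_trans_pairs,
                                     stringsAsFactors = FALSE),
    true_edges = as.data.frame(tj$true_edges, stringsAsFactors = FALSE),
    instrument_map = unlist(tj$instrument_map),
    gwama_pvalues = unlist(tj$gwama_pvalues),
    genes = tj$genes, tissues = tj$tissues
  )
  cfg_path <- file.path(dir, "config.yaml")
  config <- if (file.exists(cfg_path)) {
    structure(yaml::read_yaml(cfg_path), class = "cortnet_sim_config")
  } else NULL

  structure(list(genotypes = vd$geno, snp_info = snp_info,
                 expression = expression, gene_info = gene_info,
                 gwama = gwama, truth = truth, config = config,
                 replication = replication),
            class = "cortnet_cohort")
}
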