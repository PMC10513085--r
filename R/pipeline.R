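# Stage orchestration: simulate -> scan -> gr_filter -> network -> enrich
# -> replicate, with on-disk artifacts, a JSON manifest of parameters and
# content hashes, and deterministic seeds.

.stages <- c("simulate", "scan", "gr_filter", "network", "enrich",
             "replicate")

#' Pipeline configuration
#'
#' @param sim A [sim_config()] describing the synthetic cohort (the
#'   simulate stage's input).
#' @param gwas_p_threshold GWAS significance filter (default 5e-8).
#' @param trans_fdr Global FDR for the trans-eQTL selection (default
#'   0.15).
#' @param network_fdr Global FDR for network edges (default 0.10).
#' @param min_targets Minimum surviving targets per network regulator
#'   (default 4).
#' @param instrument_posterior Minimum primary-linkage posterior for a
#'   valid cis instrument (default 0.75).
#' @param cis_window Cis window in base pairs (default 1 Mb).
#' @param n_bg_draws Random background sets per replication comparison.
#' @param seed Master seed (stage seeds are derived from it).
#' @return An object of class `cortnet_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            gwas_p_threshold = 5e-8,
                            trans_fdr = 0.15, network_fdr = 0.10,
                            min_targets = 4L,
                            instrument_posterior = 0.75,
                            cis_window = 1e6, n_bg_draws = 1L,
                            seed = sim$seed) {
  for (thr in c(trans_fdr, network_fdr, instrument_posterior)) {
    if (thr <= 0 || thr >= 1) stop("thresholds must be in (0, 1)")
  }
  if (gwas_p_threshold <= 0 || gwas_p_threshold >= 1) {
    stop("gwas_p_threshold must be in (0, 1)")
  }
  structure(list(sim = .validate_sim_config(sim),
                 gwas_p_threshold = gwas_p_threshold,
                 trans_fdr = trans_fdr, network_fdr = network_fdr,
                 min_targets = as.integer(min_targets),
                 instrument_posterior = instrument_posterior,
                 cis_window = cis_window,
                 n_bg_draws = as.integer(n_bg_draws),
                 seed = as.integer(seed)),
            class = "cortnet_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipeline_config()] arguments; the `sim` block
#' mirrors [sim_config()].  Keys omitted from the file keep their
#' defaults, and arguments passed through `...` override the file.
#'
#' @param path YAML file path.
#' @param ... Overrides for [pipeline_config()] arguments.
#' @return A `cortnet_pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  y$sim <- do.call(sim_config, sim_args)
  over <- list(...)
  y[names(over)] <- over
  do.call(pipeline_config, y)
}

.catalog_paths <- function(dir) {
  c(catalog = file.path(dir, "gr_catalog.gmt"),
    murine = file.path(dir, "murine_dex.tsv"),
    applicability = file.path(dir, "applicability.json"),
    tf_sets = file.path(dir, "tf_sets.gmt"))
}

.write_catalog <- function(catalog, tf_sets, dir) {
  p <- .catalog_paths(dir)
  sets <- c(stats::setNames(catalog$tf_db_sets,
                            paste0("db:", names(catalog$tf_db_sets))),
            list("chipseq" = catalog$chipseq_set,
                 "dex_de" = catalog$dex_de_set))
  write_gmt(sets, p["catalog"])
  .write_tsv(catalog$murine_dex %||%
               data.frame(gene = character(0), fc = numeric(0),
                          pval = numeric(0)), p["murine"])
  jsonlite::write_json(catalog$applicability, p["applicability"],
                       auto_unbox = FALSE)
  write_gmt(tf_sets, p["tf_sets"])
  p
}

.read_catalog <- function(dir) {
  p <- .catalog_paths(dir)
  sets <- read_gmt(p["catalog"])
  db <- sets[grepl("^db:", names(sets))]
  names(db) <- sub("^db:", "", names(db))
  murine <- .read_tsv(p["murine"])
  app <- jsonlite::read_json(p["applicability"], simplifyVector = TRUE)
  catalog <- evidence_catalog(
    tf_db_sets = db,
    chipseq_set = sets[["chipseq"]] %||% character(0),
    dex_de_set = sets[["dex_de"]] %||% character(0),
    murine_dex = if (nrow(murine)) murine else NULL,
    applicability = app)
  list(catalog = catalog, tf_sets = read_gmt(p["tf_sets"]))
}

.require_artifacts <- function(paths, stage) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop(sprintf("stage '%s': missing upstream artifact %s", stage,
                 missing[1]), call. = FALSE)
  }
}

#' Run a single pipeline stage
#'
#' Executes exactly one stage against the artifacts already present in
#' `out_dir`, writing that stage's outputs under `out_dir/<stage>`.
#' Missing upstream artifacts raise an error naming the artifact.
#'
#' @param name One of `"simulate"`, `"scan"`, `"gr_filter"`, `"network"`,
#'   `"enrich"`, `"replicate"`.
#' @param config A [pipeline_config()].
#' @param out_dir Run directory.
#' @return List with `outputs` (paths) and `counts` (record counts),
#'   invisibly.
#' @export
run_stage <- function(name, config, out_dir) {
  name <- match.arg(name, .stages)
  stopifnot(inherits(config, "cortnet_pipeline_config"))
  stage_dir <- file.path(out_dir, name)
  if (!dir.exists(stage_dir)) dir.create(stage_dir, recursive = TRUE)
  fn <- switch(name,
    simulate = .stage_simulate, scan = .stage_scan,
    gr_filter = .stage_gr_filter, network = .stage_network,
    enrich = .stage_enrich, replicate = .stage_replicate)
  res <- fn(config, out_dir, stage_dir)
  invisible(res)
}

.stage_simulate <- function(config, out_dir, stage_dir) {
  cohort <- simulate_cohort(config$sim)
  repl <- simulate_replication(cohort$truth, config$sim)
  paths <- write_cohort(cohort, stage_dir, replication = repl)
  cat_paths <- .write_catalog(synthetic_gr_catalog(cohort),
                              synthetic_tf_sets(cohort), stage_dir)
  list(outputs = c(paths, cat_paths),
       counts = list(n_samples = nrow(cohort$genotypes),
                     n_snps = ncol(cohort$genotypes),
                     n_genes = nrow(cohort$expression[[1]]),
                     n_true_edges = nrow(cohort$truth$true_edges)))
}

.cohort_dir <- function(out_dir) file.path(out_dir, "simulate")

.load_cohort <- function(out_dir, stage) {
  .require_artifacts(file.path(.cohort_dir(out_dir), "genotypes.vcf"),
                     stage)
  read_cohort(.cohort_dir(out_dir))
}

.stage_scan <- function(config, out_dir, stage_dir) {
  cohort <- .load_cohort(out_dir, "scan")
  snps <- filter_gwas_snps(cohort$gwama, config$gwas_p_threshold)
  outputs <- character(0)
  selections <- list()
  n_rec <- 0L
  for (t in names(cohort$expression)) {
    rec <- scan_tissue(snps, cohort$genotypes, cohort$expression[[t]], t,
                       snp_info = cohort$snp_info,
                       gene_info = cohort$gene_info,
                       cis_window = config$cis_window)
    sel <- select_by_global_fdr(rec, config$trans_fdr)
    key <- paste(rec$snp, rec$gene)
    rec$selected <- key %in% paste(sel$records$snp, sel$records$gene)
    p <- file.path(stage_dir, sprintf("associations_%s.tsv", t))
    .write_tsv(rec, p)
    outputs[sprintf("associations_%s", t)] <- p
    selections[[t]] <- sel
    n_rec <- n_rec + nrow(rec)
  }
  sharing <- tabulate_sharing(selections)
  sp <- file.path(stage_dir, "sharing.json")
  jsonlite::write_json(sharing, sp, auto_unbox = TRUE, digits = NA)
  outputs["sharing"] <- sp
  list(outputs = outputs,
       counts = list(n_snps_filtered = length(snps), n_records = n_rec,
                     n_selected = sum(vapply(selections,
                                             function(s) s$n_selected,
                                             integer(1)))))
}

.stage_gr_filter <- function(config, out_dir, stage_dir) {
  cohort <- .load_cohort(out_dir, "gr_filter")
  assoc_files <- list.files(file.path(out_dir, "scan"),
                            pattern = "^associations_.*\\.tsv$",
                            full.names = TRUE)
  if (!length(assoc_files)) {
    stop("stage 'gr_filter': missing upstream artifact ",
         file.path(out_dir, "scan", "associations_<tissue>.tsv"),
         call. = FALSE)
  }
  cat_ <- .read_catalog(.cohort_dir(out_dir))
  scores <- list(); trans <- list()
  for (f in assoc_files) {
    t <- sub("^associations_(.*)\\.tsv$", "\\1", basename(f))
    rec <- .read_tsv(f)
    sel_genes <- sort(unique(rec$gene[rec$selected & !rec$cis]))
    if (!length(sel_genes)) next
    trans[[t]] <- data.frame(gene = sel_genes, tissue = t,
                             stringsAsFactors = FALSE)
    scores[[t]] <- score_gr_evidence(sel_genes, t, cat_$catalog)
  }
  scores <- do.call(rbind, scores) %||%
    data.frame(gene = character(0), tissue = character(0),
               score = integer(0), criteria = character(0))
  trans <- do.call(rbind, trans) %||%
    data.frame(gene = character(0), tissue = character(0))
  gr <- if (nrow(trans)) filter_gr_trans_genes(trans, scores) else
    scores[0, , drop = FALSE]
  regs <- if (nrow(gr)) {
    select_instrumented_regulators(
      gr, cohort$genotypes, cohort$expression, cohort$snp_info,
      cohort$gene_info, posterior_threshold = config$instrument_posterior,
      cis_window = config$cis_window)
  } else {
    data.frame(gene = character(0), tissue = character(0),
               instrument_snp = character(0),
               instrument_posterior = numeric(0))
  }
  outputs <- c(
    gr_scores = .write_tsv(scores, file.path(stage_dir, "gr_scores.tsv")),
    regulators = .write_tsv(regs, file.path(stage_dir, "regulators.tsv")),
    dropped = .write_tsv(attr(regs, "dropped") %||%
                           data.frame(gene = character(0),
                                      tissue = character(0),
                                      reason = character(0)),
                         file.path(stage_dir, "dropped.tsv")))
  list(outputs = outputs,
       counts = list(n_scored = nrow(scores), n_gr = nrow(gr),
                     n_instrumented = nrow(regs)))
}

.stage_network <- function(config, out_dir, stage_dir) {
  cohort <- .load_cohort(out_dir, "network")
  reg_path <- file.path(out_dir, "gr_filter", "regulators.tsv")
  .require_artifacts(reg_path, "network")
  regs <- .read_tsv(reg_path)
  levels <- sort(unique(c(config$network_fdr, config$trans_fdr)))
  outputs <- character(0)
  table1 <- list(); skipped <- list()
  n_edges <- 0L
  for (t in unique(regs$tissue)) {
    rt <- regs[regs$tissue == t, , drop = FALSE]
    cand <- list()
    for (i in seq_len(nrow(rt))) {
      e <- tryCatch(
        score_all_pairs(rt$gene[i], rt$instrument_snp[i],
                        cohort$genotypes, cohort$expression[[t]], t),
        error = function(err) {
          skipped[[length(skipped) + 1L]] <<- data.frame(
            regulator = rt$gene[i], tissue = t,
            reason = conditionMessage(err), stringsAsFactors = FALSE)
          NULL
        })
      if (!is.null(e)) cand[[length(cand) + 1L]] <- e
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    for (lev in levels) {
      nw <- build_network(cand, lev, min_targets = config$min_targets)
      lev_tag <- sprintf("%02.0f", 100 * lev)
      p <- file.path(stage_dir, sprintf("edges_%s_fdr%s.tsv", t, lev_tag))
      .write_tsv(nw$edges, p)
      outputs[sprintf("edges_%s_fdr%s", t, lev_tag)] <- p
      table1[[length(table1) + 1L]] <- network_stats(nw)
      if (lev == config$network_fdr) {
        g <- file.path(stage_dir, sprintf("network_%s.graphml", t))
        write_network_graphml(nw, g)
        outputs[sprintf("network_%s", t)] <- g
        n_edges <- n_edges + nrow(nw$edges)
      }
    }
  }
  t1 <- do.call(rbind, table1) %||%
    data.frame(tissue = character(0), fdr = numeric(0),
               total_targets = integer(0), regulator = character(0),
               regulator_targets = integer(0))
  outputs["table1"] <- .write_tsv(t1, file.path(stage_dir, "table1.tsv"))
  outputs["skipped"] <- .write_tsv(
    do.call(rbind, skipped) %||%
      data.frame(regulator = character(0), tissue = character(0),
                 reason = character(0)),
    file.path(stage_dir, "skipped.tsv"))
  list(outputs = outputs,
       counts = list(n_network_edges = n_edges,
                     n_regulators_skipped = length(skipped)))
}

.read_stage_networks <- function(out_dir, config, stage) {
  net_dir <- file.path(out_dir, "network")
  lev_tag <- sprintf("%02.0f", 100 * config$network_fdr)
  fs <- list.files(net_dir,
                   pattern = sprintf("^edges_.*_fdr%s\\.tsv$", lev_tag),
                   full.names = TRUE)
  if (!length(fs)) {
    stop(sprintf("stage '%s': missing upstream artifact %s", stage,
                 file.path(net_dir, sprintf("edges_<tissue>_fdr%s.tsv",
                                            lev_tag))), call. = FALSE)
  }
  stats::setNames(lapply(fs, .read_tsv),
                  sub(sprintf("^edges_(.*)_fdr%s\\.tsv$", lev_tag), "\\1",
                      basename(fs)))
}

.stage_enrich <- function(config, out_dir, stage_dir) {
  cohort <- .load_cohort(out_dir, "enrich")
  cat_ <- .read_catalog(.cohort_dir(out_dir))
  net_dir <- file.path(out_dir, "network")
  .require_artifacts(file.path(net_dir, "table1.tsv"), "enrich")
  levels <- sort(unique(c(config$network_fdr, config$trans_fdr)))
  rows <- list()
  for (t in names(cohort$expression)) {
    background <- rownames(cohort$expression[[t]])
    networks <- list()
    for (lev in levels) {
      p <- file.path(net_dir, sprintf("edges_%s_fdr%02.0f.tsv", t,
                                      100 * lev))
      if (!file.exists(p)) next
      ed <- .read_tsv(p)
      if (!nrow(ed)) next
      networks[[as.character(lev)]] <- structure(
        list(edges = ed, regulators = sort(unique(ed$regulator)),
             tissue = t, fdr_threshold = lev,
             achieved_fdr = 1 - mean(ed$posterior),
             dropped_regulators = character(0)),
        class = "cortnet_network")
    }
    if (!length(networks)) next
    res <- enrichment_scan(networks, cat_$tf_sets, background)
    if (nrow(res)) {
      res$tissue <- t
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows) %||%
    data.frame(tf = character(0), regulator = character(0),
               fdr_level = character(0), a = integer(0), b = integer(0),
               c = integer(0), d = integer(0), odds_ratio = numeric(0),
               pvalue = numeric(0), tissue = character(0))
  # TSV convention: infinite odds ratios rendered as "inf"
  out$odds_ratio <- ifelse(is.infinite(out$odds_ratio), "inf",
                           as.character(out$odds_ratio))
  p <- .write_tsv(out, file.path(stage_dir, "enrichment.tsv"))
  list(outputs = c(enrichment = p), counts = list(n_tests = nrow(out)))
}

.stage_replicate <- function(config, out_dir, stage_dir) {
  cohort <- .load_cohort(out_dir, "replicate")
  if (is.null(cohort$replication)) {
    stop("stage 'replicate': missing upstream artifact ",
         file.path(.cohort_dir(out_dir), "repl_<tissue>.tsv"),
         call. = FALSE)
  }
  networks <- .read_stage_networks(out_dir, config, "replicate")
  rows <- list(); outputs <- character(0)
  for (t in names(networks)) {
    ed <- networks[[t]]
    if (!nrow(ed)) next
    repl <- cohort$replication[[t]]
    if (is.null(repl)) next
    disc <- cohort$expression[[t]]
    for (reg in sort(unique(ed$regulator))) {
      targets <- ed$target[ed$regulator == reg]
      if (length(targets) < 2) next
      rr <- replicate_network(targets, disc, repl, regulator = reg,
                              dataset = sprintf("replication_%s", t),
                              n_draws = config$n_bg_draws,
                              seed = config$seed + 17L)
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = rr$dataset, tissue = t, regulator = reg,
        kw_statistic = rr$kw_statistic, pvalue = rr$pvalue,
        n_target_genes = rr$n_targets, stringsAsFactors = FALSE)
      for (side in c("discovery", "replication")) {
        m <- if (side == "discovery") rr$discovery_corr else
          rr$replication_corr
        p <- file.path(stage_dir, sprintf("corr_%s_%s_%s.tsv", side, t,
                                          reg))
        .write_tsv(data.frame(gene_id = rownames(m), m,
                              check.names = FALSE), p)
        outputs[sprintf("corr_%s_%s_%s", side, t, reg)] <- p
      }
    }
  }
  t2 <- do.call(rbind, rows) %||%
    data.frame(dataset = character(0), tissue = character(0),
               regulator = character(0), kw_statistic = numeric(0),
               pvalue = numeric(0), n_target_genes = integer(0))
  outputs["table2"] <- .write_tsv(t2, file.path(stage_dir, "table2.tsv"))
  list(outputs = outputs, counts = list(n_replications = nrow(t2)))
}

#' Run the full pipeline
#'
#' Executes all stages in order into `out_dir` and writes
#' `manifest.json` recording the configuration, each stage's parameters,
#' record counts and MD5 content hashes of every output file (timings are
#' stored under a separate `timings` key so that two runs with identical
#' config and seed produce identical manifests apart from it).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created if absent).
#' @param resume Skip stages whose output directory already has a
#'   manifest entry from a previous run (their artifacts are reused);
#'   downstream stages are still executed.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE) {
  stopifnot(inherits(config, "cortnet_pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  old <- if (resume && file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  } else NULL

  stages <- list(); timings <- list()
  for (s in .stages) {
    prev <- old$stages[[s]]
    if (resume && !is.null(prev) &&
        all(file.exists(file.path(out_dir,
                                  names(unlist(prev$outputs_md5)))))) {
      stages[[s]] <- prev
      timings[[s]] <- "resumed"
      next
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(run_stage(s, config, out_dir), error = function(e) {
      stop(sprintf("[stage:%s] %s", s, conditionMessage(e)), call. = FALSE)
    })
    timings[[s]] <- round(proc.time()[["elapsed"]] - t0, 3)
    files <- unname(res$outputs)
    md5 <- as.list(tools::md5sum(files))
    # keys relative to the run directory so identical runs in different
    # directories produce identical manifests
    names(md5) <- sub(paste0("^", normalizePath(out_dir), "/?"), "",
                      normalizePath(files))
    stages[[s]] <- list(outputs_md5 = md5, counts = res$counts)
  }
  cfg <- unclass(config)
  cfg$sim <- unclass(cfg$sim)
  manifest <- list(config = cfg, stages = stages, timings = timings)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
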