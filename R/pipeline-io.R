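# File formats (GMT gene sets, TSV expression/annotation/network tables,
# CSV survival tables), pipeline configuration and the end-to-end runner
# with a reproducibility manifest.

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: one set per line as
#' `name<TAB>description<TAB>member...`. Lines with fewer than three fields,
#' empty member lists or duplicate set names are errors.
#'
#' @param path file path.
#' @return named list of character vectors; descriptions in attribute
#'   `descriptions`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file", call. = FALSE)
  sets <- list(); descs <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("malformed GMT line %d: need name, description and >= 1 member", i),
           call. = FALSE)
    nm <- f[[1]]
    if (nm %in% names(sets))
      stop(sprintf("duplicate set name '%s' at line %d", nm, i), call. = FALSE)
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members))
      stop(sprintf("empty member list at line %d", i), call. = FALSE)
    sets[[nm]] <- members
    descs[nm] <- f[[2]]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named descriptions (default set names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- descriptions %||% setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, descriptions[[nm]] %||% nm, sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a gene signature as a two-set GMT
#'
#' Emits the up and down sets as `<name>_UP` and `<name>_DN`.
#'
#' @param signature a [gene_signature()].
#' @param path output path.
#' @param name base set name (default "signature").
#' @return `path`, invisibly.
#' @export
write_signature_gmt <- function(signature, path, name = "signature") {
  desc <- sprintf("fdr<%g |FC|>%g support>=%d", signature$fdr_cutoff,
                  signature$fc_cutoff, signature$min_support)
  write_gmt(setNames(list(signature$up, signature$down),
                     paste0(name, c("_UP", "_DN"))),
            path,
            descriptions = setNames(c(desc, desc), paste0(name, c("_UP", "_DN"))))
}

#' Read a gene-by-sample expression TSV
#'
#' Expects a header row of sample ids and a first column of gene ids; the
#' body must be fully numeric with no missing values.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  d <- tryCatch(
    read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
               colClasses = "character", quote = ""),
    error = function(e) stop("empty or unreadable expression file",
                             call. = FALSE))
  if (!nrow(d) || ncol(d) < 2L) stop("empty expression file", call. = FALSE)
  genes <- d[[1]]
  if (anyDuplicated(genes))
    stop(sprintf("duplicate gene id '%s'", genes[duplicated(genes)][1]),
         call. = FALSE)
  body <- as.matrix(d[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing value at gene '%s', sample '%s'",
                 genes[bad[1]], colnames(body)[bad[2]]), call. = FALSE)
  }
  dimnames(num) <- list(genes, colnames(body))
  num
}

#' Write a gene-by-sample expression TSV
#'
#' @param expr numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @param id_col name of the gene-id column (default "gene").
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, id_col = "gene") {
  # full "%.17g" precision so write/read round trips are bit-identical
  body <- matrix(sprintf("%.17g", expr), nrow = nrow(expr),
                 dimnames = dimnames(expr))
  d <- data.frame(rownames(expr), body, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1] <- id_col
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a directed network edge list
#'
#' TSV with columns `parent`, `child` and optionally `support` (defaults to
#' 1.0 with a warning when absent) and `cohorts`. Self-loops are rejected.
#'
#' @param path file path.
#' @return data.frame (parent, child, support\[, cohorts\]).
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                  quote = "")
  if (!all(c("parent", "child") %in% names(d)))
    stop("network file needs columns parent and child", call. = FALSE)
  if (any(d$parent == d$child))
    stop(sprintf("self-loop at '%s'", d$parent[d$parent == d$child][1]),
         call. = FALSE)
  if (!"support" %in% names(d)) {
    warning("no `support` column; defaulting to 1.0")
    d$support <- 1.0
  }
  d
}

#' Write a directed network edge list
#'
#' Edges are written in stable lexicographic (parent, child) order with
#' supports at full precision.
#'
#' @param network edge data.frame or `consensus_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  e <- as_edge_df(network)
  e <- e[order(e$parent, e$child), , drop = FALSE]
  if ("support" %in% names(e))
    e$support <- sprintf("%.17g", e$support)
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a survival table CSV
#'
#' Columns: sample, time, event, group, anchor_expr (group optional on read;
#' recomputed from the median split of `anchor_expr` when absent).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  d <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("sample", "time", "event") %in% names(d)))
    stop("survival file needs columns sample, time, event", call. = FALSE)
  if (!"group" %in% names(d)) {
    if (!"anchor_expr" %in% names(d))
      stop("survival file needs `group` or `anchor_expr`", call. = FALSE)
    d$group <- stratify_by_median(d$anchor_expr)
  }
  validate_survival_table(d)
}

#' @rdname read_survival
#' @param table survival data.frame.
#' @export
write_survival <- function(table, path) {
  write.table(table, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the seeds, thresholds and synthetic-scenario sizes of an
#' end-to-end run. All thresholds are validated against their domains at
#' construction time.
#'
#' @param seed master seed; every stage that samples derives its own seed
#'   from it.
#' @param out_dir output directory for artifacts and the manifest.
#' @param n_genes,mean_out_degree,n_tfs ground-truth network size.
#' @param n_samples per-cohort sample count; `cohorts` the cohort labels.
#' @param kd_delta knockdown shift of the anchor's exogenous input;
#'   `n_per_group` samples per knockdown arm; `n_replicates` knockdown
#'   replicates (shRNA analogs).
#' @param true_hr,censor_frac survival-generator parameters.
#' @param de_fdr,de_fc,min_support consensus-signature thresholds (defaults
#'   0.05, 1.3, 2).
#' @param rho_cutoff anchor-correlation threshold (default 0.2).
#' @param consensus_threshold MCMC consensus support threshold (default 0.3).
#' @param kda_fdr key-driver FDR cutoff (default 0.05).
#' @param kda_h key-driver neighborhood depth (default 6).
#' @param n_chains,n_iter,max_parents MCMC settings for the pipeline run.
#' @param n_mimics,n_reversers,n_nulls,concordance compendium settings.
#' @param synthetic run in synthetic mode (the only mode of the bundled
#'   runner; file-driven stages accept user tables via the reader functions).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("anchornet_run_"),
                            n_genes = 20, mean_out_degree = 2, n_tfs = 3,
                            n_samples = 300, cohorts = c("cohortA", "cohortB"),
                            kd_delta = 3, n_per_group = 50, n_replicates = 3,
                            true_hr = 2, censor_frac = 0.3,
                            de_fdr = 0.05, de_fc = 1.3, min_support = 2,
                            rho_cutoff = 0.2, consensus_threshold = 0.3,
                            kda_fdr = 0.05, kda_h = 6,
                            n_chains = 25, n_iter = 200000, max_parents = 3,
                            n_mimics = 1, n_reversers = 1, n_nulls = 10,
                            concordance = 1, synthetic = TRUE) {
  assert_prob(de_fdr, "de_fdr"); assert_prob(kda_fdr, "kda_fdr")
  if (de_fc <= 1) stop("`de_fc` must be > 1", call. = FALSE)
  if (consensus_threshold < 0 || consensus_threshold >= 1)
    stop("`consensus_threshold` must be in [0, 1)", call. = FALSE)
  if (rho_cutoff < 0 || rho_cutoff > 1)
    stop("`rho_cutoff` must be in [0, 1]", call. = FALSE)
  if (censor_frac < 0 || censor_frac >= 1)
    stop("`censor_frac` must be in [0, 1)", call. = FALSE)
  if (true_hr <= 0) stop("`true_hr` must be > 0", call. = FALSE)
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the synthetic end-to-end analysis
#'
#' Executes the full pipeline on data generated from one seeded ground-truth
#' network: cohort simulation, tumor-vs-normal differential expression and
#' cross-cohort meta-analysis, knockdown replicates and the consensus
#' signature, anchor correlation, survival stratification (KM, log-rank,
#' Cox), drug-compendium construction and connectivity query, per-cohort
#' MCMC network learning with consensus and union, shortest-path subnetwork
#' extraction, layer-wise enrichment and key-driver analysis. Every artifact
#' is written under `config$out_dir` together with a JSON manifest (seeds,
#' thresholds, file digests); rerunning with the same config reproduces all
#' tables byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with the in-memory results and `manifest` path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!isTRUE(config$synthetic))
    stop("the bundled runner operates in synthetic mode; use the reader ",
         "functions and stage functions directly for user data", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- setNames(derive_seeds(config$seed, 8L),
                    c("dag", "cohort", "knockdown", "survival", "compendium",
                      "mcmc", "cna", "spare"))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }
  res <- list(seeds = seeds)
  paths <- character(0)

  run_stage("simulate", {
    res$net <- generate_true_dag(config$n_genes, config$mean_out_degree,
                                 config$n_tfs, seed = seeds["dag"])
    anchor <- names(res$net$roles)[res$net$roles == "anchor"]
    res$anchor <- anchor
    cseeds <- derive_seeds(seeds["cohort"], length(config$cohorts))
    # per cohort: a control arm ("tumor-like", anchor fully expressed) and a
    # comparison arm with the anchor's exogenous input shifted down
    res$cohorts <- lapply(seq_along(config$cohorts), function(k) {
      kd <- simulate_knockdown_signature(res$net, anchor, config$kd_delta,
                                         config$n_samples, seed = cseeds[k])
      colnames(kd$expr) <- sprintf("%s_%s", config$cohorts[k],
                                   colnames(kd$expr))
      kd
    })
    names(res$cohorts) <- config$cohorts
    for (k in seq_along(res$cohorts)) {
      p <- file.path(config$out_dir,
                     sprintf("expression_%s.tsv", config$cohorts[k]))
      write_expression(res$cohorts[[k]]$expr, p)
      paths <- c(paths, p)
    }
    p <- file.path(config$out_dir, "true_network.tsv")
    write_network(res$net$edges, p); paths <- c(paths, p)
    pipeline_log("simulate", "network %d nodes / %d edges, anchor %s, %d cohorts",
                 config$n_genes, nrow(res$net$edges), anchor,
                 length(config$cohorts))
  })

  run_stage("de", {
    res$de <- lapply(res$cohorts, function(co)
      differential_expression(co$expr,
                              colnames(co$expr)[co$group == "control"],
                              colnames(co$expr)[co$group == "knockdown"]))
    for (k in seq_along(res$de)) {
      p <- file.path(config$out_dir, sprintf("de_%s.tsv", names(res$de)[k]))
      write.table(res$de[[k]], p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    }
  })

  run_stage("meta", {
    res$meta <- meta_combine(res$de)
    p <- file.path(config$out_dir, "meta.tsv")
    write.table(res$meta, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    pipeline_log("meta", "top meta gene: %s (score %.2f)",
                 res$meta$gene[1], res$meta$score[1])
  })

  run_stage("signature", {
    kseeds <- derive_seeds(seeds["knockdown"], config$n_replicates)
    res$knockdowns <- lapply(kseeds, function(s)
      simulate_knockdown_signature(res$net, res$anchor, config$kd_delta,
                                   config$n_per_group, seed = s))
    kd_de <- lapply(res$knockdowns, function(kd)
      differential_expression(kd$expr,
                              colnames(kd$expr)[kd$group == "knockdown"],
                              colnames(kd$expr)[kd$group == "control"]))
    res$signature <- consensus_signature(kd_de, config$de_fdr, config$de_fc,
                                         config$min_support)
    p <- file.path(config$out_dir, "signature.gmt")
    write_signature_gmt(res$signature, p, "knockdown"); paths <- c(paths, p)
    pipeline_log("signature", "%d up / %d down genes",
                 length(res$signature$up), length(res$signature$down))
  })

  run_stage("correlate", {
    res$correlation <- correlate_anchor(res$cohorts[[1]]$expr, res$anchor,
                                        rho_cutoff = config$rho_cutoff)
    p <- file.path(config$out_dir, "anchor_correlation.tsv")
    write.table(res$correlation, p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  })

  run_stage("survival", {
    ctrl <- res$cohorts[[1]]$group == "control"
    expr <- res$cohorts[[1]]$expr[res$anchor, ctrl]
    res$survival <- simulate_survival_times(expr, config$true_hr,
                                            config$censor_frac,
                                            seed = seeds["survival"])
    res$logrank <- logrank_test(res$survival)
    res$cox <- cox_hazard_ratio(res$survival)
    p <- file.path(config$out_dir, "survival.csv")
    write_survival(res$survival, p); paths <- c(paths, p)
    p <- file.path(config$out_dir, "cox_fit.tsv")
    write.table(as.data.frame(res$cox), p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
    pipeline_log("survival", "Cox HR %.2f (p %.3g), log-rank p %.3g",
                 res$cox$hr, res$cox$p, res$logrank$p)
  })

  run_stage("connect", {
    res$compendium <- simulate_drug_compendium(
      res$signature, config$n_mimics, config$n_reversers, config$n_nulls,
      config$concordance, seed = seeds["compendium"])
    res$connectivity <- query_compendium(res$compendium, res$signature)
    p <- file.path(config$out_dir, "connectivity.tsv")
    write.table(res$connectivity, p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
    pipeline_log("connect", "top instance: %s (s = %.3f)",
                 res$connectivity$instance[1], res$connectivity$s[1])
  })

  run_stage("network", {
    constraints <- prior_constraints(res$net$tf_pairs)
    mseeds <- derive_seeds(seeds["mcmc"], length(res$cohorts))
    res$consensus <- lapply(seq_along(res$cohorts), function(k) {
      co <- res$cohorts[[k]]
      cfg <- chain_config(n_chains = config$n_chains, n_iter = config$n_iter,
                          burn_in = floor(0.8 * config$n_iter),
                          seed = mseeds[k], max_parents = config$max_parents)
      chains <- mcmc_sample_networks(co$expr[, co$group == "control"],
                                     constraints, cfg)
      consensus_network(chains, config$consensus_threshold)
    })
    names(res$consensus) <- names(res$cohorts)
    res$super <- union_networks(res$consensus)
    for (k in seq_along(res$consensus)) {
      p <- file.path(config$out_dir,
                     sprintf("consensus_%s.tsv", names(res$consensus)[k]))
      write_network(res$consensus[[k]], p); paths <- c(paths, p)
    }
    p <- file.path(config$out_dir, "super_network.tsv")
    write_network(res$super, p); paths <- c(paths, p)
    pipeline_log("network", "super network: %d edges over %d nodes",
                 nrow(res$super$edges), length(res$super$nodes))
  })

  run_stage("subnetwork", {
    esg <- unique(res$net$tf_pairs$target)
    if (!length(esg)) esg <- res$signature$down
    res$esg <- esg
    res$subnetwork <- shortest_path_subnetwork(res$super, res$anchor, esg)
    p <- file.path(config$out_dir, "subnetwork_edges.tsv")
    write.table(res$subnetwork$edges, p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
    p <- file.path(config$out_dir, "subnetwork_nodes.tsv")
    write.table(res$subnetwork$nodes, p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  })

  run_stage("enrichment", {
    sig_dn <- res$signature$down
    if (length(sig_dn)) {
      res$layer_enrichment <- layer_enrichment_profile(
        res$super, res$anchor, sig_dn, k_max = config$kda_h,
        universe = res$net$nodes)
      p <- file.path(config$out_dir, "layer_enrichment.tsv")
      write.table(res$layer_enrichment, p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      paths <- c(paths, p)
    } else pipeline_log("enrichment", "empty down-signature; skipped")
  })

  run_stage("kda", {
    res$kda <- key_driver_analysis(res$super, res$esg, h = config$kda_h,
                                   fdr_cutoff = config$kda_fdr)
    p <- file.path(config$out_dir, "kda.tsv")
    write.table(res$kda, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    pipeline_log("kda", "%d driver(s) at FDR < %g", sum(res$kda$is_driver),
                 config$kda_fdr)
  })

  manifest <- list(
    package = "anchornet",
    version = as.character(utils::packageVersion("anchornet")),
    seed = config$seed,
    stage_seeds = as.list(seeds),
    thresholds = unclass(config)[c("de_fdr", "de_fc", "min_support",
                                   "rho_cutoff", "consensus_threshold",
                                   "kda_fdr", "kda_h")],
    scenario = unclass(config)[c("n_genes", "mean_out_degree", "n_tfs",
                                 "n_samples", "cohorts", "kd_delta",
                                 "n_per_group", "n_replicates", "true_hr",
                                 "censor_frac", "n_chains", "n_iter",
                                 "max_parents", "n_mimics", "n_reversers",
                                 "n_nulls", "concordance")],
    files = as.list(setNames(unname(tools::md5sum(paths)), basename(paths))))
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  res$manifest <- mpath
  res$files <- paths
  pipeline_log("done", "manifest written to %s", mpath)
  invisible(res)
}

#' Replay a pipeline manifest
#'
#' Reruns the pipeline with the seed and scenario recorded in a manifest and
#' verifies that every output file reproduces its recorded digest.
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [run_pipeline()].
#' @param out_dir directory for the replayed run (default: a fresh tempdir).
#' @return logical: TRUE when every digest matches; the replayed result list
#'   in attribute `result`.
#' @export
replay_manifest <- function(manifest_path, out_dir = tempfile("anchornet_replay_")) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- do.call(pipeline_config,
                 c(list(seed = m$seed, out_dir = out_dir),
                   m$thresholds, m$scenario))
  res <- run_pipeline(cfg)
  new_digests <- tools::md5sum(res$files)
  names(new_digests) <- basename(res$files)
  ok <- identical(as.list(new_digests[names(m$files)]), as.list(unlist(m$files)))
  structure(ok, result = res)
}
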