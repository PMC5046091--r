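#' Validate and normalize a pipeline configuration
#'
#' Accepts either a YAML file path or a list, fills in the analysis
#' defaults (alpha 0.05, k_min 3, require_direction TRUE, B 5000
#' permutations, promoter window 1500/500, motif p-threshold 0.05, top
#' fraction 0.01, enrichment FDR 0.05) and rejects contradictions: missing
#' dataset paths, `k_min` larger than the number of datasets, or an empty
#' dataset list.
#'
#' Expected structure: `datasets`: list of entries with `path`,
#' `groups_path`, optional `log2_input`, `include_samples`, `id`;
#' `consensus`: alpha / k_min / require_direction / B / seed;
#' `databases`: validated / predicted / tf_mirna paths; `motif_scan`:
#' motifs / promoters / tss paths + upstream / downstream / p_threshold /
#' top_fraction; `enrichment`: gmt path + fdr; `out_dir`.
#'
#' @param cfg list or path to a YAML config file.
#' @return The validated config list (class `PipelineConfig`).
#' @export
validate_config <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  if (!is.list(cfg) || !length(cfg))
    stop("empty config; required fields: datasets, out_dir", call. = FALSE)
  if (is.null(cfg$datasets) || !length(cfg$datasets))
    stop("config must list at least one dataset", call. = FALSE)
  if (is.null(cfg$out_dir))
    stop("config must name an output directory (out_dir)", call. = FALSE)
  defaults <- list(alpha = 0.05, k_min = 3L, require_direction = TRUE,
                   B = 5000L, seed = 1L)
  cfg$consensus <- utils::modifyList(defaults,
                                     as.list(cfg$consensus %||% list()))
  ms_defaults <- list(upstream = 1500L, downstream = 500L,
                      p_threshold = 0.05, top_fraction = 0.01)
  cfg$motif_scan <- utils::modifyList(ms_defaults,
                                      as.list(cfg$motif_scan %||% list()))
  cfg$enrichment <- utils::modifyList(list(fdr = 0.05),
                                      as.list(cfg$enrichment %||% list()))
  if (cfg$consensus$k_min > length(cfg$datasets))
    stop("k_min (", cfg$consensus$k_min, ") exceeds the number of datasets (",
         length(cfg$datasets), ")", call. = FALSE)
  for (i in seq_along(cfg$datasets)) {
    d <- cfg$datasets[[i]]
    if (is.null(d$path) || is.null(d$groups_path))
      stop("dataset ", i, ": path and groups_path are required",
           call. = FALSE)
    for (p in c(d$path, d$groups_path))
      if (!file.exists(p)) stop("dataset ", i, ": missing file ", p,
                                call. = FALSE)
    if (is.null(d$id)) cfg$datasets[[i]]$id <- paste0("dataset", i)
  }
  structure(cfg, class = "PipelineConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the staged consensus-network analysis
#'
#' Executes the full pipeline on a validated config: read and preprocess
#' the expression datasets, per-dataset differential expression, consensus
#' selection, permutation tests (overlap-only and directional), target
#' database filtering and merging, feedback-partner augmentation, optional
#' promoter motif scanning, signed network assembly, loop enumeration,
#' gene-set enrichment and subnetwork extraction. Every artifact is written
#' under `cfg$out_dir` and recorded (with an md5 content hash) in
#' `manifest.json`. All randomness derives from `cfg$consensus$seed`, fanned
#' out to the stages by fixed offsets so stages can be rerun in isolation.
#'
#' @param cfg a config accepted by [validate_config()].
#' @param skip_motif_scan logical; skip the promoter-scanning stage (the
#'   network is then built from the validated/predicted target tables and
#'   curated TF records only).
#' @return The manifest, invisibly: list of stage -> named file paths.
#' @export
run_pipeline <- function(cfg, skip_motif_scan = FALSE) {
  cfg <- validate_config(cfg)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  log_stage <- function(...) message("[mirnetcons] ", sprintf(...))
  emit <- function(stage, name, path) {
    manifest[[stage]] <- c(manifest[[stage]],
                           stats::setNames(list(path), name))
    assign("manifest", manifest, envir = parent.env(environment()))
  }

  ## preprocess + per-dataset DE
  de_tables <- list(); universes <- list(); directions <- list()
  for (d in cfg$datasets) {
    ds <- read_expression_matrix(d$path, d$groups_path,
                                 log2_input = isTRUE(d$log2_input),
                                 include_samples = d$include_samples,
                                 dataset_id = d$id)
    de <- differential_expression(ds)
    de_tables[[d$id]] <- de
    universes[[d$id]] <- de$feature
    directions[[d$id]] <- stats::setNames(de$direction, de$feature)
    de_path <- file.path(out, paste0("de_", d$id, ".tsv"))
    utils::write.table(de, de_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit("de", d$id, de_path)
    log_stage("DE %s: %d features, %d significant at alpha=%g", d$id,
              nrow(de), sum(de$p_value <= cfg$consensus$alpha),
              cfg$consensus$alpha)
  }

  ## consensus + permutation tests
  ccfg <- consensus_config(cfg$consensus$alpha, cfg$consensus$k_min,
                           cfg$consensus$require_direction)
  cons <- consensus_select(de_tables, ccfg)
  cons_path <- file.path(out, "consensus.tsv")
  utils::write.table(cons, cons_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  emit("consensus", "consensus", cons_path)
  log_stage("consensus: %d pass overlap, %d pass direction",
            sum(cons$passes_overlap), sum(cons$passes_direction))
  de_sets <- lapply(de_tables, function(tab)
    tab$feature[tab$p_value <= ccfg$alpha])
  perm_overlap <- permutation_consensus_test(
    universes, de_sets, consensus_config(ccfg$alpha, ccfg$k_min, FALSE),
    B = cfg$consensus$B, seed = cfg$consensus$seed + 100L)
  perm_dir <- permutation_consensus_test(
    universes, de_sets, consensus_config(ccfg$alpha, ccfg$k_min, TRUE),
    B = cfg$consensus$B, seed = cfg$consensus$seed + 101L,
    directions = directions)
  perm_path <- file.path(out, "permutation.json")
  jsonlite::write_json(list(
    overlap = perm_summary(perm_overlap),
    directional = perm_summary(perm_dir)),
    perm_path, auto_unbox = TRUE, digits = NA)
  emit("permutation", "permutation", perm_path)
  log_stage("permutation: overlap T=%d p%s%g; directional T=%d p%s%g",
            perm_overlap$observed,
            if (perm_overlap$p_is_bound) "<" else "=",
            perm_overlap$p_report, perm_dir$observed,
            if (perm_dir$p_is_bound) "<" else "=", perm_dir$p_report)

  ## target integration
  edge_sets <- list(); tfregs <- NULL
  if (!is.null(cfg$databases)) {
    validated <- filter_validated(read_edge_table(cfg$databases$validated))
    predicted <- filter_predicted(read_edge_table(cfg$databases$predicted))
    target_edges <- merge_target_edges(validated, predicted)
    log_stage("targets: %d validated, %d predicted, %d merged",
              nrow(validated), nrow(predicted), nrow(target_edges))
    if (!is.null(cfg$databases$tf_mirna)) {
      tfregs <- read_edge_table(cfg$databases$tf_mirna)
      tfregs$feedback <- isTRUE_vec(tfregs$feedback)
      target_edges <- feedback_partner_edges(tfregs, target_edges)
      log_stage("targets: %d after feedback-partner augmentation",
                nrow(target_edges))
    }
    te_path <- file.path(out, "target_edges.tsv")
    utils::write.table(target_edges, te_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit("integration", "target_edges", te_path)
    edge_sets$targets <- target_edges
    if (!is.null(tfregs)) {
      edge_sets$tf_mirna <- data.frame(
        src = toupper(tfregs$tf), dst = tfregs$mirna,
        sign = normalize_sign(tfregs$sign), category = "tf_mirna",
        evidence = "validated", stringsAsFactors = FALSE)
    }
  }

  ## motif scan
  if (!skip_motif_scan && !is.null(cfg$motif_scan$motifs)) {
    motifs <- read_motifs_meme(cfg$motif_scan$motifs)
    proms <- read_fasta(cfg$motif_scan$promoters)
    hits <- scan_promoters(proms, motifs,
                           p_threshold = cfg$motif_scan$p_threshold)
    hits_path <- file.path(out, "tf_hits.tsv")
    utils::write.table(hits, hits_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit("motif_scan", "tf_hits", hits_path)
    predicted_tf <- rank_and_truncate(hits, cfg$motif_scan$top_fraction)
    pred_path <- file.path(out, "tf_predicted.tsv")
    utils::write.table(predicted_tf, pred_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit("motif_scan", "tf_predicted", pred_path)
    log_stage("motif scan: %d hits, %d pairs retained after top-%g%%",
              nrow(hits), nrow(predicted_tf),
              100 * cfg$motif_scan$top_fraction)
    if (nrow(predicted_tf)) {
      mirna_like <- grepl("^(hsa-)?(miR|let|mir)", predicted_tf$target)
      edge_sets$tf_predicted <- data.frame(
        src = predicted_tf$tf, dst = predicted_tf$target,
        sign = 1L,
        category = ifelse(mirna_like, "tf_mirna", "tf_gene"),
        evidence = "predicted", stringsAsFactors = FALSE)
    }
  }

  ## network + loops
  overrides <- if (!is.null(tfregs))
    data.frame(src = toupper(tfregs$tf), dst = tfregs$mirna,
               sign = tfregs$sign, stringsAsFactors = FALSE)
  net <- assemble_network(edge_sets, overrides = overrides)
  net_dir <- file.path(out, "network")
  write_network(net, net_dir)
  emit("network", "network", net_dir)
  summ <- network_summary(net)
  jsonlite::write_json(summ, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  emit("network", "summary", file.path(out, "summary.json"))
  log_stage("network: %d nodes, %d edges", summ$n_nodes, summ$n_edges)
  fbl <- find_feedback_loops(net)
  ffl <- find_feedforward_loops(net)
  utils::write.table(fbl, file.path(out, "loops_fbl.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ffl, file.path(out, "loops_ffl.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  emit("loops", "fbl", file.path(out, "loops_fbl.tsv"))
  emit("loops", "ffl", file.path(out, "loops_ffl.tsv"))
  log_stage("loops: %d FBLs, %d FFLs (%d coherent)", nrow(fbl), nrow(ffl),
            sum(ffl$coherent))

  ## enrichment + subnetworks
  if (!is.null(cfg$enrichment$gmt)) {
    sets <- read_gene_sets_gmt(cfg$enrichment$gmt)
    is_gene <- vapply(net$nodes, function(r) !"mirna" %in% r, logical(1))
    query <- names(net$nodes)[is_gene]
    enr <- hypergeometric_enrichment(query, sets, fdr = cfg$enrichment$fdr)
    enr_path <- file.path(out, "enrichment.tsv")
    utils::write.table(enr, enr_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit("enrichment", "enrichment", enr_path)
    log_stage("enrichment: %d terms tested, %d enriched at FDR<=%g",
              nrow(enr), sum(enr$enriched), cfg$enrichment$fdr)
    sub_dir <- file.path(out, "subnetworks")
    dir.create(sub_dir, showWarnings = FALSE)
    enriched_terms <- enr$term_id[enr$enriched]
    subs <- list()
    for (term in enriched_terms) {
      sn <- extract_subnetwork(net, sets[[term]]$genes)
      subs[[term]] <- sn
      sif <- data.frame(src = sn$edges$src,
                        sign = ifelse(sn$edges$sign > 0, "activation",
                                      "repression"),
                        dst = sn$edges$dst)
      sif_path <- file.path(sub_dir, paste0(gsub("[^A-Za-z0-9._-]", "_",
                                                 term), ".sif"))
      utils::write.table(sif, sif_path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      emit("subnetworks", term, sif_path)
    }
    if (length(subs)) {
      mtm <- mirna_term_matrix(subs)
      mtm_path <- file.path(out, "mirna_term_matrix.tsv")
      utils::write.table(
        data.frame(term = rownames(mtm), mtm, check.names = FALSE),
        mtm_path, sep = "\t", quote = FALSE, row.names = FALSE)
      emit("subnetworks", "mirna_term_matrix", mtm_path)
    }
  }

  ## manifest with content hashes
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out, "manifest.json"))
  hashes <- tools::md5sum(files)
  manifest_json <- list(
    stages = lapply(manifest, function(s) lapply(s, as.character)),
    files = stats::setNames(as.list(unname(hashes)),
                            sub(paste0("^", out, "/?"), "", files)))
  jsonlite::write_json(manifest_json, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest_json)
}

perm_summary <- function(p) {
  list(observed = p$observed, B = p$B, exceedances = p$exceedances,
       p_report = p$p_report, p_is_bound = p$p_is_bound,
       null_mean = mean(p$null_counts), null_max = max(p$null_counts))
}
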