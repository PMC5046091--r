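#' Specification of a synthetic multi-dataset expression study
#'
#' Describes the simulated study: a number of case/control microarray
#' datasets with partially overlapping feature universes and planted
#' differential-expression signals. Defaults emulate a four-platform blood
#' miRNA study: 850 measured features per platform (microarray platforms of
#' the era carried fewer than 900 mature miRNA identifiers), per-dataset
#' group sizes spanning small (8 vs 8) to large (70 vs 23) cohorts, and
#' three classes of planted features: `consensus` (differentially expressed
#' with a consistent direction in at least 3 datasets), `inconsistent`
#' (significant in >= 3 datasets but with conflicting directions) and
#' `sporadic` (significant in at most 2 datasets).
#'
#' Intensities are lognormal: each feature has a lognormal baseline mean,
#' samples scatter around it with log-scale standard deviation `noise_sd`,
#' and planted case samples are multiplied (direction up) or divided
#' (direction down) by `effect_size`, so that the ratio-of-means
#' fold-change targets `effect_size` in expectation.
#'
#' @param n_datasets number of datasets.
#' @param universe_size features measured per platform.
#' @param universe_overlap_fraction fraction of each platform's universe
#'   drawn from a core shared by all platforms; the rest is
#'   platform-private.
#' @param n_case,n_control per-dataset group sizes (recycled to
#'   `n_datasets`).
#' @param n_true_consensus,n_inconsistent,n_sporadic planted feature counts
#'   per class.
#' @param effect_size multiplicative case shift delta > 1.
#' @param noise_sd log-scale (natural log) standard deviation of sample
#'   noise.
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of the
#'   per-feature baseline mean.
#' @param feature_prefix prefix for generated feature names.
#' @param seed integer seed; all outputs are pure functions of
#'   (spec, seed).
#' @return A `SimulationSpec` list.
#' @export
simulation_spec <- function(n_datasets = 4L, universe_size = 850L,
                            universe_overlap_fraction = 0.5,
                            n_case = c(20L, 59L, 23L, 8L),
                            n_control = c(21L, 37L, 70L, 8L),
                            n_true_consensus = 18L, n_inconsistent = 21L,
                            n_sporadic = 60L, effect_size = 2,
                            noise_sd = 0.5,
                            baseline_meanlog = 5, baseline_sdlog = 1,
                            feature_prefix = "miR-sim-", seed = 1L) {
  stopifnot(n_datasets >= 1, universe_size >= 1,
            universe_overlap_fraction > 0, universe_overlap_fraction <= 1,
            effect_size > 1, noise_sd > 0,
            n_true_consensus >= 0, n_inconsistent >= 0, n_sporadic >= 0)
  n_case <- rep_len(as.integer(n_case), n_datasets)
  n_control <- rep_len(as.integer(n_control), n_datasets)
  stopifnot(all(n_case >= 2), all(n_control >= 2))
  shared <- round(universe_size * universe_overlap_fraction)
  planted <- n_true_consensus + n_inconsistent + n_sporadic
  if (planted > shared)
    stop("infeasible spec: ", planted, " planted features exceed the ",
         shared, "-feature shared universe", call. = FALSE)
  structure(list(n_datasets = as.integer(n_datasets),
                 universe_size = as.integer(universe_size),
                 universe_overlap_fraction = universe_overlap_fraction,
                 n_case = n_case, n_control = n_control,
                 n_true_consensus = as.integer(n_true_consensus),
                 n_inconsistent = as.integer(n_inconsistent),
                 n_sporadic = as.integer(n_sporadic),
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 feature_prefix = feature_prefix,
                 seed = as.integer(seed)),
            class = "SimulationSpec")
}

#' Simulate multi-platform expression datasets with planted signals
#'
#' Generates `spec$n_datasets` case/control expression datasets on
#' partially overlapping feature universes (a shared core plus
#' platform-private features), plants the differential-expression classes
#' described in [simulation_spec()] into the shared core, and records the
#' ground truth.
#'
#' @param spec a [simulation_spec()].
#' @return A list with `datasets` (list of `ExpressionDataset`) and `truth`
#'   (list: `features` data.frame with feature, class, direction;
#'   `directions` feature x dataset matrix of "up"/"down"/NA for planted
#'   effects).
#' @export
simulate_expression_datasets <- function(spec) {
  # sample() treats a length-1 numeric as 1:n; this helper never does
  resample <- function(x) x[sample.int(length(x), 1L)]
  set.seed(spec$seed)
  n_shared <- round(spec$universe_size * spec$universe_overlap_fraction)
  n_private <- spec$universe_size - n_shared
  total_feat <- n_shared + n_private * spec$n_datasets
  feats <- sprintf("%s%04d", spec$feature_prefix, seq_len(total_feat))
  shared <- feats[seq_len(n_shared)]
  universes <- lapply(seq_len(spec$n_datasets), function(d) {
    priv <- feats[n_shared + (d - 1L) * n_private + seq_len(n_private)]
    c(shared, priv)
  })
  # plant into the shared core
  n_pl <- c(consensus = spec$n_true_consensus,
            inconsistent = spec$n_inconsistent,
            sporadic = spec$n_sporadic)
  planted <- if (sum(n_pl)) sample(shared, sum(n_pl)) else character(0)
  class_of <- rep(names(n_pl), n_pl)
  dirmat <- matrix(NA_character_, nrow = length(planted),
                   ncol = spec$n_datasets,
                   dimnames = list(planted, paste0("dataset", 1:spec$n_datasets)))
  k_min_plant <- min(3L, spec$n_datasets)
  for (i in seq_along(planted)) {
    cls <- class_of[i]
    if (cls == "consensus") {
      nd <- resample(k_min_plant:spec$n_datasets)
      ds <- sample(spec$n_datasets, nd)
      dirmat[i, ds] <- sample(c("up", "down"), 1)
    } else if (cls == "inconsistent") {
      nd <- resample(k_min_plant:spec$n_datasets)
      ds <- sample(spec$n_datasets, nd)
      dirs <- sample(c("up", "down"), nd, replace = TRUE)
      if (length(unique(dirs)) == 1L)  # force a conflict
        dirs[sample(nd, 1)] <- setdiff(c("up", "down"), dirs[1])
      dirmat[i, ds] <- dirs
    } else {
      nd <- resample(seq_len(min(2L, spec$n_datasets)))
      ds <- sample(spec$n_datasets, nd)
      dirmat[i, ds] <- sample(c("up", "down"), nd, replace = TRUE)
    }
  }
  baseline <- stats::setNames(
    stats::rlnorm(total_feat, spec$baseline_meanlog, spec$baseline_sdlog),
    feats)
  datasets <- lapply(seq_len(spec$n_datasets), function(d) {
    uni <- universes[[d]]
    nc <- spec$n_case[d]; nt <- spec$n_control[d]
    samples <- c(sprintf("case_%02d", seq_len(nc)),
                 sprintf("ctrl_%02d", seq_len(nt)))
    groups <- stats::setNames(rep(c("case", "control"), c(nc, nt)), samples)
    vals <- baseline[uni] *
      exp(matrix(stats::rnorm(length(uni) * (nc + nt), 0, spec$noise_sd),
                 nrow = length(uni)))
    dimnames(vals) <- list(uni, samples)
    pl_here <- planted[!is.na(dirmat[, d]) & planted %in% uni]
    if (length(pl_here)) {
      mult <- ifelse(dirmat[pl_here, d] == "up",
                     spec$effect_size, 1 / spec$effect_size)
      vals[pl_here, seq_len(nc)] <-
        vals[pl_here, seq_len(nc), drop = FALSE] * mult
    }
    expression_dataset(vals, groups, dataset_id = paste0("dataset", d))
  })
  names(datasets) <- paste0("dataset", seq_len(spec$n_datasets))
  truth_feats <- data.frame(
    feature = planted, class = class_of,
    direction = vapply(seq_along(planted), function(i) {
      d <- dirmat[i, ]; d <- d[!is.na(d)]
      if (length(unique(d)) == 1L) d[1] else "mixed"
    }, character(1)) , row.names = NULL, stringsAsFactors = FALSE)
  list(datasets = datasets,
       truth = list(features = truth_feats, directions = dirmat,
                    universes = stats::setNames(universes,
                                                names(datasets))))
}

#' Simulate interaction-database fixture tables
#'
#' Emits normalized validated-target, predicted-target and TF-miRNA tables
#' whose records deliberately exercise every filtering rule: TarBase
#' methods spanning reporter gene assay / microarray / sequencing,
#' miRTarBase support types strong and weak, prediction scores placed on
#' both sides of (and exactly at) the database cutoffs, pairs present above
#' cutoff in all three prediction databases versus only two, and TF-miRNA
#' regulations with activation/repression signs and feedback flags. The
#' returned truth lists which pairs must survive each filter.
#'
#' @param mirnas character vector of miRNA names to draw regulators from.
#' @param n_genes size of the invented target-gene pool.
#' @param n_validated,n_predicted_pairs,n_tf number of validated records,
#'   candidate predicted pairs, and TF-miRNA records.
#' @param seed integer seed.
#' @return A list: `validated`, `predicted`, `tf_mirna` (data.frames in the
#'   normalized schemas) and `truth` (expected surviving pair keys per
#'   filter).
#' @export
simulate_interaction_databases <- function(mirnas, n_genes = 60L,
                                           n_validated = 80L,
                                           n_predicted_pairs = 50L,
                                           n_tf = 10L, seed = 1L) {
  set.seed(seed)
  genes <- sprintf("GENE%03d", seq_len(n_genes))
  pair <- function(n) data.frame(
    mirna = sample(mirnas, n, replace = TRUE),
    gene = sample(genes, n, replace = TRUE), stringsAsFactors = FALSE)
  ## validated records
  vp <- unique(pair(n_validated))
  db <- sample(c("tarbase", "mirtarbase"), nrow(vp), replace = TRUE)
  method <- ifelse(db == "tarbase",
                   sample(c("reporter gene assay", "microarray",
                            "sequencing"), nrow(vp), replace = TRUE),
                   NA_character_)
  support <- ifelse(db == "mirtarbase",
                    sample(c("strong", "weak"), nrow(vp), replace = TRUE,
                           prob = c(.6, .4)),
                    NA_character_)
  validated <- data.frame(mirna = vp$mirna, gene = vp$gene, database = db,
                          method = method, support = support,
                          stringsAsFactors = FALSE)
  keep_v <- ifelse(db == "tarbase", method == "reporter gene assay",
                   support != "weak")
  ## predicted records: per pair, pick how many databases it appears in and
  ## whether each appearance passes its cutoff
  pp <- unique(pair(n_predicted_pairs))
  pp <- pp[!paste(pp$mirna, pp$gene) %in% paste(vp$mirna, vp$gene), ,
           drop = FALSE]
  dbs <- c("targetscan", "microt_cds", "mirdb")
  cutoffs <- c(targetscan = -0.19, microt_cds = 0.993, mirdb = 84)
  pred_rows <- list(); pass_all <- character(0)
  for (i in seq_len(nrow(pp))) {
    in_dbs <- sample(dbs, sample(1:3, 1))
    pass <- stats::setNames(sample(c(TRUE, FALSE), length(in_dbs),
                                   replace = TRUE, prob = c(.7, .3)),
                            in_dbs)
    # occasionally sit exactly on the boundary (counts as passing)
    boundary <- stats::runif(length(in_dbs)) < 0.15
    for (j in seq_along(in_dbs)) {
      d <- in_dbs[j]
      score <- if (boundary[j]) { pass[j] <- TRUE; cutoffs[[d]] }
      else switch(d,
        targetscan = if (pass[j]) stats::runif(1, -0.6, -0.20)
                     else stats::runif(1, -0.18, 0),
        microt_cds = if (pass[j]) stats::runif(1, 0.994, 1)
                     else stats::runif(1, 0.5, 0.992),
        mirdb = if (pass[j]) stats::runif(1, 85, 100)
                else stats::runif(1, 50, 83))
      pred_rows[[length(pred_rows) + 1L]] <- data.frame(
        mirna = pp$mirna[i], gene = pp$gene[i], database = d,
        score = score, stringsAsFactors = FALSE)
    }
    if (length(in_dbs) == 3L && all(pass))
      pass_all <- c(pass_all, paste(pp$mirna[i], toupper(pp$gene[i])))
  }
  predicted <- do.call(rbind, pred_rows)
  ## TF-miRNA regulations
  tfs <- sprintf("TF%02d", seq_len(n_tf))
  tf_mirna <- data.frame(
    tf = sample(tfs, n_tf), mirna = sample(mirnas, n_tf, replace = TRUE),
    sign = sample(c("activation", "repression"), n_tf, replace = TRUE),
    feedback = stats::runif(n_tf) < 0.3, stringsAsFactors = FALSE)
  tf_mirna <- unique(tf_mirna)
  list(validated = validated, predicted = predicted, tf_mirna = tf_mirna,
       truth = list(
         validated_pass = sort(unique(paste(vp$mirna[keep_v],
                                            toupper(vp$gene[keep_v])))),
         predicted_pass = sort(unique(pass_all))))
}

#' Simulate promoter sequences with planted motif sites
#'
#' Generates `n_promoters` background sequences of length 2000 (the
#' promoter-window length) with bases drawn i.i.d. from the motif set's
#' background distribution. A `plant_fraction` of the promoters receives,
#' at a recorded offset and strand, the maximal-probability consensus
#' string of a randomly chosen motif (reverse-complemented for minus-strand
#' plants). A fraction of the unplanted promoters carries a masked run of N
#' to exercise footprint skipping.
#'
#' @param motifs a `MotifSet`.
#' @param n_promoters number of sequences.
#' @param plant_fraction fraction of promoters that receive a planted site.
#' @param window_length promoter length in bases.
#' @param mask_fraction fraction of unplanted promoters given an N run.
#' @param promoter_names optional character vector naming the promoters
#'   (e.g. after the genes and miRNAs whose promoters they emulate);
#'   overrides `n_promoters`.
#' @param seed integer seed.
#' @return list: `sequences` (named character vector), `tss` (data.frame
#'   target, seq_name, tss, strand — identity windows), `sites` (data.frame
#'   tf, promoter, offset, strand of planted sites).
#' @export
simulate_promoters <- function(motifs, n_promoters = 20L,
                               plant_fraction = 0.5, window_length = 2000L,
                               mask_fraction = 0.2, promoter_names = NULL,
                               seed = 1L) {
  set.seed(seed)
  stopifnot(all(vapply(motifs$motifs, nrow, 0L) < window_length))
  bases <- c("A", "C", "G", "T")
  bg <- motifs$background
  ids <- if (!is.null(promoter_names)) unique(promoter_names)
         else sprintf("promoter%03d", seq_len(n_promoters))
  n_promoters <- length(ids)
  seqs <- vapply(ids, function(id)
    paste(sample(bases, window_length, replace = TRUE, prob = bg),
          collapse = ""), character(1))
  n_plant <- round(plant_fraction * n_promoters)
  planted_ids <- if (n_plant) sample(ids, n_plant) else character(0)
  sites <- list()
  for (id in planted_ids) {
    tf <- sample(names(motifs$motifs), 1)
    ppm <- motifs$motifs[[tf]]
    consensus <- paste(bases[apply(ppm, 1, which.max)], collapse = "")
    L <- nchar(consensus)
    offset <- sample(0:(window_length - L), 1)
    strand <- sample(c("+", "-"), 1)
    site <- if (strand == "+") consensus else revcomp(consensus)
    substr(seqs[id], offset + 1L, offset + L) <- site
    sites[[length(sites) + 1L]] <- data.frame(
      tf = tf, promoter = id, offset = offset, strand = strand,
      stringsAsFactors = FALSE)
  }
  unplanted <- setdiff(ids, planted_ids)
  masked <- unplanted[stats::runif(length(unplanted)) < mask_fraction]
  for (id in masked) {
    run <- 50L
    at <- sample(0:(window_length - run), 1)
    substr(seqs[id], at + 1L, at + run) <- strrep("N", run)
  }
  tss <- data.frame(target = ids, seq_name = ids, tss = 1500L,
                    strand = "+", stringsAsFactors = FALSE)
  sites <- if (length(sites)) do.call(rbind, sites)
  else data.frame(tf = character(), promoter = character(),
                  offset = integer(), strand = character())
  list(sequences = seqs, tss = tss, sites = sites)
}

#' Simulate a gene-set collection over a gene pool
#'
#' Builds a GMT-style collection: each term samples its genes from the
#' pool, with a bias towards a designated "signal" subset for the first
#' few terms so that enrichment of that subset is detectable.
#'
#' @param genes character vector, the gene pool (background).
#' @param signal_genes subset to over-represent in the first
#'   `n_signal_sets` terms.
#' @param n_sets number of terms.
#' @param n_signal_sets how many terms are biased towards `signal_genes`.
#' @param set_size_range min/max genes per term.
#' @param seed integer seed.
#' @return A `GeneSetCollection`.
#' @export
simulate_gene_sets <- function(genes, signal_genes = character(0),
                               n_sets = 15L, n_signal_sets = 3L,
                               set_size_range = c(8L, 25L), seed = 1L) {
  set.seed(seed)
  genes <- unique(toupper(genes))
  signal_genes <- intersect(unique(toupper(signal_genes)), genes)
  sets <- list()
  for (i in seq_len(n_sets)) {
    size <- sample(set_size_range[1]:set_size_range[2], 1)
    size <- min(size, length(genes))
    members <- if (i <= n_signal_sets && length(signal_genes)) {
      n_sig <- min(length(signal_genes), max(2L, round(size * 0.6)))
      unique(c(sample(signal_genes, n_sig),
               sample(genes, size - n_sig)))
    } else sample(genes, size)
    sets[[sprintf("TERM:%04d", i)]] <-
      list(name = sprintf("synthetic term %d", i), genes = members)
  }
  structure(sets, class = "GeneSetCollection")
}

#' Write a GeneSetCollection to GMT
#'
#' @param sets a `GeneSetCollection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id)
    paste(c(id, sets[[id]]$name, sets[[id]]$genes), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a complete synthetic study directory
#'
#' Emits every file the pipeline reads: per-dataset expression matrices and
#' group files, the interaction tables, a MEME motif file, promoter FASTA +
#' TSS table, and a GMT gene-set collection, plus `truth.json` recording
#' the planted ground truth.
#'
#' @param dir output directory.
#' @param spec a [simulation_spec()].
#' @param motifs optional `MotifSet`; a small built-in set is used when
#'   NULL.
#' @return The directory path, invisibly (attribute `truth`: the combined
#'   ground truth).
#' @export
write_study_fixtures <- function(dir, spec = simulation_spec(),
                                 motifs = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_expression_datasets(spec)
  for (d in names(sim$datasets)) {
    write_expression_matrix(sim$datasets[[d]],
                            file.path(dir, paste0(d, ".tsv")),
                            file.path(dir, paste0(d, "_groups.tsv")))
  }
  cons_feats <- sim$truth$features$feature[
    sim$truth$features$class == "consensus"]
  mirnas <- if (length(cons_feats)) cons_feats else
    sim$truth$universes[[1]][1:5]
  dbs <- simulate_interaction_databases(mirnas, n_genes = 150L,
                                        n_validated = 120L,
                                        n_predicted_pairs = 80L,
                                        seed = spec$seed + 1L)
  utils::write.table(dbs$validated, file.path(dir, "validated_targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dbs$predicted, file.path(dir, "predicted_targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dbs$tf_mirna, file.path(dir, "tf_mirna.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (is.null(motifs))
    motifs <- simulate_motif_set(12L, seed = spec$seed + 4L)
  write_motifs_meme(motifs, file.path(dir, "motifs.meme"))
  # genes that survive the target filters: these form the network, so
  # promoters are named after them (and the consensus miRNAs) and the
  # signal gene sets over-represent them
  pass_pairs <- unique(c(dbs$truth$validated_pass,
                         dbs$truth$predicted_pass))
  net_genes <- unique(sub("^\\S+ ", "", pass_pairs))
  prom_names <- c(mirnas, utils::head(net_genes, 60))
  prom <- simulate_promoters(motifs, promoter_names = prom_names,
                             plant_fraction = 0.3, seed = spec$seed + 2L)
  # co-regulation structure: a curated TF whose motif is in the scanned
  # set also gets sites planted in the promoter of its regulated miRNA
  # and of up to two of that miRNA's targets, emulating TFs that regulate
  # both a miRNA and the miRNA's targets
  set.seed(spec$seed + 5L)
  bases <- c("A", "C", "G", "T")
  occupied <- lapply(split(seq_len(nrow(prom$sites)),
                           prom$sites$promoter),
                     function(i) cbind(prom$sites$offset[i],
                                       prom$sites$offset[i] + 12L))
  plant <- function(tf, promoter) {
    ppm <- motifs$motifs[[tf]]
    L <- nrow(ppm)
    site <- paste(bases[apply(ppm, 1, which.max)], collapse = "")
    offset <- sample(0:(nchar(prom$sequences[[promoter]]) - L), 1)
    taken <- occupied[[promoter]]
    if (!is.null(taken) &&
        any(offset < taken[, 2] & offset + L > taken[, 1])) return()
    substr(prom$sequences[[promoter]], offset + 1L, offset + L) <<- site
    occupied[[promoter]] <<- rbind(taken, c(offset, offset + L))
    prom$sites <<- rbind(prom$sites, data.frame(
      tf = tf, promoter = promoter, offset = offset, strand = "+",
      stringsAsFactors = FALSE))
  }
  for (r in seq_len(min(6L, nrow(dbs$tf_mirna)))) {
    tf <- dbs$tf_mirna$tf[r]; mir <- dbs$tf_mirna$mirna[r]
    if (!tf %in% names(motifs$motifs) || !mir %in% prom_names) next
    plant(tf, mir)
    mir_targets <- sub("^\\S+ ", "",
                       pass_pairs[startsWith(pass_pairs,
                                             paste0(mir, " "))])
    for (g in utils::head(intersect(mir_targets, prom_names), 2))
      plant(tf, g)
  }
  write_fasta(prom$sequences, file.path(dir, "promoters.fasta"))
  utils::write.table(prom$tss, file.path(dir, "tss.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gene_pool <- unique(toupper(c(dbs$validated$gene, dbs$predicted$gene)))
  gmt <- simulate_gene_sets(gene_pool, signal_genes = net_genes,
                            seed = spec$seed + 3L)
  write_gene_sets_gmt(gmt, file.path(dir, "gene_sets.gmt"))
  truth <- list(expression = sim$truth,
                interactions = dbs$truth, sites = prom$sites)
  jsonlite::write_json(
    list(planted = sim$truth$features,
         validated_pass = dbs$truth$validated_pass,
         predicted_pass = dbs$truth$predicted_pass,
         planted_sites = prom$sites),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  out <- dir
  attr(out, "truth") <- truth
  invisible(out)
}

#' Simulate a set of sharp binding motifs
#'
#' Generates position probability matrices around random consensus
#' strings: at each position the consensus base carries probability
#' `sharpness` and the other three bases share the remainder. Motif names
#' default to a TF-style series so they can coincide with the regulators
#' of a curated TF-miRNA table.
#'
#' @param n_motifs number of motifs.
#' @param motif_names names; defaults to TF01, TF02, ...
#' @param length_range min/max motif length in bases.
#' @param sharpness consensus-base probability per position.
#' @param background background distribution over A, C, G, T.
#' @param seed integer seed.
#' @return A `MotifSet`.
#' @export
simulate_motif_set <- function(n_motifs = 12L,
                               motif_names = sprintf("TF%02d",
                                                     seq_len(n_motifs)),
                               length_range = c(8L, 12L),
                               sharpness = 0.85,
                               background = c(A = .25, C = .25, G = .25,
                                              T = .25),
                               seed = 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  motifs <- lapply(seq_len(n_motifs), function(i) {
    L <- sample(length_range[1]:length_range[2], 1)
    cons <- sample(bases, L, replace = TRUE)
    m <- matrix((1 - sharpness) / 3, nrow = L, ncol = 4,
                dimnames = list(NULL, bases))
    m[cbind(seq_len(L), match(cons, bases))] <- sharpness
    m
  })
  names(motifs) <- motif_names
  structure(list(motifs = motifs, background = background),
            class = "MotifSet")
}

# small, sharp motif set used when no MEME file is supplied
builtin_motifs <- function() {
  sharp <- function(cons) {
    m <- matrix(0.04, nrow = nchar(cons), ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
    idx <- match(strsplit(cons, "")[[1]], colnames(m))
    m[cbind(seq_len(nrow(m)), idx)] <- 0.88
    m
  }
  structure(list(motifs = list(TFA = sharp("ACGTACGTAC"),
                               TFB = sharp("GGGATTTCC"),
                               TFC = sharp("TGACGTCA")),
                 background = c(A = .25, C = .25, G = .25, T = .25)),
            class = "MotifSet")
}
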