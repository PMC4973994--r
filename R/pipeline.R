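# Orchestration of the stratified analyses (mother/child x labor/PROM/all):
# simulate or load inputs, QC, per-stratum association, clumping,
# enrichment, Manhattan-plot data and the top-SNP overlap report.

#' Select samples belonging to a stratum
#'
#' @param pheno Phenotype data frame (`sample_id`, `ga_days`, `onset`,
#'   `genome`).
#' @param onset `"labor"`, `"PROM"` or `"all"` (labor plus PROM).
#' @param genome `"mother"`, `"child"` or `"all"`.
#' @return Character vector of sample ids.
#' @export
stratify_samples <- function(pheno, onset = c("all", "labor", "PROM"),
                             genome = c("all", "mother", "child")) {
  onset <- match.arg(onset)
  genome <- match.arg(genome)
  stopifnot(all(c("onset", "genome") %in% names(pheno)),
            !anyNA(pheno$onset), !anyNA(pheno$genome))
  sel <- rep(TRUE, nrow(pheno))
  if (onset != "all") sel <- sel & pheno$onset == onset
  if (genome != "all") sel <- sel & pheno$genome == genome
  ids <- pheno$sample_id[sel]
  log_note("stratify", genome, "/", onset, ": ", length(ids), " sample(s)")
  ids
}

#' Overlap report for top-SNP lists
#'
#' Exact Venn-region counts among ranked SNP lists truncated to their top
#' `k` entries (e.g. the three onset strata within one genome type).
#'
#' @param ranked_lists Named list of character vectors of SNP ids, ranked
#'   best-first.
#' @param k Top-list size (default 1000); lists shorter than `k` are used
#'   in full with a log note.
#' @return Data frame with one row per Venn region (`region` names which
#'   lists contain the SNPs, joined by `&`) and the exact `count`.
#' @export
overlap_report <- function(ranked_lists, k = 1000L) {
  stopifnot(is.list(ranked_lists), length(ranked_lists) >= 2,
            !is.null(names(ranked_lists)))
  tops <- lapply(names(ranked_lists), function(nm) {
    x <- ranked_lists[[nm]]
    if (length(x) < k)
      log_note("overlap", "list '", nm, "' has only ", length(x),
               " SNPs; using all")
    utils::head(x, k)
  })
  names(tops) <- names(ranked_lists)
  all_snps <- unique(unlist(tops))
  member <- vapply(tops, function(s) all_snps %in% s,
                   logical(length(all_snps)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1)
  key <- apply(member, 1, function(r)
    paste(names(tops)[r], collapse = "&"))
  regions <- vapply(seq_len(2^length(tops) - 1), function(bits) {
    inset <- as.logical(bitwAnd(bits, 2^(seq_along(tops) - 1)))
    paste(names(tops)[inset], collapse = "&")
  }, character(1))
  counts <- vapply(regions, function(r) sum(key == r), integer(1))
  data.frame(region = regions, count = counts, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pipeline run configuration
#'
#' Either simulation-driven (`sim_cfg` + `corpus`) or file-driven (paths to
#' PED/MAP, phenotype TSV, gene map, GMT). Every stage seed is derived
#' deterministically from the global seed and the stage/stratum labels.
#'
#' @param sim_cfg Optional [sim_config()]; when given, all inputs are
#'   simulated.
#' @param corpus Optional [corpus_spec()] accompanying `sim_cfg`.
#' @param paths Optional named list for file-driven runs: `ped`, `map`,
#'   `ref` (optional), `pheno`, `gene_map`, `gene_sets`.
#' @param qc [qc_params()] or `NULL` to skip QC.
#' @param perm [permutation_params()].
#' @param clump [clump_params()].
#' @param enrich [enrichment_params()].
#' @param strata Data frame with columns `genome` and `onset`; default the
#'   six analyses mother/child x labor/PROM/all.
#' @param top_k_overlap Top-list size for the overlap report.
#' @param seed Global seed.
#' @param out_dir Optional output directory; when set, all result tables
#'   are written as TSV plus a JSON run manifest.
#' @return A `run_config` list.
#' @export
run_config <- function(sim_cfg = NULL, corpus = corpus_spec(),
                       paths = NULL,
                       qc = qc_params(), perm = permutation_params(),
                       clump = clump_params(), enrich = enrichment_params(),
                       strata = NULL, top_k_overlap = 1000L,
                       seed = 1L, out_dir = NULL) {
  if (is.null(sim_cfg) && is.null(paths))
    stop("run_config: provide sim_cfg or paths")
  if (is.null(strata))
    strata <- expand.grid(genome = c("mother", "child"),
                          onset = c("labor", "PROM", "all"),
                          stringsAsFactors = FALSE)
  structure(list(sim_cfg = sim_cfg, corpus = corpus, paths = paths,
                 qc = qc, perm = perm, clump = clump, enrich = enrich,
                 strata = strata, top_k_overlap = as.integer(top_k_overlap),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Simulate (or load) inputs, run QC, then for each configured stratum:
#' association under the three genetic models with adaptive permutations,
#' per-SNP min-p combination, greedy LD clumping, interval preparation and
#' gene-set enrichment; finally the Manhattan data tables and the top-SNP
#' overlap report per genome type. Re-running with the same configuration
#' reproduces every table exactly.
#'
#' @param config A [run_config()].
#' @return List: `inputs` (genotypes, phenotype, gene map, sets), `qc`
#'   (summary or NULL), `strata` (per stratum: `assoc`, `best`, `clumps`,
#'   `intervals`, `enrichment`, `manhattan`), `overlap` (per genome type),
#'   and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$sim_cfg)) {
    cfg <- config$sim_cfg
    G <- simulate_genotypes(cfg)
    pheno <- simulate_phenotype(G, cfg)
    ann <- simulate_annotation_and_corpus(cfg, config$corpus)
    gene_map <- ann$gene_map
    sets <- ann$sets
  } else {
    p <- config$paths
    G <- read_pedmap(p$ped, p$map, p$ref %||% NULL)
    pheno <- utils::read.table(p$pheno, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    gene_map <- read_gene_map(p$gene_map)
    sets <- read_gmt(p$gene_sets)
    ann <- NULL
  }

  qc_out <- NULL
  if (!is.null(config$qc)) {
    qp <- config$qc
    qp$seed <- derive_seed(config$seed, "qc")
    groups <- pheno$genome[match(G$samples$id, pheno$sample_id)]
    qc_out <- run_qc(G, qp, groups = groups)
    G <- qc_out$G
  }

  strata_res <- list()
  for (i in seq_len(nrow(config$strata))) {
    genome <- config$strata$genome[i]
    onset <- config$strata$onset[i]
    label <- paste(genome, onset, sep = "/")
    ids <- stratify_samples(pheno, onset = onset, genome = genome)
    ids <- intersect(ids, G$samples$id)
    if (length(ids) < 10) {
      log_note("pipeline", "stratum ", label, " too small (", length(ids),
               "); skipped")
      next
    }
    Gs <- subset_genotypes(G, samples = ids)
    pp <- config$perm
    pp$seed <- derive_seed(config$seed, paste0("assoc/", label))
    assoc <- adaptive_permutation(Gs, pheno, params = pp)
    best <- min_p_combine(assoc)
    clumps <- clump(best, Gs, config$clump)
    ep <- config$enrich
    ep$seed <- derive_seed(config$seed, paste0("enrich/", label))
    intervals <- prepare_intervals(clumps, gene_map, ep)
    enr <- enrichment_test(intervals, sets, gene_map, Gs$snp_map, ep)
    member_of <- rep(NA_character_, nrow(best))
    for (ci in seq_len(nrow(clumps)))
      member_of[best$snp %in% clumps$members[[ci]]] <- clumps$index_snp[ci]
    manhattan <- data.frame(snp = best$snp, chr = best$chr, bp = best$bp,
                            neglog10_p = -log10(best$emp_p),
                            clump_index = member_of,
                            stringsAsFactors = FALSE)
    strata_res[[label]] <- list(assoc = assoc, best = best, clumps = clumps,
                                intervals = intervals, enrichment = enr,
                                manhattan = manhattan)
  }

  overlap <- list()
  for (g in unique(config$strata$genome)) {
    lists <- list()
    for (o in c("labor", "PROM", "all")) {
      lab <- paste(g, o, sep = "/")
      if (!is.null(strata_res[[lab]]))
        lists[[o]] <- strata_res[[lab]]$best$snp
    }
    if (length(lists) >= 2)
      overlap[[g]] <- overlap_report(lists, config$top_k_overlap)
  }

  manifest <- list(seed = config$seed,
                   strata = names(strata_res),
                   n_samples = nrow(G$calls), n_snps = ncol(G$calls),
                   stage_seeds = lapply(names(strata_res), function(l)
                     c(assoc = derive_seed(config$seed, paste0("assoc/", l)),
                       enrich = derive_seed(config$seed, paste0("enrich/", l)))))
  res <- list(inputs = list(G = G, pheno = pheno, gene_map = gene_map,
                            sets = sets, annotation = ann),
              qc = if (!is.null(qc_out)) qc_out$summary else NULL,
              strata = strata_res, overlap = overlap, manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_run_outputs(res, config$out_dir)
  }
  res
}

# write all result tables as TSV plus a JSON manifest
write_run_outputs <- function(res, out_dir) {
  slug <- function(x) gsub("/", "_", x)
  for (lab in names(res$strata)) {
    s <- res$strata[[lab]]
    write_results(s$assoc$tests,
                  file.path(out_dir, paste0("assoc_", slug(lab), ".tsv")))
    write_results(s$best,
                  file.path(out_dir, paste0("best_", slug(lab), ".tsv")))
    cl <- s$clumps
    write_results(cl, file.path(out_dir, paste0("clumps_", slug(lab), ".tsv")))
    write_results(s$intervals,
                  file.path(out_dir, paste0("intervals_", slug(lab), ".tsv")))
    write_results(s$enrichment,
                  file.path(out_dir, paste0("enrichment_", slug(lab), ".tsv")))
    write_results(s$manhattan,
                  file.path(out_dir, paste0("manhattan_", slug(lab), ".tsv")))
  }
  for (g in names(res$overlap))
    write_results(res$overlap[[g]],
                  file.path(out_dir, paste0("overlap_", g, ".tsv")))
  if (!is.null(res$qc))
    write_results(res$qc, file.path(out_dir, "qc_summary.tsv"))
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Reference planted-signal cohort configuration
#'
#' The package's standard end-to-end simulation scenario: 1,000 samples,
#' 5,000 SNPs (10 chromosomes x 50 blocks x 10 SNPs), five causal SNPs in
#' distinct LD blocks (three additive, one recessive, one dominant), each
#' sized to explain roughly 2% of phenotypic variance at intermediate
#' allele frequency, with the bimodal case-oversampled phenotype design.
#'
#' @param seed Integer seed.
#' @return List with `sim_cfg` ([sim_config()]) and `corpus`
#'   ([corpus_spec()]).
#' @export
planted_cohort_config <- function(seed = 1L) {
  # global SNP index of the middle SNP of block b on chromosome c
  snp_at <- function(c, b) ((c - 1) * 50 + (b - 1)) * 10 + 5
  # GA-lowering effects in days, calibrated so each locus explains ~2% of
  # the realized (case-oversampled) phenotypic variance; the baseline is
  # shifted upward to re-centre the cohort after the allele effects
  causal <- list(
    list(snp = snp_at(1, 10), model = "additive",  effect = -4),
    list(snp = snp_at(2, 25), model = "additive",  effect = -4),
    list(snp = snp_at(3, 40), model = "additive",  effect = -4),
    list(snp = snp_at(4, 15), model = "recessive", effect = -8),
    list(snp = snp_at(5, 30), model = "dominant",  effect = -7))
  list(sim_cfg = sim_config(n_samples = 1000L, n_chromosomes = 10L,
                            blocks_per_chr = 50L, snps_per_block = 10L,
                            founder_haplotypes_per_block = 8L,
                            maf_range = c(0.15, 0.5), recomb_prob = 0.5,
                            causal_spec = causal, noise_sd = 12,
                            baseline_ga = 284, seed = seed),
       corpus = corpus_spec(seed = seed))
}
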