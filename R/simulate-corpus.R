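# Synthetic gene annotation, gene-set collection and labelled abstract
# corpus. Genes tile the simulated chromosomes one per LD block (so every
# planted causal SNP falls inside a gene by construction), and the corpus
# embeds gene symbols and keyword terms together with every trap kind the
# mining filters must handle, each abstract carrying its ground-truth label.

#' Corpus generation parameters
#'
#' @param n_true_abstracts Abstracts generated per (keyword, gene) pair;
#'   with the default 2, every true gene passes the more-than-one-abstract
#'   filter.
#' @param n_trap_abstracts Number of trap abstracts (>= 7: one non-human
#'   and one condition trap, two acronym-collision, one single-mention and
#'   two multi-keyword traps; extras alternate non-human/condition).
#' @param genes_per_keyword True genes embedded per keyword.
#' @param cand_set_size,ctrl_set_size Sizes of the candidate-analog and
#'   control-analog gene-sets used for enrichment; defaults scale with the
#'   gene count (8% and 24% of genes) so the null hit distribution stays
#'   informative at desk scale.
#' @param seed Integer seed.
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(n_true_abstracts = 2L, n_trap_abstracts = 7L,
                        genes_per_keyword = 2L,
                        cand_set_size = NULL, ctrl_set_size = NULL,
                        seed = 1L) {
  if (n_trap_abstracts < 7L)
    stop("corpus_spec: n_trap_abstracts must be >= 7 to cover all trap kinds")
  structure(list(n_true_abstracts = as.integer(n_true_abstracts),
                 n_trap_abstracts = as.integer(n_trap_abstracts),
                 genes_per_keyword = as.integer(genes_per_keyword),
                 cand_set_size = cand_set_size, ctrl_set_size = ctrl_set_size,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Simulate gene annotation, gene-sets and a labelled abstract corpus
#'
#' Builds (a) a gene map with one gene per LD block spanning the block's
#' SNPs, (b) an enrichment gene-set collection keyed by the default keyword
#' names in which the designated truth set (`"preterm"`) contains every
#' gene overlapping a planted causal SNP, and (c) an abstract corpus whose
#' expected mining output is known exactly, including non-human, condition,
#' acronym-collision, single-mention and multi-keyword trap abstracts.
#'
#' @param cfg A [sim_config()] (defines the genome layout and causal SNPs).
#' @param spec A [corpus_spec()].
#' @return A list of class `synthetic_annotation`: `gene_map`, `sets`
#'   (enrichment [gene_set_collection()], truth set name in attribute
#'   `truth_set`), `truth_genes`, `corpus` (data frame), `labels` (per
#'   abstract: label and reason), `expected_sets` (ground-truth mining
#'   output), `keywords` and `filters` ready for [build_gene_sets()].
#' @export
simulate_annotation_and_corpus <- function(cfg, spec = corpus_spec()) {
  stopifnot(inherits(cfg, "sim_config"), inherits(spec, "corpus_spec"))
  lay <- genome_layout(cfg)
  nb <- cfg$blocks_per_chr; m_blk <- cfg$snps_per_block
  n_genes <- cfg$n_chromosomes * nb
  gene_map <- do.call(rbind, lapply(seq_along(lay$chrs), function(ci) {
    data.frame(
      symbol = sprintf("SG%04d", (ci - 1) * nb + seq_len(nb)),
      chr = lay$chrs[ci],
      start = lay$bp[(seq_len(nb) - 1) * m_blk + 1L],
      end = lay$bp[seq_len(nb) * m_blk],
      stringsAsFactors = FALSE)
  }))

  # causal SNP -> containing gene (one gene per block, by construction)
  causal_gene_of <- function(snp_idx) {
    ci <- (snp_idx - 1L) %/% lay$n_snps_chr + 1L
    within <- (snp_idx - 1L) %% lay$n_snps_chr
    b <- within %/% m_blk + 1L
    gene_map$symbol[(ci - 1L) * nb + b]
  }
  truth_genes <- unique(vapply(cfg$causal_spec,
                               function(cs) causal_gene_of(cs$snp),
                               character(1)))

  keywords <- default_keywords()
  cand <- names(keywords)[1:12]
  ctrl <- names(keywords)[13:28]
  truth_kw <- "preterm"
  cand_size <- spec$cand_set_size %||% max(3L, round(0.08 * n_genes))
  ctrl_size <- spec$ctrl_set_size %||% max(3L, round(0.24 * n_genes))
  if (cand_size > n_genes || ctrl_size > n_genes ||
      length(truth_genes) > n_genes)
    stop("simulate_annotation_and_corpus: set size exceeds available genes")

  out <- with_seed(derive_seed(spec$seed, "annotation"), {
    sets <- list()
    for (nm in cand) {
      s <- sample(gene_map$symbol, cand_size)
      if (nm == truth_kw)
        s <- c(truth_genes,
               sample(setdiff(gene_map$symbol, truth_genes),
                      max(0L, cand_size - length(truth_genes))))
      sets[[nm]] <- s
    }
    for (nm in ctrl) sets[[nm]] <- sample(gene_map$symbol, ctrl_size)

    # corpus genes: 4 reserved trap genes, the rest used cyclically
    if (n_genes < 5L)
      stop("simulate_annotation_and_corpus: need at least 5 genes for the corpus")
    reserve <- utils::tail(gene_map$symbol, 4L)
    pool <- setdiff(gene_map$symbol, reserve)
    gpk <- spec$genes_per_keyword
    kw_genes <- lapply(seq_along(keywords), function(k) {
      pool[((k - 1L) * gpk + seq_len(gpk) - 1L) %% length(pool) + 1L]
    })
    names(kw_genes) <- names(keywords)

    recs <- list(); labels <- list()
    add_abs <- function(title, text, mesh, label, reason, keyword, genes) {
      i <- length(recs) + 1L
      recs[[i]] <<- list(id = sprintf("abs%04d", i), title = title,
                         abstract = text, mesh_terms = mesh)
      labels[[i]] <<- data.frame(
        id = sprintf("abs%04d", i), label = label, reason = reason,
        keyword = keyword, genes = paste(genes, collapse = ","),
        stringsAsFactors = FALSE)
    }
    for (nm in names(keywords)) {
      term <- keywords[[nm]]$terms[1]
      for (g in kw_genes[[nm]]) {
        for (rep_i in seq_len(spec$n_true_abstracts)) {
          if (rep_i == 2L && g == kw_genes[[nm]][1]) {
            # genetic context carried by MeSH terms only
            add_abs(sprintf("Regulatory variation and %s", term),
                    sprintf("Analysis of %s in %s cohorts revealed regulatory variation.",
                            g, term),
                    c("genes"), "keep", "true", nm, g)
          } else {
            add_abs(sprintf("Genetic studies of %s", term),
                    sprintf("Analysis of the gene %s in %s cohorts revealed regulatory variation.",
                            g, term),
                    character(0), "keep", "true", nm, g)
          }
        }
      }
    }
    trap_term <- keywords[[truth_kw]]$terms[1]
    add_abs("Comparative mapping", sprintf(
      "A bovine model of %s implicated the gene %s in this trait.",
      trap_term, reserve[1]), character(0),
      "drop", "nonhuman", truth_kw, reserve[1])
    add_abs("Infection genetics", sprintf(
      "In listeriosis complicating %s the gene %s was induced.",
      trap_term, reserve[2]), character(0),
      "drop", "condition", truth_kw, reserve[2])
    for (i in 1:2)
      add_abs("Acronym usage", sprintf(
        "Spontaneous preterm birth (SPTB) is heritable; gene mapping of SPTB cohort %d is ongoing.",
        i), character(0),
        "keep-no-gene", "acronym", truth_kw, "SPTB")
    add_abs("Single mention", sprintf(
      "Analysis of the gene %s in %s cohorts revealed regulatory variation.",
      reserve[3], trap_term), character(0),
      "keep", "single-mention", truth_kw, reserve[3])
    for (i in 1:2)
      add_abs("Two anatomies", sprintf(
        "The gene %s acts in both cervix and uterus tissue (replicate %d).",
        reserve[4], i), character(0),
        "excluded", "multi-keyword", "cervix+uterus", reserve[4])
    extra <- spec$n_trap_abstracts - 7L
    if (extra > 0) for (i in seq_len(extra)) {
      if (i %% 2L == 1L)
        add_abs("Comparative mapping", sprintf(
          "A murine model of %s implicated the gene %s here.",
          trap_term, reserve[1]), character(0),
          "drop", "nonhuman", truth_kw, reserve[1])
      else
        add_abs("Infection genetics", sprintf(
          "In hepatitis complicating %s the gene %s was induced.",
          trap_term, reserve[2]), character(0),
          "drop", "condition", truth_kw, reserve[2])
    }

    corpus <- data.frame(
      id = vapply(recs, `[[`, character(1), "id"),
      title = vapply(recs, `[[`, character(1), "title"),
      abstract = vapply(recs, `[[`, character(1), "abstract"),
      stringsAsFactors = FALSE)
    corpus$mesh_terms <- lapply(recs, `[[`, "mesh_terms")
    labels <- do.call(rbind, labels)

    expected <- lapply(names(keywords), function(nm) {
      if (spec$n_true_abstracts >= 2L) sort(kw_genes[[nm]]) else character(0)
    })
    names(expected) <- names(keywords)

    list(sets = sets, corpus = corpus, labels = labels, expected = expected)
  })

  hg <- c(gene_map$symbol, "SPTB")
  sets <- gene_set_collection(out$sets)
  attr(sets, "truth_set") <- truth_kw
  structure(list(gene_map = gene_map, sets = sets,
                 truth_genes = truth_genes,
                 corpus = out$corpus, labels = out$labels,
                 expected_sets = suppressWarnings(gene_set_collection(out$expected)),
                 keywords = keywords,
                 filters = mining_filters(hgnc_symbols = hg)),
            class = "synthetic_annotation")
}
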