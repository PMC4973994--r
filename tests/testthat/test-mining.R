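# Abstract mining: condition blacklist construction, query matching,
# symbol recognition with acronym disambiguation, set construction with
# frequency and exclusivity filters.

test_that("condition blacklist keeps suffix words and honours the allowlist", {
  bl <- build_condition_blacklist(
    c("suspected listeriosis", "acute hepatitis B", "neuroblastoma stage 4",
      "uterus scan normal", "differential diagnosis", "septicemia"))
  expect_true(all(c("listeriosis", "hepatitis", "neuroblastoma",
                    "septicemia") %in% bl))
  expect_false("uterus" %in% bl)     # no matching suffix
  expect_false("diagnosis" %in% bl)  # allowlisted
  expect_false("acute" %in% bl)
  expect_warning(out <- build_condition_blacklist(character(0)), "empty")
  expect_identical(out, character(0))
})

test_that("abstract matching applies the query clauses in order", {
  filters <- mining_filters(hgnc_symbols = "TLR4")
  kw <- keyword_spec("preterm", c("preterm", "premature"),
                     "pregnancy-condition")
  ok <- list(title = "Genetics of preterm birth",
             abstract = "A gene near TLR4 was implicated.")
  expect_true(match_abstract(ok, kw, filters)$match)
  nog <- list(title = "Clinical notes", abstract = "Preterm outcomes vary.")
  expect_identical(match_abstract(nog, kw, filters)$reason, "not-genetic")
  nok <- list(title = "Physiology", abstract = "No relevant words here.")
  expect_identical(match_abstract(nok, kw, filters)$reason, "no-keyword")
  cow <- list(title = "Bovine gestation", abstract = "Preterm calving gene study.")
  expect_identical(match_abstract(cow, kw, filters)$reason, "nonhuman")
  dis <- list(title = "Hepatitis and prematurity",
              abstract = "A gene associated with preterm birth.")
  expect_identical(match_abstract(dis, kw, filters)$reason, "condition")
  # genetic context via MeSH only
  mesh <- list(title = "Preterm study", abstract = "A cohort analysis.",
               mesh_terms = c("Genes"))
  expect_true(match_abstract(mesh, kw, filters)$match)
})

test_that("keyword terms match as whole tokens, case-insensitively", {
  filters <- mining_filters(hgnc_symbols = character(0))
  kw <- keyword_spec("uterus", c("uterus", "uterine"), "female-anatomy")
  yes <- list(title = "", abstract = "The Uterine gene program.")
  no <- list(title = "", abstract = "The uterusX gene program.")
  expect_true(match_abstract(yes, kw, filters)$match)
  expect_identical(match_abstract(no, kw, filters)$reason, "no-keyword")
})

test_that("gene mentions require capitalisation or exact symbol match", {
  filters <- mining_filters(hgnc_symbols = c("TLR4", "Sptbn1", "ENG"))
  expect_identical(
    extract_gene_mentions(list(title = "", abstract = "the TLR4 receptor"),
                          filters), "TLR4")
  # lowercase fails the capitalisation rule
  expect_identical(
    extract_gene_mentions(list(title = "", abstract = "the tlr4 receptor"),
                          filters), character(0))
  # mixed-case symbol only matches exactly
  expect_identical(
    extract_gene_mentions(list(title = "", abstract = "variant of Sptbn1"),
                          filters), "Sptbn1")
  expect_identical(
    extract_gene_mentions(list(title = "", abstract = "variant of SPTBN1"),
                          filters), "Sptbn1")
  # 'ENG' inside a word is not a token
  expect_identical(
    extract_gene_mentions(list(title = "", abstract = "engineering ENGine"),
                          filters), character(0))
})

test_that("blacklisted acronyms are dropped only in their forbidden context", {
  filters <- mining_filters(hgnc_symbols = c("SPTB", "TLR4"))
  ctx <- list(title = "Spontaneous preterm birth (SPTB)",
              abstract = "SPTB and TLR4 were studied.")
  expect_identical(extract_gene_mentions(ctx, filters), "TLR4")
  noctx <- list(title = "Spectrin genetics",
                abstract = "SPTB encodes beta-spectrin.")
  expect_identical(extract_gene_mentions(noctx, filters), "SPTB")
})

test_that("set construction enforces frequency and exclusivity filters", {
  kws <- list(
    cervix = keyword_spec("cervix", "cervix", "female-anatomy"),
    uterus = keyword_spec("uterus", "uterus", "female-anatomy"),
    pregnancy = keyword_spec("pregnancy", "pregnancy", "pregnancy-condition",
                             exclusivity_exempt = TRUE))
  filters <- mining_filters(hgnc_symbols = c("AAA1", "BBB2", "CCC3"))
  corpus <- data.frame(
    id = sprintf("a%d", 1:6),
    title = "",
    abstract = c(
      "The gene AAA1 in cervix tissue.",          # cervix x1
      "The gene AAA1 in cervix biology.",         # cervix x2 -> AAA1 in
      "The gene BBB2 in cervix tissue.",          # BBB2 only once -> out
      "The gene CCC3 in cervix and uterus.",      # multi-keyword -> neither
      "The gene CCC3 in cervix and uterus now.",  # (twice, still excluded)
      "The gene AAA1 in pregnancy and cervix."),  # exempt kw: pregnancy pool
    stringsAsFactors = FALSE)
  corpus$mesh_terms <- rep(list(character(0)), 6)
  sets <- suppressWarnings(build_gene_sets(corpus, kws, filters))
  expect_identical(sets$cervix, "AAA1")
  expect_identical(sets$uterus, character(0))
  # pregnancy pool only has one AAA1 abstract -> below the threshold
  expect_identical(sets$pregnancy, character(0))
  # raising the threshold never adds genes (monotonicity)
  filters3 <- filters; filters3$min_abstracts_per_gene <- 3L
  sets3 <- suppressWarnings(build_gene_sets(corpus, kws, filters3))
  for (nm in names(sets3))
    expect_true(all(sets3[[nm]] %in% sets[[nm]]))
  # abstract a6 matches cervix (non-exempt) and pregnancy (exempt): it still
  # counts for cervix, so AAA1 has 3 cervix abstracts
  ev <- attr(sets, "evidence")
  expect_identical(sort(ev$abstract_id[ev$keyword == "cervix"]),
                   c("a1", "a2", "a6"))
})

test_that("the labelled fixture corpus is recovered exactly", {
  cfg <- sim_config(n_samples = 20, n_chromosomes = 2, blocks_per_chr = 6,
                    snps_per_block = 4,
                    causal_spec = list(list(snp = 2, model = "additive",
                                            effect = -3)),
                    seed = 19)
  ann <- simulate_annotation_and_corpus(cfg, corpus_spec(seed = 19))
  expect_gte(nrow(ann$corpus), 40)
  expect_true(all(c("nonhuman", "condition", "acronym", "single-mention",
                    "multi-keyword") %in% ann$labels$reason))
  got <- suppressWarnings(
    build_gene_sets(ann$corpus, ann$keywords, ann$filters))
  for (nm in names(ann$expected_sets)) {
    expect_identical(sort(got[[nm]]), sort(ann$expected_sets[[nm]]))
  }
  # determinism: same corpus and config give identical sets
  got2 <- suppressWarnings(
    build_gene_sets(ann$corpus, ann$keywords, ann$filters))
  expect_identical(unclass(got)[order(names(got))],
                   unclass(got2)[order(names(got2))])
})

test_that("the shipped YAML keyword config equals the in-code defaults", {
  path <- system.file("extdata", "keywords.yaml", package = "litgwas")
  expect_true(nzchar(path))
  kws <- read_keywords(path)
  def <- default_keywords()
  expect_identical(names(kws), names(def))
  for (nm in names(def)) {
    expect_identical(kws[[nm]]$terms, def[[nm]]$terms)
    expect_identical(kws[[nm]]$class, def[[nm]]$class)
    expect_identical(kws[[nm]]$exclusivity_exempt,
                     def[[nm]]$exclusivity_exempt)
  }
})

test_that("the default keyword configuration ships 12 + 16 keywords", {
  kws <- default_keywords()
  cls <- vapply(kws, `[[`, character(1), "class")
  expect_identical(sum(cls %in% c("pregnancy-condition", "female-anatomy",
                                  "fetal-anatomy")), 12L)
  expect_identical(sum(cls %in% c("control-condition", "control-anatomy")), 16L)
  expect_identical(length(default_nonhuman_indicators()), 65L)
  expect_true(all(vapply(kws, function(k) length(k$terms) >= 1, logical(1))))
})
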