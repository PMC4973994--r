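# Literature mining of keyword gene-sets from an abstract corpus: keyword
# query matching with genetic-context requirement, non-human and
# medical-condition blacklists, HGNC symbol recognition with acronym
# disambiguation, a more-than-one-abstract frequency filter and a
# keyword-exclusivity filter.

#' Keyword specification
#'
#' @param name Keyword name (set name in the output GMT).
#' @param terms Character vector of morphological/Latin/Greek variants,
#'   matched case-insensitively as whole tokens.
#' @param class One of `"pregnancy-condition"`, `"female-anatomy"`,
#'   `"fetal-anatomy"`, `"control-condition"`, `"control-anatomy"`.
#' @param exclusivity_exempt Very common and control keywords are exempt
#'   from the one-keyword-per-abstract exclusivity filter.
#' @return A `keyword_spec` list.
#' @export
keyword_spec <- function(name, terms,
                         class = c("pregnancy-condition", "female-anatomy",
                                   "fetal-anatomy", "control-condition",
                                   "control-anatomy"),
                         exclusivity_exempt = FALSE) {
  stopifnot(length(terms) >= 1)
  structure(list(name = name, terms = tolower(terms),
                 class = match.arg(class),
                 exclusivity_exempt = isTRUE(exclusivity_exempt)),
            class = "keyword_spec")
}

#' Default keyword configuration
#'
#' Twelve candidate keywords (4 pregnancy conditions, 4 female-anatomy, 4
#' fetal-anatomy) and sixteen control keywords (8 conditions, 8 anatomy)
#' unrelated to pregnancy. Term variant lists are curated package defaults.
#' The very common keywords (`pregnancy`, `gestation`) and all controls are
#' exempt from the exclusivity filter.
#'
#' @return Named list of [keyword_spec()] objects (28 keywords).
#' @export
default_keywords <- function() {
  k <- list(
    keyword_spec("gestation", c("gestation", "gestational"),
                 "pregnancy-condition", exclusivity_exempt = TRUE),
    keyword_spec("parturition", c("parturition", "parturient"),
                 "pregnancy-condition"),
    keyword_spec("pregnancy", c("pregnancy", "pregnancies", "pregnant", "gravid"),
                 "pregnancy-condition", exclusivity_exempt = TRUE),
    keyword_spec("preterm", c("preterm", "premature", "prematurity"),
                 "pregnancy-condition"),
    keyword_spec("cervix", c("cervix", "cervical"), "female-anatomy"),
    keyword_spec("endometrium", c("endometrium", "endometrial"), "female-anatomy"),
    keyword_spec("myometrium", c("myometrium", "myometrial"), "female-anatomy"),
    keyword_spec("uterus", c("uterus", "uterine", "utero"), "female-anatomy"),
    keyword_spec("fetus", c("fetus", "foetus", "fetal", "foetal", "embryo",
                            "embryonic"), "fetal-anatomy"),
    keyword_spec("chorion", c("chorion", "chorionic"), "fetal-anatomy"),
    keyword_spec("amnion", c("amnion", "amniotic"), "fetal-anatomy"),
    keyword_spec("placenta", c("placenta", "placental"), "fetal-anatomy")
  )
  ctrl_cond <- list(
    c("ageing", "ageing", "aging"), c("obesity", "obesity", "obese"),
    c("asthma", "asthma", "asthmatic"), c("migraine", "migraine", "migraines"),
    c("insomnia", "insomnia"), c("hypertension", "hypertension", "hypertensive"),
    c("diabetes", "diabetes", "diabetic"), c("epilepsy", "epilepsy", "epileptic"))
  ctrl_anat <- list(
    c("kidney", "kidney", "renal"), c("liver", "liver", "hepatic"),
    c("retina", "retina", "retinal"), c("cochlea", "cochlea", "cochlear"),
    c("pancreas", "pancreas", "pancreatic"), c("thyroid", "thyroid"),
    c("tendon", "tendon", "tendinous"), c("skin", "skin", "cutaneous"))
  for (x in ctrl_cond)
    k[[length(k) + 1L]] <- keyword_spec(x[1], x[-1], "control-condition",
                                        exclusivity_exempt = TRUE)
  for (x in ctrl_anat)
    k[[length(k) + 1L]] <- keyword_spec(x[1], x[-1], "control-anatomy",
                                        exclusivity_exempt = TRUE)
  stats::setNames(k, vapply(k, `[[`, character(1), "name"))
}

#' Read a keyword configuration from YAML
#'
#' The YAML maps keyword names to `terms`, `class` and
#' `exclusivity_exempt`; the shipped default lives at
#' `system.file("extdata", "keywords.yaml", package = "litgwas")` and
#' mirrors [default_keywords()].
#'
#' @param path Path to a keywords YAML file.
#' @return Named list of [keyword_spec()] objects.
#' @export
read_keywords <- function(path) {
  y <- yaml::read_yaml(path)
  out <- lapply(names(y), function(nm)
    keyword_spec(nm, y[[nm]]$terms, y[[nm]]$class,
                 isTRUE(y[[nm]]$exclusivity_exempt)))
  stats::setNames(out, names(y))
}

# Curated default vocabulary standing in for an ICD-style description file;
# only used to build the default condition blacklist.
default_condition_vocabulary <- function() {
  c("listeriosis", "tuberculosis", "sarcoidosis", "endometriosis",
    "amyloidosis", "cirrhosis", "fibrosis", "thrombosis", "psychosis",
    "acidosis", "ketosis", "mycosis", "stenosis", "scoliosis", "silicosis",
    "hepatitis", "arthritis", "dermatitis", "bronchitis", "gastritis",
    "meningitis", "nephritis", "pancreatitis", "sinusitis", "colitis",
    "vasculitis", "encephalitis", "cystitis", "mastitis", "myositis",
    "anemia", "anaemia", "leukemia", "leukaemia", "septicemia", "ischemia",
    "uremia", "bacteremia", "hypoglycemia", "hyperglycemia", "toxemia",
    "viremia", "azotemia", "hyperlipidemia",
    "neuroblastoma", "melanoma", "carcinoma", "lymphoma", "glioma",
    "sarcoma", "myeloma", "adenoma", "hepatoma", "retinoblastoma",
    "osteosarcoma", "mesothelioma", "papilloma", "hematoma", "granuloma",
    # words with a matching suffix that are not conditions (allowlisted)
    "diagnosis", "prognosis", "apoptosis", "meiosis", "mitosis")
}

#' Default suffix allowlist
#'
#' Words that end in a disease suffix but are not medical conditions, kept
#' out of the condition blacklist.
#'
#' @return Character vector.
#' @export
default_suffix_allowlist <- function() {
  c("diagnosis", "prognosis", "apoptosis", "meiosis", "mitosis",
    "anastomosis", "symbiosis", "biosis", "exostosis")
}

#' Build a medical-condition blacklist from vocabulary terms
#'
#' Mirrors mining an ICD-style code-description file: lowercase words of
#' length >= 5 that end in a configured disease suffix, deduplicated, minus
#' an allowlist of non-condition words.
#'
#' @param vocabulary_terms Character vector of description strings.
#' @param suffixes Disease suffixes (default `-osis`, `-itis`, `-emia`,
#'   `-oma`).
#' @param allowlist Words to exclude (default [default_suffix_allowlist()]).
#' @return Character vector of condition-indicator words.
#' @examples
#' build_condition_blacklist(c("suspected listeriosis", "uterus scan"))
#' @export
build_condition_blacklist <- function(vocabulary_terms,
                                      suffixes = c("osis", "itis", "emia", "oma"),
                                      allowlist = default_suffix_allowlist()) {
  if (length(vocabulary_terms) == 0L) {
    warning("build_condition_blacklist: empty vocabulary")
    return(character(0))
  }
  words <- unlist(strsplit(tolower(vocabulary_terms), "[^a-z]+"))
  words <- unique(words[nchar(words) >= 5])
  pat <- paste0("(", paste(suffixes, collapse = "|"), ")$")
  hits <- words[grepl(pat, words)]
  sort(setdiff(hits, tolower(allowlist)))
}

#' Mining filter configuration
#'
#' @param genetic_terms Words indicating the genetic nature of an abstract;
#'   matched in text tokens or MeSH terms.
#' @param nonhuman_indicators Non-human subject indicator words (curated
#'   default of 65 terms).
#' @param condition_indicators Medical-condition indicator words; default
#'   built by [build_condition_blacklist()] from a curated vocabulary.
#' @param disease_suffixes Suffixes used when building condition indicators.
#' @param acronym_blacklist Named list: gene symbol -> character vector of
#'   forbidden context phrases; a mention of the symbol is dropped when any
#'   phrase co-occurs in the abstract.
#' @param min_abstracts_per_gene A gene enters a set only when mentioned in
#'   at least this many of the set's abstracts (default 2, i.e. "more than
#'   one abstract").
#' @param hgnc_symbols Authoritative gene symbol list used for mention
#'   recognition.
#' @return A `mining_filters` list.
#' @export
mining_filters <- function(genetic_terms = c("gene", "genes", "genomic",
                                             "genetic", "gwas"),
                           nonhuman_indicators = default_nonhuman_indicators(),
                           condition_indicators =
                             build_condition_blacklist(default_condition_vocabulary()),
                           disease_suffixes = c("osis", "itis", "emia", "oma"),
                           acronym_blacklist = default_acronym_blacklist(),
                           min_abstracts_per_gene = 2L,
                           hgnc_symbols = character(0)) {
  structure(list(genetic_terms = tolower(genetic_terms),
                 nonhuman_indicators = tolower(nonhuman_indicators),
                 condition_indicators = tolower(condition_indicators),
                 disease_suffixes = disease_suffixes,
                 acronym_blacklist = acronym_blacklist,
                 min_abstracts_per_gene = as.integer(min_abstracts_per_gene),
                 hgnc_symbols = hgnc_symbols),
            class = "mining_filters")
}

#' Default non-human subject indicators
#'
#' Curated list of 65 words flagging non-human study subjects.
#'
#' @return Character vector of 65 terms.
#' @export
default_nonhuman_indicators <- function() {
  c("cat", "feline", "cow", "bovine", "mouse", "mice", "murine", "rat",
    "rats", "rattus", "dog", "canine", "pig", "porcine", "swine", "sheep",
    "ovine", "goat", "caprine", "horse", "equine", "chicken", "avian",
    "zebrafish", "drosophila", "yeast", "elegans", "rabbit", "ferret",
    "hamster", "gerbil", "monkey", "macaque", "rhesus", "baboon",
    "chimpanzee", "gorilla", "salmon", "trout", "xenopus", "frog", "toad",
    "lizard", "snake", "turtle", "quail", "turkey", "duck", "goose",
    "buffalo", "bison", "deer", "camel", "llama", "alpaca", "donkey",
    "whale", "dolphin", "seal", "opossum", "kangaroo", "wallaby",
    "mosquito", "nematode", "insect")
}

#' Default acronym blacklist
#'
#' Gene symbols that collide with common obstetric acronyms, each with the
#' context phrases that mark the acronym usage (e.g. the symbol SPTB next
#' to "spontaneous preterm birth").
#'
#' @return Named list of character vectors.
#' @export
default_acronym_blacklist <- function() {
  list(SPTB = c("spontaneous preterm birth"),
       AGA  = c("appropriate for gestational age"),
       FGR  = c("fetal growth retardation", "fetal growth restriction"))
}

# tokenization on non-alphanumeric boundaries; hyphen kept inside tokens
tokenize <- function(text) {
  t <- unlist(strsplit(text, "[^A-Za-z0-9-]+"))
  t[nzchar(t)]
}

abstract_text <- function(abstract) {
  paste(abstract$title %||% "", abstract$abstract %||% "")
}

abstract_mesh <- function(abstract) {
  mt <- abstract$mesh_terms %||% character(0)
  if (is.list(mt)) mt <- unlist(mt)
  as.character(mt)
}

#' Match one abstract against a keyword query
#'
#' An abstract matches when (a) at least one keyword term is present, (b)
#' at least one genetic term is present in text or MeSH terms, (c) no
#' non-human indicator is present, and (d) no condition indicator is
#' present. The reject reason names the first failed clause.
#'
#' @param abstract List or one-row data frame with `title`, `abstract`,
#'   optional `mesh_terms`.
#' @param keyword A [keyword_spec()].
#' @param filters [mining_filters()].
#' @return List with logical `match` and, when `FALSE`, a `reason`
#'   (`"no-keyword"`, `"not-genetic"`, `"nonhuman"`, `"condition"`).
#' @export
match_abstract <- function(abstract, keyword, filters = mining_filters()) {
  toks <- tolower(tokenize(abstract_text(abstract)))
  mesh <- tolower(abstract_mesh(abstract))
  mesh_toks <- tolower(unlist(lapply(mesh, tokenize)))
  if (!any(keyword$terms %in% toks))
    return(list(match = FALSE, reason = "no-keyword"))
  if (!any(filters$genetic_terms %in% c(toks, mesh_toks)))
    return(list(match = FALSE, reason = "not-genetic"))
  if (any(filters$nonhuman_indicators %in% c(toks, mesh_toks)))
    return(list(match = FALSE, reason = "nonhuman"))
  if (any(filters$condition_indicators %in% c(toks, mesh_toks)))
    return(list(match = FALSE, reason = "condition"))
  list(match = TRUE, reason = NA_character_)
}

#' Extract gene-symbol mentions from an abstract
#'
#' A token is a mention when it equals an HGNC symbol case-sensitively, or
#' is all-uppercase (length >= 2) and equals a symbol case-insensitively.
#' Mentions of blacklisted acronyms are dropped when any of their forbidden
#' context phrases co-occurs in the abstract. Returns the deduplicated
#' symbol set.
#'
#' @param abstract As in [match_abstract()].
#' @param filters [mining_filters()] with non-empty `hgnc_symbols`.
#' @return Character vector of gene symbols.
#' @export
extract_gene_mentions <- function(abstract, filters) {
  toks <- tokenize(abstract_text(abstract))
  hg <- filters$hgnc_symbols
  exact <- toks[toks %in% hg]
  upper <- toks[toks == toupper(toks) & nchar(toks) >= 2 & grepl("[A-Z]", toks)]
  ci <- hg[toupper(hg) %in% toupper(upper)]
  found <- unique(c(exact, ci))
  if (length(found)) {
    low <- tolower(abstract_text(abstract))
    for (sym in intersect(found, names(filters$acronym_blacklist))) {
      phrases <- tolower(filters$acronym_blacklist[[sym]])
      if (any(vapply(phrases, function(p) grepl(p, low, fixed = TRUE),
                     logical(1))))
        found <- setdiff(found, sym)
    }
  }
  found
}

#' Build keyword gene-sets from an abstract corpus
#'
#' For each keyword: collect matching abstracts; apply the exclusivity
#' filter (an abstract contributing to a non-exempt keyword must not match
#' any other non-exempt keyword); extract gene mentions; keep genes
#' mentioned in at least `min_abstracts_per_gene` of the keyword's
#' abstracts.
#'
#' @param corpus Data frame as from [read_corpus()].
#' @param keywords Named list of [keyword_spec()] (default
#'   [default_keywords()]).
#' @param filters [mining_filters()] with `hgnc_symbols` set.
#' @return A [gene_set_collection()] (one set per keyword, possibly empty)
#'   with an `evidence` attribute: data frame of keyword, gene, abstract id.
#' @export
build_gene_sets <- function(corpus, keywords = default_keywords(),
                            filters = mining_filters()) {
  if (length(filters$hgnc_symbols) == 0L)
    warning("build_gene_sets: hgnc_symbols is empty; no genes can be found")
  na <- nrow(corpus)
  nk <- length(keywords)
  match_mat <- matrix(FALSE, na, nk, dimnames = list(corpus$id, names(keywords)))
  for (i in seq_len(na)) {
    ab <- list(title = corpus$title[i], abstract = corpus$abstract[i],
               mesh_terms = corpus$mesh_terms[[i]])
    for (k in seq_len(nk))
      match_mat[i, k] <- match_abstract(ab, keywords[[k]], filters)$match
  }
  exempt <- vapply(keywords, `[[`, logical(1), "exclusivity_exempt")
  n_nonexempt <- rowSums(match_mat[, !exempt, drop = FALSE])
  mentions <- lapply(seq_len(na), function(i) {
    if (!any(match_mat[i, ])) return(character(0))
    extract_gene_mentions(list(title = corpus$title[i],
                               abstract = corpus$abstract[i]), filters)
  })
  sets <- list(); evidence <- list()
  for (k in seq_len(nk)) {
    kw <- keywords[[k]]
    sel <- which(match_mat[, k])
    if (!kw$exclusivity_exempt)
      sel <- sel[n_nonexempt[sel] <= 1]  # only this non-exempt keyword
    if (!length(sel)) {
      warning("keyword '", kw$name, "' matched no abstracts")
      sets[[kw$name]] <- character(0)
      next
    }
    gene_by_ab <- mentions[sel]
    tab <- table(unlist(gene_by_ab))
    genes <- sort(names(tab)[tab >= filters$min_abstracts_per_gene])
    sets[[kw$name]] <- genes
    if (length(genes)) {
      ev <- do.call(rbind, lapply(seq_along(sel), function(ii) {
        g <- intersect(gene_by_ab[[ii]], genes)
        if (!length(g)) return(NULL)
        data.frame(keyword = kw$name, gene = g,
                   abstract_id = corpus$id[sel[ii]], stringsAsFactors = FALSE)
      }))
      evidence[[kw$name]] <- ev
    }
  }
  out <- suppressWarnings(gene_set_collection(sets))
  attr(out, "evidence") <- do.call(rbind, evidence)
  out
}
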