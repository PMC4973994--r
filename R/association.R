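# Per-SNP association of continuous gestational age under three genetic
# models, with adaptive permutation empirical p-values (PLINK-style aperm
# semantics: one shared phenotype permutation per replicate, early stopping
# of clearly non-significant tests) and per-SNP min-p combination.

#' Adaptive permutation parameters
#'
#' Defaults mirror the cited adaptive-permutation settings: alpha = beta =
#' 5e-8, minimum 10 replicates, pruning checkpoints spaced by
#' `max(1, ceiling(init + slope * N))`. The production cap of 1e9
#' replicates is available via `max_perms`; the package default is the desk
#' scale 1e5.
#'
#' @param alpha Target significance level the pruning interval is tested
#'   against.
#' @param beta Confidence parameter of the pruning interval (two-sided
#'   normal interval at level `1 - beta`).
#' @param min_perms Replicates every test performs before any pruning.
#' @param max_perms Hard cap on replicates.
#' @param prune_interval_init,prune_interval_slope Checkpoint spacing
#'   parameters (`init` + `slope * N`).
#' @param adaptive If `FALSE`, pruning is disabled and every test runs
#'   exactly `max_perms` replicates.
#' @param seed Integer seed for the permutation stream.
#' @return A `permutation_params` list.
#' @export
permutation_params <- function(alpha = 5e-8, beta = 5e-8,
                               min_perms = 10L, max_perms = 1e5,
                               prune_interval_init = 1,
                               prune_interval_slope = 0.001,
                               adaptive = TRUE, seed = 1L) {
  if (max_perms < min_perms)
    stop("permutation_params: max_perms < min_perms")
  stopifnot(min_perms >= 1, alpha > 0, alpha < 1, beta > 0, beta < 1)
  structure(list(alpha = alpha, beta = beta,
                 min_perms = as.integer(min_perms),
                 max_perms = as.double(max_perms),
                 prune_interval_init = prune_interval_init,
                 prune_interval_slope = prune_interval_slope,
                 adaptive = isTRUE(adaptive), seed = as.integer(seed)),
            class = "permutation_params")
}

#' Encode a genotype call under a genetic model
#'
#' The call counts copies of the minor (effect) allele. Additive keeps the
#' count; recessive codes 1 only for the minor homozygote; dominant codes 1
#' for any minor-allele carrier. Missing propagates.
#'
#' @param call Integer vector of calls in `{0, 1, 2, NA}`.
#' @param model One of `"additive"`, `"recessive"`, `"dominant"`.
#' @return Numeric dosage vector.
#' @export
encode_genotype <- function(call, model) {
  switch(match.arg(model, c("additive", "recessive", "dominant")),
         additive  = as.numeric(call),
         recessive = as.numeric(call == 2L),
         dominant  = as.numeric(call >= 1L))
}

is_x_chr <- function(chr) toupper(as.character(chr)) %in% c("X", "23")

align_phenotype <- function(G, phenotype) {
  if (is.data.frame(phenotype)) {
    stopifnot(all(c("sample_id", "ga_days") %in% names(phenotype)))
    as.numeric(phenotype$ga_days[match(G$samples$id, phenotype$sample_id)])
  } else {
    stopifnot(length(phenotype) == nrow(G$calls))
    as.numeric(phenotype)
  }
}

#' Simple-regression statistic for one SNP model
#'
#' Simple linear regression of the phenotype on the coded dosage with
#' pairwise deletion of missing values: slope, |t| = |beta|/SE, two-sided
#' asymptotic p from the t distribution with n - 2 df, and genotypic group
#' summaries when the raw calls are supplied.
#'
#' @param dosage Coded dosage vector (may contain `NA`).
#' @param phenotype Numeric phenotype vector, same length.
#' @param calls Optional raw minor-allele counts for group summaries.
#' @return List with `status` (`"completed"` or `"skipped-degenerate"`),
#'   `beta`, `t_abs`, `p_asymp`, `n`, and `groups` (counts `n_EE`, `n_ER`,
#'   `n_RR` and means `m_EE`, `m_ER`, `m_RR`) when `calls` is given.
#' @export
model_statistic <- function(dosage, phenotype, calls = NULL) {
  ok <- !is.na(dosage) & !is.na(phenotype)
  x <- dosage[ok]; y <- phenotype[ok]
  n <- length(x)
  groups <- NULL
  if (!is.null(calls)) {
    cc <- calls[ok]
    groups <- list(n_EE = sum(cc == 2L), n_ER = sum(cc == 1L),
                   n_RR = sum(cc == 0L),
                   m_EE = if (any(cc == 2L)) mean(y[cc == 2L]) else NA_real_,
                   m_ER = if (any(cc == 1L)) mean(y[cc == 1L]) else NA_real_,
                   m_RR = if (any(cc == 0L)) mean(y[cc == 0L]) else NA_real_)
  }
  sxx <- sum(x^2) - n * mean(x)^2
  if (n < 3 || sxx <= 0)
    return(list(status = "skipped-degenerate", beta = NA_real_,
                t_abs = NA_real_, p_asymp = NA_real_, n = n,
                groups = groups))
  syy <- sum(y^2) - n * mean(y)^2
  sxy <- sum(x * y) - n * mean(x) * mean(y)
  beta <- sxy / sxx
  if (syy <= 0) {                      # constant phenotype: beta = 0, p = 1
    return(list(status = "completed", beta = 0, t_abs = 0, p_asymp = 1,
                n = n, groups = groups))
  }
  r <- sxy / sqrt(sxx * syy)
  r2 <- min(r^2, 1)
  t_abs <- if (r2 >= 1) Inf else abs(r) * sqrt((n - 2) / (1 - r2))
  p <- 2 * stats::pt(-t_abs, df = n - 2)
  list(status = "completed", beta = beta, t_abs = t_abs, p_asymp = p,
       n = n, groups = groups)
}

# Pruning checkpoint schedule: first at min_perms, then whenever N grows by
# max(1, ceiling(init + slope * N)).
perm_checkpoints <- function(params) {
  if (!params$adaptive) return(numeric(0))
  cps <- numeric(0)
  N <- params$min_perms
  while (N <= params$max_perms) {
    cps <- c(cps, N)
    N <- N + max(1, ceiling(params$prune_interval_init +
                              params$prune_interval_slope * N))
  }
  cps
}

#' Per-SNP association with adaptive permutation p-values
#'
#' Tests every SNP under the requested genetic models (X-chromosome SNPs
#' under the additive model only). The observed statistic is |t| from
#' simple linear regression of phenotype on coded minor-allele dosage. Each
#' permutation replicate is one shared relabelling of the phenotype vector
#' applied to all tests still active; a replicate counts as an exceedance
#' when the permuted |t| is greater than or equal to the observed one (ties
#' count). The empirical p is (R + 1) / (N + 1). At checkpoints, a
#' two-sided normal interval at confidence `1 - beta` around R/N prunes
#' tests whose interval excludes `alpha` from below.
#'
#' @param G A QC-passed [genotype_matrix()].
#' @param phenotype Numeric vector aligned with `G`, or a phenotype data
#'   frame with `sample_id` and `ga_days`. Samples with missing phenotype
#'   are dropped.
#' @param models Subset of `c("additive", "recessive", "dominant")`.
#' @param params [permutation_params()].
#' @return An `association_result`: list with `tests` (one row per SNP x
#'   model: group counts/means, slope, |t|, asymptotic p, exceedances `R`,
#'   replicates `N`, `emp_p`, `status`) and `params`.
#' @export
adaptive_permutation <- function(G, phenotype,
                                 models = c("additive", "recessive", "dominant"),
                                 params = permutation_params()) {
  models <- match.arg(models, several.ok = TRUE)
  y_all <- align_phenotype(G, phenotype)
  if (anyNA(y_all)) {
    keep <- !is.na(y_all)
    log_note("assoc", "dropping ", sum(!keep), " sample(s) without phenotype")
    G <- subset_genotypes(G, samples = keep)
    y_all <- y_all[keep]
  }
  n <- length(y_all)
  D <- minor_dosage(G)
  eff <- ifelse(a2_is_minor(G), G$snp_map$a2, G$snp_map$a1)
  ref <- ifelse(a2_is_minor(G), G$snp_map$a1, G$snp_map$a2)
  xchr <- is_x_chr(G$snp_map$chr)
  m <- ncol(D)

  # test table: SNP x model, X-chromosome SNPs additive-only
  tt <- do.call(rbind, lapply(models, function(mod) {
    snps <- if (mod == "additive") seq_len(m) else which(!xchr)
    data.frame(snp_idx = snps, model = mod, stringsAsFactors = FALSE)
  }))
  nt <- nrow(tt)

  # observed statistics and per-test constants
  obs <- vector("list", nt)
  mask_key <- character(nt)
  for (i in seq_len(nt)) {
    j <- tt$snp_idx[i]
    d <- encode_genotype(D[, j], tt$model[i])
    st <- model_statistic(d, y_all, calls = D[, j])
    ok <- !is.na(d)
    obs[[i]] <- list(st = st, dosage = d, ok = ok)
    mask_key[i] <- if (all(ok)) "" else paste(which(!ok), collapse = ",")
  }
  status <- vapply(obs, function(o) o$st$status, character(1))
  r_obs <- vapply(seq_len(nt), function(i) {
    o <- obs[[i]]
    if (o$st$status != "completed") return(NA_real_)
    x <- o$dosage[o$ok]; yy <- y_all[o$ok]
    sxy <- sum(x * yy) - length(x) * mean(x) * mean(yy)
    den <- sqrt((sum(x^2) - length(x) * mean(x)^2) *
                  (sum(yy^2) - length(yy) * mean(yy)^2))
    if (den <= 0) 0 else abs(sxy / den)
  }, numeric(1))

  active <- which(status == "completed")
  R <- numeric(nt); Nstop <- numeric(nt)
  z <- stats::qnorm(1 - params$beta / 2)
  cps_all <- perm_checkpoints(params)
  N <- 0

  with_seed(params$seed, {
    while (length(active) > 0 && N < params$max_perms) {
      B <- as.integer(min(max(256, N),
                          params$max_perms - N,
                          max(256, floor(5e7 / length(active)))))
      Yp <- vapply(seq_len(B), function(b) y_all[sample.int(n)], numeric(n))
      # exceedance indicators for active tests, grouped by missingness mask
      E <- matrix(FALSE, B, length(active))
      for (key in unique(mask_key[active])) {
        sel <- which(mask_key[active] == key)
        ids <- active[sel]
        rows <- if (key == "") seq_len(n) else
          setdiff(seq_len(n), as.integer(strsplit(key, ",")[[1]]))
        Yb <- Yp[rows, , drop = FALSE]
        ng <- length(rows)
        Sy <- colSums(Yb); Syy <- colSums(Yb^2)
        sdy2 <- Syy - Sy^2 / ng
        Xg <- vapply(ids, function(i) obs[[i]]$dosage[rows], numeric(ng))
        xbar <- colMeans(Xg)
        sxx <- colSums(Xg^2) - ng * xbar^2
        num <- crossprod(Yb, Xg)                  # B x k
        num <- abs(num - outer(Sy, xbar))
        den <- outer(sqrt(pmax(sdy2, 0)), sqrt(pmax(sxx, 0)))
        rp <- num / den
        rp[!is.finite(rp)] <- 0
        E[, sel] <- rp >= rep(r_obs[ids] - 1e-12, each = B)
      }
      cps <- cps_all[cps_all > N & cps_all <= N + B]
      if (length(cps)) {
        Ecum <- apply(E, 2, cumsum)
        if (is.null(dim(Ecum))) Ecum <- matrix(Ecum, nrow = B)
        alive <- rep(TRUE, length(active))
        for (cp in cps) {
          row <- cp - N
          al <- which(alive)
          if (!length(al)) break
          Rcp <- R[active[al]] + Ecum[row, al]
          phat <- Rcp / cp
          hw <- z * sqrt(phat * (1 - phat) / cp)
          prune <- phat - hw > params$alpha
          if (any(prune)) {
            ids <- active[al[prune]]
            status[ids] <- "pruned"
            R[ids] <- Rcp[prune]
            Nstop[ids] <- cp
            alive[al[prune]] <- FALSE
          }
        }
        keep <- which(alive)
        R[active[keep]] <- R[active[keep]] + Ecum[B, keep]
        active <- active[keep]
      } else {
        R[active] <- R[active] + colSums(E)
      }
      N <- N + B
    }
    invisible(NULL)
  })
  status[active] <- "completed"
  Nstop[active] <- N
  Nstop[status == "skipped-degenerate"] <- 0

  gr <- lapply(obs, function(o)
    o$st$groups %||% list(n_EE = NA, n_ER = NA, n_RR = NA,
                          m_EE = NA, m_ER = NA, m_RR = NA))
  tests <- data.frame(
    snp = G$snp_map$id[tt$snp_idx],
    chr = G$snp_map$chr[tt$snp_idx],
    bp = G$snp_map$bp[tt$snp_idx],
    model = tt$model,
    effect_allele = eff[tt$snp_idx],
    ref_allele = ref[tt$snp_idx],
    n_EE = vapply(gr, function(g) as.numeric(g$n_EE), numeric(1)),
    n_ER = vapply(gr, function(g) as.numeric(g$n_ER), numeric(1)),
    n_RR = vapply(gr, function(g) as.numeric(g$n_RR), numeric(1)),
    m_EE = vapply(gr, function(g) as.numeric(g$m_EE), numeric(1)),
    m_ER = vapply(gr, function(g) as.numeric(g$m_ER), numeric(1)),
    m_RR = vapply(gr, function(g) as.numeric(g$m_RR), numeric(1)),
    beta = vapply(obs, function(o) o$st$beta, numeric(1)),
    t_abs = vapply(obs, function(o) o$st$t_abs, numeric(1)),
    p_asymp = vapply(obs, function(o) o$st$p_asymp, numeric(1)),
    R = R, N = Nstop,
    emp_p = ifelse(status == "skipped-degenerate", NA_real_,
                   (R + 1) / (Nstop + 1)),
    status = status,
    stringsAsFactors = FALSE)
  structure(list(tests = tests, params = params),
            class = "association_result")
}

#' Combine the three model p-values into a per-SNP best record
#'
#' The per-SNP combined p is the minimum empirical p over non-skipped
#' models (uncorrected, mirroring the min-p reporting convention); ties
#' break additive > dominant > recessive. SNPs with all models skipped are
#' excluded with a logged reason.
#'
#' @param result An `association_result` from [adaptive_permutation()].
#' @return Data frame with one row per SNP: `snp`, `chr`, `bp`,
#'   `effect_allele`, `ref_allele`, `model`, `emp_p`, group counts/means of
#'   the best model, sorted by `emp_p`.
#' @export
min_p_combine <- function(result) {
  tests <- if (inherits(result, "association_result")) result$tests else result
  ok <- tests[tests$status != "skipped-degenerate", , drop = FALSE]
  skipped <- setdiff(unique(tests$snp), unique(ok$snp))
  if (length(skipped))
    log_note("assoc", length(skipped),
             " SNP(s) excluded from ranking: all models degenerate")
  if (nrow(ok) == 0L) return(ok)
  model_rank <- match(ok$model, c("additive", "dominant", "recessive"))
  ord <- order(ok$snp, ok$emp_p, model_rank)
  ok <- ok[ord, , drop = FALSE]
  best <- ok[!duplicated(ok$snp), , drop = FALSE]
  best <- best[order(best$emp_p, best$chr, best$bp), , drop = FALSE]
  rownames(best) <- NULL
  best
}
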