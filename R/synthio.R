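#' Configuration for the synthetic-data generator
#'
#' Defines a latent-factor expression model with `n_clusters` planted
#' co-expression clusters, two spread-type groups (miliary vs non-miliary)
#' with per-cluster mean shifts, survival driven by a signature score, and
#' analyte panels coupled to the latent factors.
#'
#' Each clustered gene g in cluster c is generated as
#' `x_gs = a_g * f_cs + delta * 1[miliary(s)] * d_c + eps_gs`
#' with factor `f_cs ~ N(0,1)`, loading `a_g` drawn from `loading_range`
#' (hub genes sit at the top of the range), direction `d_c` alternating
#' +1/-1 over clusters, and noise `eps ~ N(0, noise_sd^2)`. Remaining genes
#' are pure noise. A gene-specific baseline on the log2 scale is added so
#' values resemble log-expression.
#'
#' @param n_genes,n_samples,n_clusters dimensions of the dataset.
#' @param cluster_sizes integer vector of planted cluster sizes
#'   (`sum(cluster_sizes) <= n_genes`).
#' @param loading_range range the factor loadings are drawn from.
#' @param noise_sd residual standard deviation (> 0).
#' @param group_effect per-cluster mean shift delta between groups.
#' @param hub_fraction fraction of each cluster drawn with loadings at the
#'   top of `loading_range`.
#' @param hazard_coef log-hazard coefficient on the true signature score.
#' @param censor_rate target fraction of censored survival records, in [0, 1).
#' @param analyte_coupling linear coupling of analytes to cluster factors.
#' @param nested_parent_loading loading of a shared parent factor mixed into
#'   every cluster factor (0 disables nesting).
#' @param seed integer seed; all generators are deterministic given the seed.
#' @return a `synth_config` object.
#' @export
synth_config <- function(n_genes = 600, n_samples = 80, n_clusters = 3,
                         cluster_sizes = rep(50L, n_clusters),
                         loading_range = c(0.8, 0.95), noise_sd = 0.5,
                         group_effect = 1.5, hub_fraction = 0.1,
                         hazard_coef = 1.1, censor_rate = 0.3,
                         analyte_coupling = 1, nested_parent_loading = 0,
                         seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              n_clusters = as.integer(n_clusters),
              cluster_sizes = as.integer(cluster_sizes),
              loading_range = as.numeric(loading_range),
              noise_sd = noise_sd, group_effect = group_effect,
              hub_fraction = hub_fraction, hazard_coef = hazard_coef,
              censor_rate = censor_rate, analyte_coupling = analyte_coupling,
              nested_parent_loading = nested_parent_loading,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (length(cfg$cluster_sizes) != cfg$n_clusters)
    stop("cluster_sizes: length must equal n_clusters")
  if (sum(cfg$cluster_sizes) > cfg$n_genes)
    stop("cluster_sizes: sum(cluster_sizes) must be <= n_genes")
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd <= 0)
    stop("noise_sd: must be > 0")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stop("censor_rate: must be in [0, 1)")
  if (cfg$hub_fraction < 0 || cfg$hub_fraction > 1)
    stop("hub_fraction: must be in [0, 1]")
  if (length(cfg$loading_range) != 2 || diff(cfg$loading_range) < 0)
    stop("loading_range: must be an increasing interval")
  if (cfg$n_samples < 4) stop("n_samples: must be >= 4")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0("synthetic-data config: %d genes (%d clusters: %s), ",
                     "%d samples\n  loadings [%.2f, %.2f], noise sd %.2f, ",
                     "group effect %.2f, hazard coef %.2f, seed %d\n"),
              x$n_genes, x$n_clusters, paste(x$cluster_sizes, collapse = "/"),
              x$n_samples, x$loading_range[1], x$loading_range[2], x$noise_sd,
              x$group_effect, x$hazard_coef, x$seed))
  invisible(x)
}

#' Generate a synthetic expression matrix with planted clusters
#'
#' Draws log2-scale expression from the latent-factor model described in
#' [synth_config()] and returns both the matrix and the ground truth used
#' downstream for parameter-recovery checks.
#'
#' @param config a [synth_config()].
#' @return list with elements `expr` (an [expression_matrix()], log2 scale)
#'   and `truth`: cluster membership per gene (NA = background), hub genes,
#'   group labels per sample, the per-sample true signature score (centred),
#'   the true log-hazard coefficient, and the latent factor matrix
#'   (clusters x samples).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  set.seed(config$seed)
  n <- config$n_genes; S <- config$n_samples; K <- config$n_clusters
  sizes <- config$cluster_sizes
  gene_ids <- sprintf("g%04d", seq_len(n))
  sample_ids <- sprintf("s%03d", seq_len(S))

  groups <- sample(rep(c("miliary", "non_miliary"), length.out = S))
  mil <- as.numeric(groups == "miliary")

  f <- matrix(rnorm(K * S), K, S, dimnames = list(NULL, sample_ids))
  if (config$nested_parent_loading > 0) {
    b <- config$nested_parent_loading
    fp <- rnorm(S)
    f <- sqrt(1 - b^2) * f + b * matrix(fp, K, S, byrow = TRUE)
  }
  d <- rep(c(1, -1), length.out = K)

  membership <- rep(NA_integer_, n)
  loadings <- rep(NA_real_, n)
  hubs <- character(0)
  X <- matrix(rnorm(n * S, sd = config$noise_sd), n, S,
              dimnames = list(gene_ids, sample_ids))
  pos <- 1L
  for (c_ in seq_len(K)) {
    idx <- seq.int(pos, pos + sizes[c_] - 1L)
    pos <- pos + sizes[c_]
    membership[idx] <- c_
    a <- runif(sizes[c_], config$loading_range[1], config$loading_range[2])
    n_hub <- round(config$hub_fraction * sizes[c_])
    if (n_hub > 0) {
      a[seq_len(n_hub)] <- config$loading_range[2]
      hubs <- c(hubs, gene_ids[idx[seq_len(n_hub)]])
    }
    loadings[idx] <- a
    X[idx, ] <- X[idx, ] + a %o% f[c_, ] +
      config$group_effect * d[c_] * matrix(mil, sizes[c_], S, byrow = TRUE)
  }
  baseline <- rnorm(n, mean = 6, sd = 0.5)
  X <- X + baseline

  names(membership) <- gene_ids
  sig <- numeric(S)
  if (K >= 1 && sizes[1] > 0) {
    a1 <- loadings[which(membership == 1L)]
    sig <- mean(a1) * f[1, ] + config$group_effect * d[1] * mil
    sig <- sig - mean(sig)
  }
  names(sig) <- sample_ids
  truth <- list(cluster_membership = membership,
                hub_genes = hubs,
                group_labels = setNames(factor(groups,
                                               levels = c("non_miliary", "miliary")),
                                        sample_ids),
                true_signature = sig,
                true_beta = config$hazard_coef,
                cluster_direction = d,
                loadings = setNames(loadings, gene_ids),
                factors = f)
  list(expr = expression_matrix(X, "log2"), truth = truth)
}

#' Generate negative-binomial counts from log2 expression
#'
#' Per-sample means are proportional to `2^x`, scaled to the requested
#' library size. `dispersion = 0` degenerates to Poisson sampling.
#'
#' @param expr log2-scale [expression_matrix()].
#' @param lib_sizes per-sample library sizes (positive).
#' @param dispersion negative-binomial dispersion (>= 0).
#' @param seed optional seed.
#' @return counts-scale [expression_matrix()].
#' @export
generate_counts <- function(expr, lib_sizes, dispersion = 0.1, seed = NULL) {
  if (length(lib_sizes) == 1) lib_sizes <- rep(lib_sizes, ncol(expr))
  if (any(lib_sizes <= 0)) stop("lib_sizes must be positive")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  lambda <- 2^unclass(expr)
  mu <- sweep(lambda, 2, colSums(lambda), "/")
  mu <- sweep(mu, 2, lib_sizes, "*")
  cnt <- if (dispersion == 0) {
    matrix(rpois(length(mu), mu), nrow(mu), ncol(mu))
  } else {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
           nrow(mu), ncol(mu))
  }
  dimnames(cnt) <- dimnames(expr)
  expression_matrix(cnt, "counts")
}

#' Generate survival records driven by a signature score
#'
#' Event times are exponential with hazard
#' `baseline * exp(truth_beta * score)`. Censoring is independent uniform on
#' `[0, T_max]` with `T_max` solved numerically so the expected censoring
#' fraction equals `censor_rate`.
#'
#' @param scores named per-sample score vector.
#' @param truth_beta log-hazard coefficient.
#' @param baseline baseline hazard (> 0), per month.
#' @param censor_rate target censoring fraction in [0, 1).
#' @param seed optional seed.
#' @return data.frame with columns `sample`, `time`, `event` (1 = event
#'   observed, 0 = censored).
#' @export
generate_survival <- function(scores, truth_beta, baseline = 0.02,
                              censor_rate = 0.3, seed = NULL) {
  if (baseline <= 0) stop("baseline hazard must be > 0")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n <- length(scores)
  rate <- baseline * exp(truth_beta * scores)
  tt <- rexp(n, rate)
  if (censor_rate == 0) {
    out <- data.frame(sample = names2(scores), time = tt, event = 1L)
    return(out)
  }
  # expected censor fraction for uniform censoring on [0, tmax]
  cens_frac <- function(tmax) mean((1 - exp(-rate * tmax)) / (rate * tmax)) -
    censor_rate
  tmax <- uniroot(cens_frac, lower = 1e-9, upper = 1e9, tol = 1e-10)$root
  cc <- runif(n, 0, tmax)
  data.frame(sample = names2(scores), time = pmin(tt, cc),
             event = as.integer(tt <= cc))
}

#' Generate analyte panels coupled to latent factors
#'
#' Each column of `pc1s` gives one coupled analyte
#' `coupling * PC1_k + noise`; `n_null` additional analytes are pure noise.
#'
#' @param pc1s samples x factors matrix (e.g. the true latent factors or
#'   estimated cluster PC1s).
#' @param coupling linear coupling coefficient (finite).
#' @param noise_sd noise standard deviation.
#' @param n_null number of uncoupled analytes.
#' @param seed optional seed.
#' @return list with `analytes` (samples x analytes matrix) and `truth`
#'   (data.frame mapping coupled analytes to their factor and sign).
#' @export
generate_analytes <- function(pc1s, coupling = 1, noise_sd = 1, n_null = 20,
                              seed = NULL) {
  if (!is.finite(coupling)) stop("coupling must be finite")
  if (!is.null(seed)) set.seed(seed)
  pc1s <- as.matrix(pc1s)
  S <- nrow(pc1s); K <- ncol(pc1s)
  if (is.null(colnames(pc1s))) colnames(pc1s) <- paste0("factor", seq_len(K))
  coupled <- coupling * pc1s +
    matrix(rnorm(S * K, sd = noise_sd), S, K)
  colnames(coupled) <- paste0("analyte_", colnames(pc1s))
  nulls <- matrix(rnorm(S * n_null, sd = noise_sd), S, n_null)
  colnames(nulls) <- sprintf("analyte_null%02d", seq_len(n_null))
  analytes <- cbind(coupled, nulls)
  rownames(analytes) <- rownames(pc1s)
  truth <- if (coupling == 0) {
    data.frame(analyte = character(0), factor = character(0), sign = integer(0))
  } else {
    data.frame(analyte = colnames(coupled), factor = colnames(pc1s),
               sign = as.integer(sign(coupling)))
  }
  list(analytes = analytes, truth = truth)
}

names2 <- function(x) {
  if (is.null(names(x))) as.character(seq_along(x)) else names(x)
}

#' Write a synthetic dataset to a directory
#'
#' Expression as TSV, ground truth as JSON, survival and analytes as CSV.
#'
#' @param config a [synth_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the list of written paths.
#' @export
write_synth_dataset <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_expression(config)
  surv <- generate_survival(sim$truth$true_signature, config$hazard_coef,
                            censor_rate = config$censor_rate,
                            seed = config$seed + 1L)
  anal <- generate_analytes(t(sim$truth$factors),
                            coupling = config$analyte_coupling,
                            seed = config$seed + 2L)
  paths <- list(
    expr = file.path(outdir, "expression.tsv"),
    truth = file.path(outdir, "truth.json"),
    survival = file.path(outdir, "survival.csv"),
    analytes = file.path(outdir, "analytes.csv"))
  write_expression_tsv(sim$expr, paths$expr)
  tr <- sim$truth
  tr$group_labels <- as.character(tr$group_labels)
  tr$factors <- NULL
  jsonlite::write_json(tr, paths$truth, auto_unbox = TRUE, digits = NA,
                       na = "null")
  utils::write.csv(surv, paths$survival, row.names = FALSE)
  utils::write.csv(data.frame(sample = rownames(anal$analytes),
                              anal$analytes, check.names = FALSE),
                   paths$analytes, row.names = FALSE)
  invisible(paths)
}
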