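#' Configuration of a synthetic microbial community
#'
#' Parameter presets emulate the three community types of a coastal sponge
#' holobiont study: HMA (high-microbial-abundance) sponges with rich, even,
#' temporally stable and tightly co-varying communities; LMA
#' (low-microbial-abundance) sponges with few, dominance-skewed, high-turnover
#' taxa and a larger overlap with the seawater pool; and seawater itself, the
#' richest community and the source of the shared ASV pool.
#'
#' @param phenotype `"HMA"`, `"LMA"` or `"seawater"`; sets defaults for all
#'   unsupplied parameters.
#' @param richness number of ASVs in the community.
#' @param evenness Dirichlet concentration of the base composition (higher =
#'   more even).
#' @param turnover per-time-point log-abundance jitter scale (sd of the
#'   lognormal perturbation); drives temporal turnover.
#' @param assoc_strength fraction (0-1) of the temporal jitter shared within
#'   co-response modules; drives internal co-occurrence correlation.
#' @param module_size number of ASVs per co-response module.
#' @param env_response slope of the top-decile ASVs on the standardized
#'   temperature driver.
#' @param seawater_share fraction of the ASV id pool drawn from the shared
#'   seawater pool.
#' @param replicate_noise extra idiosyncratic log jitter per replicate;
#'   low for the tightly regulated HMA community.
#' @param depth reads per sample (>= 1000).
#' @param n_timepoints,n_replicates sampling design (defaults 5 and 3).
#' @return list of class `community_config`.
#' @export
community_config <- function(phenotype = c("HMA", "LMA", "seawater"),
                             richness = NULL, evenness = NULL,
                             turnover = NULL, assoc_strength = NULL,
                             module_size = NULL, env_response = NULL,
                             seawater_share = NULL, replicate_noise = NULL,
                             depth = 10000L, n_timepoints = 5L,
                             n_replicates = 3L) {
  phenotype <- match.arg(phenotype)
  defaults <- switch(phenotype,
    HMA = list(richness = 500L, evenness = 2, turnover = 1.0,
               assoc_strength = 0.98, module_size = 25L, env_response = 0.2,
               seawater_share = 0.2, replicate_noise = 0.03),
    LMA = list(richness = 150L, evenness = 0.25, turnover = 1.5,
               assoc_strength = 0.4, module_size = 15L, env_response = 0.6,
               seawater_share = 0.45, replicate_noise = 0.2),
    seawater = list(richness = 1200L, evenness = 1.2, turnover = 0.5,
                    assoc_strength = 0.3, module_size = 25L,
                    env_response = 0.8, seawater_share = 1,
                    replicate_noise = 0.15))
  cfg <- list(phenotype = phenotype,
              richness = richness %||% defaults$richness,
              evenness = evenness %||% defaults$evenness,
              turnover = turnover %||% defaults$turnover,
              assoc_strength = assoc_strength %||% defaults$assoc_strength,
              module_size = module_size %||% defaults$module_size,
              env_response = env_response %||% defaults$env_response,
              seawater_share = seawater_share %||% defaults$seawater_share,
              replicate_noise = replicate_noise %||% defaults$replicate_noise,
              depth = as.integer(depth),
              n_timepoints = as.integer(n_timepoints),
              n_replicates = as.integer(n_replicates))
  stopifnot(cfg$richness >= 1L, cfg$depth >= 1000L,
            cfg$seawater_share >= 0, cfg$seawater_share <= 1,
            cfg$assoc_strength >= 0, cfg$assoc_strength <= 1)
  structure(cfg, class = "community_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a seasonal environmental-variable series
#'
#' Five sampling months with a seasonal temperature sinusoid (about 14-30
#' degrees C, peaking at the middle time point), dissolved oxygen
#' anti-correlated with temperature, and the remaining variables drawn
#' lognormally around fixed coastal means.
#'
#' @param seed integer seed.
#' @param n_timepoints number of time points (default 5).
#' @return data.frame with month, temperature, salinity, DO, pH and
#'   nutrient columns (NO3, NO2, NH4, DIP, DOP, TDP, TP, SiO3).
#' @export
generate_env_series <- function(seed = 1L, n_timepoints = 5L) {
  set.seed(as.integer(seed))
  idx <- seq_len(n_timepoints)
  months <- if (n_timepoints == 5L) c(1L, 4L, 6L, 8L, 10L) else idx
  temp <- 14 + 16 * sin(pi * (idx - 1) / (n_timepoints - 1)) +
    stats::rnorm(n_timepoints, 0, 0.4)
  do <- 9.5 - 0.18 * (temp - 14) + stats::rnorm(n_timepoints, 0, 0.15)
  lnorm <- function(mu, sd = 0.3) stats::rlnorm(n_timepoints, log(mu), sd)
  dip <- lnorm(0.5)
  dop <- lnorm(0.3)
  data.frame(
    month = months,
    temperature = temp,
    salinity = 33 + stats::rnorm(n_timepoints, 0, 0.4),
    DO = do,
    pH = 8.1 + stats::rnorm(n_timepoints, 0, 0.05),
    NO3 = lnorm(5), NO2 = lnorm(0.5), NH4 = lnorm(2),
    DIP = dip, DOP = dop, TDP = dip + dop,
    TP = dip + dop + lnorm(0.2), SiO3 = lnorm(20))
}

#' Generate a synthetic community time series
#'
#' Base composition is Dirichlet (gamma draws with shape `evenness`); each
#' time point receives a lognormal log-abundance perturbation of scale
#' `turnover` split between a module-shared component (weight
#' `assoc_strength`, one latent factor per co-response module per time
#' point) and an idiosyncratic component, plus an environmental response of
#' the top-decile ASVs to the standardized temperature driver. Replicates
#' add small idiosyncratic jitter, and counts are multinomial at the
#' configured depth. A fraction `seawater_share` of the ASV ids is drawn
#' from `seawater_pool`, so shared-ASV summaries against the seawater table
#' are meaningful.
#'
#' @param cfg a [community_config()].
#' @param env optional environmental series from [generate_env_series()];
#'   when NULL the environmental driver is zero.
#' @param seed integer seed.
#' @param host_label prefix for sample and host-specific ASV ids.
#' @param seawater_pool character vector of seawater ASV ids to share from.
#' @return list with `table` (an [asv_table()]), `metadata` (data.frame) and
#'   `cfg`.
#' @export
generate_community <- function(cfg, env = NULL, seed = 1L,
                               host_label = cfg$phenotype,
                               seawater_pool = NULL) {
  stopifnot(inherits(cfg, "community_config"))
  set.seed(as.integer(seed))
  r <- cfg$richness
  n_shared <- round(cfg$seawater_share * r)
  if (is.null(seawater_pool)) n_shared <- 0L
  if (n_shared > 0L && length(seawater_pool) < n_shared) {
    stop("seawater pool smaller than the requested shared fraction")
  }
  ids <- character(r)
  if (n_shared > 0L) {
    ids[seq_len(n_shared)] <- sample(seawater_pool, n_shared)
  }
  if (n_shared < r) {
    ids[(n_shared + 1L):r] <- sprintf("%s_ASV%04d", host_label,
                                      seq_len(r - n_shared))
  }
  base <- stats::rgamma(r, shape = cfg$evenness, rate = 1)
  base <- base / sum(base)
  top_decile <- base >= stats::quantile(base, 0.9)
  n_mod <- max(1L, ceiling(r / cfg$module_size))
  module <- sample(rep(seq_len(n_mod), length.out = r))
  z_env <- if (is.null(env)) rep(0, cfg$n_timepoints) else
    as.numeric(scale(env$temperature))
  months <- if (!is.null(env)) env$month else seq_len(cfg$n_timepoints)

  w <- cfg$assoc_strength
  counts <- matrix(0L, r, cfg$n_timepoints * cfg$n_replicates)
  meta <- vector("list", ncol(counts))
  k <- 0L
  for (t in seq_len(cfg$n_timepoints)) {
    f <- stats::rnorm(n_mod)
    eps <- stats::rnorm(r)
    eta_t <- cfg$turnover * (w * f[module] + sqrt(1 - w^2) * eps) +
      ifelse(top_decile, cfg$env_response * z_env[t], 0)
    for (rep_i in seq_len(cfg$n_replicates)) {
      k <- k + 1L
      eta <- eta_t + cfg$replicate_noise * stats::rnorm(r)
      p <- base * exp(eta)
      p <- p / sum(p)
      counts[, k] <- stats::rmultinom(1L, cfg$depth, p)[, 1L]
      meta[[k]] <- data.frame(
        sample_id = sprintf("%s_T%02d_R%d", host_label, months[t], rep_i),
        host = host_label,
        phenotype = if (cfg$phenotype == "seawater") NA_character_ else
          cfg$phenotype,
        habitat = if (cfg$phenotype == "seawater") "seawater" else "sponge",
        month = months[t], replicate = rep_i,
        stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta)
  dimnames(counts) <- list(ids, meta$sample_id)
  list(table = asv_table(counts), metadata = meta, cfg = cfg)
}

#' Plant a ground-truth association network
#'
#' @param n_nodes number of ASVs.
#' @param n_edges number of planted associations.
#' @param rho latent correlation magnitude in (0, 1).
#' @param frac_negative fraction of planted edges with negative sign.
#' @param structure `"matching"` plants vertex-disjoint pairs (always
#'   positive definite); `"random"` plants arbitrary pairs (may need
#'   thinning downstream).
#' @param seed integer seed.
#' @return list of class `ground_truth_network`: `edges` (data.frame from,
#'   to, sign), `n_nodes`, `rho`, `asv_ids`.
#' @export
generate_ground_truth <- function(n_nodes, n_edges, rho = 0.8,
                                  frac_negative = 0,
                                  structure = c("matching", "random"),
                                  seed = 1L) {
  structure_type <- match.arg(structure)
  stopifnot(rho > 0, rho < 1)
  set.seed(as.integer(seed))
  ids <- sprintf("ASV%04d", seq_len(n_nodes))
  if (structure_type == "matching") {
    if (2L * n_edges > n_nodes) stop("too many edges for a matching")
    picked <- sample(ids, 2L * n_edges)
    edges <- data.frame(from = picked[seq_len(n_edges)],
                        to = picked[n_edges + seq_len(n_edges)],
                        stringsAsFactors = FALSE)
  } else {
    all_pairs <- utils::combn(ids, 2L)
    pick <- sample(ncol(all_pairs), n_edges)
    edges <- data.frame(from = all_pairs[1L, pick], to = all_pairs[2L, pick],
                        stringsAsFactors = FALSE)
  }
  edges$sign <- ifelse(stats::runif(n_edges) < frac_negative, -1L, 1L)
  base::structure(list(edges = edges, n_nodes = n_nodes, rho = rho,
                       asv_ids = ids),
                  class = "ground_truth_network")
}

#' Generate counts with planted pairwise correlations
#'
#' A latent Gaussian copula: unit-variance normals with correlation
#' +/- rho on the planted edges and zero elsewhere; each ASV's latent values
#' are pushed through a monotone lognormal map (preserving rank
#' correlations) and samples are drawn multinomially at the requested depth.
#' If the requested correlation matrix is not positive definite, edges are
#' thinned at random (with a warning) until it is; the edges actually
#' planted are returned.
#'
#' @param gt a `ground_truth_network` from [generate_ground_truth()].
#' @param n_samples number of samples to draw.
#' @param depth reads per sample.
#' @param seed integer seed.
#' @param log_sd spread of per-ASV base log abundances.
#' @return list with `table` (an [asv_table()]) and `ground_truth` (the
#'   possibly thinned `ground_truth_network`).
#' @export
generate_correlated_counts <- function(gt, n_samples, depth = 50000L,
                                       seed = 1L, log_sd = 1) {
  stopifnot(inherits(gt, "ground_truth_network"))
  set.seed(as.integer(seed))
  ids <- gt$asv_ids
  idx <- stats::setNames(seq_along(ids), ids)
  edges <- gt$edges
  sigma_of <- function(e) {
    s <- diag(length(ids))
    for (k in seq_len(nrow(e))) {
      i <- idx[[e$from[k]]]; j <- idx[[e$to[k]]]
      s[i, j] <- s[j, i] <- e$sign[k] * gt$rho
    }
    s
  }
  sigma <- sigma_of(edges)
  while (nrow(edges) > 0L &&
         min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <
           1e-8) {
    drop_k <- sample.int(nrow(edges), 1L)
    edges <- edges[-drop_k, , drop = FALSE]
    warning("planted edge dropped to keep the copula positive definite")
    sigma <- sigma_of(edges)
  }
  z <- matrix(stats::rnorm(n_samples * length(ids)), n_samples) %*%
    chol(sigma)
  mu <- stats::rnorm(length(ids), 0, log_sd)
  a <- exp(sweep(0.8 * z, 2L, mu, "+"))
  counts <- apply(a, 1L, function(row) {
    stats::rmultinom(1L, depth, row / sum(row))[, 1L]
  })
  dimnames(counts) <- list(ids, sprintf("S%03d", seq_len(n_samples)))
  gt$edges <- edges
  list(table = asv_table(counts), ground_truth = gt)
}

#' Precision and recall of planted-edge recovery
#'
#' Compares the edge set of an inferred network against the planted ground
#' truth (unordered pairs).
#'
#' @param g an [igraph::graph] (inferred network).
#' @param gt a `ground_truth_network`.
#' @return list with `precision`, `recall`, `n_inferred`, `n_true`.
#' @export
edge_recovery <- function(g, gt) {
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  el <- igraph::as_data_frame(g, what = "edges")
  inferred <- if (nrow(el)) pair_key(el$from, el$to) else character(0)
  truth <- pair_key(gt$edges$from, gt$edges$to)
  hit <- intersect(inferred, truth)
  list(precision = if (length(inferred)) length(hit) / length(inferred)
         else NA_real_,
       recall = if (length(truth)) length(hit) / length(truth) else NA_real_,
       n_inferred = length(inferred), n_true = length(truth))
}

#' Generate a full synthetic holobiont study
#'
#' Emulates the sampling design of a coastal sponge time series: seawater
#' plus three sponge hosts (one HMA-like, two LMA-like), each sampled at 5
#' time points in 3 replicates, with a shared environmental series and a
#' common seawater ASV pool.
#'
#' @param seed integer seed.
#' @param depth reads per sample for every community.
#' @return list with `groups` (named list of `generate_community()` outputs
#'   for Seawater, Spongia_like (HMA), Tedania_like and Haliclona_like
#'   (LMA)), `env`, `combined` (merged [asv_table()]) and `metadata`.
#' @export
generate_holobiont_dataset <- function(seed = 1L, depth = 10000L) {
  set.seed(as.integer(seed))
  sub <- sample.int(1e6, 5L)
  env <- generate_env_series(seed = sub[1L])
  sw <- generate_community(community_config("seawater", depth = depth),
                           env, seed = sub[2L], host_label = "SW")
  pool <- rownames(sw$table)
  groups <- list(
    Seawater = sw,
    Spongia_like = generate_community(community_config("HMA", depth = depth),
                                      env, seed = sub[3L],
                                      host_label = "Spongia_like",
                                      seawater_pool = pool),
    Tedania_like = generate_community(community_config("LMA", depth = depth),
                                      env, seed = sub[4L],
                                      host_label = "Tedania_like",
                                      seawater_pool = pool),
    Haliclona_like = generate_community(community_config("LMA",
                                                         depth = depth),
                                        env, seed = sub[5L],
                                        host_label = "Haliclona_like",
                                        seawater_pool = pool))
  combined <- merge_asv_tables(lapply(groups, `[[`, "table"))
  metadata <- do.call(rbind, lapply(groups, `[[`, "metadata"))
  rownames(metadata) <- NULL
  list(groups = groups, env = env, combined = combined, metadata = metadata)
}
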