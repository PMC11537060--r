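#' Default pipeline configuration
#'
#' @param input optional list of file paths (`asv_table`, `metadata`,
#'   `env`) to analyze real data; when NULL a synthetic holobiont study is
#'   generated.
#' @param depth reads per sample for the synthetic generator.
#' @param prevalence prevalence cutoff before network / LSA construction.
#' @param max_network_nodes cap on network size (top ASVs by mean relative
#'   abundance after the prevalence filter).
#' @param rmt_scan,rmt_step,rmt_alpha RMT threshold scan parameters.
#' @param null_n null-ensemble size per network.
#' @param n_perm permutations for the community tests (ANOSIM, PERMANOVA,
#'   MRPP, Mantel).
#' @param lsa_D,lsa_n_perm,lsa_q_max,max_lsa_nodes LSA parameters.
#' @param vif_threshold collinearity cutoff for environmental screening.
#' @return configuration list.
#' @export
pipeline_config <- function(input = NULL, depth = 10000L, prevalence = 0.5,
                            max_network_nodes = 500L,
                            rmt_scan = c(0.30, 0.99), rmt_step = 0.01,
                            rmt_alpha = 0.05, null_n = 100L, n_perm = 999L,
                            lsa_D = 1L, lsa_n_perm = 999L, lsa_q_max = 0.05,
                            max_lsa_nodes = 100L, vif_threshold = 20) {
  as.list(environment())
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

top_abundant <- function(tab, k) {
  if (nrow(tab) <= k) return(tab)
  rel <- to_relative(tab)
  keep <- order(rowMeans(rel), decreasing = TRUE)[seq_len(k)]
  out <- as_plain_matrix(tab)[sort(keep), , drop = FALSE]
  asv_table(out)
}

rmt_threshold_or_best <- function(c_mat, config) {
  tryCatch({
    th <- rmt_threshold(c_mat, scan = config$rmt_scan,
                        step = config$rmt_step, alpha = config$rmt_alpha)
    list(threshold = th$threshold, flagged = FALSE,
         diagnostics = th$diagnostics)
  }, rmt_no_threshold = function(e) {
    d <- e$diagnostics
    best <- d$s[which.max(ifelse(is.na(d$p_poisson), -1, d$p_poisson))]
    warning("no Poisson-consistent threshold; using best-fitting s = ",
            best, call. = FALSE)
    list(threshold = best, flagged = TRUE, diagnostics = d)
  })
}

#' Run the full holobiont microbiome analysis
#'
#' Sequences the whole workflow on real or synthetic inputs: data loading or
#' generation, abundance-class partitioning, alpha/beta diversity with
#' permutation tests and environmental screening, Levins niche breadth,
#' per-group co-occurrence networks (RMT threshold, topology, null
#' ensemble, keystones), and bipartite host-seawater LSA networks. All
#' randomness derives from `seed`, so a rerun with the same configuration
#' and seed reproduces the report exactly.
#'
#' @param config list from [pipeline_config()].
#' @param seed integer master seed.
#' @param out_dir optional directory; when given, the JSON report and
#'   per-stage TSV/newick/GraphML files are written there.
#' @return list of class `analysis_report` (see sections `data`, `classes`,
#'   `community`, `niche`, `networks`, `lsa`, `provenance`).
#' @export
run_full_analysis <- function(config = pipeline_config(), seed = 1L,
                              out_dir = NULL) {
  seed <- as.integer(seed)
  set.seed(seed)
  sub <- sample.int(1e6, 6L)

  dat <- stage("core_data", {
    if (is.null(config$input)) {
      generate_holobiont_dataset(seed = sub[1L], depth = config$depth)
    } else {
      for (f in c("asv_table", "metadata")) {
        if (is.null(config$input[[f]])) {
          stop("config$input is missing the '", f, "' field")
        }
      }
      combined <- read_asv_table(config$input$asv_table)
      metadata <- read_sample_metadata(config$input$metadata)
      validate_metadata(combined, metadata)
      env <- if (!is.null(config$input$env)) {
        utils::read.delim(config$input$env, check.names = FALSE)
      }
      groups <- lapply(split(metadata, metadata$host), function(md) {
        tab <- combined[, md$sample_id, drop = FALSE]
        class(tab) <- c("asv_table", "matrix", "array")
        list(table = tab, metadata = md)
      })
      list(groups = groups, env = env, combined = combined,
           metadata = metadata)
    }
  })
  groups <- dat$groups
  host_of <- stats::setNames(dat$metadata$host, dat$metadata$sample_id)
  sponge_hosts <- names(groups)[vapply(groups, function(g) {
    g$metadata$habitat[1L] == "sponge"
  }, logical(1))]
  seawater_name <- setdiff(names(groups), sponge_hosts)[1L]

  classes <- stage("abundance_classes", {
    lapply(groups, function(g) classify_table(to_relative(g$table)))
  })

  community <- stage("community_stats", {
    alpha <- alpha_diversity_table(dat$combined)
    alpha$host <- unname(host_of[alpha$sample_id])
    bc <- bray_curtis(dat$combined)
    tree <- upgma_tree(bc)
    grp <- host_of[colnames(dat$combined)]
    tests <- list(
      anosim = anosim_test(bc, grp, n_perm = config$n_perm, seed = sub[2L]),
      permanova = permanova_test(bc, grp, n_perm = config$n_perm,
                                 seed = sub[2L]),
      mrpp = mrpp_test(bc, grp, n_perm = config$n_perm, seed = sub[2L]))
    mantel <- vif <- NULL
    if (!is.null(dat$env)) {
      env_cols <- setdiff(names(dat$env), "month")
      env_by_sample <- dat$env[match(dat$metadata$month, dat$env$month),
                               env_cols]
      rownames(env_by_sample) <- dat$metadata$sample_id
      env_by_sample <- env_by_sample[colnames(dat$combined), ]
      vif <- vif_screen(env_by_sample, threshold = config$vif_threshold)
      denv <- stats::dist(scale(env_by_sample[, vif$retained, drop = FALSE]))
      mantel <- mantel_test(bc, denv, n_perm = config$n_perm,
                            seed = sub[3L])
    }
    list(alpha = alpha, bray_curtis = bc, newick = ape::write.tree(tree),
         tests = tests, mantel = mantel, vif = vif)
  })

  shared <- stage("shared_asvs", {
    if (length(sponge_hosts) && !is.na(seawater_name)) {
      sw_tab <- groups[[seawater_name]]$table
      lapply(groups[sponge_hosts], function(g) {
        shared_asv_summary(g$table, sw_tab)
      })
    }
  })

  niche <- stage("niche_breadth", {
    lapply(groups, function(g) community_niche_width(g$table))
  })

  networks <- stage("comen", {
    out <- list()
    for (nm in names(groups)) {
      tab <- filter_prevalence(groups[[nm]]$table, config$prevalence)
      tab <- top_abundant(tab, config$max_network_nodes)
      if (nrow(tab) < 10L) {
        out[[nm]] <- list(skipped = TRUE,
                          reason = "fewer than 10 prevalent ASVs")
        next
      }
      cm <- suppressWarnings(spearman_matrix(tab))
      th <- suppressWarnings(rmt_threshold_or_best(cm, config))
      g <- build_network(cm, th$threshold)
      if (igraph::vcount(g) == 0L || igraph::ecount(g) < 2L) {
        out[[nm]] <- list(skipped = TRUE, threshold = th$threshold,
                          reason = "network empty at the RMT threshold")
        next
      }
      topo <- network_topology(g)
      nulls <- null_ensemble(g, n = config$null_n, seed = sub[4L])
      keys <- keystone_species(topo, k = 10L)
      out[[nm]] <- list(skipped = FALSE, threshold = th$threshold,
                        threshold_flagged = th$flagged, graph = g,
                        topology = topo, null_ensemble = nulls,
                        keystones = keys, n_candidate_asvs = nrow(tab))
    }
    out
  })

  lsa <- stage("lsa_bipartite", {
    sw_tab <- groups[[seawater_name]]$table
    sw_rel <- to_relative(filter_prevalence(sw_tab, config$prevalence))
    sw_rel <- sw_rel[utils::head(order(rowMeans(sw_rel), decreasing = TRUE),
                                 config$max_lsa_nodes), , drop = FALSE]
    sw_series <- average_replicates(sw_rel,
                                    groups[[seawater_name]]$metadata$month)
    out <- list()
    for (nm in sponge_hosts) {
      sp_tab <- groups[[nm]]$table
      sp_rel <- to_relative(filter_prevalence(sp_tab, config$prevalence))
      sp_rel <- sp_rel[utils::head(order(rowMeans(sp_rel),
                                         decreasing = TRUE),
                                   config$max_lsa_nodes), , drop = FALSE]
      sp_series <- average_replicates(sp_rel, groups[[nm]]$metadata$month)
      # shared ASVs may sit in both tables; disambiguate node ids by side
      rownames(sp_series) <- paste0("sponge:", rownames(sp_series))
      sw_series2 <- sw_series
      rownames(sw_series2) <- paste0("seawater:", rownames(sw_series))
      res <- suppressMessages(
        lsa_all_pairs(sp_series, sw_series2, D = config$lsa_D,
                      n_perm = config$lsa_n_perm, seed = sub[5L],
                      q_max = config$lsa_q_max))
      habitat <- c(stats::setNames(rep("sponge", nrow(sp_series)),
                                   rownames(sp_series)),
                   stats::setNames(rep("seawater", nrow(sw_series2)),
                                   rownames(sw_series2)))
      out[[nm]] <- list(results = res,
                        summary = bipartite_summary(res, habitat))
    }
    out
  })

  report <- structure(list(
    data = list(n_samples = ncol(dat$combined), n_asvs = nrow(dat$combined),
                groups = names(groups), seawater_group = seawater_name),
    classes = classes, community = community, shared = shared,
    niche = niche, networks = networks, lsa = lsa,
    provenance = list(seed = seed, config = config,
                      package_version =
                        as.character(utils::packageVersion("spongenet")),
                      r_version = R.version.string)),
    class = "analysis_report")
  attr(report, "dataset") <- dat

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write an analysis report to disk
#'
#' Writes `report.json` plus per-stage TSV, newick and GraphML files.
#' Volatile fields (timestamps, file paths) are not recorded, so reruns
#' with the same seed produce byte-identical output.
#'
#' @param report an `analysis_report` from [run_full_analysis()].
#' @param out_dir output directory (created if needed).
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$community$alpha,
                     file.path(out_dir, "alpha_diversity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(report$community$newick, file.path(out_dir, "dendrogram.nwk"))
  for (nm in names(report$classes)) {
    write_abundance_classes(report$classes[[nm]],
                            file.path(out_dir,
                                      paste0("classes_", nm, ".tsv")))
  }
  for (nm in names(report$networks)) {
    nw <- report$networks[[nm]]
    if (isTRUE(nw$skipped)) next
    write_network_edgelist(nw$graph,
                           file.path(out_dir, paste0("network_", nm,
                                                     ".tsv")))
    write_network_graphml(nw$graph,
                          file.path(out_dir, paste0("network_", nm,
                                                    ".graphml")))
  }
  jsonlite::write_json(report_to_list(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# strip non-serializable members (graphs, dist objects) for the JSON report
report_to_list <- function(report) {
  perm_as_list <- function(p) {
    if (is.null(p)) return(NULL)
    unclass(p)
  }
  list(
    data = report$data,
    classes = lapply(report$classes, function(cl) cl$summary),
    community = list(
      alpha = report$community$alpha,
      newick = report$community$newick,
      tests = lapply(report$community$tests, perm_as_list),
      mantel = perm_as_list(report$community$mantel),
      vif = report$community$vif),
    shared = report$shared,
    niche = lapply(report$niche, function(nw) {
      list(community_mean_B = nw$community_mean_B,
           community_se_B = nw$community_se_B, r = nw$r,
           n_asvs = nrow(nw$per_asv))
    }),
    networks = lapply(report$networks, function(nw) {
      if (isTRUE(nw$skipped)) return(nw[c("skipped", "reason")])
      list(skipped = FALSE, threshold = nw$threshold,
           threshold_flagged = nw$threshold_flagged,
           topology = nw$topology[c("n_nodes", "n_links", "links_per_node",
                                    "avgK", "modularity", "connectedness")],
           null_ensemble = nw$null_ensemble$summary,
           keystones = nw$keystones,
           n_candidate_asvs = nw$n_candidate_asvs)
    }),
    lsa = lapply(report$lsa, function(l) {
      list(n_pairs_tested = nrow(l$results),
           summary = l$summary[c("n_edges", "frac_positive",
                                 "frac_negative")],
           breakdown = l$summary$breakdown)
    }),
    provenance = report$provenance)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Holobiont microbiome analysis report\n")
  cat(sprintf("  %d samples, %d ASVs, groups: %s\n", x$data$n_samples,
              x$data$n_asvs, paste(x$data$groups, collapse = ", ")))
  for (nm in names(x$networks)) {
    nw <- x$networks[[nm]]
    if (isTRUE(nw$skipped)) {
      cat(sprintf("  network %s: skipped (%s)\n", nm, nw$reason))
    } else {
      cat(sprintf("  network %s: s_t = %.2f, N = %d, L = %d, avgK = %.2f\n",
                  nm, nw$threshold, nw$topology$n_nodes,
                  nw$topology$n_links, nw$topology$avgK))
    }
  }
  invisible(x)
}
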