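# Orchestration: one config drives the whole workflow from expression
# table to enrichment, plus the qPCR branch; every stage logs record
# counts into a manifest that is written on success and on failure.

#' Build and validate a pipeline configuration
#'
#' @param expression,groups,annotation,interactions,gene_sets Paths to
#'   the input tables (see the `read_*` functions for formats).
#' @param out_dir Output directory (created if absent).
#' @param ct Optional path to a qPCR Ct table; enables the qPCR branch.
#' @param contrasts List of group pairs for feature selection.
#' @param disease_groups The two group labels whose consensus signatures
#'   seed the disease networks.
#' @param n1,n2 Signature half-lengths (defaults 100/100).
#' @param k Similarity-graph percentile (default 10).
#' @param alpha Feature-selection p-value threshold (default 0.01).
#' @param fdr Enrichment q-value threshold (default 0.05).
#' @param scale Expression scale, `"linear"` or `"log2"`.
#' @param taxon Interactome taxon filter (default 9606).
#' @param universe Enrichment background: `"annotation"` (all annotated
#'   platform genes, the default) or `"interactome"` (all interactome
#'   nodes).
#' @param ct_reference_genes,ct_control_group,ct_contrast qPCR branch
#'   settings: reference genes, calibrator group, and the two groups to
#'   compare by rank product.
#' @param n_perm Rank-product permutations (default 10000).
#' @param seed Integer seed for the permutation draw.
#' @param include_timestamps Record wall-clock times in the manifest;
#'   off by default so that identical config + seed reproduce the output
#'   tree byte for byte.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, groups, annotation, interactions,
                            gene_sets, out_dir,
                            ct = NULL,
                            contrasts = list(c("T2DM_CTRL", "NONT2DM_CTRL"),
                                             c("T2DM_AD", "NONT2DM_AD")),
                            disease_groups = c("T2DM_CTRL", "NONT2DM_AD"),
                            n1 = 100, n2 = 100, k = 10,
                            alpha = 0.01, fdr = 0.05,
                            scale = c("linear", "log2"),
                            taxon = 9606L,
                            universe = c("annotation", "interactome"),
                            ct_reference_genes = NULL,
                            ct_control_group = NULL,
                            ct_contrast = NULL,
                            n_perm = 10000, seed = 1,
                            include_timestamps = FALSE) {
  scale <- match.arg(scale)
  universe <- match.arg(universe)
  for (p in c(expression, groups, annotation, interactions, gene_sets, ct)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  stopifnot(n1 >= 1, n2 >= 1, k > 0, k <= 100,
            alpha > 0, alpha < 1, fdr > 0, fdr <= 1,
            length(disease_groups) == 2, n_perm >= 1)
  if (!is.null(ct)) {
    if (is.null(ct_reference_genes) || is.null(ct_control_group) ||
        is.null(ct_contrast) || length(ct_contrast) != 2) {
      stop("the qPCR branch needs ct_reference_genes, ct_control_group ",
           "and a length-2 ct_contrast", call. = FALSE)
    }
  }
  structure(
    list(expression = expression, groups = groups, annotation = annotation,
         interactions = interactions, gene_sets = gene_sets, ct = ct,
         out_dir = out_dir, contrasts = contrasts,
         disease_groups = disease_groups,
         n1 = n1, n2 = n2, k = k, alpha = alpha, fdr = fdr, scale = scale,
         taxon = taxon, universe = universe,
         ct_reference_genes = ct_reference_genes,
         ct_control_group = ct_control_group, ct_contrast = ct_contrast,
         n_perm = n_perm, seed = seed,
         include_timestamps = include_timestamps),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; `contrasts` is a
#' list of two-element lists. Relative paths are resolved against the
#' config file's directory.
#'
#' @param path Path to the YAML config.
#' @param ... Overrides passed on to [pipeline_config()] (CLI flags win
#'   over config keys).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("expression", "groups", "annotation", "interactions",
                "gene_sets", "ct", "out_dir")) {
    if (!is.null(cfg[[key]]) && !grepl("^(/|[A-Za-z]:)", cfg[[key]])) {
      cfg[[key]] <- file.path(base, cfg[[key]])
    }
  }
  if (!is.null(cfg$contrasts)) {
    cfg$contrasts <- lapply(cfg$contrasts, unlist)
  }
  if (!is.null(cfg$disease_groups)) cfg$disease_groups <- unlist(cfg$disease_groups)
  if (!is.null(cfg$ct_contrast)) cfg$ct_contrast <- unlist(cfg$ct_contrast)
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  do.call(pipeline_config, cfg)
}

write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

#' Run the full cross-disease workflow
#'
#' Stages: read inputs, fold-change profiles, feature selection,
#' subject signatures, distance matrix and similarity graph, consensus
#' signature per group, probe-to-gene translation for the two disease
#' groups, interactome construction, 1-step seed expansion per disease,
#' network overlap, over-representation of the overlap genes, and
#' (optionally) the qPCR branch. All stage outputs are written as
#' tab-separated tables under `config$out_dir`; a `manifest.json` with
#' the config snapshot and per-stage record counts is written on both
#' success and failure. Any stage error aborts with the stage name.
#'
#' @param config A `pipeline_config`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    config = unclass(config),
    version = as.character(utils::packageVersion("sig2net")),
    status = "running",
    stages = list()
  )
  if (config$include_timestamps) {
    manifest$started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  }
  finish <- function(status, error = NULL) {
    manifest$status <<- status
    if (!is.null(error)) manifest$error <<- error
    if (config$include_timestamps) {
      manifest$finished <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    }
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  current_stage <- "setup"
  stage <- function(name, expr) {
    current_stage <<- name
    expr
  }

  result <- tryCatch({
    expr <- groups <- ann <- records <- sets <- NULL
    stage("read_inputs", {
      expr <- read_expression_matrix(config$expression)
      groups <- validate_sample_groups(read_sample_groups(config$groups),
                                       colnames(expr))
      ann <- read_probe_annotation(config$annotation)
      records <- read_interactions(config$interactions)
      sets <- read_gene_sets(config$gene_sets)
      manifest$stages$read_inputs <- list(
        probes = nrow(expr), samples = ncol(expr),
        groups = length(unique(groups)),
        interaction_rows = nrow(records),
        interaction_rows_skipped = attr(records, "skipped"),
        gene_sets = length(sets)
      )
    })

    fc <- NULL
    stage("fold_change", {
      fc <- fold_change_profiles(expr, scale = config$scale)
      manifest$stages$fold_change <- list(features = nrow(fc),
                                           scale = config$scale)
    })

    features <- NULL
    stage("feature_selection", {
      features <- select_features(fc, groups, config$contrasts,
                                  alpha = config$alpha)
      fc_sel <- fc[features, , drop = FALSE]
      write_tsv(data.table::data.table(feature = rownames(fc_sel),
                                       data.table::as.data.table(fc_sel)),
                file.path(config$out_dir, "fold_change_selected.tsv"))
      manifest$stages$feature_selection <-
        list(selected = length(features), alpha = config$alpha)
    })

    sigs <- NULL
    stage("signatures", {
      sigs <- extract_signatures(fc, features, n1 = config$n1, n2 = config$n2)
      tab <- do.call(rbind, lapply(sigs, function(s) {
        data.frame(sample = s$sample,
                   direction = rep(c("up", "down"),
                                   c(length(s$up), length(s$down))),
                   rank = c(seq_along(s$up), seq_along(s$down)),
                   feature = c(s$up, s$down), stringsAsFactors = FALSE)
      }))
      write_tsv(tab, file.path(config$out_dir, "signatures.tsv"))
      manifest$stages$signatures <- list(samples = length(sigs),
                                          n1 = config$n1, n2 = config$n2)
    })

    dmat <- graph <- NULL
    stage("distance_matrix", {
      dmat <- distance_matrix(sigs)
      write_tsv(data.table::data.table(sample = rownames(dmat),
                                       data.table::as.data.table(dmat)),
                file.path(config$out_dir, "distance_matrix.tsv"))
      manifest$stages$distance_matrix <- list(samples = nrow(dmat))
    })
    stage("similarity_graph", {
      graph <- similarity_graph(dmat, k = config$k)
      write_tsv(graph$edges, file.path(config$out_dir, "graph_edges.tsv"))
      manifest$stages$similarity_graph <-
        list(edges = nrow(graph$edges), threshold = graph$threshold,
             k = config$k)
    })

    consensus <- list()
    stage("consensus", {
      for (g in unique(groups)) {
        cs <- consensus_signature(sigs[names(groups)[groups == g]],
                                  n1 = config$n1, n2 = config$n2, group = g)
        consensus[[g]] <- cs
        tab <- rbind(
          data.frame(feature = cs$up, direction = "up",
                     consensus_rank = seq_along(cs$up),
                     stringsAsFactors = FALSE),
          data.frame(feature = cs$down, direction = "down",
                     consensus_rank = seq_along(cs$down),
                     stringsAsFactors = FALSE)
        )
        pop <- rbind(cs$up_popularity, cs$down_popularity)
        tab$popularity <- pop$count[match(tab$feature, pop$feature)]
        write_tsv(tab, file.path(config$out_dir,
                                 sprintf("consensus_%s.tsv", g)))
      }
      manifest$stages$consensus <- lapply(
        consensus, function(cs) list(size = length(cs$up) + length(cs$down)))
    })

    seed_genes <- list()
    stage("gene_mapping", {
      for (g in config$disease_groups) {
        if (is.null(consensus[[g]])) {
          stop("disease group '", g, "' is not a group of the dataset")
        }
        probes <- c(consensus[[g]]$up, consensus[[g]]$down)
        seed_genes[[g]] <- map_probes_to_genes(probes, ann)
        writeLines(seed_genes[[g]],
                   file.path(config$out_dir,
                             sprintf("consensus_genes_%s.txt", g)))
      }
      manifest$stages$gene_mapping <- lapply(seed_genes, length)
    })

    inter <- NULL
    stage("interactome", {
      inter <- build_interactome(records, taxon = config$taxon)
      manifest$stages$interactome <- inter$counts
    })

    nets <- list()
    stage("networks", {
      for (g in config$disease_groups) {
        net <- expand_seed_network(inter, seed_genes[[g]], label = g)
        nets[[g]] <- net
        write_tsv(net$edges,
                  file.path(config$out_dir, sprintf("network_%s_edges.tsv", g)))
        write_tsv(network_node_table(net),
                  file.path(config$out_dir, sprintf("network_%s_nodes.tsv", g)))
      }
      manifest$stages$networks <- lapply(nets, function(n) {
        list(nodes = length(n$nodes), edges = nrow(n$edges),
             unmapped_seeds = length(n$unmapped))
      })
    })

    ov <- NULL
    stage("overlap", {
      ov <- overlap_network(nets[[1]], nets[[2]])
      writeLines(ov$nodes, file.path(config$out_dir, "overlap_nodes.txt"))
      write_tsv(ov$edges, file.path(config$out_dir, "overlap_edges.tsv"))
      manifest$stages$overlap <- list(nodes = length(ov$nodes),
                                       edges = nrow(ov$edges))
    })

    stage("enrichment", {
      uni <- if (config$universe == "annotation") {
        unique(ann[nzchar(ann)])
      } else {
        inter$nodes
      }
      res <- enrich(ov$nodes, sets, uni, fdr = config$fdr)
      write_tsv(res, file.path(config$out_dir, "enrichment.tsv"))
      manifest$stages$enrichment <-
        list(tested = nrow(res), significant = sum(res$significant),
             universe = length(uni), fdr = config$fdr)
    })

    if (!is.null(config$ct)) {
      stage("qpcr", {
        ct <- read_ct_table(config$ct, config$ct_reference_genes)
        rel <- ddct_relative_expression(ct, config$ct_control_group)
        write_tsv(data.table::data.table(
          gene = rownames(rel$ratios),
          data.table::as.data.table(rel$ratios)),
          file.path(config$out_dir, "qpcr_relative_expression.tsv"))
        rp <- rank_product_test(rel, config$ct_contrast[1],
                                config$ct_contrast[2],
                                n_perm = config$n_perm, seed = config$seed)
        rp$q_up <- bh_adjust(rp$p_up)
        rp$q_down <- bh_adjust(rp$p_down)
        write_tsv(rp, file.path(config$out_dir, "qpcr_rank_product.tsv"))
        manifest$stages$qpcr <-
          list(genes = nrow(rp),
               comparisons = attr(rp, "n_comparisons"),
               n_perm = config$n_perm)
      })
    }

    finish("ok")
    manifest
  }, error = function(e) {
    finish("failed", error = list(stage = current_stage,
                                  message = conditionMessage(e)))
    stop("pipeline failed at stage '", current_stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}

#' Write a complete synthetic dataset directory
#'
#' Generates every input the pipeline needs — expression matrix, sample
#' groups, probe annotation, interaction table, gene-set collection and
#' qPCR Ct table — together with a `truth.json` recording all planted
#' structure, and writes them under `dir`. The interactome carries a
#' planted path module through the planted up-regulated genes of the two
#' disease groups, so their expanded networks are guaranteed to overlap;
#' the planted gene set overlaps the same module.
#'
#' @param dir Output directory (created if absent).
#' @param seed Integer master seed; stage seeds are derived as small
#'   offsets.
#' @param n_features,group_sizes,planted_per_group,effect_size,noise_sd,scale
#'   Passed to [generate_expression_dataset()].
#' @param disease_groups The two groups treated as diseases downstream.
#' @param n_edges Random interactome edges (default 30000).
#' @param n_sets,set_size Gene-set collection shape (defaults 200 x 20).
#' @param set_overlap Planted-set overlap with the module genes
#'   (default 10).
#' @param ct_genes,ct_group_sizes,ct_reference,ct_planted_n,ct_planted_fold,ct_noise_sd
#'   Passed to [generate_ct_table()]; defaults plant a 2-fold change on
#'   5 of 80 genes.
#' @return Invisibly, a list with the file paths and the combined truth.
#' @export
simulate_dataset <- function(dir, seed = 1,
                             n_features = 20000,
                             group_sizes = default_group_sizes(),
                             planted_per_group = 10,
                             effect_size = 2, noise_sd = 1,
                             scale = "linear",
                             disease_groups = names(group_sizes)[c(1, length(group_sizes))],
                             n_edges = 30000,
                             n_sets = 200, set_size = 20, set_overlap = 10,
                             ct_genes = 80,
                             ct_group_sizes = c(CONTROL = 6L, TREATED = 6L),
                             ct_reference = 3,
                             ct_planted_n = 5, ct_planted_fold = 2,
                             ct_noise_sd = 0.25) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- generate_expression_dataset(
    n_features = n_features, group_sizes = group_sizes,
    planted_per_group = planted_per_group, effect_size = effect_size,
    noise_sd = noise_sd, scale = scale, seed = seed
  )
  probes <- rownames(ds$expression)
  symbols <- sprintf("GN%05d", seq_along(probes))
  annotation <- stats::setNames(symbols, probes)
  probe_to_symbol <- function(p) unname(annotation[p])

  module <- unlist(lapply(disease_groups, function(g) {
    probe_to_symbol(ds$truth$planted_up[[g]])
  }))
  interactions <- generate_interactome(symbols, n_edges = n_edges,
                                       planted_module = module,
                                       seed = seed + 1L)
  sets <- generate_gene_sets(symbols, n_sets = n_sets, set_size = set_size,
                             planted_query = module,
                             planted_overlap = min(set_overlap, length(module)),
                             seed = seed + 2L)
  ct_targets <- sprintf("G%03d", seq_len(ct_genes))
  ct_planted <- stats::setNames(rep(ct_planted_fold, ct_planted_n),
                                ct_targets[seq_len(ct_planted_n)])
  ct <- generate_ct_table(n_genes = ct_genes, group_sizes = ct_group_sizes,
                          n_reference = ct_reference, planted = ct_planted,
                          ct_noise_sd = ct_noise_sd, seed = seed + 3L)

  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    groups = file.path(dir, "groups.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    interactions = file.path(dir, "interactions.tab"),
    gene_sets = file.path(dir, "sets.gmt"),
    ct = file.path(dir, "ct.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_expression_matrix(ds$expression, paths$expression)
  write_tsv(data.frame(sample_id = names(ds$groups), group = ds$groups),
            paths$groups)
  write_tsv(data.frame(probe_id = probes, symbol = symbols), paths$annotation)
  write_interactions(interactions, paths$interactions)
  write_gene_sets(sets, paths$gene_sets)
  write_ct_table(ct, paths$ct)

  truth <- ds$truth
  truth$planted_up_symbols <- lapply(truth$planted_up, probe_to_symbol)
  truth$planted_down_symbols <- lapply(truth$planted_down, probe_to_symbol)
  truth$planted_module <- module
  truth$planted_set <- attr(sets, "planted")
  truth$ct_planted <- as.list(attr(ct, "planted"))
  truth$disease_groups <- disease_groups
  write_truth(truth, paths$truth)
  invisible(list(paths = paths, truth = truth))
}
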