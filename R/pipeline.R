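#' Default pipeline configuration
#'
#' Returns the full configuration list with every tunable at its default;
#' override entries via `...`. The defaults mirror the analysis conventions:
#' tau threshold 0.9, network threshold 0.7 excluding text mining with prior
#' 0.041, minimum subnetwork size 4, 100,000 enrichment resamples, 2,000
#' association simulations, 5% SFS cutoff.
#'
#' @param ... Named overrides.
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    list_a = NULL, list_b = NULL, ages = NULL, exceptions = NULL,
    orthologs = NULL, paralogs = NULL, collapse_paralogs = FALSE,
    background_props = c(A = 0.83, B = 0.06, C = 0.04, D = 0.03, E = 0.04),
    expression = NULL, tau_threshold = 0.9,
    target_tissues = character(), tau_transform = "log2",
    edges = NULL, network_threshold = 0.7,
    exclude_channels = "textmining", prior = 0.041,
    min_subnetwork_size = 4, enrichment_universe = "subnetworks",
    n_resamples = 100000, repro_flags = NULL, n_assoc_sim = 2000,
    mkt_counts = NULL, mkt_sfs = NULL, sfs_cutoff = 0.05,
    neutral_rescale = TRUE,
    seed = NULL, out_dir = NULL
  )
  modifyList(defaults, list(...))
}

#' Write a YAML configuration template
#'
#' @param path Output YAML path.
#' @param ... Overrides passed to [pipeline_config()].
#' @return `path`, invisibly.
#' @export
write_config_template <- function(path, ...) {
  cfg <- pipeline_config(...)
  cfg$background_props <- as.list(cfg$background_props)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write a complete synthetic input bundle
#'
#' Generates every input class the pipeline consumes — candidate gene lists,
#' age table (with one planted age-less exception gene), deep-ortholog
#' validation calls with planted discrepancies, a 31-tissue expression matrix
#' with planted male-reproductive-gland specificity, a planted-block
#' interaction network with channel scores and text-mining decoys,
#' reproductive-function flags, paralog groups, and two-population
#' polymorphism/divergence count tables with SFS sidecars — and writes them as
#' TSV files plus a ground-truth JSON. The defaults reproduce the marginal
#' structure of the study system: 357 genes with a 228-gene conservative core,
#' 178 ortholog checks with 5 discrepancies, subnetwork blocks of sizes
#' 64/13/6/5/5/5 among 163 networked genes.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param n_genes,overlap,class_props Catalog structure.
#' @param n_checked,n_discrepant Ortholog validation structure.
#' @param block_sizes,n_networked Network structure.
#' @param true_alpha,frac_deleterious MKT generator truth.
#' @return A [pipeline_config()] list pointing at the written files (also
#'   serialised to `config.yaml`), with the truth at `truth.json`.
#' @export
write_input_bundle <- function(dir, seed, n_genes = 357, overlap = 228 / 357,
                               class_props = c(A = 0.62, B = 0.10, C = 0.10,
                                               D = 0.08, E = 0.10),
                               n_checked = 178, n_discrepant = 5,
                               block_sizes = c(64, 13, 6, 5, 5, 5),
                               n_networked = 163, true_alpha = 0.3,
                               frac_deleterious = 0.3) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)

  cat_sim <- gen_catalog(n = n_genes, class_props = class_props,
                         overlap = overlap, seed = seed)
  write_tsv_strict(cat_sim$list_a, p("list_a.tsv"))
  write_tsv_strict(cat_sim$list_b, p("list_b.tsv"))

  # one planted exception gene without an age call (pseudogene analogue)
  exception_id <- cat_sim$age_table$gene_id[1]
  ages <- cat_sim$age_table[cat_sim$age_table$gene_id != exception_id, ]
  write_tsv_strict(ages, p("ages.tsv"))
  write_tsv_strict(tibble(gene_id = exception_id), p("exceptions.tsv"))

  orth <- gen_ortholog_calls(ages, n_checked, n_discrepant, seed)
  write_tsv_strict(tibble(gene_id = orth$ortholog_ids), p("orthologs.tsv"))

  # near-zero background so planted genes clear tau >= 0.9 on the log scale
  expr <- gen_expression(n_genes = n_genes, n_tissues = 31,
                         frac_specific = 0.6, fg_level = 500, bg_level = 0.3,
                         noise_cv = 0.2, target_tissue = "male_accessory_gland",
                         gene_ids = cat_sim$age_table$gene_id, seed = seed)
  write_tsv_strict(expr$expression, p("expression.tsv"))

  networked <- with_seed(child_seed(seed, "bundle_networked"),
                         sample(ages$gene_id, n_networked))
  age_vec <- setNames(ages$age_class, ages$gene_id)
  net <- gen_network(block_sizes = block_sizes, p_in = 0.35, p_out = 0,
                     n_nonsfp = 150, p_cross = 0.02,
                     block_repro_props = c(0.85, 0.15, 0.6, 0.15, 0.6, 0.6),
                     n_decoy = 30, sfp_gene_ids = networked,
                     age_classes = age_vec, seed = seed)
  write_tsv_strict(net$edges, p("edges.tsv"))

  # reproductive flags for every catalog gene; networked genes keep the
  # block-structured flags
  flags <- with_seed(child_seed(seed, "bundle_repro"), {
    f <- setNames(runif(n_genes) < 0.5, cat_sim$age_table$gene_id)
    planted <- net$truth[net$truth$is_sfp, ]
    f[planted$gene_id] <- planted$reproductive_flag
    f
  })
  write_tsv_strict(tibble(gene_id = names(flags),
                          reproductive_flag = unname(flags)),
                   p("repro_flags.tsv"))

  paralogs <- gen_paralog_groups(cat_sim$age_table$gene_id, 10, 3, seed)
  write_tsv_strict(paralogs, p("paralogs.tsv"))

  mkt_ral <- gen_mkt_counts(gene_ids = cat_sim$age_table$gene_id,
                            true_alpha = true_alpha,
                            frac_deleterious = frac_deleterious,
                            population = "RAL", seed = seed)
  mkt_zi <- gen_mkt_counts(gene_ids = cat_sim$age_table$gene_id,
                           true_alpha = true_alpha,
                           frac_deleterious = frac_deleterious,
                           population = "ZI", seed = seed)
  write_tsv_strict(dplyr::bind_rows(mkt_ral$counts, mkt_zi$counts),
                   p("mkt_counts.tsv"))
  write_tsv_strict(dplyr::bind_rows(
    mutate(mkt_ral$sfs, population = "RAL"),
    mutate(mkt_zi$sfs, population = "ZI")), p("mkt_sfs.tsv"))

  truth <- list(catalog = cat_sim$truth, orthologs = orth$truth,
                expression = expr$truth, network = net$truth,
                exception_id = exception_id)
  jsonlite::write_json(truth, p("truth.json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)

  cfg <- pipeline_config(
    list_a = p("list_a.tsv"), list_b = p("list_b.tsv"), ages = p("ages.tsv"),
    exceptions = p("exceptions.tsv"), orthologs = p("orthologs.tsv"),
    paralogs = p("paralogs.tsv"), expression = p("expression.tsv"),
    target_tissues = "male_accessory_gland", edges = p("edges.tsv"),
    repro_flags = p("repro_flags.tsv"), mkt_counts = p("mkt_counts.tsv"),
    mkt_sfs = p("mkt_sfs.tsv"), seed = seed, out_dir = file.path(dir, "out"))
  cfg_yaml <- cfg
  cfg_yaml$background_props <- as.list(cfg_yaml$background_props)
  yaml::write_yaml(cfg_yaml, p("config.yaml"))
  cfg
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- do.call(pipeline_config, config)
  cfg$background_props <- unlist(cfg$background_props)
  if (is.null(cfg$seed)) abort("config: seed is mandatory")
  if (is.null(cfg$out_dir)) abort("config: out_dir is mandatory")
  for (f in c("list_a", "list_b", "ages")) {
    if (is.null(cfg[[f]])) abort(paste0("config: ", f, " is mandatory"))
  }
  for (f in c("list_a", "list_b", "ages", "exceptions", "orthologs",
              "paralogs", "expression", "edges", "repro_flags", "mkt_counts",
              "mkt_sfs")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      abort(paste0("config: input not found: ", cfg[[f]]))
    }
  }
  cfg
}

#' Run the full analysis pipeline from a configuration
#'
#' Stage order: catalog assembly, age assignment, ortholog cross-validation,
#' age-class composition tests (full and conservative set), tau and
#' specificity calls, interaction network (degree partition, subnetworks,
#' Monte Carlo age-class enrichment, reproductive association, GraphML
#' export), and per-population MKT rates with age-class comparisons. Stages
#' whose inputs are not configured are skipped with a note in the manifest.
#' All outputs are deterministic given the same config and seed; only the
#' manifest carries a timestamp.
#'
#' @param config A [pipeline_config()] list or path to a YAML file.
#' @return A list with every stage result, invisibly; files are written to
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- .load_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  res <- list()
  skipped <- character(0)

  # --- catalog ---
  list_a <- read_gene_table(cfg$list_a)
  list_b <- read_gene_table(cfg$list_b)
  catalog <- assemble_catalog(list_a$gene_id, list_b$gene_id)
  ages <- read_gene_table(cfg$ages)
  exceptions <- if (!is.null(cfg$exceptions)) {
    read_gene_table(cfg$exceptions)$gene_id
  } else character(0)
  catalog <- assign_ages(catalog, ages, exceptions = exceptions)
  if (!is.null(cfg$repro_flags)) {
    rf <- read_gene_table(cfg$repro_flags)
    catalog <- left_join(catalog, rf, by = "gene_id")
  }
  if (isTRUE(cfg$collapse_paralogs) && !is.null(cfg$paralogs)) {
    catalog <- collapse_paralogs(catalog, read_gene_table(cfg$paralogs))
  }
  res$catalog <- catalog
  write_tsv_strict(catalog, out("catalog.tsv"))

  # --- validation ---
  if (!is.null(cfg$orthologs)) {
    orth <- read_gene_table(cfg$orthologs)
    res$validation <- cross_validate_ages(catalog, orth$gene_id)
    jsonlite::write_json(unclass(res$validation), out("validation.json"),
                         auto_unbox = TRUE, digits = NA)
  } else skipped <- c(skipped, "validation")

  # --- composition ---
  res$composition_full <- age_composition_test(catalog, cfg$background_props)
  res$composition_conservative <-
    age_composition_test(conservative_set(catalog), cfg$background_props)
  comp_out <- list(
    full = c(res$composition_full[c("chi2", "df", "p", "total")],
             list(residuals = res$composition_full$residuals)),
    conservative = c(res$composition_conservative[c("chi2", "df", "p", "total")],
                     list(residuals = res$composition_conservative$residuals)))
  jsonlite::write_json(comp_out, out("composition.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)

  # --- tau ---
  if (!is.null(cfg$expression)) {
    expr <- read_gene_table(cfg$expression)
    res$tau <- specificity_calls(expr, threshold = cfg$tau_threshold,
                                 target_tissues = cfg$target_tissues,
                                 transform = cfg$tau_transform)
    write_tsv_strict(res$tau, out("tau.tsv"))
    res$tau_by_age <- compare_tau_by_age(res$tau, catalog)
    jsonlite::write_json(
      list(omnibus = unclass(res$tau_by_age$omnibus)[c("statistic", "df", "p",
                                                       "method")],
           groups = res$tau_by_age$groups,
           pairwise = res$tau_by_age$pairwise),
      out("tau_by_age.json"), dataframe = "columns", auto_unbox = TRUE,
      digits = NA)
  } else skipped <- c(skipped, "tau")

  # --- network ---
  if (!is.null(cfg$edges)) {
    edges <- read_tsv_strict(cfg$edges)
    net <- build_network(edges, catalog$gene_id,
                         threshold = cfg$network_threshold,
                         exclude = cfg$exclude_channels, prior = cfg$prior)
    res$network <- net
    res$degree <- degree_partition(net)
    write_tsv_strict(res$degree, out("degree.tsv"))
    res$subnetworks <- extract_subnetworks(net, cfg$min_subnetwork_size)
    write_tsv_strict(res$subnetworks, out("subnetworks.tsv"))
    if (nrow(res$subnetworks) > 0) {
      universe <- if (identical(cfg$enrichment_universe, "all_sfp")) {
        intersect(catalog$gene_id[catalog$age_class != "UNASSIGNED"],
                  igraph::V(net$graph)$name)
      } else NULL
      age_map <- setNames(catalog$age_class, catalog$gene_id)
      res$enrichment <- mc_age_enrichment(res$subnetworks, age_map,
                                          universe = universe,
                                          n_resamples = cfg$n_resamples,
                                          seed = cfg$seed)
      write_tsv_strict(res$enrichment, out("enrichment.tsv"))
      if (!is.null(cfg$repro_flags) && "reproductive_flag" %in% names(catalog)) {
        flags <- setNames(catalog$reproductive_flag, catalog$gene_id)
        res$association <- reproductive_association(res$subnetworks, flags,
                                                    n_sim = cfg$n_assoc_sim,
                                                    seed = cfg$seed)
        jsonlite::write_json(
          list(test = unclass(res$association$test)[c("statistic", "p",
                                                      "method", "n_sim")],
               posthoc = res$association$posthoc),
          out("repro_association.json"), dataframe = "columns",
          auto_unbox = TRUE, digits = NA)
      }
    }
    export_network(net, out("network"), subnetworks = res$subnetworks,
                   catalog = catalog, format = "both")
  } else skipped <- c(skipped, "network")

  # --- mkt ---
  if (!is.null(cfg$mkt_counts)) {
    # gene ids repeat across populations, so no per-file dedup here
    counts <- read_tsv_strict(cfg$mkt_counts)
    counts$gene_id <- as.character(counts$gene_id)
    if (!"population" %in% names(counts)) counts$population <- "ALL"
    sfs <- if (!is.null(cfg$mkt_sfs)) read_tsv_strict(cfg$mkt_sfs) else NULL
    pops <- unique(counts$population)
    res$mkt <- purrr::map_dfr(pops, function(popn) {
      cnt <- counts[counts$population == popn, ]
      s <- if (!is.null(sfs) && "population" %in% names(sfs)) {
        sfs[sfs$population == popn, ]
      } else sfs
      mkt(cnt, sfs = s, cutoff = cfg$sfs_cutoff,
          neutral_rescale = cfg$neutral_rescale)
    })
    write_tsv_strict(res$mkt, out("mkt.tsv"))
    age_groups <- tibble(gene_id = catalog$gene_id,
                         group = catalog$age_class) %>%
      filter(.data$group != "UNASSIGNED")
    res$rates_by_age <- lapply(setNames(pops, pops), function(popn) {
      compare_rates(res$mkt[res$mkt$population == popn, ], age_groups,
                    metric = "omega")
    })
    jsonlite::write_json(
      lapply(res$rates_by_age, function(gc) {
        list(omnibus = unclass(gc$omnibus)[c("statistic", "df", "p", "method")],
             groups = gc$groups, pairwise = gc$pairwise)
      }),
      out("rates_by_age.json"), dataframe = "columns", auto_unbox = TRUE,
      digits = NA)
  } else skipped <- c(skipped, "mkt")

  # --- manifest + summary ---
  manifest <- list(
    config = lapply(cfg, function(x) if (is.numeric(x)) unname(x) else x),
    seed = cfg$seed, skipped = skipped,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("sfpage")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)

  lines <- c(
    sprintf("catalog: %d genes (%d conservative)", nrow(catalog),
            nrow(conservative_set(catalog))),
    if (!is.null(res$validation)) {
      sprintf("age validation: %d/%d discrepant (%.2f%%)",
              res$validation$n_discrepant, res$validation$n_checked,
              res$validation$rate_percent)
    },
    sprintf("composition: chi2 = %.2f, df = %d, p = %.3g",
            res$composition_full$chi2, res$composition_full$df,
            res$composition_full$p),
    if (!is.null(res$subnetworks) && nrow(res$subnetworks) > 0) {
      sprintf("network: %d subnetworks >= %d members, core size %d",
              max(res$subnetworks$subnetwork), cfg$min_subnetwork_size,
              max(res$subnetworks$size))
    },
    if (length(skipped) > 0) paste("skipped stages:",
                                   paste(skipped, collapse = ", ")))
  writeLines(lines, out("summary.txt"))
  invisible(res)
}
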