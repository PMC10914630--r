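# End-to-end orchestration: DE -> synapse enrichment -> filtered synaptosome
# DE -> rhythmicity per group -> differential rhythmicity -> modules /
# MDC / hubs -> optional ORA, with one master seed spawning per-stage
# substreams and a manifest of what ran.

#' Pipeline configuration
#'
#' @param p_max,lfc_min DE thresholds (defaults 0.05 and 0.26).
#' @param enrich_alpha,enrich_fold_min Synapse-enrichment thresholds
#'   (defaults 0.05 and 1.25).
#' @param rhythm_alpha Rhythmicity / differential-rhythmicity threshold.
#' @param n_perm Permutations for every permutation test (>= 100).
#' @param beta Soft power (NULL = choose by scale-free criterion).
#' @param min_size,merge_cut Module detection parameters.
#' @param hub_quantile,n_hops Hub-calling parameters.
#' @param covariates Covariates adjusted for in DE.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(p_max = 0.05, lfc_min = 0.26, enrich_alpha = 0.05,
                            enrich_fold_min = 1.25, rhythm_alpha = 0.05,
                            n_perm = 1000, beta = NULL, min_size = 30,
                            merge_cut = 0.25, hub_quantile = 0.90, n_hops = 1,
                            covariates = c("plex", "sex", "age", "pmi"),
                            seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (p_max <= 0 || p_max > 1 || enrich_alpha <= 0 || enrich_alpha > 1 ||
      rhythm_alpha <= 0 || rhythm_alpha > 1) stop("thresholds must lie in (0, 1]")
  if (lfc_min < 0 || enrich_fold_min < 1) stop("invalid effect-size thresholds")
  structure(list(p_max = p_max, lfc_min = lfc_min, enrich_alpha = enrich_alpha,
                 enrich_fold_min = enrich_fold_min, rhythm_alpha = rhythm_alpha,
                 n_perm = n_perm, beta = beta, min_size = min_size,
                 merge_cut = merge_cut, hub_quantile = hub_quantile,
                 n_hops = n_hops, covariates = covariates, seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis on paired homogenate/synaptosome datasets
#'
#' Stages: homogenate DE; per-group synapse enrichment and union filter;
#' synaptosome DE on enriched proteins; cosinor rhythmicity per group and
#' preparation; differential rhythmicity on the synaptosome; module
#' detection on unaffected synaptosome samples with MDC and hub calling;
#' optional ORA of DE proteins. Outputs are written as TSV/JSON under
#' `outdir` when given; identical config and inputs reproduce identical
#' results.
#'
#' @param hom,syn `pr_dataset`s for the two preparations.
#' @param config A [pipeline_config()].
#' @param gene_sets Optional GMT collection for ORA.
#' @param outdir Optional output directory.
#' @return List of stage results plus a `manifest`.
#' @export
run_pipeline <- function(hom, syn, config = pipeline_config(),
                         gene_sets = NULL, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- spawn_seeds(config$seed, 4)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  de_hom <- stage("de_homogenate",
                  classify_de(fit_de(hom, config$covariates),
                              config$p_max, config$lfc_min))

  enr <- stage("enrichment", {
    lapply(c(unaffected = "unaffected", OUD = "OUD"), function(g) {
      classify_enriched(compute_enrichment(hom, syn, g),
                        config$enrich_alpha, config$enrich_fold_min)
    })
  })
  syn_f <- stage("filter_enriched", filter_to_enriched(syn, enr))

  de_syn <- stage("de_synaptosome",
                  classify_de(fit_de(syn_f, config$covariates),
                              config$p_max, config$lfc_min))

  rhythm <- stage("rhythmicity", {
    lapply(list(homogenate = hom, synaptosome = syn_f), function(ds) {
      lapply(c(unaffected = "unaffected", OUD = "OUD"), function(g) {
        cosinor_rhythmicity(ds, g, n_perm = config$n_perm, seed = seeds[1])
      })
    })
  })

  drhythm <- stage("differential_rhythmicity", {
    differential_rhythmicity(syn_f, rhythm$synaptosome$unaffected,
                             rhythm$synaptosome$OUD,
                             alpha = config$rhythm_alpha,
                             n_perm = config$n_perm, seed = seeds[2])
  })

  overlap <- stage("rhythmic_overlap", {
    rhythmic_overlap_test(
      rhythmic_set(rhythm$synaptosome$unaffected, config$rhythm_alpha),
      rhythmic_set(rhythm$synaptosome$OUD, config$rhythm_alpha),
      rownames(syn_f$expr))
  })

  network <- stage("network", {
    ds_u <- subset_dataset(syn_f, samples = syn_f$subjects$sample_id[
      syn_f$subjects$group == "unaffected"])
    ds_o <- subset_dataset(syn_f, samples = syn_f$subjects$sample_id[
      syn_f$subjects$group == "OUD"])
    beta <- if (is.null(config$beta)) pick_soft_power(ds_u)$beta else config$beta
    adj_u <- build_adjacency(ds_u, beta)
    adj_o <- build_adjacency(ds_o, beta)
    modules <- detect_modules(adj_u, expr = ds_u, min_size = config$min_size,
                              merge_cut = config$merge_cut)
    mod_names <- setdiff(unique(modules), "grey")
    per_module <- lapply(stats::setNames(mod_names, mod_names), function(m) {
      members <- names(modules)[modules == m]
      mdc <- mdc_test(ds_u, ds_o, members, beta = beta,
                      n_perm = config$n_perm, seed = seeds[3])
      hub_u <- identify_hubs(adj_u, members, config$hub_quantile, config$n_hops)
      hub_o <- identify_hubs(adj_o, members, config$hub_quantile, config$n_hops)
      list(members = members, mdc = mdc, hubs_unaffected = hub_u$hubs,
           hubs_oud = hub_o$hubs,
           disease_hubs = disease_specific_hubs(hub_u$hubs, hub_o$hubs),
           de_enrichment = module_flag_enrichment(
             members, de_syn$protein_id[de_syn$de_flag != "none"],
             rownames(syn_f$expr)),
           rhythm_enrichment = module_flag_enrichment(
             members, rhythmic_set(rhythm$synaptosome$unaffected,
                                   config$rhythm_alpha),
             rownames(syn_f$expr)))
    })
    list(beta = beta, modules = modules, per_module = per_module)
  })

  ora <- if (!is.null(gene_sets)) {
    stage("ora", run_ora(de_hom$protein_id[de_hom$de_flag != "none"],
                         de_hom$protein_id, gene_sets))
  } else NULL

  manifest <- list(
    seed = config$seed,
    stages = c("de_homogenate", "enrichment", "filter_enriched",
               "de_synaptosome", "rhythmicity", "differential_rhythmicity",
               "rhythmic_overlap", "network", if (!is.null(ora)) "ora"),
    counts = list(
      proteins_homogenate = nrow(hom$expr),
      proteins_synaptosome = nrow(syn$expr),
      enriched_union = nrow(syn_f$expr),
      de_homogenate = sum(de_hom$de_flag != "none"),
      de_synaptosome = sum(de_syn$de_flag != "none"),
      rhythmic_syn_unaffected = length(rhythmic_set(
        rhythm$synaptosome$unaffected, config$rhythm_alpha)),
      rhythmic_syn_oud = length(rhythmic_set(
        rhythm$synaptosome$OUD, config$rhythm_alpha)),
      rhythm_loss = sum(drhythm$change_class == "loss"),
      rhythm_gain = sum(drhythm$change_class == "gain"),
      n_modules = length(network$per_module),
      modules_losing_connectivity = sum(vapply(
        network$per_module, function(m) m$mdc$direction == "loss", logical(1)))
    )
  )

  result <- list(de_homogenate = de_hom, enrichment = enr,
                 synaptosome_filtered = syn_f, de_synaptosome = de_syn,
                 rhythm = rhythm, differential_rhythmicity = drhythm,
                 rhythmic_overlap = overlap, network = network, ora = ora,
                 manifest = manifest)
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  result
}

#' @noRd
write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(result$de_homogenate, "de_homogenate.tsv")
  wt(result$de_synaptosome, "de_synaptosome.tsv")
  for (g in names(result$enrichment)) {
    wt(result$enrichment[[g]], sprintf("enrichment_%s.tsv", g))
  }
  for (prep in names(result$rhythm)) {
    for (g in names(result$rhythm[[prep]])) {
      wt(result$rhythm[[prep]][[g]], sprintf("rhythm_%s_%s.tsv", prep, g))
    }
  }
  wt(result$differential_rhythmicity, "differential_rhythmicity.tsv")
  mods <- result$network$modules
  wt(data.frame(protein_id = names(mods), module = unname(mods)),
     "modules.tsv")
  mdc_rows <- lapply(names(result$network$per_module), function(m) {
    x <- result$network$per_module[[m]]
    data.frame(module = m, size = length(x$members),
               connectivity_unaffected = x$mdc$connectivity_unaffected,
               connectivity_oud = x$mdc$connectivity_oud,
               mdc = x$mdc$mdc, p_mdc = x$mdc$p_mdc,
               direction = x$mdc$direction, stringsAsFactors = FALSE)
  })
  if (length(mdc_rows)) wt(do.call(rbind, mdc_rows), "mdc_summary.tsv")
  if (!is.null(result$ora)) wt(result$ora, "ora.tsv")
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
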