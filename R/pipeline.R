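#' Run the full downstream analysis pipeline
#'
#' Chains the stages in their canonical order: contamination screen ->
#' depth filter -> rarefaction -> genus aggregation -> rare-genus filter ->
#' relative / Hellinger transforms -> per-sample diversity (+ group tests) ->
#' Bray-Curtis PCoA -> PERMANOVA -> per-genus and per-axis group screens ->
#' co-occurrence network. Every intermediate artifact is written under
#' `outdir` as TSV/JSON, along with a machine-readable run log recording the
#' seed, thresholds and every filtering decision.
#'
#' All randomness derives from `config$seed` via fixed per-stage offsets, so
#' the whole result bundle is byte-identical across runs with the same
#' inputs and config.
#'
#' @param counts OTU count tibble.
#' @param meta Sample metadata tibble.
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed); `NULL` skips writing.
#' @return Invisibly, a list with every stage result (`contamination`,
#'   `rarefied`, `genus_counts`, `genus_rel`, `genus_hel`, `diversity`,
#'   `diversity_tests`, `dist`, `ordination`, `permanova`, `pc_tests`,
#'   `genus_tests`, `network`, `log`).
#' @export
run_pipeline <- function(counts, meta, config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list(
    package_version = as.character(utils::packageVersion("otunet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    thresholds = list(
      min_reads = config$min_reads, rarefy_depth = config$rarefy_depth,
      rare_genus_fraction = config$rare_genus_fraction,
      contamination_alpha = config$contamination_alpha,
      min_prevalence = config$network$min_prevalence,
      rho_threshold = config$network$rho_threshold,
      network_alpha = config$network$alpha,
      n_perm = config$network$n_perm
    ),
    grouping = config$grouping,
    season_correction = config$season_correction,
    p_value_status = if (config$season_correction) "season-corrected" else "uncorrected"
  )
  seed <- config$seed

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
            class = "otunet_stage_error", parent = e)
    })
  }

  contam <- stage("contamination", filter_contaminants(counts, meta,
                                                       alpha = config$contamination_alpha))
  log$contaminant_otus_flagged <- sum(contam$report$flagged)
  log$reads_removed_contamination <- contam$reads_removed

  eff_min <- max(config$min_reads, config$rarefy_depth)
  if (eff_min != config$min_reads) {
    log$depth_filter_note <- sprintf(
      "effective discard threshold raised from %d to the rarefaction depth %d",
      config$min_reads, eff_min)
  }
  pre_samples <- otu_sample_ids(contam$counts)
  deep <- stage("depth_filter", discard_low_depth(contam$counts, min_reads = eff_min))
  log$samples_discarded <- setdiff(pre_samples, otu_sample_ids(deep))
  log$n_samples_retained <- length(otu_sample_ids(deep))

  rare <- stage("rarefy", rarefy_counts(deep, depth = config$rarefy_depth,
                                        seed = seed + 101L))
  log$rarefied_depth <- config$rarefy_depth
  log$rarefied_column_sums <- unname(colSums(otu_matrix(rare)))

  gcounts <- stage("genus_aggregate", aggregate_genus(rare))
  log$n_genera_aggregated <- nrow(gcounts)
  gcounts <- stage("rare_filter",
                   filter_rare_genera(gcounts, config$rare_genus_fraction))
  log$n_genera_retained <- nrow(gcounts)

  grel <- to_relative(gcounts)
  ghel <- hellinger_transform(gcounts)

  meta_kept <- align_meta(meta, genus_sample_ids(gcounts))

  div <- stage("diversity", diversity_table(gcounts))
  in_a <- grouping_indicator(meta_kept, config$grouping)
  div_tests <- purrr::map_dfr(c("evenness", "chao1"), function(idx) {
    v <- div[[idx]]
    if (config$season_correction) v <- season_correct(v, meta_kept$season)
    w <- wilcoxon_mw(v[in_a], v[!in_a])
    tibble::tibble(index = idx, statistic = w$statistic, p_value = w$p_value)
  })
  div_tests$p_adjusted <- bh_adjust(div_tests$p_value)

  d <- stage("ordination", bray_curtis(ghel))
  ord <- pcoa(d)
  perm <- stage("permanova", {
    labels <- ifelse(in_a, "A", "B")
    permanova(d, labels, n_perm = config$network$n_perm, seed = seed + 202L)
  })
  pc_tests <- stage("pc_tests",
                    pc_axis_tests(ord, meta_kept, config$grouping,
                                  season_correction = config$season_correction))
  gen_tests <- stage("group_tests",
                     group_comparison(ghel, meta_kept, config$grouping,
                                      season_correction = config$season_correction))

  netcfg <- config$network
  netcfg$seed <- seed + 303L
  tax <- genus_phylum_lookup(counts)
  net <- stage("network", cooccurrence_network(grel, meta_kept, netcfg,
                                               taxonomy = tax))
  log$n_edges_robust <- sum(net$edges$robust)
  log$n_communities_reported <-
    length(unique(net$communities$community[net$communities$reported]))

  bundle <- list(contamination = contam, rarefied = rare,
                 genus_counts = gcounts, genus_rel = grel, genus_hel = ghel,
                 diversity = div, diversity_tests = div_tests,
                 dist = d, ordination = ord, permanova = perm,
                 pc_tests = pc_tests, genus_tests = gen_tests,
                 network = net, log = log)
  if (!is.null(outdir)) write_pipeline_bundle(bundle, outdir, config)
  invisible(bundle)
}

# genus -> phylum map parsed from OTU taxonomy strings
genus_phylum_lookup <- function(counts) {
  genus <- parse_genus(counts$taxonomy)
  phy <- sub("^p__", "", regmatches(counts$taxonomy,
                                    regexpr("p__[^;]*", counts$taxonomy)))
  ok <- !is.na(genus) & nzchar(phy)
  setNames(phy[ok], genus[ok])[!duplicated(genus[ok])]
}

write_tsv_plain <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_pipeline_bundle <- function(bundle, outdir, config) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_tsv_plain(bundle$contamination$report, p("contamination_report.tsv"))
  write_count_table(bundle$rarefied, p("rarefied_counts.tsv"))
  write_genus_table(bundle$genus_counts, p("genus_counts.tsv"))
  write_genus_table(bundle$genus_rel, p("genus_relative.tsv"))
  write_genus_table(bundle$genus_hel, p("genus_hellinger.tsv"))
  write_tsv_plain(bundle$diversity, p("diversity.tsv"))
  write_tsv_plain(bundle$diversity_tests, p("diversity_tests.tsv"))
  dm <- as.matrix(bundle$dist)
  write.table(data.frame(sample_id = rownames(dm), dm, check.names = FALSE),
              p("bray_curtis.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv_plain(bundle$ordination$coordinates, p("pcoa_coordinates.tsv"))
  write_tsv_plain(tibble::tibble(axis = seq_along(bundle$ordination$eigenvalues),
                                 eigenvalue = bundle$ordination$eigenvalues),
                  p("pcoa_eigenvalues.tsv"))
  write_tsv_plain(generics::tidy(bundle$permanova), p("permanova.tsv"))
  write_tsv_plain(bundle$pc_tests, p("pc_tests.tsv"))
  write_tsv_plain(bundle$genus_tests, p("genus_tests.tsv"))
  write_tsv_plain(bundle$network$edges, p("network_edges.tsv"))
  write_tsv_plain(bundle$network$communities, p("network_communities.tsv"))
  write_tsv_plain(bundle$network$nodes, p("network_nodes.tsv"))
  write_pipeline_config(config, p("config.json"))
  jsonlite::write_json(bundle$log, p("run_log.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(outdir)
}
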