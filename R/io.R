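#' Read / write OTU count tables
#'
#' The canonical interchange format is TSV: one row per OTU with columns
#' `otu_id`, `taxonomy` (a ranked lineage such as
#' `"k__Bacteria;p__Firmicutes;g__Streptococcus"`), then one integer column
#' per sample. BIOM (JSON, format 1.0) is supported through the biomformat
#' package.
#'
#' @param path File path.
#' @param format `"tsv"` or `"biom"`.
#' @return `read_count_table` returns an OTU count tibble;
#'   `write_count_table` returns `path` invisibly.
#' @export
read_count_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path),
                                class = "otunet_data_error")
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("the biomformat package is required for BIOM input")
    }
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
    om <- biomformat::observation_metadata(b)
    taxonomy <- if (is.null(om)) rep("", nrow(m)) else {
      apply(as.matrix(om), 1, function(r) paste(r[!is.na(r) & r != ""], collapse = ";"))
    }
    tbl <- tibble::as_tibble(cbind(
      tibble::tibble(otu_id = rownames(m), taxonomy = unname(taxonomy)),
      tibble::as_tibble(m)
    ))
  } else {
    raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE)
    if (!all(c("otu_id", "taxonomy") %in% names(raw))) {
      abort("TSV must have `otu_id` and `taxonomy` columns",
            class = "otunet_data_error")
    }
    tbl <- tibble::as_tibble(raw)
  }
  bad_tax <- which(!grepl("__", tbl$taxonomy))
  if (length(bad_tax)) {
    abort(sprintf("malformed taxonomy string at line %d: %s",
                  bad_tax[1] + 1L, tbl$taxonomy[bad_tax[1]]),
          class = "otunet_data_error")
  }
  check_otu_table(tbl)
  tbl
}

#' @rdname read_count_table
#' @param counts OTU count tibble.
#' @export
write_count_table <- function(counts, path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  check_otu_table(counts)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("the biomformat package is required for BIOM output")
    }
    m <- otu_matrix(counts)
    om <- data.frame(taxonomy = counts$taxonomy, row.names = counts$otu_id)
    b <- biomformat::make_biom(m, observation_metadata = om)
    biomformat::write_biom(b, path)
  } else {
    write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write sample metadata
#'
#' TSV with columns `sample_id`, `group` (severe/mild/control), `season`
#' (winter/summer), `gc_treatment` (logical), `conc_run1..3` (non-negative
#' amplicon concentrations, one per library amplification run).
#'
#' @param path File path.
#' @return A metadata tibble.
#' @export
read_metadata <- function(path) {
  raw <- tibble::as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  need <- c("sample_id", "group", "season", "gc_treatment",
            "conc_run1", "conc_run2", "conc_run3")
  if (!all(need %in% names(raw))) {
    abort(sprintf("metadata lacks column(s): %s",
                  paste(setdiff(need, names(raw)), collapse = ", ")),
          class = "otunet_data_error")
  }
  raw$gc_treatment <- as.logical(raw$gc_treatment)
  raw
}

#' @rdname read_metadata
#' @param meta Metadata tibble.
#' @export
write_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genus table as TSV
#'
#' @param gt Genus table.
#' @param path File path.
#' @export
write_genus_table <- function(gt, path) {
  write.table(as.data.frame(gt), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genus_table
#' @param transform Declared transform state of the stored table.
#' @export
read_genus_table <- function(path, transform = c("counts", "relative", "hellinger")) {
  transform <- match.arg(transform)
  raw <- tibble::as_tibble(read.delim(path, sep = "\t", check.names = FALSE))
  genus_table(raw, transform = transform)
}

#' Pipeline configuration
#'
#' Bundles every tunable threshold of the analysis; serializes losslessly to
#' JSON. Defaults follow the low-biomass amplicon workflow: libraries are
#' rarefied to 722 reads, samples that cannot support that depth are
#' discarded (`min_reads = 700` with the effective threshold being
#' `max(min_reads, rarefy_depth)`), genera under 0.01% of all reads are
#' dropped, and the network uses 1000 permutations with a 0.5 rho threshold.
#'
#' @param min_reads Minimum library size (default 700).
#' @param rarefy_depth Common rarefaction depth (default 722).
#' @param rare_genus_fraction Rare-genus threshold (default 1e-4).
#' @param contamination_alpha Significance level of the contamination screen.
#' @param grouping Binary contrast, see [grouping_indicator()].
#' @param season_correction Apply seasonal median correction to tested
#'   scalars (default `TRUE`).
#' @param seed Master seed; per-stage substreams are derived from it.
#' @param network A [network_config()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_reads = 700L, rarefy_depth = 722L,
                            rare_genus_fraction = 1e-4,
                            contamination_alpha = 0.05,
                            grouping = "severe_vs_rest",
                            season_correction = TRUE,
                            seed = 1L,
                            network = network_config()) {
  for (v in c(min_reads, rarefy_depth, rare_genus_fraction, contamination_alpha)) {
    if (!is.numeric(v) || v <= 0) abort("pipeline thresholds must be positive",
                                        class = "otunet_config_error")
  }
  structure(list(min_reads = as.integer(min_reads),
                 rarefy_depth = as.integer(rarefy_depth),
                 rare_genus_fraction = rare_genus_fraction,
                 contamination_alpha = contamination_alpha,
                 grouping = grouping,
                 season_correction = isTRUE(season_correction),
                 seed = as.integer(seed),
                 network = network),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path File path for the JSON form.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$network <- unclass(x$network)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- x$network %||% list()
  netcfg <- do.call(network_config, net[!vapply(net, is.null, TRUE)])
  args <- x[setdiff(names(x), "network")]
  args$network <- netcfg
  do.call(pipeline_config, args)
}
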