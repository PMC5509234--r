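# shared fixture builders; everything is generated in code

# tiny OTU tibble from a matrix and taxonomy strings
toy_counts <- function(m, taxonomy = NULL, otu_id = NULL) {
  otu_id <- otu_id %||% sprintf("OTU%02d", seq_len(nrow(m)))
  taxonomy <- taxonomy %||% sprintf("k__Bacteria;p__Firmicutes;g__G%02d", seq_len(nrow(m)))
  colnames(m) <- colnames(m) %||% sprintf("S%02d", seq_len(ncol(m)))
  tibble::as_tibble(cbind(tibble::tibble(otu_id = otu_id, taxonomy = taxonomy),
                          tibble::as_tibble(m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# generator config without any planted nuisance, for block-recovery work
recovery_config <- function(seed) {
  sim_config(seed = seed, n_contaminant_otus = 0L, n_season_affected = 0L)
}

# standard preprocessing chain: depth filter -> rarefy -> genus -> rare filter
to_genus_counts <- function(counts, seed) {
  suppressMessages(filter_rare_genera(aggregate_genus(
    rarefy_counts(discard_low_depth(counts, 722), 722, seed = seed))))
}

# planted-block labels vs detected communities, over block genera;
# genera in no community get unique singleton labels
community_ari <- function(truth, communities) {
  blkg <- names(truth$block_membership)
  pred <- communities$community[match(blkg, communities$genus)]
  pred[is.na(pred)] <- -seq_len(sum(is.na(pred)))
  mclust::adjustedRandIndex(truth$block_membership, pred)
}

n_reported_communities <- function(communities) {
  length(unique(communities$community[communities$reported]))
}
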