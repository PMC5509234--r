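#' Screen OTUs for reagent contamination
#'
#' Low-biomass amplicon libraries are dominated by reagent contamination when
#' little template DNA is present, so a contaminant's relative abundance
#' falls as the sample's amplicon concentration rises. For every OTU and each
#' of the three library amplification runs, the Spearman correlation between
#' the OTU's relative abundance and that run's per-sample amplicon
#' concentration is tested (two-sided; exact permutation null for n <= 10
#' samples, t approximation otherwise, average ranks for ties). An OTU is
#' flagged — and all of its reads removed — if any run shows `rho < 0` with
#' `P < alpha`.
#'
#' @param counts OTU count tibble.
#' @param meta Sample metadata with `conc_run1..3`.
#' @param alpha Per-test significance level (default 0.05).
#' @return List of class `contamination_result`: `counts` (filtered table),
#'   `report` (tibble with per-run rho/P and a `flagged` column), and
#'   `reads_removed` (total count mass of flagged OTUs).
#' @export
filter_contaminants <- function(counts, meta, alpha = 0.05) {
  check_otu_table(counts)
  m <- otu_matrix(counts)
  n <- ncol(m)
  if (n < 4) abort("contamination screen needs at least 4 samples",
                   class = "otunet_data_error")
  meta <- align_meta(meta, colnames(m))
  tot <- colSums(m)
  rel <- sweep(m, 2, ifelse(tot == 0, 1, tot), "/")

  runs <- c("conc_run1", "conc_run2", "conc_run3")
  report <- tibble::tibble(otu_id = rownames(m))
  flagged <- rep(FALSE, nrow(m))
  for (r in seq_along(runs)) {
    conc <- meta[[runs[r]]]
    if (is.null(conc)) abort(sprintf("metadata lacks %s", runs[r]),
                             class = "otunet_data_error")
    if (length(unique(conc)) == 1L) {
      warn(sprintf("%s is constant; Spearman undefined, run skipped", runs[r]))
      report[[sprintf("rho_run%d", r)]] <- NA_real_
      report[[sprintf("p_run%d", r)]] <- NA_real_
      next
    }
    res <- apply(rel, 1, function(x) {
      if (length(unique(x)) == 1L) return(c(NA_real_, NA_real_))
      ct <- suppressWarnings(
        cor.test(x, conc, method = "spearman", exact = n <= 10)
      )
      c(unname(ct$estimate), ct$p.value)
    })
    rho <- res[1, ]
    p <- res[2, ]
    report[[sprintf("rho_run%d", r)]] <- rho
    report[[sprintf("p_run%d", r)]] <- p
    flagged <- flagged | (!is.na(rho) & rho < 0 & !is.na(p) & p < alpha)
  }
  report$flagged <- flagged
  reads_removed <- sum(m[flagged, , drop = FALSE])
  inform(sprintf("contamination screen: %d/%d OTUs flagged, %d reads removed",
                 sum(flagged), nrow(m), as.integer(reads_removed)))
  structure(list(
    counts = counts[!flagged, , drop = FALSE],
    report = report,
    reads_removed = reads_removed
  ), class = "contamination_result")
}

#' Discard shallow libraries
#'
#' Removes samples whose total read count is below `min_reads`, preserving
#' the order of survivors.
#'
#' @param counts OTU count tibble.
#' @param min_reads Minimum library size (default 700 reads).
#' @return Filtered OTU count tibble.
#' @export
discard_low_depth <- function(counts, min_reads = 700) {
  check_otu_table(counts)
  m <- otu_matrix(counts)
  keep <- colSums(m) >= min_reads
  if (!any(keep)) abort("all samples below the depth threshold",
                        class = "otunet_data_error")
  if (any(!keep)) {
    inform(sprintf("discarding %d sample(s) below %d reads: %s",
                   sum(!keep), min_reads,
                   paste(colnames(m)[!keep], collapse = ", ")))
  }
  counts[, c("otu_id", "taxonomy", colnames(m)[keep])]
}

#' Rarefy each library to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' (per-OTU counts follow a multivariate hypergeometric distribution). Rows
#' that become all-zero are retained so OTU ids stay stable.
#'
#' @param counts OTU count tibble; every column sum must be `>= depth`.
#' @param depth Target depth (default 722 reads).
#' @param seed Optional seed for reproducible subsampling.
#' @return Rarefied OTU count tibble; every column sums to `depth`.
#' @export
rarefy_counts <- function(counts, depth = 722, seed = NULL) {
  check_otu_table(counts)
  m <- otu_matrix(counts)
  tot <- colSums(m)
  if (any(tot < depth)) {
    abort(sprintf("sample(s) below rarefaction depth %d: %s", depth,
                  paste(colnames(m)[tot < depth], collapse = ", ")),
          class = "otunet_data_error")
  }
  out <- with_seed_if(seed, {
    apply(m, 2, function(col) {
      if (sum(col) == depth) return(col)
      reads <- rep.int(seq_along(col), col)
      kept <- reads[sample.int(length(reads), depth)]
      tabulate(kept, nbins = length(col))
    })
  })
  if (!is.matrix(out)) out <- matrix(out, ncol = 1, dimnames = dimnames(m))
  rownames(out) <- rownames(m)
  res <- counts
  res[, colnames(m)] <- tibble::as_tibble(out)
  res
}

# genus string from a "k__...;g__Genus" lineage; NA when unclassified
parse_genus <- function(taxonomy) {
  g <- regmatches(taxonomy, regexpr("g__[^;]*", taxonomy))
  out <- rep(NA_character_, length(taxonomy))
  hit <- grepl("g__[^;]*", taxonomy)
  val <- sub("^g__", "", g)
  val[val == "" | grepl("^unclassified", val, ignore.case = TRUE)] <- NA_character_
  out[hit] <- val
  out
}

#' Aggregate OTU counts to genus level
#'
#' Counts of all OTUs classified to the same genus are summed; OTUs with no
#' genus-level classification are dropped (their total read mass is reported
#' via a message).
#'
#' @param counts OTU count tibble with taxonomy strings containing a `g__`
#'   rank.
#' @return A [genus_table()] in state `"counts"`.
#' @export
aggregate_genus <- function(counts) {
  check_otu_table(counts)
  m <- otu_matrix(counts)
  genus <- parse_genus(counts$taxonomy)
  uncl <- is.na(genus)
  if (any(uncl)) {
    inform(sprintf("%d OTU(s) unclassified at genus level excluded (%d reads)",
                   sum(uncl), as.integer(sum(m[uncl, , drop = FALSE]))))
  }
  m <- m[!uncl, , drop = FALSE]
  genus <- genus[!uncl]
  agg <- rowsum(m, group = genus, reorder = FALSE)
  genus_from_matrix(agg, transform = "counts")
}

#' Drop rare genera
#'
#' A genus is removed when its abundance across the whole dataset falls below
#' `threshold_fraction` (default 0.01\%). Two readings of "abundance within
#' the total number of samples" are available: the default compares each
#' genus's total read count with the grand total; `"mean_relative"` compares
#' its mean per-sample relative abundance with the threshold.
#'
#' @param gt Genus table in state `"counts"`.
#' @param threshold_fraction Removal threshold (default `1e-4`).
#' @param method `"total_reads"` (default) or `"mean_relative"`.
#' @return Filtered genus table, still in state `"counts"`.
#' @export
filter_rare_genera <- function(gt, threshold_fraction = 1e-4,
                               method = c("total_reads", "mean_relative")) {
  method <- match.arg(method)
  require_transform(gt, "counts", "filter_rare_genera")
  m <- genus_matrix(gt)
  if (nrow(m) == 0 || sum(m) == 0) abort("empty genus table",
                                         class = "otunet_data_error")
  frac <- if (method == "total_reads") {
    rowSums(m) / sum(m)
  } else {
    tot <- colSums(m)
    rowMeans(sweep(m, 2, ifelse(tot == 0, 1, tot), "/"))
  }
  keep <- frac >= threshold_fraction
  if (any(!keep)) {
    inform(sprintf("rare-genus filter removed %d of %d genera", sum(!keep), nrow(m)))
  }
  genus_from_matrix(m[keep, , drop = FALSE], transform = "counts")
}

#' Convert genus counts to relative abundances
#'
#' @param gt Genus table in state `"counts"`.
#' @return Genus table in state `"relative"`; every non-zero column sums to 1.
#' @export
to_relative <- function(gt) {
  require_transform(gt, "counts", "to_relative")
  m <- genus_matrix(gt)
  tot <- colSums(m)
  genus_from_matrix(sweep(m, 2, ifelse(tot == 0, 1, tot), "/"),
                    transform = "relative")
}

#' Hellinger-transform genus abundances
#'
#' Entries become the square root of the within-sample relative abundance, so
#' each non-zero column has unit Euclidean norm. This makes Euclidean-geometry
#' methods (and Bray-Curtis ordination of compositional data) well behaved.
#'
#' @param gt Genus table in state `"counts"` or `"relative"`.
#' @return Genus table in state `"hellinger"`.
#' @export
hellinger_transform <- function(gt) {
  require_transform(gt, c("counts", "relative"), "hellinger_transform")
  m <- genus_matrix(gt)
  tot <- colSums(m)
  genus_from_matrix(sqrt(sweep(m, 2, ifelse(tot == 0, 1, tot), "/")),
                    transform = "hellinger")
}

#' Season (processing-batch) median correction
#'
#' Subtracts from each sample's value the median of that value over all
#' samples processed in the same season. Applicable to any per-sample scalar:
#' a genus's abundance, a diversity index, or a principal coordinate.
#'
#' @param x Numeric vector, one value per sample.
#' @param season Character/factor vector of the same length (e.g. `"winter"`,
#'   `"summer"`).
#' @return Numeric vector of season-centred values.
#' @examples
#' season_correct(c(1, 2, 3, 10, 20, 30),
#'                c("w", "w", "w", "s", "s", "s"))
#' @export
season_correct <- function(x, season) {
  if (length(x) != length(season)) {
    abort("`x` and `season` lengths differ", class = "otunet_data_error")
  }
  if (anyNA(season)) abort("every sample needs a season", class = "otunet_data_error")
  x - stats::ave(x, as.character(season), FUN = median)
}
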