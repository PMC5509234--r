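#' Co-occurrence network configuration
#'
#' @param min_prevalence Keep genera with non-zero abundance in at least this
#'   many samples (default 5).
#' @param rho_threshold Spearman threshold an edge must pass (default 0.5).
#' @param alpha Significance level for the permutation P (default 0.05).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional seed for the permutation null.
#' @param min_community_size_report Components smaller than this are kept in
#'   the data but flagged as unreported (default 3, i.e. communities of at
#'   most 2 genera are suppressed from display).
#' @param mode `"positive"` requires `rho >= rho_threshold`; `"absolute"`
#'   uses `|rho|`.
#' @param robustness `"both"` (default) re-applies the full edge rule (P and
#'   rho) after seasonal correction; `"p_only"` re-checks only the P
#'   criterion.
#' @return A validated `network_config` list.
#' @export
network_config <- function(min_prevalence = 5L, rho_threshold = 0.5,
                           alpha = 0.05, n_perm = 1000L, seed = NULL,
                           min_community_size_report = 3L,
                           mode = c("positive", "absolute"),
                           robustness = c("both", "p_only")) {
  mode <- match.arg(mode)
  robustness <- match.arg(robustness)
  if (alpha <= 0 || alpha >= 1) abort("invalid `alpha`: need 0 < alpha < 1",
                                      class = "otunet_config_error")
  stopifnot_scalar_count(n_perm, "n_perm")
  structure(list(min_prevalence = as.integer(min_prevalence),
                 rho_threshold = rho_threshold, alpha = alpha,
                 n_perm = as.integer(n_perm), seed = seed,
                 min_community_size_report = as.integer(min_community_size_report),
                 mode = mode, robustness = robustness),
            class = "network_config")
}

#' Prevalence filter
#'
#' Retains genera detected (abundance > 0) in at least `min_prevalence`
#' samples.
#'
#' @param gt Genus table in state `"relative"`.
#' @param min_prevalence Minimum number of samples with non-zero abundance.
#' @return Filtered genus table.
#' @export
prevalence_filter <- function(gt, min_prevalence = 5L) {
  require_transform(gt, "relative", "prevalence_filter")
  m <- genus_matrix(gt)
  keep <- rowSums(m > 0) >= min_prevalence
  genus_from_matrix(m[keep, , drop = FALSE], transform = "relative")
}

#' Pairwise Spearman correlation matrix between genera
#'
#' Average ranks for ties; a constant genus has undefined correlation,
#' recorded as `NA`.
#'
#' @param gt Genus table (any transform) or numeric matrix (genera x samples).
#' @return Symmetric matrix of rho with unit diagonal.
#' @export
spearman_matrix <- function(gt) {
  m <- if (is.matrix(gt)) gt else genus_matrix(gt)
  if (ncol(m) < 3) abort("need at least 3 samples", class = "otunet_data_error")
  rho <- suppressWarnings(cor(t(m), method = "spearman"))
  diag(rho) <- 1
  rho
}

#' Permutation P-values for pairwise Spearman correlations
#'
#' Compositionality-aware null in the spirit of ReBoot/CCREPE: in each round
#' every genus's values are permuted independently across samples, each
#' sample's composition is re-closed (columns renormalized to sum 1), and the
#' full Spearman matrix is recomputed. The two-sided P-value for a pair is
#' `(#\{|rho_null| >= |rho_obs|\} + 1) / (n_perm + 1)`.
#'
#' For season-corrected (non-compositional, possibly negative) input set
#' `renormalize = FALSE`; the null then permutes each genus without
#' re-closure.
#'
#' @param gt Genus table in state `"relative"`, or a numeric matrix when
#'   `renormalize = FALSE`.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional seed.
#' @param renormalize Re-close compositions after permuting (default `TRUE`).
#' @return List: `rho` (observed matrix), `p` (symmetric matrix in (0, 1]),
#'   `n_perm`.
#' @export
permutation_pvalues <- function(gt, n_perm = 1000, seed = NULL,
                                renormalize = TRUE) {
  if (n_perm < 1) abort("`n_perm` must be >= 1", class = "otunet_config_error")
  m <- if (is.matrix(gt)) gt else {
    if (renormalize) require_transform(gt, "relative", "permutation_pvalues")
    genus_matrix(gt)
  }
  g <- nrow(m)
  n <- ncol(m)
  rho_obs <- spearman_matrix(m)
  target <- abs(rho_obs) - 1e-12
  exceed <- matrix(0, g, g)
  na_obs <- is.na(rho_obs)
  with_seed_if(seed, {
    for (b in seq_len(n_perm)) {
      mp <- m
      for (i in seq_len(g)) mp[i, ] <- mp[i, sample.int(n)]
      if (renormalize) {
        tot <- colSums(mp)
        mp <- sweep(mp, 2, ifelse(tot == 0, 1, tot), "/")
      }
      rho_b <- suppressWarnings(cor(t(mp), method = "spearman"))
      exceed <- exceed + (!is.na(rho_b) & abs(rho_b) >= target)
    }
  })
  p <- (exceed + 1) / (n_perm + 1)
  p[na_obs] <- NA_real_
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(rho_obs)
  list(rho = rho_obs, p = p, n_perm = n_perm)
}

#' Edge rule: correlation and significance thresholds
#'
#' An unordered genus pair becomes an edge when its correlation passes
#' `rho_threshold` (positively by default, in absolute value with
#' `mode = "absolute"`) and its permutation P is below `alpha`. Pairs with
#' undefined rho never form edges.
#'
#' @param rho,p Conformable symmetric matrices.
#' @param config A [network_config()].
#' @return Tibble `genus_a`, `genus_b`, `rho`, `p`.
#' @export
build_edges <- function(rho, p, config = network_config()) {
  stopifnot(identical(dim(rho), dim(p)))
  g <- nrow(rho)
  ids <- rownames(rho) %||% as.character(seq_len(g))
  pairs <- which(upper.tri(rho), arr.ind = TRUE)
  rho_v <- rho[pairs]
  p_v <- p[pairs]
  crit_rho <- if (config$mode == "absolute") abs(rho_v) else rho_v
  keep <- !is.na(rho_v) & !is.na(p_v) &
    crit_rho >= config$rho_threshold & p_v < config$alpha
  tibble::tibble(
    genus_a = ids[pairs[keep, 1]],
    genus_b = ids[pairs[keep, 2]],
    rho = rho_v[keep],
    p = p_v[keep]
  )
}

#' Seasonal robustness check for network edges
#'
#' Re-derives each edge after removing the seasonal batch signal: every
#' genus's abundances are season-corrected by per-season median subtraction,
#' Spearman rho and the permutation P are recomputed (without compositional
#' re-closure, since corrected values are no longer compositional), and an
#' edge is kept only if it still satisfies the edge rule (`robustness =
#' "p_only"` re-checks only the P criterion).
#'
#' @param edges Edge tibble from [build_edges()].
#' @param gt The genus table the edges came from (state `"relative"`).
#' @param meta Sample metadata with a `season` column.
#' @param config A [network_config()].
#' @return `edges` with added logical `robust`, recomputed `rho_corrected`,
#'   `p_corrected`.
#' @export
season_robustness_filter <- function(edges, gt, meta, config = network_config()) {
  if (nrow(edges) == 0) {
    return(dplyr::mutate(edges, rho_corrected = numeric(0),
                         p_corrected = numeric(0), robust = logical(0)))
  }
  m <- genus_matrix(gt)
  meta <- align_meta(meta, colnames(m))
  mc <- t(apply(m, 1, season_correct, season = meta$season))
  rownames(mc) <- rownames(m)
  perm <- permutation_pvalues(mc, n_perm = config$n_perm, seed = config$seed,
                              renormalize = FALSE)
  ia <- match(edges$genus_a, rownames(m))
  ib <- match(edges$genus_b, rownames(m))
  rho_c <- perm$rho[cbind(ia, ib)]
  p_c <- perm$p[cbind(ia, ib)]
  crit_rho <- if (config$mode == "absolute") abs(rho_c) else rho_c
  robust <- !is.na(p_c) & p_c < config$alpha
  if (config$robustness == "both") {
    robust <- robust & !is.na(rho_c) & crit_rho >= config$rho_threshold
  }
  dplyr::mutate(edges, rho_corrected = rho_c, p_corrected = p_c,
                robust = robust)
}

#' Connected-component communities
#'
#' @param edges Edge tibble with `genus_a`, `genus_b` (only rows with
#'   `robust = TRUE` are used if the column is present).
#' @param min_community_size_report Components below this size are flagged
#'   `reported = FALSE`.
#' @return Tibble `genus`, `community`, `community_size`, `reported`.
#' @export
network_communities <- function(edges, min_community_size_report = 3L) {
  if ("robust" %in% names(edges)) edges <- edges[edges$robust, , drop = FALSE]
  if (nrow(edges) == 0) {
    return(tibble::tibble(genus = character(0), community = integer(0),
                          community_size = integer(0), reported = logical(0)))
  }
  gr <- igraph::graph_from_data_frame(edges[, c("genus_a", "genus_b")],
                                      directed = FALSE)
  comp <- igraph::components(gr)
  sizes <- comp$csize[comp$membership]
  tibble::tibble(
    genus = names(comp$membership),
    community = as.integer(comp$membership),
    community_size = as.integer(sizes),
    reported = sizes >= min_community_size_report
  )
}

#' Disease-group association score per genus
#'
#' Mean relative abundance in severe-subtype samples minus mean in
#' mild-subtype plus control samples; positive scores mark severe-associated
#' genera (red in the conventional network coloring), negative scores
#' mild/control-associated (blue).
#'
#' @param gt Genus table in state `"relative"`.
#' @param meta Sample metadata.
#' @return Tibble `genus`, `association`.
#' @export
node_association <- function(gt, meta) {
  require_transform(gt, "relative", "node_association")
  m <- genus_matrix(gt)
  meta <- align_meta(meta, colnames(m))
  sev <- meta$group == "severe"
  tibble::tibble(
    genus = rownames(m),
    association = rowMeans(m[, sev, drop = FALSE]) -
      rowMeans(m[, !sev, drop = FALSE])
  )
}

#' Build the full co-occurrence network
#'
#' Chains prevalence filtering, the Spearman matrix, the
#' compositionality-aware permutation null, the edge rule, the seasonal
#' robustness check and connected-component community detection, and
#' annotates nodes with the severe-vs-rest association score and phylum
#' (when a taxonomy lookup is supplied).
#'
#' @param gt Genus table in state `"relative"` (post rare-genus filtering).
#' @param meta Sample metadata.
#' @param config A [network_config()].
#' @param taxonomy Optional named character vector genus -> phylum.
#' @return Object of class `cooc_network`: `nodes`, `edges` (all initial
#'   edges with robustness columns), `communities`, `rho` (post-filter
#'   matrix), `config`.
#' @export
cooccurrence_network <- function(gt, meta, config = network_config(),
                                 taxonomy = NULL) {
  filt <- prevalence_filter(gt, config$min_prevalence)
  perm <- permutation_pvalues(filt, n_perm = config$n_perm, seed = config$seed)
  edges <- build_edges(perm$rho, perm$p, config)
  edges <- season_robustness_filter(edges, filt, meta, config)
  comm <- network_communities(edges, config$min_community_size_report)
  assoc <- node_association(filt, meta)
  nodes <- dplyr::left_join(assoc, comm, by = "genus")
  if (!is.null(taxonomy)) {
    nodes$phylum <- unname(taxonomy[nodes$genus])
  }
  deg <- table(c(edges$genus_a[edges$robust], edges$genus_b[edges$robust]))
  nodes$degree <- as.integer(deg[nodes$genus])
  nodes$degree[is.na(nodes$degree)] <- 0L
  structure(list(nodes = nodes, edges = edges, communities = comm,
                 rho = perm$rho, p = perm$p, config = config),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  nrep <- length(unique(x$communities$community[x$communities$reported]))
  cat(sprintf("Co-occurrence network: %d genera, %d robust edges, %d communities (%d reported, size >= %d)\n",
              nrow(x$nodes), sum(x$edges$robust),
              length(unique(x$communities$community)), nrep,
              x$config$min_community_size_report))
  invisible(x)
}

#' @export
tidy.cooc_network <- function(x, ...) x$edges

#' @export
glance.cooc_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges_initial = nrow(x$edges),
    n_edges_robust = sum(x$edges$robust),
    n_communities = length(unique(x$communities$community)),
    n_communities_reported = length(unique(x$communities$community[x$communities$reported]))
  )
}

#' Community-ordered correlation matrix for heatmap display
#'
#' Rows/columns are grouped by community (then the unassigned genera),
#' within a community ordered by degree, descending. Band labels for the
#' community color strips are returned alongside.
#'
#' @param net A [cooccurrence_network()] result, or a list with `rho`,
#'   `communities` and optionally `nodes`.
#' @param drop_unassigned Drop genera in no community (default `TRUE`).
#' @return List: `rho` (reordered matrix), `bands` (tibble `genus`,
#'   `community`).
#' @export
community_heatmap_data <- function(net, drop_unassigned = TRUE) {
  comm <- net$communities
  if (nrow(comm) == 0) {
    return(list(rho = net$rho[0, 0, drop = FALSE],
                bands = tibble::tibble(genus = character(0), community = integer(0))))
  }
  deg <- if (!is.null(net$nodes)) setNames(net$nodes$degree, net$nodes$genus) else
    setNames(rep(0L, nrow(comm)), comm$genus)
  comm$degree <- unname(deg[comm$genus])
  ord <- comm[order(comm$community, -comm$degree, comm$genus), ]
  ids <- ord$genus
  if (!drop_unassigned) {
    rest <- setdiff(rownames(net$rho), ids)
    ids <- c(ids, rest)
    ord <- dplyr::bind_rows(ord, tibble::tibble(genus = rest, community = NA_integer_))
  }
  list(rho = net$rho[ids, ids, drop = FALSE],
       bands = tibble::as_tibble(ord[, c("genus", "community")]))
}

#' Heatmap of community-ordered correlations
#'
#' @param object A `cooc_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cooc_network <- function(object, ...) {
  hm <- community_heatmap_data(object)
  if (nrow(hm$bands) == 0) {
    abort("network has no communities to draw", class = "otunet_data_error")
  }
  df <- tibble::as_tibble(as.data.frame.table(hm$rho, responseName = "rho"))
  names(df)[1:2] <- c("genus_a", "genus_b")
  df$genus_a <- factor(df$genus_a, levels = rownames(hm$rho))
  df$genus_b <- factor(df$genus_b, levels = rev(rownames(hm$rho)))
  ggplot2::ggplot(df, ggplot2::aes(.data$genus_a, .data$genus_b,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho")
}
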