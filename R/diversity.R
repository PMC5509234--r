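#' Pielou's evenness
#'
#' Shannon entropy (natural log) of the relative abundances divided by its
#' maximum `ln(S)`, where `S` is the number of taxa with positive count.
#' By convention a single-taxon community has evenness 0.
#'
#' @param x Non-negative abundance vector with at least one positive entry.
#' @return Evenness in `[0, 1]`.
#' @examples
#' pielou_evenness(c(10, 10, 10, 10)) # 1
#' @export
pielou_evenness <- function(x) {
  if (all(x == 0)) abort("all-zero abundance vector", class = "otunet_data_error")
  p <- x[x > 0] / sum(x)
  s <- length(p)
  if (s == 1L) return(0)
  -sum(p * log(p)) / log(s)
}

#' Chao1 richness estimator
#'
#' `S_obs + F1^2 / (2 F2)` where `F1`/`F2` are the numbers of taxa observed
#' exactly once/twice; when no doubletons exist the bias-corrected form
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` is used.
#'
#' @param x Non-negative integer count vector.
#' @return Estimated richness (>= observed richness).
#' @export
chao1_richness <- function(x) {
  if (any(x != round(x)) || any(x < 0)) {
    abort("Chao1 requires non-negative integer counts", class = "otunet_data_error")
  }
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

#' Rarefaction curve by repeated subsampling
#'
#' For each depth, reads are subsampled without replacement `reps` times and
#' the mean number of taxa observed at least once is recorded.
#'
#' @param x Non-negative integer count vector for one sample.
#' @param depths Integer depths, each `<= sum(x)`.
#' @param reps Subsamples per depth (default 100).
#' @param seed Optional seed.
#' @return Tibble with columns `depth` and `richness`.
#' @export
rarefaction_curve <- function(x, depths, reps = 100, seed = NULL) {
  if (any(x != round(x)) || any(x < 0)) {
    abort("rarefaction requires non-negative integer counts",
          class = "otunet_data_error")
  }
  total <- sum(x)
  if (any(depths > total)) abort("depth exceeds total count",
                                 class = "otunet_data_error")
  reads <- rep.int(seq_along(x), x)
  with_seed_if(seed, {
    rich <- vapply(depths, function(d) {
      mean(vapply(seq_len(reps), function(i) {
        length(unique(reads[sample.int(total, d)]))
      }, numeric(1)))
    }, numeric(1))
    tibble::tibble(depth = as.integer(depths), richness = rich)
  })
}

#' Per-sample diversity summary
#'
#' Convenience wrapper computing depth, observed richness, Pielou evenness
#' and Chao1 for every sample of a genus count table.
#'
#' @param gt Genus table in state `"counts"`.
#' @return Tibble `sample_id`, `depth`, `observed`, `evenness`, `chao1`.
#' @export
diversity_table <- function(gt) {
  require_transform(gt, "counts", "diversity_table")
  m <- genus_matrix(gt)
  tibble::tibble(
    sample_id = colnames(m),
    depth = colSums(m),
    observed = colSums(m > 0),
    evenness = apply(m, 2, pielou_evenness),
    chao1 = apply(m, 2, chao1_richness)
  )
}

#' Rarefaction curves for every sample of a table
#'
#' @param gt Genus table in state `"counts"` (or an OTU tibble passed through
#'   [otu_matrix()] upstream).
#' @param depths Depths; defaults to 10 steps up to the smallest library.
#' @param reps Subsamples per depth.
#' @param seed Optional seed.
#' @return Tibble `sample_id`, `depth`, `richness`.
#' @export
rarefaction_curves <- function(gt, depths = NULL, reps = 50, seed = NULL) {
  m <- if (inherits(gt, "genus_tbl")) genus_matrix(gt) else otu_matrix(gt)
  if (is.null(depths)) {
    depths <- unique(pmax(1L, as.integer(seq(1, min(colSums(m)), length.out = 10))))
  }
  with_seed_if(seed, {
    purrr::map_dfr(colnames(m), function(s) {
      dplyr::mutate(rarefaction_curve(m[, s], depths, reps = reps),
                    sample_id = s, .before = 1)
    })
  })
}

#' Plot rarefaction curves
#'
#' @param curves Output of [rarefaction_curves()].
#' @param meta Optional metadata tibble for coloring by `group`.
#' @return A ggplot object.
#' @export
plot_rarefaction <- function(curves, meta = NULL) {
  if (!is.null(meta)) {
    curves <- dplyr::left_join(curves, meta[, c("sample_id", "group")],
                               by = "sample_id")
    ggplot2::ggplot(curves, ggplot2::aes(.data$depth, .data$richness,
                                         group = .data$sample_id,
                                         colour = .data$group)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "reads subsampled", y = "observed taxa")
  } else {
    ggplot2::ggplot(curves, ggplot2::aes(.data$depth, .data$richness,
                                         group = .data$sample_id)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "reads subsampled", y = "observed taxa")
  }
}
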