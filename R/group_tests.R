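#' Two-sided Wilcoxon-Mann-Whitney test
#'
#' Exact null distribution (full enumeration) when the combined sample size
#' is at most 20 and there are no ties; otherwise the normal approximation
#' with tie-corrected variance and continuity correction. Constant pooled
#' data (every value identical) is defined to give `P = 1`.
#'
#' @param x,y Non-empty numeric vectors.
#' @return One-row tibble: `statistic` (Mann-Whitney U for `x`), `p_value`,
#'   `method`, `exact`.
#' @examples
#' wilcoxon_mw(c(1, 2, 3), c(4, 5, 6)) # exact two-sided P = 0.1
#' @export
wilcoxon_mw <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    abort("both samples must be non-empty", class = "otunet_data_error")
  }
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    return(tibble::tibble(statistic = length(x) * length(y) / 2, p_value = 1,
                          method = "Wilcoxon-Mann-Whitney", exact = FALSE))
  }
  ties <- anyDuplicated(pooled) > 0
  exact <- (length(pooled) <= 20) && !ties
  ht <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                     exact = exact, correct = TRUE))
  p <- ht$p.value
  if (is.na(p)) p <- 1
  tibble::tibble(statistic = unname(ht$statistic), p_value = min(p, 1),
                 method = "Wilcoxon-Mann-Whitney", exact = exact)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; monotone, capped at 1, input
#' order preserved.
#'
#' @param p Numeric vector of P-values in `[0, 1]`.
#' @return Adjusted P-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("P-values must lie in [0, 1]", class = "otunet_data_error")
  }
  p.adjust(p, method = "BH")
}

#' Binary sample groupings used by the study design
#'
#' `"severe_vs_rest"` contrasts the severe CT subtype against mild subtype
#' plus controls; `"case_vs_control"` contrasts all COPD cases against
#' controls; `"gc"` contrasts glucocorticoid-treated against untreated.
#'
#' @param meta Sample metadata.
#' @param grouping One of `"severe_vs_rest"`, `"case_vs_control"`, `"gc"`.
#' @return Logical vector: `TRUE` for the first-named side.
#' @export
grouping_indicator <- function(meta, grouping = c("severe_vs_rest",
                                                  "case_vs_control", "gc")) {
  grouping <- match.arg(grouping)
  switch(grouping,
    severe_vs_rest = meta$group == "severe",
    case_vs_control = meta$group %in% c("severe", "mild"),
    gc = as.logical(meta$gc_treatment)
  )
}

#' Per-genus group screen with seasonal correction
#'
#' For every genus, the abundance vector is (optionally) season-corrected by
#' per-season median subtraction and the two groups are compared with a
#' two-sided Wilcoxon-Mann-Whitney test; Benjamini-Hochberg adjustment is
#' applied across all genera of the screen (one BH family per grouping).
#'
#' @param gt Genus table, normally Hellinger-transformed (a message is
#'   emitted otherwise).
#' @param meta Sample metadata.
#' @param grouping See [grouping_indicator()].
#' @param season_correction Apply per-season median centring first
#'   (default `TRUE`).
#' @return Tibble `genus`, `statistic`, `p_value`, `p_adjusted`, `method`,
#'   sorted as in the input table.
#' @export
group_comparison <- function(gt, meta, grouping = "severe_vs_rest",
                             season_correction = TRUE) {
  if (genus_transform(gt) != "hellinger") {
    inform(sprintf("group_comparison on a \"%s\" table (Hellinger is conventional)",
                   genus_transform(gt)))
  }
  m <- genus_matrix(gt)
  meta <- align_meta(meta, colnames(m))
  in_a <- grouping_indicator(meta, grouping)
  res <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    if (season_correction) v <- season_correct(v, meta$season)
    w <- wilcoxon_mw(v[in_a], v[!in_a])
    tibble::tibble(genus = rownames(m)[i], statistic = w$statistic,
                   p_value = w$p_value, method = w$method)
  })
  res$p_adjusted <- bh_adjust(res$p_value)
  res
}

#' Group tests on principal coordinates
#'
#' Season-corrects each requested principal coordinate and compares the two
#' groups with a Wilcoxon-Mann-Whitney test; BH adjustment across the tested
#' axes (they form one reporting family).
#'
#' @param ord A [pcoa()] result.
#' @param meta Sample metadata.
#' @param grouping See [grouping_indicator()].
#' @param axes Integer axes to test (default first two).
#' @param season_correction Apply per-season median centring (default `TRUE`).
#' @return Tibble `axis`, `statistic`, `p_value`, `p_adjusted`.
#' @export
pc_axis_tests <- function(ord, meta, grouping = "severe_vs_rest",
                          axes = c(1, 2), season_correction = TRUE) {
  coords <- ord$coordinates
  meta <- align_meta(meta, coords$sample_id)
  in_a <- grouping_indicator(meta, grouping)
  axes <- axes[paste0("PC", axes) %in% names(coords)]
  res <- purrr::map_dfr(axes, function(ax) {
    v <- coords[[paste0("PC", ax)]]
    if (season_correction) v <- season_correct(v, meta$season)
    w <- wilcoxon_mw(v[in_a], v[!in_a])
    tibble::tibble(axis = paste0("PC", ax), statistic = w$statistic,
                   p_value = w$p_value)
  })
  res$p_adjusted <- bh_adjust(res$p_value)
  res
}
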