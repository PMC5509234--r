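#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)`, bounded in `[0, 1]`.
#' Two all-zero samples are defined to have distance 0. The function is
#' transform-agnostic: counts, relative abundances or Hellinger values are
#' accepted.
#'
#' @param gt Genus table (any transform state).
#' @return A `dist` object labelled by sample id.
#' @export
bray_curtis <- function(gt) {
  m <- genus_matrix(gt)
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      denom <- sum(m[, i] + m[, j])
      d[i, j] <- d[j, i] <- if (denom == 0) 0 else sum(abs(m[, i] - m[, j])) / denom
    }
  }
  stats::as.dist(d)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a distance matrix: the squared distances are
#' double-centred and eigendecomposed; coordinates are eigenvectors scaled by
#' the square root of their (positive) eigenvalues. Negative eigenvalues are
#' reported but excluded from coordinates and from the denominator of the
#' proportion explained. Eigenvector sign is arbitrary, so each axis is
#' flipped, if needed, to make its largest-magnitude loading positive.
#'
#' @param d A `dist` or symmetric matrix with zero diagonal.
#' @return Object of class `pcoa_result`: `coordinates` (tibble `sample_id`,
#'   `PC1`, ...), `eigenvalues` (all, non-increasing), `proportion_explained`
#'   (over positive eigenvalues).
#' @export
pcoa <- function(d) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d), tol = 1e-8)) {
      abort("distance matrix must be symmetric", class = "otunet_data_error")
    }
    d <- stats::as.dist(d)
  }
  labels <- attr(d, "Labels") %||% as.character(seq_len(attr(d, "Size")))
  n <- attr(d, "Size")
  fit <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  ord <- order(eig, decreasing = TRUE)
  eig <- eig[ord]
  tolpos <- 1e-9 * max(abs(eig), 1)
  npos <- sum(eig > tolpos)
  if (npos == 0) {
    coords <- matrix(0, n, 1, dimnames = list(labels, "PC1"))
    prop <- 0
  } else {
    pts <- fit$points[, seq_len(min(npos, ncol(fit$points))), drop = FALSE]
    # fix sign: largest-magnitude loading positive
    for (j in seq_len(ncol(pts))) {
      v <- pts[, j]
      if (v[which.max(abs(v))] < 0) pts[, j] <- -v
    }
    colnames(pts) <- paste0("PC", seq_len(ncol(pts)))
    rownames(pts) <- labels
    coords <- pts
    prop <- eig[seq_len(ncol(pts))] / sum(eig[eig > tolpos])
  }
  structure(list(
    coordinates = tibble::as_tibble(cbind(tibble::tibble(sample_id = labels),
                                          tibble::as_tibble(coords))),
    eigenvalues = eig,
    proportion_explained = prop
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- length(x$proportion_explained)
  cat(sprintf("PCoA: %d samples, %d positive axes; PC1 %.1f%%, PC2 %.1f%% of variation\n",
              nrow(x$coordinates), k,
              100 * x$proportion_explained[1],
              if (k >= 2) 100 * x$proportion_explained[2] else NA))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.pcoa_result <- function(x, ...) x$coordinates

#' @importFrom generics glance
#' @export
glance.pcoa_result <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$coordinates),
    n_positive_axes = length(x$proportion_explained),
    pc1_prop = x$proportion_explained[1],
    pc2_prop = if (length(x$proportion_explained) >= 2) x$proportion_explained[2] else NA_real_
  )
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.pcoa_result <- function(object, meta = NULL, axes = c(1, 2), ...) {
  coords <- object$coordinates
  ax <- paste0("PC", axes)
  lab <- sprintf("%s (%.1f%%)", ax, 100 * object$proportion_explained[axes])
  if (!is.null(meta)) {
    coords <- dplyr::left_join(coords, meta, by = "sample_id")
    p <- ggplot2::ggplot(coords, ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]],
                                              colour = .data$group)) +
      ggplot2::geom_point(size = 2)
  } else {
    p <- ggplot2::ggplot(coords, ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]])) +
      ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(x = lab[1], y = lab[2])
}

# pseudo-F from a squared-distance matrix and a list of within-group index sets
permanova_f <- function(d2, idx_list, n, a) {
  ss_total <- sum(d2) / (2 * n)
  ss_within <- 0
  for (idx in idx_list) {
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Partitions the total sum of squared distances into between- and
#' within-group components and forms the pseudo-F statistic
#' `F = (SS_between / (a - 1)) / (SS_within / (N - a))`. Significance is
#' assessed by permuting group labels; the add-one estimator
#' `P = (#\{F_perm >= F_obs\} + 1) / (n_perm + 1)` avoids zero P-values.
#' With `n_perm = "exhaustive"` all distinct label assignments are
#' enumerated and the P-value is the exact tail proportion.
#'
#' @param d `dist` or symmetric distance matrix.
#' @param groups Group label per sample (>= 2 groups, each with >= 2 samples).
#' @param n_perm Number of label permutations (default 999), or
#'   `"exhaustive"`.
#' @param seed Optional seed for the permutations.
#' @return Object of class `permanova_result` with `statistic` (pseudo-F),
#'   `p_value`, `df`, sums of squares and `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  groups <- as.character(groups)
  if (length(groups) != n) abort("`groups` length must match the distance matrix",
                                 class = "otunet_data_error")
  tab <- table(groups)
  if (length(tab) < 2) abort("need at least 2 groups", class = "otunet_data_error")
  if (any(tab < 2)) abort("every group needs at least 2 samples",
                          class = "otunet_data_error")
  a <- length(tab)
  idx_of <- function(g) split(seq_len(n), g)
  f_obs <- permanova_f(d2, idx_of(groups), n, a)

  exhaustive <- identical(n_perm, "exhaustive")
  if (exhaustive) {
    perms <- all_label_assignments(groups)
    f_perm <- vapply(perms, function(g) permanova_f(d2, idx_of(g), n, a), numeric(1))
    p <- mean(f_perm >= f_obs - 1e-12)
    n_perm_used <- length(perms)
  } else {
    f_perm <- with_seed_if(seed, {
      vapply(seq_len(n_perm), function(i) {
        permanova_f(d2, idx_of(sample(groups)), n, a)
      }, numeric(1))
    })
    p <- (sum(f_perm >= f_obs - 1e-12) + 1) / (n_perm + 1)
    n_perm_used <- n_perm
  }

  ss_total <- sum(d2) / (2 * n)
  ss_within <- sum(vapply(idx_of(groups), function(idx) sum(d2[idx, idx]) / (2 * length(idx)),
                          numeric(1)))
  structure(list(
    statistic = f_obs, p_value = p,
    df_between = a - 1, df_within = n - a,
    ss_between = ss_total - ss_within, ss_within = ss_within, ss_total = ss_total,
    n_perm = n_perm_used, exhaustive = exhaustive, method = "PERMANOVA (pseudo-F)"
  ), class = "permanova_result")
}

# every distinct assignment of the multiset of labels to positions
all_label_assignments <- function(groups) {
  n <- length(groups)
  lev <- unique(groups)
  out <- list()
  rec <- function(pos, remaining, current) {
    if (length(pos) == 0) {
      out[[length(out) + 1]] <<- current
      return(invisible())
    }
    for (l in lev) {
      if (remaining[l] > 0) {
        remaining[l] <- remaining[l] - 1
        current[pos[1]] <- l
        rec(pos[-1], remaining, current)
        remaining[l] <- remaining[l] + 1
      }
    }
  }
  counts <- table(groups)
  remaining <- setNames(as.integer(counts), names(counts))
  rec(seq_len(n), remaining, character(n))
  out
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("%s: F = %.3f (df %d, %d), P = %.4g [%s permutations]\n",
              x$method, x$statistic, x$df_between, x$df_within, x$p_value,
              if (x$exhaustive) "exhaustive" else format(x$n_perm)))
  invisible(x)
}

#' @export
tidy.permanova_result <- function(x, ...) {
  tibble::tibble(
    term = c("between", "within", "total"),
    df = c(x$df_between, x$df_within, x$df_between + x$df_within),
    sum_of_squares = c(x$ss_between, x$ss_within, x$ss_total),
    statistic = c(x$statistic, NA, NA),
    p.value = c(x$p_value, NA, NA)
  )
}

#' @export
glance.permanova_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 n_perm = x$n_perm,
                 r.squared = x$ss_between / x$ss_total)
}
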