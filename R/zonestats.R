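## Zone-comparison statistics: classical one-way ANOVA across sampling zones
## and agglomerative hierarchical clustering of the metals for source
## attribution.

#' One-way ANOVA
#'
#' Classical fixed-effects one-way analysis of variance (no Welch
#' correction): F = MSB/MSW with (k - 1, N - k) degrees of freedom, p from
#' the F distribution via [stats::oneway.test()] with `var.equal = TRUE`.
#' Zero within-group variance with non-zero between-group variance is
#' reported as an infinite-F sentinel with p = 0; completely constant data
#' are undefined and flagged with `NA`.
#'
#' @param groups A list of numeric vectors, one per group; at least two
#'   groups of at least two finite observations each.
#' @return A list of class `anova_result`: `F`, `df1`, `df2`, `p`,
#'   `significant_at_0_05`.
#' @export
#' @examples
#' oneway_anova(list(c(1, 2, 3), c(2, 3, 4)))
oneway_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("Need at least two groups", call. = FALSE)
  }
  if (any(vapply(groups, length, 1L) < 2)) {
    stop("Each group needs at least two observations", call. = FALSE)
  }
  y <- unlist(groups)
  if (any(!is.finite(y))) stop("Observations must be finite", call. = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  df1 <- nlevels(g) - 1L
  df2 <- length(y) - nlevels(g)

  within_var <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1))
  between_var <- sum(vapply(groups, function(v) length(v) * (mean(v) - mean(y))^2, 1))
  if (within_var == 0 && between_var == 0) {
    res <- list(F = NA_real_, df1 = df1, df2 = df2, p = NA_real_,
                significant_at_0_05 = NA)
  } else if (within_var == 0) {
    res <- list(F = Inf, df1 = df1, df2 = df2, p = 0,
                significant_at_0_05 = TRUE)
  } else {
    ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
    res <- list(F = unname(ft$statistic), df1 = df1, df2 = df2,
                p = unname(ft$p.value),
                significant_at_0_05 = unname(ft$p.value) < 0.05)
  }
  structure(res, class = "anova_result")
}

#' Per-metal ANOVA across zones
#'
#' Runs [oneway_anova()] for each metal within each site, comparing either
#' all seven zones (omnibus, default) or the pooled right-of-way zones
#' (trench, working, piling) against the pooled 50 m reference plots.
#'
#' @param samples A sample table.
#' @param contrast `"all_zones"` or `"row_vs_50"`.
#' @param log_scale Analyse log-transformed concentrations (default `FALSE`).
#' @return A tibble with columns `site`, `metal`, `F`, `df1`, `df2`, `p`,
#'   `significant_at_0_05`.
#' @export
#' @examples
#' anova_by_zone(generate_transects(seed = 1))
anova_by_zone <- function(samples, contrast = c("all_zones", "row_vs_50"),
                          log_scale = FALSE) {
  contrast <- match.arg(contrast)
  samples <- as_sample_table(samples)
  rows <- list()
  for (site in unique(samples$site)) {
    sub <- samples[samples$site == site, ]
    grp <- switch(contrast,
      all_zones = sub$zone,
      row_vs_50 = ifelse(sub$distance_m <= 10, "row",
                         ifelse(sub$distance_m == 50, "d50", NA))
    )
    keep <- !is.na(grp)
    for (m in metal_ids()) {
      v <- sub[[m]][keep]
      if (log_scale) v <- log(v)
      groups <- split(v, grp[keep])
      a <- oneway_anova(groups)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        site = site, metal = m, F = a$F, df1 = a$df1, df2 = a$df2, p = a$p,
        significant_at_0_05 = a$significant_at_0_05
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Hierarchical clustering of metals
#'
#' Agglomerative clustering of the metal columns for pollution-source
#' grouping. Default dissimilarity is one minus the Pearson correlation
#' between metal concentration columns; the alternative is squared Euclidean
#' distance between z-scored columns. Default linkage is average
#' (UPGMA). Columns are processed in the canonical metal order, which makes
#' tie-breaking deterministic.
#'
#' @param x A sample table or a numeric matrix/data frame with one column
#'   per metal.
#' @param distance `"correlation"` (default) or `"euclidean_z"`.
#' @param linkage `"average"` (default), `"complete"` or `"ward"`.
#' @return A list of class `metal_dendrogram`: `hclust` (the
#'   [stats::hclust] tree), `merge`, `height`, `labels`, `distance`,
#'   `linkage`.
#' @export
#' @examples
#' d <- metal_clustering(generate_transects(seed = 1))
#' cluster_groups(d, k = 2)
metal_clustering <- function(x, distance = c("correlation", "euclidean_z"),
                             linkage = c("average", "complete", "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (is.data.frame(x) && all(metal_ids() %in% names(x))) {
    M <- as.matrix(x[, metal_ids()])
  } else {
    M <- as.matrix(x)
  }
  if (is.null(colnames(M))) stop("Metal columns must be named", call. = FALSE)
  M <- M[, intersect(metal_ids(), colnames(M)), drop = FALSE]
  if (ncol(M) < 2) stop("Need at least two metal columns", call. = FALSE)
  if (nrow(M) < 3) stop("Need at least three samples", call. = FALSE)
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0)) {
    stop("Constant concentration column(s): ",
         paste(colnames(M)[sds == 0], collapse = ", "), call. = FALSE)
  }
  d <- switch(distance,
    correlation = as.dist(1 - cor(M)),
    euclidean_z = stats::dist(t(scale(M)))^2
  )
  method <- switch(linkage, average = "average", complete = "complete",
                   ward = "ward.D2")
  hc <- hclust(d, method = method)
  structure(
    list(hclust = hc, merge = hc$merge, height = hc$height,
         labels = hc$labels, distance = distance, linkage = linkage),
    class = "metal_dendrogram"
  )
}

#' Cut a metal dendrogram into groups
#'
#' @param dendrogram A `metal_dendrogram` from [metal_clustering()].
#' @param k Number of groups (default 2, the source dichotomy).
#' @return Named integer vector of group memberships.
#' @export
cluster_groups <- function(dendrogram, k = 2) {
  stopifnot(inherits(dendrogram, "metal_dendrogram"))
  cutree(dendrogram$hclust, k = k)
}

#' Serialise a metal dendrogram
#'
#' @param dendrogram A `metal_dendrogram`.
#' @param newick Also return a Newick string (requires the ape package).
#' @return A list with `labels`, `merge` (list of `(a, b, height)` steps,
#'   negative indices = leaves), `distance`, `linkage`, and optionally
#'   `newick`.
#' @export
dendrogram_to_list <- function(dendrogram, newick = TRUE) {
  stopifnot(inherits(dendrogram, "metal_dendrogram"))
  hc <- dendrogram$hclust
  out <- list(
    labels = hc$labels,
    merge = lapply(seq_len(nrow(hc$merge)), function(i) {
      list(a = hc$merge[i, 1], b = hc$merge[i, 2], height = hc$height[i])
    }),
    distance = dendrogram$distance,
    linkage = dendrogram$linkage
  )
  if (newick && requireNamespace("ape", quietly = TRUE)) {
    out$newick <- ape::write.tree(ape::as.phylo(hc))
  }
  out
}
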