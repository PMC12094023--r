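# Core-clade detection: binomial enrichment of host-derived tips, culture
# ubiquity, and within-clade homology; plus the occupancy power law.

# Tip index sets for every node, by one postorder pass.
clade_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- i
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (k in seq_len(nrow(edge))) {
    sets[[edge[k, 1]]] <- c(sets[[edge[k, 1]]], sets[[edge[k, 2]]])
  }
  sets
}

#' Enumerate candidate clades of a tree
#'
#' Candidate clades for the enrichment scan are all internal nodes except the
#' root whose subtree holds at least `min_tips` tips, in preorder.
#'
#' @param tree An [ape::phylo] object.
#' @param min_tips Minimum number of tips per clade (default 2).
#' @return A list with one element per clade: `list(node = <node id>, tips =
#'   <tip labels>)`.
#' @export
enumerate_clades <- function(tree, min_tips = 2) {
  stopifnot(min_tips >= 2)
  tree <- validate_tree(tree)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  sets <- clade_tip_sets(tree)
  edge_pre <- ape::reorder.phylo(tree, "cladewise")$edge
  pre_nodes <- unique(as.vector(t(edge_pre)))
  internal <- pre_nodes[pre_nodes > n_tip & pre_nodes != root]
  out <- lapply(internal, function(nd) {
    tips <- sets[[nd]]
    if (length(tips) < min_tips) return(NULL)
    list(node = nd, tips = tree$tip.label[tips])
  })
  out[!vapply(out, is.null, logical(1))]
}

#' One-sided binomial enrichment p-value for a clade
#'
#' Probability of observing at least `k_host` host-derived tips among `n_tips`
#' clade members when host tips are binomially distributed across the tree
#' with global fraction `p_global`.
#'
#' @param k_host Number of host-class tips in the clade.
#' @param n_tips Clade size.
#' @param p_global Global fraction of host-class tips (strictly in (0, 1)).
#' @return Upper-tail probability \eqn{P(X \ge k_{host})}.
#' @examples
#' clade_enrichment_p(5, 5, 0.5)  # 0.03125
#' @export
clade_enrichment_p <- function(k_host, n_tips, p_global) {
  stopifnot(k_host >= 0, k_host <= n_tips)
  if (p_global <= 0 || p_global >= 1) {
    stop("`p_global` must be strictly between 0 and 1", call. = FALSE)
  }
  pbinom(k_host - 1, n_tips, p_global, lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' Each p-value is multiplied by the number of tests and capped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "bonferroni")
}

#' Culture ubiquity of a clade
#'
#' Fraction of all sampled cultures in which the clade's host-class tips were
#' collectively observed.
#'
#' @param clade_tips Tip labels of the clade.
#' @param annotations A [tip_annotations()] data frame.
#' @param all_cultures Character vector of all sampled culture identifiers.
#' @return Fraction in \[0, 1\]; 0 for clades without host tips.
#' @export
clade_ubiquity <- function(clade_tips, annotations, all_cultures) {
  if (length(all_cultures) == 0) stop("`all_cultures` must be non-empty", call. = FALSE)
  idx <- match(clade_tips, annotations$tip_id)
  idx <- idx[!is.na(idx)]
  host <- idx[annotations$source_class[idx] == "host"]
  if (length(host) == 0) return(0)
  seen <- unique(unlist(annotations$cultures[host]))
  length(intersect(seen, all_cultures)) / length(unique(all_cultures))
}

#' Maximum within-clade patristic distance
#'
#' The diameter of a clade in tree units: the largest tip-to-tip patristic
#' distance among its members. Zero diameter means complete sequence homology
#' under the clade. Singleton clades have diameter 0.
#'
#' @param tree An [ape::phylo] object.
#' @param clade_tips Tip labels of the clade.
#' @return Maximum pairwise distance (0 for singletons).
#' @export
clade_max_within_distance <- function(tree, clade_tips) {
  stopifnot(length(clade_tips) >= 1)
  if (length(clade_tips) == 1) return(0)
  d <- tip_distance_matrix(tree)
  idx <- match(clade_tips, rownames(d))
  if (anyNA(idx)) stop("unknown tip in clade", call. = FALSE)
  max(d[idx, idx])
}

#' Find core clades of a labelled phylogeny
#'
#' Scans every candidate clade (non-root internal node with at least
#' `min_tips` tips) against three criteria:
#' \enumerate{
#'   \item significant enrichment of host-derived tips (one-sided binomial
#'     test against the global host fraction, Bonferroni-adjusted
#'     p < `alpha`);
#'   \item culture ubiquity: the clade's host tips collectively observed in at
#'     least `ubiquity_min` of all sampled cultures;
#'   \item homology: maximum within-clade patristic distance at most `tol`
#'     (zero branch length means 100% sequence identity).
#' }
#' Among nested clades that all pass, only the maximal (most tip-rich) clade
#' is flagged as core.
#'
#' @param tree An [ape::phylo] object; every tip must be annotated.
#' @param annotations A [tip_annotations()] data frame covering all tips.
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param ubiquity_min Minimum culture ubiquity (default 0.8).
#' @param tol Maximum within-clade distance (default 0; use a small epsilon
#'   such as 1e-9 for floating-point trees).
#' @param min_tips Minimum clade size to consider (default 2).
#' @param all_cultures Culture universe; defaults to the union of all culture
#'   sets in `annotations`.
#' @param abundance Optional relative `abundance_table` whose feature ids are
#'   tip labels; if given, each clade's maximal per-sample summed relative
#'   abundance is reported.
#' @return A data frame of class `"clade_report"`, one row per candidate
#'   clade, sorted by adjusted p-value, with columns `clade_id`, `n_tips`,
#'   `k_host`, `p_raw`, `p_adj`, `ubiquity_fraction`, `max_within_distance`,
#'   `is_core` (and `max_relative_abundance` when `abundance` is given), plus
#'   a `tips` list-column.
#' @export
find_core_clades <- function(tree, annotations, alpha = 0.05, ubiquity_min = 0.8,
                             tol = 0, min_tips = 2, all_cultures = NULL,
                             abundance = NULL) {
  tree <- validate_tree(tree)
  validate_tip_annotations(annotations, tree)
  unann <- setdiff(tree$tip.label, annotations$tip_id)
  if (length(unann) > 0) {
    stop(sprintf("tip(s) without annotation: %s",
                 paste(head(unann, 5), collapse = ", ")), call. = FALSE)
  }
  is_host <- annotations$source_class[match(tree$tip.label, annotations$tip_id)] == "host"
  if (!any(is_host)) stop("tree has no host-class tips", call. = FALSE)
  if (all(is_host)) stop("tree has no environment-class tips", call. = FALSE)
  p_global <- mean(is_host)
  if (is.null(all_cultures)) all_cultures <- unique(unlist(annotations$cultures))
  clades <- enumerate_clades(tree, min_tips = min_tips)
  if (length(clades) == 0) {
    stop("no candidate clades at this `min_tips`", call. = FALSE)
  }
  d <- tip_distance_matrix(tree)
  host_by_tip <- stats::setNames(is_host, tree$tip.label)

  rows <- lapply(clades, function(cl) {
    tips <- cl$tips
    k <- sum(host_by_tip[tips])
    idx <- match(tips, rownames(d))
    data.frame(
      clade_id = cl$node,
      n_tips = length(tips),
      k_host = k,
      p_raw = clade_enrichment_p(k, length(tips), p_global),
      ubiquity_fraction = clade_ubiquity(tips, annotations, all_cultures),
      max_within_distance = max(d[idx, idx]),
      stringsAsFactors = FALSE
    )
  })
  rep_df <- do.call(rbind, rows)
  rep_df$p_adj <- bonferroni(rep_df$p_raw)
  rep_df$is_core <- rep_df$p_adj < alpha &
    rep_df$ubiquity_fraction >= ubiquity_min &
    rep_df$max_within_distance <= tol
  rep_df$tips <- lapply(clades, `[[`, "tips")

  # Nested passing clades collapse to the maximal clade: a passing clade
  # strictly contained in another passing clade is not reported as core.
  pass <- which(rep_df$is_core)
  if (length(pass) > 1) {
    for (i in pass) {
      for (j in pass) {
        if (i != j && rep_df$n_tips[i] < rep_df$n_tips[j] &&
            all(rep_df$tips[[i]] %in% rep_df$tips[[j]])) {
          rep_df$is_core[i] <- FALSE
          break
        }
      }
    }
  }

  if (!is.null(abundance)) {
    stopifnot(inherits(abundance, "abundance_table"))
    v <- abundance$values
    rep_df$max_relative_abundance <- vapply(rep_df$tips, function(tips) {
      cols <- intersect(tips, colnames(v))
      if (length(cols) == 0) return(NA_real_)
      max(rowSums(v[, cols, drop = FALSE]))
    }, numeric(1))
  }

  ord <- order(rep_df$p_adj, -rep_df$n_tips, rep_df$clade_id)
  rep_df <- rep_df[ord, , drop = FALSE]
  rownames(rep_df) <- NULL
  first <- c("clade_id", "n_tips", "k_host", "p_raw", "p_adj",
             "ubiquity_fraction", "max_within_distance", "is_core")
  rep_df <- rep_df[, c(first, setdiff(names(rep_df), first)), drop = FALSE]
  attr(rep_df, "alpha") <- alpha
  attr(rep_df, "ubiquity_min") <- ubiquity_min
  attr(rep_df, "tol") <- tol
  attr(rep_df, "p_global") <- p_global
  attr(rep_df, "n_tests") <- nrow(rep_df)
  class(rep_df) <- c("clade_report", "data.frame")
  rep_df
}

#' @export
print.clade_report <- function(x, n = 10, ...) {
  cat(sprintf(
    "clade_report: %d candidate clades tested (alpha = %g, ubiquity >= %g, tol = %g)\n",
    nrow(x), attr(x, "alpha"), attr(x, "ubiquity_min"), attr(x, "tol")))
  cat(sprintf("core clades: %d\n", sum(x$is_core)))
  cols <- setdiff(names(x), "tips")
  print.data.frame(head(as.data.frame(x)[, cols], n))
  if (nrow(x) > n) cat(sprintf("... and %d more rows\n", nrow(x) - n))
  invisible(x)
}

#' Occupancy-frequency spectrum of phylogenetic clusters
#'
#' Given the set of cultures each cluster occurs in, counts how many clusters
#' occur in exactly f cultures for each occurrence frequency f.
#'
#' @param cluster_cultures Named list: cluster id -> character vector of
#'   culture identifiers (each non-empty).
#' @return A data frame of class `"occurrence_spectrum"` with columns `f` and
#'   `N` (only frequencies with N > 0 are listed).
#' @export
occurrence_spectrum <- function(cluster_cultures) {
  if (length(cluster_cultures) == 0) stop("empty cluster map", call. = FALSE)
  f <- vapply(cluster_cultures, function(x) length(unique(x)), integer(1))
  if (any(f == 0)) stop("cluster(s) with empty culture set", call. = FALSE)
  tab <- table(f)
  out <- data.frame(f = as.integer(names(tab)), N = as.integer(tab))
  out <- out[order(out$f), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("occurrence_spectrum", "data.frame")
  out
}

#' Fit the occupancy power law N(f) ~ f^-a
#'
#' Ordinary least squares of log N(f) on log f over the spectrum's non-zero
#' points. The exponent is reported as the magnitude `a` of the log-log
#' slope: a steeper decline (larger `a`) means the community is dominated by
#' a few nearly ubiquitous clusters.
#'
#' @param spectrum An [occurrence_spectrum()] (or data frame with columns `f`,
#'   `N`); at least 3 non-zero points required.
#' @return An object of class `"powerlaw_fit"` with elements `exponent`
#'   (\eqn{a > 0} for a declining spectrum), `intercept` (log scale),
#'   `r_squared`, `n_points`, and the fitted `lm` object as `fit`.
#' @export
fit_power_law <- function(spectrum) {
  stopifnot(all(c("f", "N") %in% names(spectrum)))
  pts <- spectrum[spectrum$N > 0, , drop = FALSE]
  if (nrow(pts) < 3) stop("need at least 3 non-zero spectrum points", call. = FALSE)
  fit <- lm(log(N) ~ log(f), data = pts)
  # R^2 computed directly; summary.lm warns on an exactly collinear input
  log_n <- log(pts$N)
  ss_tot <- sum((log_n - mean(log_n))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  res <- list(
    exponent = -unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    n_points = nrow(pts),
    fit = fit
  )
  class(res) <- "powerlaw_fit"
  res
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat("Occupancy-frequency power law  N(f) ~ f^-a\n")
  cat(sprintf("  exponent a : %.4f\n", x$exponent))
  cat(sprintf("  fit R^2    : %.4f  (%d points)\n", x$r_squared, x$n_points))
  invisible(x)
}

#' @export
plot.powerlaw_fit <- function(x, ...) {
  md <- x$fit$model
  graphics::plot(exp(md$`log(f)`), exp(md$`log(N)`), log = "xy",
                 xlab = "occurrence frequency f (cultures)",
                 ylab = "number of clusters N(f)", ...)
  curve_f <- seq(min(exp(md$`log(f)`)), max(exp(md$`log(f)`)), length.out = 100)
  graphics::lines(curve_f, exp(x$intercept) * curve_f^(-x$exponent), col = 2)
  invisible(x)
}
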