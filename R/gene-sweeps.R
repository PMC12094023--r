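# Niche-adaptive gene sweeps: families universal among focal-niche genomes
# yet rare in congeneric background genomes.

#' Prevalence of a gene family among background genomes
#'
#' @param x A [gene_pa_matrix()].
#' @param family_id Gene family (column) identifier.
#' @param background_ids Genome ids forming the background set.
#' @return Fraction of background genomes carrying the family.
#' @export
background_prevalence <- function(x, family_id, background_ids) {
  stopifnot(inherits(x, "gene_pa_matrix"))
  if (!(family_id %in% colnames(x$values))) {
    stop(sprintf("unknown gene family '%s'", family_id), call. = FALSE)
  }
  if (length(background_ids) == 0) stop("empty background set", call. = FALSE)
  missing <- setdiff(background_ids, rownames(x$values))
  if (length(missing) > 0) {
    stop(sprintf("unknown genome(s): %s", paste(head(missing, 5), collapse = ", ")),
         call. = FALSE)
  }
  mean(x$values[background_ids, family_id])
}

#' Detect niche-adaptive gene sweeps
#'
#' Within each clade group (e.g. taxonomic order), screens every gene family
#' for the sweep signature: present in \emph{all} focal genomes of the group
#' and rare among background genomes of the same genera. The background of a
#' group is its non-focal genomes whose genus matches a focal genus.
#'
#' In `"pooled"` mode the rarity condition is `background prevalence <
#' max_bg_prev` over the group's pooled background; in `"per_genus"` mode it
#' must hold within every genus separately.
#'
#' @param x A [gene_pa_matrix()].
#' @param mode `"pooled"` (default) or `"per_genus"`.
#' @param max_bg_prev Strict upper bound on background prevalence
#'   (default 0.10).
#' @return A data frame of class `"sweep_report"`, one row per sweep family,
#'   ordered by background prevalence then family id, with columns
#'   `family_id`, `clade_group`, `focal_prevalence` (always 1),
#'   `background_prevalence`, `background_n`, and a `per_genus` list-column of
#'   named per-genus background prevalences.
#' @export
find_sweep_genes <- function(x, mode = c("pooled", "per_genus"), max_bg_prev = 0.10) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "gene_pa_matrix"), max_bg_prev > 0)
  md <- x$metadata
  v <- x$values
  groups <- unique(md$clade_group[md$focal])
  rows <- list()
  for (grp in groups) {
    focal_ids <- rownames(v)[md$focal & md$clade_group == grp]
    focal_genera <- unique(md$genus[md$focal & md$clade_group == grp])
    bg_sel <- !md$focal & md$clade_group == grp & md$genus %in% focal_genera
    bg_ids <- rownames(v)[bg_sel]
    if (length(bg_ids) == 0) {
      stop(sprintf("no background genomes for clade group '%s'", grp), call. = FALSE)
    }
    focal_prev <- colMeans(v[focal_ids, , drop = FALSE])
    bg_prev <- colMeans(v[bg_ids, , drop = FALSE])
    universal <- focal_prev == 1
    if (mode == "pooled") {
      hit <- universal & bg_prev < max_bg_prev
    } else {
      genera <- md$genus[bg_sel]
      per_genus_ok <- rep(TRUE, ncol(v))
      for (g in unique(genera)) {
        ids_g <- bg_ids[genera == g]
        per_genus_ok <- per_genus_ok & colMeans(v[ids_g, , drop = FALSE]) < max_bg_prev
      }
      hit <- universal & per_genus_ok
    }
    fams <- colnames(v)[hit]
    if (length(fams) == 0) next
    genera <- md$genus[bg_sel]
    per_genus <- lapply(fams, function(fam) {
      vapply(split(v[bg_ids, fam], genera), mean, numeric(1))
    })
    df <- data.frame(
      family_id = fams,
      clade_group = grp,
      focal_prevalence = 1,
      background_prevalence = unname(bg_prev[fams]),
      background_n = length(bg_ids),
      stringsAsFactors = FALSE
    )
    df$per_genus <- per_genus
    rows[[length(rows) + 1]] <- df
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else {
    data.frame(family_id = character(0), clade_group = character(0),
               focal_prevalence = numeric(0), background_prevalence = numeric(0),
               background_n = integer(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$background_prevalence, out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  attr(out, "max_bg_prev") <- max_bg_prev
  class(out) <- c("sweep_report", "data.frame")
  out
}

#' @export
print.sweep_report <- function(x, ...) {
  cat(sprintf("sweep_report: %d gene sweep(s) (mode = %s, background prevalence < %g)\n",
              nrow(x), attr(x, "mode"), attr(x, "max_bg_prev")))
  if (nrow(x) > 0) {
    cols <- setdiff(names(x), "per_genus")
    print.data.frame(as.data.frame(x)[, cols])
  }
  invisible(x)
}
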