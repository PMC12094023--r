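# Larvae-to-source community similarity across developmental stages.

#' Bray-Curtis similarity of two relative-abundance vectors
#'
#' Computed as \eqn{1 - \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}. For vectors
#' each summing to 1 this lies in \[0, 1\], equals 1 iff the vectors are
#' identical and 0 iff their supports are disjoint.
#'
#' @param x,y Numeric vectors on the same feature space, each summing to
#'   1 (within 1e-9).
#' @return Similarity in \[0, 1\]; symmetric.
#' @examples
#' bray_curtis_similarity(c(0.5, 0.5, 0), c(1, 0, 0))  # 0.5
#' @export
bray_curtis_similarity <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  if (sum(x) == 0 || sum(y) == 0) stop("zero vector", call. = FALSE)
  if (abs(sum(x) - 1) > 1e-9 || abs(sum(y) - 1) > 1e-9) {
    stop("inputs must be relative abundances summing to 1", call. = FALSE)
  }
  1 - sum(abs(x - y)) / sum(x + y)
}

#' Fraction of features shared by two communities
#'
#' Presence is abundance strictly above `detection_threshold`; the fraction is
#' |present in both| / |present in either| (Jaccard index of the supports).
#'
#' @param x,y Numeric abundance vectors on the same feature space.
#' @param detection_threshold Presence threshold (default 0: any non-zero).
#' @return Fraction in \[0, 1\].
#' @export
shared_fraction <- function(x, y, detection_threshold = 0) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  stopifnot(detection_threshold >= 0)
  px <- x > detection_threshold
  py <- y > detection_threshold
  union_n <- sum(px | py)
  if (union_n == 0) stop("no features present after thresholding", call. = FALSE)
  sum(px & py) / union_n
}

# Zero-fill a matrix onto a feature universe (columns), preserving order.
expand_features <- function(values, universe) {
  out <- matrix(0, nrow(values), length(universe),
                dimnames = list(rownames(values), universe))
  out[, colnames(values)] <- values
  out
}

#' Similarity trajectory of larval communities to candidate sources
#'
#' For each developmental stage, compares larval samples at that stage with
#' the composition of each candidate source (seawater, feed, probiotics, ...),
#' reporting the mean Bray-Curtis similarity and the mean shared-feature
#' fraction. Feature universes are unioned with zero fill, so sources and
#' larvae need not share identical feature sets.
#'
#' Each source table may carry its own `stage` metadata, in which case the
#' larvae at a stage are compared with the source's mean composition at that
#' same stage; a source without stage metadata contributes a single mean
#' profile used at every stage.
#'
#' @param larvae A relative `abundance_table` whose metadata has a `stage`
#'   column (ordered factor or sortable values).
#' @param sources Named list of relative `abundance_table`s, one per candidate
#'   source.
#' @param detection_threshold Presence threshold for the shared fraction.
#' @param mode `"mean"` (default) compares each larval sample with the source
#'   mean profile; `"pairwise"` averages over all larva-sample x source-sample
#'   pairs.
#' @return A data frame of class `"similarity_trajectory"` with columns
#'   `stage`, `source`, `bray_curtis`, `shared_fraction`, `n_larvae`.
#' @export
source_trajectory <- function(larvae, sources, detection_threshold = 0,
                              mode = c("mean", "pairwise")) {
  mode <- match.arg(mode)
  stopifnot(inherits(larvae, "abundance_table"))
  if (length(sources) == 0) stop("`sources` must be a non-empty named list", call. = FALSE)
  if (is.null(names(sources)) || any(!nzchar(names(sources)))) {
    stop("every source needs a name", call. = FALSE)
  }
  if (is.null(larvae$metadata) || !("stage" %in% names(larvae$metadata))) {
    stop("larvae metadata must include a `stage` column", call. = FALSE)
  }
  for (s in sources) stopifnot(inherits(s, "abundance_table"))

  universe <- Reduce(union, c(list(colnames(larvae$values)),
                              lapply(sources, function(s) colnames(s$values))))
  lv <- expand_features(larvae$values, universe)
  stages <- larvae$metadata$stage
  stage_levels <- if (is.factor(stages)) levels(stages) else sort(unique(stages))

  src_values <- lapply(sources, function(s) expand_features(s$values, universe))
  src_stage <- lapply(sources, function(s) {
    if (!is.null(s$metadata) && "stage" %in% names(s$metadata)) s$metadata$stage else NULL
  })

  rows <- list()
  for (st in stage_levels) {
    sel <- which(stages == st)
    if (length(sel) == 0) {
      warning(sprintf("stage '%s' has no larval samples; skipped", st))
      next
    }
    for (nm in names(sources)) {
      sv <- src_values[[nm]]
      sst <- src_stage[[nm]]
      if (!is.null(sst)) {
        keep <- which(sst == st)
        if (length(keep) == 0) keep <- seq_len(nrow(sv))
        sv <- sv[keep, , drop = FALSE]
      }
      if (mode == "mean") {
        prof <- colMeans(sv)
        prof <- prof / sum(prof)
        bc <- mean(vapply(sel, function(i) {
          bray_curtis_similarity(lv[i, ] / sum(lv[i, ]), prof)
        }, numeric(1)))
        sf <- mean(vapply(sel, function(i) {
          shared_fraction(lv[i, ], prof, detection_threshold)
        }, numeric(1)))
      } else {
        pairs <- expand.grid(i = sel, j = seq_len(nrow(sv)))
        bc <- mean(mapply(function(i, j) {
          bray_curtis_similarity(lv[i, ] / sum(lv[i, ]), sv[j, ] / sum(sv[j, ]))
        }, pairs$i, pairs$j))
        sf <- mean(mapply(function(i, j) {
          shared_fraction(lv[i, ], sv[j, ], detection_threshold)
        }, pairs$i, pairs$j))
      }
      rows[[length(rows) + 1]] <- data.frame(
        stage = st, source = nm, bray_curtis = bc, shared_fraction = sf,
        n_larvae = length(sel), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("similarity_trajectory", "data.frame")
  out
}

#' @export
print.similarity_trajectory <- function(x, ...) {
  cat("Larvae-source similarity trajectory\n")
  print.data.frame(as.data.frame(x))
  invisible(x)
}

#' @export
plot.similarity_trajectory <- function(x, which = c("bray_curtis", "shared_fraction"), ...) {
  which <- match.arg(which)
  src <- unique(x$source)
  stages <- unique(x$stage)
  graphics::plot(NULL, xlim = c(1, length(stages)), ylim = c(0, 1),
                 xaxt = "n", xlab = "developmental stage", ylab = which, ...)
  graphics::axis(1, at = seq_along(stages), labels = stages)
  for (k in seq_along(src)) {
    sub <- x[x$source == src[k], ]
    graphics::lines(match(sub$stage, stages), sub[[which]], col = k, type = "b", pch = 16)
  }
  graphics::legend("topright", legend = src, col = seq_along(src), lty = 1, pch = 16)
  invisible(x)
}
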