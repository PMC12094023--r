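#' Read a rooted phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the tree contract used
#' throughout the package: at least two tips, unique tip labels, and
#' non-negative branch lengths. Edges without a stated length are set to zero
#' with a warning.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] object.
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", tf)
#' tr <- read_newick(tf)
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("\\(", txt)))
  n_close <- lengths(regmatches(txt, gregexpr("\\)", txt)))
  if (n_open != n_close) {
    stop(sprintf(
      "Newick parse error in '%s': %d '(' vs %d ')' (unbalanced parentheses)",
      path, n_open, n_close
    ), call. = FALSE)
  }
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop(sprintf("Newick parse error in '%s'", path), call. = FALSE)
  validate_tree(tree)
}

#' Validate a phylogeny against the package's tree contract
#'
#' @param tree An [ape::phylo] object.
#' @return The validated (possibly repaired) tree, invisibly usable downstream.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be an ape 'phylo' object", call. = FALSE)
  if (length(tree$tip.label) < 2) stop("tree must have at least 2 tips", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate tip label(s): %s", paste(dup, collapse = ", ")), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; treating all as 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths treated as 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths are not allowed", call. = FALSE)
  tree
}

#' Write a phylogeny to a Newick file
#'
#' Branch lengths are written with 15 significant digits so that a write/read
#' cycle preserves patristic distances to better than 1e-12 (the stock Newick
#' writers truncate at 10 digits).
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @param digits Significant digits for branch lengths (default 15).
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, digits = 15) {
  tree <- validate_tree(tree)
  n_tip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- function(node, edge_idx) {
    label <- if (node <= n_tip) {
      tree$tip.label[node]
    } else {
      kids <- children[[as.character(node)]]
      paste0("(", paste(vapply(kids, function(e) fmt(tree$edge[e, 2], e),
                               character(1)), collapse = ","), ")")
    }
    if (is.na(edge_idx)) {
      label
    } else {
      paste0(label, ":", sprintf("%.*g", digits, tree$edge.length[edge_idx]))
    }
  }
  writeLines(paste0(fmt(n_tip + 1L, NA_integer_), ";"), path)
  invisible(path)
}

#' Construct tip annotations (source class and culture occurrence)
#'
#' Each tree tip carries a source class — `"host"` for host-associated
#' sequences, `"environment"` for environmental (e.g. seawater) sequences —
#' and the set of cultures (farms) in which the tip's ASV was observed.
#'
#' @param tip_id Character vector of tip labels.
#' @param source_class Character vector, `"host"` or `"environment"`.
#' @param cultures List of character vectors (one per tip); culture identifiers
#'   where the tip occurs. May be empty only for environment tips.
#' @return A data frame of class `"tip_annotations"` with a `cultures`
#'   list-column.
#' @export
tip_annotations <- function(tip_id, source_class, cultures = NULL) {
  tip_id <- as.character(tip_id)
  source_class <- as.character(source_class)
  if (length(tip_id) != length(source_class)) {
    stop("`tip_id` and `source_class` must have equal length", call. = FALSE)
  }
  if (is.null(cultures)) cultures <- rep(list(character(0)), length(tip_id))
  if (!is.list(cultures) || length(cultures) != length(tip_id)) {
    stop("`cultures` must be a list with one entry per tip", call. = FALSE)
  }
  cultures <- lapply(cultures, function(x) unique(as.character(x)))
  ann <- data.frame(tip_id = tip_id, source_class = source_class,
                    stringsAsFactors = FALSE)
  ann$cultures <- cultures
  class(ann) <- c("tip_annotations", "data.frame")
  validate_tip_annotations(ann)
}

#' Validate tip annotations, optionally against a tree
#'
#' @param ann A `tip_annotations` data frame.
#' @param tree Optional [ape::phylo]; if given, every annotated tip must exist
#'   in the tree.
#' @return The validated annotations.
#' @export
validate_tip_annotations <- function(ann, tree = NULL) {
  if (anyDuplicated(ann$tip_id)) {
    stop("duplicate tip_id in annotations", call. = FALSE)
  }
  bad <- setdiff(unique(ann$source_class), c("host", "environment"))
  if (length(bad) > 0) {
    stop(sprintf("unknown source_class value(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  empty_host <- ann$tip_id[ann$source_class == "host" & lengths(ann$cultures) == 0]
  if (length(empty_host) > 0) {
    stop(sprintf("host tip(s) with empty culture set: %s",
                 paste(head(empty_host, 5), collapse = ", ")), call. = FALSE)
  }
  if (!is.null(tree)) {
    missing <- setdiff(ann$tip_id, tree$tip.label)
    if (length(missing) > 0) {
      stop(sprintf("annotated tip(s) not in tree: %s",
                   paste(head(missing, 5), collapse = ", ")), call. = FALSE)
    }
  }
  ann
}

#' Read tip annotations from a TSV file
#'
#' Expects columns `tip_id`, `source_class` and optionally `cultures`
#' (comma-separated culture identifiers; empty for no occurrences).
#'
#' @param path Path to a TSV file.
#' @param tree Optional tree to validate tip identifiers against.
#' @return A `tip_annotations` data frame.
#' @export
read_tip_annotations <- function(path, tree = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("tip_id", "source_class")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    stop(sprintf("tip annotation file lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  cultures <- if ("cultures" %in% names(df)) {
    lapply(strsplit(df$cultures, ",", fixed = TRUE), function(x) x[nzchar(x)])
  } else {
    NULL
  }
  ann <- tip_annotations(df$tip_id, df$source_class, cultures)
  validate_tip_annotations(ann, tree)
}

#' Write tip annotations to a TSV file
#'
#' @param ann A `tip_annotations` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tip_annotations <- function(ann, path) {
  out <- data.frame(
    tip_id = ann$tip_id,
    source_class = ann$source_class,
    cultures = vapply(ann$cultures, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a sample-by-feature abundance table
#'
#' @param values Numeric matrix, samples in rows (rownames = sample ids),
#'   features in columns (colnames = feature ids). Non-negative.
#' @param metadata Optional data frame of per-sample metadata with rownames (or
#'   a `sample_id` column) matching the sample ids. Conventional columns are
#'   `site`, `stage` and an outcome such as `survival_rate` or `body_weight`,
#'   but any columns are kept.
#' @param relative Logical; `TRUE` if rows are relative abundances (each
#'   summing to 1), `FALSE` for counts or other non-negative measures.
#' @return An object of class `"abundance_table"`: a list with elements
#'   `values`, `metadata`, `relative`.
#' @export
abundance_table <- function(values, metadata = NULL, relative = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("F", seq_len(ncol(values)))
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if ("sample_id" %in% names(metadata) && !identical(rownames(metadata), metadata$sample_id)) {
      rownames(metadata) <- metadata$sample_id
    }
    missing <- setdiff(rownames(values), rownames(metadata))
    if (length(missing) > 0) {
      stop(sprintf("sample(s) lacking metadata: %s",
                   paste(head(missing, 5), collapse = ", ")), call. = FALSE)
    }
    metadata <- metadata[rownames(values), , drop = FALSE]
  }
  obj <- structure(list(values = values, metadata = metadata,
                        relative = isTRUE(relative)),
                   class = "abundance_table")
  validate_abundance_table(obj)
}

#' Validate an abundance table
#'
#' @param x An `abundance_table`.
#' @return The validated object.
#' @export
validate_abundance_table <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  v <- x$values
  if (anyNA(v)) stop("abundance table contains NA", call. = FALSE)
  if (any(v < 0)) {
    bad <- which(v < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at sample '%s', feature '%s'",
                 rownames(v)[bad[1]], colnames(v)[bad[2]]), call. = FALSE)
  }
  if (anyDuplicated(rownames(v))) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(colnames(v))) stop("duplicate feature ids", call. = FALSE)
  if (x$relative) {
    s <- rowSums(v)
    off <- which(abs(s - 1) > 1e-9)
    if (length(off) > 0) {
      stop(sprintf("relative table rows not summing to 1: %s",
                   paste(head(rownames(v)[off], 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  x
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$relative) "relative" else "counts"))
  if (!is.null(x$metadata)) {
    cat("metadata columns:", paste(names(x$metadata), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.matrix.abundance_table <- function(x, ...) x$values

#' Read an abundance table and its sample metadata from TSV files
#'
#' The table file has sample ids in the first column and one column per
#' feature. The metadata file is keyed by its first column (or a `sample_id`
#' column). Every sample in the table must have a metadata row.
#'
#' @param table_path Path to the abundance TSV.
#' @param metadata_path Optional path to the sample metadata TSV.
#' @param relative Logical; whether values are relative abundances.
#' @return An `abundance_table`.
#' @export
read_abundance_table <- function(table_path, metadata_path = NULL, relative = FALSE) {
  tab <- read.delim(table_path, stringsAsFactors = FALSE, check.names = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- as.character(tab[[1]])
  metadata <- NULL
  if (!is.null(metadata_path)) {
    metadata <- read.delim(metadata_path, stringsAsFactors = FALSE, check.names = FALSE)
    key <- if ("sample_id" %in% names(metadata)) "sample_id" else names(metadata)[1]
    rownames(metadata) <- as.character(metadata[[key]])
  }
  abundance_table(values, metadata, relative = relative)
}

#' Write an abundance table (and optionally its metadata) to TSV
#'
#' @param x An `abundance_table`.
#' @param table_path Output path for the value matrix.
#' @param metadata_path Optional output path for the metadata.
#' @return `table_path`, invisibly.
#' @export
write_abundance_table <- function(x, table_path, metadata_path = NULL) {
  df <- data.frame(sample_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path) && !is.null(x$metadata)) {
    md <- data.frame(sample_id = rownames(x$metadata), x$metadata,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(md, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(table_path)
}

#' Normalise a count table to relative abundances
#'
#' Each count is divided by the total read count of its sample, so every row
#' sums to 1. Zero features stay zero. Already-relative tables pass through
#' unchanged (the operation is idempotent).
#'
#' @param x An `abundance_table` of counts (or already relative).
#' @return An `abundance_table` with `relative = TRUE`.
#' @examples
#' tab <- abundance_table(matrix(c(2, 3, 5), 1, dimnames = list("S1", NULL)))
#' normalize_relative(tab)$values  # 0.2 0.3 0.5
#' @export
normalize_relative <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  totals <- rowSums(x$values)
  zero <- which(totals == 0)
  if (length(zero) > 0) {
    stop(sprintf("all-zero sample(s): %s",
                 paste(head(rownames(x$values)[zero], 5), collapse = ", ")),
         call. = FALSE)
  }
  x$values <- x$values / totals
  x$relative <- TRUE
  validate_abundance_table(x)
}

#' Construct a genome-by-gene-family presence/absence matrix
#'
#' @param values Binary matrix, genomes in rows (rownames = genome ids), gene
#'   families in columns (colnames = family ids); entries 0/1.
#' @param metadata Data frame keyed by genome id with columns `genus`,
#'   `focal` (logical: genome isolated from the focal niche) and optionally
#'   `clade_group` (e.g. taxonomic order; defaults to a single group).
#' @return An object of class `"gene_pa_matrix"`.
#' @export
gene_pa_matrix <- function(values, metadata) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) stop("genome ids (rownames) required", call. = FALSE)
  if (is.null(colnames(values))) colnames(values) <- paste0("fam", seq_len(ncol(values)))
  metadata <- as.data.frame(metadata)
  if ("genome_id" %in% names(metadata) && !identical(rownames(metadata), metadata$genome_id)) {
    rownames(metadata) <- metadata$genome_id
  }
  if (!("clade_group" %in% names(metadata))) metadata$clade_group <- "all"
  missing <- setdiff(rownames(values), rownames(metadata))
  if (length(missing) > 0) {
    stop(sprintf("genome(s) lacking metadata: %s",
                 paste(head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  metadata <- metadata[rownames(values), , drop = FALSE]
  metadata$focal <- as.logical(metadata$focal)
  obj <- structure(list(values = values, metadata = metadata),
                   class = "gene_pa_matrix")
  validate_gene_pa_matrix(obj)
}

#' Validate a gene presence/absence matrix
#'
#' @param x A `gene_pa_matrix`.
#' @return The validated object.
#' @export
validate_gene_pa_matrix <- function(x) {
  stopifnot(inherits(x, "gene_pa_matrix"))
  v <- x$values
  if (anyNA(v) || !all(v %in% c(0, 1))) {
    stop("gene matrix entries must all be 0 or 1", call. = FALSE)
  }
  md <- x$metadata
  if (anyNA(md$focal)) stop("`focal` flag must be TRUE/FALSE for every genome", call. = FALSE)
  if (!any(md$focal)) stop("no focal genomes in matrix", call. = FALSE)
  if (!any(!md$focal)) stop("no background genomes in matrix", call. = FALSE)
  no_genus <- rownames(v)[md$focal & (is.na(md$genus) | !nzchar(md$genus))]
  if (length(no_genus) > 0) {
    stop(sprintf("focal genome(s) without genus: %s",
                 paste(head(no_genus, 5), collapse = ", ")), call. = FALSE)
  }
  x
}

#' @export
print.gene_pa_matrix <- function(x, ...) {
  cat(sprintf("gene_pa_matrix: %d genomes (%d focal) x %d gene families\n",
              nrow(x$values), sum(x$metadata$focal), ncol(x$values)))
  invisible(x)
}

#' Read a gene presence/absence matrix and genome metadata from TSV files
#'
#' @param path Path to the 0/1 matrix TSV (first column genome id).
#' @param metadata_path Path to genome metadata TSV (columns `genome_id`,
#'   `genus`, `focal`, optionally `clade_group`).
#' @return A `gene_pa_matrix`.
#' @export
read_gene_matrix <- function(path, metadata_path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- as.character(tab[[1]])
  md <- read.delim(metadata_path, stringsAsFactors = FALSE, check.names = FALSE)
  key <- if ("genome_id" %in% names(md)) "genome_id" else names(md)[1]
  rownames(md) <- as.character(md[[key]])
  gene_pa_matrix(values, md)
}

#' Write a gene presence/absence matrix and its metadata to TSV
#'
#' @param x A `gene_pa_matrix`.
#' @param path Output path for the matrix.
#' @param metadata_path Optional output path for genome metadata.
#' @return `path`, invisibly.
#' @export
write_gene_matrix <- function(x, path, metadata_path = NULL) {
  df <- data.frame(genome_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path)) {
    md <- data.frame(genome_id = rownames(x$metadata), x$metadata,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(md, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
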