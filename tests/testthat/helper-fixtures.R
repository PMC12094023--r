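# Shared fixtures and independent oracles, built in code at test time.

tree_from_text <- function(txt) ape::read.tree(text = txt)

# Random host/environment labels; every host tip gets a culture so the
# annotation contract holds.
random_annotations <- function(tree, p_host = 0.5, seed = 1) {
  n <- length(tree$tip.label)
  cls <- aquacore:::with_seed(seed, {
    ifelse(runif(n) < p_host, "host", "environment")
  })
  if (!any(cls == "host")) cls[1] <- "host"
  if (!any(cls == "environment")) cls[n] <- "environment"
  cultures <- lapply(cls, function(x) if (x == "host") "C1" else character(0))
  tip_annotations(tree$tip.label, cls, cultures)
}

# Brute-force cross-class MPD: explicit double loop over tip pairs using
# per-pair path distances. Independent of the matrix-based implementation.
brute_force_mpd <- function(tree, annotations) {
  hosts <- annotations$tip_id[annotations$source_class == "host"]
  envs <- annotations$tip_id[annotations$source_class == "environment"]
  total <- 0
  for (a in hosts) for (b in envs) total <- total + patristic_distance(tree, a, b)
  total / (length(hosts) * length(envs))
}

# Brute-force upper-tail binomial probability by direct pmf summation.
brute_force_binom_tail <- function(k, n, p) {
  sum(vapply(k:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j), numeric(1)))
}

# Brute-force gene-sweep scan: per clade group, loop over every family and
# test the two conditions literally.
brute_force_sweeps <- function(x, max_bg_prev = 0.10) {
  md <- x$metadata
  v <- x$values
  hits <- character(0)
  for (grp in unique(md$clade_group[md$focal])) {
    focal <- rownames(v)[md$focal & md$clade_group == grp]
    genera <- unique(md$genus[md$focal & md$clade_group == grp])
    bg <- rownames(v)[!md$focal & md$clade_group == grp & md$genus %in% genera]
    for (fam in colnames(v)) {
      if (all(v[focal, fam] == 1) && mean(v[bg, fam]) < max_bg_prev) {
        hits <- c(hits, fam)
      }
    }
  }
  sort(unique(hits))
}

# Small hand-built gene matrix: 1 focal + 5 background genomes, 4 families.
tiny_gene_matrix <- function() {
  v <- rbind(
    g_focal = c(1, 1, 0, 1),
    g_bg1 = c(0, 1, 1, 0),
    g_bg2 = c(0, 1, 0, 0),
    g_bg3 = c(0, 1, 0, 0),
    g_bg4 = c(0, 0, 0, 0),
    g_bg5 = c(0, 0, 0, 1)
  )
  colnames(v) <- paste0("fam", 1:4)
  md <- data.frame(
    genome_id = rownames(v),
    genus = "g",
    clade_group = "grp",
    focal = c(TRUE, rep(FALSE, 5))
  )
  gene_pa_matrix(v, md)
}

# Fast model configuration for heavy cross-validation loops.
fast_config <- function(n_trees = 100) model_config("ranger", n_trees = n_trees)
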