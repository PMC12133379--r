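# Independent oracles and web constructors used across the metric tests.
# The oracles deliberately use different machinery (igraph, exhaustive
# enumeration) from the package's own implementations.

webFromEdges <- function(species, edges_chr, cell_id = "w") {
  ed <- if (length(edges_chr)) {
    parts <- do.call(rbind, strsplit(edges_chr, "->", fixed = TRUE))
    data.frame(consumer = parts[, 1], resource = parts[, 2],
               stringsAsFactors = FALSE)
  } else {
    data.frame(consumer = character(), resource = character(),
               stringsAsFactors = FALSE)
  }
  w <- methods::new("LocalFoodWeb", cell_id = cell_id, species = species,
                    edges = ed, roles = character(0))
  w@roles <- classifyRoles(w)
  w
}

chainWeb <- function(k) {
  sp <- LETTERS[seq_len(k)]
  webFromEdges(sp, if (k > 1)
    paste0(sp[2:k], "->", sp[1:(k - 1)]) else character(0))
}

randomWeb <- function(n, p, seed) {
  set.seed(seed)
  sp <- LETTERS[seq_len(n)]
  pairs <- expand.grid(consumer = sp, resource = sp,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$consumer != pairs$resource, ]
  ed <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
  w <- methods::new("LocalFoodWeb", cell_id = sprintf("rw%d", seed),
                    species = sp, edges = ed, roles = character(0))
  w@roles <- classifyRoles(w)
  w
}

webIgraph <- function(web) {
  igraph::graph_from_data_frame(web@edges, directed = TRUE,
                                vertices = data.frame(name = web@species))
}

# Mean links over maximal simple paths, via igraph path enumeration.
oracleMFCL <- function(web) {
  if (!nrow(web@edges)) return(NA_real_)
  g <- webIgraph(web)
  lens <- numeric(0)
  for (v in web@species) {
    for (p in igraph::all_simple_paths(g, from = v, mode = "out")) {
      nm <- names(p)
      innb <- names(igraph::neighbors(g, nm[1], mode = "in"))
      outnb <- names(igraph::neighbors(g, nm[length(nm)], mode = "out"))
      if (all(innb %in% nm) && all(outnb %in% nm))
        lens <- c(lens, length(nm) - 1)
    }
  }
  if (!length(lens)) NA_real_ else mean(lens)
}

# All set partitions of n elements as restricted-growth membership vectors.
allPartitions <- function(n) {
  res <- list()
  rec <- function(prefix, maxb) {
    if (length(prefix) == n) {
      res[[length(res) + 1]] <<- prefix
      return()
    }
    for (b in seq_len(maxb + 1)) rec(c(prefix, b), max(maxb, b))
  }
  rec(integer(0), 0L)
  res
}

# Exhaustive-maximum modularity on the undirected projection, scored with
# igraph's modularity routine.
oracleModularity <- function(web) {
  if (!nrow(web@edges)) return(NA_real_)
  g <- igraph::as_undirected(webIgraph(web), mode = "collapse")
  best <- -Inf
  for (p in allPartitions(length(web@species))) {
    q <- igraph::modularity(g, p)
    if (q > best) best <- q
  }
  best
}

# Minimal union-find, as an independent connected-components oracle.
ufComponents <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}
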