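# Independent oracles and fixture builders used across the test files.

# Hydrophilic-only residue pool: every 19-window mean stays below 1.6 by
# construction (max index in the pool is G at -0.4), so planted hydrophobic
# stretches are the only possible TM calls.
HYDROPHILIC <- c("D", "E", "G", "K", "N", "Q", "S", "T")

AA20_test <- function() setdiff(names(kyte_doolittle()), "X")

random_core <- function(len = 435L, cat_r = 320L, cat_y = 349L) {
  chars <- sample(HYDROPHILIC, len, replace = TRUE)
  chars[cat_r] <- "R"
  chars[cat_y] <- "Y"
  paste(chars, collapse = "")
}

# Brute-force TM oracle: score every window centre with an explicit mean,
# threshold, merge runs separated by < 3 centres, report full-window spans.
brute_tm <- function(sequence, window = 19L, threshold = 1.6) {
  kd10 <- round(10 * kyte_doolittle())  # the scale is exact in tenths
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  half <- window %/% 2L
  centers <- integer(0)
  for (c in seq_len(n)) {
    if (c - half < 1 || c + half > n) next
    if (sum(kd10[chars[(c - half):(c + half)]]) / (10 * window) >= threshold) {
      centers <- c(centers, c)
    }
  }
  if (length(centers) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  runs <- list(c(centers[1], centers[1]))
  for (c in centers[-1]) {
    last <- runs[[length(runs)]]
    if (c - last[2] - 1 < 3) {
      runs[[length(runs)]][2] <- c
    } else {
      runs[[length(runs) + 1]] <- c(c, c)
    }
  }
  data.frame(start = vapply(runs, function(r) max(1L, r[1] - half), integer(1)),
             end = vapply(runs, function(r) min(n, r[2] + half), integer(1)))
}

# Least-squares topology oracle: enumerate every unrooted topology, fit
# branch lengths by ordinary least squares on path distances, and return
# the canonical split set of the best-scoring topology.
path_design_matrix <- function(tree) {
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  parent <- integer(ntip + tree$Nnode)
  parent_edge <- integer(ntip + tree$Nnode)
  for (k in seq_len(nedge)) {
    parent[tree$edge[k, 2]] <- tree$edge[k, 1]
    parent_edge[tree$edge[k, 2]] <- k
  }
  to_root <- function(node) {
    edges <- integer(0)
    while (parent[node] != 0) {
      edges <- c(edges, parent_edge[node])
      node <- parent[node]
    }
    edges
  }
  pairs <- utils::combn(ntip, 2)
  A <- matrix(0, ncol(pairs), nedge)
  for (p in seq_len(ncol(pairs))) {
    e1 <- to_root(pairs[1, p])
    e2 <- to_root(pairs[2, p])
    onpath <- union(setdiff(e1, e2), setdiff(e2, e1))
    A[p, onpath] <- 1
  }
  A
}

split_set <- function(tree) sort(tree_splits(tree)$key)

ls_best_topology <- function(dm) {
  labels <- rownames(dm)
  n <- length(labels)
  topos <- phangorn::allTrees(n, rooted = FALSE, tip.label = labels)
  topos <- lapply(seq_along(topos), function(i) topos[[i]])
  pairs <- utils::combn(n, 2)
  dvec <- apply(pairs, 2, function(p) dm[p[1], p[2]])
  best <- NULL
  for (tr in topos) {
    A <- path_design_matrix(tr)
    fit <- qr.solve(crossprod(A), crossprod(A, dvec))
    rss <- sum((A %*% fit - dvec)^2)
    if (is.null(best) || rss < best$rss) best <- list(rss = rss, tree = tr)
  }
  split_set(best$tree)
}

# Random unrooted tree with positive branch lengths and its additive
# distance matrix (path sums).
random_additive_matrix <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE,
                   tip.label = paste0("t", sprintf("%02d", seq_len(n))))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.5)
  dm <- cophenetic(tr)
  ord <- sort(rownames(dm))
  list(tree = tr, dm = dm[ord, ord])
}

# The five targeting archetypes as plain sequences over a shared core.
archetype_sequence <- function(core, kind) {
  switch(kind,
         I = paste0(strrep("SR", 30), core),
         II = paste0(core, strrep("I", 21), "RRRRRW"),
         II_no_cluster = paste0(core, strrep("I", 21), "SSSSSS"),
         III_pts1 = paste0(core, "AKI"),
         III_cyto = core,
         stop("unknown archetype: ", kind))
}

# Co-aligned archetype family (shared coordinate frame, REF row = core).
archetype_family <- function(core) {
  pad <- function(s, left, right) paste0(strrep("-", left), s, strrep("-", right))
  ids <- c("REF", "arch_I", "arch_II", "arch_IInc", "arch_IIIp", "arch_IIIc")
  seqs <- c(pad(core, 60, 30),
            paste0(strrep("SR", 30), core, strrep("-", 30)),
            pad(paste0(core, strrep("I", 21), "RRRRRW"), 60, 3),
            pad(paste0(core, strrep("I", 21), "SSSSSS"), 60, 3),
            paste0(strrep("-", 60), core, strrep("-", 27), "AKI"),
            pad(core, 60, 30))
  aln <- structure(list(ids = ids, seqs = stats::setNames(seqs, ids),
                        alignment_length = nchar(seqs[1])),
                   class = "mdar_alignment")
  recs <- data.frame(id = ids,
                     sequence = gsub("-", "", seqs, fixed = TRUE),
                     species = "Synthetica", lineage = "synthetic",
                     stringsAsFactors = FALSE)
  list(records = recs, aligned = aln)
}
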