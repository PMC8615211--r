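#' Pairwise distances from a protein alignment
#'
#' p-distance with pairwise deletion: for each pair of rows, comparable
#' columns are those where neither row has a gap, and the distance is the
#' mismatch fraction over comparable columns. `X` counts as a mismatch
#' against everything, including another `X`. An optional Poisson
#' correction `-ln(1 - p)` is available.
#'
#' @param aligned an `mdar_alignment` with at least 2 rows.
#' @param correction `"p"` (default) or `"poisson"`.
#' @param min_comparable minimum comparable columns required per pair
#'   (default 10); a pair below this is an error naming the pair.
#' @return A symmetric numeric matrix with the sequence ids as dimnames.
#' @export
p_distance <- function(aligned, correction = c("p", "poisson"),
                       min_comparable = 10L) {
  correction <- match.arg(correction)
  n <- length(aligned$ids)
  if (n < 2) stop("alignment must contain at least 2 sequences")
  m <- alignment_matrix(aligned)
  alphabet <- c("-", AA_ALPHABET20X)
  codes <- matrix(match(m, alphabet), nrow = n)
  if (anyNA(codes)) stop("alignment contains characters outside the alphabet")
  gap <- 1L
  xcode <- match("X", alphabet)
  d <- matrix(0, n, n, dimnames = list(aligned$ids, aligned$ids))
  for (i in seq_len(n - 1L)) {
    a <- codes[i, ]
    for (j in (i + 1L):n) {
      b <- codes[j, ]
      comp <- a != gap & b != gap
      nc <- sum(comp)
      if (nc < min_comparable) {
        stop("pair ('", aligned$ids[i], "', '", aligned$ids[j],
             "') has only ", nc, " comparable columns (need ",
             min_comparable, ")")
      }
      mism <- sum(comp & (a != b | a == xcode | b == xcode))
      p <- mism / nc
      if (correction == "poisson") {
        if (p >= 1) stop("Poisson correction undefined at p = 1 for pair ('",
                         aligned$ids[i], "', '", aligned$ids[j], "')")
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

# Lexicographic comparison key for a joined pair of cluster labels.
pair_key <- function(ki, kj) {
  if (ki <= kj) paste0(ki, "\r", kj) else paste0(kj, "\r", ki)
}

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomeration: at each step the pair minimising
#' `Q(i,j) = (m-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is joined, pendant
#' lengths follow the standard formula, and the reduced distances are
#' `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`. Negative pendant lengths are
#' clamped to zero with the deficit moved to the sister branch, preserving
#' the path length between the joined pair. Ties in Q are broken by the
#' lexicographic order of the joined pair's smallest leaf labels, so the
#' result is deterministic across platforms. Two taxa yield a single edge
#' split equally; the final three clusters are joined at a trifurcation
#' (the usual unrooted representation), with negatives there clamped to
#' zero.
#'
#' @param dm symmetric distance matrix with labels as dimnames (from
#'   [p_distance()]).
#' @return An unrooted `ape::phylo` tree.
#' @export
#' @examples
#' d <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- nj_tree(d)
nj_tree <- function(dm) {
  labels <- rownames(dm)
  if (is.null(labels)) stop("distance matrix must have labelled rows")
  n <- length(labels)
  if (n < 2) stop("need at least 2 taxa")
  if (any(!is.finite(dm))) stop("distance matrix has non-finite entries")
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  if (n == 2) {
    half <- dm[1, 2] / 2
    txt <- paste0("(", labels[1], ":", fmt(half), ",",
                  labels[2], ":", fmt(half), ");")
    return(ape::read.tree(text = txt))
  }
  d <- dm
  node_str <- labels        # newick fragment per active cluster
  node_key <- labels        # smallest leaf label per active cluster
  while (length(node_str) > 3) {
    m <- nrow(d)
    r <- rowSums(d)
    best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        q <- (m - 2) * d[i, j] - r[i] - r[j]
        key <- pair_key(node_key[i], node_key[j])
        if (is.null(best) || q < best$q - 1e-12 ||
            (abs(q - best$q) <= 1e-12 && key < best$key)) {
          best <- list(q = q, i = i, j = j, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_str <- paste0("(", node_str[i], ":", fmt(li), ",",
                      node_str[j], ":", fmt(lj), ")")
    new_key <- min(node_key[i], node_key[j])
    others <- setdiff(seq_len(m), c(i, j))
    du <- (d[i, others] + d[j, others] - d[i, j]) / 2
    d_new <- rbind(cbind(d[others, others, drop = FALSE], du),
                   c(du, 0))
    d <- d_new
    node_str <- c(node_str[others], new_str)
    node_key <- c(node_key[others], new_key)
  }
  # terminal trifurcation from the three-point formulas
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- paste0("(", node_str[1], ":", fmt(la), ",",
                node_str[2], ":", fmt(lb), ",",
                node_str[3], ":", fmt(lc), ");")
  ape::read.tree(text = txt)
}

# Descendant tip labels for every node (tips + internal), as a list.
node_descendants <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", ntip + nnode)
  for (t in seq_len(ntip)) desc[[t]] <- tree$tip.label[t]
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

canonical_split <- function(side, all_tips) {
  smallest <- min(all_tips)
  if (!(smallest %in% side)) side <- setdiff(all_tips, side)
  paste(sort(side), collapse = "\r")
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge defines a split of the leaf set; splits are returned
#' in a canonical orientation (the side containing the alphabetically
#' smallest leaf) so that two trees over the same leaves can be compared
#' directly.
#'
#' @param tree an `ape::phylo`.
#' @return Data frame with columns `node` (the internal node below the
#'   edge) and `key` (canonical split key).
#' @export
tree_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  all_tips <- tree$tip.label
  desc <- node_descendants(tree)
  root <- ntip + 1L
  internal <- setdiff(seq_len(ntip + tree$Nnode)[-seq_len(ntip)], root)
  keep <- vapply(internal, function(nd) {
    sz <- length(desc[[nd]])
    sz >= 2 && sz <= ntip - 2
  }, logical(1))
  internal <- internal[keep]
  data.frame(node = internal,
             key = vapply(internal, function(nd) {
               canonical_split(desc[[nd]], all_tips)
             }, character(1)),
             stringsAsFactors = FALSE)
}

#' Bootstrap support of the split separating a set of leaves
#'
#' Looks up the internal split of `tree` whose one side equals
#' `tip_subset` and returns its `node.label` support, or `NA` when the
#' tree does not contain that split.
#'
#' @param tree a `phylo` with supports in `node.label` (from
#'   [bootstrap_supports()]).
#' @param tip_subset character vector of leaf labels forming one side.
#' @return Integer support in [0, 100], or `NA` if the split is absent.
#' @export
split_support <- function(tree, tip_subset) {
  all_tips <- tree$tip.label
  if (!all(tip_subset %in% all_tips)) {
    stop("tip(s) not in tree: ",
         paste(setdiff(tip_subset, all_tips), collapse = ", "))
  }
  key <- canonical_split(tip_subset, all_tips)
  sp <- tree_splits(tree)
  hit <- sp$node[sp$key == key]
  if (length(hit) == 0) return(NA_integer_)
  lab <- tree$node.label[hit[1] - length(all_tips)]
  if (is.null(lab) || is.na(lab) || !nzchar(lab)) NA_integer_ else
    as.integer(lab)
}

#' Bootstrap supports for the full-data NJ tree
#'
#' Alignment columns are resampled with replacement, the NJ tree is rebuilt
#' per replicate, and each internal split of the full-data tree is scored
#' by the percentage of replicates containing it (rounded to the nearest
#' integer). Supports are attached as `node.label` on the full-data tree.
#' A replicate whose resampled columns leave some pair with too few
#' comparable columns is redrawn (at most 10 retries).
#'
#' @param aligned an `mdar_alignment`.
#' @param n_reps number of bootstrap replicates (default 1000).
#' @param seed integer seed; the run is deterministic for a fixed seed.
#' @param correction distance correction, passed to [p_distance()].
#' @return The full-data `phylo` tree with integer supports in
#'   `node.label` ("" at the root).
#' @export
bootstrap_supports <- function(aligned, n_reps = 1000L, seed = 1L,
                               correction = "p") {
  if (n_reps < 1) stop("n_reps must be at least 1")
  full <- nj_tree(p_distance(aligned, correction = correction))
  splits <- tree_splits(full)
  counts <- setNames(rep(0L, nrow(splits)), splits$key)
  m <- alignment_matrix(aligned)
  ncols <- ncol(m)
  set.seed(seed)
  for (rep in seq_len(n_reps)) {
    tries <- 0L
    repeat {
      cols <- sample.int(ncols, ncols, replace = TRUE)
      res <- tryCatch({
        rows <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
        boot_aln <- new_alignment(aligned$ids, unname(rows))
        nj_tree(p_distance(boot_aln, correction = correction))
      }, error = function(e) e)
      if (!inherits(res, "error")) break
      tries <- tries + 1L
      if (tries > 10L) {
        stop("bootstrap replicate failed after 10 retries: ",
             conditionMessage(res))
      }
    }
    rep_keys <- tree_splits(res)$key
    hit <- splits$key %in% rep_keys
    counts[hit] <- counts[hit] + 1L
  }
  support <- round(100 * counts / n_reps)
  ntip <- length(full$tip.label)
  labels <- rep("", full$Nnode)
  labels[splits$node - ntip] <- as.character(as.integer(support))
  full$node.label <- labels
  full
}
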