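#' @importFrom stats setNames
NULL

AA_ALPHABET20X <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                    "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

validate_sequences <- function(seqs, ids, allow_gap = FALSE) {
  allowed <- AA_ALPHABET20X
  if (allow_gap) allowed <- c(allowed, "-")
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(chars), allowed)
    if (length(bad)) {
      stop("record '", ids[[i]], "' contains invalid characters: ",
           paste(bad, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Read a protein FASTA file
#'
#' Parses a plain (ungapped) protein FASTA file into a record table. The
#' identifier is the header token before the first whitespace; the full
#' header is retained as `description`. Sequences are uppercased and must
#' use the 20 standard amino-acid letters plus `X`.
#'
#' @param path path to a FASTA file.
#' @param species_map optional data frame with columns `id`, `species`,
#'   `lineage` (see [read_species_map()]); matched rows populate the
#'   corresponding record columns.
#' @return A data frame with columns `id`, `sequence`, `species`,
#'   `lineage`, `description`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 demo", "MKT"), tf)
#' read_fasta(tf)
read_fasta <- function(path, species_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1)
  if (anyNA(ids) || any(!nzchar(ids))) stop("FASTA entry with empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0)) {
    stop("zero-length sequence for id: ", ids[nchar(seqs) == 0][1])
  }
  validate_sequences(seqs, ids, allow_gap = FALSE)
  out <- data.frame(id = ids, sequence = unname(seqs),
                    species = NA_character_, lineage = NA_character_,
                    description = headers, stringsAsFactors = FALSE)
  if (!is.null(species_map)) {
    m <- match(out$id, species_map$id)
    out$species <- species_map$species[m]
    out$lineage <- species_map$lineage[m]
  }
  out
}

#' Write protein records to FASTA
#'
#' @param records a record data frame (columns `id`, `sequence`) as
#'   returned by [read_fasta()] or [generate_family()].
#' @param path output path.
#' @param width line-wrap width in residues.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (nrow(records) == 0) stop("no records to write")
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con, sep = "\n")
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read an aligned (gapped) FASTA file
#'
#' @param path path to an aligned FASTA file; `-` is the gap character.
#' @return An object of class `mdar_alignment`: a list with `ids`,
#'   `seqs` (named character vector of gapped rows) and
#'   `alignment_length`.
#' @export
read_aligned_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty alignment file: ", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    i <- which(lens != lens[1])[1]
    stop("ragged alignment: row '", ids[1], "' has length ", lens[1],
         " but row '", ids[i], "' has length ", lens[i])
  }
  validate_sequences(seqs, ids, allow_gap = TRUE)
  new_alignment(ids, unname(seqs))
}

new_alignment <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs))
  structure(list(ids = ids, seqs = setNames(seqs, ids),
                 alignment_length = if (length(seqs)) nchar(seqs[[1]]) else 0L),
            class = "mdar_alignment")
}

#' @export
print.mdar_alignment <- function(x, ...) {
  cat("MDAR alignment:", length(x$ids), "sequences x",
      x$alignment_length, "columns\n")
  invisible(x)
}

#' Write an aligned set to gapped FASTA
#'
#' @param aligned an `mdar_alignment`.
#' @param path output path.
#' @param width line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_aligned_fasta <- function(aligned, path, width = 60L) {
  recs <- data.frame(id = aligned$ids, sequence = unname(aligned$seqs),
                     stringsAsFactors = FALSE)
  write_fasta(recs, path, width = width)
}

#' Convert an alignment to a character matrix (rows = sequences)
#'
#' @param aligned an `mdar_alignment`.
#' @return A character matrix with one row per sequence, rownames = ids.
#' @export
alignment_matrix <- function(aligned) {
  m <- do.call(rbind, strsplit(unname(aligned$seqs), "", fixed = TRUE))
  rownames(m) <- aligned$ids
  m
}

#' Remove gaps from one alignment row
#'
#' @param aligned an `mdar_alignment`.
#' @param id row identifier.
#' @return The ungapped sequence string.
#' @export
ungap_row <- function(aligned, id) {
  if (!id %in% aligned$ids) stop("id not in alignment: ", id)
  gsub("-", "", aligned$seqs[[id]], fixed = TRUE)
}

#' Read a species map
#'
#' Tab-separated file with header columns `id`, `species`, `lineage`.
#'
#' @param path path to the TSV file.
#' @return A data frame with those three columns.
#' @export
read_species_map <- function(path) {
  sm <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "species", "lineage")
  if (!all(need %in% names(sm))) {
    stop("species map must have columns: ", paste(need, collapse = ", "))
  }
  sm[need]
}

newick_node <- function(tree, node, children, lab_of) {
  ntip <- length(tree$tip.label)
  kids <- children[[as.character(node)]]
  parts <- vapply(seq_len(nrow(kids)), function(i) {
    child <- kids$child[i]
    len <- sprintf("%.6f", kids$length[i])
    if (child <= ntip) {
      paste0(tree$tip.label[child], ":", len)
    } else {
      paste0(newick_node(tree, child, children, lab_of),
             lab_of(child), ":", len)
    }
  }, character(1))
  paste0("(", paste(parts, collapse = ","), ")")
}

#' Write a phylogenetic tree to Newick
#'
#' Branch lengths are written with six decimals; integer bootstrap supports
#' stored in `node.label` become internal node labels. A two-leaf tree is
#' written with its single distance split equally across the two pendant
#' edges (the convention fixed at construction time by [nj_tree()]).
#'
#' @param tree an `ape::phylo` object with named leaves and edge lengths.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  ntip <- length(tree$tip.label)
  if (ntip < 2) stop("tree must have at least 2 leaves")
  if (anyNA(tree$tip.label) || any(!nzchar(tree$tip.label))) {
    stop("tree contains an unnamed leaf")
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  edges <- data.frame(parent = tree$edge[, 1], child = tree$edge[, 2],
                      length = tree$edge.length)
  children <- split(edges, edges$parent)
  root <- ntip + 1L
  lab_of <- function(node) {
    if (is.null(tree$node.label)) return("")
    lab <- tree$node.label[node - ntip]
    if (is.na(lab) || !nzchar(lab)) "" else lab
  }
  str <- paste0(newick_node(tree, root, children, lab_of), lab_of(root), ";")
  writeLines(str, path)
  invisible(path)
}

#' Write the per-sequence classification report
#'
#' Tab-separated, one row per sequence, with the full evidence trail. Flag
#' sets are joined with `;` in sorted order so that identical inputs always
#' produce byte-identical files.
#'
#' @param classifications an `mdar_classification` object (or a data frame
#'   with the report columns) from [classify_family()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(classifications, path) {
  cls <- as.data.frame(classifications)
  if (nrow(cls) == 0) stop("no classifications to write")
  cols <- c("id", "species", "lineage", "class", "subclass_flags",
            "pts1_tripeptide", "tm_spans", "basic_cluster",
            "nterm_extension_len", "organellar_score", "catalytic_ok",
            "atypical_flags", "evidence")
  if ("primary_class" %in% names(cls) && !"class" %in% names(cls)) {
    cls$class <- cls$primary_class
  }
  missing <- setdiff(cols, names(cls))
  if (length(missing)) {
    stop("classification table lacks columns: ",
         paste(missing, collapse = ", "))
  }
  out <- cls[cols]
  out$organellar_score <- sprintf("%.4f", out$organellar_score)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con, sep = "\n")
  for (i in seq_len(nrow(out))) {
    writeLines(paste(vapply(out[i, ], as.character, character(1)),
                     collapse = "\t"), con, sep = "\n")
  }
  invisible(path)
}

# Stable ';'-joined representation of a flag set (sorted, deduplicated).
join_flags <- function(flags) {
  if (length(flags) == 0) return("")
  paste(sort(unique(flags)), collapse = ";")
}
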