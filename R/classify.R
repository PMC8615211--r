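#' Assign one sequence to an MDAR targeting class
#'
#' Applies the signal precedence rules: (1) a failed catalytic check demotes
#' the sequence to "MDAR-like"; (2) a C-terminal transmembrane span makes it
#' class II (peroxisomal membrane), flagged `tm_no_basic_cluster` when the
#' adjacent basic cluster is missing; (3) an organellar N-terminal extension
#' without a PTS1 makes it class I (chloroplastic/mitochondrial); (4)
#' everything else is class III (cytosolic/peroxisomal), flagged
#' `cytosol_specific` without a PTS1 or `dual_targeting_pts1` with one. An
#' organellar extension together with a PTS1 stays class III with a
#' `conflict` flag — contradictory signals are recorded, never silently
#' resolved. Atypicality flags are carried through.
#'
#' @param signals an `mdar_signals` object from [scan_signals()].
#' @return List with `primary_class` ("I", "II", "III" or "MDAR-like"),
#'   `subclass_flags` (character vector), `evidence` (ordered character
#'   vector of fired rules).
#' @export
classify_sequence <- function(signals) {
  need <- c("pts1", "mpts", "nterm", "catalytic", "atypical")
  missing <- need[!need %in% names(signals)]
  if (length(missing)) {
    stop("signal set lacks component(s): ", paste(missing, collapse = ", "))
  }
  flags <- character(0)
  evidence <- character(0)
  atypical <- signals$atypical
  atyp_flags <- c(if (isTRUE(atypical$length_atypical)) "atypical_length",
                  if (isTRUE(atypical$dual_catalytic_core)) "dual_core")

  if (!signals$catalytic$ok) {
    evidence <- c(evidence, paste0(
      "catalytic check failed (",
      paste(names(signals$catalytic$residues_found),
            signals$catalytic$residues_found, sep = "=", collapse = ","),
      ")"))
    return(list(primary_class = "MDAR-like",
                subclass_flags = sort(unique(atyp_flags)),
                evidence = evidence))
  }
  evidence <- c(evidence, "catalytic residues intact")

  pts1 <- signals$pts1$present && signals$pts1$tier %in% c("canonical", "listed")

  if (signals$mpts$has_cterm_tm) {
    evidence <- c(evidence, "C-terminal transmembrane span")
    if (signals$mpts$basic_cluster) {
      evidence <- c(evidence,
                    paste0("basic cluster ", signals$mpts$cluster_seq))
    } else {
      flags <- c(flags, "tm_no_basic_cluster")
      evidence <- c(evidence, "no adjacent basic cluster")
    }
    return(list(primary_class = "II",
                subclass_flags = sort(unique(c(flags, atyp_flags))),
                evidence = evidence))
  }

  organellar <- isTRUE(signals$nterm$organellar)
  if (organellar && !pts1) {
    evidence <- c(evidence,
                  paste0("organellar N-terminal extension (",
                         signals$nterm$length, " aa, score ",
                         sprintf("%.3f", signals$nterm$organellar_score), ")"))
    return(list(primary_class = "I",
                subclass_flags = sort(unique(atyp_flags)),
                evidence = evidence))
  }

  if (pts1) {
    flags <- c(flags, "dual_targeting_pts1")
    evidence <- c(evidence, paste0("PTS1-like tripeptide ",
                                   signals$pts1$tripeptide, " (",
                                   signals$pts1$tier, ")"))
    if (organellar) {
      flags <- c(flags, "conflict")
      evidence <- c(evidence,
                    "conflicting organellar extension alongside PTS1")
    }
  } else {
    flags <- c(flags, "cytosol_specific")
    evidence <- c(evidence, "no targeting signal: cytosol-restricted")
  }
  list(primary_class = "III",
       subclass_flags = sort(unique(c(flags, atyp_flags))),
       evidence = evidence)
}

format_spans <- function(tm_spans) {
  if (is.null(tm_spans) || nrow(tm_spans) == 0) return("")
  paste(paste0(tm_spans$start, "-", tm_spans$end), collapse = ";")
}

#' Classify a whole family, optionally corroborated by a tree
#'
#' Runs [classify_sequence()] on every record. When a tree is supplied,
#' each sequence's smallest surrounding clade with at least 3 leaves and at
#' least 2 other signal-classified (non-MDAR-like) members votes a
#' `clade_class` by majority; disagreement with the signal-derived class
#' adds a `conflict` flag but never changes the class itself.
#'
#' @param records record data frame (from [read_fasta()] or
#'   [generate_family()]).
#' @param signals_all named list of `mdar_signals`, one per record id.
#' @param tree optional `ape::phylo`; leaves must be a subset of record ids.
#' @return An object of class `mdar_classification`: a data frame with the
#'   class, subclass flags, clade class and the full evidence columns used
#'   by [write_report()].
#' @export
classify_family <- function(records, signals_all, tree = NULL) {
  ids <- records$id
  missing <- setdiff(ids, names(signals_all))
  if (length(missing)) {
    stop("no signals for record(s): ", paste(missing, collapse = ", "))
  }
  base <- lapply(ids, function(id) classify_sequence(signals_all[[id]]))
  names(base) <- ids
  primary <- vapply(base, `[[`, character(1), "primary_class")
  flags <- lapply(base, `[[`, "subclass_flags")
  evidence <- lapply(base, `[[`, "evidence")
  clade_class <- setNames(rep(NA_character_, length(ids)), ids)

  if (!is.null(tree)) {
    extra <- setdiff(tree$tip.label, ids)
    if (length(extra)) {
      stop("tree leaf not among records: ", paste(extra, collapse = ", "))
    }
    # unrooted clade voting: for each leaf, the candidate clades are the
    # split sides containing it (the rooting of the phylo object is
    # presentational and must not matter), smallest first, with the whole
    # leaf set as the final fallback
    ntip <- length(tree$tip.label)
    desc <- node_descendants(tree)
    sides <- lapply(tree_splits(tree)$node, function(nd) desc[[nd]])
    all_tips <- tree$tip.label
    for (id in all_tips) {
      if (primary[[id]] == "MDAR-like") next
      cands <- lapply(sides, function(s) if (id %in% s) s else
        setdiff(all_tips, s))
      cands <- c(cands, list(all_tips))
      keys <- vapply(cands, function(s) paste(sort(s), collapse = "\r"),
                     character(1))
      cands <- cands[!duplicated(keys)]
      cands <- cands[order(lengths(cands))]
      for (members in cands) {
        voters <- setdiff(members, id)
        voters <- voters[primary[voters] != "MDAR-like"]
        if (length(members) < 3 || length(voters) < 2) next
        tab <- table(primary[voters])
        top <- names(tab)[tab == max(tab)]
        if (length(top) > 1) next  # tied: consult the next larger clade
        clade_class[[id]] <- top
        if (top != primary[[id]]) {
          flags[[id]] <- sort(unique(c(flags[[id]], "conflict")))
          evidence[[id]] <- c(evidence[[id]],
                              paste0("clade majority is class ", top))
        }
        break
      }
    }
  }

  sig_field <- function(f) lapply(ids, function(id) f(signals_all[[id]]))
  out <- data.frame(
    id = ids,
    species = if ("species" %in% names(records)) records$species else NA,
    lineage = if ("lineage" %in% names(records)) records$lineage else NA,
    class = unname(primary),
    subclass_flags = vapply(flags, join_flags, character(1)),
    clade_class = unname(clade_class),
    pts1_tripeptide = vapply(sig_field(function(s) s$pts1$tripeptide),
                             identity, character(1)),
    tm_spans = vapply(sig_field(function(s) format_spans(s$tm_spans)),
                      identity, character(1)),
    basic_cluster = vapply(sig_field(function(s) s$mpts$basic_cluster),
                           identity, logical(1)),
    nterm_extension_len = vapply(sig_field(function(s) s$nterm$length),
                                 as.integer, integer(1)),
    organellar_score = vapply(sig_field(function(s) s$nterm$organellar_score),
                              as.numeric, numeric(1)),
    catalytic_ok = vapply(sig_field(function(s) s$catalytic$ok),
                          identity, logical(1)),
    atypical_flags = vapply(ids, function(id) {
      a <- signals_all[[id]]$atypical
      join_flags(c(if (isTRUE(a$length_atypical)) "atypical_length",
                   if (isTRUE(a$dual_catalytic_core)) "dual_core"))
    }, character(1)),
    evidence = vapply(evidence, function(e) paste(e, collapse = "; "),
                      character(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("mdar_classification", "data.frame")
  out
}

#' @export
print.mdar_classification <- function(x, ...) {
  cat("MDAR classification of", nrow(x), "sequences\n")
  cols <- intersect(c("id", "species", "class", "subclass_flags",
                      "clade_class"), names(x))
  print.data.frame(as.data.frame(x)[cols], ...)
  invisible(x)
}

#' @export
summary.mdar_classification <- function(object, ...) {
  tab <- table(factor(object$class, levels = c("I", "II", "III", "MDAR-like")))
  cyto <- sum(grepl("cytosol_specific", object$subclass_flags))
  conf <- sum(grepl("conflict", object$subclass_flags))
  cat("Class counts:\n")
  print(tab)
  cat("cytosol-specific (class III without PTS1):", cyto, "\n")
  cat("signal/clade conflicts flagged:", conf, "\n")
  invisible(list(classes = tab, cytosol_specific = cyto, conflicts = conf))
}

#' Per-species isoform counts
#'
#' @param classifications an `mdar_classification`.
#' @param species_map optional data frame (`id`, `species`, `lineage`)
#'   overriding the species column; every classified id must resolve to a
#'   species.
#' @return Data frame, one row per species, with counts of class I, II,
#'   III, cytosol-specific class III, MDAR-like, and the total.
#' @export
summarize_counts <- function(classifications, species_map = NULL) {
  cls <- as.data.frame(classifications)
  if (nrow(cls) == 0) stop("no classifications to summarize")
  species <- cls$species
  if (!is.null(species_map)) {
    species <- species_map$species[match(cls$id, species_map$id)]
  }
  if (anyNA(species)) {
    stop("missing species for id(s): ",
         paste(cls$id[is.na(species)], collapse = ", "))
  }
  sp <- sort(unique(species))
  count <- function(s, pred) sum(species == s & pred)
  out <- data.frame(
    species = sp,
    class_I = vapply(sp, function(s) count(s, cls$class == "I"), numeric(1)),
    class_II = vapply(sp, function(s) count(s, cls$class == "II"), numeric(1)),
    class_III = vapply(sp, function(s) count(s, cls$class == "III"), numeric(1)),
    class_III_cytosol_specific = vapply(sp, function(s) {
      count(s, cls$class == "III" & grepl("cytosol_specific", cls$subclass_flags))
    }, numeric(1)),
    mdar_like = vapply(sp, function(s) count(s, cls$class == "MDAR-like"),
                       numeric(1)),
    stringsAsFactors = FALSE
  )
  out$total <- out$class_I + out$class_II + out$class_III + out$mdar_like
  rownames(out) <- NULL
  out
}
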