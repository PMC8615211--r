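AA20 <- setdiff(AA_ALPHABET20X, "X")

#' Specification for a synthetic MDAR family
#'
#' Describes the family the generator emulates: a set of plant species each
#' carrying a fixed complement of MDAR isoforms (a chloroplastic/
#' mitochondrial class I, a membrane-bound class II, a PTS1-carrying class
#' III, and cytosol-restricted class III paralogs), diverged from one
#' ancestral core by point substitutions along a paralog-clade structure.
#'
#' @param n_species number of species (default 5).
#' @param classes_per_species named integer vector over the labels
#'   `I`, `II`, `III_pts1`, `III_cyto`, `MDAR_like` giving isoform counts
#'   per species (default 1, 1, 1, 2, 0 — an Arabidopsis-like complement).
#' @param core_length residues in the conserved enzymatic core (default
#'   435, within the typical 400-552 range).
#' @param mutation_rate substitutions per site per lineage segment, in
#'   [0, 0.3) (default 0.05).
#' @param indels allow indels (default FALSE; with indels the generator
#'   returns no alignment, since alignment construction is out of scope).
#' @param seed integer seed; the generator is fully deterministic given the
#'   spec.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(n_species = 5L,
                        classes_per_species = c(I = 1L, II = 1L,
                                                III_pts1 = 1L, III_cyto = 2L,
                                                MDAR_like = 0L),
                        core_length = 435L, mutation_rate = 0.05,
                        indels = FALSE, seed = 1L) {
  labels <- c("I", "II", "III_pts1", "III_cyto", "MDAR_like")
  full <- setNames(integer(5), labels)
  if (is.null(names(classes_per_species)) ||
      !all(names(classes_per_species) %in% labels)) {
    stop("classes_per_species must be named with labels from: ",
         paste(labels, collapse = ", "))
  }
  full[names(classes_per_species)] <- as.integer(classes_per_species)
  if (any(full < 0)) stop("isoform counts must be >= 0")
  if (n_species < 1) stop("need at least one species")
  if (mutation_rate < 0 || mutation_rate >= 0.3) {
    stop("mutation_rate must be in [0, 0.3)")
  }
  if (core_length < 400 || core_length > 552) {
    stop("core_length must lie in [400, 552]")
  }
  structure(list(n_species = as.integer(n_species),
                 classes_per_species = full,
                 core_length = as.integer(core_length),
                 mutation_rate = mutation_rate,
                 indels = isTRUE(indels), seed = as.integer(seed)),
            class = "family_spec")
}

# Draw a core with fixed catalytic residues, no accidental hydrophobic
# 19-window (so TM detection has no false positives by construction) and
# no accidental PTS1-like C-terminal tripeptide.
draw_core <- function(len, cat_pos, window = 19L, threshold = 1.6) {
  core <- sample(AA20, len, replace = TRUE)
  core[cat_pos["R"]] <- "R"
  core[cat_pos["Y"]] <- "Y"
  half <- window %/% 2L
  repeat {
    prof <- hydropathy_profile(paste(core, collapse = ""), window)
    bad <- which(!is.na(prof) & prof >= threshold)
    if (length(bad) == 0) break
    redraw <- unique(unlist(lapply(bad, function(c) (c - half):(c + half))))
    redraw <- setdiff(redraw[redraw >= 1 & redraw <= len], cat_pos)
    core[redraw] <- sample(AA20, length(redraw), replace = TRUE)
  }
  repeat {
    tri <- paste(core[(len - 2L):len], collapse = "")
    if (scan_pts1(paste0("AAA", tri))$tier == "none" &&
        !grepl("^[ASC][KRNS][LIVMF]$", tri)) break
    core[(len - 2L):len] <- sample(AA20, 3L, replace = TRUE)
  }
  core
}

# Point substitutions at `rate` per eligible site; protected positions and
# the C-terminal tripeptide (the decoration site) are never touched. A
# substitution set that drifts some 19-window of the core over the TM
# hydropathy threshold is resampled, preserving the construction guarantee
# that planted stretches are the only TM calls.
mutate_core <- function(core, rate, protected, window = 19L,
                        threshold = 1.6) {
  if (rate <= 0) return(core)
  len <- length(core)
  eligible <- setdiff(seq_len(len), c(protected, (len - 2L):len))
  repeat {
    cand <- core
    hit <- eligible[stats::runif(length(eligible)) < rate]
    for (i in hit) {
      cand[i] <- sample(setdiff(AA20, cand[i]), 1L)
    }
    prof <- hydropathy_profile(paste(cand, collapse = ""), window)
    if (!any(!is.na(prof) & prof >= threshold)) return(cand)
  }
}

draw_extension <- function(len = 60L) {
  # transit-peptide-like composition: S and R at 0.3 each, remainder uniform
  probs <- setNames(rep(0.4 / 18, 20), AA20)
  probs["S"] <- 0.3
  probs["R"] <- 0.3
  paste(sample(AA20, len, replace = TRUE, prob = probs), collapse = "")
}

draw_tm <- function(len = 21L) {
  paste(sample(c("I", "L", "V", "F"), len, replace = TRUE), collapse = "")
}

#' Generate a synthetic MDAR family with planted signals and truth labels
#'
#' One random ancestral core (fixed catalytic R/Y at the configured
#' positions) is decorated per class — class I gets a 60-residue S/R-rich
#' N-terminal extension, class II a 21-residue I/L/V/F transmembrane
#' stretch plus the basic cluster RRRRRW, class III (PTS1 subtype) a
#' tripeptide from the accepted PTS1 list, cytosolic class III nothing, and
#' MDAR-like sequences carry the core with the catalytic arginine replaced
#' by alanine. Each class/paralog forms its own clade: the paralog ancestor
#' diverges from the root core by point substitutions at `mutation_rate`,
#' and each species' sequence diverges again from its paralog ancestor.
#' Planted signal residues and catalytic positions are never mutated.
#' Without indels all records share one coordinate frame, so the exact
#' alignment is emitted alongside the sequences; an undecorated, unmutated
#' reference row `REF_CYTO` is always included.
#'
#' @param spec a [family_spec()].
#' @param catalytic_positions named integer vector `c(R = ..., Y = ...)` of
#'   core positions for the two catalytic residues (default 320 and 349,
#'   mirroring rice OsaMDAR3 numbering).
#' @param pts1_list tripeptides to plant in PTS1 isoforms.
#' @return List of class `mdar_family` with `records` (data frame: id,
#'   sequence, species, lineage), `aligned` (`mdar_alignment`, or NULL with
#'   indels), `truth` (data frame of planted classes and signal strings),
#'   and `catalytic_context` (the 7-residue ancestral window around the
#'   catalytic arginine, usable as a dual-core probe motif).
#' @export
generate_family <- function(spec,
                            catalytic_positions = c(R = 320L, Y = 349L),
                            pts1_list = mdar_config()$pts1_list) {
  if (!inherits(spec, "family_spec")) stop("spec must be a family_spec")
  if (max(catalytic_positions) > spec$core_length) {
    stop("catalytic positions exceed core length")
  }
  set.seed(spec$seed)
  len <- spec$core_length
  root <- draw_core(len, catalytic_positions)
  cat_context <- paste(root[(catalytic_positions["R"] - 3L):
                              (catalytic_positions["R"] + 3L)], collapse = "")
  species <- sprintf("Sp%02d", seq_len(spec$n_species))

  ext_len <- 60L
  tm_len <- 21L
  cluster <- "RRRRRW"
  rows <- list()
  add_row <- function(id, sp, label, core_chars, ext, tm, clus, tri) {
    core_seq <- paste(core_chars, collapse = "")
    seq <- paste0(ext, core_seq, tm, clus, tri)
    # shared column frame: [ext 60][core][tm 21 + cluster 6][pts1 3]
    aln <- paste0(
      if (nzchar(ext)) ext else strrep("-", ext_len),
      core_seq,
      if (nzchar(tm)) paste0(tm, clus) else strrep("-", tm_len + 6L),
      if (nzchar(tri)) tri else "---")
    rows[[length(rows) + 1L]] <<- list(
      id = id, species = sp, label = label, seq = seq, aln = aln,
      ext = ext, tm = tm, clus = clus, tri = tri)
  }

  add_row("REF_CYTO", "reference", "III_cyto", root, "", "", "", "")

  counts <- spec$classes_per_species
  for (label in names(counts)) {
    for (k in seq_len(counts[[label]])) {
      paralog_core <- root
      if (label == "MDAR_like") paralog_core[catalytic_positions["R"]] <- "A"
      paralog_core <- mutate_core(paralog_core, spec$mutation_rate,
                                  protected = catalytic_positions)
      ext <- if (label == "I") draw_extension(ext_len) else ""
      tm <- if (label == "II") draw_tm(tm_len) else ""
      clus <- if (label == "II") cluster else ""
      tri <- if (label == "III_pts1") sample(pts1_list, 1L) else ""
      for (s in seq_len(spec$n_species)) {
        core_s <- mutate_core(paralog_core, spec$mutation_rate,
                              protected = catalytic_positions)
        id <- paste0(species[s], "_", label, "_", k)
        add_row(id, species[s], label, core_s, ext, tm, clus, tri)
      }
    }
  }

  if (spec$indels) {
    # drop a short random block from a few cores; coordinates no longer
    # shared, so no alignment is produced
    for (i in sample(seq_along(rows), max(1L, length(rows) %/% 5L))) {
      s <- rows[[i]]$seq
      start <- sample(seq(ext_len + 10L, ext_len + 100L), 1L)
      rows[[i]]$seq <- paste0(substr(s, 1, start - 1L),
                              substr(s, start + 3L, nchar(s)))
    }
  }

  records <- data.frame(
    id = vapply(rows, `[[`, character(1), "id"),
    sequence = vapply(rows, `[[`, character(1), "seq"),
    species = vapply(rows, `[[`, character(1), "species"),
    lineage = "synthetic",
    stringsAsFactors = FALSE
  )
  aligned <- if (spec$indels) NULL else {
    new_alignment(records$id, vapply(rows, `[[`, character(1), "aln"))
  }
  truth <- data.frame(
    id = records$id,
    species = records$species,
    class = vapply(rows, `[[`, character(1), "label"),
    extension_seq = vapply(rows, `[[`, character(1), "ext"),
    tm_seq = vapply(rows, `[[`, character(1), "tm"),
    cluster_seq = vapply(rows, `[[`, character(1), "clus"),
    pts1_tripeptide = vapply(rows, `[[`, character(1), "tri"),
    catalytic_R_pos = unname(catalytic_positions["R"]),
    catalytic_Y_pos = unname(catalytic_positions["Y"]),
    stringsAsFactors = FALSE
  )
  structure(list(records = records, aligned = aligned, truth = truth,
                 catalytic_context = cat_context, spec = spec),
            class = "mdar_family")
}

#' @export
print.mdar_family <- function(x, ...) {
  cat("Synthetic MDAR family:", nrow(x$records), "sequences,",
      x$spec$n_species, "species, mutation rate", x$spec$mutation_rate, "\n")
  print(table(x$truth$class))
  invisible(x)
}

#' Scan signals for every record of a family
#'
#' @param records record data frame.
#' @param aligned `mdar_alignment` containing every record id plus the
#'   reference row.
#' @param ref_id cytosolic-core reference row id (default "REF_CYTO").
#' @param config configuration list from [mdar_config()].
#' @param catalytic_context_motif optional motif for [detect_atypical()].
#' @return Named list of `mdar_signals`, one per record id.
#' @export
scan_family <- function(records, aligned, ref_id = "REF_CYTO",
                        config = mdar_config(),
                        catalytic_context_motif = NULL) {
  sig <- lapply(seq_len(nrow(records)), function(i) {
    scan_signals(records$sequence[i], aligned, ref_id, records$id[i],
                 config = config,
                 catalytic_context_motif = catalytic_context_motif)
  })
  names(sig) <- records$id
  sig
}

# Truth label implied by a classification row (class + decisive flag).
classified_label <- function(class, subclass_flags) {
  if (class == "MDAR-like") return("MDAR_like")
  if (class == "III") {
    if (grepl("cytosol_specific", subclass_flags)) return("III_cyto")
    if (grepl("dual_targeting_pts1", subclass_flags)) return("III_pts1")
    return("III_other")
  }
  class
}

#' Fraction of planted classes recovered by the classifier
#'
#' Compares subclass-resolved labels (I, II, III_pts1, III_cyto, MDAR_like)
#' between a classification and the generator's truth table.
#'
#' @param classifications an `mdar_classification`.
#' @param truth the `truth` data frame from [generate_family()].
#' @return Recovery accuracy in [0, 1].
#' @export
recovery_accuracy <- function(classifications, truth) {
  cls <- as.data.frame(classifications)
  m <- match(truth$id, cls$id)
  if (anyNA(m)) stop("classification lacks id(s): ",
                     paste(truth$id[is.na(m)], collapse = ", "))
  got <- vapply(m, function(i) {
    classified_label(cls$class[i], cls$subclass_flags[i])
  }, character(1))
  mean(got == truth$class)
}

#' Multinomial genotype counts from a segregation model
#'
#' @param model a [segregation_model()].
#' @param n number of progeny.
#' @param seed integer seed.
#' @return Named integer vector of counts over the survivor genotypes.
#' @export
generate_genotype_counts <- function(model, n, seed = 1L) {
  if (n < 1) stop("n must be at least 1")
  probs <- expected_freqs(model)
  set.seed(seed)
  counts <- stats::rmultinom(1, n, probs)[, 1]
  setNames(as.integer(counts), names(probs))
}
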