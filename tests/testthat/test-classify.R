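fixture_signals <- function() {
  set.seed(37)
  core <- random_core()
  fx <- archetype_family(core)
  list(fx = fx, signals = scan_family(fx$records, fx$aligned, ref_id = "REF"))
}

test_that("signal precedence reproduces the archetype class assignments", {
  fs <- fixture_signals()
  sig <- fs$signals

  # TM + basic cluster -> class II, no subclass flag
  c2 <- classify_sequence(sig$arch_II)
  expect_equal(c2$primary_class, "II")
  expect_equal(c2$subclass_flags, character(0))

  # TM without the cluster -> class II + flag (Poaceae-like subclass)
  c2n <- classify_sequence(sig$arch_IInc)
  expect_equal(c2n$primary_class, "II")
  expect_equal(c2n$subclass_flags, "tm_no_basic_cluster")

  # organellar extension, no PTS1 -> class I
  c1 <- classify_sequence(sig$arch_I)
  expect_equal(c1$primary_class, "I")

  # PTS1 without other signals -> class III, dual targeting
  c3p <- classify_sequence(sig$arch_IIIp)
  expect_equal(c3p$primary_class, "III")
  expect_equal(c3p$subclass_flags, "dual_targeting_pts1")

  # nothing at all -> cytosol-restricted class III
  c3c <- classify_sequence(sig$arch_IIIc)
  expect_equal(c3c$primary_class, "III")
  expect_equal(c3c$subclass_flags, "cytosol_specific")

  expect_error(classify_sequence(sig$arch_I[c("pts1", "mpts")]), "lacks")
})

test_that("catalytic failure demotes to MDAR-like regardless of signals", {
  set.seed(41)
  core <- random_core()
  chars <- strsplit(core, "")[[1]]
  chars[320] <- "A"
  broken <- paste(chars, collapse = "")
  # give the broken core a PTS1 too: the catalytic rule must win
  aln <- structure(list(
    ids = c("REF", "q"),
    seqs = c(REF = paste0(core, "---"), q = paste0(broken, "AKI")),
    alignment_length = nchar(core) + 3L), class = "mdar_alignment")
  sig <- scan_signals(paste0(broken, "AKI"), aln, "REF", "q")
  res <- classify_sequence(sig)
  expect_equal(res$primary_class, "MDAR-like")
  expect_true(all(res$subclass_flags %in% c("atypical_length", "dual_core")))
})

test_that("organellar extension together with a PTS1 is flagged, not resolved", {
  set.seed(43)
  core <- random_core()
  ext <- strrep("SR", 30)
  seqq <- paste0(ext, core, "AKI")
  aln <- structure(list(
    ids = c("REF", "q"),
    seqs = c(REF = paste0(strrep("-", 60), core, "---"),
             q = paste0(ext, core, "AKI")),
    alignment_length = 60L + nchar(core) + 3L), class = "mdar_alignment")
  sig <- scan_signals(seqq, aln, "REF", "q")
  res <- classify_sequence(sig)
  expect_equal(res$primary_class, "III")
  expect_true(all(c("conflict", "dual_targeting_pts1") %in% res$subclass_flags))
})

test_that("the tree corroborates but never overrides signal classes", {
  fam <- generate_family(family_spec(seed = 2))
  sig <- scan_family(fam$records, fam$aligned)
  tree <- nj_tree(p_distance(fam$aligned))

  no_tree <- classify_family(fam$records, sig)
  with_tree <- classify_family(fam$records, sig, tree = tree)
  expect_equal(with_tree$class, no_tree$class)
  expect_true(all(is.na(no_tree$clade_class)))

  # clades agree with the (correct) signals for every planted sequence;
  # only the basal reference row, whose attachment point is arbitrary, is
  # allowed to pick up a clade vote from a neighbouring class
  planted <- as.data.frame(with_tree)
  planted <- planted[planted$id != "REF_CYTO", ]
  expect_false(any(grepl("conflict", planted$subclass_flags)))
  agree <- !is.na(planted$clade_class)
  expect_true(any(agree))
  expect_true(all(planted$clade_class[agree] == planted$class[agree]))

  bad_tree <- tree
  bad_tree$tip.label[1] <- "not_a_record"
  expect_error(classify_family(fam$records, sig, tree = bad_tree),
               "not_a_record")
})

test_that("a PTS1 sequence planted inside a class-I clade is flagged", {
  set.seed(47)
  core <- random_core()
  ext <- strrep("SR", 30)
  n_i <- 4
  ids <- c("REF", paste0("cladeI_", seq_len(n_i)), "intruder")
  mut <- function(s, k) {
    chars <- strsplit(s, "")[[1]]
    idx <- sample(setdiff(seq(1, 300), c(320, 349)), k)
    chars[idx] <- vapply(chars[idx], function(ch) {
      sample(setdiff(HYDROPHILIC, ch), 1)
    }, character(1))
    paste(chars, collapse = "")
  }
  cores <- c(core, replicate(n_i, mut(core, 8)), mut(core, 8))
  seqs <- c(paste0(strrep("-", 60), cores[1], "---"),
            paste0(ext, cores[2:5], "---"),
            paste0(strrep("-", 60), cores[6], "AKI"))
  aln <- structure(list(ids = ids, seqs = stats::setNames(seqs, ids),
                        alignment_length = nchar(seqs[1])),
                   class = "mdar_alignment")
  recs <- data.frame(id = ids, sequence = gsub("-", "", seqs),
                     species = "Synthetica", lineage = "synthetic",
                     stringsAsFactors = FALSE)
  sig <- scan_family(recs, aln, ref_id = "REF")
  tree <- nj_tree(p_distance(aln))
  cls <- classify_family(recs, sig, tree = tree)
  intr <- cls[cls$id == "intruder", ]
  expect_equal(intr$class, "III")  # the signal stands
  expect_true(grepl("conflict", intr$subclass_flags))
  expect_equal(intr$clade_class, "I")
})

test_that("per-species summaries mirror known isoform complements", {
  fs <- fixture_signals()
  # Arabidopsis-like: 1 class I, 1 class II, 1 PTS1 class III, 2 cytosolic
  ids <- c("at_I", "at_II", "at_IIIp", "at_IIIc1", "at_IIIc2")
  src <- c("arch_I", "arch_II", "arch_IIIp", "arch_IIIc", "arch_IIIc")
  sig <- stats::setNames(fs$signals[src], ids)
  recs <- data.frame(id = ids, sequence = "M", species = "Arabidopsis-like",
                     lineage = "Brassicaceae", stringsAsFactors = FALSE)
  counts <- summarize_counts(classify_family(recs, sig))
  expect_equal(counts$total, 5)
  expect_equal(counts$class_I, 1)
  expect_equal(counts$class_II, 1)
  expect_equal(counts$class_III, 3)
  expect_equal(counts$class_III_cytosol_specific, 2)

  # tomato-like: three genes, no cytosol-specific isoform
  ids2 <- c("sl_I", "sl_II", "sl_IIIp")
  sig2 <- stats::setNames(fs$signals[c("arch_I", "arch_II", "arch_IIIp")], ids2)
  recs2 <- data.frame(id = ids2, sequence = "M", species = "tomato-like",
                      lineage = "Solanaceae", stringsAsFactors = FALSE)
  counts2 <- summarize_counts(classify_family(recs2, sig2))
  expect_equal(counts2$total, 3)
  expect_equal(counts2$class_III_cytosol_specific, 0)

  cls <- classify_family(recs2, sig2)
  expect_error(summarize_counts(cls[0, ]), "summarize")
  cls$species[1] <- NA
  expect_error(summarize_counts(cls), "missing species")
})
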