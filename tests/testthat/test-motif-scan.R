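test_that("PTS1 scan distinguishes canonical, listed, pattern, none tiers", {
  expect_equal(scan_pts1("MAAASKL")$tier, "canonical")
  listed <- c("AKI", "AKV", "ASL", "SNL", "SKV", "SKI", "SKF", "SRI",
              "CKM", "CKI")
  for (tri in listed) {
    res <- scan_pts1(paste0("MEQNK", tri))
    expect_equal(res$tier, "listed")
    expect_true(res$present)
    expect_equal(res$tripeptide, tri)
  }
  none <- scan_pts1("MAAAAAA")
  expect_equal(none$tier, "none")
  expect_false(none$present)
  expect_equal(none$tripeptide, "")

  # pattern tier only when enabled; it admits the algal-style SRM, while
  # tripeptides outside [ASC][KRNS][LIVMF] stay out
  expect_equal(scan_pts1("MMMANL")$tier, "none")
  expect_equal(scan_pts1("MMMANL", enable_pattern = TRUE)$tier, "pattern")
  expect_equal(scan_pts1("MMMSRM", enable_pattern = TRUE)$tier, "pattern")
  expect_equal(scan_pts1("MMMKKL", enable_pattern = TRUE)$tier, "none")

  expect_error(scan_pts1("MK"), "shorter")
})

test_that("PTS1 result depends only on the final three residues", {
  set.seed(5)
  tails <- c("AKI", "SKL", "QQQ", "SKV", "GGG")
  for (tail in tails) {
    base <- scan_pts1(paste0("MMM", tail))
    for (i in 1:10) {
      prefix <- paste(sample(strsplit(paste(AA20_test(), collapse = ""),
                                      "")[[1]], sample(3:80, 1),
                             replace = TRUE), collapse = "")
      with_prefix <- scan_pts1(paste0(prefix, "MMM", tail))
      expect_equal(with_prefix[c("present", "tier", "tripeptide")],
                   base[c("present", "tier", "tripeptide")])
    }
  }
})

test_that("hydropathy profile matches the published scale", {
  # single full window of Ile / Arg gives the raw index back
  expect_equal(hydropathy_profile(strrep("I", 19), 19)[10], 4.5)
  expect_equal(hydropathy_profile(strrep("R", 19), 19)[10], -4.5)
  prof <- hydropathy_profile(strrep("A", 25), 19)
  expect_true(all(is.na(prof[1:9])))
  expect_true(all(is.na(prof[17:25])))
  expect_equal(unname(prof[10:16]), rep(1.8, 7))
  expect_error(hydropathy_profile("MKT", 19), "exceeds")
  expect_error(hydropathy_profile(strrep("A", 30), 18), "odd")
})

test_that("TM detection finds planted spans and nothing else", {
  set.seed(9)
  flank <- function(n) paste(sample(HYDROPHILIC, n, replace = TRUE),
                             collapse = "")
  planted <- paste0(flank(120), strrep("L", 21), flank(120))
  spans <- detect_tm(planted)
  expect_equal(nrow(spans), 1)
  # span covers the planted 21-mer (121..141) plus at most half a window
  expect_lte(spans$start, 121)
  expect_gte(spans$end, 141)
  expect_lte(121 - spans$start, 9)
  expect_lte(spans$end - 141, 9)

  expect_equal(nrow(detect_tm(strrep("S", 200))), 0)

  two <- paste0(flank(80), strrep("V", 21), flank(50), strrep("F", 21),
                flank(80))
  expect_equal(nrow(detect_tm(two)), 2)
})

test_that("TM detection agrees with the brute-force window oracle", {
  set.seed(42)
  pools <- list(AA20_test(), c("I", "L", "V", "F", "S", "T", "G", "K"),
                c("A", "M", "C", "F", "D", "E"))
  for (case in 1:200) {
    pool <- pools[[(case %% 3) + 1]]
    seqn <- paste(sample(pool, 100, replace = TRUE), collapse = "")
    got <- detect_tm(seqn)
    want <- brute_tm(seqn)
    expect_equal(got$start, want$start, info = seqn)
    expect_equal(got$end, want$end, info = seqn)
  }
})

test_that("mPTS scan recognizes the basic-cluster archetypes", {
  set.seed(13)
  core <- random_core()
  with_cluster <- archetype_sequence(core, "II")
  spans <- detect_tm(with_cluster)
  res <- scan_mpts(with_cluster, spans)
  expect_true(res$has_cterm_tm)
  expect_true(res$basic_cluster)
  expect_equal(res$cluster_seq, "RRRRRW")

  no_cluster <- archetype_sequence(core, "II_no_cluster")
  res2 <- scan_mpts(no_cluster, detect_tm(no_cluster))
  expect_true(res2$has_cterm_tm)
  expect_false(res2$basic_cluster)
  expect_equal(res2$cluster_seq, "")

  res3 <- scan_mpts(core, detect_tm(core))
  expect_false(res3$has_cterm_tm)
  expect_false(res3$basic_cluster)

  # an internal TM far from the C-terminus is not an mPTS
  internal <- paste0(substr(core, 1, 200), strrep("I", 21), core)
  res4 <- scan_mpts(internal, detect_tm(internal))
  expect_false(res4$has_cterm_tm)
})

test_that("N-terminal extension is measured against the reference start", {
  set.seed(17)
  core <- random_core(200, cat_r = 100, cat_y = 120)
  ext60 <- paste(sample(c("S", "R", "A"), 60, replace = TRUE), collapse = "")
  aln <- structure(list(
    ids = c("REF", "same", "ext60", "ext10"),
    seqs = c(REF = paste0(strrep("-", 60), core),
             same = paste0(strrep("-", 60), core),
             ext60 = paste0(ext60, core),
             ext10 = paste0(strrep("-", 50), substr(ext60, 1, 10), core)),
    alignment_length = 260L), class = "mdar_alignment")

  none <- detect_nterm_extension(aln, "REF", "same")
  expect_equal(none$length, 0)
  expect_false(none$organellar)

  full <- detect_nterm_extension(aln, "REF", "ext60")
  expect_equal(full$length, 60)
  expect_equal(full$extension_seq, ext60)
  expect_true(full$organellar)

  short <- detect_nterm_extension(aln, "REF", "ext10")
  expect_equal(short$length, 10)
  expect_false(short$organellar)  # below the 30-residue threshold

  expect_error(detect_nterm_extension(aln, "REF", "nope"), "nope")
})

test_that("organellar heuristic scores transit-peptide composition", {
  pos <- predict_organellar("SSSSSRRRRR")
  expect_equal(pos$score, 1.0)
  expect_true(pos$organellar)

  neg <- predict_organellar("DDDDDEEEEE")
  expect_equal(neg$score, -1.0)
  expect_false(neg$organellar)

  zero <- predict_organellar("AAAAAAAAAA")
  expect_equal(zero$score, 0.0)
  expect_false(zero$organellar)  # threshold is strict

  expect_error(predict_organellar(""), "empty")
})

test_that("catalytic check reports substitutions and deletions per column", {
  core <- random_core(400, cat_r = 320, cat_y = 349)
  chars <- strsplit(core, "")[[1]]
  sub_chars <- chars; sub_chars[320] <- "A"
  del_chars <- chars; del_chars[349] <- "-"
  aln <- structure(list(
    ids = c("REF", "good", "sub", "del"),
    seqs = c(REF = core, good = core,
             sub = paste(sub_chars, collapse = ""),
             del = paste(del_chars, collapse = "")),
    alignment_length = 400L), class = "mdar_alignment")

  ok <- check_catalytic(aln, "REF", "good")
  expect_true(ok$ok)
  expect_equal(ok$residues_found, c(R320 = "R", Y349 = "Y"))

  sub <- check_catalytic(aln, "REF", "sub")
  expect_false(sub$ok)
  expect_equal(unname(sub$residues_found["R320"]), "A")

  del <- check_catalytic(aln, "REF", "del")
  expect_false(del$ok)
  expect_equal(unname(del$residues_found["Y349"]), "-")

  short_ref <- structure(list(
    ids = c("REF", "q"),
    seqs = c(REF = substr(core, 1, 100), q = substr(core, 1, 100)),
    alignment_length = 100L), class = "mdar_alignment")
  expect_error(check_catalytic(short_ref, "REF", "q"), "out of range")
})

test_that("catalytic check is stable through an alignment write/read trip", {
  fam <- generate_family(family_spec(n_species = 2, seed = 7))
  before <- lapply(fam$records$id, function(id) {
    check_catalytic(fam$aligned, "REF_CYTO", id)
  })
  tf <- tempfile(fileext = ".aln.fasta")
  write_aligned_fasta(fam$aligned, tf)
  back <- read_aligned_fasta(tf)
  after <- lapply(fam$records$id, function(id) {
    check_catalytic(back, "REF_CYTO", id)
  })
  expect_equal(after, before)
})

test_that("atypicality flags follow length range and dual-core motif", {
  set.seed(31)
  core <- random_core()
  none <- detect_atypical(core)
  expect_false(none$length_atypical)
  expect_false(none$dual_catalytic_core)
  expect_equal(none$length, 435)

  long560 <- paste0(core, random_core(125, 60, 80))
  res560 <- detect_atypical(long560)
  expect_true(res560$length_atypical)
  expect_false(res560$dual_catalytic_core)

  motif <- substr(core, 317, 323)
  tandem <- paste0(core, substr(core, 1, 100), core)  # two cores ~535 apart
  dual <- detect_atypical(tandem, catalytic_context_motif = motif)
  expect_true(dual$length_atypical)   # 970 residues
  expect_true(dual$dual_catalytic_core)

  # two motif copies too close together are a single core region
  close_pair <- paste0(motif, strrep("G", 50), motif, strrep("G", 380))
  near <- detect_atypical(close_pair, catalytic_context_motif = motif)
  expect_false(near$dual_catalytic_core)
})
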