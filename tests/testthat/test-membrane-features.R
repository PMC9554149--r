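# Extracellular feature engine: segment filtering, charge counts,
# physicochemical sums, and the direction-stratified summary.

tab <- aa_property_table()

make_record <- function(seq, segs, id = "P1", gene = "G1") {
  protein_record(id, gene, seq, segs)
}

test_that("segment extraction applies the 10-residue rule at the boundary", {
  seq <- paste(rep("A", 40), collapse = "")
  rec9 <- make_record(seq, data.frame(segment_type = "extracellular",
                                      start = 1, end = 9))
  rec10 <- make_record(seq, data.frame(segment_type = "extracellular",
                                       start = 1, end = 10))
  rec_none <- make_record(seq, data.frame(segment_type = "intracellular",
                                          start = 1, end = 40))
  expect_identical(extract_extracellular_segments(rec9), character(0))
  expect_length(extract_extracellular_segments(rec10), 1L)
  expect_identical(nchar(extract_extracellular_segments(rec10)), 10L)
  expect_identical(extract_extracellular_segments(rec_none), character(0))
})

test_that("invalid topology records are rejected with the protein named", {
  expect_error(make_record("AAAA", data.frame(segment_type = "extracellular",
                                              start = 2, end = 9), id = "PX"),
               "PX")
  expect_error(make_record("AAAAAAAA",
                           data.frame(segment_type = "extracellular",
                                      start = c(1, 3), end = c(5, 8))),
               "overlapping")
})

test_that("charge counts and physchem sums match hand-computed values", {
  cc <- charge_counts("RHKDEGGGGG", tab)
  expect_equal(unname(cc), c(3, 2, 1))
  expect_equal(unname(charge_counts("GGGGGGGGGG", tab)), c(0, 0, 0))
  ps <- physchem_sums(paste(rep("G", 10), collapse = ""), tab)
  expect_equal(ps[["EW"]], 10 * 75.07)
  ps_i <- physchem_sums(paste(rep("I", 10), collapse = ""), tab)
  expect_equal(ps_i[["EH"]], 45.0)
  empty <- physchem_sums(character(0), tab)
  expect_equal(unname(empty), c(0, 0))
})

test_that("features match the brute-force character tally on random segments", {
  set.seed(42)
  for (i in 1:20) {
    seg <- paste(sample(tab$alphabet, 200, replace = TRUE), collapse = "")
    cc <- charge_counts(seg, tab)
    ps <- physchem_sums(seg, tab)
    orc <- oracle_features(seg, tab)
    expect_equal(unname(c(cc, ps)), unname(orc[c("EP", "EN", "EC", "EW", "EH")]))
  }
})

test_that("feature vectors obey invariants and composition properties", {
  set.seed(7)
  recs <- lapply(1:50, random_record)
  v <- compute_feature_vectors(recs, tab)
  expect_identical(nrow(v), 50L)
  expect_true(all(v$EC == v$EP - v$EN))
  expect_true(all((v$EW == 0) == (v$n_segments_used == 0)))

  # permutation invariance: features depend on composition only
  r <- recs[[1]]
  segs <- extract_extracellular_segments(r)
  if (length(segs) > 0) {
    shuffled <- vapply(segs, function(s) {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }, character(1))
    expect_equal(charge_counts(shuffled, tab), charge_counts(segs, tab))
    expect_equal(physchem_sums(shuffled, tab), physchem_sums(segs, tab))
  }

  # splitting a 20-residue segment into two 10s changes nothing
  seq20 <- paste(sample(tab$alphabet, 20, replace = TRUE), collapse = "")
  whole <- make_record(seq20, data.frame(segment_type = "extracellular",
                                         start = 1, end = 20))
  split2 <- make_record(seq20, data.frame(segment_type = "extracellular",
                                          start = c(1, 11), end = c(10, 20)))
  vw <- compute_feature_vectors(list(whole), tab)
  vs <- compute_feature_vectors(list(split2), tab)
  expect_equal(vw[, c("EP", "EN", "EC", "EW", "EH")],
               vs[, c("EP", "EN", "EC", "EW", "EH")])

  # appending a qualifying segment with k arginines raises EP by exactly k
  base <- make_record(paste(rep("G", 30), collapse = ""),
                      data.frame(segment_type = "extracellular",
                                 start = 1, end = 12))
  grown <- make_record(paste(c(rep("G", 12), rep("A", 5), rep("R", 3),
                               rep("G", 7), rep("A", 10)), collapse = ""),
                       data.frame(segment_type = c("extracellular",
                                                   "extracellular"),
                                  start = c(1, 13), end = c(12, 22)))
  vb <- compute_feature_vectors(list(base), tab)
  vg <- compute_feature_vectors(list(grown), tab)
  expect_equal(vg$EP - vb$EP, 3)
})

test_that("duplicate protein ids and ambiguity codes are handled", {
  r <- make_record("AAAAAAAAAAAA", data.frame(segment_type = "extracellular",
                                              start = 1, end = 12))
  expect_error(compute_feature_vectors(list(r, r), tab), "duplicate")
  rx <- make_record("AAAAAXAAAAAA", data.frame(segment_type = "extracellular",
                                               start = 1, end = 12))
  # the charge tally and the weight/hydropathy tally each warn once
  expect_warning(expect_warning(
    v <- compute_feature_vectors(list(rx), tab), "ambiguity"), "ambiguity")
  expect_equal(v$EW, 11 * tab$W[["A"]])
})

test_that("summary table uses strict charge/hydropathy buckets and medians", {
  v <- data.frame(protein_id = paste0("P", 1:6),
                  gene_id = paste0("G", 1:6),
                  EP = c(2, 1, 1, 5, 0, 2), EN = c(1, 3, 1, 1, 0, 2),
                  EC = c(1, -2, 0, 4, 0, 0),
                  EW = c(100, 200, 300, 150, 250, 350),
                  EH = c(2, -1, 0, -3, -5, 1),
                  n_segments_used = 1)
  dir <- setNames(c(rep("up", 3), rep("down", 3)), v$protein_id)
  s <- summarize_feature_table(v, dir)
  up <- s[s$direction == "up", ]
  expect_identical(c(up$EC_positive, up$EC_negative), c(1L, 1L))
  expect_identical(c(up$EH_positive, up$EH_negative), c(1L, 1L))
  expect_equal(up$median_EW, 200)
  down <- s[s$direction == "down", ]
  expect_identical(c(down$EC_positive, down$EC_negative), c(1L, 0L))
  expect_equal(down$median_EW, 250)
  expect_error(summarize_feature_table(v[0, ], dir), "empty")
  expect_error(summarize_feature_table(v, dir[-1]), "missing direction")
})
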