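test_that("coordinate strings parse, compute lengths, and round-trip", {
  sp <- parse_isomir_coordinate("hg38:chr22:46112751-46112773:+")
  expect_equal(sp$assembly, "hg38")
  expect_equal(sp$chrom, "chr22")
  expect_equal(sp$start, 46112751L)
  expect_equal(sp$end, 46112773L)
  expect_equal(sp$strand, "+")
  expect_equal(span_length(sp), 23L)
  expect_equal(span_length(parse_isomir_coordinate("hg38:chr1:100-100:-")), 1L)

  # round-trip identity over randomly generated valid spans
  withr::with_seed(7, {
    for (i in 1:50) {
      s <- sample.int(1e8, 1)
      txt <- sprintf("%s:chr%d:%d-%d:%s", sample(c("hg38", "mm10"), 1),
                     sample(1:22, 1), s, s + sample(0:30, 1),
                     sample(c("+", "-"), 1))
      expect_identical(format_isomir_coordinate(parse_isomir_coordinate(txt)),
                       txt)
    }
  })
})

test_that("malformed coordinates fail with an error naming the problem", {
  expect_error(parse_isomir_coordinate("hg38:chr1:200-100:+"), "start")
  expect_error(parse_isomir_coordinate("hg38:chr1:100-200:?"), "strand")
  expect_error(parse_isomir_coordinate("chr1:100-200:+"), "malformed")
  expect_error(genomic_span("hg38", "chr1", 200, 100, "+"), "start")
})

test_that("classify_shift reports transcript-orientation offsets on both strands", {
  ann <- genomic_span("hg38", "chr22", 52, 73, "+")
  expect_equal(classify_shift(genomic_span("hg38", "chr22", 53, 74, "+"), ann),
               list(offset5 = 1L, offset3 = 1L))
  expect_equal(classify_shift(genomic_span("hg38", "chr22", 52, 71, "+"), ann),
               list(offset5 = 0L, offset3 = -2L))
  expect_equal(classify_shift(ann, ann), list(offset5 = 0L, offset3 = 0L))

  # minus strand: the genomic end is the transcript 5' end
  ann_m <- genomic_span("hg38", "chr22", 52, 73, "-")
  expect_equal(classify_shift(genomic_span("hg38", "chr22", 52, 72, "-"), ann_m),
               list(offset5 = 1L, offset3 = 0L))
  expect_equal(classify_shift(genomic_span("hg38", "chr22", 50, 73, "-"), ann_m),
               list(offset5 = 0L, offset3 = 2L))

  expect_error(classify_shift(genomic_span("hg38", "chr1", 52, 73, "+"), ann),
               "chromosome")
  expect_error(classify_shift(genomic_span("hg38", "chr22", 52, 73, "-"), ann),
               "strand")
})

test_that("classify_shift is antisymmetric and zero on identical spans", {
  withr::with_seed(11, {
    for (i in 1:25) {
      strand <- sample(c("+", "-"), 1)
      s1 <- sample.int(1e6, 1)
      a <- genomic_span("hg38", "chr5", s1, s1 + 21, strand)
      b <- genomic_span("hg38", "chr5", s1 + sample(-3:3, 1),
                        s1 + 21 + sample(-3:3, 1), strand)
      ab <- classify_shift(a, b)
      ba <- classify_shift(b, a)
      expect_equal(ab$offset5, -ba$offset5)
      expect_equal(ab$offset3, -ba$offset3)
      expect_equal(classify_shift(a, a), list(offset5 = 0L, offset3 = 0L))
    }
  })
})

test_that("extract_seed takes positions 2-8 and rejects short input", {
  expect_equal(extract_seed("UGAGGUAGUAGGUUGUAUAGUU"), "GAGGUAG")
  expect_equal(extract_seed("TGAGGTAGTAGGTTGTATAGTT"), "GAGGUAG") # DNA input
  withr::with_seed(3, {
    for (s in random_rna_strings(20, 22))
      expect_identical(extract_seed(s), substr(s, 2, 8))
  })
  expect_error(extract_seed("GAGGUAG"), "seed")
})

test_that("enumerate_seed_variants groups by (seed, shift), labels with signed shifts, and excludes |shift| > 5", {
  ann <- genomic_span("hg38", "chr22", 46112751, 46112772, "+")
  ref <- "CCGAUUGAGGUAGUAGGUUGUAUAGUUAGGCCAAUU"
  mk <- function(off5, off3, id) {
    start <- 46112751 + off5; end <- 46112772 + off3
    data.frame(isomir_id = id, locus_id = "let-7", arm = "5p",
               coordinate = sprintf("hg38:chr22:%d-%d:+", start, end),
               sequence = substr(ref, 5 + off5, 26 + off3),
               stringsAsFactors = FALSE)
  }
  recs <- rbind(mk(0, 0, "a"), mk(1, 1, "b"), mk(-2, 0, "c"),
                mk(0, 2, "d"), mk(6, 6, "e"))
  ev <- enumerate_seed_variants(recs, ann)
  expect_equal(sort(ev$variants$label),
               sort(c("let-7-5p+0", "let-7-5p+1", "let-7-5p-2")))
  expect_equal(ev$variants$is_annotated, ev$variants$shift == 0L)
  # 3'-only record "d" shares the annotated variant
  v0 <- ev$variants[ev$variants$shift == 0L, ]
  expect_equal(v0$n_isomirs, 2L)
  expect_setequal(strsplit(v0$isomir_ids, ",")[[1]], c("a", "d"))
  expect_equal(ev$excluded$isomir_id, "e")
  expect_equal(ev$excluded$offset5, 6L)
  # conservation: variants + excluded-distinct = distinct (seed, offset5)
  expect_equal(nrow(ev$variants) + nrow(unique(ev$excluded)), 4L)
  # empty input
  ev0 <- enumerate_seed_variants(recs[0, ], ann)
  expect_equal(nrow(ev0$variants), 0L)
})

test_that("dedup_multicopy collapses to one representative or drops all", {
  recs <- data.frame(
    isomir_id = c("i1", "i2", "i3", "i4"),
    locus_id = c("let-7a-2", "let-7a-1", "let-7a-3", "mir-10"),
    sequence = c("AAAA", "AAAA", "AAAA", "CCCC"),
    stringsAsFactors = FALSE)
  d <- dedup_multicopy(recs)
  expect_equal(sort(d$kept$isomir_id), c("i2", "i4"))
  expect_equal(d$kept$locus_id[d$kept$sequence == "AAAA"], "let-7a-1")
  expect_equal(nrow(d$dropped), 2L)
  expect_true(all(d$dropped$duplicate_of == "i2"))

  d2 <- dedup_multicopy(recs, mode = "drop_all")
  expect_equal(d2$kept$isomir_id, "i4")
  expect_equal(nrow(d2$dropped), 3L)

  # all distinct: identity
  d3 <- dedup_multicopy(recs[c(1, 4), ])
  expect_equal(nrow(d3$dropped), 0L)
  expect_equal(d3$kept$isomir_id, c("i1", "i4"))
})

test_that("position frequency matrix columns sum to 1 over observed residues", {
  m <- position_frequency_matrix(c("AAAA", "AAAA"))
  expect_equal(unname(m["A", ]), rep(1, 4))
  m2 <- position_frequency_matrix(c("AU", "AA"))
  expect_equal(unname(m2["A", 2]), 0.5)
  expect_equal(unname(m2["U", 2]), 0.5)
  # ragged input: short sequences drop out of trailing denominators
  m3 <- position_frequency_matrix(c("AU", "A"))
  expect_equal(unname(m3["U", 2]), 1)
  expect_equal(attr(m3, "n_observed"), c(2L, 1L))
  # property: column sums are 1 +/- 1e-9 on random sequences, checked
  # against a direct tally
  withr::with_seed(5, {
    seqs <- random_rna_strings(100, 22)
    m4 <- position_frequency_matrix(seqs)
    expect_true(all(abs(colSums(m4) - 1) < 1e-9))
    tally <- table(substr(seqs, 7, 7))
    expect_equal(unname(m4["G", 7]), unname(tally["G"]) / 100)
  })
  expect_error(position_frequency_matrix(character(0)), "zero")
})
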