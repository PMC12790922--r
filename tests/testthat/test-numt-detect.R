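make_records <- function(chrom, pos, mate_chrom, mate_pos, mapq = 60L,
                         sample_id = "s1", is_split = FALSE,
                         segments = NA_character_) {
  n <- max(length(chrom), length(pos), length(mate_chrom), length(mate_pos))
  tibble::tibble(
    read_id = sprintf("r%03d", seq_len(n)), sample_id = sample_id,
    chrom = rep_len(chrom, n), pos = as.integer(rep_len(pos, n)),
    strand = "+", mate_chrom = rep_len(mate_chrom, n),
    mate_pos = as.integer(rep_len(mate_pos, n)), mate_strand = "+",
    is_split = rep_len(is_split, n), segments = rep_len(segments, n),
    mapq = rep_len(as.integer(mapq), n))
}

test_that("discordant selection keeps exactly one-mito-one-nuclear pairs above MAPQ", {
  rec <- make_records(
    chrom = c("chr1", "chr1", "chrM", "chr1"),
    pos = c(100L, 200L, 300L, 400L),
    mate_chrom = c("chrM", "chr2", "chrM", "chrM"),
    mate_pos = c(5000L, 600L, 700L, 800L),
    mapq = c(60L, 60L, 60L, 10L))
  d <- select_discordant(rec, min_mapq = 20)
  expect_equal(nrow(d), 1L) # chr1<->chr2 and chrM<->chrM dropped; low MAPQ dropped
  expect_equal(d$nuclear_chrom, "chr1")
  expect_equal(d$nuclear_pos, 100L)
  expect_equal(d$mito_pos, 5000L)
  # mito-anchored record is normalised the same way
  rec2 <- make_records("chrM", 9000L, "chr5", 1234L)
  d2 <- select_discordant(rec2)
  expect_equal(d2$nuclear_chrom, "chr5")
  expect_equal(d2$nuclear_pos, 1234L)
  expect_equal(d2$mito_pos, 9000L)
})

test_that("clustering chains within 500 bp and discards clusters under five pairs", {
  mk_pairs <- function(pos) tibble::tibble(
    sample_id = "s1", read_id = sprintf("p%03d", seq_along(pos)),
    nuclear_chrom = "chr1", nuclear_pos = as.integer(pos),
    nuclear_strand = "+", mito_pos = 1000L, mito_strand = "+",
    mapq_min = 60L)
  # five pairs spanning 100..500 chain into one retained cluster
  c1 <- cluster_discordant(mk_pairs(c(100, 200, 300, 400, 500)))
  expect_equal(nrow(c1), 1L)
  expect_equal(c1$n_pairs, 5L)
  expect_equal(c1$span_start, 100L)
  expect_equal(c1$span_end, 500L)
  # four tightly packed pairs are below threshold
  expect_equal(nrow(cluster_discordant(mk_pairs(c(100, 102, 104, 110)))), 0L)
  # gaps of 501 do not chain: three singletons, all discarded
  expect_equal(nrow(cluster_discordant(mk_pairs(c(100, 601, 1102)))), 0L)
  # but with min_pairs = 1 they surface as three clusters
  c3 <- cluster_discordant(mk_pairs(c(100, 601, 1102)), min_pairs = 1)
  expect_equal(nrow(c3), 3L)
  # gap of exactly 500 chains
  c4 <- cluster_discordant(mk_pairs(c(100, 600, 1100)), min_pairs = 1)
  expect_equal(nrow(c4), 1L)
})

test_that("clustering is order-independent and matches the union-find oracle", {
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(5:80, 1)
    pos <- sample.int(20000, n, replace = TRUE)
    pairs <- tibble::tibble(
      sample_id = "s1", read_id = sprintf("p%04d", seq_len(n)),
      nuclear_chrom = "chr1", nuclear_pos = as.integer(pos),
      nuclear_strand = "+", mito_pos = 1L, mito_strand = "+", mapq_min = 60L)
    got <- cluster_discordant(pairs, max_gap = 500, min_pairs = 1)
    got_sig <- sort(vapply(got$member_ids, function(ids) {
      paste(sort(pairs$nuclear_pos[match(ids, pairs$read_id)]),
            collapse = ",")
    }, character(1)))
    comp <- oracle_single_linkage(pos, 500)
    expect_identical(got_sig, cluster_signature(pos, comp))
    # permuting the input leaves the clustering unchanged
    got_perm <- cluster_discordant(pairs[sample.int(n), ], max_gap = 500,
                                   min_pairs = 1)
    expect_identical(got_sig, sort(vapply(got_perm$member_ids, function(ids) {
      paste(sort(pairs$nuclear_pos[match(ids, pairs$read_id)]),
            collapse = ",")
    }, character(1))))
  }
})

test_that("event grouping joins midpoints within 1000 bp and counts samples once", {
  mk_cluster <- function(sample, mid) tibble::tibble(
    sample_id = sample, nuclear_chrom = "chr1",
    span_start = as.integer(mid - 50), span_end = as.integer(mid + 50),
    midpoint = mid, n_pairs = 6L, member_ids = list(character(0)),
    mito_pos_min = 1L, mito_pos_max = 100L)
  ev <- group_events(dplyr::bind_rows(mk_cluster("a", 5000),
                                      mk_cluster("b", 6000)))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_samples, 2L)
  ev2 <- group_events(dplyr::bind_rows(mk_cluster("a", 5000),
                                       mk_cluster("b", 6001)))
  expect_equal(nrow(ev2), 2L)
  # one sample contributing two clusters still counts once
  ev3 <- group_events(dplyr::bind_rows(mk_cluster("a", 5000),
                                       mk_cluster("a", 5600)))
  expect_equal(ev3$n_samples, 1L)
  # no two retained events on one chromosome sit within 1000 bp
  set.seed(4)
  cl <- dplyr::bind_rows(lapply(1:40, function(i)
    mk_cluster(sample(letters, 1), sample.int(1e5, 1))))
  evs <- group_events(cl)
  if (nrow(evs) > 1L) {
    expect_true(all(diff(sort(evs$anchor)) > 1000))
  }
})

test_that("split-read refinement requires exact agreement of at least two reads", {
  event <- group_events(tibble::tibble(
    sample_id = "s1", nuclear_chrom = "chr1", span_start = 9500L,
    span_end = 10500L, midpoint = 10000, n_pairs = 6L,
    member_ids = list(character(0)), mito_pos_min = 3000L,
    mito_pos_max = 3400L))

  mk_split <- function(n_left, n_right, nuc_bp = 10000L, mito_bp = 3000L,
                       jitter = 0L) {
    rows <- list()
    for (i in seq_len(n_left)) {
      bp <- nuc_bp + if (i == 1) 0L else jitter
      rows[[length(rows) + 1L]] <- make_records(
        "chr1", bp - 49L, "chr1", 9000L, is_split = TRUE,
        segments = sprintf("chr1:%d-%d;chrM:%d-%d", bp - 49L, bp,
                           mito_bp, mito_bp + 49L))
    }
    for (i in seq_len(n_right)) {
      rows[[length(rows) + 1L]] <- make_records(
        "chrM", 3351L, "chr1", 11000L, is_split = TRUE,
        segments = sprintf("chrM:%d-%d;chr1:%d-%d", 3351L, 3400L,
                           nuc_bp + 1L, nuc_bp + 50L))
    }
    d <- dplyr::bind_rows(rows)
    d$read_id <- sprintf("sr%03d", seq_len(nrow(d)))
    d
  }

  # three left + two right reads agreeing exactly: refined with exact breakpoints
  r1 <- refine_breakpoints(event, mk_split(3, 2))
  expect_true(r1$refined)
  expect_equal(r1$nuclear_bp_left, 10000L)
  expect_equal(r1$nuclear_bp_right, 10001L)
  expect_equal(r1$mito_bp_a, 3000L)
  expect_equal(r1$mito_bp_b, 3400L)
  expect_equal(r1$size_bp, 400L) # forward arc 3000 -> 3400

  # a single split read cannot confirm; the event survives unrefined
  r2 <- refine_breakpoints(event, mk_split(1, 1))
  expect_false(r2$refined)
  expect_true(is.na(r2$mito_bp_a))

  # two left reads disagreeing by 1 bp never confirm the left junction
  r3 <- refine_breakpoints(event, mk_split(2, 2, jitter = 1L))
  expect_false(r3$refined)

  # a failing aligner skips the read with a warning instead of aborting
  expect_warning(
    refine_breakpoints(event, mk_split(3, 2),
                       aligner = function(rec) stop("boom")),
    "skipped")
})

test_that("insertion size follows circular-arc arithmetic", {
  expect_equal(numt_size(1000, 1119), 119L)
  expect_equal(numt_size(16500, 100, "a_to_b"), 169L) # wraps the origin
  expect_equal(numt_size(42, 42), 16568L)             # full circle
  expect_equal(numt_size(100, 16500, "shorter"), 169L)
  expect_equal(numt_size(100, 16500, "a_to_b"), 16400L)
  expect_error(numt_size(0, 10), "1..16,569")
  # forward and reverse arcs always sum to the genome length
  set.seed(2)
  a <- sample.int(16569, 50)
  b <- sample.int(16569, 50)
  distinct <- a != b
  expect_true(all(numt_size(a, b, "a_to_b")[distinct] +
                    numt_size(b, a, "a_to_b")[distinct] == 16569L))
})

test_that("known-NUMT flagging pads intervals by 500 bp on both sides", {
  events <- tibble::tibble(
    event_id = c("e1", "e2", "e3"), nuclear_chrom = "chr1",
    span_start = c(9990L, 11500L, 50000L), span_end = c(10010L, 11520L, 50020L),
    nuclear_bp_left = c(10000L, NA, NA), nuclear_bp_right = c(10001L, NA, NA))
  known <- tibble::tibble(chrom = "chr1", start = 10300, end = 10400,
                          name = NA_character_, feature_class = NA_character_)
  r <- flag_known(events, known) # padded to [9800, 10900] 1-based 9801..10900
  expect_true(r$known[1])   # breakpoint 10000 inside the pad
  expect_false(r$known[2])  # span starts 600 beyond the padded end
  expect_false(r$known[3])
  expect_false(any(flag_known(events, known[0, ])$known))
})

test_that("per-sample statistics include zero-count samples and use sample SD", {
  events <- tibble::tibble(samples = list(c("a", "b"), "a", c("a", "b"), "a"))
  st <- per_sample_numt_stats(events, c("a", "b", "c"))
  expect_equal(st$per_sample$n_numts, c(4L, 2L, 0L))
  expect_equal(st$summary$mean, 2)
  expect_equal(st$summary$sd, sd(c(4, 2, 0)))
})

test_that("planted insertions are recovered exactly and sub-threshold decoys are never called", {
  sim <- gen_numt_reads(8, n_decoys = 6, seed = 21)
  pairs <- select_discordant(sim$records)
  ev <- cluster_discordant(pairs) |>
    group_events() |>
    refine_breakpoints(sim$records)
  truth <- sim$truth[!sim$truth$is_decoy, ]
  expect_equal(nrow(ev), nrow(truth))
  expect_true(all(ev$refined))
  m <- match(ev$nuclear_bp_left, truth$nuclear_bp_left)
  expect_false(anyNA(m))
  expect_equal(ev$mito_bp_a, truth$mito_bp_a[m])
  expect_equal(ev$mito_bp_b, truth$mito_bp_b[m])
  expect_equal(ev$size_bp, truth$arc_len[m])
  expect_equal(ev$n_samples, truth$n_carriers[m])
})
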